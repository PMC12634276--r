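#' Generate a synthetic word-rating pool
#'
#' Builds a rating-task pool emulating a pre-scan word-rating session:
#' 50 disorder-related, 50 generally anxiety-provoking and 50 neutral word
#' tokens, each with an anxiety rating on the 1--9 Likert scale and a
#' syllable count. Ratings for the two anxiety categories concentrate at the
#' high end of the scale and neutral ratings at the low end, so that the
#' top/bottom-20 selection rules have realistic tie structure.
#'
#' @param seed Integer seed for the pool draw.
#' @param n_per_category Words per category (default 50).
#' @return A tibble with columns `word`, `category` (one of `"disorder"`,
#'   `"general"`, `"neutral"`), `rating` (1--9) and `syllables`.
#' @export
make_word_pool <- function(seed = 1L, n_per_category = 50L) {
  stopifnot(n_per_category >= 1L)
  withr::with_seed(seed, {
    cats <- c("disorder", "general", "neutral")
    pool <- purrr::map_dfr(cats, function(cat) {
      mu <- switch(cat, disorder = 7, general = 6.5, neutral = 2)
      rating <- round(pmin(9, pmax(1, stats::rnorm(n_per_category, mu, 1.2))), 1)
      tibble::tibble(
        word = sprintf("%s_%02d", cat, seq_len(n_per_category)),
        category = cat,
        rating = rating,
        syllables = 1L + stats::rbinom(n_per_category, 4L, 0.35)
      )
    })
    pool
  })
}

#' Select the per-participant stimulus set
#'
#' Applies the study's stimulus-selection rule to a rated word pool: the 20
#' highest-rated words of the group-relevant anxiety category (disorder words
#' for the AN group, general anxiety words for controls) form the anxiety
#' set, and the 20 lowest-rated neutral words form the neutral set. When
#' several neutral words tie at the rating cut-off, the tied subset whose
#' mean syllable count best matches the anxiety set is chosen, making the
#' selection deterministic given the pool.
#'
#' @param pool A word-rating tibble as from [make_word_pool()].
#' @param group `"AN"` or `"CON"`; decides which anxiety category is used.
#' @param n_words Words per set (default 20).
#' @return A list of class `stimulus_set` with tibbles `anxiety_words` and
#'   `neutral_words`.
#' @export
select_stimuli <- function(pool, group = c("AN", "CON"), n_words = 20L) {
  group <- match.arg(group)
  stopifnot(is.data.frame(pool), all(c("word", "category", "rating", "syllables") %in% names(pool)))
  anx_cat <- if (group == "AN") "disorder" else "general"

  anx_pool <- dplyr::filter(pool, .data$category == anx_cat)
  neu_pool <- dplyr::filter(pool, .data$category == "neutral")
  if (nrow(anx_pool) < n_words) {
    stop(sprintf("fewer than %d candidate words in category '%s'", n_words, anx_cat))
  }
  if (nrow(neu_pool) < n_words) {
    stop(sprintf("fewer than %d candidate words in category 'neutral'", n_words))
  }

  # anxiety set: top-rated, ties broken by word token for determinism
  anx <- dplyr::arrange(anx_pool, dplyr::desc(.data$rating), .data$word)[seq_len(n_words), ]

  # neutral set: lowest-rated; resolve boundary ties by syllable matching
  neu_sorted <- dplyr::arrange(neu_pool, .data$rating, .data$word)
  cutoff <- neu_sorted$rating[n_words]
  forced <- dplyr::filter(neu_sorted, .data$rating < cutoff)
  tied <- dplyr::filter(neu_sorted, .data$rating == cutoff)
  k <- n_words - nrow(forced)
  target <- mean(anx$syllables)
  if (k == nrow(tied)) {
    pick <- tied
  } else {
    pick <- tied[best_syllable_subset(tied$syllables, k, sum(forced$syllables), n_words, target), ]
  }
  neu <- dplyr::arrange(dplyr::bind_rows(forced, pick), .data$rating, .data$word)

  structure(list(anxiety_words = anx, neutral_words = neu), class = "stimulus_set")
}

# Choose k indices among tied candidates minimising
# |mean syllables of the full neutral set - target|. Exhaustive when the
# number of subsets is small; otherwise a deterministic greedy swap search.
best_syllable_subset <- function(syll, k, forced_sum, n_total, target) {
  n <- length(syll)
  if (choose(n, k) <= 5000) {
    combos <- utils::combn(n, k)
    obj <- apply(combos, 2, function(idx) {
      abs((forced_sum + sum(syll[idx])) / n_total - target)
    })
    return(combos[, which.min(obj)])
  }
  # greedy: start from the k candidates closest to the per-word target,
  # then improve by single swaps until no swap helps
  per_word <- (target * n_total - forced_sum) / k
  idx <- order(abs(syll - per_word), seq_len(n))[seq_len(k)]
  obj <- function(sel) abs((forced_sum + sum(syll[sel])) / n_total - target)
  repeat {
    best <- obj(idx); improved <- FALSE
    for (i in seq_along(idx)) {
      for (j in setdiff(seq_len(n), idx)) {
        cand <- idx; cand[i] <- j
        if (obj(cand) < best - 1e-12) {
          idx <- cand; best <- obj(cand); improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  sort(idx)
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat("<stimulus_set>\n")
  cat("  anxiety words:", nrow(x$anxiety_words),
      sprintf("(mean rating %.2f, mean syllables %.2f)\n",
              mean(x$anxiety_words$rating), mean(x$anxiety_words$syllables)))
  cat("  neutral words:", nrow(x$neutral_words),
      sprintf("(mean rating %.2f, mean syllables %.2f)\n",
              mean(x$neutral_words$rating), mean(x$neutral_words$syllables)))
  invisible(x)
}
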