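test_that("similarity matrix matches hand-computed correlations", {
  p <- rbind(c(1, 2, 3), c(2, 4, 6))
  expect_equal(similarity_matrix(p)[1, 2], 1)
  p2 <- rbind(c(1, 2, 3), c(3, 2, 1))
  expect_equal(similarity_matrix(p2)[1, 2], -1)
  # brute-force covariance/sd oracle on random patterns
  withr::with_seed(60, p3 <- matrix(rnorm(30), 3, 10))
  sm <- similarity_matrix(p3)
  for (i in 1:3) for (j in 1:3) {
    num <- mean((p3[i, ] - mean(p3[i, ])) * (p3[j, ] - mean(p3[j, ])))
    den <- sqrt(mean((p3[i, ] - mean(p3[i, ]))^2) * mean((p3[j, ] - mean(p3[j, ]))^2))
    if (i != j) expect_equal(sm[i, j], num / den, tolerance = 1e-12)
  }
  expect_equal(diag(sm), rep(1, 3), ignore_attr = TRUE)
  expect_equal(sm, t(sm), ignore_attr = TRUE)
})

test_that("zero-variance trials are excluded with a warning", {
  p <- rbind(c(1, 2, 3), c(5, 5, 5), c(3, 1, 2))
  expect_warning(sm <- similarity_matrix(p), "zero-variance")
  expect_equal(dim(sm), c(2L, 2L))
})

test_that("mean pairwise RS averages the strict lower triangle", {
  m <- diag(3)
  m[lower.tri(m)] <- c(0.2, 0.4, 0.6)
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  expect_equal(mean_pairwise_rs(m), 0.4)
  expect_equal(mean_pairwise_rs(diag(4)), 0)
  # brute-force pair enumeration oracle
  withr::with_seed(61, {
    r <- matrix(runif(25, -1, 1), 5); r <- (r + t(r)) / 2; diag(r) <- 1
  })
  acc <- 0; np <- 0
  for (i in 2:5) for (j in 1:(i - 1)) { acc <- acc + r[i, j]; np <- np + 1 }
  expect_equal(mean_pairwise_rs(r), acc / np)
})

test_that("fisher transform is atanh with clipping", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5))
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  expect_true(is.finite(fisher_z(1)))
  expect_true(is.finite(fisher_z(-1)))
  expect_equal(fisher_z(1), atanh(1 - 1e-7))
  expect_error(fisher_z(1.5))
})

test_that("sphere offsets enumerate lattice points within the radius", {
  expect_equal(nrow(sphere_offsets(2)), 33L)
  expect_equal(nrow(sphere_offsets(0)), 1L)
  expect_equal(nrow(sphere_offsets(1)), 7L)
  off <- sphere_offsets(2)
  expect_true(any(rowSums(abs(off)) == 0))          # contains the centre
  # closed under sign flips and axis permutations
  key <- function(m) sort(apply(m, 1, paste, collapse = ","))
  expect_equal(key(off), key(-off))
  expect_equal(key(off), key(off[, c(2, 3, 1)]))
  expect_true(all(rowSums(off^2) <= 4))
})

test_that("searchlight map equals a brute-force per-voxel loop", {
  mask <- array(FALSE, dim = c(10L, 10L, 10L))
  mask[2:9, 2:9, 2:9] <- TRUE
  withr::with_seed(62, patterns <- matrix(rnorm(8 * sum(mask)), 8))
  slm <- searchlight_rs(patterns, mask, radius = 2, min_voxels = 5L)
  # independent loop implementation
  lin <- which(mask)
  coords <- arrayInd(lin, dim(mask))
  off <- as.matrix(expand.grid(-2:2, -2:2, -2:2))
  off <- off[rowSums(off^2) <= 4, ]
  for (i in sample(seq_along(lin), 40)) {
    nb <- sweep(off, 2, coords[i, ], "+")
    ok <- apply(nb, 1, function(v) all(v >= 1 & v <= 10) && mask[v[1], v[2], v[3]])
    cols <- match(
      (nb[ok, 1]) + 10 * (nb[ok, 2] - 1) + 100 * (nb[ok, 3] - 1), lin)
    cm <- cor(t(patterns[, cols]))
    expect_equal(slm[lin[i]], mean(cm[lower.tri(cm)]), tolerance = 1e-12)
  }
})

test_that("an interior sphere intersected with a large mask has 33 voxels", {
  mask <- array(TRUE, dim = c(9L, 9L, 9L))
  centre <- c(5L, 5L, 5L)
  nb <- sweep(sphere_offsets(2), 2, centre, "+")
  inside <- nb[, 1] >= 1 & nb[, 1] <= 9 & nb[, 2] >= 1 & nb[, 2] <= 9 &
    nb[, 3] >= 1 & nb[, 3] <= 9
  expect_equal(sum(mask[nb[inside, , drop = FALSE]]), 33L)
})

test_that("perfectly reliable noiseless patterns give unit interior map values", {
  mask <- array(TRUE, dim = c(7L, 7L, 7L))
  withr::with_seed(63, patterns <- gen_patterns(6, sum(mask), rho = 1))
  slm <- searchlight_rs(patterns, mask, radius = 2)
  expect_equal(slm[4, 4, 4], 1, tolerance = 1e-10)
})

test_that("searchlight errors with fewer than two trials", {
  mask <- array(TRUE, dim = c(6L, 6L, 6L))
  expect_error(searchlight_rs(matrix(rnorm(sum(mask)), 1), mask), "2 trials")
})

test_that("mask summaries carry their aggregation mode explicitly", {
  mask <- array(TRUE, dim = c(6L, 6L, 6L))
  withr::with_seed(64, patterns <- gen_patterns(10, sum(mask), rho = 0.5))
  stack <- make_stack(patterns, mask)
  s1 <- mask_rs_summary(stack, mask, mode = "searchlight", radius = 2)
  s2 <- mask_rs_summary(stack, mask, mode = "pairs")
  expect_equal(s1$mode, "searchlight")
  expect_equal(s2$mode, "pairs")
  expect_false(isTRUE(all.equal(s1$mean_z, s2$mean_z)))
})

test_that("a constant searchlight map summarises to its own z value", {
  mask <- array(FALSE, dim = c(5L, 5L, 5L))
  mask[2:4, 2:4, 2:4] <- TRUE
  map <- array(NA_real_, dim = dim(mask))
  map[which(mask)] <- 0.5
  class(map) <- c("searchlight_map", "array")
  s <- mask_rs_summary(map, mask, mode = "searchlight")
  expect_equal(s$mean_z, atanh(0.5))
  expect_equal(s$log_value, log(atanh(0.5)))
  # single defined voxel: summary equals that voxel's z
  map2 <- array(NA_real_, dim = dim(mask))
  map2[3, 3, 3] <- 0.3
  class(map2) <- c("searchlight_map", "array")
  expect_equal(mask_rs_summary(map2, mask)$mean_z, atanh(0.3))
})

test_that("the two aggregation modes rank subjects consistently", {
  mask <- array(TRUE, dim = c(6L, 6L, 6L))
  rhos <- seq(0.05, 0.9, length.out = 15)
  withr::with_seed(65, {
    res <- purrr::map_dfr(seq_along(rhos), function(i) {
      stack <- make_stack(gen_patterns(20, sum(mask), rhos[i]), mask)
      dplyr::bind_rows(
        mask_rs_summary(stack, mask, mode = "searchlight", radius = 2,
                        subject_id = as.character(i)),
        mask_rs_summary(stack, mask, mode = "pairs",
                        subject_id = as.character(i)))
    })
  })
  wide <- tidyr::pivot_wider(res[, c("subject_id", "mode", "mean_z")],
                             names_from = "mode", values_from = "mean_z")
  expect_gte(cor(wide$searchlight, wide$pairs, method = "spearman"), 0.9)
  expect_true(all(sign(wide$searchlight) == sign(wide$pairs)))
})

test_that("RS statistics are invariant to per-trial affine rescaling", {
  withr::with_seed(66, p <- gen_patterns(8, 50, 0.4))
  p2 <- p * rep(runif(8, 0.5, 3), 50) + rep(rnorm(8), 50)
  expect_equal(similarity_matrix(p), similarity_matrix(p2), tolerance = 1e-10)
})

test_that("cross-condition RS behaves at the degenerate extremes", {
  withr::with_seed(67, x <- matrix(rnorm(40), 4, 10, byrow = FALSE))
  same <- matrix(rep(x[1, ], 3), nrow = 3, byrow = TRUE)
  r <- cross_condition_rs(same, same)
  expect_equal(r$mean_z, atanh(1 - 1e-7))  # clipped maximal z
  withr::with_seed(68, {
    a <- gen_patterns(15, 300, 0.5)
    b <- gen_patterns(15, 300, 0.5)
  })
  expect_lt(abs(cross_condition_rs(a, b)$mean_z), 0.05)
  expect_error(cross_condition_rs(a, b[, 1:100]), "mismatch")
})

test_that("cross-condition RS recovers kappa * sqrt(rho_a rho_b)", {
  kappa <- 0.6; rho_a <- 0.5; rho_b <- 0.7
  withr::with_seed(69, {
    vals <- vapply(1:40, function(rep) {
      nv <- 200
      c1 <- rnorm(nv); c2 <- kappa * c1 + sqrt(1 - kappa^2) * rnorm(nv)
      a <- gen_patterns(15, nv, rho_a, template = c1)
      b <- gen_patterns(15, nv, rho_b, template = c2)
      cross_condition_rs(a, b)$mean_r
    }, numeric(1))
  })
  expect_equal(mean(vals), kappa * sqrt(rho_a * rho_b), tolerance = 0.05)
})

test_that("cohort log transform shifts only when needed and records it", {
  v <- c(0.2, 0.5, 1.1)
  lt <- log_transform_rs(v)
  expect_equal(as.numeric(lt), log(v))
  expect_equal(attr(lt, "shift"), 0)
  v2 <- c(-0.1, 0.2, 0.5)
  lt2 <- log_transform_rs(v2)
  expect_equal(attr(lt2, "shift"), 0.11)
  expect_equal(as.numeric(lt2), log(v2 + 0.11))
  expect_error(log_transform_rs(v2, shift = FALSE), "shift")
})
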