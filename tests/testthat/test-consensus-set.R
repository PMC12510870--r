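fake_mapping2 <- function(Z1, Z2, ids = NULL) {
  n <- nrow(Z1)
  if (is.null(ids)) ids <- sprintf("p%03d", seq_len(n))
  structure(list(ids = ids, Z = list(Z1, Z2),
                 consensus_error = sqrt(rowSums((Z1 - Z2)^2)),
                 representation_error = array(0, c(n, 2, 2)),
                 labels = c("s1", "s2"), scales = c(1, 1)),
            class = "consensus_mapping")
}

test_that("agreement ranking sorts by consensus error with id tie-breaks", {
  m <- structure(list(ids = c("a", "b", "c"),
                      consensus_error = c(0.5, 0.1, 0.3),
                      Z = list(matrix(0, 3, 2), matrix(0, 3, 2))),
                 class = "consensus_mapping")
  expect_equal(agreement_ranking(m), c("b", "c", "a"))
  m$consensus_error <- c(0.2, 0.2, 0.2)
  expect_equal(agreement_ranking(m), c("a", "b", "c"))
  m$consensus_error <- c(0.5, 0.1, 0.3) + 7
  expect_equal(agreement_ranking(m), c("b", "c", "a"))
})

test_that("sliced Wasserstein: zero on equal clouds, 1-D reduction, symmetry", {
  set.seed(41)
  A <- matrix(rnorm(60), 30, 2)
  cfg <- sw_config(kappa = 50L, seed = 3L)
  expect_equal(sliced_wasserstein(A, A, cfg), 0)
  # d = 1: projections are +-1 and W1 is sign-invariant
  a <- matrix(rnorm(20), 20, 1); b <- matrix(rnorm(25), 25, 1)
  expect_equal(sliced_wasserstein(a, b, sw_config(kappa = 7L, seed = 2L)),
               wasserstein_1d(a[, 1], b[, 1]), tolerance = 1e-12)
  B <- matrix(rnorm(60, mean = 1), 30, 2)
  U <- cc_ns$random_projections(50L, 2L, 3L)
  expect_equal(sliced_wasserstein(A, B, projections = U),
               sliced_wasserstein(B, A, projections = U), tolerance = 1e-12)
  expect_error(sliced_wasserstein(A, matrix(0, 3, 3), cfg), "dimension")
})

test_that("sliced Wasserstein with shared projections obeys the triangle inequality", {
  set.seed(42)
  U <- cc_ns$random_projections(40L, 3L, 9L)
  for (trial in 1:10) {
    A <- matrix(rnorm(45), 15, 3)
    B <- matrix(rnorm(45, mean = rnorm(1)), 15, 3)
    C <- matrix(rnorm(45, sd = runif(1, 0.5, 2)), 15, 3)
    dAB <- sliced_wasserstein(A, B, projections = U)
    dBC <- sliced_wasserstein(B, C, projections = U)
    dAC <- sliced_wasserstein(A, C, projections = U)
    expect_lte(dAC, dAB + dBC + 1e-12)
  }
})

test_that("sliced estimate self-converges as projections increase", {
  set.seed(43)
  A <- matrix(rnorm(400), 200, 2)
  B <- matrix(rnorm(400, mean = 0.5), 200, 2)
  est <- sliced_wasserstein(A, B, sw_config(kappa = 200L, seed = 1L))
  ref <- sliced_wasserstein(A, B, sw_config(kappa = 5000L, seed = 2L))
  expect_lt(abs(est - ref) / ref, 0.05)
})

test_that("permutation test: degenerate, decisive, and verbatim-text cases", {
  set.seed(44)
  A <- matrix(rnorm(80), 40, 2)
  cfg <- sw_config(kappa = 30L, seed = 5L)
  # A vs itself: d_obs = 0 and every permuted distance is >= 0 -> p = 1
  pt <- permutation_pvalue(A, A, cfg)
  expect_equal(pt$d_obs, 0)
  expect_equal(pt$p_value, 1)
  # far-separated clouds: d_obs beats all 100 permutations -> p = 1/101
  B <- A + 50
  pt2 <- permutation_pvalue(A, B, cfg, n_perm = 100L)
  expect_equal(pt2$p_value, 1 / 101)
  expect_true(all(pt2$permuted < pt2$d_obs))
  # the verbatim reading reports the complementary proportion
  pt3 <- permutation_pvalue(A, B, cfg, n_perm = 100L, direction = "paper-text")
  expect_equal(pt3$p_value, 1)
  expect_error(permutation_pvalue(A, B[1:10, ], cfg), "same number")
})

test_that("observed distance is label-symmetric", {
  set.seed(45)
  A <- matrix(rnorm(60), 30, 2)
  B <- matrix(rnorm(60, 1), 30, 2)
  cfg <- sw_config(kappa = 25L, seed = 6L)
  expect_equal(permutation_pvalue(A, B, cfg)$d_obs,
               permutation_pvalue(B, A, cfg)$d_obs, tolerance = 1e-12)
})

test_that("null rejection rate stays near the nominal level (smoke)", {
  rejections <- 0L
  for (trial in 1:40) {
    set.seed(500 + trial)
    A <- matrix(rnorm(300), 100, 3)
    B <- matrix(rnorm(300), 100, 3)
    pt <- permutation_pvalue(A, B, sw_config(kappa = 50L, seed = 500 + trial),
                             n_perm = 100L)
    rejections <- rejections + (pt$p_value < 0.05)
  }
  # 40 null trials at alpha 0.05: >= 7 rejections would be wildly off
  expect_lte(rejections, 6L)
})

test_that("sweep keeps everything when the projections are identical", {
  set.seed(46)
  Z <- matrix(rnorm(400), 200, 2)
  m <- fake_mapping2(Z, Z)
  sel <- threshold_sweep(m, sw_config(kappa = 20L, seed = 2L),
                         K_grid = c(50L, 100L, 150L, 200L), n_perm = 50L)
  expect_equal(sel$K_star, 200L)
  expect_setequal(sel$selected_ids, m$ids)
  expect_equal(nrow(sel$sweep), 4L)
})

test_that("sweep input validation", {
  set.seed(47)
  Z <- matrix(rnorm(100), 50, 2)
  m <- fake_mapping2(Z, Z + rnorm(100, sd = 0.01))
  expect_error(threshold_sweep(m, alpha = 1), "alpha")
  expect_error(threshold_sweep(m, alpha = 0), "alpha")
  expect_error(threshold_sweep(m, K_grid = integer(0)), "empty|K_grid")
  expect_error(threshold_sweep(m, K_grid = c(10L, 60L)), "K_grid")
})

test_that("selection files round-trip ids and the sweep table", {
  set.seed(48)
  Z <- matrix(rnorm(200), 100, 2)
  m <- fake_mapping2(Z, Z)
  sel <- threshold_sweep(m, sw_config(kappa = 10L, seed = 1L),
                         K_grid = c(50L, 100L), n_perm = 20L)
  ids_p <- withr::local_tempfile(fileext = ".txt")
  sweep_p <- withr::local_tempfile(fileext = ".csv")
  write_selection(sel, ids_p, sweep_p)
  expect_equal(readLines(ids_p), sel$selected_ids)
  back <- data.table::fread(sweep_p, data.table = FALSE)
  expect_equal(back$p_value, sel$sweep$p_value)
})
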