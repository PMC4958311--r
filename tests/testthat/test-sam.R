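test_that("d-statistic matches hand arithmetic and errors on degenerate scatter", {
  m <- matrix(c(2, 2, 0, 0), 1, 4,
              dimnames = list("f1", paste0("s", 1:4)))
  in_class <- c(TRUE, TRUE, FALSE, FALSE)
  # zero within-class scatter: s = 0, so s0 must be positive
  expect_error(sam_d_statistics(m, in_class, s0 = 0), "s0")
  expect_equal(sam_d_statistics(m, in_class, s0 = 1)$d[["f1"]], 2)

  # identical values in both classes give d = 0
  m2 <- rbind(m, f2 = c(3, 3, 3, 3))
  expect_equal(sam_d_statistics(m2, in_class, s0 = 1)$d[["f2"]], 0)

  expect_error(sam_d_statistics(m, c(TRUE, FALSE, FALSE, FALSE), s0 = 1),
               ">= 2 samples")
})

test_that("d-statistics agree with an independently coded formula", {
  set.seed(42)
  m <- matrix(rnorm(10 * 8), 10, 8,
              dimnames = list(sprintf("f%02d", 1:10), sprintf("s%d", 1:8)))
  in_class <- rep(c(TRUE, FALSE), each = 4)
  st <- sam_d_statistics(m, in_class, s0 = 0.2)
  expect_equal(unname(st$d), unname(sam_d_oracle(m, in_class, s0 = 0.2)),
               tolerance = 1e-10)
})

test_that("label swap negates every d", {
  set.seed(7)
  m <- matrix(rnorm(20 * 10), 20, 10,
              dimnames = list(sprintf("f%02d", 1:20), sprintf("s%d", 1:10)))
  in_class <- rep(c(TRUE, FALSE), each = 5)
  d1 <- sam_d_statistics(m, in_class, s0 = 0.1)$d
  d2 <- sam_d_statistics(m, !in_class, s0 = 0.1)$d
  expect_equal(d1, -d2)
})

test_that("permutation null enumerates small designs and is deterministic", {
  set.seed(1)
  m <- matrix(rnorm(5 * 4), 5, 4,
              dimnames = list(sprintf("f%d", 1:5), sprintf("s%d", 1:4)))
  in_class <- c(TRUE, TRUE, FALSE, FALSE)
  null <- permutation_null(m, in_class, n_permutations = 1000, s0 = 0.1)
  expect_true(null$enumerated)
  expect_equal(null$n_permutations, choose(4, 2) - 1)  # identity excluded

  # identical data across samples: every permuted d is zero
  m0 <- matrix(5, 3, 4, dimnames = list(letters[1:3], sprintf("s%d", 1:4)))
  n0 <- permutation_null(m0, in_class, n_permutations = 10, s0 = 1)
  expect_true(all(n0$d_perm == 0))

  # fixed seed reproduces the sampled null exactly
  m2 <- matrix(rnorm(6 * 12), 6, 12,
               dimnames = list(letters[1:6], sprintf("s%02d", 1:12)))
  icl <- rep(c(TRUE, FALSE), each = 6)
  a <- permutation_null(m2, icl, n_permutations = 50, seed = 9, s0 = 0.1)
  b <- permutation_null(m2, icl, n_permutations = 50, seed = 9, s0 = 0.1)
  expect_identical(a$d_perm, b$d_perm)
  expect_false(a$enumerated)
})

test_that("delta calibration is monotone and vacuous at target 1", {
  set.seed(3)
  m <- matrix(rnorm(40 * 12), 40, 12,
              dimnames = list(sprintf("f%02d", 1:40), sprintf("s%02d", 1:12)))
  m[1, 1:6] <- m[1, 1:6] + 5
  lab <- rep(c("X", "Y"), each = 6)
  r0 <- sam_analysis(m, lab, "X", target_fdr = 0, n_permutations = 200,
                     seed = 4)
  r5 <- sam_analysis(m, lab, "X", target_fdr = 0.5, n_permutations = 200,
                     seed = 4)
  r1 <- sam_analysis(m, lab, "X", target_fdr = 1, n_permutations = 200,
                     seed = 4)
  n0 <- length(r0$called_up) + length(r0$called_down)
  n5 <- length(r5$called_up) + length(r5$called_down)
  n1 <- length(r1$called_up) + length(r1$called_down)
  expect_true(n0 <= n5)               # tightening FDR never enlarges calls
  expect_true(n5 <= n1)
  expect_true(r0$delta >= r5$delta)
  o <- order(r1$d)
  dev <- r1$d[o] - r1$d_expected
  expect_equal(n1, sum(abs(dev) > 0))  # target 1 calls everything deviating
})

test_that("a strongly shifted feature is called alone at target FDR 0", {
  set.seed(11)
  m <- matrix(rnorm(200 * 14), 200, 14,
              dimnames = list(sprintf("f%03d", 1:200), sprintf("s%02d", 1:14)))
  m[7, 1:7] <- m[7, 1:7] + 10
  lab <- rep(c("X", "Y"), each = 7)
  r <- sam_analysis(m, lab, "X", target_fdr = 0, n_permutations = 300,
                    seed = 2)
  expect_identical(r$called_up, "f007")
  expect_length(r$called_down, 0)
  expect_equal(r$est_fdr, 0)
})

test_that("sampled FDR estimate is consistent with full enumeration", {
  set.seed(21)
  m <- matrix(rnorm(10 * 8), 10, 8,
              dimnames = list(sprintf("f%02d", 1:10), sprintf("s%d", 1:8)))
  in_class <- rep(c(TRUE, FALSE), each = 4)
  st <- sam_d_statistics(m, in_class, s0 = 0.2)
  full <- permutation_null(m, in_class, n_permutations = 100, s0 = 0.2)
  expect_true(full$enumerated)          # C(8,4) - 1 = 69 <= 100
  samp <- permutation_null(m, in_class, n_permutations = 40, seed = 5,
                           s0 = 0.2)
  expect_false(samp$enumerated)
  # median false-call count at a mid-range delta: the sampled median must
  # fall inside the central mass of the exact per-permutation distribution
  o <- order(st$d)
  delta <- stats::median(abs(st$d[o] - full$d_expected))
  cnt_full <- colSums(abs(full$d_perm - full$d_expected) > delta)
  cnt_samp <- colSums(abs(samp$d_perm - samp$d_expected) > delta)
  expect_true(stats::median(cnt_samp) >= stats::quantile(cnt_full, 0.1) - 1)
  expect_true(stats::median(cnt_samp) <= stats::quantile(cnt_full, 0.9) + 1)
})

test_that("sam_analysis is invariant to sample column order", {
  set.seed(13)
  m <- matrix(rnorm(30 * 12), 30, 12,
              dimnames = list(sprintf("f%02d", 1:30), sprintf("s%02d", 1:12)))
  m[3, 1:6] <- m[3, 1:6] + 4
  lab <- stats::setNames(rep(c("X", "Y"), each = 6), colnames(m))
  perm <- sample(ncol(m))
  r1 <- sam_analysis(m, lab, "X", n_permutations = 100, seed = 8)
  r2 <- sam_analysis(m[, perm], lab[perm], "X", n_permutations = 100,
                     seed = 8)
  expect_equal(r1$d, r2$d)
  expect_identical(sort(r1$called_up), sort(r2$called_up))
})
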