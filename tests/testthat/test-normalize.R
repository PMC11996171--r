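test_that("TMM factors are 1 for identical and depth-scaled samples", {
  set.seed(11)
  base <- rpois(800, 60)
  m <- count_matrix(matrix(rep(base, 3), ncol = 3,
                           dimnames = list(paste0("g", 1:800), paste0("s", 1:3))))
  expect_equal(unname(tmm_factors(m)$factors), rep(1, 3))

  # pure depth scaling: one sample is another times 3
  m2 <- count_matrix(cbind(s1 = base, s2 = base * 3,
                           s3 = base) |> `rownames<-`(paste0("g", 1:800)))
  f <- tmm_factors(m2)$factors
  expect_equal(unname(f), rep(1, 3), tolerance = 1e-12)
})

test_that("TMM matches an independent step-by-step oracle on a composition fixture", {
  # 1000 genes equal in both samples, 100 genes 10x up in sample B only
  set.seed(21)
  mu <- rexp(1100, 1 / 200) + 20
  a <- rpois(1100, mu)
  b_mu <- mu; b_mu[1:100] <- b_mu[1:100] * 10
  b <- rpois(1100, b_mu)
  m <- count_matrix(cbind(A = a, B = b) |> `rownames<-`(paste0("g", 1:1100)))
  f <- tmm_factors(m)$factors
  o <- oracle_tmm(m$counts)
  expect_equal(unname(f), unname(o), tolerance = 1e-8)
  # composition bias detected: sample B is scaled down relative to A
  expect_lt(f["B"], f["A"])
})

test_that("TMM factors are invariant to rescaling one sample", {
  set.seed(31)
  m <- toy_counts(n_genes = 500, n_samples = 4, lambda = 80)
  scaled <- m$counts; scaled[, 2] <- scaled[, 2] * 5
  f1 <- tmm_factors(m)$factors
  f2 <- tmm_factors(count_matrix(scaled))$factors
  # invariance is exact in the M-values and approximate in the precision
  # weights, so factors agree closely but not to machine precision
  expect_equal(unname(f1), unname(f2), tolerance = 0.005)
})

test_that("CPM follows the documented arithmetic and sums to 1e6 without prior", {
  cm <- count_matrix(matrix(c(100, 10), 1, 2,
                            dimnames = list("g1", c("s1", "s2"))),
                     lib_size = c(s1 = 1e6, s2 = 1e6))
  expect_equal(cpm_matrix(cm)["g1", "s1"], 100)

  # prior 0.5, count 10, lib 1e6 (equal libs so r = 1):
  # (10 + 0.5) / (1e6 + 1) * 1e6
  expect_equal(cpm_matrix(cm, prior_count = 0.5)["g1", "s2"],
               10.5 / (1e6 + 1) * 1e6)

  m <- toy_counts(n_genes = 50, n_samples = 3)
  expect_equal(unname(colSums(cpm_matrix(m))), rep(1e6, 3))
  # prior-free CPM agrees with the edgeR implementation
  expect_equal(cpm_matrix(m), edgeR::cpm(m$counts, lib.size = m$lib_size),
               ignore_attr = TRUE)
  # zero count, prior 0 -> 0
  z <- m$counts; z[1, 1] <- 0
  expect_equal(cpm_matrix(count_matrix(z))[1, 1], 0)
})

test_that("the expression filter keeps genes at or above threshold in every sample", {
  cpm <- matrix(c(0.10, 0.10, 0.10,   # boundary: retained (inclusive)
                  5.00, 0.09, 3.00,   # one low sample: dropped
                  0.00, 1.00, 1.00,   # zero: dropped
                  2.00, 2.00, 2.00,   # retained
                  0.11, 0.12, 0.13),  # retained
                5, 3, byrow = TRUE,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:3)))
  expect_equal(filter_low_expression(cpm), c("g1", "g4", "g5"))
  expect_warning(filter_low_expression(cpm, threshold = 10), "no gene")
  expect_error(filter_low_expression(cpm, threshold = 0),
               class = "parallevo_validation_error")
})

test_that("BCV^2 is near zero for Poisson counts and recovered for NB counts", {
  set.seed(41)
  pois <- count_matrix(matrix(rpois(500 * 20, 1000), 500, 20,
                              dimnames = list(sprintf("g%03d", 1:500),
                                              sprintf("i%02d", 1:20))))
  est <- estimate_bcv2(pois)
  expect_lt(median(est$bcv2), 0.01)

  nb <- count_matrix(matrix(rnbinom(2000 * 20, mu = 1000, size = 1 / 0.09),
                            2000, 20,
                            dimnames = list(sprintf("g%04d", 1:2000),
                                            sprintf("i%02d", 1:20))))
  est <- estimate_bcv2(nb)
  expect_equal(mean(est$bcv2), 0.09, tolerance = 0.03)
  expect_true(all(est$bcv2 >= 0))
})

test_that("all-zero genes are flagged as undefined dispersion", {
  set.seed(42)
  m <- matrix(rpois(100 * 8, 50), 100, 8,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("i%d", 1:8)))
  m[7, ] <- 0
  est <- estimate_bcv2(count_matrix(m))
  expect_true(est$flagged[7])
  expect_true(is.na(est$bcv2[7]))
})

test_that("two panels from identical parameters rank genes concordantly", {
  set.seed(43)
  truth <- gen_causal_truth("V", 600)
  mu <- exp(rnorm(600, log(300), 0.8))
  p1 <- gen_individual_panel(truth, 20, mu, seed = 101)
  p2 <- gen_individual_panel(truth, 20, mu, seed = 102)
  b1 <- estimate_bcv2(p1); b2 <- estimate_bcv2(p2)
  rho <- cor(b1$bcv2, b2$bcv2, method = "spearman", use = "complete.obs")
  expect_gt(rho, 0.5)
})

test_that("the BCV^2 estimator tightens with panel size", {
  err <- function(n) {
    mean(vapply(1:4, function(r) {
      set.seed(100 * n + r)
      m <- count_matrix(matrix(rnbinom(1000 * n, mu = 500, size = 1 / 0.09),
                               1000, n,
                               dimnames = list(sprintf("g%04d", 1:1000),
                                               sprintf("i%03d", seq_len(n)))))
      abs(mean(estimate_bcv2(m)$bcv2) - 0.09)
    }, 0))
  }
  errs <- vapply(c(10, 40, 160), err, 0)
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 0.005)
})
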