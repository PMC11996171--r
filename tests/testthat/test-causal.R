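make_causal_data <- function(model = "III", n = 2000, seed = 1, ...) {
  truth <- gen_causal_truth(model, n, seed = seed, ...)
  d <- data.frame(gene_id = truth$gene_id, Pa = truth$Pa, A = truth$A,
                  Pl = truth$Pl)
  std <- function(x) (x - mean(x)) / sd(x)
  d$Pa_std <- std(d$Pa); d$A_std <- std(d$A); d$Pl_std <- std(d$Pl)
  class(d) <- c("causal_data", "data.frame")
  d
}

test_that("build_causal_data applies the log transforms and drops degenerate genes", {
  stats <- data.frame(gene_id = c("g1", "g2", "g3"),
                      parallelism = c(0.25, 1, NA))
  disp <- data.frame(gene_id = c("g1", "g2", "g3"), bcv2 = c(0.09, 0.2, 0.1))
  genes <- sprintf("g%d", 1:3)
  pt <- pleiotropy_table(
    tissues = gen_tissue_profile(setNames(c(0.2, 0.5, 0.8), genes), 5, seed = 1),
    genes = genes)
  # fewer than 30 usable genes must refuse to fit
  expect_error(build_causal_data(stats, disp, pt),
               class = "parallevo_validation_error", regexp = "30")

  # scale up to check the transform values themselves
  n <- 60
  stats <- data.frame(gene_id = sprintf("g%02d", 1:n),
                      parallelism = rep(c(0.25, 2), n / 2))
  disp <- data.frame(gene_id = stats$gene_id, bcv2 = rep(c(0.09, 0.3), n / 2))
  pt <- pleiotropy_table(
    tissues = gen_tissue_profile(setNames(runif(n, 0.2, 0.8), stats$gene_id),
                                 5, seed = 2),
    genes = stats$gene_id)
  d <- build_causal_data(stats, disp, pt)
  expect_equal(d$Pa[1], log(0.25), tolerance = 1e-12)  # F = 4
  expect_equal(d$A[1], log(0.09), tolerance = 1e-12)
  expect_equal(mean(d$Pa_std), 0, tolerance = 1e-12)
  expect_equal(sd(d$Pa_std), 1, tolerance = 1e-12)
})

test_that("model log-likelihoods factorize, nest, and give the arithmetic BIC", {
  d <- make_causal_data("III", n = 500, seed = 81)
  fits <- lapply(setNames(nm = c("I", "II", "III", "IV", "V")),
                 fit_causal_model, d = d)
  expect_equal(vapply(fits, `[[`, 0L, "k"),
               c(I = 8L, II = 8L, III = 9L, IV = 8L, V = 6L))
  # V: sum of three univariate Gaussian MLE log-likelihoods
  ll1 <- function(x) {
    s2 <- mean((x - mean(x))^2)
    -(length(x) / 2) * (log(2 * pi * s2) + 1)
  }
  expect_equal(fits$V$loglik, ll1(d$Pa) + ll1(d$A) + ll1(d$Pl))
  # nesting: III contains I and II
  expect_gte(fits$III$loglik, fits$I$loglik)
  expect_gte(fits$III$loglik, fits$II$loglik)
  # BIC arithmetic: -2 lnL + k ln n
  expect_equal(fits$IV$bic, -2 * fits$IV$loglik + 8 * log(500))
  expect_equal(-2 * (-50) + 6 * log(100), 127.6310, tolerance = 1e-4)
})

test_that("the shared p(Pl) factor shifts every BIC equally", {
  d <- make_causal_data("I", n = 400, seed = 82)
  sel <- select_causal_model(d)
  ll_pl <- {
    s2 <- mean((d$Pl - mean(d$Pl))^2)
    -(400 / 2) * (log(2 * pi * s2) + 1)
  }
  # removing the identical 2-parameter Pl marginal from every model
  # changes each BIC by the same constant
  shift <- unique(round((-2 * (sel$table$loglik - ll_pl) +
                           (sel$table$k - 2) * log(400)) - sel$table$bic, 9))
  expect_length(shift, 1L)
})

test_that("BIC(III) - BIC(I) equals ln n minus twice the loglik gain of the Pl term", {
  d <- make_causal_data("I", n = 700, seed = 83)
  f1 <- fit_causal_model("I", d); f3 <- fit_causal_model("III", d)
  n <- nrow(d)
  rss <- function(fit) sum(resid(fit)^2)
  ll <- function(r) -(n / 2) * (log(2 * pi * r / n) + 1)
  gain <- ll(rss(lm(Pa ~ A + Pl, d))) - ll(rss(lm(Pa ~ A, d)))
  expect_equal(f3$bic - f1$bic, log(n) - 2 * gain, tolerance = 1e-8)
})

test_that("BIC recovers the generating causal model", {
  sel_for <- function(model, seed) {
    d <- make_causal_data(model, n = 5000, seed = seed)
    select_causal_model(d)$selected
  }
  expect_equal(sel_for("I", 84), "I")
  expect_equal(sel_for("II", 85), "II")
  expect_equal(sel_for("III", 86), "III")
  expect_equal(sel_for("IV", 87), "IV")
  expect_equal(sel_for("V", 88), "V")
})

test_that("selecting the independence model gets easier with more genes", {
  prop_v <- vapply(c(200, 1000, 5000), function(n) {
    mean(vapply(1:25, function(s) {
      d <- make_causal_data("V", n = n, seed = 1000 + 17 * s + n)
      select_causal_model(d)$selected == "V"
    }, TRUE))
  }, 0)
  expect_gte(prop_v[3], prop_v[1])
  expect_gte(prop_v[3], 0.9)
})

test_that("standardization is idempotent", {
  d <- make_causal_data("III", n = 300, seed = 89)
  again <- (d$Pa_std - mean(d$Pa_std)) / sd(d$Pa_std)
  expect_equal(again, d$Pa_std, tolerance = 1e-12)
})

test_that("path analysis satisfies the OLS identity cor(Pl,Pa) = b2 + b1*b3", {
  for (s in 90:94) {
    d <- make_causal_data(sample(c("I", "III", "V"), 1), n = 300, seed = s)
    pf <- path_analysis(d, n_boot = 100, seed = s)
    expect_equal(cor(d$Pl, d$Pa), pf$beta2 + pf$beta1 * pf$beta3,
                 tolerance = 1e-10)
  }
})

test_that("path analysis recovers generating effects and flags independence", {
  # magnitudes comparable to the observed effect sizes, unit residuals
  b1 <- -0.181; b2 <- 0.127; b3 <- -0.332
  set.seed(95)
  n <- 5000
  Pl <- rnorm(n)
  A <- b3 * Pl + rnorm(n)
  Pa <- b1 * A + b2 * Pl + rnorm(n)
  std <- function(x) (x - mean(x)) / sd(x)
  d <- data.frame(gene_id = seq_len(n), Pa = Pa, A = A, Pl = Pl,
                  Pa_std = std(Pa), A_std = std(A), Pl_std = std(Pl))
  pf <- path_analysis(d, n_boot = 300, seed = 95)
  expect_lt(abs(pf$beta1 - b1), 3 * pf$se["beta1"])
  expect_lt(abs(pf$beta2 - b2), 3 * pf$se["beta2"])
  expect_lt(abs(pf$beta3 - b3), 3 * pf$se["beta3"])
  expect_equal(pf$indirect, 0.060, tolerance = 0.02)
  expect_true(pf$indirect_ci[1] < pf$indirect & pf$indirect < pf$indirect_ci[2])

  # Pl independent of (A, Pa): both direct paths vanish
  dV <- make_causal_data("V", n = 3000, seed = 96)
  pfV <- path_analysis(dV, n_boot = 100, seed = 96)
  expect_lt(abs(pfV$beta2), 3 * pfV$se["beta2"])
  expect_lt(abs(pfV$beta3), 3 * pfV$se["beta3"])
})
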