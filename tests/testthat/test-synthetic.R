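test_that("causal truth honors the independence structure of each model", {
  n <- 5000; band <- 3 / sqrt(n)
  # model V: all three latents mutually independent
  tV <- gen_causal_truth("V", n, seed = 101)
  expect_lt(abs(cor(tV$Pl, tV$A)), band)
  expect_lt(abs(cor(tV$Pl, tV$Pa)), band)
  expect_lt(abs(cor(tV$A, tV$Pa)), band)

  # model I: Pa d-separated from Pl given A (chain)
  tI <- gen_causal_truth("I", n, coefficients = list(a = -0.5, b = -0.4),
                         seed = 102)
  expect_lt(abs(oracle_partial_cor(tI$Pa, tI$Pl, tI$A)), band)
  expect_gt(abs(cor(tI$Pl, tI$Pa)), band)  # marginally dependent

  # model IV: A independent of Pl
  tIV <- gen_causal_truth("IV", n, seed = 103)
  expect_lt(abs(cor(tIV$Pl, tIV$A)), band)
})

test_that("marginal correlations match the exact path-rule oracle", {
  n <- 20000
  for (model in c("I", "II", "III", "IV")) {
    tt <- gen_causal_truth(model, n,
                           coefficients = list(a = -0.33, b = -0.18, c = 0.13),
                           seed = 104)
    want <- oracle_cor_pl_pa(model, -0.33, -0.18, 0.13)
    expect_lt(abs(cor(tt$Pl, tt$Pa) - want), 3 / sqrt(n))
  }
  # and the rule-of-thumb product form for the mediated-plus-direct model
  expect_lt(abs(oracle_cor_pl_pa("III", -0.33, -0.18, 0.13) -
                  (0.13 + (-0.33) * (-0.18))), 0.01)
})

test_that("generators are deterministic given a seed", {
  a <- simulate_study(n_genes = 60, seed = 105)
  b <- simulate_study(n_genes = 60, seed = 105)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth, b$truth)
  expect_identical(unclass(a$tissues), unclass(b$tissues))
  expect_identical(a$network, b$network)
  c_ <- simulate_study(n_genes = 60, seed = 106)
  expect_false(identical(a$counts$counts, c_$counts$counts))
})

test_that("tissue profiles reproduce their target tau exactly", {
  set.seed(107)
  targets <- c(0, runif(50), 1, 0.625)
  names(targets) <- sprintf("g%02d", seq_along(targets))
  tp <- gen_tissue_profile(targets, n_tissues = 3, seed = 107)
  expect_equal(unname(tau(tp)), unname(targets), tolerance = 1e-12)
  # the hand case: target 0.625, N = 3 -> profile (1, 0.375, 0.375)
  prof <- sort(unclass(tp)["g53", ], decreasing = TRUE)
  expect_equal(unname(prof), c(1, 0.375, 0.375))
  expect_error(gen_tissue_profile(0.5, n_tissues = 1),
               class = "parallevo_validation_error")
})

test_that("generated networks achieve their connectivity targets", {
  # two genes with equal targets: a single edge carrying that weight
  net <- gen_network(c(gA = 0.7, gB = 0.7), seed = 108)
  expect_equal(nrow(net), 1L)
  expect_equal(net$weight, 0.7)

  # star: hub k*w against k spokes of w
  targ <- c(hub = 4 * 0.3, s1 = 0.3, s2 = 0.3, s3 = 0.3, s4 = 0.3)
  net <- gen_network(targ, seed = 109)
  expect_equal(connectivity(net, names(targ)), targ, ignore_attr = TRUE)

  # random feasible targets are met exactly up to one unmatched remainder
  set.seed(110)
  targ <- setNames(rexp(40), sprintf("g%02d", 1:40))
  net <- gen_network(targ, seed = 110)
  got <- connectivity(net, names(targ))
  expect_lte(sum(abs(got - targ) > 1e-9), 1L)
})

test_that("founder haplotypes are polymorphic with law-consistent frequencies", {
  H <- gen_founder_haplotypes(200, 400, freq_law = function(n) rep(0.5, n),
                              seed = 111)
  p <- colMeans(H)
  expect_true(all(p > 0 & p < 1))
  # 4-SD binomial band: ~0.025 expected exceedances over 400 loci
  expect_true(all(abs(p - 0.5) < 4 * sqrt(0.25 / 200)))

  # two haplotypes: conditioning forces exactly one copy of each allele
  H2 <- gen_founder_haplotypes(2, 50, seed = 112)
  expect_true(all(colSums(H2) == 1L))

  # default Beta(0.2, 0.2) law: mean minor-allele frequency matches a
  # direct-sampling Monte-Carlo oracle of the conditional law
  H3 <- gen_founder_haplotypes(189, 5000, seed = 113)
  maf <- pmin(colMeans(H3), 1 - colMeans(H3))
  set.seed(113)
  oracle <- replicate(20000, {
    repeat {
      x <- rbinom(1, 189, rbeta(1, 0.2, 0.2))
      if (x > 0 && x < 189) return(min(x, 189 - x) / 189)
    }
  })
  se <- sqrt(var(maf) / length(maf) + var(oracle) / length(oracle))
  expect_lt(abs(mean(maf) - mean(oracle)), 3 * se)
})

test_that("generated counts honor their means and degenerate limits", {
  truth <- gen_causal_truth("V", 50, seed = 114)
  design <- study_design(2, 2, 1000)  # many ancestral draws to average over
  mu <- rep(200, 50)
  cm <- gen_counts_from_truth(truth, design, mu, bcv2_center = 0.09,
                              seed = 114)
  anc <- cm$counts[, 1:1000]
  phi <- attr(cm, "dispersion")
  emp <- rowMeans(anc)
  se <- sqrt((200 + phi * 200^2) / 1000)
  expect_true(all(abs(emp - 200) < 4 * se))

  # dispersion 0: Poisson counts, variance ~ mean
  cm0 <- gen_counts_from_truth(truth, design, mu, bcv2_center = 0,
                               seed = 115)
  ratio <- apply(cm0$counts[, 1:1000], 1, var) / rowMeans(cm0$counts[, 1:1000])
  expect_true(all(abs(ratio - 1) < 0.3))

  # huge Pa latent: across-population SD collapses, all populations share
  # one true log2 fold change
  truth_hi <- gen_causal_truth("V", 20, seed = 116)
  truth_hi$Pa <- 40
  cmh <- gen_counts_from_truth(truth_hi, study_design(10, 3, 5), rep(100, 20),
                               seed = 116)
  lfc <- attr(cmh, "true_log2fc")
  expect_lt(max(apply(lfc, 1, sd)), 1e-6)

  expect_error(gen_counts_from_truth(truth, design, rep(-1, 50)),
               class = "parallevo_validation_error")
})
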