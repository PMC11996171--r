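# Causal analysis of the gene-level triple (Pl, A, Pa): pleiotropy proxy,
# ancestral expression variation (ln BCV^2) and parallelism (ln 1/F).
# Five causal graphs are compared through their Gaussian maximum
# likelihood and BIC:
#
#   I    Pl -> A -> Pa            L = p(Pa|A)    p(A|Pl) p(Pl)   k = 8
#   II   A  <- Pl -> Pa           L = p(Pa|Pl)   p(A|Pl) p(Pl)   k = 8
#   III  Pl -> A -> Pa, Pl -> Pa  L = p(Pa|A,Pl) p(A|Pl) p(Pl)   k = 9
#   IV   A -> Pa <- Pl, A indep.  L = p(Pa|A,Pl) p(A)    p(Pl)   k = 8
#   V    all independent          L = p(Pa)      p(A)    p(Pl)   k = 6
#
# Marginals are Gaussian MLE fits (variance with 1/n), conditionals OLS
# with MLE residual variance RSS/n, so every factor contributes
# -(n/2) (ln(2 pi sigma^2) + 1) and BIC = -2 ln L + k ln n is internally
# consistent. k counts every mean/intercept/slope and every variance.

CAUSAL_MODELS <- c("I", "II", "III", "IV", "V")

#' Assemble the gene-level causal data
#'
#' Joins the parallelism statistics, the ancestral-variance estimates and
#' a pleiotropy proxy over a gene set (typically the putatively adaptive
#' genes), applies the natural-log transforms `Pa = ln(1/F)` and
#' `A = ln(BCV^2)` that render both approximately Gaussian, and adds
#' standardized copies. Genes with a non-finite transform are dropped with
#' a message.
#'
#' @param stats a [evo_stats()] table.
#' @param disp a [estimate_bcv2()] table.
#' @param pt a [pleiotropy_table()].
#' @param genes gene ids to use (default: all shared genes).
#' @param proxy `"tissue"` (expression breadth, 1 - tau) or
#'   `"connectivity"`.
#' @param log_connectivity apply `ln(1 + x)` to connectivity before use
#'   (off by default; the proxies are standardized but not otherwise
#'   transformed).
#' @return A `causal_data` data frame with columns `gene_id`, `Pa`, `A`,
#'   `Pl` and standardized copies `Pa_std`, `A_std`, `Pl_std`.
#' @export
build_causal_data <- function(stats, disp, pt, genes = NULL,
                              proxy = c("tissue", "connectivity"),
                              log_connectivity = FALSE) {
  proxy <- match.arg(proxy)
  if (is.null(genes)) {
    genes <- Reduce(intersect, list(stats$gene_id, disp$gene_id, pt$gene_id))
  }
  pa <- log(stats$parallelism[match(genes, stats$gene_id)])
  a <- log(disp$bcv2[match(genes, disp$gene_id)])
  pl <- if (proxy == "tissue") {
    pt$pleiotropy_tissue[match(genes, pt$gene_id)]
  } else {
    x <- pt$connectivity[match(genes, pt$gene_id)]
    if (log_connectivity) log1p(x) else x
  }
  ok <- is.finite(pa) & is.finite(a) & is.finite(pl)
  if (any(!ok)) {
    message(sprintf("dropping %d gene(s) with non-finite Pa, A or Pl", sum(!ok)))
  }
  genes <- genes[ok]; pa <- pa[ok]; a <- a[ok]; pl <- pl[ok]
  if (length(genes) < 30L) {
    pv_stop("fewer than 30 usable genes; causal model fitting is unreliable")
  }
  std <- function(x) {
    s <- sd(x)
    if (s == 0) pv_stop("cannot standardize a constant column")
    (x - mean(x)) / s
  }
  out <- data.frame(gene_id = genes, Pa = pa, A = a, Pl = pl,
                    Pa_std = std(pa), A_std = std(a), Pl_std = std(pl),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("causal_data", "data.frame")
  out
}

# Gaussian MLE log-likelihood of a marginal: 2 parameters (mean, variance)
ll_marginal <- function(x) {
  n <- length(x)
  s2 <- mean((x - mean(x))^2)
  list(loglik = -(n / 2) * (log(2 * pi * s2) + 1), k = 2L,
       coef = c(mean = mean(x), var = s2))
}

# Gaussian OLS conditional: intercept + slopes + residual variance (RSS/n)
ll_conditional <- function(y, X) {
  X1 <- cbind(`(Intercept)` = 1, X)
  qr_ <- qr(X1)
  if (qr_$rank < ncol(X1)) pv_stop("singular design: constant regressor")
  beta <- qr.coef(qr_, y)
  res <- y - X1 %*% beta
  n <- length(y)
  s2 <- mean(res^2)
  list(loglik = -(n / 2) * (log(2 * pi * s2) + 1), k = ncol(X1) + 1L,
       coef = c(beta, var = s2))
}

#' Fit one causal model by Gaussian maximum likelihood
#'
#' @param model one of `"I"`..`"V"` (see the model table in the package
#'   source/vignette).
#' @param d a [build_causal_data()] table.
#' @param standardized fit on the standardized columns instead of the
#'   transformed ones (default `FALSE`; BIC ranking uses the transformed
#'   scale, path analysis the standardized one).
#' @return A `causal_fit` list: `model`, `loglik`, `k`, `bic`,
#'   `n`, and per-factor `coefficients`.
#' @export
fit_causal_model <- function(model, d, standardized = FALSE) {
  model <- match.arg(model, CAUSAL_MODELS)
  sfx <- if (standardized) "_std" else ""
  Pa <- d[[paste0("Pa", sfx)]]; A <- d[[paste0("A", sfx)]]
  Pl <- d[[paste0("Pl", sfx)]]
  n <- nrow(d)
  factors <- switch(model,
    I   = list(Pa = ll_conditional(Pa, cbind(A = A)),
               A  = ll_conditional(A, cbind(Pl = Pl)),
               Pl = ll_marginal(Pl)),
    II  = list(Pa = ll_conditional(Pa, cbind(Pl = Pl)),
               A  = ll_conditional(A, cbind(Pl = Pl)),
               Pl = ll_marginal(Pl)),
    III = list(Pa = ll_conditional(Pa, cbind(A = A, Pl = Pl)),
               A  = ll_conditional(A, cbind(Pl = Pl)),
               Pl = ll_marginal(Pl)),
    IV  = list(Pa = ll_conditional(Pa, cbind(A = A, Pl = Pl)),
               A  = ll_marginal(A),
               Pl = ll_marginal(Pl)),
    V   = list(Pa = ll_marginal(Pa),
               A  = ll_marginal(A),
               Pl = ll_marginal(Pl)))
  loglik <- sum(vapply(factors, `[[`, 0, "loglik"))
  k <- sum(vapply(factors, `[[`, 0L, "k"))
  structure(list(model = model, loglik = loglik, k = k,
                 bic = -2 * loglik + k * log(n), n = n,
                 coefficients = lapply(factors, `[[`, "coef")),
            class = "causal_fit")
}

#' @export
print.causal_fit <- function(x, ...) {
  cat(sprintf("causal model %s: loglik = %.3f, k = %d, BIC = %.3f (n = %d)\n",
              x$model, x$loglik, x$k, x$bic, x$n))
  invisible(x)
}

#' Fit all five causal models and select by BIC
#'
#' The model with the smallest `BIC = -2 ln L + k ln n` is selected; ties
#' within `1e-9` resolve to the model with fewer parameters (and are
#' reported via a message).
#'
#' @inheritParams fit_causal_model
#' @return A `causal_selection` list: `fits` (named list of
#'   [fit_causal_model()] results), `table` (model/loglik/k/BIC data
#'   frame), `selected` (model id).
#' @export
select_causal_model <- function(d, standardized = FALSE) {
  fits <- lapply(setNames(CAUSAL_MODELS, CAUSAL_MODELS), fit_causal_model,
                 d = d, standardized = standardized)
  tab <- data.frame(model = CAUSAL_MODELS,
                    loglik = vapply(fits, `[[`, 0, "loglik"),
                    k = vapply(fits, `[[`, 0L, "k"),
                    bic = vapply(fits, `[[`, 0, "bic"),
                    row.names = NULL)
  best <- min(tab$bic)
  cand <- which(tab$bic <= best + 1e-9)
  if (length(cand) > 1L) {
    message("BIC tie between models ",
            paste(tab$model[cand], collapse = ", "), "; choosing smallest k")
    cand <- cand[which.min(tab$k[cand])]
  }
  structure(list(fits = fits, table = tab, selected = tab$model[cand]),
            class = "causal_selection")
}

#' @export
print.causal_selection <- function(x, ...) {
  print(transform(x$table, bic = round(bic, 3), loglik = round(loglik, 3)))
  cat("selected:", x$selected, "\n")
  invisible(x)
}

#' Path analysis: direct and indirect effects of pleiotropy
#'
#' On standardized data, fits `Pa = b1 * A + b2 * Pl + e` and
#' `A = b3 * Pl + e`. The direct effect of pleiotropy on parallelism is
#' `b2`; the indirect effect, routed through ancestral variation, is
#' `b1 * b3`. On standardized data `cor(Pl, Pa) = b2 + b1 * b3` exactly.
#' The indirect effect's confidence interval comes from a nonparametric
#' bootstrap over genes (percentile method).
#'
#' @param d a [build_causal_data()] table.
#' @param n_boot bootstrap resamples for the indirect-effect CI
#'   (default 1000; below 100 a warning is issued).
#' @param conf confidence level of the bootstrap interval (default 0.95).
#' @param seed optional RNG seed for the bootstrap.
#' @return A `path_fit` list: `beta1`, `beta2`, `beta3` (with standard
#'   errors), `direct`, `indirect`, `indirect_ci`, `n`, `n_boot`.
#' @export
path_analysis <- function(d, n_boot = 1000, conf = 0.95, seed = NULL) {
  if (n_boot < 100) warning("fewer than 100 bootstrap resamples")
  fit1 <- lm(Pa_std ~ A_std + Pl_std, data = d)
  fit2 <- lm(A_std ~ Pl_std, data = d)
  s1 <- summary(fit1)$coefficients
  s2 <- summary(fit2)$coefficients
  beta1 <- unname(coef(fit1)["A_std"]); beta2 <- unname(coef(fit1)["Pl_std"])
  beta3 <- unname(coef(fit2)["Pl_std"])
  boot <- with_seed(seed, {
    n <- nrow(d)
    replicate(n_boot, {
      idx <- sample.int(n, n, replace = TRUE)
      db <- d[idx, , drop = FALSE]
      b1 <- coef(lm(Pa_std ~ A_std + Pl_std, data = db))
      b3 <- coef(lm(A_std ~ Pl_std, data = db))["Pl_std"]
      unname(b1["A_std"] * b3)
    })
  })
  alpha <- (1 - conf) / 2
  structure(list(
    beta1 = beta1, beta2 = beta2, beta3 = beta3,
    se = c(beta1 = s1["A_std", "Std. Error"],
           beta2 = s1["Pl_std", "Std. Error"],
           beta3 = s2["Pl_std", "Std. Error"]),
    direct = beta2, indirect = beta1 * beta3,
    indirect_ci = unname(quantile(boot, c(alpha, 1 - alpha))),
    conf = conf, n = nrow(d), n_boot = n_boot),
    class = "path_fit")
}

#' @export
print.path_fit <- function(x, ...) {
  cat(sprintf("path analysis (n = %d genes)\n", x$n))
  cat(sprintf("  direct effect    b2        = %7.4f (SE %.4f)\n",
              x$direct, x$se["beta2"]))
  cat(sprintf("  indirect effect  b1 * b3   = %7.4f [%0.4f, %0.4f] (%d%% bootstrap)\n",
              x$indirect, x$indirect_ci[1], x$indirect_ci[2],
              round(100 * x$conf)))
  cat(sprintf("  coefficients: b1 = %.4f, b3 = %.4f\n", x$beta1, x$beta3))
  invisible(x)
}
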