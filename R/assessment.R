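#' Deviance of a parameter state
#'
#' `-2` times the Bernoulli log-likelihood of `Y` at the given state (cell
#' likelihoods floored at 1e-12).
#'
#' @inheritParams loglik_testlet
#' @export
deviance_testlet <- function(Y, params, design, model = "n2plt") {
  -2 * loglik_testlet(Y, params, design, model)
}

#' Deviance information criterion of a fitted model
#'
#' `DIC = D_bar + p_D` with `D_bar` the posterior mean deviance,
#' `p_D = D_bar - D_hat`, and `D_hat` the deviance at the posterior means of
#' *all* sampled quantities (item parameters, abilities, testlet effects) --
#' the conditional form of the criterion, since the person-level latents are
#' sampled parameters here.  Equivalently `DIC = 2 D_bar - D_hat`.  Smaller
#' is better.
#'
#' @param fit A `testlet_fit`.
#' @return One-row tibble: `model`, `DIC`, `D_bar`, `D_hat`, `p_D`,
#'   `log_cvpd`.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "testlet_fit"))
  D_bar <- mean(fit$deviance)
  at_mean <- list(a = fit$post_mean$a, b = fit$post_mean$b,
                  theta = fit$post_mean$theta, eta = fit$post_mean$eta)
  D_hat <- deviance_testlet(fit$Y, at_mean, fit$design,
                            c("2pl", "t2plt", "n2plt")[fit$model_code + 1])
  p_D <- D_bar - D_hat
  tibble(model = fit$model, DIC = D_bar + p_D, D_bar = D_bar, D_hat = D_hat,
         p_D = p_D, log_cvpd = log_cvpd_sum(fit))
}

#' Cross-validation predictive densities (harmonic-mean estimator)
#'
#' Per-cell estimate of `p(y_ij | y_without_that_cell)` from `M` posterior
#' draws: the inverse of the mean of the inverse per-draw cell likelihoods,
#' `[mean_m 1 / p(y_ij | state_m)]^-1` -- an importance-sampling identity, so
#' no refitting is needed.  Per-draw cell likelihoods are floored at 1e-12
#' before inversion, which bounds each term and prevents overflow.
#'
#' @param fit A `testlet_fit`.
#' @return An `n x J` matrix with entries in (0, 1].
#' @export
cvpd_matrix <- function(fit) {
  stopifnot(inherits(fit, "testlet_fit"))
  m <- 1 / fit$invlik_mean
  if (any(!is.finite(m)) || any(m <= 0))
    stop("invalid predictive-density estimate (zero cell likelihood)")
  m
}

#' @rdname cvpd_matrix
#' @export
log_cvpd_sum <- function(fit) {
  -sum(log(fit$invlik_mean))
}

#' Log pseudo-Bayes factor between two fitted models
#'
#' The log of the ratio of the products of cross-validation predictive
#' densities of two models fitted to the same data:
#' `sum log CVPD_A - sum log CVPD_B`.  Positive values support model A.
#'
#' @param fit_a,fit_b Two `testlet_fit` objects on the same response matrix.
#' @export
log_psbf <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "testlet_fit"), inherits(fit_b, "testlet_fit"))
  if (!all(dim(fit_a$Y) == dim(fit_b$Y)))
    stop_invalid("the two fits are not on the same data (shape mismatch)")
  log_cvpd_sum(fit_a) - log_cvpd_sum(fit_b)
}

#' Fit and rank competing testlet models
#'
#' Fits each requested model to the same data and tabulates DIC and the
#' summed log cross-validation predictive density.  The best model has the
#' smallest DIC and the largest log-CVPD; exact ties share a rank.
#'
#' @param Y Binary response matrix, or a named list of `testlet_fit` objects
#'   (in which case no fitting is done and the remaining fit arguments are
#'   ignored).
#' @param design A [testlet_design()]; unused when `Y` is a list of fits.
#' @param models Character vector of models to fit.
#' @param ... Passed to [fit_testlet()] (e.g. `iter`, `burnin`, `prior`).
#' @param seed Optional seed applied to the whole comparison.
#' @return A tibble with one row per model, ranked by DIC, with columns
#'   `model`, `DIC`, `D_bar`, `D_hat`, `p_D`, `log_cvpd`, `rank_dic`,
#'   `rank_cvpd`.
#' @export
compare_testlet_models <- function(Y, design = NULL,
                                   models = c("2pl", "t2plt", "n2plt"),
                                   ..., seed = NULL) {
  fits <- if (is.list(Y) && all(vapply(Y, inherits, logical(1), "testlet_fit")))
    Y
  else {
    run <- function() lapply(models, function(m)
      fit_testlet(Y, design, model = m, ...))
    setNames(if (is.null(seed)) run() else withr::with_seed(seed, run()),
             models)
  }
  out <- purrr::map_dfr(fits, dic)
  out$rank_dic <- rank(round(out$DIC, 8), ties.method = "min")
  out$rank_cvpd <- rank(round(-out$log_cvpd, 8), ties.method = "min")
  dplyr::arrange(out, .data$DIC)
}
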