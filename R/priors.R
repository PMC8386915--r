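#' Prior configuration for the slice-Gibbs sampler
#'
#' Item slopes get a positive-truncated normal prior `N(mu_a, sigma2_a) I(0,
#' Inf)` and difficulties a normal `N(mu_b, sigma2_b)`, or, alternatively, a
#' uniform prior on a finite support for both.  Under the normal family the
#' prior variances `sigma2_a`, `sigma2_b` and the testlet-effect variances
#' `sigma2_eta[k]` carry inverse-gamma hyperpriors `IG(v, tau)` and are updated
#' by their conjugate full conditionals; `sigma2_a`/`sigma2_b` updates can be
#' switched off to keep a fixed-variance prior.
#'
#' @param family `"normal"` (truncated-normal slope / normal difficulty) or
#'   `"uniform"`.
#' @param mu_a,mu_b,mu_eta Prior means (defaults 0).
#' @param sigma2_a,sigma2_b Initial (or fixed) prior variances.
#' @param update_sigma2 Update `sigma2_a`/`sigma2_b` by their inverse-gamma
#'   full conditionals?  Ignored (always off) for the uniform family.
#' @param v,tau Inverse-gamma hyperparameters, length 3: for `sigma2_a`,
#'   `sigma2_b` and `sigma2_eta` respectively (defaults 0.001).
#' @param a_support,b_support Supports for the uniform family.
#' @return A list of class `sliceirt_prior`.
#' @seealso [prior_type()] for the three stock prior specifications used in
#'   the prior-sensitivity study.
#' @export
prior_config <- function(family = c("normal", "uniform"),
                         mu_a = 0, mu_b = 0, mu_eta = 0,
                         sigma2_a = 100, sigma2_b = 100,
                         update_sigma2 = TRUE,
                         v = c(0.001, 0.001, 0.001),
                         tau = c(0.001, 0.001, 0.001),
                         a_support = c(0, 100),
                         b_support = c(-100, 100)) {
  family <- match.arg(family)
  v <- rep_len(as.numeric(v), 3)
  tau <- rep_len(as.numeric(tau), 3)
  if (any(v <= 0) || any(tau <= 0))
    stop_invalid("inverse-gamma hyperparameters must be strictly positive")
  if (sigma2_a <= 0 || sigma2_b <= 0)
    stop_invalid("prior variances must be strictly positive")
  if (family == "uniform") {
    if (!all(is.finite(c(a_support, b_support))) ||
        a_support[1] >= a_support[2] || b_support[1] >= b_support[2])
      stop_invalid("uniform prior bounds must be finite with lower < upper")
    if (a_support[1] < 0) a_support[1] <- 0
    update_sigma2 <- FALSE
  }
  structure(list(family = family, mu_a = mu_a, mu_b = mu_b, mu_eta = mu_eta,
                 sigma2_a = sigma2_a, sigma2_b = sigma2_b,
                 update_sigma2 = isTRUE(update_sigma2), v = v, tau = tau,
                 a_support = as.numeric(a_support),
                 b_support = as.numeric(b_support)),
            class = "sliceirt_prior")
}

#' Stock prior types for the prior-sensitivity study
#'
#' Type I: informative, slopes `N(0,1)I(0,Inf)`, difficulties `N(0,1)`.
#' Type II: noninformative, `N(0,100)` variants.  Type III: noninformative
#' uniform, slopes `U(0,100)` and difficulties on a symmetric support
#' `U(-100,100)`.  Types I and II keep the inverse-gamma updates of the prior
#' variances active (the stated variance is the chain's initial value); the
#' uniform family has no normal variance parameters to update.
#'
#' @param type `"I"`, `"II"` or `"III"`.
#' @return A [prior_config()].
#' @export
prior_type <- function(type = c("II", "I", "III")) {
  type <- match.arg(as.character(type), c("II", "I", "III"))
  switch(type,
    "I" = prior_config("normal", sigma2_a = 1, sigma2_b = 1),
    "II" = prior_config("normal", sigma2_a = 100, sigma2_b = 100),
    "III" = prior_config("uniform"))
}

as_prior <- function(prior) {
  if (inherits(prior, "sliceirt_prior")) return(prior)
  if (is.character(prior) && length(prior) == 1 &&
      prior %in% c("I", "II", "III")) return(prior_type(prior))
  stop_invalid("'prior' must be a prior_config() or a type label I/II/III")
}

# flatten for the C++ sampler
prior_cfg_list <- function(prior) {
  list(family = if (prior$family == "uniform") 1L else 0L,
       mu_a = prior$mu_a, mu_b = prior$mu_b, mu_eta = prior$mu_eta,
       v1 = prior$v[1], tau1 = prior$tau[1],
       v2 = prior$v[2], tau2 = prior$tau[2],
       v3 = prior$v[3], tau3 = prior$tau[3],
       unif_a_lo = prior$a_support[1], unif_a_hi = prior$a_support[2],
       unif_b_lo = prior$b_support[1], unif_b_hi = prior$b_support[2],
       update_s2a = prior$update_sigma2, update_s2b = prior$update_sigma2,
       update_s2eta = TRUE)
}
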