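#' Draw true parameters for a simulation condition
#'
#' Emulates the generating process of the simulation studies: slopes
#' `a_j ~ N(0,1)I(0, +Inf)` (standard normal truncated to the positive axis),
#' difficulties `b_j ~ N(0,1)`, abilities `theta_i ~ N(0,1)` and testlet
#' effects `eta_ik ~ N(0, sigma2_eta[k])`.  The identification constraints
#' are imposed on the truth itself: `a_1 = 1` and `b_1 = 0`, so that recovery
#' error for the fixed item is exactly zero.
#'
#' @param n Number of persons.
#' @param design A [testlet_design()].
#' @param sigma2_eta Testlet-effect variance(s); scalar or length `K`.
#' @param seed Optional integer seed.
#' @param identify Pin `a_1 = 1`, `b_1 = 0` (default TRUE).
#' @return List with `a`, `b`, `theta`, `eta` (`n x K`), `sigma2_eta`, plus
#'   the unit generating variances `sigma2_a = sigma2_b = 1`.
#' @export
sim_true_params <- function(n, design, sigma2_eta = 0.25, seed = NULL,
                            identify = TRUE) {
  design <- as_design(design)
  s2e <- rep_len(sigma2_eta, design$K)
  if (any(s2e < 0)) stop_invalid("sigma2_eta must be non-negative")
  draw <- function() {
    a <- abs(rnorm(design$J))
    b <- rnorm(design$J)
    if (identify) { a[1] <- 1; b[1] <- 0 }
    theta <- rnorm(n)
    eta <- matrix(rnorm(n * design$K, 0, rep(sqrt(s2e), each = n)),
                  n, design$K)
    list(a = a, b = b, theta = theta, eta = eta,
         sigma2_a = 1, sigma2_b = 1, sigma2_eta = s2e)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
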