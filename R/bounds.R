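# Auxiliary-variable machinery exposed for inspection and testing.  The
# sampler itself runs these computations in compiled code; the wrappers here
# call the same compiled bound routines on an explicit state.

#' Sample the uniform slice variables
#'
#' For every observed cell one auxiliary variable is drawn: where `y_ij = 1`,
#' `lambda_ij ~ Uniform(0, p_ij)`; where `y_ij = 0`,
#' `phi_ij ~ Uniform(0, q_ij)` with `q = 1 - p`.  The counterpart variable at
#' each cell is unused and returned as `NA`.
#'
#' @param Y Binary response matrix.
#' @param params Parameter state (`a`, `b`, `theta`, `eta`).
#' @param design A [testlet_design()].
#' @param model Model label.
#' @return List with matrices `lambda`, `phi` and the implied logit-scale
#'   thresholds `threshold` (`logit(lambda)` at `y = 1` cells,
#'   `logit(1 - phi)` at `y = 0` cells).
#' @export
sample_auxiliary <- function(Y, params, design, model = "n2plt") {
  Y <- as_response_matrix(Y)
  design <- as_design(design)
  P <- prob_matrix(params, design, model)
  U <- matrix(runif(length(P)), nrow(P), ncol(P))
  lambda <- ifelse(Y == 1L, U * P, NA_real_)
  phi <- ifelse(Y == 0L, U * (1 - P), NA_real_)
  threshold <- ifelse(Y == 1L, qlogis(lambda), qlogis(1 - phi))
  list(lambda = lambda, phi = phi, threshold = threshold)
}

aux_state <- function(Y, params, design, model, aux) {
  design <- as_design(design)
  eta <- params$eta %||% matrix(0, length(params$theta), design$K)
  list(Y = as_response_matrix(Y), it = design$assignment - 1L,
       code = model_code(model), a = params$a, b = params$b,
       theta = params$theta, eta = eta, tmat = aux$threshold)
}

#' Truncation bounds for the slice-Gibbs full conditionals
#'
#' Given the current state and auxiliary variables, these return the interval
#' to which the prior of one parameter is truncated so that every slice
#' indicator keeps holding.  `slice_bounds_a()` can optionally drop the
#' constraints contributed by the sibling items of the same testlet (which
#' arise under the `n2plt` model because the testlet discrimination
#' `alpha_d` contains `a_j`); the sampler always keeps them.
#'
#' @param j Item index (1-based); `i` person index; `k` testlet index.
#' @param Y Binary response matrix.
#' @param aux Auxiliary variables from [sample_auxiliary()].
#' @param params Parameter state (`a`, `b`, `theta`, `eta`).
#' @param design A [testlet_design()].
#' @param model Model label.
#' @param include_siblings Keep the sibling-cell constraints (default TRUE).
#' @return `c(lower, upper)`; for the slope the interval is already
#'   intersected with `(0, Inf)`.
#' @export
slice_bounds_a <- function(j, Y, aux, params, design, model = "n2plt",
                           include_siblings = TRUE) {
  s <- aux_state(Y, params, design, model, aux)
  b <- cpp_bounds("a", as.integer(j), 0L, s$Y, s$it, s$code, s$a, s$b,
                  s$theta, s$eta, s$tmat, isTRUE(include_siblings))
  c(lower = b[1], upper = b[2])
}

#' @rdname slice_bounds_a
#' @export
slice_bounds_b <- function(j, Y, aux, params, design, model = "n2plt") {
  s <- aux_state(Y, params, design, model, aux)
  b <- cpp_bounds("b", as.integer(j), 0L, s$Y, s$it, s$code, s$a, s$b,
                  s$theta, s$eta, s$tmat, TRUE)
  c(lower = b[1], upper = b[2])
}

#' @rdname slice_bounds_a
#' @param i Person index (1-based).
#' @export
slice_bounds_theta <- function(i, Y, aux, params, design, model = "n2plt") {
  s <- aux_state(Y, params, design, model, aux)
  b <- cpp_bounds("theta", as.integer(i), 0L, s$Y, s$it, s$code, s$a, s$b,
                  s$theta, s$eta, s$tmat, TRUE)
  c(lower = b[1], upper = b[2])
}

#' @rdname slice_bounds_a
#' @param k Testlet index (1-based).
#' @export
slice_bounds_eta <- function(i, k, Y, aux, params, design, model = "n2plt") {
  s <- aux_state(Y, params, design, model, aux)
  b <- cpp_bounds("eta", as.integer(i), as.integer(k), s$Y, s$it, s$code,
                  s$a, s$b, s$theta, s$eta, s$tmat, TRUE)
  c(lower = b[1], upper = b[2])
}

#' Truncated-normal random draws
#'
#' Inverse-CDF sampling on the normal-CDF scale with an exponential-rejection
#' fallback when the whole interval lies more than six standard deviations
#' into a tail (where the naive inverse CDF underflows).
#'
#' @param n Number of draws.
#' @param mean,sd Location and scale of the untruncated normal.
#' @param lower,upper Truncation bounds (may be infinite).
#' @export
rtruncnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  if (lower > upper) stop_invalid("lower > upper in rtruncnorm")
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  if (a >= 6 || b <= -6) {
    # delegate tail draws to the same compiled routine the sampler uses,
    # via one-at-a-time inverse sampling of the exponential proposal
    flip <- b <= -6
    if (flip) { tmp <- a; a <- -b; b <- -tmp }
    out <- vapply(seq_len(n), function(...) {
      repeat {
        x <- a + rexp(1, a)
        if (x <= b && runif(1) <= exp(-0.5 * (x - a)^2)) return(x)
      }
    }, numeric(1))
    if (flip) out <- -out
    return(mean + sd * out)
  }
  pa <- pnorm(a); pb <- pnorm(b)
  u <- runif(n, pa, pb)
  x <- qnorm(u)
  mean + sd * pmin(pmax(x, a), b)
}

#' Draw an item slope from its truncated prior
#'
#' Draws from the slope prior restricted to `[lower, upper]` intersected with
#' the prior support (`(0, Inf)` for the truncated-normal family, the finite
#' support for the uniform family).
#'
#' @param bounds `c(lower, upper)` from [slice_bounds_a()].
#' @param prior A [prior_config()].
#' @param n Number of draws.
#' @export
sample_item_slope <- function(bounds, prior = prior_config(), n = 1) {
  prior <- as_prior(prior)
  lo <- max(bounds[1], 0)
  hi <- bounds[2]
  if (prior$family == "uniform") {
    lo <- max(lo, prior$a_support[1]); hi <- min(hi, prior$a_support[2])
    if (lo > hi) stop_invalid("empty truncation interval")
    runif(n, lo, hi)
  } else {
    rtruncnorm(n, prior$mu_a, sqrt(prior$sigma2_a), lo, hi)
  }
}

#' Inverse-gamma draws and the conjugate variance updates
#'
#' `rinvgamma()` draws from the inverse-gamma distribution with density
#' proportional to `x^-(shape+1) exp(-scale/x)`.  `conj_variance_draw()`
#' performs the conjugate update shared by the three variance parameters:
#' given values `x` with prior mean `mu` and hyperprior `IG(v, tau)`, it
#' draws from `IG(length(x)/2 + v, sum((x - mu)^2)/2 + tau)`.
#'
#' @param n Number of draws.
#' @param shape,scale Inverse-gamma parameters.
#' @export
rinvgamma <- function(n, shape, scale) {
  scale / rgamma(n, shape = shape, rate = 1)
}

#' @rdname rinvgamma
#' @param x Current parameter values (e.g. the slope vector for `sigma2_a`,
#'   one testlet-effect column for `sigma2_eta[k]`).
#' @param mu Prior mean of `x`.
#' @param v,tau Inverse-gamma hyperparameters.
#' @export
conj_variance_draw <- function(x, mu = 0, v = 0.001, tau = 0.001, n = 1) {
  if (length(x) == 0) stop_invalid("empty parameter vector")
  rinvgamma(n, shape = length(x) / 2 + v, scale = sum((x - mu)^2) / 2 + tau)
}
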