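model_code <- function(model) {
  m <- tolower(as.character(model)[1])
  m <- sub("tm$", "t", sub("m$", "", m))      # accept 2plm, n2pltm, ...
  switch(m,
    "2pl" = 0L, "t2pl" = 1L, "t2plt" = 1L, "n2pl" = 2L, "n2plt" = 2L,
    stop_invalid("unknown model '%s' (use 2pl, t2plt or n2plt)", model))
}

model_label <- function(code) c("2PL", "T2PLTM", "N2PLTM")[code + 1L]

#' Testlet discrimination parameters
#'
#' The testlet discrimination of testlet `d` is the arithmetic mean of the
#' item slopes in that testlet, `alpha_d = sum_{j in S_d} a_j / n_d`.  It
#' loads the person-by-testlet random effect in the N2PLTM.
#'
#' @param a Positive item slopes, length `J`.
#' @param design A [testlet_design()] (or something coercible to one).
#' @return Numeric vector of length `K`.
#' @examples
#' testlet_discrimination(c(1, 3, 2, 2), testlet_design(c(1, 1, 2, 2)))
#' @export
testlet_discrimination <- function(a, design) {
  design <- as_design(design)
  if (length(a) != design$J)
    stop_invalid("length(a) = %d but the design has J = %d items",
                 length(a), design$J)
  if (any(a <= 0)) stop_invalid("all slopes must be strictly positive")
  vapply(design$sets, function(s) mean(a[s]), numeric(1))
}

#' Correct-response probability under the three models
#'
#' The linear predictor is `a (theta - b) + alpha eta` for the N2PLTM,
#' `a (theta - b + eta)` for the T2PLTM and `a (theta - b)` for the 2PL; the
#' probability is its logistic transform.  Arguments are recycled.
#'
#' @param model `"2pl"`, `"t2plt"` or `"n2plt"`.
#' @param theta Ability.
#' @param a Item slope, strictly positive.
#' @param b Item difficulty.
#' @param eta Person-by-testlet random effect (ignored by the 2PL).
#' @param alpha Testlet discrimination (required, positive, for the N2PLTM).
#' @return Probabilities strictly inside (0, 1).
#' @export
response_probability <- function(model, theta, a, b, eta = 0, alpha = NULL) {
  code <- model_code(model)
  if (any(a <= 0)) stop_invalid("item slopes must be strictly positive")
  z <- a * (theta - b)
  if (code == 1L) z <- z + a * eta
  if (code == 2L) {
    if (is.null(alpha)) stop_invalid("the n2plt model needs 'alpha'")
    if (any(alpha <= 0)) stop_invalid("'alpha' must be strictly positive")
    z <- z + alpha * eta
  }
  plogis(z)
}

prob_matrix <- function(params, design, model) {
  design <- as_design(design)
  code <- model_code(model)
  eta <- params$eta
  if (is.null(eta)) eta <- matrix(0, length(params$theta), design$K)
  cpp_prob_matrix(design$assignment - 1L, code, params$a, params$b,
                  params$theta, eta)
}

#' Simulate binary testlet responses
#'
#' Draws `y_ij ~ Bernoulli(p_ij)` independently given the parameters, with
#' `p_ij` from [response_probability()] under the chosen model.
#'
#' @param params List with `a`, `b` (length `J`), `theta` (length `n`) and
#'   `eta` (`n x K` matrix; optional, defaults to zero), e.g. from
#'   [sim_true_params()].
#' @param design A [testlet_design()].
#' @param model Model label; default `"n2plt"`.
#' @param seed Optional integer seed (the draw is reproducible given it).
#' @return Integer `n x J` matrix with columns `item1..itemJ`.
#' @export
sim_responses <- function(params, design, model = "n2plt", seed = NULL) {
  design <- as_design(design)
  check_params(params, design)
  P <- prob_matrix(params, design, model)
  draw <- function() {
    Y <- matrix(rbinom(length(P), 1L, P), nrow(P), ncol(P))
    dimnames(Y) <- list(NULL, paste0("item", seq_len(ncol(P))))
    storage.mode(Y) <- "integer"
    Y
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

check_params <- function(params, design) {
  J <- design$J
  if (length(params$a) != J || length(params$b) != J)
    stop_invalid("item parameter vectors must have length J = %d", J)
  if (any(params$a <= 0)) stop_invalid("slopes must be strictly positive")
  n <- length(params$theta)
  if (!is.null(params$eta)) {
    if (!is.matrix(params$eta) || nrow(params$eta) != n ||
        ncol(params$eta) != design$K)
      stop_invalid("eta must be an n x K matrix (%d x %d)", n, design$K)
  }
  invisible(TRUE)
}

#' Bernoulli log-likelihood of a response matrix
#'
#' `sum_ij [y log p + (1 - y) log(1 - p)]`, with cell likelihoods floored at
#' 1e-12 so the result is always finite.
#'
#' @inheritParams sim_responses
#' @param Y Binary response matrix (`n x J`).
#' @export
loglik_testlet <- function(Y, params, design, model = "n2plt") {
  design <- as_design(design)
  Y <- as_response_matrix(Y)
  check_params(params, design)
  if (ncol(Y) != design$J || nrow(Y) != length(params$theta))
    stop_invalid("response matrix is %d x %d but parameters imply %d x %d",
                 nrow(Y), ncol(Y), length(params$theta), design$J)
  eta <- params$eta
  if (is.null(eta)) eta <- matrix(0, nrow(Y), design$K)
  cpp_loglik(Y, design$assignment - 1L, model_code(model),
             params$a, params$b, params$theta, eta)
}

#' Log unnormalized joint posterior density
#'
#' The log of the product of the Bernoulli likelihood, the `N(0,1)` ability
#' prior, the (truncated-)normal item priors, the normal testlet-effect
#' priors and the inverse-gamma variance hyperpriors, up to an additive
#' constant.  This is the analytic target density the sampler must leave
#' invariant; it is exposed for use as a testing oracle.
#'
#' @inheritParams loglik_testlet
#' @param params Full parameter state: additionally `eta` (`n x K`),
#'   `sigma2_a`, `sigma2_b`, `sigma2_eta` (length `K`).
#' @param prior A [prior_config()] (normal family).
#' @return A finite number, or `-Inf` outside the support (`a <= 0` or any
#'   variance `<= 0`).
#' @export
log_unnorm_posterior <- function(params, Y, design, prior = prior_config(),
                                 model = "n2plt") {
  design <- as_design(design)
  Y <- as_response_matrix(Y)
  prior <- as_prior(prior)
  a <- params$a; b <- params$b; theta <- params$theta
  eta <- params$eta
  if (is.null(eta)) eta <- matrix(0, length(theta), design$K)
  s2a <- params$sigma2_a %||% prior$sigma2_a
  s2b <- params$sigma2_b %||% prior$sigma2_b
  s2e <- rep_len(params$sigma2_eta %||% 1, design$K)
  if (any(a <= 0) || s2a <= 0 || s2b <= 0 || any(s2e <= 0)) return(-Inf)
  ll <- loglik_testlet(Y, params, design, model)
  lp <- sum(dnorm(theta, 0, 1, log = TRUE))
  lp <- lp + sum(-(a - prior$mu_a)^2 / (2 * s2a)) - length(a) / 2 * log(s2a)
  lp <- lp + sum(-(b - prior$mu_b)^2 / (2 * s2b)) - length(b) / 2 * log(s2b)
  # inverse-gamma hyperpriors
  lp <- lp - (prior$v[1] + 1) * log(s2a) - prior$tau[1] / s2a
  lp <- lp - (prior$v[2] + 1) * log(s2b) - prior$tau[2] / s2b
  n <- nrow(Y)
  for (k in seq_len(design$K)) {
    lp <- lp + sum(dnorm(eta[, k], prior$mu_eta, sqrt(s2e[k]), log = TRUE))
    lp <- lp - (prior$v[3] + 1) * log(s2e[k]) - prior$tau[3] / s2e[k]
  }
  ll + lp
}

`%||%` <- function(x, y) if (is.null(x)) y else x
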