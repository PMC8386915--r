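par_names <- function(J, K, n, code, store_latent) {
  nm <- c(paste0("a[", seq_len(J), "]"), paste0("b[", seq_len(J), "]"),
          "sigma2_a", "sigma2_b")
  if (code != 0L) nm <- c(nm, paste0("sigma2_eta[", seq_len(K), "]"))
  if (store_latent) {
    nm <- c(nm, paste0("theta[", seq_len(n), "]"))
    if (code != 0L)
      nm <- c(nm, paste0("eta[", rep(seq_len(n), K), ",",
                         rep(seq_len(K), each = n), "]"))
  }
  nm
}

default_init <- function(J, K, n, prior) {
  list(a = rep(1, J), b = rep(0, J), theta = rep(0, n),
       eta = matrix(0, n, K), s2a = prior$sigma2_a, s2b = prior$sigma2_b,
       s2eta = rep(1, K))
}

# overdispersed starting values: defaults jittered by +/- 2 prior SDs
jitter_init <- function(init) {
  init$a <- pmax(0.05, init$a + runif(length(init$a), -2, 2))
  init$b <- init$b + runif(length(init$b), -2, 2)
  init$theta <- init$theta + runif(length(init$theta), -2, 2)
  init$eta <- init$eta + runif(length(init$eta), -2, 2)
  init
}

resolve_update <- function(update, J, identify) {
  upd <- list(a = rep(TRUE, J), b = rep(TRUE, J), theta = TRUE, eta = TRUE)
  if (!is.null(update)) {
    for (f in c("a", "b")) if (!is.null(update[[f]]))
      upd[[f]] <- rep_len(as.logical(update[[f]]), J)
    for (f in c("theta", "eta")) if (!is.null(update[[f]]))
      upd[[f]] <- isTRUE(update[[f]])
  }
  if (identify) { upd$a[1] <- FALSE; upd$b[1] <- FALSE }
  upd
}

#' Fit a testlet response model by slice-Gibbs sampling
#'
#' Runs the auxiliary-variable slice-Gibbs sampler: each sweep refreshes the
#' uniform slice variables (one per observed cell), then draws every item
#' slope, item difficulty, person ability and person-by-testlet effect from
#' its prior truncated to the interval on which all slice indicators hold,
#' and finally the variance parameters from their conjugate inverse-gamma
#' full conditionals.  No proposal is ever rejected.  Identification fixes
#' `a_1 = 1`, `b_1 = 0` and the ability prior at `N(0,1)`.
#'
#' @param Y Binary response matrix (`n x J`), a data frame of 0/1 columns, or
#'   a path readable by [read_responses()].
#' @param design A [testlet_design()] (or an assignment vector).
#' @param model `"n2plt"` (testlet-discrimination model), `"t2plt"`
#'   (random-effects testlet model) or `"2pl"`.
#' @param iter,burnin,thin Chain length, burn-in and thinning (defaults
#'   20000 / 10000 / 1).
#' @param chains Number of chains; chains after the first start from
#'   overdispersed (jittered) values unless `inits = "fixed"`.
#' @param seed Optional integer seed; the whole run is reproducible given it.
#' @param prior A [prior_config()] or a type label `"I"`, `"II"`, `"III"`.
#' @param inits `"overdispersed"` (default; chain 1 still starts at the
#'   neutral state) or `"fixed"`, or a named list giving explicit starting
#'   values (`a`, `b`, `theta`, `eta`, `s2a`, `s2b`, `s2eta`).
#' @param identify Impose `a_1 = 1`, `b_1 = 0` (default TRUE).
#' @param store_latent Keep the ability and testlet-effect draws in the
#'   returned chains (posterior means are always accumulated).
#' @param update Optional named list clamping parameter blocks, e.g.
#'   `list(b = c(FALSE, TRUE), theta = FALSE)`; clamped blocks keep their
#'   initial values.  Intended for debugging and validation.
#' @param debug 0 (off), 1 (audit the slice indicators after every sweep
#'   step) or 2 (after every single parameter draw; small problems only).
#' @return An object of class `testlet_fit`.
#' @export
fit_testlet <- function(Y, design, model = c("n2plt", "t2plt", "2pl"),
                        iter = 20000, burnin = 10000, thin = 1, chains = 1,
                        seed = NULL, prior = prior_config(),
                        inits = "overdispersed", identify = TRUE,
                        store_latent = FALSE, update = NULL, debug = 0) {
  if (is.character(Y) && length(Y) == 1) Y <- read_responses(Y)
  Y <- as_response_matrix(Y)
  design <- as_design(design)
  if (ncol(Y) != design$J)
    stop_invalid("response matrix has %d columns but the design has J = %d",
                 ncol(Y), design$J)
  code <- model_code(model[1])
  prior <- as_prior(prior)
  if (burnin >= iter) stop_invalid("burnin must be smaller than iter")
  if (chains < 1) stop_invalid("chains must be >= 1")
  if (all(Y == 1L) || all(Y == 0L))
    warning("degenerate response matrix: all responses identical")
  n <- nrow(Y); J <- ncol(Y); K <- design$K
  upd <- resolve_update(update, J, identify)
  ctrl <- list(upd_a = upd$a, upd_b = upd$b, upd_theta = upd$theta,
               upd_eta = upd$eta, store_latent = isTRUE(store_latent),
               debug = as.integer(debug))
  init0 <- default_init(J, K, n, prior)
  if (is.list(inits)) {
    for (f in names(inits)) init0[[f]] <- inits[[f]]
    inits_mode <- "fixed"
  } else inits_mode <- match.arg(inits, c("overdispersed", "fixed"))

  run_all <- function() {
    lapply(seq_len(chains), function(ch) {
      ini <- if (ch > 1 && inits_mode == "overdispersed") {
        ji <- jitter_init(init0)
        # clamped blocks (identification or user masks) keep their values
        ji$a[!upd$a] <- init0$a[!upd$a]
        ji$b[!upd$b] <- init0$b[!upd$b]
        if (!upd$theta) ji$theta <- init0$theta
        if (!upd$eta) ji$eta <- init0$eta
        ji
      } else init0
      res <- cpp_run_chain(Y, design$assignment - 1L, code,
                           as.integer(iter), as.integer(burnin),
                           as.integer(thin), prior_cfg_list(prior), ini, ctrl)
      colnames(res$draws) <- par_names(J, K, n, code, isTRUE(store_latent))
      res
    })
  }
  res <- if (is.null(seed)) run_all() else withr::with_seed(seed, run_all())

  n_stored <- sum(vapply(res, function(r) r$n_stored, numeric(1)))
  pm_names <- c("a", "b", "theta", "s2a", "s2b")
  post_mean <- lapply(setNames(pm_names, pm_names), function(f)
    Reduce(`+`, lapply(res, function(r) r$post_mean[[f]])) / chains)
  post_mean$eta <- Reduce(`+`, lapply(res, function(r) r$post_mean$eta)) /
    chains
  post_mean$s2eta <- Reduce(`+`, lapply(res, function(r) r$post_mean$s2eta)) /
    chains
  invlik_mean <- Reduce(`+`, lapply(res, function(r) r$invlik_mean)) / chains

  structure(list(
    draws = lapply(res, `[[`, "draws"),
    deviance = unlist(lapply(res, `[[`, "deviance"), use.names = FALSE),
    invlik_mean = invlik_mean,
    post_mean = post_mean,
    Y = Y, design = design, model = model_label(code), model_code = code,
    config = list(iter = iter, burnin = burnin, thin = thin, chains = chains,
                  seed = seed, prior = prior, inits = inits_mode,
                  identify = identify, store_latent = isTRUE(store_latent)),
    n_stored = n_stored,
    slice_checks = sum(vapply(res, function(r) r$checks_run, numeric(1))),
    slice_violations = sum(vapply(res, function(r) r$violations, numeric(1)))
  ), class = "testlet_fit")
}

#' @export
print.testlet_fit <- function(x, ...) {
  cat(sprintf("<testlet_fit> %s, n = %d persons x J = %d items, K = %d testlets\n",
              x$model, nrow(x$Y), ncol(x$Y), x$design$K))
  cat(sprintf("  %d chain(s), %d stored draws (iter %d, burn-in %d, thin %d)\n",
              x$config$chains, x$n_stored, x$config$iter, x$config$burnin,
              x$config$thin))
  g <- glance(x)
  cat(sprintf("  DIC = %.2f (p_D = %.1f), sum log CVPD = %.2f\n",
              g$DIC, g$p_D, g$log_cvpd))
  invisible(x)
}

# stack chains for one named parameter column
draw_matrix <- function(fit, parameter) {
  sapply(fit$draws, function(d) d[, parameter])
}

all_draws <- function(fit) do.call(rbind, fit$draws)

#' Posterior summary of a fitted testlet model
#'
#' One row per stored parameter: posterior mean (EAP), posterior SD, the
#' highest-posterior-density interval at `level`, and (for two or more
#' chains) the Gelman-Rubin potential scale reduction factor.
#'
#' @param object A `testlet_fit`.
#' @param level HPDI coverage (default 0.95).
#' @param ... Unused.
#' @return A tibble with columns `parameter`, `EAP`, `SD`, `hpdi_low`,
#'   `hpdi_high`, `rhat`.
#' @export
summary.testlet_fit <- function(object, level = 0.95, ...) {
  D <- all_draws(object)
  rh <- if (object$config$chains >= 2)
    vapply(colnames(D), function(p) psrf(draw_matrix(object, p)), numeric(1))
  else rep(NA_real_, ncol(D))
  purrr::map_dfr(seq_len(ncol(D)), function(i) {
    s <- posterior_summary(D[, i], level = level)
    tibble(parameter = colnames(D)[i], EAP = s$EAP, SD = s$SD,
           hpdi_low = s$hpdi[1], hpdi_high = s$hpdi[2], rhat = rh[i])
  })
}

#' @rdname summary.testlet_fit
#' @param x A `testlet_fit`.
#' @export
tidy.testlet_fit <- function(x, level = 0.95, ...) {
  s <- summary(x, level = level)
  tibble(term = s$parameter, estimate = s$EAP, std.error = s$SD,
         conf.low = s$hpdi_low, conf.high = s$hpdi_high, rhat = s$rhat)
}

#' One-row model-level summary (DIC, effective parameters, predictive fit)
#' @param x A `testlet_fit`.
#' @param ... Unused.
#' @export
glance.testlet_fit <- function(x, ...) {
  d <- dic(x)
  tibble(model = x$model, DIC = d$DIC, D_bar = d$D_bar, D_hat = d$D_hat,
         p_D = d$p_D, log_cvpd = d$log_cvpd,
         max_rhat = if (x$config$chains >= 2) max_psrf(x) else NA_real_,
         n_draws = x$n_stored)
}

#' Trace plots for a fitted testlet model
#'
#' @param object A `testlet_fit`.
#' @param pars Parameters to plot (default: up to 6 item parameters).
#' @param ... Unused.
#' @export
autoplot.testlet_fit <- function(object, pars = NULL, ...) {
  if (is.null(pars)) {
    nm <- colnames(object$draws[[1]])
    pars <- head(nm[grepl("^[ab]\\[", nm)], 6)
  }
  df <- purrr::map_dfr(seq_along(object$draws), function(ch) {
    d <- object$draws[[ch]][, pars, drop = FALSE]
    tibble(iteration = rep(seq_len(nrow(d)), length(pars)),
           chain = factor(ch),
           parameter = rep(pars, each = nrow(d)),
           value = as.vector(d))
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$value,
                                   colour = .data$chain)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "stored iteration", y = "draw") +
    ggplot2::theme_minimal()
}
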