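#' Bias and mean squared error over replications
#'
#' `bias()` is the mean of `estimates - truth`; `mse()` the mean of
#' `(estimates - truth)^2`.  `truth` may be a scalar or one value per
#' replication (when the truth is redrawn each replication).
#'
#' @param estimates Numeric vector of per-replication estimates.
#' @param truth True value(s).
#' @export
bias <- function(estimates, truth) {
  if (length(estimates) == 0) stop_invalid("no estimates supplied")
  mean(estimates - truth)
}

#' @rdname bias
#' @export
mse <- function(estimates, truth) {
  if (length(estimates) == 0) stop_invalid("no estimates supplied")
  mean((estimates - truth)^2)
}

# deterministic sub-seed for replication `rep`, attempt `attempt`
sub_seed <- function(base, rep, attempt = 1) {
  as.integer((as.numeric(base) %% 65011 * 33013 + rep * 9973 +
                attempt * 131) %% 2147483629 + 1)
}

# fit with deterministic re-seeding on numerical failure
fit_with_retry <- function(Y, design, seed, max_attempts = 3, ...) {
  for (att in seq_len(max_attempts)) {
    res <- tryCatch(fit_testlet(Y, design, seed = seed + att - 1L, ...),
                    error = function(e) e)
    if (!inherits(res, "error")) return(res)
    message(sprintf("fit attempt %d failed (%s); re-seeding", att,
                    conditionMessage(res)))
  }
  stop(res)
}

rep_truth_data <- function(rep, seed, n, design, sigma2_eta, redraw_truth,
                           fixed_truth) {
  truth <- if (redraw_truth)
    sim_true_params(n, design, sigma2_eta, seed = sub_seed(seed, rep, 2))
  else fixed_truth
  Y <- sim_responses(truth, design, "n2plt", seed = sub_seed(seed, rep, 3))
  list(truth = truth, Y = Y)
}

truth_vector <- function(truth, design) {
  c(setNames(truth$a, paste0("a[", seq_along(truth$a), "]")),
    setNames(truth$b, paste0("b[", seq_along(truth$b), "]")),
    sigma2_a = 1, sigma2_b = 1,
    setNames(rep_len(truth$sigma2_eta, design$K),
             paste0("sigma2_eta[", seq_len(design$K), "]")))
}

#' Parameter-recovery study
#'
#' Replicates the first simulation design: per replication, draw true
#' parameters (slopes half-normal, difficulties and abilities standard
#' normal, testlet effects `N(0, sigma2_eta)`), simulate responses from the
#' testlet-discrimination model, fit, and record the posterior means.  Bias
#' and MSE are then computed per parameter across replications.
#' Identification-fixed parameters (`a_1`, `b_1`) are recovered exactly by
#' construction and reported as exact zeros.
#'
#' @param n Persons per replication (500 by default).
#' @param design A [testlet_design()]; default 4 testlets of 5 items.
#' @param sigma2_eta True testlet-effect variance (default 0.25).
#' @param reps Number of replications `S` (default 25).
#' @param iter,burnin,chains Chain settings per fit (defaults 5000 / 2500 /
#'   1; single-chain estimation, since auditing convergence in every
#'   replication is impractical and the estimand is the posterior mean).
#' @param model Model to fit (default the generating `"n2plt"`).
#' @param prior Prior configuration (default: hierarchical normal family).
#' @param seed Base seed; every replication derives its own sub-seed.
#' @param redraw_truth Redraw the true parameters each replication (default
#'   TRUE); if FALSE one truth is drawn up front and shared.
#' @param progress Print one line per replication.
#' @return An object of class `recovery_study`: list with `estimates` (long
#'   tibble: rep, parameter, truth, estimate), `summary` (per parameter:
#'   bias, mse, fixed flag) and `condition`.
#' @export
run_recovery_study <- function(n = 500, design = testlet_design_blocks(4, 5),
                               sigma2_eta = 0.25, reps = 25,
                               iter = 5000, burnin = 2500, chains = 1,
                               model = "n2plt", prior = prior_config(),
                               seed = 1, redraw_truth = TRUE,
                               progress = FALSE) {
  design <- as_design(design)
  fixed_truth <- if (!redraw_truth)
    sim_true_params(n, design, sigma2_eta, seed = sub_seed(seed, 0, 2))
  else NULL
  est <- purrr::map_dfr(seq_len(reps), function(r) {
    td <- rep_truth_data(r, seed, n, design, sigma2_eta, redraw_truth,
                         fixed_truth)
    fit <- fit_with_retry(td$Y, design, seed = sub_seed(seed, r, 4),
                          model = model, iter = iter, burnin = burnin,
                          chains = chains, prior = prior)
    ev <- c(setNames(fit$post_mean$a, paste0("a[", seq_len(design$J), "]")),
            setNames(fit$post_mean$b, paste0("b[", seq_len(design$J), "]")),
            sigma2_a = fit$post_mean$s2a, sigma2_b = fit$post_mean$s2b,
            setNames(fit$post_mean$s2eta,
                     paste0("sigma2_eta[", seq_len(design$K), "]")))
    tv <- truth_vector(td$truth, design)
    if (progress) message(sprintf("replication %d/%d done", r, reps))
    tibble(rep = r, parameter = names(tv), truth = unname(tv),
           estimate = unname(ev[names(tv)]))
  })
  fixed_pars <- c("a[1]", "b[1]")
  summary <- est |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(bias = bias(.data$estimate, .data$truth),
                     mse = mse(.data$estimate, .data$truth),
                     .groups = "drop") |>
    dplyr::mutate(fixed = .data$parameter %in% fixed_pars,
                  bias = ifelse(.data$fixed, 0, .data$bias),
                  mse = ifelse(.data$fixed, 0, .data$mse))
  structure(list(estimates = est, summary = summary,
                 condition = list(n = n, design = design,
                                  sigma2_eta = sigma2_eta, reps = reps,
                                  iter = iter, burnin = burnin,
                                  chains = chains, seed = seed,
                                  redraw_truth = redraw_truth,
                                  model = model)),
            class = "recovery_study")
}

#' @export
print.recovery_study <- function(x, ...) {
  cn <- x$condition
  cat(sprintf("<recovery_study> N = %d, J = %d, K = %d, sigma2_eta = %s, S = %d\n",
              cn$n, cn$design$J, cn$design$K,
              paste(cn$sigma2_eta, collapse = "/"), cn$reps))
  print(x$summary, n = 12)
  invisible(x)
}

# mean over replications per item, then over the non-fixed items
item_averages <- function(summary_tbl, what = c("a", "b")) {
  what <- match.arg(what)
  pat <- paste0("^", what, "\\[")
  rows <- summary_tbl[grepl(pat, summary_tbl$parameter) & !summary_tbl$fixed, ]
  c(bias = mean(rows$bias), mse = mean(rows$mse))
}

#' Prior-sensitivity study
#'
#' Runs the recovery design once per prior type on *shared* datasets (the
#' truth and responses of replication `r` are identical across types, so the
#' comparison isolates the prior) and reports the average bias and MSE of
#' the item parameter estimates -- averaged over replications per item, then
#' over the non-identification-fixed items.
#'
#' @inheritParams run_recovery_study
#' @param types Prior types to compare (see [prior_type()]).
#' @param reps Replications per type (default 20).
#' @return Object of class `prior_study`: `summary` tibble (type, parameter
#'   class, bias, mse), plus the per-type `recovery_study` objects.
#' @export
run_prior_sensitivity_study <- function(types = c("I", "II", "III"), n = 500,
                                        design = testlet_design_blocks(4, 5),
                                        sigma2_eta = 0.25, reps = 20,
                                        iter = 5000, burnin = 2500,
                                        seed = 1, redraw_truth = TRUE,
                                        progress = FALSE) {
  design <- as_design(design)
  studies <- lapply(setNames(types, types), function(tp) {
    run_recovery_study(n = n, design = design, sigma2_eta = sigma2_eta,
                       reps = reps, iter = iter, burnin = burnin,
                       prior = prior_type(tp), seed = seed,
                       redraw_truth = redraw_truth, progress = progress)
  })
  summary <- purrr::map_dfr(types, function(tp) {
    s <- studies[[tp]]$summary
    dplyr::bind_rows(
      tibble(type = tp, parameter = "discrimination",
             bias = item_averages(s, "a")[["bias"]],
             mse = item_averages(s, "a")[["mse"]]),
      tibble(type = tp, parameter = "difficulty",
             bias = item_averages(s, "b")[["bias"]],
             mse = item_averages(s, "b")[["mse"]]))
  })
  structure(list(summary = summary, studies = studies),
            class = "prior_study")
}

#' @export
print.prior_study <- function(x, ...) {
  cat("<prior_study> average item-parameter bias/MSE by prior type\n")
  print(x$summary)
  invisible(x)
}

#' Model-selection study
#'
#' Generates data from the testlet-discrimination model and fits the three
#' competing models to every replication, recording DIC and the summed log
#' cross-validation predictive density; reports quartiles across
#' replications per model and criterion (inclusive empirical quantiles,
#' R type 7).
#'
#' @inheritParams run_recovery_study
#' @param models Models fitted to each replication.
#' @param reps Replications (default 10).
#' @return Object of class `selection_study`: `results` (rep x model tibble
#'   with DIC and log_cvpd) and `summary` (model x criterion quartiles).
#' @export
run_selection_study <- function(n = 500, design = testlet_design_blocks(4, 5),
                                sigma2_eta = 0.25, reps = 10,
                                models = c("2pl", "t2plt", "n2plt"),
                                iter = 5000, burnin = 2500, seed = 1,
                                redraw_truth = TRUE, prior = prior_config(),
                                progress = FALSE) {
  design <- as_design(design)
  fixed_truth <- if (!redraw_truth)
    sim_true_params(n, design, sigma2_eta, seed = sub_seed(seed, 0, 2))
  else NULL
  results <- purrr::map_dfr(seq_len(reps), function(r) {
    td <- rep_truth_data(r, seed, n, design, sigma2_eta, redraw_truth,
                         fixed_truth)
    purrr::map_dfr(seq_along(models), function(mi) {
      fit <- fit_with_retry(td$Y, design, seed = sub_seed(seed, r, 10 + mi),
                            model = models[mi], iter = iter, burnin = burnin,
                            chains = 1, prior = prior)
      if (progress)
        message(sprintf("replication %d/%d, %s done", r, reps, models[mi]))
      d <- dic(fit)
      tibble(rep = r, model = d$model, DIC = d$DIC, log_cvpd = d$log_cvpd)
    })
  })
  quartiles <- function(x) {
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    tibble(q1 = q[1], median = q[2], q3 = q[3], iqr = q[3] - q[1])
  }
  summary <- results |>
    tidyr::pivot_longer(c("DIC", "log_cvpd"), names_to = "criterion") |>
    dplyr::group_by(.data$model, .data$criterion) |>
    dplyr::reframe(quartiles(.data$value))
  structure(list(results = results, summary = summary,
                 condition = list(n = n, design = design,
                                  sigma2_eta = sigma2_eta, reps = reps,
                                  iter = iter, burnin = burnin, seed = seed,
                                  models = models)),
            class = "selection_study")
}

#' @export
print.selection_study <- function(x, ...) {
  cat(sprintf("<selection_study> %d replications; true model N2PLTM\n",
              x$condition$reps))
  print(x$summary)
  invisible(x)
}

#' @export
autoplot.recovery_study <- function(object, ...) {
  s <- dplyr::filter(object$summary, !.data$fixed,
                     grepl("^[ab]\\[", .data$parameter))
  s$class <- ifelse(grepl("^a", s$parameter), "slope a", "difficulty b")
  long <- tidyr::pivot_longer(s, c("bias", "mse"), names_to = "measure")
  ggplot2::ggplot(long, ggplot2::aes(.data$parameter, .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(measure ~ class, scales = "free") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90)) +
    ggplot2::labs(x = NULL, y = NULL)
}

#' @export
autoplot.selection_study <- function(object, ...) {
  long <- tidyr::pivot_longer(object$results, c("DIC", "log_cvpd"),
                              names_to = "criterion")
  ggplot2::ggplot(long, ggplot2::aes(.data$model, .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~criterion, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL)
}
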