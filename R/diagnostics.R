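#' Gelman-Rubin potential scale reduction factor
#'
#' Classic PSRF point estimate for a scalar parameter traced by `M >= 2`
#' chains of equal length `T`:
#' `Rhat = sqrt(((T-1)/T * W + B/T) / W)` with `W` the mean within-chain
#' variance and `B = T * var(chain means)`.  Chains that are all constant and
#' equal return 1 by convention.  Values near 1 indicate convergence; the
#' usual working threshold is `Rhat < 1.1`.
#'
#' @param x A `T x M` matrix (one column per chain) or a list of equal-length
#'   numeric vectors.
#' @return The PSRF point estimate.
#' @export
psrf <- function(x) {
  if (is.list(x)) {
    len <- unique(lengths(x))
    if (length(len) != 1) stop_invalid("chains must have equal lengths")
    x <- do.call(cbind, x)
  }
  x <- as.matrix(x)
  M <- ncol(x); T_ <- nrow(x)
  if (M < 2) stop_invalid("the PSRF needs at least two chains")
  if (T_ < 2) stop_invalid("the PSRF needs at least two draws per chain")
  W <- mean(apply(x, 2, var))
  B <- T_ * var(colMeans(x))
  if (W == 0) {
    if (B == 0) return(1.0)
    return(Inf)
  }
  sqrt(((T_ - 1) / T_ * W + B / T_) / W)
}

#' Per-parameter PSRF for a multi-chain fit
#' @param fit A `testlet_fit` with at least two chains.
#' @return Tibble with columns `parameter`, `rhat`.
#' @export
psrf_all <- function(fit) {
  if (fit$config$chains < 2)
    stop_invalid("convergence diagnostic needs at least two chains")
  nm <- colnames(fit$draws[[1]])
  tibble(parameter = nm,
         rhat = vapply(nm, function(p) psrf(draw_matrix(fit, p)), numeric(1)))
}

#' @rdname psrf_all
#' @export
max_psrf <- function(fit) max(psrf_all(fit)$rhat)

#' Highest posterior density interval
#'
#' The shortest contiguous interval of the sorted draws containing a
#' `level` fraction of them.
#'
#' @param x Numeric draws.
#' @param level Coverage (default 0.95).
#' @return `c(lower, upper)`.
#' @export
hpdi <- function(x, level = 0.95) {
  x <- sort(x)
  n <- length(x)
  m <- ceiling(level * n)
  if (m >= n) return(c(x[1], x[n]))
  widths <- x[m:n] - x[1:(n - m + 1)]
  i <- which.min(widths)
  c(x[i], x[i + m - 1])
}

#' Posterior summary for a scalar parameter
#'
#' @param x At least 100 posterior draws.
#' @param level HPDI coverage.
#' @return List with `EAP` (posterior mean), `SD` and `hpdi`.
#' @export
posterior_summary <- function(x, level = 0.95) {
  if (length(x) < 100)
    stop_invalid("posterior summary needs at least 100 draws, got %d",
                 length(x))
  list(EAP = mean(x), SD = sd(x), hpdi = hpdi(x, level))
}
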