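#' Coerce to a validated binary response matrix
#'
#' @param x Matrix or data frame; every cell must be 0 or 1 and nothing may
#'   be missing.  Errors name the offending row and column.
#' @return Integer matrix with item column names.
#' @export
as_response_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) stop_invalid("responses must be a matrix or data frame")
  if (is.character(x)) {
    suppressWarnings(storage.mode(x) <- "numeric")
  }
  bad <- which(is.na(x) | !(x == 0 | x == 1), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_invalid("non-binary or missing response at row %d, column %d",
                 bad[1, 1], bad[1, 2])
  storage.mode(x) <- "integer"
  if (is.null(colnames(x))) colnames(x) <- paste0("item", seq_len(ncol(x)))
  rownames(x) <- NULL
  x
}

#' Read / write a binary response matrix (CSV)
#'
#' Comma-separated UTF-8 with a mandatory header row of item labels, one row
#' per person, cells 0/1.
#'
#' @param path File path.
#' @export
read_responses <- function(path) {
  if (!file.exists(path)) stop_invalid("response file not found: %s", path)
  nf <- utils::count.fields(path, sep = ",")
  if (length(unique(nf)) > 1)
    stop_invalid("ragged rows in %s (row %d has %d fields, expected %d)",
                 path, which(nf != nf[1])[1], nf[nf != nf[1]][1], nf[1])
  df <- read.csv(path, header = TRUE, check.names = FALSE)
  as_response_matrix(df)
}

#' @rdname read_responses
#' @param Y Binary response matrix.
#' @export
write_responses <- function(Y, path) {
  Y <- as_response_matrix(Y)
  write.csv(as.data.frame(Y), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

prior_as_list <- function(prior) {
  unclass(prior)
}

#' Persist a fitted model to a directory
#'
#' Writes one CSV of stored draws per chain (columns are parameter labels),
#' the per-draw deviances, the cross-validation predictive-density matrix
#' and a JSON manifest (seed, configuration, design, design hash, package
#' version, timestamps, chain file names, assessment summary).
#'
#' @param fit A `testlet_fit`.
#' @param dir Output directory (created if needed).
#' @export
write_fit <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  chain_files <- sprintf("draws_chain%d.csv", seq_along(fit$draws))
  for (ch in seq_along(fit$draws))
    write.csv(as.data.frame(fit$draws[[ch]]), file.path(dir, chain_files[ch]),
              row.names = FALSE, quote = FALSE)
  write.csv(data.frame(deviance = fit$deviance),
            file.path(dir, "deviance.csv"), row.names = FALSE)
  write.csv(as.data.frame(cvpd_matrix(fit)), file.path(dir, "cvpd.csv"),
            row.names = FALSE, quote = FALSE)
  manifest <- list(
    package = "sliceirt",
    version = as.character(utils::packageVersion("sliceirt")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    model = fit$model,
    seed = fit$config$seed,
    config = fit$config[c("iter", "burnin", "thin", "chains", "inits",
                          "identify", "store_latent")],
    prior = prior_as_list(fit$config$prior),
    design = list(assignment = fit$design$assignment,
                  hash = rlang::hash(fit$design$assignment)),
    n_persons = nrow(fit$Y), n_items = ncol(fit$Y),
    chain_files = chain_files,
    assessment = as.list(dic(fit)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read back a persisted fit directory
#'
#' @param dir Directory written by [write_fit()].
#' @return List with `draws` (list of matrices) and `manifest`.
#' @export
read_fit_dir <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop_invalid("no manifest.json in %s", dir)
  manifest <- jsonlite::fromJSON(mf, simplifyVector = TRUE)
  draws <- lapply(file.path(dir, manifest$chain_files), function(f) {
    as.matrix(read.csv(f, check.names = FALSE))
  })
  list(draws = draws, manifest = manifest)
}
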