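#' Testlet design
#'
#' A testlet design partitions the `J` items of a test into `K` mutually
#' exclusive and exhaustive testlets (bundles of items sharing a common
#' stimulus).  Items and testlets are indexed from 1.
#'
#' @param assignment Either an integer vector of length `J` giving the testlet
#'   of each item (values must be `1..K` with every testlet non-empty), or a
#'   list of integer vectors, one per testlet, whose elements are 1-based item
#'   indices partitioning `1..J`.
#' @return An object of class `testlet_design` with fields `J`, `K`,
#'   `assignment` (item -> testlet), `sets` (testlet -> items) and `sizes`.
#' @examples
#' testlet_design(rep(1:4, each = 5))
#' testlet_design(list(1:2, 3:4))
#' @export
testlet_design <- function(assignment) {
  if (is.list(assignment)) {
    sets <- lapply(assignment, function(x) as.integer(x))
    items <- unlist(sets, use.names = FALSE)
    J <- length(items)
    if (J == 0) stop_invalid("design contains no items")
    dup <- unique(items[duplicated(items)])
    if (length(dup) > 0)
      stop_invalid("items assigned to more than one testlet: %s",
                   paste(sort(dup), collapse = ", "))
    missing <- setdiff(seq_len(J), items)
    if (length(missing) > 0)
      stop_invalid("items missing from the design: %s",
                   paste(missing, collapse = ", "))
    assignment <- integer(J)
    for (k in seq_along(sets)) assignment[sets[[k]]] <- k
  } else {
    assignment <- as.integer(assignment)
    J <- length(assignment)
    if (J == 0) stop_invalid("design contains no items")
    if (anyNA(assignment)) stop_invalid("design contains missing assignments")
    K <- max(assignment)
    if (min(assignment) < 1 || !all(seq_len(K) %in% assignment))
      stop_invalid("testlet labels must be 1..K with every testlet non-empty")
  }
  K <- max(assignment)
  sets <- split(seq_len(J), assignment)
  names(sets) <- NULL
  structure(
    list(J = J, K = K, assignment = assignment,
         sets = sets, sizes = vapply(sets, length, integer(1))),
    class = "testlet_design")
}

#' Convenience constructor: K testlets of equal size in item order
#' @param n_testlets Number of testlets.
#' @param items_each Items per testlet.
#' @export
testlet_design_blocks <- function(n_testlets, items_each) {
  testlet_design(rep(seq_len(n_testlets), each = items_each))
}

#' @export
print.testlet_design <- function(x, ...) {
  cat(sprintf("<testlet_design> J = %d items in K = %d testlets (sizes: %s)\n",
              x$J, x$K, paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' @export
format.testlet_design <- function(x, ...) {
  sprintf("testlet_design(J=%d, K=%d)", x$J, x$K)
}

as_design <- function(design) {
  if (inherits(design, "testlet_design")) return(design)
  testlet_design(design)
}

#' Read a testlet design from JSON
#'
#' The file format is `{"testlets": {"1": [1,2,...], "2": [...]}}` with
#' 1-based item indices; testlet keys are taken in numeric order.
#'
#' @param path Path to a JSON design file.
#' @return A [testlet_design()].
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop_invalid("design file not found: %s", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(obj$testlets)) stop_invalid("design file lacks a 'testlets' field")
  keys <- names(obj$testlets)
  ord <- order(suppressWarnings(as.numeric(keys)))
  if (anyNA(suppressWarnings(as.numeric(keys))))
    stop_invalid("testlet keys must be numeric, got: %s",
                 paste(keys, collapse = ", "))
  sets <- lapply(obj$testlets[ord], as.integer)
  testlet_design(sets)
}

#' Write a testlet design to JSON
#' @param design A [testlet_design()].
#' @param path Output path.
#' @export
write_design <- function(design, path) {
  design <- as_design(design)
  sets <- design$sets
  names(sets) <- as.character(seq_along(sets))
  jsonlite::write_json(list(testlets = sets), path, auto_unbox = FALSE)
  invisible(path)
}
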