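#' Construct a case-crossover dataset
#'
#' A case-crossover dataset holds, for each case, the binary exposure status
#' at the case period (period \code{m = 0}) and at \code{M} earlier control
#' periods (\code{m = 1, ..., M}, counted backward in time), optionally
#' together with a binary time-varying confounder measured on the same
#' periods.  A positive integer multiplicity attached to each case records
#' how many identical cases the row represents; all estimators treat it as a
#' frequency weight, which lets deterministic expected-count simulations emit
#' one row per distinct history.
#'
#' @param exposure integer or numeric matrix of 0/1 values with one row per
#'   case and \code{M + 1} columns; column 1 is the case period (\code{m = 0}),
#'   column \code{m + 1} the m-th control period.  A single history may be
#'   given as a vector.
#' @param confounder optional 0/1 matrix of the same dimensions carrying the
#'   time-varying confounder.
#' @param multiplicity positive integer vector (recycled) of frequency
#'   weights, one per case.
#' @param case_id optional vector of case identifiers; defaults to
#'   \code{"case_1", ...} in row order.
#' @return An object of class \code{"cc_data"}: a list with elements
#'   \code{exposure}, \code{confounder} (or \code{NULL}), \code{multiplicity},
#'   \code{case_id} and \code{M}.
#' @examples
#' d <- cc_data(rbind(c(1, 0, 1), c(0, 1, 0), c(1, 0, 0)))
#' d
#' cc_discordance(d)
#' @seealso [read_cc_data()], [cc_discordance()], [cc_fit()]
#' @export
cc_data <- function(exposure, confounder = NULL, multiplicity = 1L,
                    case_id = NULL) {
  if (is.null(dim(exposure))) exposure <- matrix(exposure, nrow = 1L)
  exposure <- as.matrix(exposure)
  storage.mode(exposure) <- "integer"
  if (ncol(exposure) < 2L)
    stop("each case needs at least two periods (M + 1 >= 2)", call. = FALSE)
  if (any(is.na(exposure)) || !all(exposure %in% c(0L, 1L)))
    stop("exposure values must all be 0 or 1", call. = FALSE)
  n <- nrow(exposure)
  if (!is.null(confounder)) {
    if (is.null(dim(confounder))) confounder <- matrix(confounder, nrow = 1L)
    confounder <- as.matrix(confounder)
    storage.mode(confounder) <- "integer"
    if (!identical(dim(confounder), dim(exposure)))
      stop("confounder must have the same dimensions as exposure",
           call. = FALSE)
    if (any(is.na(confounder)) || !all(confounder %in% c(0L, 1L)))
      stop("confounder values must all be 0 or 1", call. = FALSE)
  }
  multiplicity <- rep_len(as.integer(multiplicity), n)
  if (any(is.na(multiplicity)) || any(multiplicity < 1L))
    stop("multiplicity must be a positive integer for every case",
         call. = FALSE)
  if (is.null(case_id)) case_id <- paste0("case_", seq_len(n))
  case_id <- as.character(case_id)
  if (length(case_id) != n || anyDuplicated(case_id))
    stop("case_id must be unique, one per case", call. = FALSE)
  dimnames(exposure) <- NULL
  if (!is.null(confounder)) dimnames(confounder) <- NULL
  structure(
    list(exposure = exposure, confounder = confounder,
         multiplicity = multiplicity, case_id = case_id,
         M = ncol(exposure) - 1L),
    class = "cc_data"
  )
}

#' @export
print.cc_data <- function(x, ...) {
  cat(sprintf(
    "Case-crossover dataset: %d case histories (%d cases), M = %d control periods%s\n",
    nrow(x$exposure), sum(x$multiplicity), x$M,
    if (is.null(x$confounder)) "" else ", with time-varying confounder"))
  invisible(x)
}

#' @export
dim.cc_data <- function(x) dim(x$exposure)

n_cases <- function(x) sum(x$multiplicity)

has_confounder <- function(x) !is.null(x$confounder)

#' Convert a case-crossover dataset to long format
#'
#' One row per (case, period), ordered by case then period, with columns
#' \code{case_id}, \code{period}, \code{exposure}, optionally
#' \code{confounder}, and \code{multiplicity}.
#'
#' @param x a [cc_data] object.
#' @param row.names,optional,... passed on conventions of the generic; unused.
#' @return A data frame in the long layout used by [write_cc_data()].
#' @export
as.data.frame.cc_data <- function(x, row.names = NULL, optional = FALSE, ...) {
  n <- nrow(x$exposure)
  p <- x$M + 1L
  out <- data.frame(
    case_id = rep(x$case_id, each = p),
    period = rep.int(0:x$M, n),
    exposure = as.integer(t(x$exposure)),
    stringsAsFactors = FALSE
  )
  if (!is.null(x$confounder)) out$confounder <- as.integer(t(x$confounder))
  out$multiplicity <- rep(x$multiplicity, each = p)
  out
}

#' Read a case-crossover dataset from delimited text
#'
#' The file must be a delimited table with a header and columns
#' \code{case_id}, \code{period}, \code{exposure}, optionally
#' \code{confounder} and \code{multiplicity}.  Every case must cover periods
#' \code{0..M} exactly once, with \code{M} common to all cases; exposure and
#' confounder values must be 0/1.  Rows may appear in any order; cases are
#' ordered by first appearance and periods by index.
#'
#' @param path file path.
#' @param sep field separator (default comma).
#' @return A [cc_data] object.
#' @export
read_cc_data <- function(path, sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", strip.white = TRUE)
  need <- c("case_id", "period", "exposure")
  if (!all(need %in% names(raw)))
    stop("input must have columns case_id, period, exposure", call. = FALSE)
  raw$period <- suppressWarnings(as.integer(raw$period))
  raw$exposure <- suppressWarnings(as.integer(raw$exposure))
  if (any(is.na(raw$period)) || any(is.na(raw$exposure)))
    stop("period and exposure must be integers", call. = FALSE)
  ids <- unique(raw$case_id)
  M <- max(raw$period)
  p <- M + 1L
  exp_mat <- matrix(NA_integer_, length(ids), p)
  conf_mat <- if ("confounder" %in% names(raw)) {
    raw$confounder <- suppressWarnings(as.integer(raw$confounder))
    matrix(NA_integer_, length(ids), p)
  }
  mult <- rep(1L, length(ids))
  idx <- match(raw$case_id, ids)
  for (k in seq_along(ids)) {
    rows <- raw[idx == k, , drop = FALSE]
    if (anyDuplicated(rows$period))
      stop(sprintf("case '%s' has duplicated periods", ids[k]), call. = FALSE)
    if (!setequal(rows$period, 0:M))
      stop(sprintf("case '%s' does not cover periods 0..%d exactly once",
                   ids[k], M), call. = FALSE)
    ord <- order(rows$period)
    exp_mat[k, ] <- rows$exposure[ord]
    if (!is.null(conf_mat)) conf_mat[k, ] <- rows$confounder[ord]
    if ("multiplicity" %in% names(rows)) {
      m <- unique(suppressWarnings(as.integer(rows$multiplicity)))
      if (length(m) != 1L || is.na(m))
        stop(sprintf("case '%s' has inconsistent multiplicity", ids[k]),
             call. = FALSE)
      mult[k] <- m
    }
  }
  bad <- which(!apply(exp_mat, 1L, function(r) all(r %in% c(0L, 1L))))
  if (length(bad))
    stop(sprintf("case '%s' has non-binary exposure values", ids[bad[1L]]),
         call. = FALSE)
  if (!is.null(conf_mat)) {
    bad <- which(!apply(conf_mat, 1L, function(r) all(r %in% c(0L, 1L))))
    if (length(bad))
      stop(sprintf("case '%s' has non-binary confounder values", ids[bad[1L]]),
           call. = FALSE)
  }
  cc_data(exp_mat, conf_mat, mult, ids)
}

#' Write a case-crossover dataset as CSV
#'
#' Writes the long layout read back by [read_cc_data()]; the round trip
#' preserves every history exactly.
#'
#' @param x a [cc_data] object.
#' @param path output file path.
#' @param sep field separator.
#' @return \code{path}, invisibly.
#' @export
write_cc_data <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "cc_data"))
  utils::write.table(as.data.frame(x), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# expand frequency-weighted rows into one row index per case
expand_index <- function(x) rep(seq_len(nrow(x$exposure)), x$multiplicity)

# rebuild a dataset from per-row resample counts (zero-count rows dropped)
reweight_cc_data <- function(x, counts) {
  keep <- counts > 0L
  cc_data(x$exposure[keep, , drop = FALSE],
          if (!is.null(x$confounder)) x$confounder[keep, , drop = FALSE],
          counts[keep],
          x$case_id[keep])
}

# subset rows of a cc_data, keeping multiplicities
subset_cc_data <- function(x, keep) {
  cc_data(x$exposure[keep, , drop = FALSE],
          if (!is.null(x$confounder)) x$confounder[keep, , drop = FALSE],
          x$multiplicity[keep],
          x$case_id[keep])
}
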