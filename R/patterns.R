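#' Exposure-sequence probability table
#'
#' A sparse map from full exposure sequences (strings over \{0,1\}, read
#' case period first) to population probabilities, as required by the
#' Vines-Farrington estimator.  Sequences absent from the table have
#' probability zero.  Tables need not sum to one: only probability ratios
#' enter the likelihood, so sub-normalised tables are accepted.
#'
#' @param sequence character vector of 0/1 strings, all the same length.
#' @param probability nonnegative numeric vector, same length.
#' @return An object of class \code{"cc_patterns"}: a data frame with
#'   columns \code{sequence} and \code{probability}.
#' @examples
#' cc_patterns(c("1101", "1011", "0110"), rep(1 / 3, 3))
#' @seealso [cc_pattern_table()] to derive a table from a simulated
#'   population, [read_cc_patterns()] for the CSV form.
#' @export
cc_patterns <- function(sequence, probability) {
  sequence <- as.character(sequence)
  probability <- as.numeric(probability)
  if (length(sequence) != length(probability) || length(sequence) == 0L)
    stop("sequence and probability must be nonempty and equal length",
         call. = FALSE)
  if (anyDuplicated(sequence))
    stop("duplicated sequences in pattern table", call. = FALSE)
  if (length(unique(nchar(sequence))) != 1L)
    stop("all sequences must have the same length", call. = FALSE)
  if (!all(grepl("^[01]+$", sequence)))
    stop("sequences must be strings over {0,1}", call. = FALSE)
  if (any(is.na(probability)) || any(probability < 0))
    stop("probabilities must be nonnegative", call. = FALSE)
  if (sum(probability) > 1 + 1e-8)
    stop("probabilities sum to more than 1", call. = FALSE)
  structure(
    data.frame(sequence = sequence, probability = probability,
               stringsAsFactors = FALSE),
    class = c("cc_patterns", "data.frame")
  )
}

#' @export
print.cc_patterns <- function(x, ...) {
  cat(sprintf("Exposure-sequence probability table: %d sequences of length %d (total mass %.4g)\n",
              nrow(x), nchar(x$sequence[1L]), sum(x$probability)))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Read / write a pattern probability table
#'
#' CSV with header \code{sequence,probability}; sequences are strings over
#' \{0,1\}, case period first.
#'
#' @param path file path.
#' @return [read_cc_patterns()] returns a [cc_patterns] object;
#'   \code{write_cc_patterns} returns \code{path} invisibly.
#' @export
read_cc_patterns <- function(path) {
  raw <- utils::read.csv(path, colClasses = c("character", "numeric"),
                         strip.white = TRUE)
  if (!all(c("sequence", "probability") %in% names(raw)))
    stop("pattern file must have columns sequence, probability",
         call. = FALSE)
  cc_patterns(raw$sequence, raw$probability)
}

#' @rdname read_cc_patterns
#' @param x a [cc_patterns] object.
#' @export
write_cc_patterns <- function(x, path) {
  stopifnot(inherits(x, "cc_patterns"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# pattern table for iid Bernoulli(p) exposure: global exchangeability
iid_patterns <- function(n_periods, p = 0.5) {
  grid <- as.matrix(expand.grid(rep(list(0:1), n_periods)))
  seqs <- apply(grid, 1L, paste, collapse = "")
  k <- rowSums(grid)
  cc_patterns(seqs, p^k * (1 - p)^(n_periods - k))
}
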