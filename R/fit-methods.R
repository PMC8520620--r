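method_label <- function(m)
  switch(m,
         scl = "standard conditional logistic regression",
         greenland = "weighting method (weighted Greenland likelihood)",
         mh = "Mantel-Haenszel",
         vf = "Vines-Farrington (permutation probabilities)")

#' @export
print.cc_fit <- function(x, digits = 3L, ...) {
  cat(sprintf("Case-crossover fit: %s\n", method_label(x$method)))
  est <- exp(x$coefficients)
  names(est) <- sub("exposure", "OR(exposure)", names(est))
  names(est) <- sub("confounder", "OR(confounder)", names(est))
  for (i in seq_along(est)) {
    term <- rownames(x$ci)[i]
    if (!is.null(term) && !is.na(term) && i <= nrow(x$ci)) {
      cat(sprintf("  %s = %.*f  [%.*f, %.*f] (%s, %g%%)\n",
                  names(est)[i], digits, est[i], digits, x$ci[i, 1L],
                  digits, x$ci[i, 2L], x$ci_kind, 100 * x$conf_level))
    } else {
      cat(sprintf("  %s = %.*f\n", names(est)[i], digits, est[i]))
    }
  }
  cat(sprintf("  informative cases: %d (%d dropped)\n",
              x$n_informative, x$n_dropped))
  if (!is.null(x$pi10))
    cat(sprintf("  pi10 = %.*f\n", digits, x$pi10))
  if (!x$converged) cat("  WARNING: fit did not converge\n")
  for (d in x$diagnostics) cat("  note:", d, "\n")
  invisible(x)
}

#' @export
coef.cc_fit <- function(object, ...) object$coefficients

#' @export
vcov.cc_fit <- function(object, ...) object$vcov

#' @export
confint.cc_fit <- function(object, parm, level = NULL, ...) {
  # on the log-odds-ratio scale, consistent with coef()
  ci <- log(object$ci)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
summary.cc_fit <- function(object, ...) {
  terms <- names(object$coefficients)
  tab <- data.frame(
    term = terms,
    log_or = unname(object$coefficients),
    or = exp(unname(object$coefficients)),
    se = if (!is.null(object$vcov)) sqrt(diag(object$vcov)) else NA_real_,
    ci_low = object$ci[match(terms, rownames(object$ci)), 1L],
    ci_high = object$ci[match(terms, rownames(object$ci)), 2L],
    row.names = NULL
  )
  structure(list(method = object$method, table = tab,
                 ci_kind = object$ci_kind, conf_level = object$conf_level,
                 n_informative = object$n_informative,
                 n_dropped = object$n_dropped,
                 converged = object$converged,
                 diagnostics = object$diagnostics,
                 pi10 = object$pi10),
            class = "summary.cc_fit")
}

#' @export
print.summary.cc_fit <- function(x, digits = 4L, ...) {
  cat(sprintf("%s\n", method_label(x$method)))
  print(x$table, digits = digits, row.names = FALSE)
  cat(sprintf("intervals: %s at %g%%; informative cases %d, dropped %d\n",
              x$ci_kind, 100 * x$conf_level, x$n_informative, x$n_dropped))
  if (!is.null(x$pi10)) cat(sprintf("pi10 = %.6g\n", x$pi10))
  for (d in x$diagnostics) cat("note:", d, "\n")
  invisible(x)
}
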