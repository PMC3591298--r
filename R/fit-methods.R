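# broom-style accessors for fitted codon models.

#' @export
print.sel_fit <- function(x, ...) {
  cat(sprintf("<sel_fit %s>  lnL = %.4f  (np = %d, %s, branch lengths %s)\n",
              x$model, x$lnL, x$np, x$convergence, x$branch_lengths))
  est <- unlist(x$params)
  est <- est[!vapply(est, is.null, TRUE)]
  show <- est[seq_len(min(length(est), 10))]
  cat(paste(sprintf("  %s = %.5g", names(show), show), collapse = "\n"), "\n")
  if (length(x$boundary_warnings) > 0)
    cat("  boundary:", paste(x$boundary_warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Tidy the parameter estimates of a fitted codon model
#'
#' @param x A `sel_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate` (`kappa` first,
#'   then the model's own parameters).
#' @export
tidy.sel_fit <- function(x, ...) {
  est <- unlist(x$params)
  tibble(term = c("kappa", names(est)),
         estimate = c(x$kappa, unname(est)))
}

#' One-row summary of a fitted codon model
#'
#' @param x A `sel_fit`.
#' @param ... Unused.
#' @return A tibble with `model`, `logLik`, `np`, `convergence`,
#'   `n_boundary_warnings`, `branch_lengths`.
#' @export
glance.sel_fit <- function(x, ...) {
  tibble(model = x$model, logLik = x$lnL, np = x$np,
         convergence = x$convergence,
         n_boundary_warnings = length(x$boundary_warnings),
         branch_lengths = x$branch_lengths)
}

#' @export
logLik.sel_fit <- function(object, ...) {
  structure(object$lnL, df = object$np, class = "logLik")
}
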