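# Amino-acid likelihood machinery: Dayhoff exchangeabilities with
# discrete-gamma among-site rate variation, and branch-length/alpha
# estimation on a fixed topology.

#' Amino-acid substitution model specification
#'
#' Dayhoff exchangeabilities with K-category discrete-gamma rate
#' variation (equal-probability categories represented by their means).
#'
#' @param alpha Gamma shape (> 0), or `NULL` to estimate it in
#'   [fit_aa_branch_lengths()].
#' @param k Number of gamma categories (default 4).
#' @param frequencies `"model"` for the Dayhoff canonical frequencies
#'   (default) or `"empirical"` (+F) counted from the alignment at fit
#'   time.
#' @return An `aa_model` list.
#' @export
aa_model <- function(alpha = NULL, k = 4,
                     frequencies = c("model", "empirical")) {
  frequencies <- match.arg(frequencies)
  if (!is.null(alpha) && alpha <= 0) stop("alpha must be positive")
  if (k < 1) stop("k must be >= 1")
  structure(list(exchangeabilities = dayhoff_exchangeabilities(),
                 frequencies = frequencies, alpha = alpha, k = k),
            class = "aa_model")
}

# Mean-rate-one generator from exchangeabilities and frequencies.
aa_Q <- function(model, freqs) {
  Q <- model$exchangeabilities * rep(freqs, each = 20)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))
  Q / mu
}

aa_freqs <- function(model, aln = NULL) {
  if (model$frequencies == "model") return(unname(dayhoff_frequencies()))
  st <- aln$states[!is.na(aln$states)]
  f <- tabulate(st, 20) + 0.5 # light smoothing against absent residues
  f / sum(f)
}

# Per-pattern log-likelihood under Dayhoff + gamma(alpha, k).
aa_loglik_data <- function(aln, tree) lik_data(aln, tree)

aa_mix_loglik <- function(d, Q, pi, alpha, k, len = NULL) {
  len <- len %||% d$len
  rates <- gamma_class_rates(alpha, k)
  edge <- d$edge
  storage.mode(edge) <- "integer"
  qi <- matrix(1L, k, nrow(edge))
  cl <- .class_site_loglik(list(Q), pi, edge, len, qi, rates, d$tips,
                           d$n_node)
  mix_loglik(cl, rep(1 / k, k), d$w)
}

#' Amino-acid log-likelihood of an alignment on a tree
#'
#' @param aln An [aa_alignment()].
#' @param tree `ape::phylo` with branch lengths (expected substitutions
#'   per site).
#' @param model An [aa_model()] with `alpha` set.
#' @return Total log-likelihood.
#' @export
aa_loglik <- function(aln, tree, model) {
  if (is.null(model$alpha)) stop("model$alpha must be set")
  d <- aa_loglik_data(aln, tree)
  pi <- aa_freqs(model, aln)
  aa_mix_loglik(d, aa_Q(model, pi), pi, model$alpha, model$k)
}

#' Optimize branch lengths (and gamma shape) under Dayhoff + gamma
#'
#' Maximizes the pruning likelihood over all branch lengths and, when
#' `model$alpha` is `NULL`, the gamma shape, on the fixed input topology.
#'
#' @param aln An [aa_alignment()].
#' @param tree `ape::phylo`; existing lengths are starting values.
#' @param model An [aa_model()].
#' @param opts [fit_opts()].
#' @return An `aa_fit`: list with `tree` (optimized lengths), `alpha`,
#'   `lnL`, `model`, `convergence`.
#' @export
fit_aa_branch_lengths <- function(aln, tree, model = aa_model(),
                                  opts = fit_opts(n_restarts = 2)) {
  check_taxa(aln, tree)
  d <- aa_loglik_data(aln, tree)
  pi <- aa_freqs(model, aln)
  Q <- aa_Q(model, pi)
  E <- nrow(d$edge)
  est_alpha <- is.null(model$alpha)
  len0 <- pmax(d$len, 1e-3)

  objective <- function(th) {
    alpha <- if (est_alpha) exp(th[1]) else model$alpha
    len <- exp(th[(if (est_alpha) 2 else 1):length(th)])
    v <- -aa_mix_loglik(d, Q, pi, alpha, model$k, len)
    if (!is.finite(v)) 1e10 else v
  }
  alpha_starts <- c(0.5, 2, 0.2, 1, 5)
  len_fac <- c(1, 0.5, 2, 1.5, 0.75)
  best <- NULL
  conv <- FALSE
  for (i in seq_len(opts$n_restarts)) {
    th0 <- c(if (est_alpha) log(alpha_starts[((i - 1) %% 5) + 1]),
             log(len0 * len_fac[((i - 1) %% 5) + 1]))
    lower <- c(if (est_alpha) log(0.01), rep(.B$llen[1], E))
    upper <- c(if (est_alpha) log(100), rep(.B$llen[2], E))
    r <- tryCatch(nlminb(th0, objective, lower = lower, upper = upper,
                         control = list(iter.max = opts$maxit,
                                        rel.tol = opts$reltol)),
                  error = function(e) NULL)
    if (!is.null(r) && (is.null(best) || r$objective < best$objective)) {
      best <- r
      conv <- r$convergence == 0
    }
  }
  if (is.null(best)) stop("branch-length optimization failed")
  alpha <- if (est_alpha) exp(best$par[1]) else model$alpha
  len <- exp(best$par[(if (est_alpha) 2 else 1):length(best$par)])
  tre <- d$tree
  tre$edge.length <- len
  fitted_model <- model
  fitted_model$alpha <- alpha
  structure(list(tree = tre, alpha = alpha, lnL = -best$objective,
                 model = fitted_model, pi = pi,
                 convergence = if (conv) "converged" else "not_converged"),
            class = "aa_fit")
}

#' @export
print.aa_fit <- function(x, ...) {
  cat(sprintf("<aa_fit Dayhoff+G%d: lnL = %.4f, alpha = %.4f, %s>\n",
              x$model$k, x$lnL, x$alpha, x$convergence))
  invisible(x)
}

#' @export
glance.aa_fit <- function(x, ...) {
  tibble(model = sprintf("Dayhoff+G%d", x$model$k), logLik = x$lnL,
         alpha = x$alpha, convergence = x$convergence)
}
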