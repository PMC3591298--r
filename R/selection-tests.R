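# Likelihood-ratio tests between nested fits and empirical-Bayes
# identification of positively selected sites (NEB and BEB).

#' Upper-tail chi-square probability
#'
#' @param x Test statistic (>= 0).
#' @param df Degrees of freedom (positive integer).
#' @return `P(X >= x)` for `X ~ chi-square(df)`.
#' @examples
#' chisq_sf(7.84, 2) # ~0.0198
#' chisq_sf(7.18, 1) # ~7.37e-3
#' @export
chisq_sf <- function(x, df) {
  if (any(df < 1)) stop("df must be a positive integer")
  if (any(x < 0)) stop("statistic must be non-negative")
  pchisq(x, df, lower.tail = FALSE)
}

#' Likelihood ratio test between nested fits
#'
#' `2 * (lnL_alt - lnL_null)` against chi-square. Negative statistics
#' within optimizer tolerance (0.02) clamp to zero with a warning; larger
#' negatives raise, signalling an optimization failure upstream.
#'
#' @param null_fit,alt_fit `sel_fit` objects (caller asserts nesting), or
#'   bare numeric log-likelihoods.
#' @param df Degrees of freedom; defaults to the frozen convention via
#'   [lrt_df()] when both arguments are `sel_fit`s.
#' @return A one-row tibble: `null_model`, `alt_model`, `lnL_null`,
#'   `lnL_alt`, `statistic`, `df`, `p`.
#' @export
lrt <- function(null_fit, alt_fit, df = NULL) {
  ln0 <- if (inherits(null_fit, "sel_fit")) null_fit$lnL else null_fit
  ln1 <- if (inherits(alt_fit, "sel_fit")) alt_fit$lnL else alt_fit
  if (is.null(df)) {
    if (!inherits(null_fit, "sel_fit") || !inherits(alt_fit, "sel_fit"))
      stop("df must be given when fits are bare log-likelihoods")
    nb <- nrow(alt_fit$tree$edge)
    df <- lrt_df(null_fit$model, alt_fit$model, n_branches = nb)
  }
  stat <- 2 * (ln1 - ln0)
  if (stat < 0) {
    if (stat > -0.02) {
      warning("negative LRT statistic within optimizer tolerance; ",
              "clamped to 0", call. = FALSE)
      stat <- 0
    } else {
      stop("lnL_alt < lnL_null by ", format(-stat / 2),
           ": alternative-model optimization failed upstream")
    }
  }
  tibble(
    null_model = if (inherits(null_fit, "sel_fit")) null_fit$model else NA,
    alt_model = if (inherits(alt_fit, "sel_fit")) alt_fit$model else NA,
    lnL_null = ln0, lnL_alt = ln1,
    statistic = stat, df = as.integer(df), p = chisq_sf(stat, df)
  )
}

# shared posterior assembly: K x P class log-liks + class weights ->
# per-site class posteriors and P(omega > 1)
.site_posterior_table <- function(cl, weights, class_gt1, pattern_of_site,
                                  method) {
  x <- cl + log(weights)
  mx <- apply(x, 2, max)
  ex <- exp(sweep(x, 2, mx, "-"))
  post <- sweep(ex, 2, colSums(ex), "/") # K x P
  p_gt1 <- colSums(post[class_gt1, , drop = FALSE])
  K <- nrow(post)
  tab <- tibble(site = seq_along(pattern_of_site))
  for (k in seq_len(K))
    tab[[paste0("P_class", k)]] <- post[k, pattern_of_site]
  tab$P_omega_gt1 <- p_gt1[pattern_of_site]
  structure(list(sites = tab, method = method, n_classes = K,
                 class_gt1 = class_gt1),
            class = "site_posterior")
}

#' @export
print.site_posterior <- function(x, ...) {
  cat(sprintf("<site_posterior %s: %d sites, %d classes>\n", x$method,
              nrow(x$sites), x$n_classes))
  top <- dplyr::arrange(x$sites, desc(.data$P_omega_gt1))
  print(utils::head(top[, c("site", "P_omega_gt1")], 8))
  invisible(x)
}

#' @export
tidy.site_posterior <- function(x, ...) x$sites

#' Naive empirical Bayes site posteriors
#'
#' Per-site class posteriors proportional to class proportion times the
#' per-class site likelihood at the maximum-likelihood estimates;
#' `P(omega > 1)` sums the posteriors of classes whose omega exceeds 1
#' (on the foreground branch type, for branch-site models).
#'
#' @param fit A `sel_fit` (for a single-class model such as M0 the sole
#'   class gets posterior 1 everywhere).
#' @return A `site_posterior` with method `"NEB"`.
#' @export
neb_site_posteriors <- function(fit) {
  .site_posterior_table(fit$class_loglik, fit$weights, fit$class_gt1,
                        fit$pattern_of_site, "NEB")
}

#' Grid specification for Bayes empirical Bayes
#'
#' @param n Points per dimension (>= 4; the published implementations
#'   default to 10). `at_mle = TRUE` requests the degenerate one-point
#'   grid at the MLEs, which reproduces NEB exactly and exists as a
#'   construction check.
#' @param omega_max Upper end of the positive-selection omega grid.
#' @param at_mle Degenerate single-point grid?
#' @return A grid spec list.
#' @export
beb_grid <- function(n = 10, omega_max = 11, at_mle = FALSE) {
  if (!at_mle && n < 4) stop("grid too coarse: need >= 4 points per dimension")
  list(n = n, omega_max = omega_max, at_mle = at_mle)
}

.grid_mids <- function(lo, hi, n) lo + (hi - lo) * (seq_len(n) - 0.5) / n

#' Bayes empirical Bayes site posteriors
#'
#' Integrates the site posteriors over a uniform prior grid on the
#' mixture parameters, weighting each grid point by its data likelihood:
#' for M2a the grid runs over (p0, p1, omega0, omega2) (proportions on
#' the simplex triangle), for M8 over (p0, p, q, omega_s). Branch
#' lengths, kappa and codon frequencies stay at their MLEs, as in the
#' standard implementation.
#'
#' @param fit A `sel_fit` for M2a or M8.
#' @param grid A [beb_grid()].
#' @return A `site_posterior` with method `"BEB"`.
#' @export
beb_site_posteriors <- function(fit, grid = beb_grid()) {
  if (!fit$model %in% c("M2a", "M8"))
    stop("BEB is implemented for M2a and M8 fits; got ", fit$model)
  d <- fit$lik_data
  pi <- fit$pi
  kappa <- fit$kappa
  len <- fit$tree$edge.length

  if (grid$at_mle) {
    pts <- list(list(weights = fit$weights,
                     omegas = as.vector(fit$omega_by_type)))
  } else if (fit$model == "M8") {
    n <- grid$n
    K <- fit$params$K
    p0g <- .grid_mids(0, 1, n)
    pg <- .grid_mids(0, 2, n)
    qg <- .grid_mids(0, 2, n)
    wsg <- .grid_mids(1, grid$omega_max, n)
    pts <- list()
    for (p0 in p0g) for (p in pg) for (q in qg) for (ws in wsg)
      pts[[length(pts) + 1]] <- list(
        weights = c(rep(p0 / K, K), 1 - p0),
        omegas = c(beta_class_means(p, q, K), ws))
  } else {
    n <- grid$n
    p0g <- .grid_mids(0, 1, n)
    p1g <- .grid_mids(0, 1, n)
    w0g <- .grid_mids(0, 1, n)
    w2g <- .grid_mids(1, grid$omega_max, n)
    pts <- list()
    for (p0 in p0g) for (p1 in p1g) {
      if (p0 + p1 >= 1) next
      for (w0 in w0g) for (w2 in w2g)
        pts[[length(pts) + 1]] <- list(
          weights = c(p0, p1, 1 - p0 - p1),
          omegas = c(w0, 1, w2))
    }
  }

  G <- length(pts)
  P <- length(fit$pattern_weight)
  n_sites <- length(fit$pattern_of_site)
  total_ll <- numeric(G)
  pgt1 <- matrix(0, G, P)
  for (g in seq_len(G)) {
    om <- pts[[g]]$omegas
    w <- pts[[g]]$weights
    cl <- class_loglik(d, kappa, pi, matrix(om, length(om), nrow(d$edge)),
                       len = len)
    x <- cl + log(w)
    mx <- apply(x, 2, max)
    per_pat <- mx + log(colSums(exp(sweep(x, 2, mx, "-"))))
    total_ll[g] <- sum(per_pat * fit$pattern_weight)
    ex <- exp(sweep(x, 2, mx, "-"))
    post <- sweep(ex, 2, colSums(ex), "/")
    gt1 <- om > 1 + 1e-9
    pgt1[g, ] <- colSums(post[gt1, , drop = FALSE])
  }
  gw <- exp(total_ll - max(total_ll))
  gw <- gw / sum(gw)
  p_site <- as.vector(gw %*% pgt1)[fit$pattern_of_site]

  tab <- tibble(site = seq_len(n_sites), P_omega_gt1 = p_site)
  structure(list(sites = tab, method = "BEB",
                 n_classes = length(fit$weights),
                 class_gt1 = fit$class_gt1, grid = grid,
                 grid_points = G),
            class = "site_posterior")
}

#' Classify sites by posterior probability of positive selection
#'
#' @param post A `site_posterior`.
#' @param thresholds Tier cut points (descending tiers reported at 0.99,
#'   0.95, 0.5 by default).
#' @return A tibble (site, P_omega_gt1, tier) sorted by decreasing
#'   `P_omega_gt1`, containing the sites above the lowest threshold.
#' @export
classify_sites <- function(post, thresholds = c(0.5, 0.95, 0.99)) {
  th <- sort(thresholds)
  tab <- dplyr::arrange(post$sites, desc(.data$P_omega_gt1),
                        .data$site)
  tab <- tab[, c("site", "P_omega_gt1")]
  tier <- vapply(tab$P_omega_gt1, function(p) {
    above <- th[p > th]
    if (length(above) == 0) NA_character_
    else paste0(">", format(max(above)))
  }, "")
  tab$tier <- tier
  dplyr::filter(tab, !is.na(.data$tier))
}

#' Plot per-site posterior probabilities of positive selection
#'
#' @param object A `site_posterior`.
#' @param threshold Reference line (default 0.5).
#' @param ... Unused.
#' @return A ggplot: site index against `P(omega > 1)`.
#' @export
autoplot.site_posterior <- function(object, threshold = 0.5, ...) {
  ggplot2::ggplot(object$sites,
                  ggplot2::aes(x = .data$site, y = .data$P_omega_gt1)) +
    ggplot2::geom_col(width = 0.8, fill = "firebrick") +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::labs(x = "codon site", y = "P(ω > 1)",
                  title = paste(object$method, "site posteriors")) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
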