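# Maximum-likelihood fits of the codon models: M0, free-ratio, the site
# models M1a/M2a/M7/M8/M8fix, branch-site model A, clade model C, and
# pairwise dN/dS. All fits share one engine: bounded quasi-Newton
# (nlminb) on transformed parameters with deterministic multi-start.

logit <- function(p) log(p / (1 - p))
expit <- function(x) 1 / (1 + exp(-x))

#' Optimizer options for model fits
#'
#' @param n_restarts Number of dispersed starting points (the best lnL is
#'   kept). Several runs from different initial values guard against
#'   local optima in the mixture models.
#' @param maxit Maximum optimizer iterations per start.
#' @param reltol Relative lnL convergence tolerance.
#' @param boundary_tol Proximity to a bound (natural scale) that triggers
#'   a boundary warning recorded in the fit.
#' @return A list of options.
#' @export
fit_opts <- function(n_restarts = 5, maxit = 1000, reltol = 1e-8,
                     boundary_tol = 1e-4) {
  list(n_restarts = n_restarts, maxit = maxit, reltol = reltol,
       boundary_tol = boundary_tol)
}

# theta-space box bounds used by every model
.B <- list(
  lkappa = c(log(0.01), log(100)),
  lomega = c(log(1e-6), log(50)),
  logit = c(-12, 12),
  lws = c(-12, log(50)),     # log(omega_s - 1)
  lbeta = c(log(0.005), log(100)),
  llen = c(log(1e-8), log(20))
)

# Deterministic multiplicative jitter for recycled starts.
.jitter_start <- function(x, i) x * (1 + 0.35 * ((i - 1) %/% 1)) ^ (1 + (i %% 3))

# Remove the degree-2 root (standard for time-reversible codon fits);
# branch/clade marks are re-keyed by descendant tip set so they survive
# the node renumbering.
unroot_marked <- function(tree) {
  if (ape::Ntip(tree) <= 2 || !ape::is.rooted(tree)) return(tree)
  bm <- attr(tree, "branch_mark")
  cm <- attr(tree, "clade_mark")
  key <- node_tipset_keys(tree)
  all_tips <- sort(tree$tip.label)
  complement <- function(k) {
    paste(setdiff(all_tips, strsplit(k, "|", fixed = TRUE)[[1]]),
          collapse = "|")
  }
  ut <- ape::unroot(tree)
  ukey <- node_tipset_keys(ut)
  n <- length(ukey)
  # a branch is a bipartition: a root-adjacent marked branch survives
  # unrooting as the edge whose child tipset is the complement
  m <- match(ukey, key)
  m2 <- match(vapply(ukey, complement, ""), key)
  full <- paste(all_tips, collapse = "|")
  m2[ukey == full] <- NA_integer_
  nbm <- integer(n); ncm <- integer(n)
  for (i in seq_len(n)) {
    # branch marks live on bipartitions: take the mark from whichever
    # side of the old (rooted) branch carried it
    if (!is.null(bm)) {
      v <- c(if (!is.na(m[i])) bm[m[i]], if (!is.na(m2[i])) bm[m2[i]])
      if (length(v) > 0) nbm[i] <- max(v)
    }
    # clade marks are directional: direct match only
    if (!is.null(cm) && !is.na(m[i])) ncm[i] <- cm[m[i]]
  }
  attr(ut, "branch_mark") <- nbm
  attr(ut, "clade_mark") <- ncm
  ut
}

node_tipset_keys <- function(tree) {
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  sets <- vector("list", n_node)
  for (i in seq_len(n_tip)) sets[[i]] <- tree$tip.label[i]
  tre <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(tre$edge))) {
    p <- tre$edge[e, 1]; ch <- tre$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  vapply(sets, function(s) paste(sort(s), collapse = "|"), "")
}

# True when no alignment column carries two distinct non-missing states:
# omega (and kappa) are then unidentifiable.
.is_uninformative <- function(d) {
  !any(apply(d$tips, 2, function(col) {
    s <- col[col > 0]
    length(unique(s)) > 1
  }))
}

# The shared fitting engine. `spec` supplies the model's packing,
# unpacking, starts, bounds and boundary checks; `etype` assigns each
# postorder edge to an omega column of the unpacked omega_by_type matrix.
codon_fit_engine <- function(aln, tree, spec, opts, co_estimate,
                             etype_fun = function(tre) rep(1L, nrow(tre$edge)),
                             pi = NULL) {
  tree <- unroot_marked(tree)
  d <- lik_data(aln, tree)
  pi <- pi %||% estimate_f3x4(aln)
  etype <- etype_fun(d$tree)
  E <- nrow(d$edge)
  uninform <- .is_uninformative(d)

  len0 <- pmax(d$len, 1e-3)
  n_model_par <- length(spec$pack(spec$starts[[1]]))
  lower <- spec$lower; upper <- spec$upper
  if (co_estimate) {
    lower <- c(lower, rep(.B$llen[1], E))
    upper <- c(upper, rep(.B$llen[2], E))
  }

  objective <- function(theta) {
    p <- spec$unpack(theta[seq_len(n_model_par)])
    len <- if (co_estimate) exp(theta[n_model_par + seq_len(E)]) else d$len
    omega_ke <- p$omega_by_type[, etype, drop = FALSE]
    cl <- class_loglik(d, p$kappa, pi, omega_ke, len)
    v <- -mix_loglik(cl, p$weights, d$w)
    if (!is.finite(v)) 1e10 else v
  }

  starts <- vector("list", opts$n_restarts)
  nbase <- length(spec$starts)
  len_fac <- c(1, 0.6, 1.6, 0.35, 2.5, 1, 0.8, 1.25)
  for (i in seq_len(opts$n_restarts)) {
    base <- spec$starts[[((i - 1) %% nbase) + 1]]
    if (i > nbase) base <- spec$perturb(base, i)
    th <- spec$pack(base)
    if (co_estimate)
      th <- c(th, log(len0 * len_fac[((i - 1) %% length(len_fac)) + 1]))
    starts[[i]] <- pmin(pmax(th, lower + 1e-9), upper - 1e-9)
  }

  # Cheap pre-phase when co-estimating lengths: optimize the model
  # parameters plus one overall branch-scale factor, then start the
  # joint optimization from there. Cuts the joint phase to a polish.
  prephase <- function(th0) {
    base_len <- exp(th0[n_model_par + seq_len(E)])
    obj2 <- function(th2) {
      p <- spec$unpack(th2[seq_len(n_model_par)])
      len <- base_len * exp(th2[n_model_par + 1])
      omega_ke <- p$omega_by_type[, etype, drop = FALSE]
      cl <- class_loglik(d, p$kappa, pi, omega_ke, pmin(len, 20))
      v <- -mix_loglik(cl, p$weights, d$w)
      if (!is.finite(v)) 1e10 else v
    }
    r2 <- tryCatch(
      nlminb(c(th0[seq_len(n_model_par)], 0), obj2,
             lower = c(lower[seq_len(n_model_par)], log(0.02)),
             upper = c(upper[seq_len(n_model_par)], log(50)),
             control = list(iter.max = 200, rel.tol = 1e-7)),
      error = function(e) NULL)
    if (is.null(r2)) return(th0)
    th <- c(r2$par[seq_len(n_model_par)],
            pmin(pmax(log(base_len) + r2$par[n_model_par + 1],
                      .B$llen[1] + 1e-9), .B$llen[2] - 1e-9))
    th
  }

  restarts <- vector("list", opts$n_restarts)
  best <- NULL
  for (i in seq_len(opts$n_restarts)) {
    th_start <- if (co_estimate) prephase(starts[[i]]) else starts[[i]]
    res <- tryCatch(
      nlminb(th_start, objective, lower = lower, upper = upper,
             control = list(iter.max = opts$maxit,
                            eval.max = 20 * opts$maxit,
                            rel.tol = opts$reltol)),
      error = function(e) NULL)
    if (is.null(res)) {
      restarts[[i]] <- tibble(restart = i, lnL = NA_real_, converged = FALSE)
      next
    }
    restarts[[i]] <- tibble(restart = i, lnL = -res$objective,
                            converged = res$convergence == 0)
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  if (is.null(best)) stop("all optimizer starts failed for model ", spec$id)

  theta <- best$par
  params <- spec$unpack(theta[seq_len(n_model_par)])
  len <- if (co_estimate) exp(theta[n_model_par + seq_len(E)]) else d$len
  tre <- d$tree
  tre$edge.length <- len
  omega_ke <- params$omega_by_type[, etype, drop = FALSE]
  cl <- class_loglik(d, params$kappa, pi, omega_ke, len)
  lnL <- mix_loglik(cl, params$weights, d$w)

  warn <- spec$boundary(params, opts$boundary_tol)
  convergence <- if (uninform) "unidentifiable"
                 else if (best$convergence == 0) "converged"
                 else "not_converged"
  if (uninform)
    warning("alignment carries no variable sites: omega/kappa unidentifiable",
            call. = FALSE)
  if (convergence == "not_converged")
    warning("optimizer did not converge for model ", spec$id, call. = FALSE)

  structure(list(
    model = spec$id,
    lnL = lnL,
    kappa = params$kappa,
    params = params$report,
    weights = params$weights,
    omega_by_type = params$omega_by_type,
    class_gt1 = apply(params$omega_by_type, 1,
                      function(r) any(r > 1 + 1e-9)),
    pi = pi,
    tree = tre,
    etype = etype,
    branch_lengths = if (co_estimate) "co_estimated" else "fixed",
    np = n_model_par + if (co_estimate) E else 0L,
    convergence = convergence,
    boundary_warnings = warn,
    restarts = dplyr::bind_rows(restarts),
    class_loglik = cl,
    pattern_of_site = d$pattern_of_site,
    pattern_weight = d$w,
    lik_data = d
  ), class = "sel_fit")
}

.default_perturb <- function(base, i) {
  lapply(base, function(v) v * exp(0.4 * sin(i * seq_along(v) + i)))
}

# ---- model specs -----------------------------------------------------

.spec_m0 <- function() list(
  id = "M0",
  pack = function(s) c(log(s$kappa), log(s$omega)),
  unpack = function(th) {
    kappa <- exp(th[1]); omega <- exp(th[2])
    list(kappa = kappa, weights = 1,
         omega_by_type = matrix(omega, 1, 1),
         report = list(omega = omega))
  },
  starts = list(list(kappa = 2, omega = 0.2), list(kappa = 4, omega = 1),
                list(kappa = 1, omega = 0.05), list(kappa = 2, omega = 2),
                list(kappa = 8, omega = 0.5)),
  perturb = .default_perturb,
  lower = c(.B$lkappa[1], .B$lomega[1]),
  upper = c(.B$lkappa[2], .B$lomega[2]),
  boundary = function(p, tol) {
    w <- character(0)
    if (p$report$omega < .B$lomega[1] + tol) w <- c(w, "omega at lower bound")
    w
  }
)

#' Fit the one-ratio (M0) codon model
#'
#' Jointly optimizes `kappa`, a single `omega`, and (by default) the
#' branch lengths; F3X4 frequencies are fixed from counts. The input tree
#' is unrooted internally (the model is time-reversible).
#'
#' @param aln A [codon_alignment()].
#' @param tree `ape::phylo`; branch lengths are starting values when
#'   co-estimating, or used as-is when `branch_lengths = "fixed"`.
#' @param opts [fit_opts()].
#' @param branch_lengths `"co_estimated"` (default) or `"fixed"`.
#' @return A `sel_fit`.
#' @export
fit_m0 <- function(aln, tree, opts = fit_opts(),
                   branch_lengths = c("co_estimated", "fixed")) {
  branch_lengths <- match.arg(branch_lengths)
  codon_fit_engine(aln, tree, .spec_m0(), opts,
                   co_estimate = branch_lengths == "co_estimated")
}

.spec_free <- function(E) list(
  id = "free_ratio",
  pack = function(s) c(log(s$kappa), log(s$omega)),
  unpack = function(th) {
    kappa <- exp(th[1]); om <- exp(th[-1])
    list(kappa = kappa, weights = 1,
         omega_by_type = matrix(om, 1, E),
         report = list(omega = om))
  },
  starts = list(list(kappa = 2, omega = rep(0.2, E)),
                list(kappa = 4, omega = rep(0.8, E)),
                list(kappa = 1.5, omega = rep(0.05, E))),
  perturb = .default_perturb,
  lower = c(.B$lkappa[1], rep(.B$lomega[1], E)),
  upper = c(.B$lkappa[2], rep(.B$lomega[2], E)),
  boundary = function(p, tol) {
    n0 <- sum(p$report$omega < 1e-5)
    if (n0 > 0) paste(n0, "branch omegas at lower bound (no nonsynonymous",
                      "information on those branches)")
    else character(0)
  }
)

#' Fit the free-ratio codon model (one omega per branch)
#'
#' @inheritParams fit_m0
#' @return A `sel_fit`; per-branch omegas are in `$params$omega`, ordered
#'   as the postorder edges of `$tree` (see [tree_edges()]).
#' @export
fit_free_ratio <- function(aln, tree, opts = fit_opts(),
                           branch_lengths = c("co_estimated", "fixed")) {
  branch_lengths <- match.arg(branch_lengths)
  tree2 <- unroot_marked(tree)
  E <- nrow(ape::reorder.phylo(tree2, "postorder")$edge)
  codon_fit_engine(aln, tree2, .spec_free(E), opts,
                   co_estimate = branch_lengths == "co_estimated",
                   etype_fun = function(tre) seq_len(nrow(tre$edge)))
}

.spec_m1a <- function() list(
  id = "M1a",
  pack = function(s) c(log(s$kappa), logit(s$p0), logit(s$omega0)),
  unpack = function(th) {
    kappa <- exp(th[1]); p0 <- expit(th[2]); w0 <- expit(th[3])
    list(kappa = kappa, weights = c(p0, 1 - p0),
         omega_by_type = matrix(c(w0, 1), 2, 1),
         report = list(p0 = p0, p1 = 1 - p0, omega0 = w0, omega1 = 1))
  },
  starts = list(list(kappa = 2, p0 = 0.8, omega0 = 0.1),
                list(kappa = 4, p0 = 0.5, omega0 = 0.3),
                list(kappa = 2, p0 = 0.95, omega0 = 0.02),
                list(kappa = 1.5, p0 = 0.3, omega0 = 0.5)),
  perturb = .default_perturb,
  lower = c(.B$lkappa[1], .B$logit[1], .B$logit[1]),
  upper = c(.B$lkappa[2], .B$logit[2], .B$logit[2]),
  boundary = function(p, tol) {
    w <- character(0)
    if (p$report$p0 > 1 - tol || p$report$p0 < tol)
      w <- c(w, "p0 at boundary")
    w
  }
)

.spec_m2a <- function() list(
  id = "M2a",
  pack = function(s) {
    a <- log(c(s$p0, s$p1) / s$p2)
    c(log(s$kappa), a, logit(s$omega0), log(s$omega2 - 1))
  },
  unpack = function(th) {
    kappa <- exp(th[1])
    ew <- exp(c(th[2], th[3], 0)); w <- ew / sum(ew)
    w0 <- expit(th[4]); w2 <- 1 + exp(th[5])
    list(kappa = kappa, weights = w,
         omega_by_type = matrix(c(w0, 1, w2), 3, 1),
         report = list(p0 = w[1], p1 = w[2], p2 = w[3],
                       omega0 = w0, omega1 = 1, omega2 = w2))
  },
  starts = list(
    list(kappa = 2, p0 = 0.8, p1 = 0.15, p2 = 0.05, omega0 = 0.1, omega2 = 3),
    list(kappa = 2, p0 = 0.85, p1 = 0.14, p2 = 0.01, omega0 = 0.05,
         omega2 = 1.001),
    list(kappa = 4, p0 = 0.6, p1 = 0.2, p2 = 0.2, omega0 = 0.3, omega2 = 8),
    list(kappa = 2, p0 = 0.45, p1 = 0.45, p2 = 0.10, omega0 = 0.02,
         omega2 = 2)),
  perturb = .default_perturb,
  lower = c(.B$lkappa[1], -20, -20, .B$logit[1], .B$lws[1]),
  upper = c(.B$lkappa[2], 20, 20, .B$logit[2], .B$lws[2]),
  boundary = function(p, tol) {
    w <- character(0)
    if (p$report$p2 < tol) w <- c(w, "p2 near 0")
    if (p$report$omega2 < 1 + tol) w <- c(w, "omega2 near 1")
    w
  }
)

.spec_m7 <- function(K) list(
  id = "M7",
  pack = function(s) c(log(s$kappa), log(s$p), log(s$q)),
  unpack = function(th) {
    kappa <- exp(th[1]); p <- exp(th[2]); q <- exp(th[3])
    om <- beta_class_means(p, q, K)
    list(kappa = kappa, weights = rep(1 / K, K),
         omega_by_type = matrix(om, K, 1),
         report = list(p = p, q = q, K = K))
  },
  starts = list(list(kappa = 2, p = 0.3, q = 1), list(kappa = 2, p = 1, q = 2),
                list(kappa = 4, p = 0.1, q = 0.5),
                list(kappa = 2, p = 2, q = 0.5)),
  perturb = .default_perturb,
  lower = c(.B$lkappa[1], .B$lbeta[1], .B$lbeta[1]),
  upper = c(.B$lkappa[2], .B$lbeta[2], .B$lbeta[2]),
  boundary = function(p, tol) character(0)
)

.spec_m8 <- function(K, fix_ws = FALSE) list(
  id = if (fix_ws) "M8fix" else "M8",
  pack = function(s) {
    th <- c(log(s$kappa), logit(s$p0), log(s$p), log(s$q))
    if (!fix_ws) th <- c(th, log(s$omega_s - 1))
    th
  },
  unpack = function(th) {
    kappa <- exp(th[1]); p0 <- expit(th[2])
    p <- exp(th[3]); q <- exp(th[4])
    ws <- if (fix_ws) 1 else 1 + exp(th[5])
    om <- c(beta_class_means(p, q, K), ws)
    list(kappa = kappa, weights = c(rep(p0 / K, K), 1 - p0),
         omega_by_type = matrix(om, K + 1, 1),
         report = list(p0 = p0, p = p, q = q, p1 = 1 - p0,
                       omega_s = ws, K = K))
  },
  starts = {
    s <- list(
      list(kappa = 2, p0 = 0.9, p = 0.3, q = 1, omega_s = 3),
      list(kappa = 2, p0 = 0.99, p = 0.15, q = 0.7, omega_s = 4.5),
      list(kappa = 4, p0 = 0.7, p = 1, q = 2, omega_s = 1.3),
      list(kappa = 2, p0 = 0.999, p = 0.3, q = 1, omega_s = 1.0005),
      list(kappa = 2, p0 = 0.5, p = 0.1, q = 0.4, omega_s = 8))
    s
  },
  perturb = .default_perturb,
  lower = c(.B$lkappa[1], .B$logit[1], .B$lbeta[1], .B$lbeta[1],
            if (!fix_ws) .B$lws[1]),
  upper = c(.B$lkappa[2], .B$logit[2], .B$lbeta[2], .B$lbeta[2],
            if (!fix_ws) .B$lws[2]),
  boundary = function(p, tol) {
    w <- character(0)
    if (!fix_ws && p$report$omega_s < 1 + tol)
      w <- c(w, "omega_s stuck near 1")
    if (p$report$p0 > 1 - tol) w <- c(w, "extra-class weight near 0")
    w
  }
)

#' Fit a site model (omega varies among sites)
#'
#' M1a (nearly neutral), M2a (positive selection), M7 (beta), M8
#' (beta + omega_s), or M8fix (M8 with omega_s pinned to 1). Following
#' common practice the branch lengths default to the values on the input
#' tree -- normally the M0 fit's lengths (`branch_lengths = "fixed"`);
#' co-estimation is available behind the flag.
#'
#' @inheritParams fit_m0
#' @param model One of `"M1a"`, `"M2a"`, `"M7"`, `"M8"`, `"M8fix"`.
#' @param K Number of equal-probability beta discretization categories
#'   for M7/M8/M8fix (category means; default 10).
#' @param branch_lengths `"fixed"` (default; lengths taken from `tree`)
#'   or `"co_estimated"`.
#' @return A `sel_fit`.
#' @export
fit_site_model <- function(aln, tree,
                           model = c("M1a", "M2a", "M7", "M8", "M8fix"),
                           opts = fit_opts(), K = 10,
                           branch_lengths = c("fixed", "co_estimated")) {
  model <- match.arg(model)
  branch_lengths <- match.arg(branch_lengths)
  spec <- switch(model,
    M1a = .spec_m1a(),
    M2a = .spec_m2a(),
    M7 = .spec_m7(K),
    M8 = .spec_m8(K, fix_ws = FALSE),
    M8fix = .spec_m8(K, fix_ws = TRUE))
  codon_fit_engine(aln, tree, spec, opts,
                   co_estimate = branch_lengths == "co_estimated")
}

.spec_bsA <- function(null_model) list(
  id = if (null_model) "branch_site_A_null" else "branch_site_A",
  # proportions via x = p0+p1, y = p0/(p0+p1):
  # p2 = (1-x) y, p3 = (1-x)(1-y) -- the standard two-proportion layout
  pack = function(s) {
    x <- s$p0 + s$p1; y <- s$p0 / x
    th <- c(log(s$kappa), logit(x), logit(y), logit(s$omega0))
    if (!null_model) th <- c(th, log(s$omega2 - 1))
    th
  },
  unpack = function(th) {
    kappa <- exp(th[1]); x <- expit(th[2]); y <- expit(th[3])
    w0 <- expit(th[4])
    w2 <- if (null_model) 1 else 1 + exp(th[5])
    w <- c(x * y, x * (1 - y), (1 - x) * y, (1 - x) * (1 - y))
    # classes x types: cols = (background, foreground)
    obt <- matrix(c(w0, w0, 1, 1, w0, w2, 1, w2), 4, 2, byrow = TRUE)
    list(kappa = kappa, weights = w, omega_by_type = obt,
         report = list(p0 = w[1], p1 = w[2], p2 = w[3], p3 = w[4],
                       omega0 = w0, omega1 = 1, omega2 = w2))
  },
  starts = list(
    list(kappa = 2, p0 = 0.7, p1 = 0.2, omega0 = 0.1, omega2 = 3),
    list(kappa = 2, p0 = 0.5, p1 = 0.3, omega0 = 0.05, omega2 = 1.001),
    list(kappa = 4, p0 = 0.4, p1 = 0.4, omega0 = 0.3, omega2 = 6),
    list(kappa = 2, p0 = 0.85, p1 = 0.1, omega0 = 0.02, omega2 = 2)),
  perturb = .default_perturb,
  lower = c(.B$lkappa[1], .B$logit[1], .B$logit[1], .B$logit[1],
            if (!null_model) .B$lws[1]),
  upper = c(.B$lkappa[2], .B$logit[2], .B$logit[2], .B$logit[2],
            if (!null_model) .B$lws[2]),
  boundary = function(p, tol) {
    w <- character(0)
    if (!null_model && p$report$omega2 < 1 + tol)
      w <- c(w, "foreground omega2 stuck near 1")
    w
  }
)

#' Fit branch-site model A
#'
#' Four site classes: background classes with `omega0 < 1` and
#' `omega1 = 1`, plus two classes whose omega on the single marked
#' foreground branch is `omega2` (free, or fixed to 1 for the null).
#'
#' @inheritParams fit_m0
#' @param null Fit the null variant (`omega2 = 1`)?
#' @param branch_lengths `"fixed"` (default) or `"co_estimated"`.
#' @return A `sel_fit`.
#' @export
fit_branch_site_a <- function(aln, tree, null = FALSE, opts = fit_opts(),
                              branch_lengths = c("fixed", "co_estimated")) {
  branch_lengths <- match.arg(branch_lengths)
  etype_fun <- function(tre) {
    bm <- attr(tre, "branch_mark")
    if (is.null(bm) || sum(bm > 0) == 0)
      stop("branch-site model A needs exactly one marked foreground branch")
    if (sum(bm > 0) > 1)
      stop("branch-site model A allows only one foreground branch; found ",
           sum(bm > 0))
    ifelse(bm[tre$edge[, 2]] > 0, 2L, 1L)
  }
  codon_fit_engine(aln, tree, .spec_bsA(null), opts,
                   co_estimate = branch_lengths == "co_estimated",
                   etype_fun = etype_fun)
}

.spec_cladeC <- function() list(
  id = "clade_C",
  pack = function(s) c(log(s$kappa), log(c(s$p0, s$p1) / s$p2),
                       logit(s$omega0), log(s$omega2_0), log(s$omega2_1)),
  unpack = function(th) {
    kappa <- exp(th[1])
    ew <- exp(c(th[2], th[3], 0)); w <- ew / sum(ew)
    w0 <- expit(th[4]); c0 <- exp(th[5]); c1 <- exp(th[6])
    obt <- matrix(c(w0, w0, 1, 1, c0, c1), 3, 2, byrow = TRUE)
    list(kappa = kappa, weights = w, omega_by_type = obt,
         report = list(p0 = w[1], p1 = w[2], p2 = w[3], omega0 = w0,
                       omega1 = 1, omega2_type0 = c0, omega2_type1 = c1))
  },
  starts = list(
    list(kappa = 2, p0 = 0.7, p1 = 0.1, p2 = 0.2, omega0 = 0.05,
         omega2_0 = 0.2, omega2_1 = 0.5),
    list(kappa = 2, p0 = 0.5, p1 = 0.25, p2 = 0.25, omega0 = 0.1,
         omega2_0 = 0.5, omega2_1 = 0.5),
    list(kappa = 4, p0 = 0.3, p1 = 0.3, p2 = 0.4, omega0 = 0.02,
         omega2_0 = 1.5, omega2_1 = 0.3)),
  perturb = .default_perturb,
  lower = c(.B$lkappa[1], -20, -20, .B$logit[1], .B$lomega[1], .B$lomega[1]),
  upper = c(.B$lkappa[2], 20, 20, .B$logit[2], .B$lomega[2], .B$lomega[2]),
  boundary = function(p, tol) character(0)
)

#' Fit clade model C
#'
#' Two shared classes (`omega0 < 1`, `omega1 = 1`) plus a divergent class
#' whose omega differs between the two branch types given by the tree's
#' clade marks (`$<int>` Newick tokens or [mark_clade()]).
#'
#' @inheritParams fit_m0
#' @param branch_lengths `"fixed"` (default) or `"co_estimated"`.
#' @return A `sel_fit`.
#' @export
fit_clade_model_c <- function(aln, tree, opts = fit_opts(),
                              branch_lengths = c("fixed", "co_estimated")) {
  branch_lengths <- match.arg(branch_lengths)
  etype_fun <- function(tre) {
    cm <- attr(tre, "clade_mark")
    if (is.null(cm) || sum(cm > 0) == 0)
      stop("clade model C needs a clade partition (clade marks)")
    et <- ifelse(cm[tre$edge[, 2]] > 0, 2L, 1L)
    if (length(unique(et)) != 2)
      stop("clade model C needs branches of both types")
    et
  }
  codon_fit_engine(aln, tree, .spec_cladeC(), opts,
                   co_estimate = branch_lengths == "co_estimated",
                   etype_fun = etype_fun)
}

# ---- pairwise dN/dS --------------------------------------------------

# Average synonymous/nonsynonymous step counts between two codon states
# over all minimal single-nucleotide paths that avoid stops.
.count_syn_nonsyn_pair <- function(a, b) {
  if (a == b) return(c(syn = 0, nonsyn = 0))
  gcinfo <- .genetic_code()
  ca <- strsplit(gcinfo$codons[a], "")[[1]]
  cb <- strsplit(gcinfo$codons[b], "")[[1]]
  pos <- which(ca != cb)
  perms <- if (length(pos) == 1) list(pos)
           else if (length(pos) == 2) list(pos, rev(pos))
           else {
             p <- pos
             list(p[c(1,2,3)], p[c(1,3,2)], p[c(2,1,3)],
                  p[c(2,3,1)], p[c(3,1,2)], p[c(3,2,1)])
           }
  tot <- c(syn = 0, nonsyn = 0); nvalid <- 0
  for (ord in perms) {
    cur <- ca; steps <- c(syn = 0, nonsyn = 0); ok <- TRUE
    for (p in ord) {
      nxt <- cur; nxt[p] <- cb[p]
      i1 <- gcinfo$lookup[paste(cur, collapse = "")]
      i2 <- gcinfo$lookup[paste(nxt, collapse = "")]
      if (i2 == 0) { ok <- FALSE; break }
      if (gcinfo$aa[i1] == gcinfo$aa[i2]) steps["syn"] <- steps["syn"] + 1
      else steps["nonsyn"] <- steps["nonsyn"] + 1
      cur <- nxt
    }
    if (ok) { tot <- tot + steps; nvalid <- nvalid + 1 }
  }
  if (nvalid == 0) return(c(syn = 0, nonsyn = length(pos)))
  tot / nvalid
}

#' Pairwise maximum-likelihood dN/dS
#'
#' Two-taxon M0 fit (`kappa`, `omega`, divergence `t`) for one pair or
#' for every pair in an alignment. Symmetric in argument order. `omega`
#' is reported as missing when the pair carries no synonymous or no
#' nonsynonymous information (counted over minimal substitution paths),
#' and `t = 0` with `omega = NA` for identical sequences.
#'
#' @param aln A [codon_alignment()].
#' @param taxa Optional length-2 character vector selecting one pair;
#'   default computes all pairs.
#' @param opts [fit_opts()] (fewer restarts are plenty here).
#' @return A tibble with columns `taxon_a`, `taxon_b`, `omega`, `kappa`,
#'   `t`, `n_codons`.
#' @export
pairwise_dnds <- function(aln, taxa = NULL, opts = fit_opts(n_restarts = 2)) {
  pairs <- if (!is.null(taxa)) {
    stopifnot(length(taxa) == 2)
    matrix(taxa, 1)
  } else {
    t(utils::combn(aln$taxa, 2))
  }
  out <- vector("list", nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    out[[r]] <- .pairwise_fit_one(aln, pairs[r, 1], pairs[r, 2], opts)
  }
  dplyr::bind_rows(out)
}

.pairwise_fit_one <- function(aln, ta, tb, opts) {
  sa <- aln$states[match(ta, aln$taxa), ]
  sb <- aln$states[match(tb, aln$taxa), ]
  keep <- !is.na(sa) & !is.na(sb)
  if (!any(keep)) stop("no overlapping non-missing codons for pair ",
                       ta, " / ", tb)
  sa <- sa[keep]; sb <- sb[keep]
  n <- length(sa)
  res <- tibble(taxon_a = ta, taxon_b = tb, omega = NA_real_,
                kappa = NA_real_, t = 0, n_codons = n)
  if (all(sa == sb)) return(res)

  counts <- rowSums(vapply(which(sa != sb), function(i)
    .count_syn_nonsyn_pair(sa[i], sb[i]), numeric(2)))
  sub <- codon_alignment(c(ta, tb), rbind(sa, sb))
  pi <- estimate_f3x4(sub)
  d <- lik_data(sub, ape::read.tree(text = sprintf("(%s:0.1,%s:0.1);", ta, tb)))

  objective <- function(th) {
    kappa <- exp(th[1]); omega <- exp(th[2]); t <- exp(th[3])
    cl <- class_loglik(d, kappa, pi, matrix(omega, 1, 2),
                       len = c(t / 2, t / 2))
    v <- -sum(cl[1, ] * d$w)
    if (!is.finite(v)) 1e10 else v
  }
  starts <- list(c(log(2), log(0.3), log(0.2)),
                 c(log(4), log(1), log(1)),
                 c(log(1.5), log(0.05), log(0.05)))
  best <- NULL
  for (i in seq_len(max(1, min(opts$n_restarts, length(starts))))) {
    r <- tryCatch(nlminb(starts[[i]], objective,
                         lower = c(.B$lkappa[1], .B$lomega[1], log(1e-7)),
                         upper = c(.B$lkappa[2], .B$lomega[2], log(20))),
                  error = function(e) NULL)
    if (!is.null(r) && (is.null(best) || r$objective < best$objective))
      best <- r
  }
  if (is.null(best)) stop("pairwise fit failed for ", ta, " / ", tb)
  res$kappa <- exp(best$par[1])
  res$t <- exp(best$par[3])
  res$omega <- if (counts["syn"] == 0 || counts["nonsyn"] == 0) NA_real_
               else exp(best$par[2])
  res
}

#' Degrees of freedom for the standard nested-model comparisons
#'
#' Frozen conventions: M1a vs M2a and M7 vs M8 use 2; M8fix vs M8,
#' and branch-site model A vs its null use 1; M0 vs free-ratio uses
#' (branches - 1); M1a vs clade model C uses 3.
#'
#' @param null_model,alt_model Model id strings as in `sel_fit$model`.
#' @param n_branches Needed for `M0` vs `free_ratio`.
#' @return Integer degrees of freedom.
#' @export
lrt_df <- function(null_model, alt_model, n_branches = NULL) {
  key <- paste(null_model, alt_model, sep = "~")
  switch(key,
    "M1a~M2a" = 2L,
    "M7~M8" = 2L,
    "M8fix~M8" = 1L,
    "branch_site_A_null~branch_site_A" = 1L,
    "M1a~branch_site_A" = 2L,
    "M1a~clade_C" = 3L,
    "M0~free_ratio" = {
      if (is.null(n_branches))
        stop("n_branches required for M0 vs free_ratio")
      as.integer(n_branches - 1L)
    },
    stop("no frozen df convention for ", key, "; pass df explicitly")
  )
}
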