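# Orchestration: the full selection scan (model fits + LRTs + site
# identification) and the reconstruction -> ddG -> statistics chain,
# with deterministic tabular/JSON outputs.

#' Run a selection scan over a set of codon models
#'
#' Fits M0 first (branch lengths co-estimated), then the requested site
#' and branch(-site) models, by default with branch lengths fixed at the
#' M0 estimates. Builds the standard nested LRTs present in the model
#' set (M0 vs free-ratio, M1a vs M2a, M7 vs M8, M8fix vs M8, branch-site
#' A vs its null, M1a vs clade C) and NEB/BEB site posteriors for M2a
#' and M8.
#'
#' @param aln A [codon_alignment()].
#' @param tree `ape::phylo` (marks required for branch-site/clade
#'   models).
#' @param models Character vector from `M0`, `free_ratio`, `M1a`, `M2a`,
#'   `M7`, `M8`, `M8fix`, `branch_site_A`, `clade_C`.
#' @param branch_lengths `"fixed_from_M0"` (default) or `"co_estimated"`
#'   for the post-M0 models.
#' @param beb Compute BEB site posteriors for M2a/M8 fits? (NEB is
#'   always computed for mixture fits.)
#' @param beb_grid_spec A [beb_grid()].
#' @param opts [fit_opts()].
#' @return A `selection_scan`: named list of fits plus `table` (one row
#'   per model: lnL and estimates), `lrts`, and `site_posteriors`.
#' @export
scan_selection <- function(aln, tree,
                           models = c("M0", "M1a", "M2a", "M7", "M8",
                                      "M8fix"),
                           branch_lengths = c("fixed_from_M0",
                                              "co_estimated"),
                           beb = TRUE, beb_grid_spec = beb_grid(),
                           opts = fit_opts()) {
  branch_lengths <- match.arg(branch_lengths)
  if (length(models) == 0) stop("empty model list")
  known <- c("M0", "free_ratio", "M1a", "M2a", "M7", "M8", "M8fix",
             "branch_site_A", "clade_C")
  bad <- setdiff(models, known)
  if (length(bad) > 0) stop("unknown models: ", paste(bad, collapse = ", "))

  fits <- list()
  fits$M0 <- fit_m0(aln, tree, opts = opts)
  base_tree <- fits$M0$tree # unrooted, optimized lengths, marks preserved
  post_mode <- if (branch_lengths == "fixed_from_M0") "fixed"
               else "co_estimated"

  for (m in setdiff(models, "M0")) {
    fits[[m]] <- switch(m,
      free_ratio = fit_free_ratio(aln, base_tree, opts = opts,
                                  branch_lengths = "co_estimated"),
      branch_site_A = fit_branch_site_a(aln, base_tree, null = FALSE,
                                        opts = opts,
                                        branch_lengths = post_mode),
      clade_C = fit_clade_model_c(aln, base_tree, opts = opts,
                                  branch_lengths = post_mode),
      fit_site_model(aln, base_tree, model = m, opts = opts,
                     branch_lengths = post_mode))
    if (m == "branch_site_A")
      fits$branch_site_A_null <- fit_branch_site_a(
        aln, base_tree, null = TRUE, opts = opts, branch_lengths = post_mode)
  }

  pairs <- list(c("M0", "free_ratio"), c("M1a", "M2a"), c("M7", "M8"),
                c("M8fix", "M8"), c("branch_site_A_null", "branch_site_A"),
                c("M1a", "branch_site_A"), c("M1a", "clade_C"))
  lrts <- list()
  for (p in pairs) {
    if (all(p %in% names(fits)))
      lrts[[paste(p, collapse = "_vs_")]] <- lrt(fits[[p[1]]], fits[[p[2]]])
  }
  lrts <- dplyr::bind_rows(lrts)

  posteriors <- list()
  for (m in intersect(names(fits), c("M1a", "M2a", "M7", "M8", "M8fix",
                                     "branch_site_A", "clade_C"))) {
    posteriors[[paste0(m, "_NEB")]] <- neb_site_posteriors(fits[[m]])
  }
  if (beb) {
    for (m in intersect(names(fits), c("M2a", "M8")))
      posteriors[[paste0(m, "_BEB")]] <-
        beb_site_posteriors(fits[[m]], grid = beb_grid_spec)
  }

  table <- dplyr::bind_rows(lapply(names(fits), function(m) {
    f <- fits[[m]]
    est <- unlist(f$params)
    est <- est[vapply(est, is.numeric, TRUE)]
    tibble(model = m, lnL = f$lnL,
           estimates = paste(sprintf("%s = %.5g", names(est), est),
                             collapse = ", "),
           kappa = f$kappa, np = f$np, convergence = f$convergence)
  }))

  structure(list(fits = fits, table = table, lrts = lrts,
                 site_posteriors = posteriors,
                 branch_lengths = branch_lengths),
            class = "selection_scan")
}

#' @export
print.selection_scan <- function(x, ...) {
  cat("<selection_scan>\n\nModel fits:\n")
  print(x$table[, c("model", "lnL", "np", "convergence")])
  if (nrow(x$lrts) > 0) {
    cat("\nLikelihood ratio tests:\n")
    print(x$lrts[, c("null_model", "alt_model", "statistic", "df", "p")])
  }
  invisible(x)
}

#' Sites selected by a scan
#'
#' @param scan A `selection_scan`.
#' @param model Which fitted model's posteriors to read (default `"M8"`).
#' @param method `"BEB"` (default) or `"NEB"`.
#' @param threshold Posterior threshold (default 0.5).
#' @return Integer vector of site numbers with `P(omega > 1)` above the
#'   threshold.
#' @export
selected_sites <- function(scan, model = "M8", method = "BEB",
                           threshold = 0.5) {
  key <- paste0(model, "_", method)
  post <- scan$site_posteriors[[key]]
  if (is.null(post)) stop("no posterior ", key, " in the scan")
  post$sites$site[post$sites$P_omega_gt1 > threshold]
}

#' Reconstruction -> substitutions -> stability report
#'
#' Fits branch lengths and gamma shape under Dayhoff+gamma, reconstructs
#' marginal ancestral sequences, maps substitutions onto branches, joins
#' stability effects, and (when a selected-site list is given) computes
#' the conditional probability of stabilization and the selected versus
#' non-selected group comparison. With no stability table the report is
#' produced in degraded mode: substitutions only, sums omitted.
#'
#' @param aa_aln An [aa_alignment()].
#' @param tree `ape::phylo` topology (lengths re-estimated).
#' @param ddg_table A `stability_table`, or `NULL`.
#' @param selected_site_list Integer sites under positive selection, or
#'   `NULL`.
#' @param model An [aa_model()].
#' @param numbering_offset Alignment-column to residue-number offset.
#' @param reversal_policy Passed to [join_ddg()].
#' @param opts [fit_opts()].
#' @return An `asr_ddg_report` list: `aa_fit`, `asr`, `substitutions`,
#'   `stability` (branch_stability or NULL), `cond_prob`, `group_test`.
#' @export
run_asr_ddg <- function(aa_aln, tree, ddg_table = NULL,
                        selected_site_list = NULL, model = aa_model(),
                        numbering_offset = 0,
                        reversal_policy = "require_entry",
                        opts = fit_opts(n_restarts = 2)) {
  fit <- fit_aa_branch_lengths(aa_aln, tree, model, opts = opts)
  asr <- marginal_asr(aa_aln, fit)
  subs <- map_substitutions(asr, numbering_offset = numbering_offset)
  stability <- NULL
  cond <- NULL
  group_test <- NULL
  if (!is.null(ddg_table) && nrow(subs) > 0) {
    stability <- join_ddg(subs, ddg_table, reversal_policy = reversal_policy)
    if (!is.null(selected_site_list)) {
      ann <- stability$substitutions
      cond <- tryCatch(
        conditional_prob_stabilizing(ann, selected_site_list),
        error = function(e) NULL)
      group_test <- tryCatch(
        compare_ddg_groups(ann, selected_site_list),
        error = function(e) NULL)
    }
  }
  structure(list(aa_fit = fit, asr = asr, substitutions = subs,
                 stability = stability, cond_prob = cond,
                 group_test = group_test,
                 degraded = is.null(ddg_table)),
            class = "asr_ddg_report")
}

#' @export
print.asr_ddg_report <- function(x, ...) {
  cat("<asr_ddg_report>\n")
  print(x$aa_fit)
  cat(sprintf("  %d substitutions mapped onto branches\n",
              nrow(x$substitutions)))
  if (x$degraded) {
    cat("  (no stability table: ddG sums omitted)\n")
  } else {
    cat(sprintf("  %d substitutions missing ddG entries\n",
                sum(x$stability$branches$n_missing)))
  }
  if (!is.null(x$cond_prob)) print(x$cond_prob)
  invisible(x)
}

# ---- serialization ---------------------------------------------------

# Branch naming for serialized fits: child-node descendant tip set,
# sorted and joined -- stable across edge reorderings.
.branch_names <- function(tree) {
  keys <- node_tipset_keys(tree)
  keys[tree$edge[, 2]]
}

#' Write a fit (or scan) to JSON
#'
#' Deterministic output: model id, lnL, parameter estimates, and branch
#' lengths keyed by the child node's descendant tip set. No timestamps.
#'
#' @param x A `sel_fit` or `selection_scan`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(x, path) {
  as_fit_list <- function(f) {
    list(model = f$model, lnL = f$lnL, kappa = f$kappa,
         params = f$params,
         convergence = f$convergence,
         branch_lengths = setNames(as.list(f$tree$edge.length),
                                   .branch_names(f$tree)))
  }
  payload <- if (inherits(x, "selection_scan")) {
    list(fits = lapply(x$fits, as_fit_list),
         lrts = x$lrts)
  } else {
    as_fit_list(x)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a per-site posterior report to TSV
#'
#' @param post A `site_posterior`.
#' @param path Output path.
#' @param thresholds Tier thresholds for the `tier` column.
#' @return `path`, invisibly.
#' @export
write_site_report <- function(post, path, thresholds = c(0.5, 0.95, 0.99)) {
  tab <- post$sites
  th <- sort(thresholds)
  tab$tier <- vapply(tab$P_omega_gt1, function(p) {
    above <- th[p > th]
    if (length(above) == 0) "" else paste0(">", format(max(above)))
  }, "")
  tab$method <- post$method
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Write a per-branch stability report to TSV
#'
#' @param x A `branch_stability`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_branch_report <- function(x, path) {
  readr::write_tsv(x$branches, path)
  invisible(path)
}
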