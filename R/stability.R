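# Folding-stability bookkeeping: mutation -> ddG tables (FoldX-style),
# joins to branch substitutions, per-branch sums, and a clearly-labelled
# surrogate ddG generator for testing. Sign convention throughout:
# ddG < 0 kcal/mol = stabilizing.

#' Load a mutation stability table
#'
#' Reads a TSV with columns `site`, `from`, `to`, `ddg` (kcal/mol) and
#' optional `replicate`/`source`. Repeated rows for the same mutation are
#' replicate runs (e.g. the five FoldX Build-Model repeats) and are
#' averaged. Values are normalized internally to the negative-stabilizing
#' convention.
#'
#' @param path TSV path.
#' @param convention Sign convention of the *input file*:
#'   `"neg_stabilizing"` (default; stored as-is) or `"pos_stabilizing"`
#'   (negated on load).
#' @param source Optional source tag recorded on the table.
#' @return A `stability_table`: tibble with `site`, `from`, `to`, `ddg`,
#'   `n_replicates`, `source`.
#' @export
load_ddg_table <- function(path,
                           convention = c("neg_stabilizing",
                                          "pos_stabilizing"),
                           source = NULL) {
  convention <- match.arg(convention)
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         progress = FALSE)
  stability_table(raw, convention = convention,
                  source = source %||% basename(path))
}

#' Build a stability table from a data frame
#'
#' @param x Data frame with columns `site`, `from`, `to`, `ddg`
#'   (replicate rows allowed).
#' @inheritParams load_ddg_table
#' @return A `stability_table`.
#' @export
stability_table <- function(x, convention = c("neg_stabilizing",
                                              "pos_stabilizing"),
                            source = "table") {
  convention <- match.arg(convention)
  need <- c("site", "from", "to", "ddg")
  if (nrow(x) == 0) {
    warning("empty stability table", call. = FALSE)
    out <- tibble(site = integer(0), from = character(0),
                  to = character(0), ddg = numeric(0),
                  n_replicates = integer(0), source = character(0))
    return(structure(out, class = c("stability_table", class(out))))
  }
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0)
    stop("stability table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  if (any(!is.finite(x$ddg))) stop("non-finite ddg values")
  if (any(x$from == x$to))
    stop("self-mutations (from == to) are not allowed in a stability table")
  sgn <- if (convention == "pos_stabilizing") -1 else 1
  out <- x |>
    dplyr::group_by(.data$site, .data$from, .data$to) |>
    dplyr::summarise(ddg = mean(sgn * .data$ddg),
                     n_replicates = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(source = source)
  structure(out, class = c("stability_table", class(out)))
}

#' Join substitutions to stability effects and sum per branch
#'
#' Annotates each branch substitution with its table ddG. Under the
#' `"antisymmetric"` policy a missing X->Y entry is filled with
#' -ddG(Y->X) when the reverse entry exists, and flagged; the default
#' `"require_entry"` leaves it missing (FoldX ddG is not exactly
#' antisymmetric). Missing entries are excluded from branch sums and
#' counted, never silently dropped.
#'
#' @param subs Substitution tibble from [map_substitutions()] (columns
#'   `branch`, `site`, `from`, `to`).
#' @param table A `stability_table`.
#' @param reversal_policy `"require_entry"` (default) or
#'   `"antisymmetric"`.
#' @return A `branch_stability` list: `substitutions` (annotated tibble
#'   with `ddg` and `filled_by_reversal`) and `branches` (per-branch
#'   `sum_ddg`, `n_substitutions`, `n_missing`).
#' @export
join_ddg <- function(subs, table,
                     reversal_policy = c("require_entry", "antisymmetric")) {
  reversal_policy <- match.arg(reversal_policy)
  ann <- dplyr::left_join(
    subs,
    dplyr::select(table, "site", "from", "to", "ddg"),
    by = c("site", "from", "to"))
  ann$filled_by_reversal <- FALSE
  if (reversal_policy == "antisymmetric") {
    rev_tab <- dplyr::select(table, site = "site", from = "to",
                             to = "from", rev_ddg = "ddg")
    ann <- dplyr::left_join(ann, rev_tab, by = c("site", "from", "to"))
    fill <- is.na(ann$ddg) & !is.na(ann$rev_ddg)
    ann$ddg[fill] <- -ann$rev_ddg[fill]
    ann$filled_by_reversal <- fill
    ann$rev_ddg <- NULL
  }
  branches <- ann |>
    dplyr::group_by(.data$branch) |>
    dplyr::summarise(
      sum_ddg = sum(.data$ddg, na.rm = TRUE),
      n_substitutions = dplyr::n(),
      n_missing = sum(is.na(.data$ddg)),
      .groups = "drop")
  structure(list(substitutions = ann, branches = branches,
                 reversal_policy = reversal_policy),
            class = "branch_stability")
}

#' @export
print.branch_stability <- function(x, ...) {
  cat(sprintf("<branch_stability: %d substitutions on %d branches, %d missing ddG>\n",
              nrow(x$substitutions), nrow(x$branches),
              sum(x$branches$n_missing)))
  print(x$branches)
  invisible(x)
}

#' Plot per-branch stability change
#'
#' Bar height is the branch ddG sum; stabilizing branches (sum < 0) in
#' red, destabilizing in blue, mirroring the usual presentation.
#'
#' @param object A `branch_stability`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.branch_stability <- function(object, ...) {
  b <- dplyr::mutate(object$branches,
                     direction = ifelse(.data$sum_ddg < 0,
                                        "stabilizing", "destabilizing"))
  ggplot2::ggplot(b, ggplot2::aes(x = .data$branch, y = .data$sum_ddg,
                                  fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(stabilizing = "firebrick",
                                          destabilizing = "steelblue")) +
    ggplot2::labs(x = NULL, y = "branch sum ΔΔG (kcal/mol)") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}

# Helix propensity scores used by the surrogate: Gly and Pro break
# helices, Ala/Leu/Glu form them. Replacing a breaker by a former lowers
# the surrogate ddG (helix context only).
.helix_score <- c(G = 0.8, P = 0.6, A = -0.2, L = -0.15, E = -0.1)
# Kyte-Doolittle-style hydrophobic gain applied at buried sites.
.hydrophobicity <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                     Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                     L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                     S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' Surrogate mutation stability effects (testing stand-in)
#'
#' A synthetic ddG generator, NOT a force-field reimplementation: draws
#' from a destabilizing-shifted distribution whose generic mean is +1.2
#' kcal/mol (the field's consensus average effect of a random point
#' mutation on a globular protein), with documented deterministic
#' offsets: in helix context, replacing a helix breaker (Gly/Pro) with a
#' helix former (Ala/Leu/Glu) shifts the draw negative (and the reverse
#' positive); at buried sites, hydrophobicity gains shift negative.
#'
#' @param from,to Single-letter residues (must differ).
#' @param site_class `"generic"`, `"helix"`, `"buried"`, or `"exposed"`.
#' @param seed Integer seed (draws are deterministic for a seed).
#' @param n Number of draws.
#' @return Numeric vector of ddG values (kcal/mol, negative =
#'   stabilizing).
#' @export
surrogate_ddg <- function(from, to,
                          site_class = c("generic", "helix", "buried",
                                         "exposed"),
                          seed = 1, n = 1) {
  site_class <- match.arg(site_class)
  if (any(from == to)) stop("from and to residues must differ")
  shift <- 0
  if (site_class == "helix") {
    h <- function(r) ifelse(r %in% names(.helix_score), .helix_score[r], 0)
    shift <- shift + (h(to) - h(from))
  }
  if (site_class == "buried") {
    shift <- shift - 0.25 * (.hydrophobicity[to] - .hydrophobicity[from])
  }
  local_seed(seed, {
    # gamma(shape 2, scale 1.1) - 1 has mean +1.2, right skew, ~23%
    # stabilizing mass
    rgamma(n, shape = 2, scale = 1.1) - 1 + shift
  })
}

#' Surrogate stability table for a substitution set
#'
#' Convenience wrapper labelling its output as surrogate data: one
#' averaged entry per distinct (site, from, to) among `subs`, drawn with
#' [surrogate_ddg()] and `n_rep` replicates.
#'
#' @param subs Substitution tibble (`site`, `from`, `to`).
#' @param site_class Passed to [surrogate_ddg()].
#' @param n_rep Replicates averaged per mutation (default 5).
#' @param seed Integer seed.
#' @return A `stability_table` with source `"surrogate"`.
#' @export
surrogate_stability_table <- function(subs, site_class = "generic",
                                      n_rep = 5, seed = 1) {
  u <- dplyr::distinct(subs[, c("site", "from", "to")])
  rows <- vector("list", nrow(u))
  for (i in seq_len(nrow(u))) {
    vals <- surrogate_ddg(u$from[i], u$to[i], site_class,
                          seed = seed + 7L * i, n = n_rep)
    rows[[i]] <- tibble(site = u$site[i], from = u$from[i], to = u$to[i],
                        ddg = vals)
  }
  stability_table(dplyr::bind_rows(rows), source = "surrogate")
}
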