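# Alignment containers and FASTA/Newick input-output.

new_alignment <- function(taxa, states, class) {
  stopifnot(is.matrix(states), nrow(states) == length(taxa))
  if (anyDuplicated(taxa))
    stop("duplicate taxon names: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  rownames(states) <- taxa
  structure(list(taxa = taxa, states = states, n_sites = ncol(states)),
            class = class)
}

#' Construct a codon alignment from encoded states
#'
#' @param taxa Character vector of unique taxon names.
#' @param states Integer matrix (taxa x codon sites) of states in 1..61,
#'   `NA` = missing. In-frame stops (state 0) are rejected.
#' @return A `codon_alignment`.
#' @export
codon_alignment <- function(taxa, states) {
  bad <- which(!is.na(states) & states == 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("in-frame stop codon in taxon '%s' at codon site %d",
                 taxa[bad[1, 1]], bad[1, 2]))
  new_alignment(taxa, states, c("codon_alignment", "selstab_alignment"))
}

#' Construct an amino-acid alignment from encoded states
#'
#' @param taxa Character vector of unique taxon names.
#' @param states Integer matrix (taxa x sites) of states in 1..20
#'   ([AA_LETTERS] order), `NA` = missing.
#' @return An `aa_alignment`.
#' @export
aa_alignment <- function(taxa, states) {
  new_alignment(taxa, states, c("aa_alignment", "selstab_alignment"))
}

#' @export
print.selstab_alignment <- function(x, ...) {
  kind <- if (inherits(x, "codon_alignment")) "codon" else "amino-acid"
  cat(sprintf("<%s alignment: %d taxa, %d sites, %.1f%% missing>\n",
              kind, length(x$taxa), x$n_sites,
              100 * mean(is.na(x$states))))
  invisible(x)
}

#' @export
dim.selstab_alignment <- function(x) dim(x$states)

#' Tidy view of an alignment
#'
#' @param x An alignment.
#' @param ... Unused.
#' @return A tibble with one row per (taxon, site) carrying the decoded
#'   codon or residue.
#' @export
as_tibble.selstab_alignment <- function(x, ...) {
  dec <- if (inherits(x, "codon_alignment")) {
    decode_codon(as.vector(x$states))
  } else {
    ifelse(is.na(as.vector(x$states)), "-", AA_LETTERS[as.vector(x$states)])
  }
  tibble(
    taxon = rep(x$taxa, times = x$n_sites),
    site = rep(seq_len(x$n_sites), each = length(x$taxa)),
    state = dec
  )
}

#' Read an aligned FASTA file
#'
#' Nucleotide input is codon-encoded over the 61 sense codons: a gap or
#' ambiguity in any of a codon's three positions makes the whole codon
#' missing for that taxon/site (the likelihood then uses a flat partial
#' vector). In-frame stop codons are an error, with the offending taxon
#' and codon column named.
#'
#' @param path FASTA file of equal-length records.
#' @param kind `"nucleotide"` (codon-encoded) or `"amino_acid"`.
#' @return A [codon_alignment()] or [aa_alignment()].
#' @export
read_fasta <- function(path, kind = c("nucleotide", "amino_acid")) {
  kind <- match.arg(kind)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path)
  taxa <- sub("\\s.*$", "", names(set))
  widths <- Biostrings::width(set)
  if (length(unique(widths)) != 1)
    stop("ragged alignment: sequence lengths ",
         paste(sort(unique(widths)), collapse = ", "))
  seqs <- as.character(set)
  if (kind == "nucleotide") {
    w <- widths[1]
    if (w %% 3 != 0)
      stop("nucleotide alignment length ", w, " is not divisible by 3")
    n_sites <- w %/% 3
    states <- matrix(NA_integer_, length(taxa), n_sites)
    starts <- 3L * seq_len(n_sites) - 2L
    for (i in seq_along(seqs)) {
      trip <- substring(seqs[i], starts, starts + 2L)
      st <- encode_codon(trip)
      stop_at <- which(!is.na(st) & st == 0L)
      if (length(stop_at) > 0)
        stop(sprintf("in-frame stop codon in taxon '%s' at codon site %d",
                     taxa[i], stop_at[1]))
      states[i, ] <- st
    }
    codon_alignment(taxa, states)
  } else {
    chars <- strsplit(toupper(seqs), "", fixed = TRUE)
    states <- do.call(rbind, lapply(chars, encode_aa))
    aa_alignment(taxa, states)
  }
}

#' Write an alignment to FASTA
#'
#' Missing codons are written as `---`, missing residues as `-`, so a
#' write/read round trip reproduces the encoded states exactly.
#'
#' @param x An alignment.
#' @param path Output path.
#' @param wrap Line width (default 60 columns; `Inf` = unwrapped).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, wrap = 60) {
  lines <- character(0)
  for (i in seq_along(x$taxa)) {
    if (inherits(x, "codon_alignment")) {
      s <- paste(decode_codon(x$states[i, ]), collapse = "")
    } else {
      r <- ifelse(is.na(x$states[i, ]), "-", AA_LETTERS[x$states[i, ]])
      s <- paste(r, collapse = "")
    }
    if (is.finite(wrap) && nchar(s) > wrap) {
      starts <- seq(1, nchar(s), by = wrap)
      s <- substring(s, starts, pmin(starts + wrap - 1, nchar(s)))
    }
    lines <- c(lines, paste0(">", x$taxa[i]), s)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Count fully conserved alignment columns
#'
#' A column counts as conserved when every taxon carries the same
#' non-missing state.
#'
#' @param x An alignment.
#' @return Integer count.
#' @export
count_conserved_columns <- function(x) {
  sum(apply(x$states, 2, function(col) {
    !anyNA(col) && length(unique(col)) == 1
  }))
}

# ---- Newick ----------------------------------------------------------

#' Read a Newick tree with optional branch/clade marks
#'
#' Supports the field's de facto foreground-mark dialect: a `#<int>`
#' token after a node labels the branch leading to that node (e.g. the
#' foreground branch of a branch-site test); `$<int>` labels the whole
#' clade (stem branch plus all descendant branches), as used by clade
#' models. Marks are stored per node in `attr(tree, "branch_mark")` and
#' `attr(tree, "clade_mark")` (integer vectors indexed by node id, 0 =
#' unmarked), so they survive edge reordering.
#'
#' @param x Path to a Newick file, or a Newick string.
#' @param default_length If branch lengths are absent, error (default)
#'   unless a numeric `default_length` is supplied to fill them.
#' @return An `ape::phylo` with mark attributes.
#' @export
read_newick <- function(x, default_length = NULL) {
  txt <- if (length(x) == 1 && grepl("(", x, fixed = TRUE)) x
         else paste(readLines(x, warn = FALSE), collapse = "")
  txt <- gsub("\\s+", "", txt)
  if (nchar(gsub("[^(]", "", txt)) != nchar(gsub("[^)]", "", txt)))
    stop("unbalanced parentheses in Newick input")
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) stop("Newick parse error: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error")

  n_node <- ape::Ntip(tree) + tree$Nnode
  labels <- c(tree$tip.label,
              if (is.null(tree$node.label)) rep("", tree$Nnode)
              else tree$node.label)
  branch_mark <- integer(n_node)
  clade_mark <- integer(n_node)
  strip_marks <- function(lab) {
    m <- regmatches(lab, regexpr("[#$][0-9]+$", lab))
    list(lab = sub("[#$][0-9]+$", "", lab), mark = m)
  }
  for (i in seq_len(n_node)) {
    s <- strip_marks(labels[i])
    if (length(s$mark) == 1 && nzchar(s$mark)) {
      val <- as.integer(substring(s$mark, 2))
      if (startsWith(s$mark, "#")) branch_mark[i] <- val
      else clade_mark[i] <- val
    }
    labels[i] <- s$lab
  }
  tree$tip.label <- labels[seq_len(ape::Ntip(tree))]
  nl <- labels[(ape::Ntip(tree) + 1):n_node]
  tree$node.label <- if (all(nl == "")) NULL else nl

  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip names: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length)) {
    if (is.null(default_length))
      stop("tree has no branch lengths; supply default_length to fill them")
    tree$edge.length <- rep(default_length, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    if (is.null(default_length))
      stop("tree has missing branch lengths; supply default_length")
    tree$edge.length[is.na(tree$edge.length)] <- default_length
  }
  if (any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed")
  if (any(!is.finite(tree$edge.length)))
    stop("non-finite branch lengths")

  # expand clade marks: a $n node marks its stem and all descendants
  marked <- which(clade_mark > 0)
  for (nd in marked) {
    desc <- tree_descendants(tree, nd)
    clade_mark[desc] <- clade_mark[nd]
  }
  attr(tree, "branch_mark") <- branch_mark
  attr(tree, "clade_mark") <- clade_mark
  tree
}

# All nodes in the subtree rooted at `node`, including `node` itself.
tree_descendants <- function(tree, node) {
  out <- node
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  while (length(kids) > 0) {
    out <- c(out, kids)
    kids <- tree$edge[tree$edge[, 1] %in% kids, 2]
  }
  out
}

#' Write a tree to Newick
#'
#' Marks are stripped by default; `marks = TRUE` re-emits `#n` branch
#' marks on marked nodes and `$n` clade marks on the top node of each
#' maximal marked subtree.
#'
#' @param tree An `ape::phylo`, possibly carrying mark attributes.
#' @param path Output path, or `NULL` to return the string.
#' @param marks Re-emit mark tokens?
#' @return The Newick string, invisibly if written to a file.
#' @export
write_newick <- function(tree, path = NULL, marks = FALSE) {
  tr <- tree
  if (marks) {
    bm <- attr(tree, "branch_mark") %||% integer(0)
    cm <- attr(tree, "clade_mark") %||% integer(0)
    n_tip <- ape::Ntip(tr)
    n_node <- n_tip + tr$Nnode
    lab <- c(tr$tip.label,
             if (is.null(tr$node.label)) rep("", tr$Nnode) else tr$node.label)
    parent_of <- rep(NA_integer_, n_node)
    parent_of[tr$edge[, 2]] <- tr$edge[, 1]
    for (i in seq_len(n_node)) {
      if (length(bm) >= i && bm[i] > 0)
        lab[i] <- paste0(lab[i], "#", bm[i])
      if (length(cm) >= i && cm[i] > 0) {
        p <- parent_of[i]
        top <- is.na(p) || length(cm) < p || cm[p] != cm[i]
        if (top) lab[i] <- paste0(lab[i], "$", cm[i])
      }
    }
    tr$tip.label <- lab[seq_len(n_tip)]
    nl <- lab[(n_tip + 1):n_node]
    tr$node.label <- if (all(nl == "")) NULL else nl
  }
  s <- ape::write.tree(tr)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Tidy edge table of a tree
#'
#' @param tree An `ape::phylo` (mark attributes honored if present).
#' @return A tibble with one row per branch: parent and child node ids,
#'   length, child label (for tips), and branch/clade marks.
#' @export
tree_edges <- function(tree) {
  bm <- attr(tree, "branch_mark") %||% integer(ape::Ntip(tree) + tree$Nnode)
  cm <- attr(tree, "clade_mark") %||% integer(ape::Ntip(tree) + tree$Nnode)
  child <- tree$edge[, 2]
  tibble(
    edge = seq_len(nrow(tree$edge)),
    parent = tree$edge[, 1],
    child = child,
    length = tree$edge.length %||% rep(NA_real_, nrow(tree$edge)),
    label = ifelse(child <= ape::Ntip(tree), tree$tip.label[child], NA),
    branch_mark = bm[child],
    clade_mark = cm[child]
  )
}

#' Mark a branch or clade programmatically
#'
#' @param tree An `ape::phylo`.
#' @param node Node id (tip or internal) whose incoming branch (for
#'   `mark_branch`) or whole subtree including its stem (for
#'   `mark_clade`) is marked.
#' @param mark Integer mark value (default 1).
#' @return The tree with updated mark attributes.
#' @export
mark_branch <- function(tree, node, mark = 1L) {
  n_node <- ape::Ntip(tree) + tree$Nnode
  bm <- attr(tree, "branch_mark") %||% integer(n_node)
  bm[node] <- as.integer(mark)
  attr(tree, "branch_mark") <- bm
  tree
}

#' @rdname mark_branch
#' @export
mark_clade <- function(tree, node, mark = 1L) {
  n_node <- ape::Ntip(tree) + tree$Nnode
  cm <- attr(tree, "clade_mark") %||% integer(n_node)
  cm[tree_descendants(tree, node)] <- as.integer(mark)
  attr(tree, "clade_mark") <- cm
  tree
}

# Validate that tree tips all have alignment rows; returns tip order.
check_taxa <- function(aln, tree) {
  missing <- setdiff(tree$tip.label, aln$taxa)
  if (length(missing) > 0)
    stop("tree tips absent from alignment: ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}
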