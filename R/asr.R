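# Marginal ancestral sequence reconstruction and per-branch substitution
# mapping.

#' Marginal ancestral sequence reconstruction
#'
#' For every internal node and site, the posterior distribution over the
#' 20 amino acids given all tip data (inside-outside recursion),
#' integrating over the discrete-gamma rate categories. The MAP residue
#' is extracted per node and site; ties break to the alphabetically first
#' residue and are flagged. Ancestors are always assigned a residue (tip
#' gaps are treated as missing data, never reconstructed as gaps).
#'
#' @param aln An [aa_alignment()].
#' @param tree An `ape::phylo` with fitted branch lengths, or an
#'   `aa_fit` from [fit_aa_branch_lengths()] (its tree and alpha are
#'   used).
#' @param model An [aa_model()] with `alpha` set; ignored when `tree` is
#'   an `aa_fit`.
#' @return An `asr` object: per-node posterior matrices, MAP sequences,
#'   and a tidy per-node-site summary (see [tidy.asr()]).
#' @export
marginal_asr <- function(aln, tree, model = NULL) {
  if (inherits(tree, "aa_fit")) {
    model <- tree$model
    tree <- tree$tree
  }
  if (is.null(model) || is.null(model$alpha))
    stop("supply an aa_model with alpha set, or an aa_fit")
  check_taxa(aln, tree)
  d <- lik_data(aln, tree)
  pi <- aa_freqs(model, aln)
  Q <- aa_Q(model, pi)
  rates <- gamma_class_rates(model$alpha, model$k)
  K <- length(rates)
  S <- 20
  E <- nrow(d$edge)
  P <- ncol(d$tips)
  n_tip <- d$n_tip
  root <- d$edge[E, 1]
  internal <- sort(unique(d$edge[, 1]))

  # per-(node, site, category) log-posterior contributions
  logpost <- array(-Inf, c(S, P, K, length(internal)))
  dimnames(logpost) <- NULL
  node_row <- match(seq_len(d$n_node), internal)

  tip_partial <- function(p) {
    m <- matrix(0, S, P)
    for (j in seq_len(P)) {
      s <- d$tips[p, j]
      if (s <= 0) m[, j] <- 1 else m[s, j] <- 1
    }
    m
  }

  for (k in seq_len(K)) {
    Pm <- lapply(seq_len(E), function(e)
      trans_prob(Q, pi, d$len[e] * rates[k]))

    inside <- vector("list", d$n_node)
    ls_in <- matrix(0, d$n_node, P)
    msg <- vector("list", E)
    ls_msg <- matrix(0, E, P)

    for (e in seq_len(E)) {
      par <- d$edge[e, 1]; ch <- d$edge[e, 2]
      chpart <- if (ch <= n_tip) tip_partial(ch) else inside[[ch]]
      m <- Pm[[e]] %*% chpart
      cmax <- apply(m, 2, max)
      cmax[cmax <= 0] <- 1
      m <- sweep(m, 2, cmax, "/")
      msg[[e]] <- m
      ls_msg[e, ] <- (if (ch <= n_tip) 0 else ls_in[ch, ]) + log(cmax)
      if (is.null(inside[[par]])) {
        inside[[par]] <- m
        ls_in[par, ] <- ls_msg[e, ]
      } else {
        inside[[par]] <- inside[[par]] * m
        ls_in[par, ] <- ls_in[par, ] + ls_msg[e, ]
      }
    }

    outside <- vector("list", d$n_node)
    ls_out <- matrix(0, d$n_node, P)
    outside[[root]] <- matrix(pi, S, P)
    for (e in rev(seq_len(E))) { # preorder
      par <- d$edge[e, 1]; ch <- d$edge[e, 2]
      if (ch <= n_tip) next
      sibs <- setdiff(which(d$edge[, 1] == par), e)
      acc <- outside[[par]]
      ls <- ls_out[par, ]
      for (se in sibs) {
        acc <- acc * msg[[se]]
        ls <- ls + ls_msg[se, ]
      }
      o <- crossprod(Pm[[e]], acc)
      cmax <- apply(o, 2, max)
      cmax[cmax <= 0] <- 1
      outside[[ch]] <- sweep(o, 2, cmax, "/")
      ls_out[ch, ] <- ls + log(cmax)
    }

    for (nd in internal) {
      lp <- log(inside[[nd]]) + log(outside[[nd]])
      lp <- sweep(lp, 2, ls_in[nd, ] + ls_out[nd, ], "+") + log(1 / K)
      logpost[, , k, node_row[nd]] <- lp
    }
  }

  posts <- vector("list", length(internal))
  names(posts) <- as.character(internal)
  for (i in seq_along(internal)) {
    lp <- logpost[, , , i, drop = FALSE]
    dim(lp) <- c(S, P, K)
    mx <- apply(lp, 2, max)
    pr <- matrix(0, S, P)
    for (k in seq_len(K))
      pr <- pr + exp(sweep(matrix(lp[, , k], S, P), 2, mx, "-"))
    pr <- sweep(pr, 2, colSums(pr), "/")
    posts[[i]] <- pr[, d$pattern_of_site, drop = FALSE]
    rownames(posts[[i]]) <- AA_LETTERS
  }

  n_sites <- length(d$pattern_of_site)
  rows <- vector("list", length(internal))
  for (i in seq_along(internal)) {
    pr <- posts[[i]]
    map_idx <- apply(pr, 2, which.max) # ties -> first = alphabetical? no:
    # AA_LETTERS is PAML order; enforce alphabetical tie-break explicitly
    tie <- logical(n_sites)
    for (s in seq_len(n_sites)) {
      mx <- max(pr[, s])
      cand <- which(pr[, s] >= mx - 1e-12)
      if (length(cand) > 1) {
        tie[s] <- TRUE
        cand <- cand[order(AA_LETTERS[cand])]
      }
      map_idx[s] <- cand[1]
    }
    second <- vapply(seq_len(n_sites), function(s) {
      o <- order(pr[, s], decreasing = TRUE)
      o[2]
    }, 0L)
    rows[[i]] <- tibble(
      node = internal[i],
      site = seq_len(n_sites),
      map_residue = AA_LETTERS[map_idx],
      map_prob = pr[cbind(map_idx, seq_len(n_sites))],
      alt_residue = AA_LETTERS[second],
      alt_prob = pr[cbind(second, seq_len(n_sites))],
      tie = tie
    )
  }
  summary <- dplyr::bind_rows(rows)

  map_states <- matrix(NA_integer_, length(internal), n_sites)
  for (i in seq_along(internal))
    map_states[i, ] <- match(summary$map_residue[summary$node == internal[i]],
                             AA_LETTERS)
  rownames(map_states) <- as.character(internal)

  structure(list(
    tree = d$tree,
    internal_nodes = internal,
    posterior = posts,
    map_states = map_states,
    summary = summary,
    mean_inference_prob = mean(summary$map_prob),
    alpha = model$alpha,
    k = model$k,
    taxa_states = aln$states[match(d$tree$tip.label, aln$taxa), ,
                             drop = FALSE]
  ), class = "asr")
}

#' @export
print.asr <- function(x, ...) {
  cat(sprintf("<asr: %d internal nodes, %d sites, mean MAP posterior %.4f>\n",
              length(x$internal_nodes), ncol(x$map_states),
              x$mean_inference_prob))
  amb <- dplyr::filter(x$summary, .data$map_prob < 0.9)
  if (nrow(amb) > 0)
    cat(sprintf("  %d node-site pairs with MAP posterior < 0.9\n", nrow(amb)))
  invisible(x)
}

#' Tidy per-node-site reconstruction summary
#'
#' One row per (internal node, site): the MAP residue and posterior, the
#' runner-up residue (reported because ambiguous sites with posterior in
#' 0.5-0.9 are best read with their alternative state), and a tie flag.
#'
#' @param x An `asr`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.asr <- function(x, ...) x$summary

#' Extract reconstructed ancestor sequences
#'
#' @param x An `asr`.
#' @param nodes Internal node ids (default all).
#' @return Named character vector of MAP amino-acid sequences.
#' @export
asr_sequences <- function(x, nodes = x$internal_nodes) {
  vapply(as.character(nodes), function(nd) {
    paste(AA_LETTERS[x$map_states[nd, ]], collapse = "")
  }, "")
}

#' Write reconstructed ancestor sequences to FASTA
#'
#' One record per internal node, labelled `node<id>` (or the tree's own
#' node label when present).
#'
#' @param x An `asr`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_asr_fasta <- function(x, path) {
  seqs <- asr_sequences(x)
  n_tip <- ape::Ntip(x$tree)
  labs <- vapply(x$internal_nodes, function(nd) {
    nl <- x$tree$node.label[nd - n_tip]
    if (!is.null(nl) && length(nl) == 1 && nzchar(nl)) nl
    else paste0("node", nd)
  }, "")
  writeLines(as.vector(rbind(paste0(">", labs), unname(seqs))), path)
  invisible(path)
}

#' Map amino-acid substitutions onto branches
#'
#' Compares the MAP sequence at each branch's parent node with the MAP
#' (internal child) or observed (tip child) sequence and emits one record
#' per differing site, in parent-to-child polarity, using the `XnY`
#' notation (e.g. `G129A`). Sites where the tip state is missing are
#' skipped.
#'
#' @param asr An [marginal_asr()] result.
#' @param numbering_offset Integer added to the alignment column to give
#'   the reported residue number (mature-chain numbering etc.; default 0).
#' @return A tibble: `parent_node`, `child_node`, `branch`, `site`,
#'   `from`, `to`, `notation`.
#' @export
map_substitutions <- function(asr, numbering_offset = 0) {
  tre <- asr$tree
  n_tip <- ape::Ntip(tre)
  rows <- list()
  node_name <- function(nd) {
    if (nd <= n_tip) tre$tip.label[nd] else paste0("node", nd)
  }
  for (e in seq_len(nrow(tre$edge))) {
    par <- tre$edge[e, 1]; ch <- tre$edge[e, 2]
    pseq <- asr$map_states[as.character(par), ]
    cseq <- if (ch <= n_tip) asr$taxa_states[ch, ]
            else asr$map_states[as.character(ch), ]
    diffs <- which(!is.na(cseq) & pseq != cseq)
    if (length(diffs) == 0) next
    rows[[length(rows) + 1]] <- tibble(
      parent_node = par,
      child_node = ch,
      branch = paste0(node_name(par), "->", node_name(ch)),
      site = diffs + numbering_offset,
      from = AA_LETTERS[pseq[diffs]],
      to = AA_LETTERS[cseq[diffs]]
    )
  }
  out <- if (length(rows) == 0) {
    tibble(parent_node = integer(0), child_node = integer(0),
           branch = character(0), site = integer(0),
           from = character(0), to = character(0))
  } else dplyr::bind_rows(rows)
  out$notation <- paste0(out$from, out$site, out$to)
  out
}
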