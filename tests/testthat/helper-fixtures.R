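# Shared fixtures, built in code at test time.

# Minimal hand-checkable codon alignment: two taxa, ATG TTT / ATG TTC.
tiny_fasta <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "tiny.fasta")
  writeLines(c(">a", "ATGTTT", ">b", "ATGTTC"), path)
  path
}

uniform_pi <- rep(1 / 61, 61)

# A small fixed quartet tree with moderate lengths.
quartet_tree <- function() {
  read_newick("((A:0.1,B:0.25):0.15,(C:0.2,D:0.05):0.1);")
}

# Deterministic simulated codon data under M0 for reuse across tests.
m0_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tr <- sim_tree(8, 0.15, seed = 101)
      aln <- simulate_codon_alignment(
        tr, 250, kappa = 2,
        classes = tibble::tibble(prop = 1, omega = 0.25), seed = 102)
      cache <<- list(tree = tr, aln = aln)
    }
    cache
  }
})

# Brute-force codon log-likelihood by enumeration over internal states
# (works for any tree with <= 3 internal nodes).
brute_force_codon_lnl <- function(aln, tree, kappa, omega, pi) {
  pr <- ape::reorder.phylo(tree, "postorder")
  st <- aln$states[match(pr$tip.label, aln$taxa), , drop = FALSE]
  E <- pr$edge
  n_tip <- ape::Ntip(pr)
  ints <- sort(unique(E[, 1]))
  stopifnot(length(ints) <= 3)
  root <- E[nrow(E), 1]
  Q <- codon_Q(kappa, omega, pi)
  Pm <- lapply(seq_len(nrow(E)), function(e)
    trans_prob(Q, pi, pr$edge.length[e]))
  grid <- do.call(expand.grid, rep(list(1:61), length(ints)))
  total <- 0
  for (s in seq_len(ncol(st))) {
    p <- pi[grid[, match(root, ints)]]
    for (e in seq_len(nrow(E))) {
      par <- E[e, 1]; ch <- E[e, 2]
      ps <- grid[, match(par, ints)]
      cs <- if (ch <= n_tip) rep(st[ch, s], nrow(grid))
            else grid[, match(ch, ints)]
      p <- p * Pm[[e]][cbind(ps, cs)]
    }
    total <- total + log(sum(p))
  }
  total
}
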