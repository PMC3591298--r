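# Goldman-Yang codon substitution machinery: F3X4 equilibrium
# frequencies, rate-matrix construction, and transition probabilities.

# Structural facts about the 61x61 codon space, computed once: which
# pairs differ at exactly one nucleotide, whether that change is a
# transition, and whether it is nonsynonymous.
.codon_struct <- function() {
  cache <- .genetic_code()
  if (is.null(cache$struct)) {
    codons <- cache$codons
    aa <- cache$aa
    n <- length(codons)
    m <- do.call(rbind, strsplit(codons, ""))
    ndiff <- matrix(0L, n, n)
    for (p in 1:3) ndiff <- ndiff + outer(m[, p], m[, p], "!=")
    single <- ndiff == 1L
    is_ts <- matrix(FALSE, n, n)
    for (p in 1:3) {
      pu <- outer(m[, p], m[, p], function(a, b) {
        (a == "A" & b == "G") | (a == "G" & b == "A") |
          (a == "C" & b == "T") | (a == "T" & b == "C")
      })
      is_ts <- is_ts | (pu & single)
    }
    nonsyn <- outer(aa, aa, "!=")
    cache$struct <- list(single = single, is_ts = is_ts & single,
                         nonsyn = nonsyn & single)
  }
  cache$struct
}

#' F3X4 codon equilibrium frequencies
#'
#' Codon frequencies proportional to the product of the average observed
#' nucleotide frequencies at the three codon positions, renormalized over
#' the 61 sense codons. Frequencies are empirical (counted over all
#' non-missing codons), never optimized. Sense codons whose product is
#' zero receive a pseudo-frequency of 1e-10 before renormalization so the
#' rate matrix stays irreducible on small alignments.
#'
#' @param aln A [codon_alignment()].
#' @return Numeric vector of length 61 summing to 1, in [sense_codons()]
#'   order.
#' @export
estimate_f3x4 <- function(aln) {
  st <- aln$states[!is.na(aln$states)]
  if (length(st) == 0) stop("alignment has no non-missing codons")
  trip <- do.call(rbind, strsplit(sense_codons()[st], ""))
  nt <- c("A", "C", "G", "T")
  f <- sapply(1:3, function(p) {
    tab <- table(factor(trip[, p], levels = nt))
    as.numeric(tab) / sum(tab)
  }) # 4 x 3
  rownames(f) <- nt
  cm <- do.call(rbind, strsplit(sense_codons(), ""))
  pi <- f[cm[, 1], 1] * f[cm[, 2], 2] * f[cm[, 3], 3]
  pi[pi == 0] <- 1e-10
  pi / sum(pi)
}

#' Goldman-Yang codon rate matrix
#'
#' `q_ij = 0` for codon pairs differing at more than one nucleotide;
#' otherwise proportional to the target frequency `pi_j`, multiplied by
#' `kappa` for transitions and `omega` for nonsynonymous changes. The
#' diagonal makes rows sum to zero and the matrix is rescaled so the
#' expected substitution rate at stationarity is one: branch lengths are
#' expected substitutions per codon.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Nonsynonymous/synonymous rate ratio (>= 0).
#' @param pi 61-vector of codon frequencies summing to 1.
#' @return 61 x 61 rate matrix in [sense_codons()] order.
#' @export
codon_Q <- function(kappa, omega, pi) {
  stopifnot(kappa > 0, omega >= 0, length(pi) == 61)
  if (abs(sum(pi) - 1) > 1e-6) stop("pi must sum to 1")
  s <- .codon_struct()
  Q <- matrix(0, 61, 61)
  Q[s$single] <- 1
  Q[s$is_ts] <- kappa
  Q[s$nonsyn] <- Q[s$nonsyn] * omega
  Q <- Q * rep(pi, each = 61)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  if (mu <= 0) stop("degenerate rate matrix (zero total rate)")
  Q / mu
}

#' Transition probability matrix of a reversible generator
#'
#' Spectral decomposition of the pi-symmetrized generator; used by the
#' simulators and as an R-side check of the compiled pruning kernel.
#'
#' @param Q Rate matrix, reversible with respect to `pi`.
#' @param pi Equilibrium distribution.
#' @param t Branch length (>= 0).
#' @return The matrix `exp(Q t)` with rows summing to 1.
#' @export
trans_prob <- function(Q, pi, t) {
  sq <- sqrt(pi)
  sym <- diag(sq) %*% Q %*% diag(1 / sq)
  sym <- (sym + t(sym)) / 2
  e <- eigen(sym, symmetric = TRUE)
  P <- diag(1 / sq) %*% e$vectors %*% diag(exp(e$values * t)) %*%
    t(e$vectors) %*% diag(sq)
  P[P < 0] <- 0
  P / rowSums(P)
}

# ---- likelihood plumbing --------------------------------------------

# Site-pattern compression plus postorder edge data for the kernel.
lik_data <- function(aln, tree) {
  check_taxa(aln, tree)
  tre <- ape::reorder.phylo(tree, "postorder")
  # reorder.phylo drops custom attributes; marks are node-indexed and
  # node ids are stable under reordering, so copy them across
  attr(tre, "branch_mark") <- attr(tree, "branch_mark")
  attr(tre, "clade_mark") <- attr(tree, "clade_mark")
  states <- aln$states[match(tre$tip.label, aln$taxa), , drop = FALSE]
  key <- apply(states, 2, paste, collapse = ",")
  first <- !duplicated(key)
  pattern_of_site <- match(key, key[first])
  tips <- states[, first, drop = FALSE]
  tips[is.na(tips)] <- 0L
  storage.mode(tips) <- "integer"
  list(
    tree = tre,
    edge = tre$edge,
    len = tre$edge.length,
    tips = tips,
    w = as.numeric(tabulate(pattern_of_site, sum(first))),
    pattern_of_site = pattern_of_site,
    n_tip = ape::Ntip(tre),
    n_node = ape::Ntip(tre) + tre$Nnode
  )
}

# Per-class per-pattern log-likelihoods. `omega_ke` is a K x E matrix of
# omega values (class x edge); `len` overrides the stored branch lengths.
class_loglik <- function(d, kappa, pi, omega_ke, len = NULL,
                         rate = rep(1, nrow(omega_ke))) {
  len <- len %||% d$len
  uo <- sort(unique(as.vector(omega_ke)))
  Qs <- lapply(uo, function(o) codon_Q(kappa, o, pi))
  qi <- matrix(match(as.vector(omega_ke), uo), nrow(omega_ke))
  storage.mode(qi) <- "integer"
  edge <- d$edge
  storage.mode(edge) <- "integer"
  .class_site_loglik(Qs, pi, edge, len, qi, rate, d$tips, d$n_node)
}

# Mixture total log-likelihood from a K x P class log-lik matrix.
mix_loglik <- function(cl, weights, w_pat) {
  x <- cl + log(weights)
  mx <- apply(x, 2, max)
  persite <- mx + log(colSums(exp(sweep(x, 2, mx, "-"))))
  sum(persite * w_pat)
}

#' Codon-model log-likelihood of an alignment on a tree
#'
#' Felsenstein pruning with per-node rescaling; mixture models weight
#' per-site class likelihoods by the class proportions. Missing codons
#' contribute flat partial vectors.
#'
#' @param aln A [codon_alignment()].
#' @param tree `ape::phylo` with branch lengths in expected substitutions
#'   per codon.
#' @param kappa,omega Model parameters; `omega` may be a scalar, or a
#'   vector of per-class values paired with `weights`.
#' @param pi Codon frequencies (default [estimate_f3x4()] of `aln`).
#' @param weights Class proportions (default single class).
#' @return List with `total` lnL and `per_site` vector.
#' @export
codon_loglik <- function(aln, tree, kappa, omega, pi = NULL,
                         weights = rep(1 / length(omega), length(omega))) {
  pi <- pi %||% estimate_f3x4(aln)
  d <- lik_data(aln, tree)
  omega_ke <- matrix(omega, nrow = length(omega), ncol = nrow(d$edge))
  cl <- class_loglik(d, kappa, pi, omega_ke)
  x <- cl + log(weights)
  mx <- apply(x, 2, max)
  per_pat <- mx + log(colSums(exp(sweep(x, 2, mx, "-"))))
  list(total = sum(per_pat * d$w),
       per_site = per_pat[d$pattern_of_site])
}

# Equal-probability discretization of Beta(p, q) into K categories
# represented by their conditional means (closed form via the regularized
# incomplete beta of shape p+1).
beta_class_means <- function(p, q, K) {
  br <- qbeta(seq(0, 1, length.out = K + 1), p, q)
  m <- (pbeta(br[-1], p + 1, q) - pbeta(br[-(K + 1)], p + 1, q)) *
    K * p / (p + q)
  pmin(pmax(m, 1e-9), 1 - 1e-9)
}

# Equal-probability discrete gamma (mean-one), category means.
gamma_class_rates <- function(alpha, K) {
  if (K == 1) return(1)
  br <- qgamma(seq(0, 1, length.out = K + 1), shape = alpha, rate = alpha)
  m <- (pgamma(br[-1], shape = alpha + 1, rate = alpha) -
          pgamma(br[-(K + 1)], shape = alpha + 1, rate = alpha)) * K
  m / mean(m)
}
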