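test_that("F3X4 frequencies match hand-computed position products", {
  # uniform composition -> 1/61 everywhere
  tr <- sim_tree(6, 0.2, seed = 3)
  aln <- simulate_codon_alignment(tr, 400, classes = tibble::tibble(
    prop = 1, omega = 1), pi = uniform_pi, seed = 4)
  # exactly uniform only in expectation; test the analytic invariance with
  # a constructed alignment covering all 61 codons once per taxon
  full <- codon_alignment(c("x", "y"), rbind(1:61, 1:61))
  pi_full <- estimate_f3x4(full)
  # hand computation: nucleotide counts per position over the 61 codons
  m <- do.call(rbind, strsplit(sense_codons(), ""))
  f <- sapply(1:3, function(p)
    table(factor(m[, p], levels = c("A", "C", "G", "T"))) / 61)
  expected <- f[, 1][m[, 1]] * f[, 2][m[, 2]] * f[, 3][m[, 3]]
  expected <- as.numeric(expected) / sum(as.numeric(expected))
  expect_equal(pi_full, expected, tolerance = 1e-12, ignore_attr = TRUE)

  # degenerate: all-ATG alignment
  atg <- codon_alignment("x", matrix(encode_codon("ATG"), 1, 5))
  pi_atg <- estimate_f3x4(atg)
  expect_gt(pi_atg[encode_codon("ATG")], 1 - 1e-6)
  expect_lt(max(pi_atg[-encode_codon("ATG")]), 1e-6)

  # 4-codon toy alignment against an independent hand count
  toy <- codon_alignment("t", matrix(encode_codon(
    c("ATG", "ATA", "CTG", "CCC")), 1))
  pi_toy <- estimate_f3x4(toy)
  f1 <- c(A = 2, C = 2, G = 0, T = 0) / 4
  f2 <- c(A = 0, C = 1, G = 0, T = 3) / 4
  f3 <- c(A = 1, C = 1, G = 2, T = 0) / 4
  mm <- do.call(rbind, strsplit(sense_codons(), ""))
  raw <- f1[mm[, 1]] * f2[mm[, 2]] * f3[mm[, 3]]
  raw[raw == 0] <- 1e-10
  expect_equal(pi_toy, as.numeric(raw / sum(raw)), tolerance = 1e-9,
               ignore_attr = TRUE)

  empty <- codon_alignment("x", matrix(NA_integer_, 1, 3))
  expect_error(estimate_f3x4(empty), "non-missing")
})

test_that("the codon rate matrix has the Goldman-Yang structure", {
  pi <- uniform_pi
  Q <- codon_Q(2, 0.5, pi)
  codons <- sense_codons()
  i <- which(codons == "TTT")
  # TTT->TTC synonymous transition (kappa), TTT->TTA nonsynonymous
  # transversion (omega): ratio = kappa / omega = 4
  expect_equal(Q[i, which(codons == "TTC")] /
                 Q[i, which(codons == "TTA")], 2 / 0.5)
  # multi-nucleotide changes forbidden
  expect_identical(Q[which(codons == "AAA"), which(codons == "TTT")], 0)
  # rows sum to zero; stationarity; detailed balance
  expect_lt(max(abs(rowSums(Q))), 1e-10)
  expect_lt(max(abs(pi %*% Q)), 1e-10)
  expect_lt(max(abs(pi * Q - t(pi * Q))), 1e-12) # pi_i q_ij = pi_j q_ji
  # mean rate one at stationarity
  expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)

  # non-uniform pi: target-frequency proportionality and reversibility
  pi2 <- estimate_f3x4(m0_sim()$aln)
  Q2 <- codon_Q(3, 0.2, pi2)
  expect_lt(max(abs(pi2 * Q2 - t(pi2 * Q2))), 1e-12)
  expect_error(codon_Q(2, 0.5, rep(1 / 61, 60)), "61|pi")
})

test_that("transition probabilities are proper stochastic matrices", {
  pi <- estimate_f3x4(m0_sim()$aln)
  Q <- codon_Q(2, 0.3, pi)
  for (t in c(0, 0.01, 0.5, 2, 10)) {
    P <- trans_prob(Q, pi, t)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
    expect_gte(min(P), -1e-12)
  }
  expect_equal(trans_prob(Q, pi, 0), diag(61), tolerance = 1e-9)
})

test_that("beta discretization reproduces the distribution mean", {
  for (pq in list(c(0.2, 0.5), c(1, 1), c(0.11682, 0.66881))) {
    m <- beta_class_means(pq[1], pq[2], 10)
    expect_length(m, 10)
    expect_true(all(diff(m) > 0))
    expect_equal(mean(m), pq[1] / sum(pq), tolerance = 1e-6)
  }
  r <- gamma_class_rates(0.46, 4)
  expect_equal(mean(r), 1, tolerance = 1e-12)
  expect_length(r, 4)
})
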