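test_that("AA likelihood machinery is reversible and matches phangorn", {
  skip_if_not_installed("phangorn")
  tr <- sim_tree(8, 0.15, seed = 5)
  aln <- simulate_aa_alignment(tr, 120, alpha = 0.6, k = 4, seed = 6)
  model <- aa_model(alpha = 0.6, k = 4)
  mine <- aa_loglik(aln, tr, model)

  chars <- matrix(AA_LETTERS[aln$states], nrow = length(aln$taxa))
  rownames(chars) <- aln$taxa
  pd <- phangorn::phyDat(chars, type = "AA")
  pm <- phangorn::pml(tr, pd, model = "Dayhoff", k = 4, shape = 0.6)
  expect_equal(mine, pm$logLik, tolerance = 1e-6)

  # invariance to re-rooting (reversible model)
  rr <- ape::root(ape::unroot(tr), outgroup = "t4", resolve.root = TRUE)
  expect_equal(aa_loglik(aln, rr, model), mine, tolerance = 1e-6)
})

test_that("embedded Dayhoff numbers equal the field's reference copy", {
  skip_if_not_installed("phangorn")
  ref <- get(".Dayhoff", getNamespace("phangorn"))
  ex <- dayhoff_exchangeabilities()
  expect_equal(ex[lower.tri(ex)], ref$Q, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(dayhoff_frequencies()), unname(ref$bf),
               tolerance = 1e-12)
  expect_true(isSymmetric(ex))
})

test_that("branch-length fitting recovers degenerate and simulated lengths", {
  # identical sequences -> connecting length collapses
  st <- matrix(rep(1:20, 2), 2, byrow = TRUE)
  aln <- aa_alignment(c("A", "B"), st)
  tr <- read_newick("(A:0.3,B:0.3);")
  fit <- fit_aa_branch_lengths(aln, tr, aa_model(alpha = 1),
                               opts = fit_opts(n_restarts = 1))
  expect_lt(sum(fit$tree$edge.length), 1e-5)

  # alpha recovery on a moderate simulation
  tr16 <- sim_tree(16, 0.12, seed = 21)
  sim <- simulate_aa_alignment(tr16, 153, alpha = 0.46, k = 4, seed = 22)
  f <- fit_aa_branch_lengths(sim, tr16, aa_model(k = 4),
                             opts = fit_opts(n_restarts = 2))
  expect_lt(abs(f$alpha - 0.46), 0.2)
  expect_identical(f$convergence, "converged")
})

test_that("marginal reconstruction equals the exhaustive oracle", {
  tr <- quartet_tree()
  aln <- simulate_aa_alignment(tr, 3, alpha = 0.8, k = 2, seed = 9)
  model <- aa_model(alpha = 0.8, k = 2)
  asr <- marginal_asr(aln, tr, model)

  pi <- unname(dayhoff_frequencies())
  Q <- selstab:::aa_Q(model, pi)
  rates <- selstab:::gamma_class_rates(0.8, 2)
  pr <- ape::reorder.phylo(tr, "postorder")
  st <- aln$states[match(pr$tip.label, aln$taxa), ]
  E <- pr$edge
  ints <- sort(unique(E[, 1]))
  root <- E[nrow(E), 1]
  grid <- do.call(expand.grid, rep(list(1:20), length(ints)))
  for (s in 1:3) {
    post <- matrix(0, 20, length(ints))
    for (k in 1:2) {
      Pm <- lapply(seq_len(nrow(E)), function(e)
        trans_prob(Q, pi, pr$edge.length[e] * rates[k]))
      p <- 0.5 * pi[grid[, match(root, ints)]]
      for (e in seq_len(nrow(E))) {
        ps <- grid[, match(E[e, 1], ints)]
        cs <- if (E[e, 2] <= 4) rep(st[E[e, 2], s], nrow(grid))
              else grid[, match(E[e, 2], ints)]
        p <- p * Pm[[e]][cbind(ps, cs)]
      }
      for (j in seq_along(ints))
        post[, j] <- post[, j] + tapply(p, grid[, j], sum)
    }
    post <- sweep(post, 2, colSums(post), "/")
    for (j in seq_along(ints))
      expect_equal(asr$posterior[[as.character(ints[j])]][, s],
                   post[, j], tolerance = 1e-9, ignore_attr = TRUE)
  }

  # a site identical across all tips reconstructs with posterior ~1
  alnC <- aa_alignment(c("A", "B", "C", "D"), matrix(7L, 4, 2))
  asrC <- marginal_asr(alnC, tr, model)
  expect_true(all(asrC$summary$map_residue == AA_LETTERS[7]))
  expect_true(all(asrC$summary$map_prob > 0.99))
})

test_that("reconstruction posteriors are invariant to root placement", {
  tr <- sim_tree(6, 0.2, seed = 31)
  aln <- simulate_aa_alignment(tr, 40, alpha = 0.7, k = 4, seed = 32)
  model <- aa_model(alpha = 0.7, k = 4)
  a1 <- marginal_asr(aln, tr, model)
  rr <- ape::root(ape::unroot(tr), outgroup = "t2", resolve.root = TRUE)
  a2 <- marginal_asr(aln, rr, model)
  # compare via descendant-tipset identity of internal nodes
  k1 <- selstab:::node_tipset_keys(a1$tree)
  k2 <- selstab:::node_tipset_keys(a2$tree)
  common <- intersect(k1[a1$internal_nodes], k2[a2$internal_nodes])
  # the two roots share the full tip set but are different vertices
  common <- setdiff(common, paste(sort(tr$tip.label), collapse = "|"))
  expect_gt(length(common), 2)
  for (key in common) {
    n1 <- as.character(which(k1 == key))
    n2 <- as.character(which(k2 == key))
    expect_equal(a1$posterior[[n1]], a2$posterior[[n2]], tolerance = 1e-7,
                 ignore_attr = TRUE)
  }
})

test_that("substitution mapping has correct polarity and notation", {
  # constructed quartet with 3 planted differences on known branches
  tr <- quartet_tree()
  model <- aa_model(alpha = 1, k = 1)
  base <- rep(8L, 6) # G everywhere
  stA <- base; stA[2] <- 1L # G -> A at site 2 on tip A
  st <- rbind(stA, base, base, base)
  aln <- aa_alignment(c("A", "B", "C", "D"), st)
  asr <- marginal_asr(aln, tr, model)
  subs <- map_substitutions(asr)
  hit <- subs[subs$site == 2, ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$from, "G")
  expect_identical(hit$to, "A")
  expect_match(hit$notation, "^G2A$")
  expect_identical(hit$child_node, 1L) # the tip carrying the change

  # numbering offset feeds the notation (G129A convention)
  subs129 <- map_substitutions(asr, numbering_offset = 127)
  expect_identical(subs129$notation[subs129$child_node == 1], "G129A")

  # identical parent and child -> empty list
  alnC <- aa_alignment(c("A", "B", "C", "D"), matrix(3L, 4, 5))
  expect_identical(nrow(map_substitutions(marginal_asr(alnC, tr, model))), 0L)
})
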