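test_that("M0 recovers simulated parameters on one dataset", {
  sim <- m0_sim() # omega 0.25, kappa 2, 8 taxa, 250 codons
  fit <- fit_m0(sim$aln, sim$tree, opts = fit_opts(n_restarts = 2))
  expect_lt(abs(fit$params$omega - 0.25), 0.08)
  expect_lt(abs(fit$kappa - 2), 0.6)
  expect_identical(fit$convergence, "converged")
  expect_identical(fit$branch_lengths, "co_estimated")
  td <- tidy(fit)
  expect_true(all(c("kappa", "omega") %in% td$term))
  expect_identical(glance(fit)$model, "M0")
})

test_that("an all-identical alignment is flagged unidentifiable, no crash", {
  st <- matrix(rep(c(5L, 9L, 30L, 44L), each = 4), 4)
  aln <- codon_alignment(c("A", "B", "C", "D"), st)
  expect_warning(fit <- fit_m0(aln, quartet_tree(),
                               opts = fit_opts(n_restarts = 1)),
                 "unidentifiable")
  expect_identical(fit$convergence, "unidentifiable")
  expect_true(is.finite(fit$lnL))
})

test_that("the nesting chain holds at convergence", {
  sim <- m0_sim()
  opts <- fit_opts(n_restarts = 2)
  f0 <- fit_m0(sim$aln, sim$tree, opts = opts)
  tol <- 0.02 # optimizer tolerance for nested-fit comparisons
  ffr <- fit_free_ratio(sim$aln, f0$tree, opts = fit_opts(n_restarts = 1))
  expect_gte(ffr$lnL, f0$lnL - tol)

  f1 <- fit_site_model(sim$aln, f0$tree, "M1a", opts = opts)
  f2 <- fit_site_model(sim$aln, f0$tree, "M2a", opts = opts)
  f7 <- fit_site_model(sim$aln, f0$tree, "M7", opts = opts)
  f8f <- fit_site_model(sim$aln, f0$tree, "M8fix", opts = opts)
  f8 <- fit_site_model(sim$aln, f0$tree, "M8", opts = opts)
  expect_gte(f2$lnL, f1$lnL - tol)
  expect_gte(f8f$lnL, f7$lnL - tol)
  expect_gte(f8$lnL, f8f$lnL - tol)

  # M0-simulated data: free-ratio improvement stays modest
  nb <- nrow(ffr$tree$edge)
  out <- lrt(f0, ffr)
  expect_identical(out$df, as.integer(nb - 1))
  expect_lt(out$statistic, 2 * nb) # far below any interesting signal
})

test_that("branch-site model A validates marks and nests its null", {
  sim <- m0_sim()
  expect_error(fit_branch_site_a(sim$aln, sim$tree), "foreground")
  tr1 <- mark_branch(sim$tree, ape::Ntip(sim$tree) + 2)
  tr2 <- mark_branch(tr1, 2)
  expect_error(fit_branch_site_a(sim$aln, tr2), "only one")

  f0 <- fit_m0(sim$aln, tr1, opts = fit_opts(n_restarts = 1))
  fa <- fit_branch_site_a(sim$aln, f0$tree, null = FALSE,
                          opts = fit_opts(n_restarts = 2))
  fn <- fit_branch_site_a(sim$aln, f0$tree, null = TRUE,
                          opts = fit_opts(n_restarts = 2))
  expect_gte(fa$lnL, fn$lnL - 0.02)
  expect_identical(sum(fa$etype == 2L), 1L) # exactly one foreground edge
  # proportions sum to one
  expect_equal(sum(fa$weights), 1, tolerance = 1e-9)
})

test_that("clade model C with equal divergent omegas is an M1a+class mixture", {
  sim <- m0_sim()
  tr <- mark_clade(sim$tree, ape::Ntip(sim$tree) + 3)
  d <- selstab:::lik_data(sim$aln, selstab:::unroot_marked(tr))
  pi <- estimate_f3x4(sim$aln)
  # clade-C class structure with omega2 equal across branch types must
  # reproduce the plain 3-class mixture likelihood exactly
  cm <- attr(d$tree, "clade_mark")
  etype <- ifelse(cm[d$tree$edge[, 2]] > 0, 2L, 1L)
  obt <- matrix(c(0.1, 0.1, 1, 1, 0.55, 0.55), 3, 2, byrow = TRUE)
  cl_clade <- selstab:::class_loglik(d, 2, pi, obt[, etype])
  cl_plain <- selstab:::class_loglik(d, 2, pi,
                                     matrix(c(0.1, 1, 0.55), 3,
                                            nrow(d$edge)))
  w <- c(0.6, 0.2, 0.2)
  expect_equal(selstab:::mix_loglik(cl_clade, w, d$w),
               selstab:::mix_loglik(cl_plain, w, d$w), tolerance = 1e-10)
  expect_error(fit_clade_model_c(sim$aln, sim$tree), "partition")
})

test_that("pairwise dN/dS is symmetric and reports undefined cases", {
  sim <- m0_sim()
  ab <- pairwise_dnds(sim$aln, taxa = c("t1", "t2"))
  ba <- pairwise_dnds(sim$aln, taxa = c("t2", "t1"))
  expect_equal(ab$omega, ba$omega, tolerance = 1e-5)
  expect_equal(ab$t, ba$t, tolerance = 1e-5)

  # identical sequences: t = 0, omega missing
  st <- sim$aln$states[1, , drop = FALSE]
  ident <- codon_alignment(c("x", "y"), rbind(st, st))
  out <- pairwise_dnds(ident, taxa = c("x", "y"))
  expect_identical(out$t, 0)
  expect_true(is.na(out$omega))

  # recovery on a simulated pair (omega 0.3, t 0.4)
  two <- read_newick("(A:0.2,B:0.2);")
  sim2 <- simulate_codon_alignment(two, 500, kappa = 2,
    classes = tibble::tibble(prop = 1, omega = 0.3), seed = 77)
  est <- pairwise_dnds(sim2, taxa = c("A", "B"))
  expect_lt(abs(est$omega - 0.3), 0.1)
  expect_lt(abs(est$t - 0.4), 0.15)

  # a 2-taxon free-ratio/M0 fit agrees with the pairwise estimate
  f2 <- fit_m0(sim2, two, opts = fit_opts(n_restarts = 1))
  expect_equal(f2$params$omega, est$omega, tolerance = 0.02)
})

test_that("free-ratio flags the elevated branch on a star tree", {
  star <- ape::stree(5, type = "star")
  star$edge.length <- rep(0.15, 5)
  star$tip.label <- paste0("t", 1:5)
  hot <- mark_branch(star, 3) # tip branch 3 evolves at omega 3
  aln <- simulate_codon_alignment(hot, 400, kappa = 2,
    classes = tibble::tibble(prop = 1, omega = 0.1, omega_fg = 3),
    seed = 55)
  fit <- fit_free_ratio(aln, star, opts = fit_opts(n_restarts = 1))
  om <- fit$params$omega
  hot_edge <- which(fit$tree$edge[, 2] == 3)
  expect_identical(which.max(om), hot_edge)
})
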