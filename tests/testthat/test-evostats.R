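test_that("conditional probability: direct and Bayes-rule routes agree", {
  # 10 substitutions at selected sites, 8 stabilizing -> 0.8
  subs <- tibble::tibble(
    site = c(rep(5, 10), rep(90, 5)),
    ddg = c(rep(-0.5, 8), 0.3, 0.4, rep(0.2, 5)))
  cp <- conditional_prob_stabilizing(subs, selected_sites = 5)
  expect_equal(cp$p_direct, 0.8, tolerance = 1e-15)
  expect_equal(cp$p_bayes, 0.8, tolerance = 1e-15)
  expect_identical(sum(cp$counts$n), 15L)

  # all stabilizing -> 1 regardless of selection status
  allst <- tibble::tibble(site = c(1, 1, 2), ddg = c(-1, -2, -0.1))
  expect_equal(conditional_prob_stabilizing(allst, 1)$p_direct, 1)

  # property: equality on random planted tables
  for (s in 1:20) {
    tab <- withr::with_seed(s, tibble::tibble(
      site = sample(1:30, 60, replace = TRUE),
      ddg = rnorm(60, mean = 0.5)))
    sel <- withr::with_seed(s + 100, sample(1:30, 8))
    cp <- tryCatch(conditional_prob_stabilizing(tab, sel),
                   error = function(e) NULL)
    if (!is.null(cp))
      expect_equal(cp$p_direct, cp$p_bayes, tolerance = 1e-15)
  }
  expect_error(conditional_prob_stabilizing(allst, 99), "selected")
})

test_that("two-sample t matches a textbook hand computation", {
  a <- c(1.1, 2.3, 1.8, 2.0, 1.5)
  b <- c(2.8, 3.1, 2.5, 3.4, 2.9)
  out <- two_sample_t(a, b)
  # hand computation, pooled variance formula
  sp2 <- (4 * var(a) + 4 * var(b)) / 8
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (2 / 5))
  pooled <- out[out$method == "pooled", ]
  expect_equal(pooled$t, t_hand, tolerance = 1e-12)
  expect_identical(pooled$df, 8)
  expect_equal(pooled$p, 2 * pt(abs(t_hand), 8, lower.tail = FALSE),
               tolerance = 1e-12)
  # symmetry: swapping flips t, keeps p
  sw <- two_sample_t(b, a)
  expect_equal(sw$t, -out$t, tolerance = 1e-12)
  expect_equal(sw$p, out$p, tolerance = 1e-12)
  # identical samples -> p = 1
  expect_identical(unique(two_sample_t(a, a)$p), 1)
  expect_error(two_sample_t(1, b), "at least 2")
})

test_that("apo-to-holo conversion is the stated offset arithmetic", {
  expect_equal(apo_to_holo(-4.8), -7.5) # horse
  expect_identical(apo_to_holo(-5, offset = 0), -5)
  terrestrial <- c(-4.4, -4.8, -4.9, -5.7, -5.8, -6.3)
  holo <- apo_to_holo(terrestrial)
  expect_true(all(holo <= -7.0 & holo >= -9.0))
})

test_that("correlation handles exact, null and affine-invariance cases", {
  x <- 1:10
  perf <- correlate(x, 2 * x + 3)
  expect_equal(perf$estimate, 1, tolerance = 1e-12)
  expect_lt(perf$p, 1e-12)

  # permutation null: mean |rho| matches the analytic null expectation
  # E|rho| ~= sqrt(2 / (pi (n-1))) ~= 0.24 at n = 12
  y <- withr::with_seed(5, rnorm(12))
  rhos <- vapply(1:500, function(i) {
    correlate(seq_len(12), withr::with_seed(i, sample(y)))$estimate
  }, 0)
  expect_lt(abs(mean(abs(rhos)) - sqrt(2 / (pi * 11))), 0.05)
  expect_lt(abs(mean(rhos)), 0.1)

  # Pearson invariance under positive affine transforms
  a <- withr::with_seed(9, rnorm(15)); b <- withr::with_seed(10, rnorm(15))
  expect_equal(correlate(a, b)$estimate,
               correlate(3 * a + 1, 0.5 * b - 7)$estimate, tolerance = 1e-12)
  expect_error(correlate(1:5, rep(1, 5)), "variance")
  expect_error(correlate(1:2, 1:2), "3")
})

test_that("group ddG comparison mirrors the printed group means", {
  # planted means 0.06 (non-selected) and -0.26 (selected)
  subs <- tibble::tibble(
    site = c(rep(5, 8), rep(50, 12)),
    ddg = c(rep(-0.26, 8), rep(0.06, 12)))
  out <- compare_ddg_groups(subs, selected_sites = 5)
  sel <- out$means$mean_ddg[out$means$group == "selected"]
  non <- out$means$mean_ddg[out$means$group == "non_selected"]
  expect_equal(non - sel, 0.32, tolerance = 1e-12)
  expect_identical(nrow(out$tests), 2L)
  expect_error(compare_ddg_groups(subs, selected_sites = 999), "non-empty")
})

test_that("published pairwise tables and phenotypes load with stated shapes", {
  cet <- published_pairwise_dnds("cetacean")
  pri <- published_pairwise_dnds("primate")
  expect_identical(nrow(cet), 36L)
  expect_identical(nrow(pri), 28L)
  ph <- mb_phenotypes()
  expect_identical(nrow(ph), 13L)
  expect_true(all(ph$dg_apo < 0))
  expect_identical(sum(!is.na(ph$c_mb)), 2L)
})
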