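test_that("replicate rows average and sign conventions normalize", {
  d <- withr::local_tempdir()
  p <- file.path(d, "ddg.tsv")
  # five replicates summing to -3.45 -> single entry -0.69
  reps <- c(-0.80, -0.55, -0.70, -0.75, -0.65)
  readr::write_tsv(tibble::tibble(site = 129, from = "G", to = "A",
                                  ddg = reps), p)
  tab <- load_ddg_table(p)
  expect_identical(nrow(tab), 1L)
  expect_equal(tab$ddg, -0.69, tolerance = 1e-12)
  expect_identical(tab$n_replicates, 5L)

  # order invariance of averaging
  readr::write_tsv(tibble::tibble(site = 129, from = "G", to = "A",
                                  ddg = rev(reps)), p)
  expect_equal(load_ddg_table(p)$ddg, tab$ddg, tolerance = 1e-15)

  # pos_stabilizing input negates on load; a double round trip preserves
  readr::write_tsv(tibble::tibble(site = 5, from = "G", to = "A",
                                  ddg = 0.7), p)
  expect_equal(load_ddg_table(p, convention = "pos_stabilizing")$ddg, -0.7)

  empty <- file.path(d, "empty.tsv")
  readr::write_tsv(tibble::tibble(site = integer(), from = character(),
                                  to = character(), ddg = numeric()), empty)
  expect_warning(et <- load_ddg_table(empty), "empty")
  expect_identical(nrow(et), 0L)

  expect_error(stability_table(tibble::tibble(site = 1, from = "A",
                                              to = "A", ddg = 1)), "self")
})

test_that("ddG joins honor the reversal policy and count missing entries", {
  tab <- stability_table(tibble::tibble(
    site = c(129, 15), from = c("G", "G"), to = c("A", "A"),
    ddg = c(-0.69, -1.2)))
  subs <- tibble::tibble(branch = c("b1", "b1", "b2"),
                         site = c(129, 15, 129),
                         from = c("G", "G", "A"), to = c("A", "A", "G"))
  strict <- join_ddg(subs, tab)
  expect_equal(strict$branches$sum_ddg[strict$branches$branch == "b1"],
               -1.89)
  expect_identical(strict$branches$n_missing[strict$branches$branch == "b2"],
                   1L)

  anti <- join_ddg(subs, tab, reversal_policy = "antisymmetric")
  b2 <- anti$substitutions[anti$substitutions$branch == "b2", ]
  expect_equal(b2$ddg, 0.69) # A129G filled as -(-0.69), flagged
  expect_true(b2$filled_by_reversal)

  # branch sums are additive under concatenation
  s1 <- subs[1:2, ]; s2 <- subs[3, ]; s2$branch <- "b1"
  tot <- join_ddg(rbind(s1, s2), tab,
                  reversal_policy = "antisymmetric")$branches$sum_ddg
  expect_equal(tot,
               sum(anti$substitutions$ddg, na.rm = TRUE), tolerance = 1e-12)

  none <- join_ddg(subs[0, ], tab)
  expect_identical(nrow(none$branches), 0L)
})

test_that("the surrogate generator has the documented mean and asymmetry", {
  expect_error(surrogate_ddg("A", "A"), "differ")
  draws <- surrogate_ddg("N", "S", "generic", seed = 9, n = 10000)
  expect_equal(mean(draws), 1.2, tolerance = 0.1)
  expect_gt(mean(draws < 0), 0.1) # some stabilizing mass
  # deterministic for a seed
  expect_identical(draws[1:5], surrogate_ddg("N", "S", "generic",
                                             seed = 9, n = 5))
  ga <- mean(surrogate_ddg("G", "A", "helix", seed = 2, n = 2000))
  ag <- mean(surrogate_ddg("A", "G", "helix", seed = 2, n = 2000))
  expect_lt(ga, ag) # helix-former gain is stabilizing-shifted
  bur <- mean(surrogate_ddg("D", "I", "buried", seed = 3, n = 2000))
  gen <- mean(surrogate_ddg("D", "I", "generic", seed = 3, n = 2000))
  expect_lt(bur, gen) # buried hydrophobic gain
})
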