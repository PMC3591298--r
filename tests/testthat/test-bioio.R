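test_that("codon encoding is a bijection over the 61 sense triplets", {
  codons <- sense_codons()
  expect_length(codons, 61)
  expect_false(any(c("TAA", "TAG", "TGA") %in% codons))
  expect_identical(encode_codon(codons), 1:61)
  expect_identical(decode_codon(1:61)[order(encode_codon(codons))],
                   codons[order(encode_codon(codons))])
  # stops, ambiguity, RNA
  expect_identical(encode_codon("TAA"), 0L)
  expect_identical(encode_codon("ATN"), NA_integer_)
  expect_identical(encode_codon("A-G"), NA_integer_)
  expect_identical(encode_codon("AUG"), encode_codon("ATG"))
  aa <- codon_amino_acids()
  expect_identical(sum(aa == "M"), 1L) # unique Met codon
})

test_that("FASTA reading encodes codons and validates frames and stops", {
  p <- tiny_fasta()
  aln <- read_fasta(p, "nucleotide")
  expect_s3_class(aln, "codon_alignment")
  expect_identical(aln$taxa, c("a", "b"))
  expect_identical(aln$n_sites, 2L)
  expect_identical(decode_codon(aln$states[1, ]), c("ATG", "TTT"))
  expect_identical(decode_codon(aln$states[2, ]), c("ATG", "TTC"))

  d <- withr::local_tempdir()
  bad <- file.path(d, "stop.fasta")
  writeLines(c(">x", "ATGTAACCC", ">y", "ATGAAACCC"), bad)
  expect_error(read_fasta(bad, "nucleotide"), "x.*codon site 2|stop")

  ragged <- file.path(d, "ragged.fasta")
  writeLines(c(">x", "ATGTTT", ">y", "ATG"), ragged)
  expect_error(read_fasta(ragged, "nucleotide"), "ragged")

  frame <- file.path(d, "frame.fasta")
  writeLines(c(">x", "ATGTT", ">y", "ATGTT"), frame)
  expect_error(read_fasta(frame, "nucleotide"), "divisible by 3")

  gap <- file.path(d, "gap.fasta")
  writeLines(c(">x", "ATGT-T", ">y", "ATGTTC"), gap)
  g <- read_fasta(gap, "nucleotide")
  expect_true(is.na(g$states[1, 2])) # partial gap masks whole codon
})

test_that("FASTA round trip reproduces states exactly", {
  d <- withr::local_tempdir()
  sim <- m0_sim()
  aln <- sim$aln
  aln$states[2, 5] <- NA # inject a missing codon
  p <- file.path(d, "rt.fasta")
  write_fasta(aln, p)
  back <- read_fasta(p, "nucleotide")
  expect_identical(back$states, aln$states)
  expect_identical(back$taxa, aln$taxa)

  aa <- simulate_aa_alignment(sim$tree, 40, alpha = 1, seed = 7)
  pa <- file.path(d, "rt_aa.fasta")
  write_fasta(aa, pa)
  back_aa <- read_fasta(pa, "amino_acid")
  expect_identical(unname(back_aa$states), unname(aa$states))
})

test_that("newick reading validates and enumerates branches correctly", {
  tr <- read_newick("((A:0.1,B:0.2):0.05,C:0.3);")
  expect_identical(ape::Ntip(tr), 3L)
  expect_identical(nrow(tr$edge), 4L) # rooted binary, 2n - 2
  expect_error(read_newick("((A,B),(A,C));"), "lengths|duplicate")
  expect_error(read_newick("((A:1,B:1):1,(A:1,C:1):1);", ), "duplicate")
  expect_error(read_newick("((A:0.1,B:0.2):0.05,C:0.3;"), "unbalanced")
  expect_error(read_newick("((A:0.1,B:-0.2):0.05,C:0.3);"), "negative")
  expect_error(read_newick("((A,B),C);"), "branch lengths")
  filled <- read_newick("((A,B),C);", default_length = 0.1)
  expect_true(all(filled$edge.length == 0.1))
  # 2n-2 rooted / 2n-3 unrooted branch enumeration
  tr8 <- sim_tree(8, seed = 1)
  expect_identical(nrow(tr8$edge), 2L * 8L - 2L)
  expect_identical(nrow(ape::unroot(tr8)$edge), 2L * 8L - 3L)
})

test_that("branch and clade marks are parsed, stored per node, written back", {
  tr <- read_newick("((A:0.1,B:0.2)#1:0.05,C:0.3);")
  ed <- tree_edges(tr)
  expect_identical(sum(ed$branch_mark > 0), 1L)
  marked_child <- ed$child[ed$branch_mark > 0]
  expect_setequal(ape::extract.clade(tr, marked_child)$tip.label, c("A", "B"))

  trc <- read_newick("((A:0.1,B:0.2)$1:0.05,C:0.3);")
  edc <- tree_edges(trc)
  expect_identical(sum(edc$clade_mark > 0), 3L) # stem + 2 descendants

  s <- write_newick(trc, marks = TRUE)
  expect_match(s, "\\$1")
  back <- read_newick(s)
  expect_identical(attr(back, "clade_mark"), attr(trc, "clade_mark"))
  expect_false(grepl("\\$", write_newick(trc))) # stripped by default
})

test_that("conserved-column counting requires full non-missing identity", {
  aln <- aa_alignment(c("a", "b", "c"),
                      rbind(c(1L, 2L, 3L, NA), c(1L, 2L, 4L, 1L),
                            c(1L, 2L, 3L, 1L)))
  expect_identical(count_conserved_columns(aln), 2L)
})
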