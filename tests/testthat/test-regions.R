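# Differential-expression selection rules and promoter-window extraction.

test_that("select_induced_genes applies inclusive fold and q boundaries", {
  expr <- data.frame(
    locus_tag = c("a", "b", "c", "d"),
    condition = "LCA",
    fold_change = c(3.0, 2.9, 10, 3.5),
    q_value = c(0.05, 0.01, 0.2, 0.001),
    stringsAsFactors = FALSE)
  expect_equal(select_induced_genes(expr, "LCA"), c("a", "d"))
  expect_error(select_induced_genes(expr, "cholesterol"), "LCA")
})

test_that("select_induced_genes is monotone in its thresholds", {
  set.seed(11)
  expr <- data.frame(
    locus_tag = sprintf("g%03d", 1:300), condition = "LCA",
    fold_change = stats::rlnorm(300, 0.5, 1),
    q_value = runif(300), stringsAsFactors = FALSE)
  base <- select_induced_genes(expr, "LCA", min_fold = 2, max_q = 0.2)
  for (mf in c(2, 3, 5, 8)) {
    for (mq in c(0.2, 0.1, 0.05, 0.01)) {
      sel <- select_induced_genes(expr, "LCA", min_fold = mf, max_q = mq)
      expect_true(all(sel %in% base))
      base_strict <- select_induced_genes(expr, "LCA", min_fold = mf + 1,
                                          max_q = mq / 2)
      expect_true(all(base_strict %in% sel))
    }
  }
})

test_that("qualifying_first_genes returns first genes of operons with any significant member", {
  ts <- toy_study()
  # opA: only g3 (index 3) is significant -> g1 returned, not g3
  # opB: g4 significant single-gene operon -> g4
  # opC: nothing significant -> absent
  expect_equal(qualifying_first_genes(ts$genes, ts$expr, "LCA"),
               c("g1", "g4"))
  none <- ts$expr
  none$q_value <- 0.5
  expect_equal(qualifying_first_genes(ts$genes, none, "LCA"), character(0))
  # significance without induction (fold <= 1) does not qualify
  down <- ts$expr
  down$fold_change[down$locus_tag == "g3"] <- 0.2
  expect_equal(qualifying_first_genes(ts$genes, down, "LCA"), "g4")
})

test_that("promoter windows have the stated geometry and truncate at edges", {
  ts <- toy_study()
  r <- extract_550bp_region(ts$genome, ts$genes[1, ])  # + strand, s = 800
  expect_equal(c(r$start, r$end), c(300, 850))
  expect_equal(nchar(r$sequence), 550)
  expect_equal(r$sequence, substr(ts$genome$chrA$sequence, 301, 850))

  near_edge <- data.frame(locus_tag = "gE", contig_id = "chrA", start = 200,
                          end = 800, strand = "+", stringsAsFactors = FALSE)
  r2 <- extract_550bp_region(ts$genome, near_edge)
  expect_equal(c(r2$start, r2$end), c(0, 250))
  expect_equal(nchar(r2$sequence), 250)

  outside <- near_edge
  outside$end <- 99999
  expect_error(extract_550bp_region(ts$genome, outside), "outside contig")
})

test_that("minus-strand extraction equals plus-strand extraction on the reverse-complemented contig", {
  set.seed(21)
  for (rep in 1:5) {
    L <- 3000
    g <- genome_record("c", random_dna(L))
    b <- sample(600:2000, 1)
    e <- b + sample(300:600, 1)
    gene_minus <- data.frame(locus_tag = "gm", contig_id = "c", start = b,
                             end = e, strand = "-", stringsAsFactors = FALSE)
    r_minus <- extract_550bp_region(g, gene_minus)
    # mirror gene on the reverse-complemented contig
    g_rc <- genome_record("c", reverse_complement(g$sequence))
    gene_plus <- data.frame(locus_tag = "gp", contig_id = "c",
                            start = L - e, end = L - b, strand = "+",
                            stringsAsFactors = FALSE)
    r_plus <- extract_550bp_region(g_rc, gene_plus)
    expect_equal(r_minus$sequence, r_plus$sequence)
    # and the genomic interval mirrors exactly
    expect_equal(c(r_minus$start, r_minus$end),
                 c(L - r_plus$end, L - r_plus$start))
  }
})

test_that("the minus-strand window starts at the start codon and runs upstream", {
  g <- genome_record("c", random_dna(2000))
  gene <- data.frame(locus_tag = "gm", contig_id = "c", start = 400,
                     end = 1000, strand = "-", stringsAsFactors = FALSE)
  r <- extract_550bp_region(g, gene)
  expect_equal(c(r$start, r$end), c(950, 1500))
  # oriented position 501 is the start codon's first base: the complement of
  # the genomic base at offset 999 (1-based position 1000)
  expect_equal(substr(r$sequence, 501, 501),
               reverse_complement(substr(g$sequence, 1000, 1000)))
})

test_that("regions_for_loci deduplicates, orders, and names missing loci", {
  ts <- toy_study()
  regs <- regions_for_loci(ts$genome, ts$genes, c("g3", "g1", "g1"))
  expect_equal(nrow(regs), 2)
  expect_equal(regs$locus_tag, c("g1", "g3"))  # ordered by interval start
  expect_error(regions_for_loci(ts$genome, ts$genes, c("g1", "nope")), "nope")
  expect_message(out <- regions_for_loci(ts$genome, ts$genes, character(0)),
                 "empty")
  expect_equal(nrow(out), 0)
})

test_that("circular contigs wrap the promoter window around the origin", {
  set.seed(5)
  seq <- random_dna(1000)
  g <- genome_record("c", seq, is_circular = TRUE)
  gene <- data.frame(locus_tag = "gw", contig_id = "c", start = 100,
                     end = 700, strand = "+", stringsAsFactors = FALSE)
  r <- extract_550bp_region(g, gene)
  expect_equal(nchar(r$sequence), 550)
  expect_equal(r$sequence, paste0(substr(seq, 601, 1000), substr(seq, 1, 150)))
})
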