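# Criterion boundaries, verdict arithmetic and the end-to-end pipeline.

test_that("criterion A is inclusive at the cap", {
  expect_true(criterion_A(fake_sites(1000, 0)))
  expect_false(criterion_A(fake_sites(1001, 0)))
  expect_true(criterion_A(fake_sites(0, 0)))
})

test_that("criterion B is strict at the fraction threshold", {
  b <- criterion_B(fake_sites(1000, 101), qual_region)
  expect_true(b$passes_B)   # 10.1% > 10%
  expect_equal(b$n_in_qualifying, 101)
  b2 <- criterion_B(fake_sites(1000, 100), qual_region)
  expect_false(b2$passes_B)  # exactly 10% fails
  b0 <- criterion_B(fake_sites(0, 0), qual_region)
  expect_false(b0$passes_B)
  expect_equal(b0$fraction, 0)
})

test_that("verdicts are pure functions of the hit set with consistent counts", {
  set.seed(71)
  for (i in 1:20) {
    n <- sample(0:50, 1)
    k <- if (n == 0) 0 else sample(0:n, 1)
    s <- fake_sites(n, k)
    v <- filter_verdict("m", s, qual_region)
    expect_lte(v$n_in_qualifying, v$n_sites)
    expect_equal(v$n_sites, n)
    expect_equal(v$passes_A, n <= 1000)
    expect_equal(v$passes_B, if (n == 0) FALSE else k / n > 0.10)
    expect_equal(v$passes, v$passes_A && v$passes_B)
  }
})

test_that("the pipeline recovers a planted regulon motif end to end", {
  cfg <- simulation_config(seed = 72, n_genes = 60, regulon_size = 14)
  sim <- simulate_regulon_study(cfg)
  res <- run_motif_pipeline(sim$genome, sim$genes, sim$expression, "LCA",
                            pipeline_config(seed = 72))
  expect_equal(res$status, "ok")
  expect_setequal(res$induced_loci,
                  sim$genes$locus_tag[sim$genes$operon_id %in%
                                        sim$regulon_operons])
  v <- res$verdicts
  hit <- v$passes & vapply(v$consensus, function(cs)
    consensus_distance(cfg$planted_consensus, cs) <= 2, logical(1))
  expect_true(any(hit))
  # the recovered motif is flagged palindromic when its consensus is one
  pal <- v$palindrome[hit]
  expect_type(pal, "logical")
  # q-passing sites of the winning motif include the planted coordinates
  sites <- res$sites[[v$motif_id[hit][1]]]
  found <- vapply(seq_len(nrow(sim$manifest)), function(i) {
    any(sites$contig_id == sim$manifest$contig_id[i] &
          abs(sites$start - sim$manifest$start[i]) <= 2)
  }, logical(1))
  expect_gte(mean(found), 0.8)
})

test_that("two identical runs produce identical motifs, sites and verdicts", {
  cfg <- simulation_config(seed = 73, n_genes = 40, regulon_size = 10)
  sim <- simulate_regulon_study(cfg)
  r1 <- run_motif_pipeline(sim$genome, sim$genes, sim$expression, "LCA",
                           pipeline_config(seed = 73))
  r2 <- run_motif_pipeline(sim$genome, sim$genes, sim$expression, "LCA",
                           pipeline_config(seed = 73))
  expect_identical(r1$verdicts, r2$verdicts)
  expect_identical(r1$sites, r2$sites)
  expect_identical(lapply(r1$motifs, function(m) m$probs),
                   lapply(r2$motifs, function(m) m$probs))
})

test_that("a motif saturating the genome fails criterion A", {
  cfg <- simulation_config(seed = 74, regulon_size = 14)
  sim <- simulate_regulon_study(cfg)
  # spray ~1400 extra consensus copies into the promoter windows of all genes
  # so the scan reports more than 1000 q-passing sites for the planted motif
  set.seed(74)
  seq <- sim$genome$sequence
  w <- nchar(cfg$planted_consensus)
  all_regions <- regions_for_loci(sim$genome, sim$genes,
                                  sim$genes$locus_tag)
  slots <- sort(unique(unlist(lapply(seq_len(nrow(all_regions)), function(i)
    seq(all_regions$start[i], all_regions$end[i] - w, by = w + 2)))))
  keep <- slots[c(TRUE, diff(slots) >= w + 2)]
  for (pos in sample(keep, min(1400, length(keep)))) {
    site <- gsub("S", sample(c("C", "G"), 1), cfg$planted_consensus)
    substr(seq, pos + 1, pos + w) <- site
  }
  sim$genome$sequence <- seq
  res <- run_motif_pipeline(sim$genome, sim$genes, sim$expression, "LCA",
                            pipeline_config(seed = 74))
  v <- res$verdicts
  hit <- vapply(v$consensus, function(cs)
    consensus_distance(cfg$planted_consensus, cs) <= 3, logical(1))
  expect_true(any(hit))
  expect_false(any(v$passes_A[hit]))
  expect_true(all(v$n_sites[hit] > 1000))
})

test_that("a table with no induced genes yields an empty result, not an error", {
  cfg <- simulation_config(seed = 75, n_genes = 30, regulon_size = 0)
  sim <- simulate_regulon_study(cfg)
  res <- run_motif_pipeline(sim$genome, sim$genes, sim$expression, "LCA",
                            pipeline_config(seed = 75))
  expect_equal(res$status, "no_induced_genes")
  expect_equal(nrow(res$verdicts), 0)
  expect_length(res$motifs, 0)
})

test_that("published-protocol default thresholds are wired through the configuration", {
  cfg <- pipeline_config()
  expect_equal(cfg$min_fold, 3)
  expect_equal(cfg$max_q_deg, 0.05)
  expect_equal(cfg$upstream, 500)
  expect_equal(cfg$downstream, 50)
  expect_equal(cfg$wmin, 8)
  expect_equal(cfg$wmax, 50)
  expect_equal(cfg$max_evalue, 0.1)
  expect_equal(cfg$max_q_site, 0.05)
  expect_equal(cfg$max_sites, 1000)
  expect_equal(cfg$min_fraction, 0.10)
  expect_equal(cfg$top_n_homologs, 20)
  expect_error(pipeline_config(bogus = 1), "unknown")
})
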