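# The study generator: reproducibility, layout, ground-truth consistency,
# expression contracts and homolog conservation.

test_that("identical configurations produce byte-identical outputs", {
  cfg <- simulation_config(seed = 91, n_genes = 20, regulon_size = 4)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(simulate_regulon_study(cfg), d1)
  write_simulation(simulate_regulon_study(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
})

test_that("genome layout respects operon structure and GC content", {
  cfg <- simulation_config(seed = 92, n_genes = 60,
                           genes_per_operon = c(3, 3), gc_content = 0.5)
  gg <- generate_genome(cfg)
  # fixed operon size 3 -> every operon indexed 1..3
  idx <- split(gg$genes$operon_index, gg$genes$operon_id)
  for (v in idx) expect_setequal(v, 1:3)
  # genes of one operon share a strand and do not overlap
  for (op in unique(gg$genes$operon_id)) {
    sub <- gg$genes[gg$genes$operon_id == op, ]
    expect_length(unique(sub$strand), 1)
  }
  g <- gg$genes[order(gg$genes$start), ]
  expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  # ~100 kb of i.i.d. bases at GC 0.5 stays within +-0.01
  expect_gt(nchar(gg$genome$sequence), 50000)
  expect_lt(abs(gc_fraction_of(gg$genome$sequence) - 0.5), 0.01)
})

test_that("operon_index 1 marks the transcriptional first gene on both strands", {
  cfg <- simulation_config(seed = 93, n_genes = 40, genes_per_operon = c(2, 4))
  gg <- generate_genome(cfg)
  for (op in unique(gg$genes$operon_id)) {
    sub <- gg$genes[gg$genes$operon_id == op, ]
    first <- sub[sub$operon_index == 1, ]
    if (first$strand == "+") expect_equal(first$start, min(sub$start))
    else expect_equal(first$end, max(sub$end))
  }
})

test_that("planted sites are recorded faithfully in the manifest", {
  cfg <- simulation_config(seed = 94, n_genes = 60, regulon_size = 12)
  sim <- simulate_regulon_study(cfg)
  expect_equal(nrow(sim$manifest), 12)
  w <- nchar(cfg$planted_consensus)
  for (i in seq_len(nrow(sim$manifest))) {
    mf <- sim$manifest[i, ]
    written <- substr(sim$genome$sequence, mf$start + 1, mf$end)
    oriented <- if (mf$strand == "-") rc_oracle(written) else written
    expect_equal(oriented, mf$site_seq)
    # the site lies inside the first gene's promoter window
    gene <- sim$genes[sim$genes$locus_tag == mf$locus_tag, ]
    reg <- extract_550bp_region(sim$genome, gene)
    expect_gte(mf$start, reg$start)
    expect_lte(mf$end, reg$end)
    expect_equal(mf$end - mf$start, w)
  }
  # no planted site overlaps a gene body
  for (i in seq_len(nrow(sim$manifest))) {
    mf <- sim$manifest[i, ]
    expect_false(any(sim$genes$start < mf$end & sim$genes$end > mf$start))
  }
})

test_that("a zero-size regulon leaves the genome untouched", {
  cfg <- simulation_config(seed = 95, n_genes = 20, regulon_size = 0)
  gg <- generate_genome(cfg)
  pl <- plant_motif(gg, cfg, character(0))
  expect_identical(pl$genome$sequence, gg$genome$sequence)
  expect_equal(nrow(pl$manifest), 0)
})

test_that("expression tables satisfy the selection contracts by construction", {
  cfg <- simulation_config(seed = 96, n_genes = 80, regulon_size = 15)
  sim <- simulate_regulon_study(cfg)
  regulon_genes <- sim$genes$locus_tag[sim$genes$operon_id %in%
                                         sim$regulon_operons]
  expect_setequal(select_induced_genes(sim$expression, "LCA"), regulon_genes)
  firsts <- sim$genes$locus_tag[sim$genes$operon_id %in% sim$regulon_operons &
                                  sim$genes$operon_index == 1]
  expect_setequal(qualifying_first_genes(sim$genes, sim$expression, "LCA"),
                  firsts)
  bg_fold <- sim$expression$fold_change[!sim$expression$locus_tag %in%
                                          regulon_genes]
  expect_true(all(bg_fold < 3))
})

test_that("scanning with the true matrix recovers every planted site", {
  cfg <- simulation_config(seed = 97, n_genes = 60, regulon_size = 12)
  sim <- simulate_regulon_study(cfg)
  pwm <- consensus_pwm(cfg$planted_consensus, strength = 0.97)
  m <- new_motif("truth", pwm)
  all_regions <- regions_for_loci(sim$genome, sim$genes, sim$genes$locus_tag)
  bg <- build_background(all_regions$sequence)
  hits <- scan_motif(all_regions, m, bg)
  for (i in seq_len(nrow(sim$manifest))) {
    expect_true(any(hits$start == sim$manifest$start[i] &
                      hits$contig_id == sim$manifest$contig_id[i]),
                label = sprintf("site %d recovered", i))
  }
})

test_that("homolog copies conserve planted sites more than flanks", {
  cfg <- simulation_config(seed = 98, n_genes = 40, regulon_size = 4)
  sim <- simulate_regulon_study(cfg)
  lt <- sim$manifest$locus_tag[1]
  reg <- extract_550bp_region(sim$genome,
                              sim$genes[sim$genes$locus_tag == lt, ])
  off <- sim$manifest$region_offset[sim$manifest$locus_tag == lt]
  w <- nchar(cfg$planted_consensus)

  ident <- generate_homologs(reg, off, w, n = 5, substitution_rate = 0,
                             seed = 98)
  expect_true(all(ident$sequence == reg$sequence))
  expect_true(all(ident$rank_score == 1))

  h <- generate_homologs(reg, off, w, n = 100, substitution_rate = 0.1,
                         site_conservation = 4, seed = 99)
  base <- strsplit(reg$sequence, "")[[1]]
  inside <- off + seq_len(w)
  id_in <- id_out <- numeric(nrow(h))
  for (i in seq_len(nrow(h))) {
    copy <- strsplit(h$sequence[i], "")[[1]]
    id_in[i] <- mean(copy[inside] == base[inside])
    id_out[i] <- mean(copy[-inside] == base[-inside])
  }
  expect_gt(mean(id_in), mean(id_out))
  expect_equal(mean(1 - h$rank_score), 0.1 * (550 - w) / 550 + 0.025 * w / 550,
               tolerance = 0.02)

  expect_error(generate_homologs(reg, off, w, n = -1), "non-negative")
  expect_equal(nrow(generate_homologs(reg, off, w, n = 0)), 0)
})
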