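# PWM scanning: log-odds closed forms, exact p-values vs brute-force
# enumeration, BH q-values vs a hand-rolled oracle, plant-and-recover scans,
# strand symmetry, tested-position accounting and p-value calibration.

uniform_bg <- build_background("ACGTACGTACGTACGT")

test_that("log-odds entries follow the closed form", {
  m <- new_motif("m", rbind(c(0.5, 0.25, 0.125, 0.125),
                            c(0.25, 0.25, 0.25, 0.25)))
  lom <- log_odds(m, uniform_bg)
  expect_equal(unname(lom[1, "A"]), 1)  # 0.5 vs 0.25 -> +1 bit
  expect_equal(unname(lom[1, "C"]), 0)  # equal to background -> 0 bits
  expect_equal(unname(lom[2, ]), rep(0, 4))  # uniform row -> all zero
  zero_bg <- list(stationary = c(A = 0, C = 0.5, G = 0.25, T = 0.25))
  class(zero_bg) <- "markov_background"
  expect_error(log_odds(m, zero_bg), "positive")
})

test_that("a unique best dimer has p-value 1/16 under a uniform background", {
  m <- new_motif("m", rbind(c(0.7, 0.1, 0.1, 0.1),
                            c(0.1, 0.1, 0.1, 0.7)))
  sd <- score_pvalues(log_odds(m, uniform_bg), uniform_bg)
  best_iscore <- sum(apply(sd$ilom, 1, max))
  expect_equal(pvalue_for_iscore(sd, best_iscore), 1 / 16, tolerance = 1e-12)
  # threshold below the minimum achievable score -> p = 1
  expect_equal(pvalue_at(sd, sd$min_score - 5), 1)
  expect_error(score_pvalues(log_odds(m, uniform_bg), uniform_bg, bins = 5),
               "bins")
})

test_that("DP p-values equal exhaustive enumeration for short motifs", {
  set.seed(61)
  for (w in c(3, 5, 7)) {
    probs <- matrix(stats::rgamma(4 * w, 1), ncol = 4)
    probs <- probs / rowSums(probs)
    m <- new_motif("m", probs)
    bg <- build_background(random_dna(500, gc = 0.6))
    sd <- score_pvalues(log_odds(m, bg), bg)
    oracle <- brute_force_pvalues(sd, unname(bg$stationary))
    for (isc in unique(round(seq(0, sum(apply(sd$ilom, 1, max)),
                                 length.out = 25)))) {
      expect_equal(pvalue_for_iscore(sd, isc), oracle(isc),
                   tolerance = 1e-6)
    }
  }
})

test_that("BH q-values match the hand-rolled step-up oracle", {
  expect_equal(bh_qvalues(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(bh_qvalues(0.07), 0.07)
  expect_equal(bh_qvalues(rep(0.2, 5)), rep(0.2, 5))
  set.seed(62)
  for (i in 1:50) {
    p <- runif(sample(1:80, 1))^sample(1:3, 1)
    p <- pmax(p, 1e-12)
    expect_equal(bh_qvalues(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_error(bh_qvalues(c(0.5, 0)), "0, 1")
  expect_error(bh_qvalues(c(0.5, 1.2)), "0, 1")
})

test_that("q-values are a monotone transform of p-values within a scan", {
  set.seed(63)
  g <- genome_record("c", random_dna(20000))
  m <- new_motif("m", consensus_pwm("TTGACAWWTATAAT"))
  bg <- build_background(g$sequence)
  hits <- scan_motif(g, m, bg, max_q = 1)
  ord <- order(hits$p_value)
  expect_true(all(diff(hits$q_value[ord]) >= -1e-12))
})

test_that("a planted perfect site is the top genome hit at its coordinate and strand", {
  set.seed(64)
  seq <- random_dna(20000)
  site <- "TTGACACGTGTGTCAA"
  substr(seq, 5001, 5016) <- site
  g <- genome_record("c", seq)
  m <- new_motif("m", consensus_pwm(site, strength = 0.97))
  bg <- build_background(seq)
  hits <- scan_motif(g, m, bg)
  expect_gte(nrow(hits), 1)
  top <- hits[which.min(hits$p_value), ]
  expect_equal(top$start, 5000)
  expect_equal(top$end, 5016)
})

test_that("scanning the reverse-complemented genome mirrors hits", {
  set.seed(65)
  seq <- random_dna(8000)
  substr(seq, 2001, 2016) <- "TTGACAAGGATCTCGT"
  m <- new_motif("m", consensus_pwm("TTGACAAGGATCTCGT"))
  bg <- uniform_bg
  L <- nchar(seq)
  h1 <- scan_motif(genome_record("c", seq), m, bg)
  h2 <- scan_motif(genome_record("c", reverse_complement(seq)), m, bg)
  expect_equal(nrow(h1), nrow(h2))
  h2m <- h2[order(L - h2$end), ]
  expect_equal(h1$start, L - h2m$end)
  expect_equal(h1$strand, ifelse(h2m$strand == "+", "-", "+"))
  expect_equal(h1$score, h2m$score, tolerance = 1e-9)
})

test_that("max_q = 0 returns no hits and width checks are enforced", {
  g <- genome_record("c", random_dna(2000))
  m <- new_motif("m", consensus_pwm("ACGTACGT"))
  hits <- scan_motif(g, m, uniform_bg, max_q = 0)
  expect_equal(nrow(hits), 0)
  wide <- new_motif("m", consensus_pwm(strrep("ACGT", 20)))
  expect_error(scan_motif(genome_record("c", random_dna(50)), wide,
                          uniform_bg), "wider")
})

test_that("the BH denominator counts both strands of every N-free window", {
  set.seed(66)
  seqs <- c(random_dna(200), random_dna(120))
  # one N in the second region kills exactly w windows
  substr(seqs[2], 60, 60) <- "N"
  regions <- data.frame(locus_tag = c("r1", "r2"), contig_id = "c",
                        start = c(0, 300), end = c(200, 420), strand = "+",
                        sequence = seqs, stringsAsFactors = FALSE)
  w <- 10
  m <- new_motif("m", consensus_pwm(strrep("AC", 5)))
  hits <- scan_motif(regions, m, uniform_bg, max_q = 1)
  expected <- 2 * ((200 - w + 1) + (120 - w + 1) - w)
  expect_equal(attr(hits, "n_tested"), expected)
})

test_that("p-values are calibrated on random genomes", {
  set.seed(67)
  g <- genome_record("c", random_dna(60000))
  probs <- matrix(stats::rgamma(40, 1), ncol = 4)
  probs <- probs / rowSums(probs)
  m <- new_motif("m", probs)
  bg <- build_background(g$sequence)
  hits <- scan_motif(g, m, bg, max_q = 1, dedup = FALSE)
  n <- attr(hits, "n_tested")
  for (alpha in c(0.001, 0.01)) {
    observed <- sum(hits$p_value <= alpha) / n
    se <- sqrt(alpha * (1 - alpha) / n)
    expect_lt(abs(observed - alpha), 3 * se + 1e-9)
  }
})

test_that("region-set hits map back to genome coordinates on both gene strands", {
  set.seed(68)
  seq <- random_dna(4000)
  site <- "TTGACAAGGATCTCGT"
  # plant inside the window of a + gene (start 2000) and of a - gene (end 1200)
  substr(seq, 1701, 1716) <- site                        # upstream of + gene
  substr(seq, 1301, 1316) <- reverse_complement(site)    # upstream of - gene
  g <- genome_record("c", seq)
  genes <- data.frame(locus_tag = c("gp", "gm"), contig_id = "c",
                      start = c(2000, 600), end = c(2600, 1200),
                      strand = c("+", "-"),
                      operon_id = c("o1", "o2"), operon_index = 1L,
                      stringsAsFactors = FALSE)
  regions <- regions_for_loci(g, genes, genes$locus_tag)
  m <- new_motif("m", consensus_pwm(site))
  hits <- scan_motif(regions, m, build_background(seq))
  expect_setequal(hits$start, c(1700, 1300))
  hp <- hits[hits$start == 1700, ]
  hm <- hits[hits$start == 1300, ]
  expect_equal(hp$strand, "+")
  expect_equal(hm$strand, "-")
  expect_equal(hp$region_locus, "gp")
  expect_equal(hm$region_locus, "gm")
  # the site sequences on the genome agree with the reported strand
  expect_equal(substr(seq, hp$start + 1, hp$end), site)
  expect_equal(reverse_complement(substr(seq, hm$start + 1, hm$end)), site)
})
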