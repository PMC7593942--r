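# Independent oracles and small fixture builders used across the suite.
# Everything here is deliberately brute-force / hand-rolled, so it cannot
# share a bug with the implementation under test.

# Hand-rolled Benjamini-Hochberg step-up.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  running <- Inf
  for (r in m:1) {
    running <- min(running, p[o[r]] * m / r)
    q[o[r]] <- min(running, 1)
  }
  q
}

# Plain-loop reverse complement over the IUPAC alphabet (independent of the
# package's chartr-based implementation).
rc_oracle <- function(x) {
  map <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
           W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
           N = "N")
  ch <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  paste(rev(unname(map[ch])), collapse = "")
}

# Enumerate every w-mer, score it with the same integer grid as a
# score_distribution, and return exact tail probabilities per integer score.
brute_force_pvalues <- function(sdist, bg) {
  w <- sdist$width
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  iscores <- integer(nrow(words))
  probs <- numeric(nrow(words))
  for (i in seq_len(nrow(words))) {
    iscores[i] <- sum(sdist$ilom[cbind(seq_len(w), words[i, ])])
    probs[i] <- prod(bg[words[i, ]])
  }
  function(iscore) sum(probs[iscores >= iscore])
}

# Random sequence of a given length / composition.
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Region set with one planted site per region (<= max_mut substitutions from
# the consensus, random offset and strand).
planted_regions <- function(n_regions, consensus, region_len = 550,
                            max_mut = 1, gc = 0.5) {
  w <- nchar(consensus)
  sets <- list(A = "A", C = "C", G = "G", T = "T", S = c("C", "G"),
               W = c("A", "T"), R = c("A", "G"), Y = c("C", "T"),
               K = c("G", "T"), M = c("A", "C"), N = c("A", "C", "G", "T"))
  truth <- data.frame(region = integer(), offset = integer(),
                      strand = character())
  seqs <- character(n_regions)
  for (i in seq_len(n_regions)) {
    s <- random_dna(region_len, gc)
    site <- vapply(strsplit(consensus, "", fixed = TRUE)[[1]],
                   function(c) sample(sets[[c]], 1), character(1),
                   USE.NAMES = FALSE)
    nm <- sample(0:max_mut, 1)
    if (nm > 0) {
      at <- sample(seq_len(w), nm)
      for (j in at) site[j] <- sample(setdiff(c("A","C","G","T"), site[j]), 1)
    }
    site_seq <- paste(site, collapse = "")
    strand <- sample(c("+", "-"), 1)
    if (strand == "-") site_seq <- regulonscan::reverse_complement(site_seq)
    o <- sample(0:(region_len - w), 1)
    substr(s, o + 1, o + w) <- site_seq
    seqs[i] <- s
    truth <- rbind(truth, data.frame(region = i, offset = o, strand = strand))
  }
  list(sequences = seqs, truth = truth)
}

# Probability matrix for an IUPAC consensus: listed bases share `strength`,
# the rest share the remainder.
consensus_pwm <- function(consensus, strength = 0.97) {
  sets <- list(A = "A", C = "C", G = "G", T = "T", S = c("C", "G"),
               W = c("A", "T"), R = c("A", "G"), Y = c("C", "T"),
               K = c("G", "T"), M = c("A", "C"),
               N = c("A", "C", "G", "T"))
  ch <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  probs <- t(vapply(ch, function(c) {
    p <- rep((1 - strength) / (4 - length(sets[[c]])), 4)
    names(p) <- c("A", "C", "G", "T")
    if (length(sets[[c]]) == 4) p[] <- 0.25
    else p[sets[[c]]] <- strength / length(sets[[c]])
    p
  }, numeric(4)))
  rownames(probs) <- NULL
  probs
}

# Tiny annotated genome shared by io / regions tests: two contigs, operons of
# both strands, deterministic sequence.
toy_study <- function(seed = 123) {
  set.seed(seed)
  genome <- list(
    genome_record("chrA", random_dna(2000)),
    genome_record("chrB", random_dna(1200)))
  names(genome) <- c("chrA", "chrB")
  genes <- data.frame(
    locus_tag = c("g1", "g2", "g3", "g4", "g5"),
    contig_id = c("chrA", "chrA", "chrA", "chrB", "chrB"),
    start = c(800, 1420, 1700, 100, 700),
    end = c(1400, 1680, 1950, 640, 1150),
    strand = c("+", "+", "+", "-", "-"),
    operon_id = c("opA", "opA", "opA", "opB", "opC"),
    operon_index = c(1L, 2L, 3L, 1L, 1L),
    stringsAsFactors = FALSE)
  expr <- data.frame(
    locus_tag = c("g1", "g2", "g3", "g4", "g5"),
    condition = "LCA",
    fold_change = c(1.0, 0.9, 5.0, 4.0, 1.1),
    q_value = c(0.8, 0.5, 0.01, 0.02, 0.9),
    stringsAsFactors = FALSE)
  list(genome = genome, genes = genes, expr = expr)
}

# GC fraction computed naively (independent of the package helper).
gc_fraction_of <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  mean(ch %in% c("G", "C"))
}

# Synthetic site tables for the criterion boundary checks: n sites, of which
# n_inside start within the single qualifying region below.
fake_sites <- function(n, n_inside, region_start = 0, region_end = 550) {
  start <- c(seq_len(n_inside) + region_start + 10,
             seq_len(max(n - n_inside, 0)) + region_end + 1000)
  data.frame(motif_id = rep("m", n), contig_id = rep("c", n), start = start,
             end = start + 15, strand = rep("+", n), score = rep(10, n),
             p_value = rep(1e-6, n), q_value = rep(1e-3, n),
             region_locus = rep(NA_character_, n),
             stringsAsFactors = FALSE)
}

qual_region <- data.frame(locus_tag = "q1", contig_id = "c", start = 0,
                          end = 550, strand = "+",
                          sequence = strrep("A", 550),
                          stringsAsFactors = FALSE)
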