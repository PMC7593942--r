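# Seeded recovery experiments: how reliably does the pipeline recover a
# planted regulon motif, and how often does it report anything on null data?
# These drive both the test suite and scripts/acceptance.R.

#' Distance between a planted consensus and a recovered one
#'
#' Recovered motifs often differ in width from the planted consensus (the
#' width sweep may settle on the planted core plus uninformative flanks), so
#' a plain Hamming distance is undefined.  This distance slides the shorter
#' string along the longer one (and along its reverse complement) and counts,
#' for the best offset, the mismatching IUPAC characters plus any planted
#' positions left uncovered.  When both strings have equal width it reduces
#' to `min(hamming(a, b), hamming(a, revcomp(b)))`.
#'
#' @param planted planted consensus (IUPAC).
#' @param recovered recovered consensus (IUPAC).
#' @return non-negative integer distance.
#' @export
consensus_distance <- function(planted, recovered) {
  a <- toupper(planted)
  slide <- function(short, long, extra) {
    s <- strsplit(short, "", fixed = TRUE)[[1]]
    l <- strsplit(long, "", fixed = TRUE)[[1]]
    m <- length(s)
    best <- m + extra
    for (o in 0:(length(l) - m)) {
      d <- sum(s != l[o + seq_len(m)]) + extra
      if (d < best) best <- d
    }
    best
  }
  dist_one <- function(b) {
    if (nchar(a) <= nchar(b)) slide(a, b, 0L)
    else slide(b, a, nchar(a) - nchar(b))
  }
  min(dist_one(toupper(recovered)), dist_one(reverse_complement(recovered)))
}

#' Planted-motif recovery rate of the main pipeline
#'
#' Runs `n_runs` independent simulations (defaults of
#' [simulation_config()]: a 30-operon induced regulon carrying the planted
#' palindrome) followed by [run_motif_pipeline()], and counts the runs in
#' which some motif passes both criteria with a consensus within
#' [consensus_distance()] `max_distance` of the plant.
#'
#' @param n_runs number of seeded simulations (default 20).
#' @param base_seed run `i` uses seed `base_seed + i`.
#' @param max_distance consensus tolerance (default 2).
#' @param config_args overrides passed to [simulation_config()].
#' @return list with `rate`, logical vector `hits`, and `n`.
#' @export
planted_recovery_rate <- function(n_runs = 20, base_seed = 1000,
                                  max_distance = 2, config_args = list()) {
  hits <- vapply(seq_len(n_runs), function(i) {
    cfg <- do.call(simulation_config,
                   modifyList(list(seed = base_seed + i), config_args))
    sim <- simulate_regulon_study(cfg)
    res <- run_motif_pipeline(sim$genome, sim$genes, sim$expression,
                              cfg$condition,
                              pipeline_config(seed = base_seed + i))
    v <- res$verdicts
    any(v$passes &
          vapply(v$consensus, function(cs)
            consensus_distance(cfg$planted_consensus, cs) <= max_distance,
            logical(1)))
  }, logical(1))
  list(rate = mean(hits), hits = hits, n = n_runs)
}

#' Footprinting recovery rate
#'
#' Runs `n_runs` simulations of an `regulon_size`-operon cluster whose first
#' genes carry the planted motif, generates ranked homolog copies of the seed
#' promoter windows (conserved inside planted sites), runs
#' [run_footprinting()], and counts the runs in which the plant is recovered
#' (consensus within `max_distance`) and the *refined* (step-5) motif passes
#' both criteria.
#'
#' @param n_runs number of seeded simulations (default 10).
#' @param base_seed run `i` uses seed `base_seed + i`.
#' @param max_distance consensus tolerance (default 2).
#' @param config_args overrides of the cluster simulation (defaults: 80
#'   genes, 8 regulon operons).
#' @return list with `rate`, logical vector `hits`, and `n`.
#' @export
footprint_recovery_rate <- function(n_runs = 10, base_seed = 2000,
                                    max_distance = 2, config_args = list()) {
  hits <- vapply(seq_len(n_runs), function(i) {
    args <- modifyList(list(seed = base_seed + i, n_genes = 80,
                            regulon_size = 8), config_args)
    cfg <- do.call(simulation_config, args)
    sim <- simulate_regulon_study(cfg)
    ht <- build_homolog_table(sim, sim$manifest$locus_tag)
    res <- tryCatch(
      run_footprinting(sim$regulon_operons, sim$genome, sim$genes,
                       sim$expression, ht, cfg$condition,
                       pipeline_config(seed = base_seed + i)),
      error = function(e) NULL)
    if (is.null(res) || length(res$kept_motifs) == 0) return(FALSE)
    any(vapply(res$kept_motifs, function(id) {
      v5 <- res$verdicts[res$verdicts$motif_id == paste0(id, "_refined"), ]
      if (nrow(v5) == 0 || !v5$passes) return(FALSE)
      m <- res$motifs[[which(vapply(res$motifs, function(m) m$motif_id,
                                    character(1)) == id)]]
      rm5 <- res$refined_motifs[[id]]
      consensus_distance(cfg$planted_consensus, m$consensus) <= max_distance ||
        (!is.null(rm5) &&
           consensus_distance(cfg$planted_consensus,
                              rm5$consensus) <= max_distance)
    }, logical(1)))
  }, logical(1))
  list(rate = mean(hits), hits = hits, n = n_runs)
}

#' False-discovery rate of the pipeline on null data
#'
#' Runs `n_runs` simulations with no planted motif and fully random
#' expression (background fold changes spanning the 3-fold threshold and
#' uniform q-values, so some genes pass the selection rule by chance) and
#' counts the runs in which any motif passes both criteria.
#'
#' @param n_runs number of seeded simulations (default 50).
#' @param base_seed run `i` uses seed `base_seed + i`.
#' @param config_args overrides of the null simulation (defaults: no
#'   regulon, background fold in (0.5, 8), background q uniform in (0, 1),
#'   so a handful of genes pass the selection rule by chance in most runs).
#' @return list with `rate`, logical vector `hits`, and `n`.
#' @export
null_pass_rate <- function(n_runs = 50, base_seed = 3000,
                           config_args = list()) {
  hits <- vapply(seq_len(n_runs), function(i) {
    args <- modifyList(list(seed = base_seed + i, regulon_size = 0,
                            background_fold = c(0.5, 8),
                            background_q = c(0, 1)), config_args)
    cfg <- do.call(simulation_config, args)
    sim <- simulate_regulon_study(cfg)
    res <- run_motif_pipeline(sim$genome, sim$genes, sim$expression,
                              cfg$condition,
                              pipeline_config(seed = base_seed + i))
    nrow(res$verdicts) > 0 && any(res$verdicts$passes)
  }, logical(1))
  list(rate = mean(hits), hits = hits, n = n_runs)
}
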