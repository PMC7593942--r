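# De novo motif discovery: ANR (any-number-of-repetitions) EM over all
# width-w windows of a region set, a width sweep, and an empirical
# shuffle-null significance estimate.  The compiled EM core lives in
# src/motif_em.cpp.

#' Default motif width sweep
#'
#' A geometric ladder (ratio ~1.4) through `[wmin, wmax]`, always including
#' `wmax`.  Exhaustively testing every width is unnecessary because EM
#' started near the true width converges to essentially the same motif.
#'
#' @param wmin,wmax width bounds (defaults 8 and 50).
#' @return integer vector of widths.
#' @export
default_width_sweep <- function(wmin = 8, wmax = 50) {
  if (wmin > wmax) stop("wmin must not exceed wmax")
  w <- wmin
  out <- integer(0)
  while (w < wmax) {
    out <- c(out, w)
    w <- as.integer(round(w * sqrt(2)))
  }
  unique(c(out, wmax))
}

seed_to_probs <- function(seed_word, match_prob = 0.5) {
  codes <- encode_dna(seed_word)
  w <- length(codes)
  p <- matrix((1 - match_prob) / 3, nrow = w, ncol = 4)
  p[cbind(seq_len(w), codes + 1L)] <- match_prob
  p
}

# Mononucleotide-preserving shuffle of integer-coded sequences; masked (-1)
# positions stay in place so the window structure is preserved.
shuffle_codes <- function(codes) {
  lapply(codes, function(v) {
    idx <- which(v >= 0L)
    if (length(idx) > 1) v[idx] <- v[idx][sample.int(length(idx))]
    v
  })
}

# BIC-style width penalty so EM objectives are comparable across widths.
width_penalty <- function(w, n_data) 1.5 * w * log(n_data)

# Best motif candidate over the width sweep for one data set.  Statistic =
# penalised objective after a fixed, short EM schedule (`select_iter`
# iterations from the best of `n_seed_starts` seed words); the same schedule
# is applied to observed and shuffled data so the two are exchangeable under
# the null.
best_candidate <- function(codes, widths, bg, gamma0, pseudo,
                           n_seed_starts, select_iter, both_strands) {
  best <- NULL
  for (w in widths) {
    seeds <- tryCatch(
      cpp_top_seeds(codes, w, bg, n_seed_starts, both_strands),
      error = function(e) character(0))
    if (length(seeds) == 0) next
    seed_obj <- vapply(seeds, function(s) {
      cpp_em_anr(codes, w, seed_to_probs(s), bg, gamma0, 0L, 1e-6,
                 pseudo, both_strands)$objective
    }, numeric(1))
    seed <- seeds[which.max(seed_obj)]
    em <- cpp_em_anr(codes, w, seed_to_probs(seed), bg, gamma0,
                     as.integer(select_iter), 1e-6, pseudo, both_strands)
    stat <- em$objective - width_penalty(w, 2 * em$n_windows)
    if (is.null(best) || stat > best$stat) {
      best <- list(width = w, seed = seed, stat = stat, em = em)
    }
  }
  best
}

#' Discover over-represented motifs in a region set
#'
#' Fits an ANR two-component mixture by EM: every width-`w` window on both
#' strands of every region is either a motif occurrence or background.  For
#' each width in the sweep the EM is started from the highest
#' background-corrected-frequency w-mers; the best width is chosen by a
#' BIC-penalised log-likelihood-ratio objective, and the winning start is
#' refined by EM to convergence.  Significance is an empirical E-value proxy:
#' the same short discovery schedule is run on `n_shuffles`
#' mononucleotide-preserving shuffles of the regions, and
#' `E = (1 + #{null >= observed}) / (n_shuffles + 1)`.  A motif is reported
#' only when `E <= max_evalue`; its sites (posterior >= 0.5) are then masked
#' and the search repeats, up to `max_motifs` motifs, returned ordered by
#' significance.
#'
#' @param regions promoter-region data.frame (column `sequence`) or character
#'   vector of sequences; at least 2 required.
#' @param wmin,wmax motif width bounds (defaults 8 and 50).
#' @param max_evalue maximum E-value proxy for a motif to be reported
#'   (default 0.1).
#' @param max_motifs maximum number of motifs (default 5).
#' @param both_strands search both strands (default TRUE).
#' @param seed integer seed driving the shuffle null.
#' @param background optional `markov_background`; estimated from the regions
#'   (order 0) when missing.
#' @param widths optional explicit width sweep overriding
#'   [default_width_sweep()].
#' @param n_shuffles shuffle replicates behind the E-value proxy (default 18,
#'   so only a motif beating every shuffle, `E = 1/19`, clears the default
#'   0.1 threshold).
#' @param n_seed_starts seed words evaluated per width (default 2).
#' @param select_iter EM iterations of the fixed width-selection schedule
#'   (default 5).
#' @param max_iter,tol convergence controls of the final refinement EM
#'   (defaults 50 and 1e-6).
#' @return list of `motif` objects; each carries extra fields `objective`,
#'   `gamma` and `sites` (data.frame of region index, offset, strand and
#'   posterior for its posterior >= 0.5 occurrences), plus attribute
#'   `n_rounds`.
#' @export
discover_motifs <- function(regions, wmin = 8, wmax = 50, max_evalue = 0.1,
                            max_motifs = 5, both_strands = TRUE, seed = 1,
                            background = NULL, widths = NULL,
                            n_shuffles = 18, n_seed_starts = 2,
                            select_iter = 5, max_iter = 50, tol = 1e-6) {
  seqs <- if (is.data.frame(regions)) regions$sequence else regions
  seqs <- toupper(as.character(seqs))
  if (length(seqs) < 2)
    stop("motif discovery needs at least 2 regions; got ", length(seqs))
  if (wmin > wmax) stop("wmin must not exceed wmax")
  widths <- if (is.null(widths)) default_width_sweep(wmin, wmax) else
    sort(unique(as.integer(widths)))
  if (any(widths < 1)) stop("widths must be positive")
  if (is.null(background)) background <- build_background(seqs, order = 0)
  bg <- unname(stationary_freqs(background))
  pseudo <- 0.1 * bg
  gamma0 <- 1 / 550

  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv), add = TRUE)
  set.seed(seed)

  codes <- lapply(seqs, encode_dna)
  # Null distribution of the selection statistic, computed once on shuffles
  # of the unmasked regions; later rounds see less (masked) data, so reusing
  # these nulls is conservative for second and further motifs.
  null_stats <- vapply(seq_len(n_shuffles), function(r) {
    sh <- shuffle_codes(codes)
    cand <- best_candidate(sh, widths, bg, gamma0, pseudo,
                           n_seed_starts, select_iter, both_strands)
    if (is.null(cand)) -Inf else cand$stat
  }, numeric(1))
  motifs <- list()
  n_rounds <- 0L
  while (length(motifs) < max_motifs) {
    n_rounds <- n_rounds + 1L
    obs <- best_candidate(codes, widths, bg, gamma0, pseudo,
                          n_seed_starts, select_iter, both_strands)
    if (is.null(obs)) break
    evalue <- (1 + sum(null_stats >= obs$stat)) / (n_shuffles + 1)
    if (evalue > max_evalue) break

    em <- cpp_em_anr(codes, obs$width, seed_to_probs(obs$seed), bg, gamma0,
                     as.integer(max_iter), tol, pseudo, both_strands)
    z <- pmax(em$zf, em$zr)
    hit <- which(z >= 0.5)
    motif <- new_motif(sprintf("motif_%d", length(motifs) + 1L),
                       em$probs, counts = em$counts, nsites = em$nsites,
                       significance = evalue)
    motif$objective <- em$objective
    motif$gamma <- em$gamma
    motif$trajectory <- em$trajectory
    motif$sites <- data.frame(
      region = em$win_seq[hit] + 1L,
      offset = em$win_pos[hit],
      strand = ifelse(em$zf[hit] >= em$zr[hit], "+", "-"),
      posterior = z[hit],
      stringsAsFactors = FALSE)
    motifs[[length(motifs) + 1L]] <- motif

    # mask the occurrences so later rounds cannot rediscover this motif
    for (i in seq_along(hit)) {
      s <- em$win_seq[hit[i]] + 1L
      p <- em$win_pos[hit[i]] + 1L
      codes[[s]][p:(p + obs$width - 1L)] <- -1L
    }
  }
  ord <- order(vapply(motifs, function(m) m$significance, numeric(1)),
               -vapply(motifs, function(m) m$objective, numeric(1)))
  motifs <- motifs[ord]
  attr(motifs, "n_rounds") <- n_rounds
  motifs
}
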