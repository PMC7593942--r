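# Genome-wide PWM scanning: log-odds scores, exact score p-values by dynamic
# programming over a discretised score grid, Benjamini-Hochberg q-values per
# motif, and mapping of window hits back to genome coordinates.

#' Log-odds scoring matrix of a motif
#'
#' Entry `[j, b] = log2(probs[j, b] / stationary[b])` — the standard PWM in
#' bits against an order-0 background.
#'
#' @param motif a `motif` object.
#' @param background background model (stationary frequencies are used).
#' @return width x 4 numeric matrix (columns A, C, G, T).
#' @export
log_odds <- function(motif, background) {
  bg <- stationary_freqs(background)
  if (any(bg <= 0)) stop("background frequencies must all be positive")
  lom <- log2(sweep(motif$probs, 2, bg, "/"))
  colnames(lom) <- DNA_BASES
  lom
}

#' Exact score distribution of a PWM under an order-0 background
#'
#' Discretises the log-odds matrix onto an integer grid of `bins` steps
#' spanning the achievable score range and convolves the per-column score
#' distributions under the stationary background.  The resulting tail
#' probabilities are exact for the discretised scores: a window scored with
#' the same integer grid gets the exact probability that a random w-mer
#' scores at least as high.
#'
#' @param lom log-odds matrix from [log_odds()].
#' @param background background model.
#' @param bins number of grid steps (default 1000; at least 10).
#' @return a `score_distribution` object: list with `ilom` (integer matrix),
#'   `delta` (grid step), `min_score` (score at grid point 0), `tail`
#'   (`P(int score >= s)` for `s = 0..max`), and `width`.
#' @export
score_pvalues <- function(lom, background, bins = 1000) {
  if (bins < 10) stop("bins must be at least 10")
  if (any(!is.finite(lom))) stop("log-odds matrix has non-finite entries")
  bg <- stationary_freqs(background)
  w <- nrow(lom)
  row_min <- apply(lom, 1, min)
  row_max <- apply(lom, 1, max)
  range <- sum(row_max) - sum(row_min)
  delta <- if (range > 0) range / bins else 1
  ilom <- matrix(as.integer(round((lom - row_min) / delta)),
                 nrow = w, dimnames = dimnames(lom))
  max_int <- sum(apply(ilom, 1, max))
  dist <- numeric(max_int + 1L)
  dist[1] <- 1
  cur_max <- 0L
  for (j in seq_len(w)) {
    nd <- numeric(max_int + 1L)
    for (b in 1:4) {
      sh <- ilom[j, b]
      idx <- seq_len(cur_max + 1L)
      nd[idx + sh] <- nd[idx + sh] + dist[idx] * bg[b]
    }
    dist <- nd
    cur_max <- cur_max + max(ilom[j, ])
  }
  tail <- rev(cumsum(rev(dist)))
  tail <- pmin(tail, 1)
  structure(list(ilom = ilom, delta = delta, min_score = sum(row_min),
                 tail = tail, width = w),
            class = "score_distribution")
}

#' P-value of a score threshold
#'
#' Probability that a random w-mer under the background scores at least
#' `score`.  Thresholds below the minimum achievable score give 1.
#'
#' @param sd a `score_distribution`.
#' @param score log-odds threshold(s) in bits.
#' @return p-value(s) in (0, 1].
#' @export
pvalue_at <- function(sd, score) {
  i <- as.integer(round((score - sd$min_score) / sd$delta))
  pvalue_for_iscore(sd, i)
}

#' @rdname pvalue_at
#' @param iscore integer grid score(s) as used in `sd$ilom`.
#' @export
pvalue_for_iscore <- function(sd, iscore) {
  n <- length(sd$tail)
  i <- pmin(pmax(iscore, 0L), n - 1L)
  sd$tail[i + 1L]
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjustment `q(i) = min over j with p(j) >= p(i) of p(j) * m / rank(j)`
#' capped at 1, order-preserving with the input.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return q-values in the input order.
#' @export
bh_qvalues <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(pvalues, method = "BH")
}

# --- window scoring ---------------------------------------------------------

# Concatenate sequences with single -1 separators; windows crossing a
# boundary contain the separator and are dropped automatically.
concat_codes <- function(seqs) {
  codes <- lapply(seqs, encode_dna)
  lens <- vapply(codes, length, integer(1))
  n <- length(codes)
  total <- sum(lens) + (n - 1L)
  v <- rep(-1L, max(total, 0L))
  starts <- integer(n)
  pos <- 1L
  for (i in seq_len(n)) {
    starts[i] <- pos
    if (lens[i] > 0) v[pos:(pos + lens[i] - 1L)] <- codes[[i]]
    pos <- pos + lens[i] + 1L
  }
  list(codes = v, starts = starts, lens = lens)
}

# Integer and real scores of every window of a coded vector; invalid windows
# (containing -1) get NA.
score_windows_int <- function(v, ilom, lom) {
  w <- nrow(ilom)
  n <- length(v) - w + 1L
  if (n < 1) return(list(iscore = integer(0), score = numeric(0)))
  isc <- integer(n)
  sc <- numeric(n)
  valid <- rep(TRUE, n)
  idx0 <- seq_len(n)
  for (j in seq_len(w)) {
    b <- v[idx0 + (j - 1L)]
    bad <- b < 0L
    valid <- valid & !bad
    b1 <- ifelse(bad, 1L, b + 1L)
    isc <- isc + ilom[j, b1]
    sc <- sc + lom[j, b1]
  }
  isc[!valid] <- NA_integer_
  sc[!valid] <- NA_real_
  list(iscore = isc, score = sc)
}

#' Scan a genome or region set for motif sites
#'
#' Scores every window on both strands, converts scores to exact p-values
#' under the order-0 stationary background, computes Benjamini-Hochberg
#' q-values per motif across *all* tested positions, and returns the hits
#' with `q <= max_q` in genome-coordinate order.
#'
#' @param targets either genome record(s) or a promoter-region data.frame
#'   (from [regions_for_loci()]); region hits are mapped back to genome
#'   coordinates when the regions carry them.
#' @param motif a `motif` object.
#' @param background background model; p-values use its stationary
#'   frequencies.
#' @param max_q maximum site q-value (default 0.05).
#' @param regions optional promoter-region data.frame used to annotate
#'   genome-scan hits with a containing region's locus (a site is "in" a
#'   region iff its start coordinate lies in the region interval).
#' @param bins score-grid resolution (default 1000).
#' @param dedup drop duplicate genome sites arising from overlapping regions
#'   (default TRUE).
#' @return site data.frame: `motif_id`, `contig_id`, `start`, `end`,
#'   `strand`, `score` (bits), `p_value`, `q_value`, `region_locus`; the
#'   number of tested positions is in attribute `n_tested`.
#' @export
scan_motif <- function(targets, motif, background, max_q = 0.05,
                       regions = NULL, bins = 1000, dedup = TRUE) {
  is_region_set <- is.data.frame(targets)
  if (is_region_set) {
    seqs <- toupper(targets$sequence)
    meta <- targets
  } else {
    if (inherits(targets, "genome_record")) targets <- list(targets)
    seqs <- vapply(targets, function(g) g$sequence, character(1))
    meta <- data.frame(
      contig_id = vapply(targets, function(g) g$contig_id, character(1)),
      stringsAsFactors = FALSE)
  }
  w <- motif$width
  if (w > max(nchar(seqs)))
    stop("motif (width ", w, ") is wider than every scanned target")
  if (w > min(nchar(seqs)))
    stop("motif (width ", w, ") is wider than the shortest scanned window")

  lom <- log_odds(motif, background)
  sd_f <- score_pvalues(lom, background, bins)
  lom_r <- lom[w:1, 4:1, drop = FALSE]
  colnames(lom_r) <- DNA_BASES
  sd_r <- score_pvalues(lom_r, background, bins)

  cc <- concat_codes(seqs)
  fwd <- score_windows_int(cc$codes, sd_f$ilom, lom)
  rev <- score_windows_int(cc$codes, sd_r$ilom, lom_r)
  ok <- which(!is.na(fwd$iscore))
  n_tested <- 2L * length(ok)

  p <- c(pvalue_for_iscore(sd_f, fwd$iscore[ok]),
         pvalue_for_iscore(sd_r, rev$iscore[ok]))
  q <- bh_qvalues(p)
  keep <- which(q <= max_q)
  nk <- length(keep)

  if (nk == 0) {
    out <- data.frame(motif_id = character(), contig_id = character(),
                      start = numeric(), end = numeric(), strand = character(),
                      score = numeric(), p_value = numeric(),
                      q_value = numeric(), region_locus = character(),
                      stringsAsFactors = FALSE)
    attr(out, "n_tested") <- n_tested
    return(out)
  }

  m <- length(ok)
  is_rev <- keep > m
  win <- ok[ifelse(is_rev, keep - m, keep)]
  piece <- findInterval(win, cc$starts)
  offset <- win - cc$starts[piece]
  score <- ifelse(is_rev, rev$score[win], fwd$score[win])

  if (is_region_set) {
    reg <- meta[piece, , drop = FALSE]
    has_coord <- !is.na(reg$start)
    contig <- ifelse(has_coord, reg$contig_id, reg$locus_tag)
    # oriented region offset -> genome interval
    start <- ifelse(reg$strand == "+" & has_coord, reg$start + offset,
             ifelse(has_coord, reg$end - offset - w, offset))
    match_on_gene_strand <- !is_rev
    strand <- ifelse(!has_coord,
                     ifelse(is_rev, "-", "+"),
              ifelse(reg$strand == "+",
                     ifelse(match_on_gene_strand, "+", "-"),
                     ifelse(match_on_gene_strand, "-", "+")))
    region_locus <- reg$locus_tag
  } else {
    contig <- meta$contig_id[piece]
    start <- offset
    strand <- ifelse(is_rev, "-", "+")
    region_locus <- NA_character_
  }

  out <- data.frame(motif_id = motif$motif_id, contig_id = contig,
                    start = start, end = start + w, strand = strand,
                    score = score, p_value = p[keep], q_value = q[keep],
                    region_locus = region_locus, stringsAsFactors = FALSE)

  if (!is_region_set && !is.null(regions) && nrow(regions) > 0) {
    out$region_locus <- assign_region(out, regions)
  }
  out <- out[order(out$contig_id, out$start, out$strand), , drop = FALSE]
  if (dedup) {
    out <- out[!duplicated(out[, c("contig_id", "start", "strand")]), ,
               drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "n_tested") <- n_tested
  out
}

# First region (by coordinate order) whose interval contains the site start.
assign_region <- function(sites, regions) {
  regions <- regions[!is.na(regions$start), , drop = FALSE]
  out <- rep(NA_character_, nrow(sites))
  for (i in seq_len(nrow(sites))) {
    hit <- which(regions$contig_id == sites$contig_id[i] &
                   regions$start <= sites$start[i] &
                   sites$start[i] < regions$end)
    if (length(hit) > 0) out[i] <- regions$locus_tag[hit[1]]
  }
  out
}
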