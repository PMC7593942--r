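# Motif container plus consensus / palindrome utilities and re-estimation of
# a motif from a set of genomic sites.

#' Construct a motif object
#'
#' @param motif_id identifier.
#' @param probs width x 4 matrix of per-position base probabilities (columns
#'   A, C, G, T); each row must sum to 1 within 1e-6.
#' @param counts optional width x 4 matrix of (possibly fractional) site
#'   counts behind `probs`.
#' @param nsites number of sites the motif was estimated from (may be
#'   fractional for EM-weighted counts).
#' @param significance empirical E-value proxy of the motif (see
#'   [discover_motifs()]); smaller is more significant.
#' @return a `motif` object (list with the fields above plus `width` and
#'   `consensus`).
#' @export
new_motif <- function(motif_id, probs, counts = NULL, nsites = NA_real_,
                      significance = NA_real_) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4) stop("probs must have 4 columns (A, C, G, T)")
  if (nrow(probs) < 1) stop("motif must have positive width")
  if (any(probs < 0)) stop("negative probability in motif ", motif_id)
  if (any(abs(rowSums(probs) - 1) > 1e-6))
    stop("probability rows of motif ", motif_id, " must sum to 1")
  colnames(probs) <- DNA_BASES
  structure(list(motif_id = motif_id,
                 width = nrow(probs),
                 probs = probs,
                 counts = counts,
                 nsites = nsites,
                 significance = significance,
                 consensus = consensus_of(probs)),
            class = "motif")
}

#' @export
print.motif <- function(x, ...) {
  cat(sprintf("motif %s  width=%d  nsites=%.1f  E=%.3g\n  consensus: %s\n",
              x$motif_id, x$width,
              if (is.na(x$nsites)) 0 else x$nsites,
              if (is.na(x$significance)) NA else x$significance,
              x$consensus))
  invisible(x)
}

IUPAC_PAIR <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")

#' IUPAC consensus of a motif
#'
#' Per column: the single base when its probability is at least `strong` and
#' it is the unique maximum; otherwise the two-letter IUPAC code when the two
#' most probable bases together reach `pair`; otherwise `N`.
#'
#' @param motif a `motif` object or a width x 4 probability matrix.
#' @param strong single-base threshold (default 0.5).
#' @param pair two-base threshold (default 0.8).
#' @return IUPAC consensus string.
#' @export
consensus_of <- function(motif, strong = 0.5, pair = 0.8) {
  probs <- if (inherits(motif, "motif")) motif$probs else as.matrix(motif)
  letters <- apply(probs, 1, function(p) {
    ord <- order(p, decreasing = TRUE)
    if (p[ord[1]] >= strong && p[ord[1]] > p[ord[2]]) {
      DNA_BASES[ord[1]]
    } else if (p[ord[1]] + p[ord[2]] >= pair) {
      key <- paste(sort(DNA_BASES[ord[1:2]]), collapse = "")
      IUPAC_PAIR[[key]]
    } else {
      "N"
    }
  })
  paste(letters, collapse = "")
}

#' Is an IUPAC consensus a perfect palindrome?
#'
#' True iff the IUPAC reverse complement of the string equals the string
#' itself (`S` and `W` are self-complementary, `R` pairs with `Y`,
#' `K` with `M`, `N` with `N`).
#'
#' @param consensus IUPAC string.
#' @return logical flag.
#' @export
is_palindrome <- function(consensus) {
  stopifnot(is.character(consensus), length(consensus) == 1)
  identical(reverse_complement(consensus), toupper(consensus))
}

#' Reverse complement of a motif
#' @param motif a `motif` object.
#' @return the reverse-complemented `motif`.
#' @export
motif_reverse_complement <- function(motif) {
  probs <- motif$probs[motif$width:1, 4:1, drop = FALSE]
  counts <- if (!is.null(motif$counts))
    motif$counts[motif$width:1, 4:1, drop = FALSE] else NULL
  new_motif(motif$motif_id, probs, counts = counts, nsites = motif$nsites,
            significance = motif$significance)
}

#' Re-estimate a motif from genomic sites
#'
#' Rebuilds a motif from the strand-oriented sequences of a site set: counts
#' the bases per column, adds a pseudocount of `0.1 *` the stationary
#' background frequency to each cell, and normalises.  This is the motif
#' refinement step of the footprinting pipeline, which re-anchors a motif
#' learned partly from homologous genomes to the sites actually found in the
#' target genome.
#'
#' @param sites site data.frame (needs `contig_id`, `start`, `end`,
#'   `strand`); all sites must have width `width`.
#' @param genome genome record(s) the coordinates refer to.
#' @param width motif width.
#' @param background background model supplying stationary frequencies.
#' @param motif_id identifier for the re-estimated motif.
#' @return a `motif` object with `nsites = nrow(sites)`.
#' @export
reestimate_from_sites <- function(sites, genome, width, background,
                                  motif_id = "reestimated") {
  if (nrow(sites) < 2)
    stop("re-estimation needs at least 2 sites; got ", nrow(sites))
  if (any(sites$end - sites$start != width))
    stop("all sites must have width ", width)
  seqs <- vapply(seq_len(nrow(sites)), function(i) {
    rec <- get_contig(genome, sites$contig_id[i])
    s <- substr(rec$sequence, sites$start[i] + 1, sites$end[i])
    if (sites$strand[i] == "-") reverse_complement(s) else s
  }, character(1))
  counts <- matrix(0, nrow = width, ncol = 4,
                   dimnames = list(NULL, DNA_BASES))
  for (s in seqs) {
    v <- encode_dna(s)
    ok <- v >= 0
    counts[cbind(which(ok), v[ok] + 1L)] <-
      counts[cbind(which(ok), v[ok] + 1L)] + 1
  }
  bg <- stationary_freqs(background)
  pseudo <- matrix(0.1 * bg, nrow = width, ncol = 4, byrow = TRUE)
  probs <- (counts + pseudo) / rowSums(counts + pseudo)
  new_motif(motif_id, probs, counts = counts, nsites = nrow(sites))
}
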