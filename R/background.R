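# Order-k Markov background model estimated from both strands of a sequence
# set, with add-0.1 smoothing per context cell.  Order 0 is the default and is
# what the scanner's exact p-values are computed under.

#' Build a Markov background model from sequences
#'
#' Counts order-`order` transitions on the sequences and their reverse
#' complements (so the model is strand-symmetric), smooths each context cell
#' by adding 0.1, and normalises.  The `stationary` slot holds the smoothed
#' mononucleotide frequencies implied by the same two-strand counts.
#'
#' @param sequences character vector of sequences over `{A,C,G,T,N}`;
#'   N-containing contexts are skipped.
#' @param order non-negative Markov order (0 = mononucleotide frequencies).
#' @return a `markov_background` object: list with `order`, `conditional`
#'   (`4^order` x 4 matrix of next-base probabilities, rownames are contexts)
#'   and `stationary` (length-4 base frequencies, names `A,C,G,T`).
#' @export
build_background <- function(sequences, order = 0) {
  if (length(order) != 1 || is.na(order) || order < 0)
    stop("background order must be a non-negative integer")
  order <- as.integer(order)
  sequences <- toupper(as.character(sequences))
  if (length(sequences) == 0 || sum(nchar(sequences)) == 0)
    stop("cannot build a background model from empty input")
  both <- c(sequences, reverse_complement(sequences))
  codes <- lapply(both, encode_dna)

  mono <- rep(0, 4)
  for (v in codes) {
    ok <- v >= 0
    if (any(ok)) mono <- mono + tabulate(v[ok] + 1L, nbins = 4)
  }
  stationary <- (mono + 0.1) / sum(mono + 0.1)
  names(stationary) <- DNA_BASES

  n_ctx <- 4L^order
  counts <- matrix(0, nrow = n_ctx, ncol = 4)
  for (v in codes) {
    L <- length(v)
    if (L < order + 1L) next
    idx <- seq_len(L - order)
    ctx <- rep(0L, length(idx))
    valid <- rep(TRUE, length(idx))
    if (order > 0) {
      for (j in seq_len(order)) {
        b <- v[idx + j - 1L]
        valid <- valid & b >= 0L
        ctx <- ctx * 4L + pmax(b, 0L)
      }
    }
    nxt <- v[idx + order]
    valid <- valid & nxt >= 0L
    if (!any(valid)) next
    tab <- table(factor(ctx[valid], levels = 0:(n_ctx - 1L)),
                 factor(nxt[valid], levels = 0:3))
    counts <- counts + as.matrix(tab)
  }
  counts <- counts + 0.1
  conditional <- counts / rowSums(counts)
  colnames(conditional) <- DNA_BASES
  rownames(conditional) <- context_labels(order)
  structure(list(order = order, conditional = conditional,
                 stationary = stationary),
            class = "markov_background")
}

context_labels <- function(order) {
  if (order == 0) return("")
  grid <- do.call(expand.grid,
                  rev(replicate(order, DNA_BASES, simplify = FALSE)))
  apply(grid[, rev(seq_len(order)), drop = FALSE], 1, paste, collapse = "")
}

#' @export
print.markov_background <- function(x, ...) {
  cat(sprintf("Markov background (order %d)\n", x$order))
  cat(sprintf("stationary: A=%.4f C=%.4f G=%.4f T=%.4f\n",
              x$stationary[1], x$stationary[2],
              x$stationary[3], x$stationary[4]))
  invisible(x)
}

# Coerce: accept either a markov_background or a bare length-4 frequency
# vector wherever only stationary frequencies are needed.
stationary_freqs <- function(background) {
  if (inherits(background, "markov_background")) return(background$stationary)
  if (is.numeric(background) && length(background) == 4) {
    bg <- background / sum(background)
    names(bg) <- DNA_BASES
    return(bg)
  }
  stop("background must be a markov_background or a length-4 frequency vector")
}
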