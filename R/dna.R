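# Low-level nucleotide helpers shared across the package.

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC complements; used for consensus strings as well as plain sequence.
IUPAC_CHARS <- "ACGTRYSWKMBDHVN"
IUPAC_COMP <- "TGCAYRSWMKVHDBN"

#' Reverse complement of DNA / IUPAC strings
#'
#' Works on plain `ACGTN` sequence and on IUPAC consensus strings
#' (ambiguity codes map to the complement of the set they denote, e.g.
#' `R` <-> `Y`, while the self-complementary codes `S`, `W` and `N` map to
#' themselves).
#'
#' @param x character vector of sequences.
#' @return character vector of reverse-complemented sequences.
#' @export
reverse_complement <- function(x) {
  stopifnot(is.character(x))
  bad <- grepl(sprintf("[^%s]", IUPAC_CHARS), toupper(x))
  if (any(bad)) {
    stop("non-IUPAC symbol in sequence: ",
         substr(gsub(sprintf("[%s]", IUPAC_CHARS), "", toupper(x[bad][1])), 1, 1))
  }
  comp <- chartr(IUPAC_CHARS, IUPAC_COMP, toupper(x))
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Integer coding: A=0, C=1, G=2, T=3, N (or masked) = -1.
encode_dna <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  v <- utf8ToInt(toupper(x))
  out <- rep(-1L, length(v))
  out[v == 65L] <- 0L  # A
  out[v == 67L] <- 1L  # C
  out[v == 71L] <- 2L  # G
  out[v == 84L] <- 3L  # T
  known <- v %in% c(65L, 67L, 71L, 84L, 78L)
  if (!all(known)) {
    stop("sequence contains a symbol outside {A,C,G,T,N}: ",
         intToUtf8(v[!known][1]))
  }
  out
}

decode_dna <- function(codes) {
  ch <- rep("N", length(codes))
  ok <- codes >= 0L & codes <= 3L
  ch[ok] <- DNA_BASES[codes[ok] + 1L]
  paste(ch, collapse = "")
}

# GC fraction of a set of sequences (N ignored).
gc_fraction <- function(x) {
  counts <- colSums(Biostrings::letterFrequency(
    Biostrings::DNAStringSet(x), c("G", "C", "A", "T")))
  sum(counts[c("G", "C")]) / sum(counts)
}
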