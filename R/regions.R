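# Differential-expression driven gene selection and extraction of the 550-bp
# promoter windows (500 bp upstream + 50 bp downstream of the start codon).

#' Select induced genes from an expression table
#'
#' Returns the loci whose expression under `condition` is at least
#' `min_fold`-fold induced with a q-value of at most `max_q`.  Both
#' boundaries are inclusive.
#'
#' @param expr expression data.frame (`locus_tag`, `condition`,
#'   `fold_change`, `q_value`).
#' @param condition condition label to filter on.
#' @param min_fold minimum fold change (default 3).
#' @param max_q maximum q-value (default 0.05).
#' @return sorted character vector of locus tags.
#' @export
select_induced_genes <- function(expr, condition, min_fold = 3,
                                 max_q = 0.05) {
  avail <- unique(expr$condition)
  if (!condition %in% avail)
    stop("condition '", condition, "' not in expression table; available: ",
         paste(avail, collapse = ", "))
  sel <- expr$condition == condition &
    expr$fold_change >= min_fold & expr$q_value <= max_q
  sort(unique(expr$locus_tag[sel]))
}

#' First genes of operons containing a significantly induced gene
#'
#' Implements the operon-level selection behind the regulator filter: an
#' operon qualifies when at least one of its genes is significantly
#' (q-value <= `max_q`) induced (fold change > 1) under `condition`; the
#' *first* gene of every qualifying operon is returned, whether or not that
#' gene itself changed.  Note there is no fold-change threshold beyond
#' directionality here — significance alone qualifies the operon.
#'
#' @param genes gene-model data.frame with operon assignments.
#' @param expr expression data.frame.
#' @param condition condition label.
#' @param max_q maximum q-value (default 0.05).
#' @return sorted character vector of first-gene locus tags.
#' @export
qualifying_first_genes <- function(genes, expr, condition, max_q = 0.05) {
  sig <- expr$locus_tag[expr$condition == condition &
                          expr$q_value <= max_q & expr$fold_change > 1]
  ops <- unique(genes$operon_id[genes$locus_tag %in% sig])
  firsts <- genes$locus_tag[genes$operon_id %in% ops & genes$operon_index == 1L]
  sort(unique(firsts))
}

#' Extract the promoter window of one gene
#'
#' For a `+` strand gene whose start codon begins at genomic offset `s`, the
#' window is `[s - upstream, s + downstream)` read forward; for a `-` strand
#' gene with interval `[b, e)` (start codon at `e - 1`), it is
#' `[e - downstream, e + upstream)` read as the reverse complement.  The
#' `downstream` bases start at, and include, the first base of the start
#' codon.  Windows are truncated at the edges of linear contigs; circular
#' contigs wrap around.
#'
#' @param genome genome record(s).
#' @param gene one-row gene-model data.frame (or equivalent list).
#' @param upstream bases upstream of the start codon (default 500).
#' @param downstream bases downstream including the start codon's first base
#'   (default 50).
#' @return one-row data.frame: `locus_tag`, `contig_id`, `start`, `end`,
#'   `strand`, `sequence` (oriented in the gene's reading direction).
#' @export
extract_550bp_region <- function(genome, gene, upstream = 500,
                                 downstream = 50) {
  rec <- get_contig(genome, gene$contig_id)
  L <- nchar(rec$sequence)
  if (gene$start < 0 || gene$end > L || gene$start >= gene$end)
    stop("gene ", gene$locus_tag, " lies outside contig ", gene$contig_id)
  if (gene$strand == "+") {
    a <- gene$start - upstream
    b <- gene$start + downstream
  } else {
    a <- gene$end - downstream
    b <- gene$end + upstream
  }
  if (rec$is_circular && L >= (b - a)) {
    idx <- ((a:(b - 1)) %% L) + 1L
    seq <- paste(strsplit(rec$sequence, "", fixed = TRUE)[[1]][idx],
                 collapse = "")
    start <- a %% L
    end <- start + (b - a)  # may exceed L to signal wrap; sequence is exact
  } else {
    a <- max(a, 0)
    b <- min(b, L)
    seq <- substr(rec$sequence, a + 1, b)
    start <- a
    end <- b
  }
  if (gene$strand == "-") seq <- reverse_complement(seq)
  data.frame(locus_tag = gene$locus_tag, contig_id = gene$contig_id,
             start = start, end = end, strand = gene$strand,
             sequence = seq, stringsAsFactors = FALSE)
}

#' Extract promoter windows for a set of loci
#'
#' One region per distinct locus, ordered by contig then interval start.
#'
#' @param genome genome record(s).
#' @param genes gene-model data.frame.
#' @param loci character vector of locus tags (duplicates collapse).
#' @param upstream,downstream window geometry, see [extract_550bp_region()].
#' @return promoter-region data.frame (possibly 0 rows).
#' @export
regions_for_loci <- function(genome, genes, loci, upstream = 500,
                             downstream = 50) {
  loci <- unique(loci)
  empty <- data.frame(locus_tag = character(), contig_id = character(),
                      start = numeric(), end = numeric(),
                      strand = character(), sequence = character(),
                      stringsAsFactors = FALSE)
  if (length(loci) == 0) {
    message("no loci supplied; returning an empty region set")
    return(empty)
  }
  missing <- setdiff(loci, genes$locus_tag)
  if (length(missing) > 0)
    stop("no gene model for locus: ", paste(missing, collapse = ", "))
  rows <- lapply(loci, function(lt) {
    extract_550bp_region(genome, genes[genes$locus_tag == lt, ],
                         upstream, downstream)
  })
  out <- do.call(rbind, rows)
  out[order(out$contig_id, out$start), , drop = FALSE]
}
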