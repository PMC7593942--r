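# External formats: FASTA genomes and regions, GFF3 gene models with an
# operon TSV, expression TSV, MEME-minimal motif files, BED6 + TSV site
# reports.  All internal coordinates are 0-based half-open; GFF3 is converted
# at this boundary.

#' Construct a genome record
#'
#' @param contig_id contig identifier.
#' @param sequence nucleotide sequence over `{A,C,G,T,N}` (lowercase is
#'   normalised to uppercase).
#' @param is_circular logical; circular contigs allow promoter windows to
#'   wrap around the origin.
#' @return a `genome_record` (list with the three fields above).
#' @export
genome_record <- function(contig_id, sequence, is_circular = FALSE) {
  stopifnot(is.character(contig_id), length(contig_id) == 1,
            is.character(sequence), length(sequence) == 1)
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1) stop("contig ", contig_id, " has empty sequence")
  if (grepl("[^ACGTN]", sequence)) {
    bad <- substr(gsub("[ACGTN]", "", sequence), 1, 1)
    stop("contig ", contig_id, " contains non-ACGTN symbol: ", bad)
  }
  structure(list(contig_id = contig_id, sequence = sequence,
                 is_circular = isTRUE(is_circular)),
            class = "genome_record")
}

#' Read a genome FASTA file
#'
#' @param path FASTA file.
#' @return named list of [genome_record()] objects, one per FASTA entry.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stop("malformed FASTA '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  if (length(ss) == 0) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  recs <- lapply(seq_along(ss), function(i) {
    genome_record(ids[i], as.character(ss[[i]]))
  })
  names(recs) <- ids
  recs
}

#' Write a genome (or any named sequence set) as FASTA
#'
#' @param genome list of [genome_record()]s, or a named character vector.
#' @param path output path.
#' @export
write_genome <- function(genome, path) {
  if (inherits(genome, "genome_record")) genome <- list(genome)
  if (is.list(genome)) {
    seqs <- vapply(genome, function(g) g$sequence, character(1))
    names(seqs) <- vapply(genome, function(g) g$contig_id, character(1))
  } else {
    seqs <- genome
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Lengths of the contigs of a genome
#' @param genome list of [genome_record()]s (or a single record).
#' @return named numeric vector of contig lengths.
#' @export
contig_lengths <- function(genome) {
  if (inherits(genome, "genome_record")) genome <- list(genome)
  setNames(vapply(genome, function(g) nchar(g$sequence), numeric(1)),
           vapply(genome, function(g) g$contig_id, character(1)))
}

get_contig <- function(genome, contig_id) {
  if (inherits(genome, "genome_record")) {
    if (genome$contig_id != contig_id)
      stop("contig not in genome: ", contig_id)
    return(genome)
  }
  ids <- vapply(genome, function(g) g$contig_id, character(1))
  i <- match(contig_id, ids)
  if (is.na(i)) stop("contig not in genome: ", contig_id)
  genome[[i]]
}

#' Read gene models from GFF3 plus an operon table
#'
#' GFF3 coordinates (1-based inclusive) are converted to the internal
#' 0-based half-open convention.  Every gene receives an operon assignment;
#' genes absent from the operon table become singleton operons with
#' `operon_index = 1` (with a warning).
#'
#' @param gff_path GFF3 file; features of type `gene` (or `CDS` when no gene
#'   features exist) are used, identified by their `locus_tag` (falling back
#'   to `ID`).
#' @param operon_path TSV with columns `locus_tag`, `operon_id`,
#'   `operon_index`.
#' @param contig_lengths optional named vector of contig lengths; when given,
#'   genes extending beyond their contig raise an error.
#' @return data.frame with columns `locus_tag`, `contig_id`, `start`, `end`,
#'   `strand`, `operon_id`, `operon_index`.
#' @export
read_annotations <- function(gff_path, operon_path, contig_lengths = NULL) {
  if (!file.exists(gff_path)) stop("GFF3 not found: ", gff_path)
  gr <- rtracklayer::import(gff_path)
  types <- as.character(gr$type)
  keep <- types == "gene"
  if (!any(keep)) keep <- types == "CDS"
  gr <- gr[keep]
  if (length(gr) == 0) stop("no gene features in ", gff_path)
  locus <- if (!is.null(gr$locus_tag)) as.character(gr$locus_tag) else NULL
  if (is.null(locus) || anyNA(locus)) {
    alt <- as.character(gr$ID)
    if (is.null(locus)) locus <- alt else locus[is.na(locus)] <- alt[is.na(locus)]
  }
  if (anyNA(locus)) stop("gene feature without locus_tag or ID in ", gff_path)
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-")))
    stop("gene feature without explicit strand in ", gff_path)
  genes <- data.frame(
    locus_tag = locus,
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = strand,
    stringsAsFactors = FALSE)
  if (anyDuplicated(genes$locus_tag))
    stop("duplicated locus_tag in ", gff_path, ": ",
         genes$locus_tag[duplicated(genes$locus_tag)][1])

  ops <- read.delim(operon_path, stringsAsFactors = FALSE)
  need <- c("locus_tag", "operon_id", "operon_index")
  if (!all(need %in% names(ops)))
    stop("operon table must have columns: ", paste(need, collapse = ", "))
  m <- match(genes$locus_tag, ops$locus_tag)
  genes$operon_id <- ops$operon_id[m]
  genes$operon_index <- as.integer(ops$operon_index[m])
  orphan <- is.na(m)
  if (any(orphan)) {
    warning(sum(orphan), " gene(s) missing from operon table; ",
            "treated as singleton operons (e.g. ",
            genes$locus_tag[orphan][1], ")")
    genes$operon_id[orphan] <- paste0("singleton_", genes$locus_tag[orphan])
    genes$operon_index[orphan] <- 1L
  }
  if (any(genes$operon_index < 1L)) stop("operon_index must be >= 1")

  if (!is.null(contig_lengths)) {
    len <- contig_lengths[genes$contig_id]
    if (anyNA(len)) stop("gene on unknown contig: ",
                         genes$contig_id[is.na(len)][1])
    bad <- genes$start < 0 | genes$end > len | genes$start >= genes$end
    if (any(bad)) stop("gene coordinates outside contig: ",
                       genes$locus_tag[bad][1])
  }
  genes[order(genes$contig_id, genes$start), , drop = FALSE]
}

#' Write gene models as GFF3
#'
#' Internal 0-based half-open coordinates are converted back to the 1-based
#' inclusive GFF3 convention.
#'
#' @param genes gene-model data.frame (see [read_annotations()]).
#' @param path output GFF3 path.
#' @export
write_gene_models <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig_id,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand)
  gr$type <- "gene"
  gr$ID <- genes$locus_tag
  gr$locus_tag <- genes$locus_tag
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write / read the operon assignment table
#' @param genes gene-model data.frame.
#' @param path TSV path.
#' @export
write_operons <- function(genes, path) {
  write.table(genes[, c("locus_tag", "operon_id", "operon_index")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression table
#'
#' @param path TSV with columns `locus_tag`, `condition`, `fold_change`,
#'   `q_value`.
#' @return validated data.frame.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression table not found: ", path)
  expr <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("locus_tag", "condition", "fold_change", "q_value")
  if (!all(need %in% names(expr)))
    stop("expression table must have columns: ", paste(need, collapse = ", "))
  if (any(expr$q_value < 0 | expr$q_value > 1))
    stop("q_value outside [0,1] in ", path)
  if (any(expr$fold_change < 0))
    stop("negative fold_change in ", path)
  expr
}

#' @rdname read_expression
#' @param expr expression data.frame.
#' @export
write_expression <- function(expr, path) {
  write.table(expr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write motifs in MEME minimal format
#'
#' Probabilities are written with six decimals; a round-trip through
#' [read_motifs()] reproduces the matrix to that precision.
#'
#' @param motifs list of [new_motif()] objects.
#' @param path output path.
#' @param background optional background model (its stationary frequencies go
#'   into the header); uniform frequencies are written otherwise.
#' @export
write_motifs <- function(motifs, path, background = NULL) {
  if (inherits(motifs, "motif")) motifs <- list(motifs)
  bg <- if (is.null(background)) rep(0.25, 4) else background$stationary
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.6f C %.6f G %.6f T %.6f", bg[1], bg[2], bg[3], bg[4]),
               ""), con)
  for (m in motifs) {
    if (any(abs(rowSums(m$probs) - 1) > 1e-4))
      stop("motif ", m$motif_id, " has an unnormalised probability row")
    writeLines(sprintf("MOTIF %s", m$motif_id), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %.2f E= %.3g",
      m$width, if (is.na(m$nsites)) 0 else m$nsites,
      if (is.na(m$significance)) 1 else m$significance), con)
    for (j in seq_len(m$width)) {
      writeLines(sprintf(" %.6f %.6f %.6f %.6f",
                         m$probs[j, 1], m$probs[j, 2],
                         m$probs[j, 3], m$probs[j, 4]), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Read motifs from a MEME minimal format file
#'
#' @param path MEME-minimal motif file.
#' @return list of [new_motif()] objects.
#' @export
read_motifs <- function(path) {
  if (!file.exists(path)) stop("motif file not found: ", path)
  lines <- readLines(path)
  hits <- grep("^MOTIF\\s+", lines)
  motifs <- vector("list", length(hits))
  for (i in seq_along(hits)) {
    id <- sub("^MOTIF\\s+(\\S+).*$", "\\1", lines[hits[i]])
    hdr_i <- hits[i] + which(grepl("^letter-probability matrix:",
                                   lines[(hits[i] + 1):length(lines)]))[1]
    hdr <- lines[hdr_i]
    w <- as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", hdr))
    nsites <- if (grepl("nsites=", hdr))
      as.numeric(sub(".*nsites=\\s*([0-9.eE+-]+).*", "\\1", hdr)) else NA_real_
    evalue <- if (grepl("E=", hdr))
      as.numeric(sub(".*E=\\s*([0-9.eE+-]+).*", "\\1", hdr)) else NA_real_
    rows <- lines[(hdr_i + 1):(hdr_i + w)]
    probs <- do.call(rbind, lapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])))
    if (ncol(probs) != 4) stop("bad probability row in motif ", id)
    motifs[[i]] <- new_motif(id, probs, nsites = nsites,
                             significance = evalue)
  }
  motifs
}

#' Write promoter regions as FASTA
#' @param regions promoter-region data.frame (see [extract_550bp_region()]).
#' @param path output FASTA path.
#' @export
write_regions_fasta <- function(regions, path) {
  seqs <- setNames(regions$sequence, regions$locus_tag)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write motif sites as BED6 plus a companion TSV
#'
#' BED intervals are 0-based half-open, the score column carries the
#' log-odds score in bits, and lines are emitted in coordinate order.  The
#' TSV adds p-value, q-value and the assigned promoter region.
#'
#' @param sites site data.frame as returned by [scan_motif()].
#' @param bed_path BED6 output path.
#' @param tsv_path TSV output path (defaults to `bed_path` with a `.tsv`
#'   extension).
#' @export
write_sites <- function(sites, bed_path, tsv_path = NULL) {
  if (is.null(tsv_path)) tsv_path <- sub("\\.bed$", ".tsv", bed_path)
  if (identical(tsv_path, bed_path)) tsv_path <- paste0(bed_path, ".tsv")
  ord <- order(sites$contig_id, sites$start, sites$strand)
  sites <- sites[ord, , drop = FALSE]
  bed <- data.frame(sites$contig_id, sites$start, sites$end,
                    sites$motif_id, sprintf("%.4f", sites$score),
                    sites$strand)
  write.table(bed, bed_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(sites, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(bed = bed_path, tsv = tsv_path))
}
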