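# Phylogenetic footprinting: pool the promoter windows of ranked homologs
# with the seed genes' own windows, discover motifs on the pooled set,
# scan the target genome's promoter windows, re-estimate each motif from its
# in-genome sites, rescan, and keep motifs passing the regulator filters in
# either scan round.

#' Assemble a footprinting region set
#'
#' Per seed gene: its own promoter window plus the `top_n` best-ranked
#' homolog promoter sequences (all available when fewer).  With `s` seeds
#' each contributing at least `top_n` homologs the set has
#' `(top_n + 1) * s` regions — e.g. 8 seeds with 20 homologs each give 168.
#'
#' @param seed_loci character vector of seed locus tags.
#' @param homolog_table data.frame with columns `seed_locus`, `homolog_id`,
#'   `rank_score` (larger = better-ranked homolog) and `region_sequence`.
#' @param genome,genes genome and gene models supplying the seeds' own
#'   windows.
#' @param top_n homologs taken per seed (default 20).
#' @param upstream,downstream window geometry.
#' @return promoter-region data.frame with a `source` column (`"seed"` or
#'   `"homolog"`); homolog rows carry sequence only (no genome coordinates).
#' @export
build_footprint_set <- function(seed_loci, homolog_table, genome, genes,
                                top_n = 20, upstream = 500, downstream = 50) {
  missing <- setdiff(seed_loci, genes$locus_tag)
  if (length(missing) > 0)
    stop("no gene model for seed locus: ", paste(missing, collapse = ", "))
  rows <- lapply(seed_loci, function(lt) {
    own <- extract_550bp_region(genome, genes[genes$locus_tag == lt, ],
                                upstream, downstream)
    own$source <- "seed"
    hl <- homolog_table[homolog_table$seed_locus == lt, , drop = FALSE]
    if (nrow(hl) > 0) {
      hl <- hl[order(-hl$rank_score), , drop = FALSE]
      hl <- head(hl, top_n)
      hom <- data.frame(locus_tag = hl$homolog_id, contig_id = NA_character_,
                        start = NA_real_, end = NA_real_, strand = "+",
                        sequence = toupper(hl$region_sequence),
                        source = "homolog", stringsAsFactors = FALSE)
      own <- rbind(own, hom)
    }
    own
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a homolog table
#' @param path TSV with columns `seed_locus`, `homolog_id`, `rank_score`,
#'   `region_sequence`.
#' @return validated data.frame.
#' @export
read_homolog_table <- function(path) {
  if (!file.exists(path)) stop("homolog table not found: ", path)
  h <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("seed_locus", "homolog_id", "rank_score", "region_sequence")
  if (!all(need %in% names(h)))
    stop("homolog table must have columns: ", paste(need, collapse = ", "))
  h
}

#' Phylogenetic-footprinting motif screen
#'
#' (1-2) the first genes of the cluster's qualifying operons (operons with at
#' least one significantly induced gene) become seeds and are pooled with
#' their ranked homolog windows; (3) motifs are discovered on the pooled set;
#' (4) each motif is scanned against the promoter windows of all genes in the
#' target genome and the regulator filters are applied; (5) each motif is
#' re-estimated from its in-genome q-passing sites only (when it has at least
#' two) and rescanned; (6) a motif is kept when its step-4 *or* step-5 sites
#' satisfy both criteria.
#'
#' @param cluster_operons operon ids delimiting the cluster of interest.
#' @param genome,genes,expr,condition as in [run_motif_pipeline()].
#' @param homolog_table see [build_footprint_set()].
#' @param config list from [pipeline_config()].
#' @return list with `status`, `seed_loci`, `footprint_regions`, `motifs`,
#'   `refined_motifs`, `sites4`, `sites5`, and `verdicts` (one row per motif
#'   and scan round, plus a `kept` flag).
#' @export
run_footprinting <- function(cluster_operons, genome, genes, expr,
                             homolog_table, condition = "LCA",
                             config = pipeline_config()) {
  cluster_genes <- genes[genes$operon_id %in% cluster_operons, , drop = FALSE]
  qual_all <- qualifying_first_genes(genes, expr, condition, config$max_q_deg)
  seeds <- intersect(cluster_genes$locus_tag[cluster_genes$operon_index == 1L],
                     qual_all)
  if (length(seeds) < 2)
    stop("footprinting needs at least 2 qualifying operons in the cluster; ",
         "got ", length(seeds))
  fp <- build_footprint_set(seeds, homolog_table, genome, genes,
                            config$top_n_homologs,
                            config$upstream, config$downstream)
  motifs <- discover_motifs(fp, wmin = config$wmin, wmax = config$wmax,
                            max_evalue = config$max_evalue,
                            max_motifs = config$max_motifs,
                            both_strands = config$both_strands,
                            seed = config$seed)
  all_regions <- regions_for_loci(genome, genes, genes$locus_tag,
                                  config$upstream, config$downstream)
  scan_bg <- build_background(all_regions$sequence, order = 0)
  qual_regions <- regions_for_loci(genome, genes, qual_all,
                                   config$upstream, config$downstream)

  sites4 <- list(); sites5 <- list(); refined <- list()
  verdicts <- NULL
  for (m in motifs) {
    s4 <- scan_motif(all_regions, m, scan_bg, max_q = config$max_q_site)
    v4 <- filter_verdict(m$motif_id, s4, qual_regions,
                         config$max_sites, config$min_fraction)
    v4$round <- 4L
    s5 <- NULL; v5 <- NULL; rm5 <- NULL
    if (nrow(s4) >= 2) {
      rm5 <- reestimate_from_sites(s4, genome, m$width, scan_bg,
                                   motif_id = paste0(m$motif_id, "_refined"))
      s5 <- scan_motif(all_regions, rm5, scan_bg, max_q = config$max_q_site)
      v5 <- filter_verdict(rm5$motif_id, s5, qual_regions,
                           config$max_sites, config$min_fraction)
      v5$round <- 5L
    }
    kept <- v4$passes || (!is.null(v5) && v5$passes)
    v4$kept <- kept
    if (!is.null(v5)) v5$kept <- kept
    verdicts <- rbind(verdicts, v4, v5)
    sites4[[m$motif_id]] <- s4
    if (!is.null(s5)) sites5[[m$motif_id]] <- s5
    if (!is.null(rm5)) refined[[m$motif_id]] <- rm5
  }
  if (is.null(verdicts)) {
    verdicts <- data.frame(motif_id = character(), n_sites = integer(),
                           n_in_qualifying = integer(), fraction = numeric(),
                           passes_A = logical(), passes_B = logical(),
                           passes = logical(), round = integer(),
                           kept = logical(), stringsAsFactors = FALSE)
  }
  kept_ids <- unique(verdicts$motif_id[verdicts$kept &
                                         !grepl("_refined$", verdicts$motif_id)])
  list(status = if (length(motifs) > 0) "ok" else "no_motifs",
       seed_loci = seeds, footprint_regions = fp, motifs = motifs,
       refined_motifs = refined, sites4 = sites4, sites5 = sites5,
       verdicts = verdicts, kept_motifs = kept_ids)
}
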