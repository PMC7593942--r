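# The two regulator-likeness filters and the end-to-end motif pipeline:
# a motif is a transcription-factor candidate when (A) it has at most 1000
# q-passing sites (more suggests promoter elements or low-complexity repeats)
# and (B) more than 10% of its sites fall in promoter windows of first genes
# of operons containing a significantly induced gene.

#' Criterion A: site-count cap
#'
#' @param sites q-passing site data.frame of one motif.
#' @param max_sites inclusive cap (default 1000): exactly `max_sites` sites
#'   still pass, one more fails.
#' @return logical flag.
#' @export
criterion_A <- function(sites, max_sites = 1000) {
  nrow(sites) <= max_sites
}

#' Criterion B: concentration in qualifying promoter windows
#'
#' The fraction of sites whose start coordinate lies inside the promoter
#' window of a qualifying first gene must strictly exceed `min_fraction`
#' ("more than 10%"): exactly 10% fails, and so does a motif with zero sites.
#'
#' @param sites q-passing site data.frame of one motif.
#' @param qualifying_regions promoter-region data.frame of the first genes of
#'   qualifying operons (see [qualifying_first_genes()]).
#' @param min_fraction strict lower bound on the fraction (default 0.10).
#' @return list with `n_sites`, `n_in_qualifying`, `fraction`, `passes_B`.
#' @export
criterion_B <- function(sites, qualifying_regions, min_fraction = 0.10) {
  n <- nrow(sites)
  if (n == 0) {
    return(list(n_sites = 0L, n_in_qualifying = 0L, fraction = 0,
                passes_B = FALSE))
  }
  inq <- !is.na(assign_region(sites, qualifying_regions))
  k <- sum(inq)
  frac <- k / n
  list(n_sites = n, n_in_qualifying = k, fraction = frac,
       passes_B = frac > min_fraction)
}

#' Per-motif filter verdict
#'
#' @param motif_id identifier.
#' @param sites q-passing site data.frame of the motif.
#' @param qualifying_regions see [criterion_B()].
#' @param max_sites,min_fraction filter thresholds.
#' @return one-row data.frame with the criterion bookkeeping.
#' @export
filter_verdict <- function(motif_id, sites, qualifying_regions,
                           max_sites = 1000, min_fraction = 0.10) {
  b <- criterion_B(sites, qualifying_regions, min_fraction)
  a <- criterion_A(sites, max_sites)
  data.frame(motif_id = motif_id, n_sites = b$n_sites,
             n_in_qualifying = b$n_in_qualifying, fraction = b$fraction,
             passes_A = a, passes_B = b$passes_B,
             passes = a && b$passes_B, stringsAsFactors = FALSE)
}

#' Default pipeline configuration
#'
#' The thresholds of the whole screen in one list: 3-fold induction at
#' q <= 0.05 selects the discovery genes, promoter windows are 500 bp up /
#' 50 bp down, motifs are 8-50 bp with E-value proxy at most 0.1, sites are
#' kept at q <= 0.05, and the filters use 1000 sites / 10% / 20 homologs.
#'
#' @param ... overrides of individual entries.
#' @return named list of parameters.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    min_fold = 3, max_q_deg = 0.05,
    upstream = 500, downstream = 50,
    wmin = 8, wmax = 50, max_evalue = 0.1, max_motifs = 5,
    max_q_site = 0.05, max_sites = 1000, min_fraction = 0.10,
    top_n_homologs = 20, both_strands = TRUE, seed = 1)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config entries: ", paste(unknown, collapse = ", "))
  modifyList(cfg, over)
}

#' Run the full motif screen
#'
#' (1) select induced genes (fold >= `min_fold`, q <= `max_q_deg`);
#' (2) extract their promoter windows; (3) discover motifs in those windows;
#' (4) scan the promoter windows of *all* genes for each motif
#' (q <= `max_q_site`); (5) apply criteria A and B.  All motifs are returned
#' with their verdicts and a palindrome annotation; pipelines with no induced
#' genes (or fewer than two discovery regions) return an empty result with an
#' explanatory status rather than an error.
#'
#' @param genome genome record(s).
#' @param genes gene-model data.frame with operon assignments.
#' @param expr expression data.frame.
#' @param condition induction condition label.
#' @param config list from [pipeline_config()].
#' @return list with `status`, `induced_loci`, `regions` (discovery regions),
#'   `motifs`, `sites` (list of q-passing site sets per motif), and
#'   `verdicts` (data.frame: motif, width, consensus, palindrome,
#'   significance and the criterion bookkeeping).
#' @export
run_motif_pipeline <- function(genome, genes, expr, condition = "LCA",
                               config = pipeline_config()) {
  empty_verdicts <- data.frame(
    motif_id = character(), width = integer(), consensus = character(),
    palindrome = logical(), significance = numeric(), n_sites = integer(),
    n_in_qualifying = integer(), fraction = numeric(), passes_A = logical(),
    passes_B = logical(), passes = logical(), stringsAsFactors = FALSE)
  induced <- select_induced_genes(expr, condition, config$min_fold,
                                  config$max_q_deg)
  if (length(induced) == 0) {
    return(list(status = "no_induced_genes", induced_loci = character(),
                regions = NULL, motifs = list(), sites = list(),
                verdicts = empty_verdicts))
  }
  disc_regions <- regions_for_loci(genome, genes, induced,
                                   config$upstream, config$downstream)
  if (nrow(disc_regions) < 2) {
    return(list(status = "insufficient_regions", induced_loci = induced,
                regions = disc_regions, motifs = list(), sites = list(),
                verdicts = empty_verdicts))
  }
  motifs <- discover_motifs(disc_regions, wmin = config$wmin,
                            wmax = config$wmax,
                            max_evalue = config$max_evalue,
                            max_motifs = config$max_motifs,
                            both_strands = config$both_strands,
                            seed = config$seed)
  if (length(motifs) == 0) {
    return(list(status = "no_motifs", induced_loci = induced,
                regions = disc_regions, motifs = list(), sites = list(),
                verdicts = empty_verdicts))
  }
  all_regions <- regions_for_loci(genome, genes, genes$locus_tag,
                                  config$upstream, config$downstream)
  scan_bg <- build_background(all_regions$sequence, order = 0)
  qual <- qualifying_first_genes(genes, expr, condition, config$max_q_deg)
  qual_regions <- regions_for_loci(genome, genes, qual,
                                   config$upstream, config$downstream)
  sites <- lapply(motifs, function(m)
    scan_motif(all_regions, m, scan_bg, max_q = config$max_q_site))
  verdicts <- do.call(rbind, lapply(seq_along(motifs), function(i) {
    v <- filter_verdict(motifs[[i]]$motif_id, sites[[i]], qual_regions,
                        config$max_sites, config$min_fraction)
    cbind(v[, "motif_id", drop = FALSE],
          data.frame(width = motifs[[i]]$width,
                     consensus = motifs[[i]]$consensus,
                     palindrome = is_palindrome(motifs[[i]]$consensus),
                     significance = motifs[[i]]$significance,
                     stringsAsFactors = FALSE),
          v[, setdiff(names(v), "motif_id"), drop = FALSE])
  }))
  names(sites) <- vapply(motifs, function(m) m$motif_id, character(1))
  list(status = "ok", induced_loci = induced, regions = disc_regions,
       motifs = motifs, sites = sites, verdicts = verdicts)
}
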