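# Synthetic study generator: a random genome with operon-structured genes, a
# palindromic motif planted upstream of a designated regulon's first genes,
# an expression table in which the regulon is induced, and mutated homolog
# copies of seed promoter windows for footprinting.  Everything is
# reproducible from the single seed in the configuration.

#' Simulation configuration
#'
#' Defaults emulate the kind of bacterial study the pipeline targets: ~120
#' genes in ~60 operons on one contig, a 30-operon regulon carrying a planted
#' 15-bp palindromic motif upstream of its first genes, induction of regulon
#' genes at 3-30 fold with q <= 0.05, background genes near 1-fold with
#' uniform q, and homologs at 10% background substitution with 4-fold
#' conservation inside planted sites.
#'
#' @param seed master seed; all generator randomness derives from it.
#' @param n_genes total gene count.
#' @param genes_per_operon inclusive integer range of operon sizes.
#' @param gene_length inclusive range of gene lengths (bp).
#' @param operon_gap range of intergenic gaps between operons (bp); must
#'   leave room for two non-overlapping promoter windows.
#' @param gene_gap range of within-operon gaps (bp).
#' @param gc_content genome GC fraction in (0, 1).
#' @param regulon_size number of operons carrying the planted motif.
#' @param planted_consensus IUPAC consensus the planted sites are drawn from.
#' @param planted_mutations maximum number of substitutions per planted site
#'   (each site receives 0..planted_mutations, uniformly).
#' @param site_offset_range admissible site start offsets within the oriented
#'   promoter window (kept inside the upstream segment by default).
#' @param induced_fold fold-change range of regulon genes (all >= 3).
#' @param induced_q q-value range of regulon genes (all <= 0.05).
#' @param background_fold fold-change range of non-regulon genes.
#' @param background_q q-value range of non-regulon genes; the default
#'   (0.06, 1) keeps background genes clear of the q <= 0.05 significance
#'   rule so the regulon maps exactly onto the qualifying operons; set to
#'   (0, 1) for a fully random null.
#' @param homolog_substitution_rate per-base substitution rate outside
#'   planted sites in homolog copies.
#' @param site_conservation factor dividing the substitution rate inside
#'   planted sites (default 4).
#' @param n_homologs homolog copies generated per seed region.
#' @param condition induction condition label.
#' @param contig_length optional fixed contig length; the layout must fit.
#' @return named list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1, n_genes = 120,
                              genes_per_operon = c(1, 3),
                              gene_length = c(500, 900),
                              operon_gap = c(1200, 1500),
                              gene_gap = c(20, 60),
                              gc_content = 0.5,
                              regulon_size = 30,
                              planted_consensus = "TCCCGGTSACCGGGA",
                              planted_mutations = 1,
                              site_offset_range = c(20, 460),
                              induced_fold = c(3, 30),
                              induced_q = c(1e-6, 0.05),
                              background_fold = c(0.8, 1.2),
                              background_q = c(0.06, 1),
                              homolog_substitution_rate = 0.10,
                              site_conservation = 4,
                              n_homologs = 20,
                              condition = "LCA",
                              contig_length = NULL) {
  cfg <- as.list(environment())
  stopifnot(cfg$gc_content > 0, cfg$gc_content < 1,
            cfg$regulon_size >= 0, cfg$n_genes >= 1,
            cfg$homolog_substitution_rate >= 0,
            cfg$homolog_substitution_rate <= 1)
  structure(cfg, class = "simulation_config")
}

sample_range <- function(range, n = 1) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' Generate a random operon-structured genome
#'
#' Single contig of i.i.d. bases at the configured GC content.  Operons are
#' laid left to right with large inter-operon gaps (promoter space) and small
#' within-operon gaps; each operon gets a uniform random strand, and
#' `operon_index` counts in transcription order (so the first gene of a `-`
#' operon is its rightmost gene).
#'
#' @param config a [simulation_config()].
#' @return list with `genome` (a [genome_record()]) and `genes` (gene-model
#'   data.frame).
#' @export
generate_genome <- function(config) {
  set.seed(config$seed)
  sizes <- integer(0)
  total <- 0L
  while (total < config$n_genes) {
    s <- sample_range(config$genes_per_operon)
    s <- min(s, config$n_genes - total)
    sizes <- c(sizes, s)
    total <- total + s
  }
  n_operons <- length(sizes)
  strands <- sample(c("+", "-"), n_operons, replace = TRUE)

  rows <- vector("list", config$n_genes)
  pos <- 0L
  gi <- 0L
  for (o in seq_len(n_operons)) {
    pos <- pos + sample_range(config$operon_gap)
    op_id <- sprintf("op%04d", o)
    k <- sizes[o]
    idx_order <- if (strands[o] == "+") seq_len(k) else rev(seq_len(k))
    for (j in seq_len(k)) {
      len <- sample_range(config$gene_length)
      gi <- gi + 1L
      rows[[gi]] <- data.frame(
        locus_tag = sprintf("GENE_%04d", gi),
        contig_id = "contig_1",
        start = pos, end = pos + len, strand = strands[o],
        operon_id = op_id, operon_index = idx_order[j],
        stringsAsFactors = FALSE)
      pos <- pos + len
      if (j < k) pos <- pos + sample_range(config$gene_gap)
    }
  }
  genes <- do.call(rbind, rows)
  L <- pos + max(config$operon_gap)
  if (!is.null(config$contig_length)) {
    if (config$contig_length < L)
      stop("genes do not fit in contig_length = ", config$contig_length,
           "; shrink gene/intergenic ranges or enlarge the contig")
    L <- config$contig_length
  }
  gc <- config$gc_content
  seq <- paste(sample(DNA_BASES, L, replace = TRUE,
                      prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
               collapse = "")
  list(genome = genome_record("contig_1", seq), genes = genes)
}

# Deterministic regulon choice given the config seed.
choose_regulon <- function(genes, config) {
  ops <- unique(genes$operon_id)
  if (config$regulon_size > length(ops))
    stop("regulon_size exceeds the number of operons")
  if (config$regulon_size == 0) return(character(0))
  set.seed(config$seed + 7L)
  sort(sample(ops, config$regulon_size))
}

# Sample one site sequence from an IUPAC consensus with 0..max_mut random
# substitutions.
sample_site <- function(consensus, max_mut) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = DNA_BASES)
  ch <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  site <- vapply(ch, function(c) {
    s <- sets[[c]]
    if (length(s) == 1) s else sample(s, 1)
  }, character(1), USE.NAMES = FALSE)
  nm <- if (max_mut > 0) sample(0:max_mut, 1) else 0L
  if (nm > 0) {
    at <- sample(seq_along(site), nm)
    for (i in at) site[i] <- sample(setdiff(DNA_BASES, site[i]), 1)
  }
  paste(site, collapse = "")
}

#' Plant motif sites upstream of the regulon's first genes
#'
#' For every regulon operon, one site sampled from the planted consensus is
#' written into the oriented promoter window of the operon's first gene, at a
#' random admissible offset and on a uniformly chosen strand.  Offsets that
#' would collide with a gene body or a previously planted site are resampled
#' (up to 100 attempts).
#'
#' @param genome_genes list from [generate_genome()].
#' @param config a [simulation_config()].
#' @param regulon_operons operon ids carrying the motif.
#' @return list with the modified `genome` and a `manifest` data.frame
#'   (`locus_tag`, `contig_id`, `start`, `end`, `strand`, `site_seq`,
#'   `region_offset`).
#' @export
plant_motif <- function(genome_genes, config, regulon_operons) {
  genome <- genome_genes$genome
  genes <- genome_genes$genes
  manifest <- data.frame(locus_tag = character(), contig_id = character(),
                         start = numeric(), end = numeric(),
                         strand = character(), site_seq = character(),
                         region_offset = integer(),
                         stringsAsFactors = FALSE)
  if (length(regulon_operons) == 0)
    return(list(genome = genome, manifest = manifest))
  set.seed(config$seed + 13L)
  w <- nchar(config$planted_consensus)
  seqchars <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
  off_lo <- config$site_offset_range[1]
  off_hi <- min(config$site_offset_range[2], 500 - w)
  planted <- NULL  # intervals already used
  for (op in regulon_operons) {
    gene <- genes[genes$operon_id == op & genes$operon_index == 1L, ]
    reg <- extract_550bp_region(genome, gene)
    site <- sample_site(config$planted_consensus, config$planted_mutations)
    strand <- sample(c("+", "-"), 1)
    ok <- FALSE
    for (try in seq_len(100)) {
      o <- sample(off_lo:off_hi, 1)
      a <- if (gene$strand == "+") reg$start + o else reg$end - o - w
      b <- a + w
      gene_hit <- any(genes$start < b & genes$end > a)
      plant_hit <- !is.null(planted) && any(planted$a < b & planted$b > a)
      if (a >= 0 && b <= nchar(genome$sequence) && !gene_hit && !plant_hit) {
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place a planted site for operon ", op,
                  " after 100 attempts")
    written <- if (strand == "+") site else reverse_complement(site)
    seqchars[(a + 1):b] <- strsplit(written, "", fixed = TRUE)[[1]]
    planted <- rbind(planted, data.frame(a = a, b = b))
    manifest <- rbind(manifest, data.frame(
      locus_tag = gene$locus_tag, contig_id = gene$contig_id,
      start = a, end = b, strand = strand, site_seq = site,
      region_offset = o, stringsAsFactors = FALSE))
  }
  genome$sequence <- paste(seqchars, collapse = "")
  list(genome = genome, manifest = manifest)
}

#' Generate an expression table with an induced regulon
#'
#' Genes of regulon operons receive fold changes from `induced_fold` (all at
#' least 3) and q-values from `induced_q` (all at most 0.05); every other
#' gene gets a fold change near 1 from `background_fold` and a uniform
#' q-value, so the standard selection rule recovers exactly the regulon.
#'
#' @param genes gene-model data.frame.
#' @param config a [simulation_config()].
#' @param regulon_operons operon ids of the induced regulon.
#' @return expression data.frame.
#' @export
generate_expression <- function(genes, config, regulon_operons) {
  set.seed(config$seed + 29L)
  n <- nrow(genes)
  induced <- genes$operon_id %in% regulon_operons
  fold <- runif(n, config$background_fold[1], config$background_fold[2])
  q <- runif(n, config$background_q[1], config$background_q[2])
  fold[induced] <- runif(sum(induced), config$induced_fold[1],
                         config$induced_fold[2])
  q[induced] <- runif(sum(induced), config$induced_q[1], config$induced_q[2])
  data.frame(locus_tag = genes$locus_tag, condition = config$condition,
             fold_change = fold, q_value = q, stringsAsFactors = FALSE)
}

#' Generate ranked homolog copies of a promoter window
#'
#' Substitution-only mutation of the oriented region sequence: the
#' configured rate outside planted sites and `rate / site_conservation`
#' inside them, emulating binding-site conservation across related genomes.
#' The rank score of a copy is `1 -` its observed divergence.
#'
#' @param region one-row promoter-region data.frame.
#' @param site_offsets integer vector of site start offsets within the
#'   oriented region (width taken from `site_width`).
#' @param site_width width of the planted sites.
#' @param n number of homolog copies (>= 0).
#' @param substitution_rate per-base substitution rate outside sites.
#' @param site_conservation factor dividing the rate inside sites.
#' @param seed RNG seed.
#' @return data.frame `homolog_id`, `rank_score`, `sequence`.
#' @export
generate_homologs <- function(region, site_offsets = integer(0),
                              site_width = 0, n = 20,
                              substitution_rate = 0.10,
                              site_conservation = 4, seed = 1) {
  if (n < 0) stop("number of homologs must be non-negative")
  set.seed(seed)
  base <- strsplit(toupper(region$sequence), "", fixed = TRUE)[[1]]
  L <- length(base)
  rate <- rep(substitution_rate, L)
  for (o in site_offsets) {
    idx <- (o + 1):min(o + site_width, L)
    rate[idx] <- substitution_rate / site_conservation
  }
  out <- vector("list", n)
  for (i in seq_len(n)) {
    mut <- runif(L) < rate
    copy <- base
    if (any(mut)) {
      copy[mut] <- vapply(base[mut],
                          function(b) sample(setdiff(DNA_BASES, b), 1),
                          character(1))
    }
    out[[i]] <- data.frame(
      homolog_id = sprintf("%s_hom%02d", region$locus_tag, i),
      rank_score = 1 - mean(mut),
      sequence = paste(copy, collapse = ""),
      stringsAsFactors = FALSE)
  }
  if (n == 0) {
    return(data.frame(homolog_id = character(), rank_score = numeric(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Run the whole synthetic-study generator
#'
#' @param config a [simulation_config()].
#' @return list with `config`, `genome`, `genes`, `regulon_operons`,
#'   `manifest` (planted-site ground truth) and `expression`.
#' @export
simulate_regulon_study <- function(config = simulation_config()) {
  gg <- generate_genome(config)
  regulon <- choose_regulon(gg$genes, config)
  pl <- plant_motif(gg, config, regulon)
  expr <- generate_expression(gg$genes, config, regulon)
  list(config = config, genome = pl$genome, genes = gg$genes,
       regulon_operons = regulon, manifest = pl$manifest,
       expression = expr)
}

#' Homolog table for a set of seed loci of a simulated study
#'
#' Builds the footprinting input contract from a simulation: for each seed
#' locus, `n` ranked homolog copies of its promoter window with planted
#' sites conserved.
#'
#' @param sim result of [simulate_regulon_study()].
#' @param seed_loci locus tags to generate homologs for.
#' @param n homologs per seed (default from the simulation config).
#' @return data.frame `seed_locus`, `homolog_id`, `rank_score`,
#'   `region_sequence`.
#' @export
build_homolog_table <- function(sim, seed_loci, n = NULL) {
  cfg <- sim$config
  if (is.null(n)) n <- cfg$n_homologs
  w <- nchar(cfg$planted_consensus)
  rows <- lapply(seq_along(seed_loci), function(i) {
    lt <- seed_loci[i]
    reg <- extract_550bp_region(sim$genome, sim$genes[sim$genes$locus_tag == lt, ])
    offs <- sim$manifest$region_offset[sim$manifest$locus_tag == lt]
    h <- generate_homologs(reg, site_offsets = offs, site_width = w, n = n,
                           substitution_rate = cfg$homolog_substitution_rate,
                           site_conservation = cfg$site_conservation,
                           seed = cfg$seed + 100L + i)
    data.frame(seed_locus = lt, homolog_id = h$homolog_id,
               rank_score = h$rank_score, region_sequence = h$sequence,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a simulated study to disk
#'
#' Emits `genome.fasta`, `genes.gff3`, `operons.tsv`, `expression.tsv`,
#' `truth_manifest.tsv`, and (when the simulation has a regulon)
#' `homologs.tsv` for up to 8 regulon seed genes.
#'
#' @param sim result of [simulate_regulon_study()].
#' @param outdir output directory (created if needed).
#' @return named vector of file paths.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    genome = file.path(outdir, "genome.fasta"),
    gff = file.path(outdir, "genes.gff3"),
    operons = file.path(outdir, "operons.tsv"),
    expression = file.path(outdir, "expression.tsv"),
    manifest = file.path(outdir, "truth_manifest.tsv"))
  write_genome(sim$genome, paths["genome"])
  write_gene_models(sim$genes, paths["gff"])
  write_operons(sim$genes, paths["operons"])
  write_expression(sim$expression, paths["expression"])
  write.table(sim$manifest, paths["manifest"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (nrow(sim$manifest) > 0) {
    seeds <- head(sim$manifest$locus_tag, 8)
    ht <- build_homolog_table(sim, seeds)
    paths <- c(paths, homologs = file.path(outdir, "homologs.tsv"))
    write.table(ht, paths["homologs"], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(paths)
}
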