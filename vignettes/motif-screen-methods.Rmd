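---
title: "Methods: promoter motif discovery and regulon filtering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter motif discovery and regulon filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In many bacteria — the motivating case is an actinobacterium catabolising
bile acids — an RNA-seq experiment yields a table of genes induced under a
condition of interest, and the question becomes: *which transcription factor
drives that response?*  A classical route is to look for a shared DNA motif
upstream of the induced transcription units.  `regulonscan` packages that
route end to end:

1. **Select induced genes** from an expression table: fold change at least 3
   (inclusive) with a multiple-testing-adjusted q-value of at most 0.05
   (inclusive).
2. **Extract promoter windows**: 500 bp upstream plus 50 bp downstream of
   each start codon, 550 bp in total, oriented in the gene's reading
   direction.
3. **Discover over-represented motifs** in those windows (widths 8–50 bp,
   any number of occurrences per window, both strands, motif E-value at
   most 0.1; palindromicity is annotated, never required).
4. **Scan the promoter windows of all genes** with each discovered motif,
   with exact position-weight-matrix p-values and Benjamini–Hochberg
   q-values; sites are kept at q ≤ 0.05.
5. **Filter for regulator-likeness**: criterion A — at most 1000 sites in
   total (more indicates a promoter element or a low-complexity repeat, not
   a transcription-factor site); criterion B — *strictly more than* 10% of
   the sites must start inside promoter windows of first genes of operons
   that contain at least one significantly (q ≤ 0.05) induced gene.

A phylogenetic-footprinting variant boosts sensitivity for a gene cluster of
interest: the first genes of the cluster's qualifying operons become seeds,
each seed's window is pooled with the windows of its 20 best-ranked homologs
from related genomes (8 seeds × 21 windows = 168 regions), motifs are
discovered on the pooled set, scanned against the target genome's windows,
re-estimated from the in-genome sites only (one refinement round, which
strips the contribution of the other genomes), rescanned, and kept when the
sites of either scan round satisfy both criteria.

Homolog retrieval itself (protein alignment against reference genome
collections) is consumed as an input table (`seed_locus`, `homolog_id`,
`rank_score`, `region_sequence`); the package does not run alignments.
`rank_score` is "larger is better": the most significant alignments rank
first.

## Coordinate and orientation conventions

All internal coordinates are 0-based half-open; GFF3 (1-based inclusive) is
converted at the I/O boundary, and BED output is 0-based half-open.  For a
`+` strand gene whose start codon begins at offset *s* the window is
`[s-500, s+50)` read forward; for a `-` strand gene with interval `[b, e)`
it is `[e-50, e+500)` read as the reverse complement.  The 50 "downstream"
bases begin **at** the first base of the start codon: the window is then a
deterministic function of the annotated gene interval, which keeps every
consumer (planting, scanning, criterion B containment) consistent.  Windows
truncate at the edges of linear contigs; contigs flagged circular wrap
around the origin.  A site is *located in* a window iff its start
coordinate lies in the window interval — a deterministic boundary rule for
criterion B.  Overlapping windows of neighbouring genes are all kept
(extraction is per gene); duplicate genomic sites found through overlapping
windows are collapsed by coordinate before the criteria are applied.

## The discovery model

Discovery fits a two-component mixture by expectation–maximisation: every
width-*w* window on both strands of every region is either one occurrence
of the motif (probability matrix θ, mixing weight γ) or background
(order-0 stationary frequencies of the region set, estimated on both
strands with add-0.1 smoothing).  This is the "any number of repetitions"
occurrence model: a region may contain zero or many sites.  The M-step is a
maximum-a-posteriori update with Dirichlet pseudocounts (0.1 × the
stationary frequency per cell — the same pseudocount used everywhere a
motif is normalised), so the penalised log-likelihood-ratio objective is
provably non-decreasing over iterations; the test suite asserts this on
every run.  γ is initialised at 1/550 (about one site per window) and
clamped to [1e-8, 0.5].

**Width selection.** Widths are swept on a geometric ladder (ratio √2:
8, 11, 16, 23, 32, 45, 50 by default) rather than exhaustively; EM started
within ~40% of the true width converges to the same core motif, possibly
with uninformative flanking columns, so a dense sweep buys little.  Per
width the EM is started from the best of the top background-corrected
most-frequent w-mers (ties broken lexicographically; two seed words by
default) and run for a fixed short schedule (5 iterations).  The widths are
compared by a BIC-penalised objective (penalty `1.5 · w · log(n_windows)`,
i.e. half the parameter count times the log data size), which prevents the
longest width from winning by accumulating near-zero-information columns.
The winning start is then refined by EM to convergence (improvement
below 1e-6, at most 50 iterations).

**Significance.** The analytic E-values of classical motif discovery tools
are not re-derived.  Instead the package uses an empirical proxy: the
*identical* short discovery schedule (same seeds rule, same widths, same
iteration count) is run on 18 mononucleotide-preserving shuffles of the
regions, and `E = (1 + #{null ≥ observed}) / 19`.  Because observed and
shuffled data are treated identically, the statistic is exchangeable under
the null, and `P(E ≤ α) ≈ α`.  Eighteen shuffles were chosen so that the
default threshold `E ≤ 0.1` is met exactly when the observed statistic
beats *every* shuffle (`E = 1/19 ≈ 0.053`); with, say, 20 shuffles a motif
beaten by one shuffle would also pass, doubling the null reporting rate for
no gain in power on real signals.  Printed E-values are therefore
placeholders for ranking, not reproductions of any published E-value.
The shuffle null is computed once per discovery call, on the unmasked
regions; masking removes a tiny fraction of windows, so reusing the null
for later rounds is slightly conservative for second and further motifs.

**Iterative masking.** After a motif is accepted, every window with
occurrence posterior ≥ 0.5 is masked (set to N) and the search repeats, up
to five motifs; discovery stops at the first motif whose E exceeds 0.1.

## The scanner

Scores are log-odds in bits against the order-0 stationary background
(even when a higher-order background is estimated, p-values always use the
order-0 marginal — the standard behaviour of PWM scanners, and a documented
source of divergence from context-aware scoring).  P-values are exact for
the discretised score: each log-odds column is rounded onto a shared integer
grid of 1000 steps spanning the achievable score range, the per-column score
distributions are convolved under the background, and a window scored with
the same integer matrix receives the exact tail probability of its integer
score.  The test suite checks this against brute-force enumeration of all
4^w words for every width up to 8 (agreement within 1e-6) and checks
calibration (`fraction of windows with p ≤ α ≈ α`) on random genomes.
Benjamini–Hochberg q-values are computed per motif across *all* tested
positions — both strands of every N-free window — via `stats::p.adjust`;
the BH denominator is asserted against the window count in the tests.

## The synthetic-data generator

The generator is first-class, tested code: it emulates the statistical
structure the pipeline assumes so every stage is exercisable without any
external data.

* **Genome**: one linear contig of i.i.d. bases at configurable GC (default
  0.5); ~120 genes (500–900 bp) in ~60 operons of 1–3 same-strand genes,
  operon strands uniform, within-operon gaps 20–60 bp, inter-operon gaps
  1200–1500 bp.  The large inter-operon gap guarantees that two adjacent
  promoter windows (divergent operons) never collide, so planted ground
  truth stays intact.  `operon_index` counts in transcription order: the
  first gene of a `-` operon is its rightmost gene.
* **Regulon and plant**: 30 operons (the default study size) receive one
  sampled site each — drawn from the planted consensus, default the 15-bp
  perfect palindrome `TCCCGGTSACCGGGA` with 0–1 random substitutions —
  written at a random upstream offset of the first gene's window on a
  uniformly chosen strand.  A manifest records exact coordinates, strands
  and realised sequences; collisions with gene bodies or earlier plants are
  re-sampled (error after 100 attempts).
* **Expression**: regulon genes draw fold changes from (3, 30) and q-values
  from (1e-6, 0.05); background genes draw fold changes from (0.8, 1.2) and
  q-values from (0.06, 1), so the selection rule recovers exactly the
  regulon and the qualifying operons are exactly the regulon operons.  For
  null experiments the background ranges are widened (fold (0.5, 8), q
  (0, 1)) so that a handful of genes pass the selection rule by chance.
* **Homologs**: substitution-only mutated copies of a seed window (default
  10% per base, divided by 4 inside planted sites to emulate binding-site
  conservation; rank score = 1 − observed divergence).  No indels: planted
  offsets stay aligned, trading phylogenetic realism for exact ground
  truth.

What passing tests on this generator do *not* show: real promoters are not
i.i.d. background (they share -10/-35 elements and low-complexity
stretches — exactly what criterion A exists to reject), real operon calls
are imprecise, real homologs diverge with indels and rearranged promoters,
and real binding sites drift in information content.  The recovery rates
reported by the test suite are statements about the implementation's
correctness under its own model, not about sensitivity on any particular
organism.

## Replicated experiments (problem sizes)

The packaged experiments use: 20 seeded pipeline runs at the default study
size for planted-motif recovery (expected ≥ 90% of runs recover the plant
within consensus distance 2 and pass both criteria); 10 seeded runs of an
8-operon cluster with 20 homologs per seed for footprinting recovery
(≥ 80%); and 50 seeded null runs for the false-discovery bound (< 10% of
runs report any motif passing both criteria).  These sizes keep the full
suite comfortably re-runnable on a single CPU while leaving the binomial
noise of the rate estimates well inside the acceptance margins.

Because recovered motif widths rarely equal the planted width exactly
(flanking columns ride along), "recovered" is operationalised with
`consensus_distance()`: the planted consensus must match a substring of the
recovered consensus (or its reverse complement) with at most 2 mismatching
IUPAC characters; if the recovered motif is narrower, uncovered planted
positions count as mismatches.  With equal widths this is plain Hamming
distance.

## Numerical choices and degenerate inputs

* Pseudocounts: 0.1 × stationary background per matrix cell, everywhere.
* Score grid: 1000 bins; widening it changes p-values by less than the
  tested 1e-6 tolerance for widths ≤ 8.
* Ties: seed words tie-broken lexicographically; equal-probability consensus
  columns fall back to two-letter IUPAC codes or N; all randomness flows
  from a single integer seed per entry point, and the RNG state is restored
  on exit.
* Degenerate inputs: single-letter regions yield no motif (the objective
  ties with its own shuffles); fewer than two regions is an error for
  discovery but a status (`no_induced_genes` / `insufficient_regions`), not
  an exception, for the pipeline; re-estimation from fewer than two sites is
  an error; zero-site motifs fail criterion B by definition.

## Known limitations

* The empirical E-value proxy saturates at 1/19 and cannot rank two strong
  motifs; ordering among reported motifs falls back to the EM objective.
* P-values condition on an order-0 background; strongly biased genomic
  contexts (e.g. GC skew along the replichore) are not modelled.
* The ANR mixture treats overlapping windows as independent observations,
  as classical motif discovery does; occurrence-count estimates (`nsites`)
  are therefore approximately, not exactly, the number of distinct sites —
  a palindromic site supports both orientations of the same window.
* Footprinting on low-divergence homolog sets discovers shared promoter
  fragments besides the regulatory signal; that is inherent to pooling
  near-identical sequences, and the step-5 re-estimation plus the two
  criteria — not discovery itself — carry the burden of rejecting them.
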