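---
title: "Methods: bin-based hyper-DMR detection and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bin-based hyper-DMR detection and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The statistical model

`methdmr` detects hypermethylated differentially methylated regions
(hyper-DMRs) between two unreplicated bisulfite methylomes — the design
used when comparing a DNA-demethylation mutant against wild type, where
each genotype contributes one pooled whole-genome methylome.

Per cytosine site $i$ the data are counts $(m_i, u_i)$ of methylated and
unmethylated read observations; the site's context (CG, CHG, CHH with
H ∈ {A, C, T}) is read from the two bases 3′ of the cytosine on its own
strand. A site enters the analysis only if $m_i + u_i \ge$ `min_cov`
(default 3). The genome is tiled with `bin_size` = 50 bp windows from
coordinate 0, and counts of all passing sites (both strands, all
contexts) are pooled per bin and genotype. Each testable bin is assessed
with the two-sided Fisher exact test on

$$\begin{pmatrix} m_{wt} & u_{wt} \\ m_{mut} & u_{mut} \end{pmatrix},$$

taking as the p-value the total probability of all tables with the
observed margins whose hypergeometric probability does not exceed the
observed table's (the standard two-sided tail, with the usual
$1 + 10^{-7}$ relative tolerance for ties). A bin is *significant* when
$p \le \alpha$ (default 0.01), the pooled level difference
$\Delta = m_{mut}/n_{mut} - m_{wt}/n_{wt} \ge$ `min_delta` (default
0.1), and the direction is hypermethylation. Significant bins are merged
left-to-right into DMRs whenever the gap to the next significant bin is
at most `merge_gap` = 50 bp; with 50-bp bins that admits at most one
intervening non-significant bin. A DMR's span is the union of its member
bins, so a lone significant bin is a valid 50-bp DMR.

Overlap between two DMR sets uses the $\ge$ 50-bp rule: a region of set
A counts (once) when its intersection with a *single* region of B
reaches `min_overlap` bp. The chance expectation is $A \cdot B / N$ with
$N$ the number of genomic bins, and enrichment is the hypergeometric
upper tail $P[X \ge k]$, $X \sim \mathrm{Hypergeom}(N, B, A)$, including
the observed count.

### Assumptions

* Counts are binomial given depth; no biological replication is
  modelled, so the Fisher p-value quantifies read-sampling noise only.
  Between-replicate variation would require a beta-binomial or
  replicate-aware model, which is out of scope by design.
* No multiple-testing correction is applied by default; the per-bin
  $\alpha$ is the operative knob, as is conventional for this family of
  bin-based plant DMR callers. A Benjamini–Hochberg mode is available
  (`dmr_params(fdr = TRUE)`) but off by default.
* Bins with zero passing reads in either genotype are untestable and
  never significant (rather than being treated as level 0); a region of
  missing coverage therefore interrupts a DMR only if it widens a gap
  beyond `merge_gap`.

## Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `bin_size` | 50 | bp | resolution of the caller |
| `merge_gap` | 50 | bp | ≤ 1 non-significant bin may be bridged |
| `min_cov` | 3 | reads | threefold-coverage site filter |
| `alpha` | 0.01 | – | conventional per-bin cutoff; uncorrected |
| `min_delta` | 0.1 | level | guards against significant-but-tiny differences at high depth |
| `min_total` | 1 | reads/bin/sample | testability floor |
| `direction` | hyper | – | the analysis targets hypermethylation |
| `context` | all | – | one pooled test per bin; per-context modes available |

Because `alpha` and `min_delta` are not forced by the method definition,
both are exposed everywhere (API and CLI) rather than hard-coded.

## Design choices where the design was open

* **Strands are kept separate throughout.** Symmetric CG positions are
  two sites; region- and bin-level pooling naturally sums both strands.
  Collapsing CG pairs pre-test would roughly halve CG site counts
  without changing pooled totals, so the pooled bin test is unaffected.
* **Region levels are read-weighted** ($\sum m / \sum n$ over passing
  sites), matching the count basis of the bin test; a `site_mean` mode
  (mean of per-site levels) is provided since region summaries in the
  literature are sometimes site-averaged.
* **Contexts are pooled within a bin for testing** (one test per bin);
  per-context calling is available via `dmr_params(context = )`.
* **Gap semantics:** the gap is `next start − current end` on 0-based
  half-open bins; gap = 50 merges, 51 does not.
* **Edge contexts:** CG needs one downstream base, CHG/CHH need two; an
  N or the sequence end inside the needed window makes the call
  `ambiguous`, and ambiguous sites are excluded from all statistics so
  undefined contexts cannot contaminate bins.
* **$N$ for the overlap null is always explicit.** Published expected
  counts of this type are not reconstructible from any single obvious
  $N$ (total bins, testable bins, covered bins all differ), so the
  package refuses to guess: `expected_overlap()` and
  `hypergeometric_enrichment()` require `N_bins`.
* **Overlap length is per single counterpart interval**; a summed-
  intersection mode exists behind `mode = "summed"` because fragmented
  overlaps are ambiguous in the rule's usual phrasing.
* **Composition priority is genic > TE > intergenic** with a ≥ 1 bp
  criterion, configurable, since a DMR can touch both a gene and a TE.
* **Metaprofile geometry:** 10 fixed-width bins per 1-kb flank and 20
  scaled gene-body bins (both configurable). Sites map to body bins by
  their strand-aware offset from the TSS, which makes the profile
  exactly invariant under reverse-complementing genome, counts and
  annotation — a property the test suite checks literally.
* **Clone analysis models top-strand amplicons only** (bisulfite PCR is
  strand-specific); bottom-strand loci are handled by
  reverse-complementing the reference first. Duplicate clones are
  reported, not dropped, and the advisory conversion proxy (per-clone
  CHH methylation fraction) never filters anything by default.

## The synthetic methylome generator

The generator exists so that every downstream stage can be validated
against known truth. It emulates:

* a random genome at configurable GC (default 0.36, plant-like), tiled
  into TE / gene / intergenic blocks (defaults: 15% TE with ~2-kb
  blocks, 50% gene with ~2.5-kb blocks, remainder intergenic) — block
  classes are drawn with probabilities proportional to
  fraction/mean-length so expected coverage matches the targets;
* context- and class-dependent baselines (defaults: TE CG/CHG/CHH =
  0.80/0.60/0.15, gene 0.05/0.02/0.02, intergenic 0.10/0.05/0.03),
  i.e. heavily methylated repeats over a lightly methylated genic
  background;
* per-site depth Poisson(`mean_depth`) or fixed (fixed depth makes
  count-level oracles exact), binomial methylated counts, and a mutant
  that adds per-context increments (defaults ΔCG = ΔCHG = 0.5,
  ΔCHH = 0.3, clipped to 1) inside planted regions of width 200–1000 bp.
  Planted regions are placed at arbitrary (not bin-aligned) coordinates
  in gene/intergenic blocks — 70%/30%, matching the predominantly genic
  location of demethylation-target hyper-DMRs — and avoid TEs, where the
  high baseline would clip the increment. The default of 80 planted
  regions on a 2-Mb genome reflects a genome-wide density of roughly 40
  regions per megabase.

Draw order is fixed (genome stream, then counts stream: wild-type
depths, wild-type counts, mutant depths, mutant counts, sites in
coordinate order), so one config + seed reproduces cytosine reports
byte-identically.

What it does **not** emulate: read-level artefacts (no FASTQ, no
mapping bias), bisulfite conversion failure, copy-number variation,
correlated depth between neighbouring sites, strand-correlated CG
methylation, and biological replicate variance. Passing the planted
validation therefore demonstrates the pipeline's correctness under the
stated sampling model, not robustness to alignment or chemistry
artefacts in real libraries.

## Numerical choices and degenerate inputs

* Fisher p-values are computed by direct hypergeometric tail summation
  over the support (vectorised `dhyper`), not by simulation; the test
  suite checks them exhaustively against an independent
  binomial-coefficient enumeration for every table with $N \le 60$ and
  against `stats::fisher.test` on random tables.
* Hypergeometric upper tails use `phyper(k − 1, …, lower.tail = FALSE)`
  and are checked exhaustively against direct pmf summation for
  $N \le 40$.
* Degenerate cases: empty chromosomes yield empty call streams; empty
  regions/bins have undefined (NA) levels rather than 0; `alpha` so
  small that nothing passes yields an empty but valid DMR table; a
  clone matrix with only missing calls has undefined levels with
  explicit zero denominators.
* Coordinates: cytosine positions are 1-based (cytosine-report
  convention); every interval table and BED file is 0-based half-open;
  in-memory interval objects are `GRanges` (1-based closed). The I/O
  helpers own all conversions.

## Validation problem sizes

The shipped validation uses: three simulated 2-Mb studies at mean depth
20 for planted-region recovery; a 500-kb fixed-depth null for
calibration; 100–400-kb genomes for unit-level properties; exhaustive
exact-test oracles at $N \le 60$ (Fisher) and $N \le 40$
(hypergeometric); and 50-clone amplicon round trips. These sizes give
stable statistics while keeping the whole suite fast enough to run
routinely.

## Known limitations

* **Boundary quantization.** Called DMRs are unions of 50-bp bins, so
  their edges snap outward by up to 49 bp beyond the true differential
  region whenever a boundary bin is only partly elevated yet still
  significant. Against arbitrarily placed planted truth of width
  200–1000 bp this costs roughly 25 bp per DMR side, i.e. ~4–5% of
  called bases fall just outside the true regions even when every true
  region is recovered.
* **Single-bin false positives.** With an uncorrected per-bin
  $\alpha = 0.01$ over tens of thousands of bins, occasional single-bin
  calls appear, concentrated in high-baseline TE bins where a 0.1 level
  difference is within a few standard errors at depth 20 (the
  co-occurrence of $p \le 0.01$ and $\Delta \ge 0.1$ runs at roughly
  0.2% per TE bin). Under the default study conditions the validation
  suite measures ~94% of called DMR bases inside planted regions with
  100% of planted regions recovered; the residual ~6% splits roughly
  4.5 points of edge quantization and 1.5 points of such single-bin
  calls. Users wanting stricter region-level precision should raise
  `min_delta`, lower `alpha`, enable `fdr = TRUE`, or filter single-bin
  DMRs — all of which trade recall for precision.
* The caller assumes comparable coverage between genotypes; extreme
  coverage imbalance makes `min_delta` asymmetrically noisy.
* The hypergeometric overlap null treats regions as exchangeable bins
  and ignores region length and genomic clustering; it is the
  conventional quick null, not a positional permutation test.
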