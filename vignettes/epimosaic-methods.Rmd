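---
title: "Methods: allele-specific methylation blocks and epimutation calling"
author: "epimosaic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific methylation blocks and epimutation calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

Intermediately methylated regions (IMRs) — loci whose aggregate
methylation sits between 0.3 and 0.7 in a normal cell population — can
arise from three very different fragment-level configurations: cellular
heterogeneity, discordant methylation along single molecules, or
allele-specific methylation (ASM). epimosaic implements the analysis
chain that distinguishes these and tracks what happens to such regions
in clonal cell populations:

1. **Methylation haplotype blocks (MHBs).** From per-read binary CpG
   calls, the methylation linkage disequilibrium (mLD) of each adjacent
   CpG pair is the squared Pearson correlation $r^2$ of the two call
   vectors over reads covering both sites, computed only when at least
   10 reads cover the pair. An MHB is a maximal run of at least four
   consecutive CpGs in which every adjacent pair has $r^2 \ge 0.5$. A
   pair that is uncomputable — too few reads, or a CpG with zero call
   variance — breaks a run rather than being assigned $r^2 = 0$:
   constitutively uniform CpGs carry no linkage information.
2. **IMR blocks.** An MHB is an IMR block when its coverage-weighted
   mean methylation lies in $[0.3, 0.7]$ in *every* normal sample.
   Bounds are inclusive wherever the 0.3–0.7 range appears in the
   package; inclusivity is the weaker reading and is applied
   consistently.
3. **Block-level calls.** Per block and sample, two conditional exact
   tests on CpG call counts: ASM compares haplotype 1 vs haplotype 2;
   epimutation compares the haplotype-combined counts against a pooled
   normal reference. A block is evaluable with at least four covered
   CpGs and an *adjusted CpG coverage* (total calls / covered CpGs) of
   at least 5 per haplotype (ASM) or at least 5 in both the sample and
   the pooled reference (epimutation; the rule is stated per sample and
   we apply it to both sides, which only guards degenerate references).
   Significance is Benjamini–Hochberg FDR < 0.05 within one invocation
   (one family per sample per analysis), plus an effect-size rule:
   |haplotype difference| > 0.4 for ASM, |sample − normal| > 0.3 for
   epimutations. A block that is both is labelled ASM — the more
   specific claim — and otherwise falls through to
   `intermediate`/`indeterminate` by its combined mean.
4. **Recurrence hotspots (WGBS arm).** Per-sample DMR sets are
   multi-intersected; segments overlapped by DMRs from at least 25
   samples (each sample counted once) that contain at least 5 CpGs of
   the pooled normal track are hotspots. The CpG filter counts CpGs in
   the pooled reference, the track that is always deep; the alternative
   (sample-track CpGs) would make the hotspot set depend on per-sample
   dropout.
5. **Clonal dynamics.** With per-block states from several single-cell
   derived clones in one haplotype frame, blocks with ASM in at least
   four clones are informative; a block is *switched* when the
   methylated haplotype differs between clones — the signature of
   random (rather than parent-of-origin) ASM. Under independent
   haplotype choice with probability $\pi = 0.5$, a block with $m$
   informative clones is concordant with probability $2^{1-m}$, the
   closed form the tests check.
6. **Tissue-specific IMRs.** Per-tissue bimodal blocks present in all
   samples of a tissue (1-bp overlap suffices; exact coordinate
   matching would retain almost nothing) are merged (minimum size
   50 bp, minimum gap 50 bp) and kept when the matched-tissue mean is
   in $[0.3, 0.7]$ with a coefficient of variation $\le 0.5$ (sample
   sd over mean, $n-1$ denominator — the conservative choice at small
   per-tissue sample counts) and the matched vs non-matched difference
   is $\ge 0.2$. The delta rule is what removes germline-imprint-like
   blocks that are intermediate in every tissue. The non-matched mean
   averages per-sample means rather than pooling counts, so deeply
   sequenced tissues do not dominate.

# The DMR caller is a stand-in

The package's contribution is the block/recurrence/ASM logic, not a
smoothed differential-methylation test. `callDMRs()` is a deliberately
simple, fully parameterised stand-in: a per-CpG two-sided Fisher exact
test on call counts, BH across tested CpGs, merging of significant CpGs
(per-CpG q < 0.05 and |difference| ≥ 0.1) within 300 bp, and a
region-level coverage-weighted |difference| > 0.3 rule (0.4 when run
between haplotypes) with at least 3 significant CpGs. It is validated
only on synthetic data and is not a reimplementation of beta-binomial
shrinkage callers; anyone with such calls can feed them to
`findHotspots()` directly. Testing is restricted to autosomes, applied
as a chromosome-name filter before testing.

# Confounder filters

ASM-looking regions are excluded when they (a) lie on a sex chromosome,
(b) overlap a known imprinted region, (c) have a structural-variant
breakpoint within 1,000 bp, or (d) overlap a 10-kb window whose SNP
density is in the top 1% genome-wide. Reasons are reported in that
precedence order. The density mask takes windows *strictly above* the
99th percentile of all tiled windows (SNP-free windows included): with
a flat density the quantile equals every count and nothing is masked,
which avoids masking the genome on degenerate input. Whether the
quantile should be computed over SNP-containing windows only is not
specified by the procedure the filter follows; all tiled windows is the
implemented choice.

# Coordinates

All on-disk formats are BED-family: tab-separated, 0-based, half-open.
Internally every position is 1-based in `GRanges`, the convention of
the interval machinery the package is built on; conversion happens only
in the parsers and writers. CpGs are keyed by the forward-strand C;
reverse-strand records are collapsed onto it by summing counts (via the
strand column when present, otherwise by position adjacency — forward
CpG starts are always at least 2 bp apart, so a record at the previous
position + 1 can only be the reverse-strand mate). Chromosome names are
compared as exact strings; no "chr" stripping.

# The synthetic generator

`simConfig()` defaults define the emulated study conditions: blocks
with a mean of 12 CpGs spanning about 186 bp on a synthetic 10-Mb
contig `chrS` plus a 1-Mb `chrX` decoy; per-cell random-ASM haplotype
choice with $\pi = 0.5$, independent across cells and blocks (the
simplest model consistent with observed haplotype switching — no
spatial correlation between blocks); per-call error $\varepsilon =
0.02$ (no quantitative per-cell error rate is published for these
blocks, so this is a free parameter chosen as a realistic ONT/WGBS
call-error scale); Poisson read coverage with mean 30 per sample; clone
epimutations at rate 0.05 per block per clone, 70% of them
hypermethylated (clone epimutations skew hyper). Confounders are
planted with defined truth: imprinted blocks have a fixed
parental-style haplotype in all cells; SV-adjacent blocks get a
breakpoint within 1,000 bp; SNP-dense blocks sit in isolated 10-kb
windows that are exactly the top 1% of window SNP counts (the default
dense-window count equals 1% of windows so the mask truth is
well-defined; raising `nSnpDense` far above that would make the
planted truth exceed the top percentile); `chrX` blocks are random-ASM
lookalikes that only the chromosome filter distinguishes.

Population bulk tracks are the exact count-sum over cells (per-cell
per-haplotype coverage `cellCoverage`, default 2): the aggregated
sampling used at large `nCells` is the Poisson-thinning identity of
that sum, and a `perCell` mode materialises per-cell tracks at small
`nCells` so the conservation invariant is testable literally.

Block discovery operates on long reads pooled across samples
(`poolReads()`), as multi-donor mLD analysis does; at a 30x mean
per-sample coverage a single sample leaves a per-pair probability of
order $10^{-2}$–$10^{-3}$ that an error-flip cluster pushes one
adjacent pair below $r^2 = 0.5$, while pooling four samples makes
boundary-exact recovery of planted blocks the overwhelming outcome.

What the generator does **not** emulate: sequence context and mapping
artefacts, bisulfite conversion failure, CpG-density heterogeneity and
genome-scale methylation domains, copy-number change, cell-type mixtures
with differential methylation, or correlated error along reads. Passing
tests therefore demonstrate correctness of the statistical machinery
under the stated generative model, not robustness to the full error
structure of real libraries.

# Numerical choices

* Exact tests use the conditional hypergeometric two-sided
  probability-mass rule; q-values by step-up BH with monotonicity, ties
  sharing the smaller value, capped at 1.
* $r^2$ is undefined (NA), never 0, for under-covered or zero-variance
  pairs.
* Zero-coverage intervals aggregate to missing, never 0, so filters can
  distinguish "unmethylated" from "unobserved".
* Fragment metrics: entropy is pattern-based Shannon entropy in bits
  over 4-CpG windows (averaged over windows with fully covering
  reads); MHL uses linear length weights $w_l = l$; MCR is the
  fraction of concordant within-read adjacent call pairs; MBS is the
  per-read sum of squared methylated-run lengths over the squared call
  count. CHALM/MCR/MBS variants differ across publications; these are
  reimplementations per the definitions above, and reads with fewer
  than two in-region calls are excluded from all of them.
* Read classification (≥ 70% methylated / ≤ 30% / undetermined) is
  applied to in-region calls; the ≥ 4-CpG span rule likewise counts
  in-region CpGs, and the ≥ 8-reads-per-allele minimum counts
  *classified* reads (the test's power depends on classified reads
  only).
* Haplotype labels are arbitrary per sample; cross-sample analyses take
  an explicit flip vector (`cloneBlockMatrix(hapFlip = ...)`) rather
  than assuming a shared frame.
* DMR-merging distance at the recurrence step is 0 (plain
  overlap/abutment union); the 50-bp size/gap rule applies only to the
  tissue block lists.

# Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
data at these sizes, chosen to exercise every rule at stable signal:
200 planted blocks (4–20 CpGs) plus 100 independence-null regions at
30x and $\varepsilon = 0.02$ for block recovery; 2,000 null and 500
planted-ASM blocks at adjusted coverage 10 for caller calibration; 11
clones over 150–200 blocks for switching; a 3-tissue × 3-sample panel
for tissue IMRs; and exhaustive 2×2 tables with margins up to 30 for
the exact-test oracle.

# Limitations

The caller battery assumes haplotype-resolved counts are correct
(phasing and haplotagging are upstream concerns), treats blocks as
given intervals once discovered, and does not model within-block
recombination of methylation state. The stand-in DMR caller has no
smoothing, so single noisy CpGs cost it power relative to shrinkage
callers at low coverage. Rates reported per region class depend on the
evaluability rules; both the evaluable-denominator and
all-regions-denominator percentages are reported because the choice
materially changes the numbers.
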