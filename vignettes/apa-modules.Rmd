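---
title: "Discovering stable APA gene modules from single-cell poly(A)-site counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering stable APA gene modules from single-cell poly(A)-site counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apamod)
```

## The problem

Most human genes carry several polyadenylation sites in their 3' UTR;
which site a transcript uses decides how much regulatory sequence
(miRNA seeds, RBP sites) the mRNA retains.  Single-nucleus RNA-seq
leaves a usable footprint of these choices: reads pile up at cleavage
sites, so per gene and per cell one can ask what fraction of a gene's
3' UTR reads come from its most distal site.  `apamod` turns a table of
candidate poly(A) sites with per-cell counts into (i) *gene modules*
whose distal-usage co-varies across cells, (ii) statistical evidence
that a module tracks a phenotype (diagnosis, sex, brain region), and
(iii) donor-aware classifiers built on module genes.  It is aimed at
cohort-scale case/control single-cell studies, with autism-spectrum
brain snRNA-seq as the motivating application.

## Stage by stage

### Site quality control

Candidate sites are first filtered for support (detected in at least 10
cells and 10 reads, both inclusive).  Surviving sites are scanned for
internal-priming artifacts: oligo-dT can prime on genomic A-stretches
and fake a poly(A) site.  Within ±50 bp of the cleavage position (read
in transcript orientation; minus-strand sites are scanned on the
reverse complement) a site is flagged when (a) it has a run of ≥ 6
adenines, (b) it has two or more A/T-rich hexamers (defaults `AAAAAT`,
`TTTTTA`) inside a 20-bp subwindow, or (c) no polyadenylation-signal
hexamer occurs in the window at all.  The PAS list defaults to AATAAA
plus the commonly used variant hexamers and is configurable, as is the
density rule — there is no community-standard threshold for "dense
A/T-rich", so we chose a transparent one and exposed it.  Flagged sites
are not discarded outright: any flagged site within ±10 bp of a site in
a user-supplied reference database (e.g. curated poly(A) atlases as BED)
is rescued.  Finally sites are restricted to 3' UTRs of protein-coding
genes; a site matching two genes' UTRs on the same strand is dropped
rather than guessed.

Coordinates are 1-based inclusive in memory; BED I/O converts to and
from the 0-based half-open disk convention.

### RUD quantification

For gene $g$ in cell $i$ with ordered 3' UTR sites $t = 1,\dots,T_g$
($T_g$ the transcriptionally most distal) and site read counts
$P_{g,i,t}$,

$$\mathrm{RUD}_{g,i} = \frac{P_{g,i,T_g}}{\sum_{t=1}^{T_g} P_{g,i,t}},$$

the fraction of the gene's 3' UTR reads at the distal site; higher
values mean longer 3' UTRs.  The denominator sums over *all* retained
sites of the gene.  Zero coverage yields a missing value, not zero —
absence of reads is not evidence of proximal usage — and genes with a
single retained site are excluded (their RUD is identically 1).
Internally the matrix is genes × cells; writers emit cells × genes.

### Sparse module-activity factorization

Each cell type's RUD matrix is repeatedly (default 10×) split into 70%
training / 30% held-out cells.  Each training matrix $X$ is factorized
as $X \approx UW$ with

* $U \ge 0$ (genes × $d$): the module dictionary, L1-penalized
  (`lambda_u`, default 0.1) so each module loads few genes;
* $W$ ($d$ × cells): per-cell module activities, hard-limited to at
  most `k` (default 15) active modules per cell.

The solver alternates a batched greedy non-negative pursuit for $W$
(an explicit L0 constraint, matching the "few active modules per cell"
reading, rather than an L1 proxy) with non-negative coordinate descent
for $U$.  The W-step keeps a cell's previous coefficients whenever the
fresh pursuit does not improve its residual, which makes the objective
$\tfrac12\|X-UW\|_F^2 + \lambda_u \sum U$ provably non-increasing — a
property the test suite checks rather than assumes.  Initialization
takes non-negative parts of the leading singular vectors (deterministic
up to the seeded random fill), so a fixed seed reproduces the
factorization exactly.

The default rank $d = 500$ is deliberately over-complete: far more
columns than expected modules.  Redundant columns end up unused and are
pruned, and the real model selection happens downstream through
stability.  Missing RUD entries are imputed with the gene's training
mean *for the factorization only*; screening statistics are computed on
activities, and differential APA returns to the masked matrix.

Desk scale: on simulated data of 1,000–2,000 genes and ≤ 1,000 cells we
run $d$ = 25–50 and $k$ = 5 with `max_iter` 25–50; these are the
problem sizes used throughout the tests and the acceptance script, and
were chosen so a full run stays in the minutes range on one core.

### Screening module activities against phenotype

A module is called phenotype-associated only if it passes **both**:

1. a two-sided Wilcoxon rank-sum test on its activity between groups,
   Benjamini–Hochberg adjusted across the modules of one cell type and
   partition, at adjusted $p < 0.01$; and
2. a Spearman correlation $\rho$ between activity and the ±1-encoded
   labels with $\rho > 0.1$ (a minimal effect size) and an empirical
   permutation $p$ (1000 label permutations by default, two-sided on
   $|\rho|$, add-one rule $(b+1)/(B+1)$), BH-adjusted, also $< 0.01$.

The conjunction intentionally couples significance with a floor on
effect size, so very large cell numbers cannot promote negligible
effects.  One practical caveat the package documents and its tests
respect: with $B$ permutations the smallest achievable raw $p$ is
$1/(B+1)$, so after BH adjustment over $m$ modules no module can clear
a threshold $\alpha$ unless $\frac{1}{B+1}\cdot\frac{m}{r} < \alpha$,
where $r$ is the number of modules tied at the minimum.  When screening
many modules at $\alpha = 0.01$, choose $B$ accordingly — our
desk-scale runs use $B = 5000$.

Covariate screening (sex, brain region; exactly two levels) reuses the
same machinery and adds a factor–covariate association score per
level: the AUC of the module activity against the covariate, rescaled
to [0, 1] and split by direction.  This score is a documented surrogate
for ensemble-classifier-based factor-covariate scoring, not a
reimplementation of any specific tool.

### Core genes and stability

Within a module, gene weights are Z-scored against the column's own
distribution; the threshold starts at 1.0 and ratchets up in steps of
0.05 until fewer than 1,000 genes remain (the cap is configurable — for
expression-based modules a tighter cap such as 800 may be preferred).
The stability of a module from partition $n$ is its *recurrence rate*:
the maximum containment $\max_j |M_{n,i} \cap M_{o,j}|/|M_{n,i}|$ of
its core set in any module of another partition $o$, aggregated (mean
by default; min/median available) over the other partitions.  Note the
denominator is the query module's size — this is containment, not a
Jaccard index, and it is asymmetric by design.  Modules at ≥ 0.80
aggregate recurrence are stable; if a cell type yields fewer than five
stable modules the threshold relaxes to 0.75.  Because stable modules
recur almost by definition, a greedy containment clustering
(`collapse_modules`) provides a de-duplicated reporting view alongside
the per-partition ids (`celltype_partition_module`, e.g. `L2-3_1_4`).

### Enrichment, differential APA, classification

Stable modules are tested for overlap with user-supplied gene sets
(cell-type markers, disease risk lists) by an upper-tail
hypergeometric test, BH-adjusted within each set family.  The
background universe is the set of genes that entered factorization for
that cell type — conditioning on testable genes avoids inflating
enrichment.

Differential APA compares RUD between conditions per gene with an
empirical-Bayes moderated t: per-gene pooled variances are shrunk
toward a prior fitted across genes (via `limma::squeezeVar`), and
significant genes are called 3' UTR *lengthening* (positive RUD shift
in the disease group) or *shortening*.  The test runs on per-cell RUD
values; users preferring pseudobulk should aggregate before calling.

Classifiers are evaluated under donor-level splits: every donor's cells
go wholly to train or test (target 7:3 by cells), so donor identity
cannot leak.  The single-modality model is gradient-boosted trees
(depth 6, learning rate 0.01, subsample 0.5, 10 rounds).  The two-view
model couples an APA-usage view and a gene-expression view with
per-view linear large-margin classifiers (squared-error loss to ±1
labels, ridge penalty) plus an agreement penalty on their decision
values, solved by alternating closed-form ridge updates; the fused
score is $\sum_v \beta_v f_v(x)$ with contribution weights $\beta_v$
softmax-normalized from each view's accuracy on an inner validation
split of the training cells.  This two-view coupling is our own
surrogate for published two-view SVM formulations whose exact objective
we do not reproduce; $\beta_v \in [0,1]$, $\sum_v \beta_v = 1$ retains
the interpretation of per-modality contribution.

## The synthetic-data generator

`generate_site_counts()` emulates the statistical structure every stage
assumes: genes with ordered 3' UTR sites on a toy genome (alternating
strands, so strand handling is genuinely exercised); per-cell library
sizes drawn negative-binomially and allocated to genes and then
multinomially to sites; planted gene modules whose distal usage
co-varies through a non-negative latent activity (coherence 0.12 RUD
per activity unit); diagnosis effects entering through a mean shift of
module activity calibrated so planted genes' between-group RUD
difference equals `group_effect`; optional sex/region effects attached
to designated modules; donor random intercepts on the usage logit
(sd 0.1) so donor-aware splitting is meaningfully testable; and
uniform dropout masking.  Usage probabilities are clipped to
[0.02, 0.98] to avoid degenerate all-or-nothing genes.

What it does **not** emulate: read-level noise and alignment artifacts,
realistic transcript structure, gene–gene correlation beyond modules,
cell-type-specific expression programs, or batch effects other than
donor intercepts.  Passing tests therefore demonstrate the machinery is
correct and calibrated under the assumed generative structure, not that
real snRNA-seq will be as clean.  Two generator behaviors worth knowing
when designing simulations: donor intercepts are shared across genes,
so with few donors a null dataset still shows a small group offset
(finite-donor noise, zero in expectation); and when several planted
modules shift in the *same* cells, their activities share a common
component and the factorization may legitimately merge them into one
disease module — per-planted-set containment in the merged core set is
the right recovery metric, and distinct-module recovery should be
tested with `group_effect = 0`.

`generate_flank_sequences()` plants internal-priming artifacts of all
three kinds (A-tract, dense A/T hexamers, PAS-free windows) against
clean windows carrying AATAAA upstream, with exact truth flags, by
construction and rejection sampling against independent base-R motif
checks (the QC module scans with Biostrings, keeping the two code paths
independent).

## Numerical choices and edge cases

* Factorization: stopping at relative objective change < 1e-5 or 100
  iterations; hitting the cap returns the best iterate with a warning,
  not an error.  Ties in atom selection break toward the lowest index,
  keeping runs deterministic.
* Screening: ranks use midranks (average ties); a constant activity
  vector has undefined $\rho$ and fails with an explicit reason; groups
  under 3 cells give $p = 1$ with a warning.
* Differential APA: genes observed in fewer than 3 cells in either
  group are skipped, as are genes constant with equal means; zero
  sample variances otherwise are handled by the shrinkage prior.
* Hypergeometric p at zero overlap is exactly 1 (the upper tail
  includes ≥ 0).
* Donor splits that cannot cover both classes on both sides resample up
  to a cap and then error; with two donors the split is one donor per
  side regardless of the ratio.

## Worked example

```{r example, eval = FALSE}
sim <- generate_site_counts(synth_config(
  n_genes = 1000, n_cells = 800, n_modules_planted = 5,
  module_size = 40, group_effect = 0.3, n_donors = 10, seed = 1))
st  <- filter_candidates(sim$sites)
res <- run_pipeline(st, pipeline_config(
  seed = 1,
  smaf = list(n_repeats = 5, d = 40, k = 5, max_iter = 50),
  screen = list(n_perm = 5000),
  refine = list(fallback_min_modules = 2)))
length(res$CT1$stable_sets)          # stable modules found
sapply(sim$truth$planted_module_genes,
       recurrence_rate, other_block_modules = res$CT1$stable_sets)
```

The same computation, plus enrichment, differential APA and the two
classifiers, is what `scripts/acceptance.R` runs; its JSON output is
the package's self-reported set of headline numbers.

## Known limitations

* The factorization solver is a greedy pursuit — good reconstructions
  and recovery in practice, but no global-optimality guarantee.
* Wilcoxon and Spearman screens are statistically related under binary
  labels; the combination primarily enforces the effect-size gate.
* The FCA-style covariate score and the two-view fusion objective are
  documented surrogates, not reimplementations of specific published
  tools.
* Per-cell differential APA treats cells as independent; donor
  pseudo-replication is not modeled (donor effects in the generator are
  deliberately small).
* Covariates with more than two levels are not supported.
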