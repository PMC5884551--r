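---
title: "Detecting positive selection on longevity branches and its aging-expression footprint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting positive selection on longevity branches and its aging-expression footprint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psgscan)
```

# The scientific problem

Long-lived rodents -- the naked mole-rat and its African mole-rat
relatives above all -- reach maximum lifespans far beyond what their body
mass predicts.  One way to ask *which genes* were remodelled on the way
to such lifespans is to scan protein-coding genes for branch-specific
positive selection: episodes in which amino-acid-changing substitutions
accumulated faster than silent ones on exactly the phylogenetic branches
where enhanced longevity evolved.  A complementary question is whether
the resulting positively selected genes (PSGs) behave *antagonistically
pleiotropically* during aging: selected for some early-life benefit, but
regulated with age in opposite directions in a long-lived versus a
short-lived species (down with age in the long-lived one, up in the
short-lived one).

`psgscan` implements this entire analysis chain at desk scale: a codon
model of branch-site selection with maximum-likelihood fitting and
likelihood-ratio testing, reciprocal-best-hit orthology with isoform
selection, a multi-branch screening layer with FDR control and control
reruns, a young-versus-old differential-expression stage feeding
quadrant and directionality statistics, and term-level enrichment.
Because genome-scale inputs for 17 species cannot be reproduced on a
desk, the package ships first-class simulators that generate every input
with known ground truth, and the test suite validates the machinery
against that truth.

# The branch-site model

Codon sequences evolve on a rooted binary phylogeny under the
Goldman-Yang substitution process over the 61 sense codons of the
universal code.  The instantaneous rate from codon $i$ to $j$ is zero
unless the codons differ at exactly one position, and otherwise

$$q_{ij} \propto \pi_j \cdot \kappa^{[\text{transition}]} \cdot
  \omega^{[\text{nonsynonymous}]},$$

where $\pi$ are equilibrium codon frequencies (estimated by F3x4:
position-specific nucleotide frequencies multiplied per codon, stops
removed, renormalized), $\kappa$ is the transition/transversion rate
ratio, and $\omega$ = dN/dS.

The branch-site model (Model A) mixes four site classes.  Writing $p_0,
p_1$ for the first two proportions and distributing the remainder
proportionally, $p_{2a} = (1 - p_0 - p_1)\,p_0/(p_0+p_1)$ and $p_{2b} =
(1 - p_0 - p_1)\,p_1/(p_0+p_1)$:

| class | proportion | background $\omega$ | foreground $\omega$ |
|-------|-----------|--------------------|--------------------|
| 0     | $p_0$     | $\omega_0 < 1$     | $\omega_0$         |
| 1     | $p_1$     | 1                  | 1                  |
| 2a    | $p_{2a}$  | $\omega_0$         | $\omega_2 \ge 1$   |
| 2b    | $p_{2b}$  | 1                  | $\omega_2 \ge 1$   |

One branch per test is designated the *foreground* (tagged `#1` in
newick files, the convention of codon-model software).  The alternative
model lets $\omega_2 \ge 1$ vary; the null fixes $\omega_2 = 1$.  Twice
the log-likelihood difference is referred to $\chi^2_1$ -- the
conservative standard -- with the 50:50 boundary mixture available as an
option (`mixture = TRUE`).  Per-site identification uses naive empirical
Bayes: plug the MLE into Bayes' rule and report sites with posterior
mass $\ge 0.5$ on classes 2a/2b (sites reaching 0.95 are flagged
separately as strong).

Site likelihoods are computed by Felsenstein pruning over site patterns,
with per-node rescaling, in compiled code; the matrix exponential uses
the eigendecomposition of the reversible generator symmetrized by
$\mathrm{diag}(\sqrt\pi)$.  Gap codons and codons containing `N` are
missing data (partial likelihood one over all 61 states).  A pure-R
brute-force reference (`log_likelihood(..., method = "enumeration")`)
sums over every assignment of codon states to internal nodes and is used
by the tests to certify the pruning path to $10^{-8}$ on 4-taxon
alignments.

## Fitting choices

* Free parameters: $\kappa$, $\omega_0$, $\omega_2$ (alternative only),
  $(p_0, p_1)$ via a softmax transform, and a single tree scale factor
  $s$.  The input tree's *relative* branch lengths are held fixed and
  only $s$ is estimated per gene; full per-branch re-estimation would
  add 2n-3 parameters per gene for little benefit at these alignment
  sizes.  This is a documented deviation from codeml's default.
* All generators share one scale so that the mixture-average background
  rate is one substitution per codon per unit branch length; the nested
  pair therefore measures branch lengths identically.
* Optimization is bounded quasi-Newton (L-BFGS-B) on transformed
  coordinates with a forward-difference gradient; convergence is an
  improvement below about $10^{-6}$ log-units.  Starts: one
  deterministic start (or a caller-supplied warm start), plus random
  restarts with $\kappa \in [0.5, 5]$, $\omega_0 \in [0.01, 0.9]$,
  $\omega_2 \in [1, 10]$ and Dirichlet-like proportions; the default is
  `n_starts = 3`.
* The alternative fit is warm-started from the null MLE with $\omega_2$
  set to 2.5 -- *not* at the boundary, where the $\log(\omega_2 - 1)$
  coordinate has vanishing gradient -- and the boundary value is used as
  a fallback so $\ln L_{alt} \ge \ln L_{null}$ always holds.
* When scanning many genes on one tree, `scan_branch()` warm-starts each
  null fit from the previous gene's MLE; this roughly triples
  throughput and is deterministic.

# Screening layer

Per branch, every testable gene (its alignment must contain at least one
species of the foreground clade and one of its sister clade, so that
detected signals cannot predate the branch) is tested; p-values are
converted to Benjamini-Hochberg q-values *per branch* (matching the
per-branch reporting of such scans; whether a joint correction is
preferable is left as configuration), and genes with $q < 0.1$ (strict)
become candidates.  Each candidate is then refit in two control reruns
from fresh random starts; "approved" is operationalized as every rerun's
nominal p-value staying within the branch's significance region (at or
below the largest nominal p among the branch's candidates), since
convergence failures are a known source of false positives in such
scans.  Approved candidates are PSGs.  Unions across branches and a
multi-branch table mirror the reporting of multi-branch scans, and
`bias_check()` compares PSGs against all tested genes on taxon coverage,
alignment length and GC composition with two-sided Mann-Whitney tests
(identical values give p = 1 by convention).

# Expression stage and the pleiotropy statistics

The differential-expression stage is a deliberately minimal negative
binomial test: median-of-ratios size factors; per-gene moment
dispersion, floored at $10^{-8}$ and shrunk halfway toward a
mean-dispersion trend fitted as $a_0 + a_1/\mu$; and a Wald test of the
log2 fold-change (old vs young) with a delta-method standard error from
the NB variance function.  It makes no claim of numerical equivalence to
DESeq2 -- a unit test checks only directional agreement with it -- and
externally produced LFC/q tables can be substituted anywhere a DE table
is consumed.  "Regulated" means $q \le 0.1$.

Genes regulated in *both* species are placed into quadrants by the signs
of their fold-changes (species A long-lived, species B short-lived):
quadrant I = (down in A, up in B), II = (down, down), III = (up, down),
IV = (up, up); genes with a fold-change of exactly zero (a measure-zero
event) are excluded rather than assigned.  Two statistics quantify the
antagonistic-pleiotropy signal:

* `quadrant_fisher()`: one-sided Fisher exact test (hypergeometric upper
  tail) of PSG excess in quadrant I against the sum of II-IV.
* `directionality_test()`: per species, a one-sided Fisher test of PSG
  preference for the longevity-consistent direction among that species'
  regulated genes; the two p-values are combined with the Lancaster
  procedure at equal weights 2, which reduces exactly to Fisher's
  method.  The original analysis did not document its Lancaster inputs
  or weights, so this two-component construction is this package's own
  choice and no equivalence to the published combined p-value is
  claimed.

# Synthetic data: what it emulates and what it does not

The generators define the study conditions used throughout the tests:

* `simulate_tree()`: random rooted binary topologies with branch lengths
  jittered around a target depth on the scale of a rodent phylogeny
  (a few hundredths to a few tenths of a substitution per site).  The
  real 17-species topology is not reproduced.
* `simulate_codon_alignment()`: sites drawn from the Model A mixture and
  evolved by exact sampling from per-branch transition matrices (root
  codon from $\pi$; reversibility makes root placement irrelevant).  No
  indels and no alignment error are simulated -- alignment inference is
  not the stage under test -- so passing tests certify the statistical
  machinery, not robustness to misalignment.
* `simulate_counts()`: negative binomial counts for two species with
  young/old cohorts of 6/3 (species A) and 4/5 (species B), matching the
  cohort sizes of the motivating liver RNA-seq comparison; a planted PSG
  set falls in quadrant I with configurable probability (default 0.8).
  The default dispersion of 0.05 is a conventional bulk-RNA-seq value;
  the original data's empirical dispersion is unknown, and a single
  shared dispersion is used because nothing more is specified.
* `simulate_cds_catalog()`: valid CDSs (ATG...stop, no internal stops)
  mutated codon-wise to a target divergence, with internal-deletion
  isoform variants and a full ortholog truth table.

# Orthology engine

BLAST is replaced by exact Smith-Waterman-Gotoh protein scoring
(BLOSUM62, gap open 11, extend 1 -- BLAST's defaults) via Biostrings:
desk-scale catalogs make heuristic search unnecessary while preserving
the reciprocal-best-hit semantics.  Gene-level scores are maxima over
isoform pairs; ties break deterministically by score then lexicographic
id.  "Best matching isoforms" has no operational definition in the
source analysis; here each species' isoform with the highest score
against the anchor's representative (longest) isoform is chosen, with
longer-then-lexicographic tie-breaks.

The per-group codon alignment is built by *anchor projection*: each
chosen protein is aligned globally (same scoring) to the anchor's
protein and projected onto anchor coordinates, with insertion runs from
different species sharing merged gap columns; codons are then
back-translated 1:1.  This replaces a progressive pairwise-to-profile
scheme: with an anchor always present it is deterministic, uses the
identical scoring engine, and is exact for the indel-free synthetic data
the package is validated on, at the cost of not optimizing
insertion-vs-insertion placement between two non-anchor species (those
columns are mutual gaps and are typically removed by the column filter).
Columns with more than 50% gaps are removed and species with fewer than
50% non-gap codons are dropped; these two values are this package's own
filters -- the internal filters of the original orthology pipeline are
not published.  The dual-assembly merge keeps a species'
transcriptome-derived CDS whenever one exists and falls back to the
genome-derived CDS otherwise.

# Problem sizes used in validation

The test suite and the acceptance script size their simulations as
follows; these are the package's chosen desk-scale study conditions.

* Likelihood oracle: 4 taxa, 20 codons, three parameter sets, both
  models, agreement to $10^{-8}$.
* Null calibration: 200 replicates, 4 taxa, 100 codons, $\omega_2 = 1$;
  rejection at $\alpha = 0.05$ must stay at or below 7% (the $\chi^2_1$
  reference is conservative at the boundary).
* Recovery/power: 20 replicates, 6 taxa, 500 codons, $\omega_2 = 8$,
  selected-class mass 0.2; the median $\hat\omega_2$ must fall in
  [4, 16] and power must be at least five times the null rate.
* FDR pipeline: 200-gene scans, 10% planted selected genes, 4 taxa, 100
  codons, tree depth 0.3; the realized false-discovery proportion among
  approved PSGs, averaged over replicates, must not exceed 0.15.
* Directionality: 50 count simulations at planting probability 0.8
  (power $\ge$ 0.9 at $\alpha = 0.05$) and 50 random-label draws
  (approximate uniformity of the combined p).
* Orthology: 50-gene catalogs; recovery $\ge$ 95% at divergence 0.05 and
  100% at 0.1.

# Known limitations

* Branch lengths are rescaled, not re-estimated per branch; genes whose
  true branch proportions deviate strongly from the input tree lose some
  power.
* Naive empirical Bayes site identification ignores parameter
  uncertainty; its site lists are noisier than a full Bayes empirical
  Bayes treatment, which is out of scope.
* The DE stage's Wald test is approximate at very small replicate
  numbers; its null calibration is verified by simulation at the cohort
  sizes used, not guaranteed beyond them.
* The enrichment stage treats annotation as a flat gene-term table; no
  ontology-graph propagation or semantic summarization is performed.
* Headline numbers of the motivating genome-scale analysis (PSG counts,
  published p-values) depend on 17-species assemblies and are not
  reproducible at desk scale; the package validates properties, not
  those numbers.

# A worked run

```{r pipeline, eval = FALSE}
cfg <- run_config(seed = 5, out_dir = "psgscan_run")
report <- run_pipeline(cfg)
str(report$scan)
str(report$expression)
```

The run directory contains the simulated tree (`tree.nwk`, foreground
tagged `#1`), per-gene alignment FASTAs, count matrices, per-branch scan
tables, the quadrant table and a machine-readable `summary.json`; every
table header names the thresholds used, and rerunning with the same
configuration reproduces every file byte for byte.
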