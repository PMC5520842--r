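---
title: "Methods: gene-family evolutionary-expansion analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-family evolutionary-expansion analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optfam)
```

`optfam` reconstructs how a gene family expanded in a genome. This
vignette is the package's own account of the models it implements, the
parameters that matter, what the simulators do and do not emulate, and
the numerical and design choices a maintainer should know about. The
running example is the sixteen-member rice oligopeptide transporter
(OsOPT) family, whose published per-pair Ka/Ks estimates ship as a
fixture (`opt_table2()`).

## Family identification

Candidates are screened for the OPT signature motif
`SPYxEVRxxVxxxDDP`, matched exactly per position with lowercase `x` as a
single-residue wildcard; all (possibly overlapping) occurrences are
reported. Protein parameters attach to each survivor:

* **Molecular weight** is the sum of average residue masses plus one
  water (18.0153 Da), reported in kDa. `X` residues get a configurable
  average mass (default: the mean of the twenty standard residues) with a
  warning.
* **Isoelectric point** solves net charge = 0 by bisection over pH 0–14
  under the Bjellqvist pKa model (ExPASy's set: side chains for
  C/D/E/H/K/R/Y, residue-specific N- and C-terminal pKa). Net charge is
  strictly decreasing in pH, so the root is unique; the solver stops at
  1e-6 pH units. The pKa table is injectable so results can be
  cross-checked against other tools exactly.
* **Transmembrane segments** use a deterministic hydropathy scan —
  Kyte–Doolittle scale, window 19, window-mean threshold 1.6, overlapping
  qualifying windows merged into segments. This is an approximation
  standing in for HMM-based topology predictors: it reliably flags
  multi-spanning membrane proteins but its absolute counts can differ
  from HMM outputs by a segment or two, which is why family screening
  windows (e.g. 12–16 segments) should be treated as soft ranges.
  Published per-protein MW/pI/TM values are reproducible only with the
  exact source sequences and the original tools' tables, so the suite
  checks these as properties (additivity, fixed-point, window oracles),
  not as printed-value targets.

## Phylogeny

Pairwise amino-acid distances use the Poisson correction
$d = -\ln(1-p)$, with $p$ the fraction of differing comparable sites.
The default gap policy is *complete deletion* (columns containing any gap
removed), matching the common default of distance-based phylogeny tools;
*pairwise deletion* is available by flag. A pair with $p \ge 1$ has no
finite distance and is reported as an error naming the pair.

Neighbor-joining follows Saitou–Nei: join the pair minimizing
$Q(i,j) = (m-2)\,d(i,j) - r_i - r_j$, estimate the two branch lengths by
the rate-corrected two-point formulas, and reduce the matrix. Two
numerical choices make results platform-deterministic and well behaved:

* **Tie-breaking**: the lowest (row, column) index pair wins when $Q$
  ties.
* **Negative branch estimates** are clamped to zero with the deficit
  transferred to the sibling branch, preserving the pair's summed length.

On additive input the returned path lengths reproduce the input matrix to
numerical precision (the suite asserts 1e-9 over random 5–8 taxon trees,
with a brute-force check over all topologies for up to 6 taxa, where
enumeration — 15 or 105 unrooted topologies — is cheap).

Bootstrap support resamples alignment columns with replacement, rebuilds
the NJ tree, and annotates each internal bipartition of the full-data
tree with its replicate percentage. A replicate whose resampled columns
saturate a pair ($p \ge 1$) counts as non-supporting, with a warning.
Default 1000 replicates; the suite uses 20–100 to keep runs fast, which
only coarsens support granularity.

Subfamily and section labels are not derivable from a split criterion
alone, so labeling is reference-based: the tree is rooted at a
user-supplied outgroup and each unlabeled taxon takes the group of the
smallest rooted clade containing it and references of exactly one group.
A taxon whose smallest reference-containing clade spans two groups is
reported `"ambiguous"`, never guessed.

## Ka/Ks and selection

`ng86_counts()` implements Nei–Gojobori (1986). Per codon, the
synonymous site fraction at each position is the share of synonymous
changes among *viable* single-base mutants, where mutations to stop
codons are excluded from the viable set; S is averaged between the two
sequences and N = 3 × codons − S. Codons differing at 2–3 positions are
resolved by averaging the synonymous/nonsynonymous step counts over all
minimal mutation pathways, excluding pathways through stop codons; in the
rare case that every pathway is blocked the average falls back to all
pathways (a documented choice — the classical method is silent here).
Proportions are corrected for multiple hits with Jukes–Cantor,
$d = -\tfrac{3}{4}\ln(1-\tfrac{4}{3}p)$; $p \ge 3/4$ is reported as
saturation. Ka/Ks is undefined (NA, class `"undetermined"`) when Ks = 0 —
never 0 or infinity. The method reconstructs the classical default of
DnaSP-style pairwise estimation; no maximum-likelihood (Goldman–Yang)
machinery is attempted.

Classification uses a symmetric band around 1: purifying below
$1-\varepsilon$, positive above $1+\varepsilon$, neutral inside;
$\varepsilon$ defaults to 0 so exactly 1 is neutral.

A subtle and easily missed property, verified empirically by the suite:
**pathway averaging can report Ka > 0 under purely synonymous
evolution**. If the two lineages fix synonymous changes at different
positions of the same codon (ancestor CGA; one lineage fixes AGA, the
other CGT — all arginine), the observed pair AGA/CGT averages over one
all-synonymous and one all-nonsynonymous pathway, contributing Nd = 1.
At 1000 codons and Ks ≈ 0.3 this happens in most simulated replicates,
so an ω = 0 simulation typically yields a tiny positive Ka (order 1e-4)
rather than exactly zero. The simulator's truth record (every fixed
substitution synonymous) is exact; the estimate is not, and the
acceptance suite states the strict expectation and documents its failure
rather than hiding it.

## Duplication mechanism

From a gene position table (1-based inclusive coordinates, per-chromosome
gene-model ranks), two genes are **tandem** duplicates when they share a
chromosome with at most `max_intervening` (default 20) gene models
between them — a rank-based rule, not base pairs, following the standard
convention. **Segmental** pairs are supported by collinear blocks: chains
of anchor gene pairs, order-consistent on both chromosomes (inverted
blocks allowed), with at most `max_gap` (default 100 kb) between
consecutive anchors on either chromosome and at least `min_anchors`
(default 5) anchors. The chaining is a transparent greedy substitute for
precomputed duplicated-segment resources; externally supplied block
tables are accepted and take the same role. When both rules hold, tandem
takes precedence: proximal duplicates inside a duplicated segment are
reported as tandem. Strand is ignored for classification.

The packaged OsOPT gene map and block set are *reconstructions*: the
published analysis never prints coordinates or ranks, so ranks are
derived from MSU locus numbering (locus number / 10) and coordinates are
synthetic regular spacing. They are fixtures for exercising the
classification (which reproduces the published 4 tandem / 3 segmental
split), not the true rice genome.

## Dating and evolutionary stages

Duplication dates use the molecular clock $T = K_s / 2\lambda$ with the
rice silent-site rate $\lambda = 6.5\times10^{-9}$ per year, reported in
million years. Reported dates and ratios **truncate** (floor) to 2 and 4
decimals respectively — inferred from the published values themselves
(e.g. 76.169… printed as 76.16, and 0.5302/0.2936 = 1.80586 printed as
1.8058, which rounding cannot produce). Truncation uses a 1e-9 epsilon
guard so exact decimals represented a hair low in binary floating point
do not fall through the floor.

Stages default to three bins (70–50, 50–20, 20–9 My, interior boundaries
belonging to the older stage). Dates outside every bin take the nearest
bin with an `out_of_range` flag; a per-event override wins over binning.
Both escape hatches exist because the published narrative itself is not
strictly binnable: the 76.16 My event is older than the oldest bin
(fallback handles it), and the 22.58 My event is narrated in the third
stage although it falls inside the second bin (the packaged override
table reproduces that assignment rather than inventing a rule).

The ancestral-gene count treats duplicated pairs as edges of a graph over
the family members: each connected component descends from one ancestral
gene, so the count is members minus (vertices − components). It is
invariant under event order and duplicate listings; the seven OsOPT pairs
over sixteen members give nine.

## Expression diversification

Tag counts normalize to tags per million per library
(tpm = count / library total × 10⁶). Presence defaults to tpm ≥ 1 — the
published analysis gives no threshold, and digital-expression reliability
conventions vary, so it is configurable. Responses use the inclusive
two-fold rule on fold = (treatment + pseudo)/(control + pseudo): up at
fold ≥ 2, down at fold ≤ 1/2. The pseudo-count defaults to 1 tpm to
stabilize zero-control folds (the source rule is silent on zeros); set
`pseudo = 0` for the exact rule, under which up/down are antisymmetric in
the argument order. Contrasts where both values sit below the presence
floor are `not_assessable`. The diversification matrix reports, per
duplicated pair, `+` in a condition class when the members' calls differ
in at least one contrast of that class — presence vectors for the tissue
class, response calls for stress/pathogen classes — in the fixed
six-class layout (tissues, salt, drought, cold, *X. oryzae*,
*M. grisea*), user-definable for other designs.

A boundary note: an effect planted *exactly* at two-fold is recovered
only about half the time under Poisson noise, because the estimate
scatters symmetrically around the inclusive threshold. Recovery claims
therefore concern unambiguous planted responders (3–5-fold and their
reciprocals); the suite verifies ≥ 95% recovery for those at control
abundance ≥ 20 tpm and 10⁶-tag depth, and separately pins the exact
boundary behavior of the rule itself.

## Simulators: what they emulate, and what they do not

All generators are deterministic under a seed and return truth records
sufficient to score every downstream call without re-derivation.

* **Codon pairs** evolve two copies of a stop-free ancestor by sequential
  random single-base mutations: stop-creating proposals are rejected,
  synonymous changes always accepted, nonsynonymous ones with relative
  probability ω. Under the site definitions of the estimator this makes
  the expected estimated ω equal the simulated ω; mutation-driven
  simulation was chosen over matrix exponentials for transparency, and
  the *realized* substitution counts (not the target) are the scoring
  truth. Simulation stops when realized synonymous events reach
  target Ks × ancestral S. No indels, no codon-usage bias, no empirical
  codon models — so the recovery results say the estimator inverts this
  generator, not that it is robust to those realities.
* **Gene maps** lay out ranked, non-overlapping genes at regular spacing
  and plant tandem pairs (chosen intervening counts) and duplicated
  segments (chosen anchor counts and strides). Real gene density
  heterogeneity and rearrangement noise are not modeled; recovery shows
  the classification rules invert the planting exactly, not that block
  detection is robust to shuffled genomes.
* **Expression matrices** draw per-gene baselines from a log-normal
  (heavy-tailed, as digital expression abundances are), multiply planted
  genes' treatment abundance by the requested fold, and draw counts as
  Poisson at the library depth, with a background row absorbing the rest
  of the transcriptome so totals match the depth. Poisson (not
  negative-binomial) noise matches the sampling character of signature
  counting without biological replication; over-dispersion across
  biological replicates is out of scope.

## Problem sizes and runtime choices

The default test run keeps simulations small enough for interactive use:
200 random additive matrices (5–8 taxa; brute-force topology checks at
n ≤ 6), 1000 single-codon oracle comparisons, 50 seeds per ω at 1000
codons, 10 planted gene maps, 20 expression seeds, bootstrap at 20–100
replicates. These sizes were chosen so the whole suite completes in
about a minute while keeping Monte-Carlo error well inside the asserted
tolerances; the acceptance script uses the same sizes.

## Known limitations

* The hydropathy transmembrane counter is a stand-in for HMM topology
  prediction; treat absolute counts as approximate.
* Ka/Ks is pairwise NG86 with Jukes–Cantor correction only; saturated
  pairs (p ≥ 3/4) error out rather than being extrapolated, and no
  codon-frequency or transition/transversion corrections are applied.
* The molecular clock uses one fixed λ with no confidence intervals and
  no rate-variation model; dates inherit all of Ks's estimation error.
* Collinear-block chaining is greedy and unscored (no synteny
  e-values); it is meant to mirror simple published gap/anchor rules and
  to accept externally computed blocks, not to compete with whole-genome
  synteny tools.
* The packaged family map/blocks are labeled synthetic reconstructions;
  conclusions drawn from them are about the pipeline's arithmetic, not
  about rice genome coordinates.
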