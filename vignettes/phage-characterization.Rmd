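---
title: "Methods: computational characterization of lytic bacteriophages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: computational characterization of lytic bacteriophages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

phagekit implements the computational stages of a phage-characterization
workflow — from plate assays to comparative genomics to
structure-informed sequence analysis — as seeded, testable functions.
This vignette documents the models, the parameters that matter, the
numerical choices, and what the synthetic-data validation does and does
not demonstrate.

## Physicochemical featurization

Each protein is described by 431 descriptors:

* amino-acid composition (20 fractions, summing to 1);
* overlapping dipeptide composition (400 fractions over `L - 1` pairs,
  summing to 1);
* 11 scalars: sequence length, molecular weight (average residue masses
  plus one water, Da), aromaticity (F+W+Y fraction), the Guruprasad
  instability index (`10/L` times the sum of dipeptide DIWV weights),
  isoelectric point, GRAVY (mean Kyte–Doolittle hydropathy), net charge
  at pH 7, helix/turn/sheet residue-set fractions, and the reduced
  extinction coefficient (`5500 nW + 1490 nY`, M⁻¹cm⁻¹).

A "thirteen descriptor" ProtParam-style menu expands naturally to 430
dimensions; sequence length is included as the 431st. Length is part of
every standard ProtParam summary, carries real signal for tail-protein
morphology (fibers vs. spikes vs. tube proteins), and completes the
fixed 431-dimensional layout that the classifier, the serialization
format and the tests all enforce.

Charge and pI use the Bjellqvist pKa set (N-terminus 7.5, C-terminus
3.55; side chains D 4.05, E 4.45, C 9.0, Y 10.0, K 10.0, R 12.0,
H 5.98), the de-facto ProtParam convention. The constants live in one
table so an alternative set can be substituted. pI is found by bisection
on [0, 14] to a charge tolerance of 1e-4 (≤ 100 iterations); the charge
is strictly decreasing in pH so the root is unique. The secondary
structure residue sets (helix {V,I,Y,F,W,L}, turn {N,P,G,S}, sheet
{E,M,A,L}) intentionally overlap on L, following the same convention.

Sanitization uppercases, strips `*` and `-`, removes ambiguity letters
(B, Z, X, U, O, J) with a warning, and rejects sequences shorter than
30 standard residues — dipeptide fractions over a handful of pairs are
noise, not signal. The threshold is a `min_length` argument, not a
constant.

## Family classification

Tail proteins are selected by case-insensitive substring match on
"tail" in the product annotation, featurized, and classified with a
1000-tree random forest. No feature scaling is applied — trees are
scale-invariant. Evaluation is stratified k-fold cross-validation
(default k = 10): within each class, members are shuffled under the
seed and dealt round-robin, so fold class counts differ by at most one
and every sample is tested exactly once. Proteins of one genome may
fall in different folds; a perfectly leakage-free protocol would group
by genome, and `assemble_dataset` keeps `genome_ids` so a caller can
implement that grouping, but the default matches the protein-level
stratification convention. Genome-level family calls aggregate
per-protein predictions by majority vote; ties break on the higher mean
class probability, then lexicographically, so calls are deterministic.

The default seed is 37 throughout the stochastic components. Training at
RefSeq scale (hundreds of phage genomes, thousands of tail proteins)
depends on dated database snapshots and downloads; the in-repo
benchmark instead uses the synthetic two-family proteomes (below),
where separability is guaranteed by construction and the classifier must reach ≥ 95 %
held-out accuracy while permuted labels must sit at chance.

## Comparative genomics

`genome_stats` reports length, GC %, and coding density as the union of
CDS intervals over genome length (overlapping CDS are merged, counted
once). Hit filtering keeps records at identity ≥ 50 %, coverage ≥ 85 %
and e-value ≤ 1e-9, all boundaries inclusive; the thresholds are
arguments with those defaults. Lysis-cassette detection finds maximal
runs of same-category, same-strand genes tolerating up to 2 intervening
genes.

Pairwise identity is Needleman–Wunsch global alignment (match +2,
mismatch −1, gap open −4, gap extend −1; configurable) with identity =
matches / alignment columns × 100. Greedy clustering is USEARCH-style:
longest-first processing, each sequence joining the first centroid at
identity ≥ 0.5 or founding a new cluster — deterministic given the
input. Pan-genome classes follow the standard definitions: core = in
all genomes, unique = in exactly one, accessory = otherwise; the three
counts always sum to the number of clusters.

ANI follows the OrthoANI scheme: both genomes are chopped into
consecutive 1020-bp windows (trailing remainder discarded), all
fragment pairs are globally aligned, and the ANI is the mean identity
over reciprocal best pairs. Fragment *alignability* is judged on the
normalized alignment score — `score / (match_score × fragment_len)` ≥
0.35 by default — rather than on raw identity, because global alignment
of unrelated random DNA under these scores still yields ~48 % column
identity (gaps let the aligner manufacture matches), so no identity
floor can separate homologous from random fragments. Unrelated
fragments score ≈ 0.10 on the normalized scale; fragments within ~30 %
substitution divergence score ≥ 0.55. Genome pairs with no alignable
reciprocal pair return an NA ANI — a distinct "undefined" signal, not
an error.

UPGMA is implemented directly (size-weighted average linkage) so that
tie-breaking is defined: equal merge distances resolve toward the
lexicographically smallest label pair, and children are ordered
lexicographically in the Newick output, making the tree a pure function
of the distance matrix. Branch lengths are half-distances, so the tree
is exactly ultrametric; the tests verify the cophenetic distances of
the re-parsed tree against `stats::hclust(method = "average")` as an
independent reference.

## Phenotype statistics

EOP is mean target PFU over mean host PFU × 100, with the host strain
at 100 % by definition. Spread: with equal replicate counts, the SD of
paired per-replicate ratios; otherwise a delta-method approximation.
Susceptibility counting requires a positive spot **and** EOP > 0 —
strains that clear a spot (lysis from without, abortive infection) but
yield no plaques are scored resistant. On the bundled host-range table
this yields 12 susceptible of 15 *K. pneumoniae* strains.

Fold reduction between log10 titers is `10^(initial − final)`;
`format_fold` rounds to two significant figures for reporting (8.5 →
5.3 log10 PFU/mL prints as ≈1.6×10³). Values below the detection limit
should be treated as censored: a fold change computed against a
detection-limit value is a lower bound, and the analysis scripts report
it as such rather than as a point estimate.

The one-step growth-curve analyzer assumes the triphasic shape. The
baseline is estimated iteratively from the first two points outward,
absorbing points while they stay ≤ `rise_factor` (default 2.0) × the
running baseline mean; the latent period is the last baseline time. The
plateau is the mean of points within 10 % of the curve maximum (for a
triphasic curve these are the tail points; the rise crosses that level
at most once). Burst size defaults to plateau/baseline — at low MOI
with adsorption before wash, infected centers equal the baseline PFU —
with `(plateau − baseline)/baseline` selectable via `subtract_baseline`
(the two differ by < 1 % at burst sizes near 150). A curve that never
exceeds `rise_factor` × baseline raises a "no burst detected" error.

## Structure and conservation

PDB parsing (via bio3d) keeps heavy atoms of MODEL 1 polymer residues:
hydrogens, waters and HETATM groups are excluded by default, and
alternate locations keep the highest occupancy (ties → 'A'). Interface
residues are those with any heavy atom within the cutoff (default
5.0 Å, inclusive) of any heavy atom of the partner chain group; the
implementation is a vectorized distance computation, validated
exhaustively against an all-pairs brute-force oracle. Contiguous-region
calling reports maximal runs of consecutive author numbers of length ≥
6. Alignment columns get occupancy (non-gap fraction) and conservation
(modal-residue frequency among non-gap entries); columns under 0.5
occupancy are flagged low-alignment-ratio (the threshold is a
parameter — no published value exists, and 0.5 marks the point where
the modal frequency is estimated from fewer than half the sequences).
Logo matrices report per-position frequencies among non-gap residues
and information content `log2(20) − H` in bits; gaps contribute blanks,
with the gap fraction reported alongside. PCA is column-centered,
unscaled SVD with the sign of each component fixed so its
largest-magnitude loading is positive.

## Synthetic data: what it shows and what it does not

The generators are pure functions of their arguments including the
seed, and each returns (or writes alongside its files) the ground truth
its consuming test reads:

* `gen_proteomes` draws residues i.i.d. from per-family frequency
  vectors (Dirichlet-sampled with concentration on disjoint residue
  sets), 5 tail proteins per genome, lengths 150–400;
* `gen_growth_curve` produces flat–rise–flat curves with multiplicative
  lognormal noise; defaults mirror the KPP105 one-step growth
  experiment (baseline 1e5
  PFU/mL, plateau 1.46e7, latent 20 min, rise complete at 60 min,
  5-minute sampling, 5 % noise);
* `mutate_genome` applies i.i.d. substitutions and reports the realized
  count;
* `gen_complex` plants contact pairs strictly inside the cutoff and
  decoys beyond cutoff + margin on a 50 Å lattice, so the planted set
  is exactly the interface; a non-positive margin is refused;
* `gen_msa` draws per-column modal residues with a specified
  conservation probability and i.i.d. gaps.

These establish *algorithmic correctness*: parameter recovery, oracle
agreement, invariances. They do not emulate real data's hard parts —
compositional signal in real tail proteins is far weaker than the
disjoint-support families; real genomes diverge by indels, inversions
and horizontal transfer, not i.i.d. substitution; real growth curves
have adsorption tails and secondary infection; real interfaces involve
side-chain packing, not planted point contacts. Passing the synthetic
suite therefore shows the computations are right, not that the
classifier's real-world accuracy or ANI's behaviour on rearranged
genomes matches any published figure.

Problem sizes in the tests and the acceptance script are chosen to keep
the full run in minutes on one core: 400 proteins (2 families × 40
genomes × 5 tails) for the classifier benchmark, 10-kb genomes (9
fragments) for ANI, 100 growth-curve draws, 100 planted complexes, and
1000 random sequences for the descriptor-oracle sweep.

## Known limitations

* The GenBank reader is a minimal single-record parser: joined
  multi-interval locations collapse to their outer span, and qualifiers
  other than `/product` and `/function` are ignored.
* The internal aligner is exact Needleman–Wunsch; for genome-scale
  inputs beyond the fragment scheme it is quadratic and slow. E-values
  attached to internally generated hits would be Karlin–Altschul-style
  approximations; `filter_hits` consumes e-values, it does not compute
  them.
* Linear contigs are assumed; wrap-around features on circular genomes
  are out of scope.
* Exact-duplicate tail proteins are not collapsed before
  cross-validation (a deduplication flag on `assemble_dataset` would be
  the natural extension); duplicates shared across folds inflate CV
  accuracy on real redundant corpora.
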