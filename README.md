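# phagekit

Computational characterization of lytic bacteriophages, for
microbiologists working up newly isolated phages against
multidrug-resistant hosts (e.g. ESBL-positive *Klebsiella pneumoniae*).
The package turns the standard characterization workflow — plate
assays, one-step growth curves, genome annotation review, taxonomy
assignment, and receptor-binding-protein (RBP) analysis — into seeded,
tested functions, with synthetic-data generators so every stage runs
and is verifiable offline.

## What it computes

**Tail-protein featurization and family classification.** Each protein
sequence is mapped to a fixed 431-dimensional physicochemical vector:
amino-acid composition (20), overlapping dipeptide composition (400,
counts/(L−1)), and 11 ProtParam-style scalars — length, molecular
weight, aromaticity, Guruprasad instability index
II = (10/L)·Σᵢ DIWV(sᵢ, sᵢ₊₁), isoelectric point (bisection on the
Henderson–Hasselbalch net charge with Bjellqvist pKa values), GRAVY
(mean Kyte–Doolittle hydropathy), charge at pH 7, helix/turn/sheet
fractions, and the reduced extinction coefficient 5500·nW + 1490·nY.
A 1000-tree random forest over these features classifies phage family
from tail proteins, evaluated by stratified 10-fold cross-validation
and aggregated to genome-level calls by majority vote.

**Comparative genomics.** Genome statistics (GC %, coding density by
CDS-interval union), BLAST-style hit filtering (identity ≥ 50 %,
coverage ≥ 85 %, e ≤ 1e-9, inclusive), lysis-cassette detection
(co-oriented gene runs with bounded gaps), greedy centroid clustering
at 50 % identity, pan-genome core/accessory/unique partitioning, 
fragment-based ANI (1020-bp windows, reciprocal best pairs — the
OrthoANI scheme), and deterministic UPGMA trees in Newick form.

**Phenotype statistics.** Efficiency of plating
EOP = (mean PFU on target / mean PFU on host) × 100 with replicate
spread; susceptibility counting (spot-positive *and* EOP > 0); fold
reduction 10^(Δlog₁₀ titer); and one-step growth-curve analysis
returning latent period, burst period and burst size
(plateau/baseline).

**Structure and conservation.** Protein–protein interface residues at
an inclusive 5 Å heavy-atom cutoff, contiguous interaction regions (≥ 6
consecutive residues), alignment occupancy/conservation profiles,
sequence-logo frequency matrices with information content in bits, and
PCA embedding of feature matrices.

## Worked example

The `analysis/` directory is a numbered workflow over the package
(simulate → featurize → classify → compare genomes → phenotype →
interface). Running it end to end:

```sh
Rscript analysis/01_simulate_data.R --seed 37
Rscript analysis/02_protein_features.R
Rscript analysis/03_family_classifier.R --seed 37
Rscript analysis/04_comparative_genomics.R --seed 37
Rscript analysis/05_phenotype_assays.R
Rscript analysis/06_interface_conservation.R
```

prints, among other output:

```
featurized 400 proteins -> 431 descriptors each
Stratified 10-fold CV (seed 37)
  overall accuracy: 1.000
ANI at 5% divergence: 94.87% (9 reciprocal pairs)
host range: 12 of 15 K. pneumoniae strains susceptible
thermal stability 50 degC/60 min: 1585-fold (~1.6e+03)
growth curve: latent 20 min, burst period 20-60 min, burst size 151 PFU/cell
interface: 25 chain-A residues within 5 A of chain B
```

Reading the numbers: the two synthetic proteome families are separable
by composition, so cross-validated accuracy reaches 1.000 (chance would
be 0.5); a genome mutated at 5 % per-site substitution returns an ANI
of ~95 %, i.e. 100·(1−rate); of the 15 *K. pneumoniae* strains in the
bundled host-range table, 12 are susceptible (spot-positive with
EOP > 0) and the three spot-positive/EOP-zero strains count as
resistant; a drop from 8.5 to 5.3 log₁₀ PFU/mL is a 10³·² ≈ 1.6×10³-fold
loss; and the simulated one-step growth curve (true burst 146, latent
20 min, 5 % noise) is recovered to within one sampling interval and a
few percent of burst size. Tables land under `results/`.

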