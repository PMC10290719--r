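---
title: "Methods: proteochemometric kinome profiling with kinprof"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteochemometric kinome profiling with kinprof}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

# The problem

Protein kinases share a strongly conserved catalytic domain, so an
inhibitor optimised against one kinase commonly binds dozens of others.
Predicting the full kinase-by-compound bioactivity matrix — and from it
the *group selectivity* of a compound — is the core task of
computational kinome profiling. kinprof implements a
proteochemometric pipeline for this task: both the protein and the
ligand are featurized, a single regression model learns the interaction
surface, and downstream statistics summarise selectivity.

Bioactivity throughout the package is defined as log10 of a potency
measurement (IC50 or Ki) expressed in nM. The anchor is 3.0 = 1 µM;
lower values mean more potent compounds. All model losses, metrics and
classification cutoffs operate on this scale.

# Data curation

`parse_activity_table()` ingests heterogeneous activity exports through
a user-supplied column map. Rows are kept only when they carry a kinase
identifier, a SMILES, an experimental IC50 or Ki value and a parseable
unit; every dropped row is logged with a machine-readable reason, and
the invariant `parsed == accepted + rejected` is enforced. Units are
normalised to nM from {nM, µM, mM, M}, case-insensitively; an unknown
unit rejects the row rather than risking silent mis-scaling.

Replicate measurements of one (kinase, canonical SMILES) pair are
collapsed by `deduplicate_pairs()` to their arithmetic mean *on the log
scale* — equivalently the geometric mean in nM — after all sources have
been merged; averaging once over the merged set (rather than per
source) was a deliberate choice, since per-source averaging followed by
a second average would weight sources unequally for no stated reason.

`strict_split()` produces leakage-free evaluation sets: holding out a
set of kinases (or compounds) moves *every* record touching them to the
test side, which the tests verify by exhaustive membership scans.

# Kinase encodings

Three representations of a kinase are supported, all derived from a
structure-validated multiple sequence alignment (MSA) of kinase domains
that the package consumes as an aligned FASTA (it never builds or trims
alignments itself):

* **identifier** — a one-hot vector of length `n_kinases` (catalog
  order fixes the index);
* **active site** — the one-hot encoding of a fixed set of alignment
  columns (29 by default) given by an `active_site_map`;
* **full alignment** — the one-hot encoding of all alignment columns.

Sequence encodings use 21 channels: the 20 standard amino acids in
alphabetical one-letter order, then the gap symbol `-` (the alignment
insertion code is taken to be a plain ASCII hyphen). The channel order
is arbitrary but must be fixed for reproducible models, so it is pinned
and documented. Non-standard residues (B, J, O, U, X, Z) are an error by
default; a lenient mode maps them to the gap channel with a warning,
because silently coercing them would corrupt encodings. Alignment
columns are 1-based everywhere (R convention, and the YAML interchange
format).

Which 29 columns constitute the active site is a property of the MSA,
not of this package; the map is therefore a configuration artifact, and
the synthetic generator emits one covering its most group-discriminative
columns so that shapes and pipelines are faithful without inventing
structural biology.

# Compound descriptors

Four blocks describe a compound; the first three are 2D, computed from
the canonical isomeric SMILES:

* **PCPP** (208): physicochemical properties — topological and
  topochemical indices, Crippen LogP and molar refractivity, Lipinski
  counts, and related descriptors. Because descriptor sets drift across
  toolkit versions, the exact membership is pinned in a shipped
  plain-text registry of 208 names whose length is asserted at load.
  Descriptors that fail or return non-finite values are recorded as 0
  with a warning; models cannot consume NaN.
* **MCFP** (167): the standard MACCS structural key fingerprint.
* **MGFP** (1792): Morgan circular fingerprints at bond radii 2, 3 and
  4, hashed to 256, 512 and 1024 bits and concatenated in radius order.
  Hash collisions at these widths are accepted as defined behaviour.

Standard toolkit primitives (SMILES parsing, descriptor evaluation,
fingerprints, distance-geometry embedding, SMARTS matching) are
delegated to an RDKit worker invoked as a batch subprocess
(`inst/python/chem_bridge.py`); results are memoised per molecule within
a session. No salt stripping or standardisation is applied beyond
canonicalisation unless the user does it upstream.

# The conformer-ensemble descriptor (3CED)

The 3D block describes a molecule as an *ensemble* of conformers rather
than a single geometry.

**Conformers.** Up to 16 conformers are embedded by distance geometry
(ETKDG) with a fixed seed, followed by heavy-atom RMSD pruning at
0.5 Å. Force-field relaxation is deliberately off by default:
determinism and speed matter more here than strained-geometry polish,
and the binned distances are coarse (3 Å bins). Rigid molecules
legitimately yield fewer conformers — methane yields one.

**Feature sites.** Pharmacophore sites are perceived from a shipped
minimal definition table of eight families — Donor, Acceptor,
PosIonizable, NegIonizable, ZnBinder, Aromatic, Hydrophobe,
LumpedHydrophobe — each defined by SMARTS patterns; a site's position is
the centroid of its matched heavy atoms. Shipping the definitions in
the package pins perception against toolkit changes.

**Signature space.** A signature indexes a (family multiset,
distance-bin assignment) combination over 2 or 3 sites, with half-open
distance bins [0,3), [3,6), [6,9) Å; site pairs at 9 Å or beyond
contribute nothing. For 2 points the space holds every unordered family
pair times one bin. For 3 points it holds every family multiset
`f1 ≤ f2 ≤ f3` times *every ordered* bin triple `(b12, b13, b23)` read
off the sites in family-sorted order. With 8 families and 3 bins the
dimension is `3·C(9,2) + 27·C(10,3) = 108 + 3240 = 3348`.

Two conventions deserve emphasis because plausible alternatives exist:

* *Symmetric bin triples are not collapsed.* Collapsing bin assignments
  under the triangle symmetry group (for tied families) would shrink
  the 3-point space to 2600 slots at 8 families; the factory convention
  used here keeps all 27 ordered triples per multiset. When tied
  families admit several site orderings, the lexicographically smallest
  bin triple is the canonical one, so counting is deterministic.
* *Geometrically impossible bin triples stay in the space.* Pruning
  triples that violate the triangle inequality at bin midpoints would
  also change the dimension; instead such slots simply never receive
  counts. A fixed, shape-stable index space is worth a few structurally
  empty columns.

**Counts and averaging.** Per conformer, each realised combination
*counts* (it is not a binary presence flag): a molecule with three
donor–acceptor pairs in the same bin scores 3. Counting preserves
multiplicity information that binarisation destroys, and the ensemble
average is then naturally non-binary. The final 3CED vector is the
element-wise arithmetic mean over the conformers, so entries lie within
the per-conformer min/max envelope, and the descriptor is invariant to
conformer order and to rigid motions of any conformer — both properties
are tested, and per-conformer counts are checked against a brute-force
O(n³) enumeration oracle.

# Model architecture

Six variants combine one kinase representation with the compound
blocks:

| variant | kinase input | 3CED |
|---------|--------------|------|
| 1-1 / 1-2 | identifier | no / yes |
| 2-1 / 2-2 | active site | no / yes |
| 3-1 / 3-2 | full alignment | no / yes |

Variant 3-2 is the full model. All variants share a five-block layout:
convolution, input attention, concatenation, output attention, output.

**Kinase branch (sequence modes).** The one-hot matrix (L × 21) passes
through a multi-kernel 1-D convolution (kernels 3/5/7, 64 channels
each, same-padding) over alignment positions, then ReLU, then
*multi-head attention pooling*: each of 4 heads holds a learned query
vector, scores every position, softmax-normalises the scores, and takes
the weighted sum of position features; head outputs are concatenated
and projected to a 128-wide embedding. Attention pooling was chosen
over full position-by-position self-attention deliberately: it costs
O(L) rather than O(L²), which keeps the full-alignment mode (L in the
thousands for real kinomes) tractable on a CPU, while retaining the
property that the network *learns where to look* along the alignment.
The identifier branch replaces all of this with a dense embedding —
convolution and attention over a length-1 sequence are vacuous.

**Compound branches.** Each descriptor block gets its own input
attention in the form of a learned sigmoid feature gate (one gate
weight per feature, applied multiplicatively) followed by a dense
encoder to the shared 128-wide embedding. A per-feature gate is the
natural analogue of positional attention for an unordered feature
vector.

**Fusion and head.** Branch embeddings are concatenated; an output
attention gate (again sigmoid, one weight per concatenated feature)
reweights the fused representation; a dense head (256 → 64 → 1, ReLU)
emits the predicted bioactivity. The forward and backward passes are
explicit matrix algebra verified against finite differences in the test
suite; the optimiser is Adam (learning rate 1e-3 by default). All
weight initialisation and minibatch shuffling derive from explicit
seeds, so builds and training runs are bit-reproducible.

Because only a handful of distinct kinases (and compounds) appear in
any minibatch, branch forward/backward passes are evaluated once per
*distinct* entity and scattered back to records — the main trick that
makes CPU training of the alignment branch practical.

Continuous blocks (PCPP, 3CED) are standardised per feature using
statistics of the training compounds; the scaling is stored on the
predictor and re-applied at prediction time. Fingerprint blocks stay
raw 0/1.

# Training and evaluation

Training minimises mean squared error with minibatches of 512 for up to
3000 epochs, with early stopping after 100 epochs without validation
improvement; the weights returned are those of the best validation
epoch. Five-fold cross-validation partitions records (by record, i.e.
by kinase–compound pair — strict splits handle entity-level leakage
separately) with a seeded shuffle; each fold's held-out part doubles as
its early-stopping validation set, a pragmatic reading given that a
separate tuning split at desk scale would starve training. The
*consensus* model averages the five fold models' predictions; the
package evaluates it on data held out from all five.

Reported metrics are Pearson correlation (PCC), R² = 1 − SSres/SStot,
RMSE and MAE, all on log10(nM). Per-entity robustness uses
`per_entity_pcc()`: within-kinase and within-compound PCC for entities
with strictly more than 10 records.

# Selectivity profiling

Interactions are classified positive (potent) when bioactivity ≤ cutoff
with the default cutoff 3.0 (1 µM); the boundary counts as positive,
a documented and configurable choice. For a compound and kinase group
the contingency table (N_GP, N_OP, N_GN, N_ON) counts positive/negative
calls inside/outside the group and yields

OR = (N_GP / N_OP) / (N_GN / N_ON).

The four counts are read as positive-in, positive-out, negative-in,
negative-out; the two "negative" symbols follow the displayed equation.
When any cell is zero the default Haldane policy adds 0.5 to *all*
cells so that profiles stay finite and rankable (a "limit" policy
returning 0/∞ is available). A compound whose calls are all positive or
all negative cannot be profiled and is skipped with a reason. The
predicted selectivity class is the argmax-OR group with deterministic
ties by group name — an explicit rule standing in for the informal
notion of a compound being "assigned to" its group.

`compare_methods()` benchmarks scorers (e.g. predicted bioactivity
against an external docking score) at potency cutoffs 0.1/1/5 µM:
scores are min–max scaled to [0,1], AUC is computed threshold-free from
ranks (scaling cannot change it), and point metrics use the scaled
threshold 0.5. `export_kinmap()` writes per-kinase annotations (name,
marker size, colour) for web kinome-tree renderers, with a linear
value-to-size mapping.

# The synthetic study generator

`simulate_dataset()` builds a complete desk-scale study so every module
is testable offline:

* **Catalog**: groups descend from a common root sequence (30%
  divergence to group consensus, 5% member divergence, 5 private gap
  columns per group), so within-group sequence identity exceeds
  between-group identity and the alignment is informative about groups.
* **Compounds**: a seeded sample from a committed library of 260
  valid, diverse drug-like SMILES (enumerated from common medicinal
  chemistry scaffolds and substituents and validated at build time).
* **Bioactivity**: `baseline + group_effect + f(compound) + noise`,
  emitted as IC50 records in nM. Selective compounds (30%, assigned
  round-robin to groups for balance) get −2 log units on their group.
  `f` is a fixed sparse linear function of three named physicochemical
  descriptors (LogP, TPSA, rotatable bonds), giving models a learnable
  compound-side signal; its coefficients were fixed so that, together
  with the selectivity effect, simulated bioactivities at the default
  configuration disperse with variance above 1 log10 unit² — the
  dispersion regime of the kinase panels the generator emulates.
  Noise is Gaussian on the log scale (σ = 0.3 by default), consistent
  with metrics being computed there.

Default study size is 24 kinases (4 groups) at alignment width 200 and
210 compounds, about 5000 records — width 200 standing in for
full-length kinase-domain alignments, and the record count sized so
the full five-fold consensus train runs in minutes on one CPU.

What the generator does *not* emulate: real kinome phylogeny,
chemotype-specific SAR, assay heterogeneity between sources, and
activity cliffs. Passing recovery tests therefore demonstrates that the
pipeline is correct and that the model can learn planted
structure-activity signal at realistic dispersion — not that it
reproduces benchmark accuracy on real kinome panels.

# Numerical choices and degenerate inputs

* Distance bins are half-open [lo, hi); a distance of exactly 3 Å falls
  in the second bin.
* Metrics with constant observed values report PCC/R² as NA with a
  degeneracy flag; RMSE/MAE are still computed.
* Odds ratios of all-zero tables are an error, not NaN.
* ReLU subgradient at 0 is 0; gates initialise at sigmoid(0) = 0.5;
  Glorot-uniform weight initialisation throughout.
* Descriptor failures produce 0.0 plus a warning, never NaN.
* Conformer embedding retries with random coordinates before failing
  with the molecule named.

# Known limitations

* The chemistry engine requires a python interpreter with RDKit on the
  PATH (configurable via `options(kinprof.python = ...)`).
* Training is CPU-bound R matrix algebra: ample for desk-scale studies
  (thousands of records), not for full public-database training runs
  (hundreds of thousands of records), which would need a GPU framework.
* Kinase point mutations are out of scope: a catalog entry is one
  sequence.
* Docking scores can be *compared* via `compare_methods()` but are
  never computed.
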