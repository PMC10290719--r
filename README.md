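# kinprof

Proteochemometric kinome profiling in R: predict kinase–ligand binding
affinities from alignment-encoded kinases and conformer-ensemble
molecular descriptors, and profile compound selectivity across kinase
groups with odds ratios.

## Who this is for

Computational chemists and chemical biologists who need desk-scale,
fully reproducible kinome-profiling pipelines: curating heterogeneous
IC50/Ki exports, featurizing kinases and compounds, training an
attention-based bioactivity regressor with five-fold consensus, and
turning the predicted bioactivity matrix into selectivity calls and
kinome-tree annotations.

## The model in brief

**Bioactivity** is log10 of a potency measurement in nM (3.0 ↔ 1 µM;
lower = more potent). A regression model *f*(kinase, compound) →
bioactivity is trained with MSE loss on curated activity records.

**Kinase representations** (one-hot): an identifier vector
(1 × n_kinases), the active-site slice of a structure-validated
multiple sequence alignment (29 × 21), or the full alignment
(width × 21); the 21 channels are the 20 amino acids plus the gap
symbol.

**Compound representations**: 208 physicochemical properties (PCPP),
167 structural keys (MCFP), 1792-bit multi-radius Morgan fingerprints
(MGFP, radii 2/3/4 at 256/512/1024 bits), and the 3D conformer-ensemble
descriptor **3CED** — the mean, over up to 16 distance-geometry
conformers, of 3348 binned 2-/3-point pharmacophore signature counts
(8 feature families; distance bins 0–3, 3–6, 6–9 Å).

**Architecture**: per-branch feature extraction (multi-kernel 1-D
convolution + multi-head attention pooling over alignment positions;
learned sigmoid feature gates over descriptor blocks), concatenation,
an output attention gate, and a dense head. Six variants (1-1 … 3-2)
cross the three kinase modes with/without 3CED; 3-2 is the full model.
Five-fold cross-validation yields five models whose prediction average
is the **consensus** model.

**Selectivity**: interactions are classified positive at a potency
cutoff (default 1 µM) and each compound × kinase-group contingency
table is summarised by the odds ratio

    OR = (N_GP / N_OP) / (N_GN / N_ON),

with OR ≫ 1 indicating group-selective inhibition; the argmax-OR group
is the predicted selectivity class.

## Worked example

A complete synthetic study — simulate, featurize, cross-validate, and
profile — on the default desk-scale configuration (24 kinases in 4
groups, 210 compounds, ~5000 records):

```r
library(kinprof)

sim   <- simulate_dataset(sim_config(seed = 1))
feats <- featurize_compounds(unique(sim$records$compound_smiles),
                             use_3ced = TRUE, seed = 1)
fs    <- build_feature_set(sim$records, sim$catalog, "3-2", feats,
                          site_map = sim$site_map)

cv <- kfold_cv(fs, k = 5,
               config = train_config(max_epochs = 70, patience = 15,
                                     batch_size = 512, lr = 3e-3, seed = 1),
               seed = 1)
print(cv)
```

```
k-fold cross-validation, 5 folds, variant 3-2
 metric      mean         sd
    pcc 0.8286772 0.01036907
     r2 0.6859544 0.01749592
   rmse 0.5795614 0.01674372
    mae 0.4087129 0.01125722
```

Per-fold held-out PCC ≈ 0.83 (± 0.01): the model recovers both the
planted group-selectivity signal and the physicochemical compound
effect from ~4000 training records per fold, against a noise floor of
0.3 log units. Profiling the planted selective compounds from their
simulated activities:

```r
planted <- sim$truth[sim$truth$selective, ]
profs <- profile_compounds(
  sim$records[sim$records$compound_smiles %in% planted$compound, ],
  sim$catalog, cutoff = 3.0)
print(profs[[1]])
```

```
selectivity profile c1cc(C2CCCCC2)nc(NC2CCCCC2)n1
  G1         OR = 37.000
  G2         OR = 0.341
  G3         OR = 0.341
  G4         OR = 0.341
  predicted group: G1
```

The compound's planted group (G1) dominates the odds-ratio profile by
two orders of magnitude; across this simulation the argmax-OR rule
recovers the true group for 96.7% of the 60 profilable planted
compounds.

A command-line entry point wrapping the same functions ships at
`inst/cli/kinprof.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","kinprof.R",package="kinprof"))')" \
  simulate --out simdir --seed 7
```

## Repository layout

- `R/` — curation, kinase encoding, 2D descriptors, 3CED, model,
  training/evaluation, profiling, synthetic data generator.
- `inst/python/chem_bridge.py` — batch RDKit worker (canonicalisation,
  descriptors, fingerprints, ETKDG conformers, SMARTS feature sites).
- `inst/extdata/` — pinned 208-descriptor registry, 8-family
  pharmacophore SMARTS table, 260-compound SMILES library.
- `vignettes/kinprof-methods.Rmd` — the methods vignette: model,
  conventions, design decisions, limitations.
- `tests/testthat/` — unit, property and acceptance tests.
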