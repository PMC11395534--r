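# pyrimqsar

2D-descriptor QSAR modelling of the antiproliferative activity of
substituted pyrimidine and uracil derivatives against the HeLa cervical
cancer cell line.

Uracil-based scaffolds (the chemical family of 5-fluorouracil) are a
productive source of candidate anticancer compounds, and their potency is
summarised as pIC50 = −log10(IC50 in mol/L). This package implements the
full quantitative structure–activity workflow for that chemical space, for
computational chemists who want to predict activities from SMILES alone or
re-derive models from their own data:

* **Molecular graphs** — a SMILES parser producing heavy-atom graphs with
  implicit-hydrogen counts, topological distance matrices, molecular
  formulae/weights and elemental composition.
* **Descriptors** — centered and averaged Broto–Moreau topological
  autocorrelations ATSC(k, w)/AATSC(k, w) weighted by Kier–Hall intrinsic
  state (s), PEOE/Gasteiger partial charges (c), Sanderson
  electronegativity (e) and atomic polarizability (p); molecular
  distance-edge descriptors between typed nitrogens (MDEN-st).
* **The published five-descriptor model**, frozen at printed precision:

      pIC50 = −4.66·AATSC2s − 1.99·MDEN-23 + 3.45·ATSC4c
              + 0.21·ATSC3e − 15.28·AATSC6p + 4.7326
      (N = 31, k = 5, R² = 0.85, q² = 0.797, F = 29.35, s² = 0.0485)

* **BMLR descriptor selection** — deterministic forward subset search under
  pairwise non-collinearity (r² < 0.6) and coefficient significance
  (|t| ≥ 2), with R², leave-one-out q², F, s² and external-set R²
  statistics.
* **Intuitive-rational splitting** — per-source-group, activity-ordered,
  symmetric test selection keeping each group's extremes in training.
* **Applicability domain** — leverages, the critical leverage
  h\* = 3(k+1)/N, standardized residuals and Williams-plot export.
* **Synthetic libraries** — a deterministic substituted-pyrimidine
  generator with planted linear activities, so the whole pipeline is
  testable without any external download.

## Worked example

```r
library(pyrimqsar)

# 5-(3-chloropropyl)-2,4-dichloropyrimidine, the most active of the
# blind-validation compounds (measured IC50 = 4.24 uM against HeLa)
mol <- parse_smiles("ClCCCc1cnc(Cl)nc1Cl", name = "cmpd41")
molecular_formula(mol)          # "C7H7Cl3N2"
molecular_weight(mol)           # 225.5
pic50_from_ic50(4.24)           # 5.372634

desc <- model_descriptors(mol)  # the five model descriptors
round(desc$AATSC2s, 4)          # -0.1336
predict(published_model(), desc)
#   cmpd41
# 5.527746
```

The prediction 5.53 against the measured 5.37 places the compound among the
actives; the applicability-domain tools then tell you whether a query sits
inside the model's training descriptor space:

```r
critical_leverage(5, 31)        # 0.581
```

End-to-end on synthetic data:

```r
fx <- grouped_fixture(seed = 7)            # 39 compounds in 3 source groups
sp <- intuitive_rational_split(fx, 0.2)    # 31 train / 8 test
pool <- attr(fx, "descriptors")
X <- prune_pool(pool[, -(1:2)])
m <- bmlr_select(X[fx$name %in% sp$train$name, ],
                 sp$train$pic50, max_k = 5)
m$training_meta$R2               # fit quality on the training set
```

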