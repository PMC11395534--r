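---
title: "Methods: 2D-descriptor QSAR for antiproliferative pyrimidines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 2D-descriptor QSAR for antiproliferative pyrimidines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyrimqsar)
```

## The modelling problem

Substituted pyrimidines and uracils are a recurring scaffold in anticancer
chemistry; their antiproliferative potency against the HeLa cervical cancer
cell line is usually summarised as pIC50, the negative decadic logarithm of
the molar IC50. `pyrimqsar` implements a complete 2D-topological QSAR
workflow for this chemical space: molecules enter as SMILES, are turned into
heavy-atom molecular graphs, descriptors are computed from graph topology and
per-atom electronic properties, and a multiple linear regression maps
descriptors to activity. The package ships one frozen five-descriptor model,

$$
\mathrm{pIC_{50}} = -4.66\,\mathrm{AATSC2s} - 1.99\,\mathrm{MDEN\text{-}23}
 + 3.45\,\mathrm{ATSC4c} + 0.21\,\mathrm{ATSC3e}
 - 15.28\,\mathrm{AATSC6p} + 4.7326,
$$

together with the machinery to derive such models from scratch: descriptor
pools, forward selection (BMLR), internal/external validation and a
leverage-based applicability domain.

## Molecular graphs

`parse_smiles()` builds a heavy-atom graph; hydrogens are implicit counts
assigned from standard neutral valences (C 4, N 3, O 2, S 2/4/6, P 3/5,
halogens 1), with bracket atoms such as `[nH]` respected verbatim.
Aromaticity is taken from lowercase notation; six-membered C/N rings written
in alternating Kekulé form are normalised to the same aromatic
representation, so `c1ccccc1` and `C1=CC=CC=C1` yield identical graphs. No
full aromaticity model is attempted: amide-containing rings written in
Kekulé form (e.g. uracil as `O=C1NC=C(R)C(=O)N1`) keep their localised
bonds, and the bundled fixtures therefore use the aromatic lactam form as
drawn in the synthesis literature. Stereo descriptors and formal charges are
parsed and discarded — the modelled compounds are neutral and every
descriptor is 2D.

Topological distances are shortest-path bond counts (`distance_matrix()`,
backed by igraph). Molecular weights use the conventional IUPAC standard
atomic weight table (H 1.00794, C 12.0107, N 14.0067, O 15.9994, Cl 35.453,
I 126.90447, ...), the table elemental-analysis software reports against;
with it the computed compositions agree with published elemental analyses of
the blind-validation compounds to the printed 0.01.

## Atomic weightings

Four per-atom property schemes weight the autocorrelation descriptors:

* **s — Kier–Hall intrinsic state**, $I = ((2/L)^2\,\delta^v + 1)/\delta$,
  with $L$ the valence-shell principal quantum number, $\delta^v$ valence
  electrons minus attached hydrogens, and $\delta$ the number of heavy-atom
  sigma bonds. Terminal heteroatoms with lone pairs score high (carbonyl O:
  7), buried carbons low.
* **c — PEOE partial charges** (Gasteiger–Marsili): six damped iterations of
  electronegativity equalisation with the published polynomial parameters;
  hydrogens participate explicitly and total charge is conserved. Nitrogen
  and oxygen atoms bearing only single bonds are assigned the sp²
  parameter set when bonded to an aromatic or multiply-bonded neighbour
  (anisole-type O, amide N), matching the type rules of the common PEOE
  implementations. Phosphorus has no published sigma parameters and raises
  an error.
* **e — Sanderson electronegativity** and **p — static atomic
  polarizability** (Å³): element table lookups, optionally scaled relative
  to carbon. The carbon-scaled values coincide with the classical
  2D-descriptor weighting tables used across descriptor software.

## Autocorrelation and distance-edge descriptors

The centered Broto–Moreau autocorrelation at lag $k$ is

$$
\mathrm{ATSC}(k, w) = \sum_{\{i,j\}:\,d_{ij}=k} (w_i - \bar w)(w_j - \bar w),
$$

and AATSC divides by the number of contributing pairs. Two conventions
circulate: unordered pairs (each $\{i,j\}$ once) and ordered pairs (the
double sum; exactly twice the unordered value). AATSC is identical under
both. The package default — used by `atsc()`/`aatsc()` and matching the
hand-computable examples in the unit tests — is unordered pairs on the
heavy-atom graph with raw property tables.

The molecular distance-edge descriptor between nitrogen types $s,t$
(1 = primary, 2 = secondary, 3 = tertiary, typed by heavy-atom degree, so
pyridine-type ring N and uracil N–H are both "secondary") is

$$
\mathrm{MDEN}_{st} = \frac{n_{st}}{(\prod d_{ij})^{1/n_{st}}},
$$

the pair count over the geometric mean of their topological distances —
algebraically equal to the classical $\lambda_{st} = n_{st}/\bar d_{st}^2$
with $\bar d_{st} = (\prod d_{ij})^{1/(2 n_{st})}$. It is zero when either
type is absent, non-negative, and invariant under atom relabelling.

## The frozen published-model configuration

Which convention the original descriptor software used (hydrogens as graph
vertices or not; ordered or unordered pair sums; raw or carbon-scaled
property tables; the intrinsic-state value of an explicit hydrogen) is not
derivable from descriptor names alone, and the choices change ATSC/AATSC
values substantially. We therefore ran a parity experiment: each
configuration in the flag space was applied to the four blind-validation
compounds and the resulting Eq.-above predictions compared against the
published predicted values. The winning configuration, frozen into
`published_descriptor_config()` and pinned inside `published_model()`, is

* hydrogen-explicit graph (hydrogens become vertices; distances change
  accordingly),
* ordered (double-sum) pair convention for ATSC, pair-count-normalised
  AATSC,
* Sanderson electronegativity and polarizability scaled relative to carbon,
* intrinsic state of hydrogen = 5, the Kier–Hall formula evaluated for H
  ($L = 1, \delta^v = 1, \delta = 1$),
* 6 PEOE iterations.

Under this configuration the recomputed predictions for the two
chain-substituted pyrimidines agree with the published values to about
0.14 and 0.19 pIC50 units; the uracil and the ring-fused compound deviate
more (about +4.1 and −0.7), indicating that the original software's
intrinsic-state handling of iodine/carbonyl-rich molecules differs from any
convention in our flag space. The discrepancy is reported as-is — the model
itself, its coefficients and its statistics are stored at printed precision
and never re-fitted, and `model_descriptors()` exposes the exact descriptor
values used so the parity experiment can be repeated against other
implementations.

## BMLR descriptor selection

`bmlr_select()` performs Best Multi-Linear Regression: forward selection of
descriptor subsets under two constraints — no selected pair of descriptors
may have pairwise squared Pearson correlation at or above 0.6, and every
coefficient must keep $|t| \ge 2$ (the significance gate; the literature
describing the procedure states a significance check without a numeric
threshold, so the conventional two-standard-error rule is used). Descriptors
are centered and scaled for the search and the final model is refit in
natural scale, which reproduces the scaled fit's fitted values to machine
precision.

The search itself generalises the classical "best pairs, then grow" recipe:

1. **Seeding.** All admissible descriptor pairs are scored in closed form
   from the correlation matrix. The seeds are the top-`beam` pairs by $R^2$
   *plus, for every descriptor, its best admissible partner*. The diversity
   seeds matter: in chemical pools the top pairs concentrate on one
   collinear cluster, and a search started only there systematically misses
   planted models (we verified this on synthetic planted data, where pure
   top-pair seeding recovered the planted subset in under half the
   replicates that diversified seeding recovers).
2. **Frontier growth.** A beam search over subset sizes: every admissible
   one-descriptor extension of every frontier subset is scored exactly via
   orthogonalised residual projections (no refit per candidate), and the
   best `2 * beam` children by $R^2$ form the next frontier. The best
   significance-gated subset is recorded at each size.
3. **Refinement.** The most promising subsets are polished by
   single-descriptor exchanges and drop-two/regrow moves, accepting only
   strict $R^2$ improvements that keep the subset admissible.

The final model is the largest admissible subset found (growth stops early
only when no extension keeps all coefficients significant), with ties broken
by $R^2$, then minimum $|t|$, then descriptor names — the whole procedure is
deterministic.

Validation statistics follow the usual definitions: $R^2$, $s^2 =
RSS/(N-k-1)$, $F = (R^2/k)/((1-R^2)/(N-k-1))$, per-coefficient $t$, and
leave-one-out $q^2 = 1 - PRESS/TSS$ computed by the exact hat-matrix
shortcut (the explicit $N$-refit loop is implemented too and agrees to
machine precision). External $R^2$ on a held-out set defaults to the squared
Pearson correlation between predictions and observations; the
bias-sensitive predictive form $1 - RSS/TSS$ is available via
`convention = "predictive"`, and the returned value carries its convention
as an attribute because the two can differ materially.

## Intuitive-rational splitting

`intuitive_rational_split()` reproduces the dataset design used for the
published model: compounds are grouped by their source assay, each group is
ordered by increasing activity, per-group test counts follow
largest-remainder allocation of the overall test fraction, and test
compounds sit at evenly spaced ranks symmetric about the group median — with
the hard rule that each group's most and least active compounds stay in
training. For groups of sizes 5/15/19 at fraction 0.2 this allocates 1/3/4
test compounds (8 of 39). Ties in activity are ordered by compound name, so
the split is a pure function of its input.

## Applicability domain

Leverages are hat-matrix diagonals $h = x'(X'X)^{-1}x$ with an intercept
column appended; the critical leverage is the conventional
$h^* = 3(k+1)/N$, which for the shipped model's $k = 5$, $N = 31$ gives
0.581. Residuals are standardized by the regression standard error $s$
(internally studentized residuals, dividing additionally by
$\sqrt{1-h_i}$, are available behind a flag since the published analysis
does not state which form it used); compounds with $|r| > 2$ and $|r| > 3$
are flagged as moderate and strong outliers, and `ad_report()` assembles the
Williams-plot table.

## Synthetic data: what it does and does not emulate

`generate_library()` enumerates a deterministic combinatorial space of three
scaffolds — uracil (pyrimidine-2,4-dione), 2,4-dimethoxypyrimidine and
2,4-dichloropyrimidine — decorated at N-1/N-3 (uracil) and C-5/C-6 with a
dozen small substituents (alkyl, haloalkyl, alkynyl, methoxy, benzyloxy,
phenyl), then samples from it with a seeded RNG whose state is restored
afterwards (no global side effects). This mirrors the substitution pattern
of the modelled chemical space and exercises every parser feature the real
compounds need (aromatic heterocycles, bracket atoms, branches, rings,
halogens).

`plant_activities()` generates pIC50 values linear in five chosen
descriptors plus Gaussian noise. Defaults: the five descriptors of the
shipped model; standardized coefficients proportional to the published
per-coefficient t statistics (t statistics measure standardized effect
strength, so this reproduces a realistic relative-importance profile);
noise $\sigma = 0.22 \approx \sqrt{0.0485}$, the residual scale of the
published fit; and an option to map the deterministic activity onto the
span 4.1–6.52 observed in the modelled dataset. `grouped_fixture()` labels
39 such compounds with source groups of sizes 5/15/19.

What passing tests on this fixture demonstrate: the pipeline is internally
consistent end to end — parsing, descriptor computation, splitting,
selection and validation interoperate, and the selector finds planted linear
structure at realistic noise. What they do not demonstrate: recovery of the
real structure–activity relationship, which is nonlinear in unknown ways,
noisier, and sampled from a chemistry broader than three scaffolds.

## Numerical choices and limitations

* Problem sizes in the test-suite simulations: selection-recovery
  experiments use one fixed 31-compound library with 100 noise redraws;
  invariance properties are checked over 100 generated molecules.
* Collinearity is pairwise only, as in the procedure being reproduced;
  multicollinearity beyond pairs is handled implicitly by the significance
  gate.
* `prune_pool()` removes descriptors with any missing value or zero
  variance before selection; `bmlr_select()` additionally refuses
  rank-deficient fits.
* Degenerate inputs: molecules with a single heavy atom have no
  intrinsic-state (isolated-atom error); disconnected SMILES parse but
  refuse a distance matrix; empty descriptor pools and constant predictions
  raise errors rather than returning NaN.
* The SMILES writer emits fully explicit bracket atoms; it is valid,
  round-trip faithful and deliberately non-canonical.
* Known limitation: exact numerical parity with the original descriptor
  software is established only partially (see the parity experiment above);
  conclusions that depend on absolute ATSC/AATSC values for iodinated or
  carbonyl-rich molecules should be drawn with the configuration flags in
  mind.
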