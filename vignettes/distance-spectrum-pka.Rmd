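---
title: "Distance-spectrum prediction of carbon acid pKa: methods and design"
author: "pKaSpectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-spectrum prediction of carbon acid pKa: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pKaSpectra)
```

## The model

Carbon acids — compounds deprotonating at a C–H activated by neighbouring
electron-withdrawing groups (carbonyls, sulphones, nitriles) — are poorly
served by global pKa predictors because public experimental data are
sparse and heterogeneous. `pKaSpectra` implements an atom-typed linear
model fast enough for batch use. Every heavy atom of a molecule receives a
six-digit atom-type code; the feature vector of an ionisation site, its
*distance spectrum*, collects for each atom-type the sum of
$1/d^2$ over the atoms of that type, where $d$ is the through-bond
(topological) distance to the site. The predicted pKa is

$$\mathrm{p}K_a \;=\; \sum_{\text{atoms } j \neq s}
   \frac{\alpha_{\,\mathrm{type}(j)}}{d(j)^2},$$

one coefficient $\alpha_t$ per atom-type, learned by an ordinary
least-squares solve via QR decomposition. There is no intercept (the
equation above has none; a flag can add one) and no regularisation: the
solve is a deterministic linear-algebra operation, so refitting identical
input reproduces bit-identical coefficients — a property the test suite
asserts on the persisted model files themselves.

A prediction is *in domain* when every atom-type in the query spectrum has
a learned coefficient. Missing types contribute zero; the prediction is
still returned, flagged out of domain, with the missing codes listed.

## The atom-typing scheme

Codes have the shape `ABBCDD`:

| digits | meaning | values |
|---|---|---|
| `A` | formal-charge class | 1 neutral, 2 cation, 0 anion |
| `BB` | atomic number, zero-padded | elements with $Z \le 99$ |
| `C` | environment class | 0 aromatic, 1 saturated, 2 doubly bonded, 3 triply bonded |
| `DD` | neighbour summary | 10 × (bonded heteroatoms, capped 9) + (bonded heavy atoms, capped 9) |

An ether oxygen is `108102`; an isolated neutral carbon `106100`. The code
is a pure function of the atom and its one-bond neighbourhood, so it is
invariant under atom renumbering, automorphic atoms always agree (all six
benzene carbons share one code), and editing an atom two or more bonds
away cannot change a code. Hydrogens are implicit: they are counted on
their heavy atom but are never graph nodes, which keeps spectra compact.
Elements beyond $Z = 99$ do not fit `BB` and are rejected rather than
truncated. The scheme version (`abbcdd/1.0`) is stored in every persisted
model, and a model refuses to score spectra produced by a different
version.

The `C` and `DD` semantics are this package's own concrete choice of
environment summary (charge class, hybridisation-like bond-order class,
neighbour counts); the scheme is deliberately a small, documented strategy
rather than a reproduction of any proprietary typing table.

## The distance spectrum

Distances are bond counts over the heavy-atom graph (a double bond is one
edge; "through-bond" is a graph metric). The site atom itself is excluded
structurally — its distance is zero, and the exclusion avoids any division
guard. Atoms unreachable from the site (counter-ions in salt forms)
contribute nothing: $1/d^2 \to 0$ as $d \to \infty$ is the natural limit.
No maximum distance is imposed; the quadratic damping already makes remote
atoms negligible. Spectra are validated against an independent
Floyd–Warshall + naive-summation oracle in the tests.

## Fitting, rank deficiency and $R^2$

The design matrix has one row per training record and one column per
atom-type in the union of the training spectra (absent types are zero).
The solve uses column-pivoted QR with a rank tolerance of `1e-10`.
Columns flagged rank-deficient receive a coefficient of exactly 0 and are
reported in the model (`deficientTypes`); the fitted values remain
least-squares optimal. This deterministic basic solution was chosen over
the minimum-norm solution, which would require a complete orthogonal
decomposition without changing any observable property used downstream
(determinism, exact recovery on full-rank designs, agreement with a
normal-equations oracle). Features are not centred or scaled: the model
has no intercept and the coefficients are meant to be read directly as
per-type pKa impacts.

The reported $R^2 = 1 - SS_{res}/SS_{tot}$ uses $SS_{tot}$ about the mean
response and is truncated to $[0, 1]$ (an intercept-free fit can otherwise
produce a negative value on pathological data). A constant response with
zero residuals reports $R^2 = 1$.

## AIBL local models and virtual training data

Within a congeneric series, a single bond length near the dissociation
site maps linearly to pKa ($\mathrm{p}K_a = m R + c$). The package
consumes bond lengths as data (tables of compound, length, pKa) — quantum
chemical geometry optimisation is explicitly out of scope — and fits the
line by OLS (`lm`). `selectBestBond()` picks the bond with the highest
$r^2$ among aligned candidates, ties broken by lexicographic bond label.
Subgroup splits (e.g. substituents on the sulphone versus the carbonyl
terminus, which give slopes of opposite sign) are expressed as separate
fit calls on user-partitioned data rather than automatic clustering,
mirroring how such splits are recognised in practice: by inspection of
geometry classes.

Mixed-solvent measurements (aqueous ethanol, aqueous DMSO) are corrected
to water by a second OLS line fitted on paired observations and composed
after the bond-length model — a composition of affine maps.

`generateVirtualRecords()` turns a fitted line plus (molecule, site, bond
length) inputs into `virtual`-provenance records ready for augmentation.
Inputs outside the training length range are flagged; the default policy
keeps them, because deliberate extrapolation to extreme pKa values is
part of the augmentation strategy, while `policy = "strict"` drops them
with a reported count. Augmented training sets can only grow the
atom-type union, so refits never lose coverage, and an in-domain query can
never become out-of-domain — both properties are asserted over 50 seeded
augmentation runs.

## Curation of replicate measurements

Literature collections carry replicate and multi-site measurements.
`dampedAverage()` walks a sorted value list and merges neighbours whose
gap is at most a tolerance (default 1.0 pKa unit, a CLI flag); the k-th
value absorbed into a cluster enters the running mean with weight $1/k$,
so each cluster reduces to its ordinary mean while genuinely distinct
macro-pKa values survive. The tolerance default is a package choice: it
collapses typical inter-laboratory scatter (a few tenths of a unit) and
preserves macro-pKa separations, which are rarely below one unit.

`assignValuesToSites()` matches accepted values to predicted sites
greedily: repeatedly take the globally smallest absolute error among
unassigned pairs. Greedy (not optimal bipartite) matching follows the
repeated-smallest-error description of the procedure it implements; ties
break to the lower site index, then the lower experimental value, making
the result independent of input order. The pipeline only attempts
compounds with one candidate site or with exactly as many sites as
accepted values; everything else is rejected with a logged reason, as is
every compound on the manual drop-list (a plain text file of ids).

## Validation tools

* `stratifiedRmse()` reports RMSE per chemical stratum (the activating
  motif around the site: sulphone-carbonyl, nitrile-carbonyl,
  di-carbonyl, other) and overall, each on all records and on the
  in-domain subset. The in-domain columns strictly exclude out-of-domain
  records; empty strata are absent, never zero.
* `binErrors()` classes absolute errors Good/Fair/Poor/Bad with
  left-closed, right-open intervals $[0,1), [1,2), [2,3), [3,\infty)$ —
  the published bin wording leaves boundaries ambiguous; this convention
  is exhaustive and mutually exclusive and places a boundary value in the
  worse bin, consistent with "Bad ≥ 3".
* `binCoefficients()` classes $|\alpha|$ into $<10, [10,20), [20,30),
  \ge 30$; small magnitudes are desirable, since no single atom-type
  should dominate a prediction.
* `yScramble()` permutes training responses, refits on the unchanged
  design, and evaluates an untouched test set. One master seed spawns
  per-replicate sub-seeds, so each replicate is individually
  reproducible; replicates whose refit fails are excluded and counted,
  not imputed. On synthetic data with genuine signal the scrambled RMSE
  exceeds the true model's in every replicate of the shipped checks.

## The synthetic generator

Because the original training and test sets are not publicly
distributable, every property of the pipeline is demonstrated on
synthetic fixtures with known ground truth. Molecules are random
connected heavy-atom graphs: a random attachment tree plus ring-closure
chords (probability 0.2 per candidate), elements drawn from C/N/O/S,
formal charges on N/O with probability 0.05, hydrogen counts from a
simple valence model, and vertex degree capped at 3. The degree cap and
restricted element set are deliberate: they bound the universe of
emittable atom-types so that, as molecules accrue, the type set
saturates and a full-column-rank design becomes reachable. Record labels
are the exact inner product of ground-truth coefficients with the
spectrum plus Gaussian noise, so with zero noise a fit must reproduce the
coefficients to numerical precision (asserted at `1e-8`; observed around
`1e-13`).

`generateRecords(ensureFullRank = TRUE)` first appends further molecules
from the same deterministic stream while rows trail columns, then drops
the few records whose rare atom-types remain exactly collinear (types
whose every occurrence is tied to another rare type in the same
records); each pass removes at least one column, so the construction
terminates with a certified full-rank design. All randomness flows
through explicit seeds and the caller's RNG state is restored.

What the generator does *not* emulate: aromatic systems (synthetic graphs
are non-aromatic; aromatic typing is exercised through SMILES fixtures),
tautomerism, stereochemistry, mixed-solvent/temperature heterogeneity
beyond a single Gaussian noise knob, and the chemical judgement behind
manually designed virtual compounds. Passing tests therefore demonstrate
the correctness of the machinery — typing, spectra, solving, domain
accounting, curation, validation — not predictive accuracy on real
carbon acids, which depends on data this package does not ship.

The end-to-end pipeline (`runPipeline()`) chains synth → curate → train →
AIBL fit → virtual generation → augment → retrain → predict → validate
from one YAML config. Its virtual bond lengths are derived from each
molecule's ground-truth pKa through the fitted line plus a small
geometric perturbation (sd 0.003 Å), emulating the premise that the
local model's labels are accurate; with the default sizes (120 training
molecules, 40 test, noise 0.3) the held-out RMSE lands at the noise
floor (about 0.4 pKa units).

## Conventions, sizes and limitations

* Atom and site indices are 1-based everywhere, including the CSV
  formats (`site_atom_index`), matching R convention; the convention is
  stated in every reader's documentation.
* Training CSVs are written with an SDF sidecar holding the exact
  graphs, because canonical SMILES renumber atoms and would silently
  invalidate site indices; readers prefer the sidecar when present. pKa
  values and persisted model coefficients are written at full precision
  (17 significant digits), making write/read round trips bit-exact.
* Shipped checks use problem sizes of 25–300 molecules, 50–200
  scramble/augmentation replicates and 100-repetition recovery loops;
  the whole suite runs in about a minute on one CPU.
* SMILES/SDF parsing, ring/aromaticity perception and SMILES rendering
  are delegated to ChemmineR/OpenBabel; the implicit-hydrogen counts use
  a simple organic valence model (base valence + formal charge − bond
  order sum), adequate for the organic subset this package targets.
* Known limitations: no tautomer enumeration, no multi-site macro-pKa
  combination, no automatic congeneric-series clustering, and site
  perception is a convenience matcher for activated C–H motifs —
  sites are primarily user-supplied.
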