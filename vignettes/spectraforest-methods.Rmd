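---
title: "SpectraForest methods: spectrum-class modelling for photosafety screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SpectraForest methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The classification problem

Photosafety assessment treats UV–Vis absorption in the 290–700 nm window as
the trigger for photoreactivity concern. Experimental spectra in literature
databases are usually available only as *lists of absorption maxima* with
molar extinction coefficients (MEC), not as full band shapes. SpectraForest
works at exactly that level of description:

* a molecule is **POS** if at least one listed maximum satisfies
  290 ≤ λ ≤ 700 nm **and** MEC ≥ 1000 L·mol⁻¹·cm⁻¹ (all bounds inclusive);
* otherwise it is **NEG** — including molecules whose peak lists are empty
  or whose in-window peaks lack a quantified MEC.

Two consequences of the peak-list representation shape everything
downstream. First, the *absence* of an in-window maximum does not guarantee
the absence of in-window absorptivity (broad bands with maxima just outside
the window still absorb inside it), so NEG labels are noisier than POS
labels near the 290 nm boundary. Second, database MECs inherit literature
transcription problems — most notably values recorded in log units. The
labelling module therefore carries *advisory* quality flags that never
affect the label but drive the triage stage:

| flag | fires when | unit/window |
|---|---|---|
| `suspect_log_mec` | every present MEC in [3, 5] | dimensionless (log-like) |
| `near_lower_endpoint` | any peak λ in [281, 317] nm | nm |
| `near_mec_threshold` | any in-window MEC in [661, 1500] | L·mol⁻¹·cm⁻¹ |
| `missing_mec` | any peak lacks an MEC | — |
| `empty_list` | no peaks listed | — |

The flag windows are the ranges observed for confidently misclassified
molecules in this kind of data: wavelengths just below or just above the
290 nm edge, MECs straddling the 1000 threshold, and log-unit artefacts.

POS molecules are sub-categorised by their strongest in-window maximum into
half-open MEC bands [1000, 5000), [5000, 10 000), [10 000, ∞). The
half-open convention resolves the boundary value 5000 into the middle band;
NEG in-window peaks are split at MEC 900 to mirror the usual reporting
convention for borderline negatives.

## Structure curation

Standardization must make tautomers, mesomers and aromatic/Kekulé forms
collapse to one representative, deterministically. SpectraForest implements
this as a round-trip through the standard InChI: SMILES → InChI → structure
→ canonical SMILES. The InChI mobile-hydrogen layer merges tautomers, its
charge rearrangement merges charge-separated mesomers (both nitro-group
conventions, N-oxides), and the final canonical SMILES fixes one
aromaticity perception. The round-trip is idempotent, which the test suite
checks directly.

Eligibility is a whitelist-and-window rule: average molecular weight within
[98, 1080] g/mol, exactly one fragment (salts are rejected, not desalted),
elements restricted to the organic subset {H, B, C, N, O, F, Si, P, S, Cl,
Se, Br, I} (anything else counts as "metal"), zero net formal charge, no
radicals, and a neutral-valence check on the explicit-hydrogen connection
table (allowed total bond orders per element, with pentavalent N admitted
because the mesomerism normalization writes nitro groups uncharged). Each
rejection carries one primary reason in the precedence order metal >
charged > radical > valence > multifragment > mw_low > mw_high. Average
(not monoisotopic) mass is used — the conventional choice when a source
does not specify — and the bounds are configurable.

Duplicates are detected by InChIKey computed on the stereochemistry-stripped
structure, so enantiomers and diastereomers collapse; the first occurrence
is kept and the spectrum peak lists of removed duplicates are *unioned*
onto the kept record. Union is the least lossy merge under a rule of the
form "one or more absorption maxima": any peak reported for any
stereoisomer can establish POS.

## Modified-distance descriptors

The Md block encodes 2D structure as a histogram over heavy-atom pairs.
For atoms *i*, *j* at topological (bond-count) distance *L* ≤ 4, the
modified distance is

d(i,j) = L · f − ρ(i) − ρ(j),  ρ(a) = r_vdW(a) · ĒN_S(neighbours of a) / EN_S(C),

with distance factor f = 4, Bondi van der Waals radii and Sanderson
electronegativities (hydrogens count as neighbours but not as pair
members). Values are binned at resolution 0.017 into 1010 intervals
anchored at 0; negative values clip to bin 0 and overflow clips to the last
bin. Only connectivity and element identity enter — no bond orders, formal
charges, aromaticity model or 3D coordinates — so the descriptor is immune
to standardization conventions. The functional form above is one concrete
realisation of the vdW-radius/neighbour-electronegativity recipe; it is
isolated behind `modifiedDistance()` so an alternative parameterisation can
be swapped in without touching the histogram logic. The histogram contract
is tested against an independent shortest-path oracle (igraph distances on
the heavy-atom graph): the histogram mass must equal the number of pairs
within 4 bonds, and the vector must be invariant under atom renumbering.

## Fingerprints and feature matrices

The circular-fingerprint family is Open Babel's ECFP4 (radius-2
environments), OR-folded from 4096 to 1024 bits; MACCS is the 166-key set;
the 1D/2D block is a 13-column set of physicochemical and constitutional
descriptors (MW, logP, TPSA, MR, HBA, HBD, atom/bond/ring/heteroatom/
halogen/unsaturation counts). CDK, PubChem and Substructure families are
deliberately not emulated: cross-toolkit bit parity is a non-goal, and the
modelling surface (Morgan + MACCS + Md + 1D/2D) is fully computable in one
toolkit. Externally computed quantum descriptors (HOMO/LUMO/GAP estimates)
enter through a 10-column pass-through loader rather than a reimplementation
of the source models. Feature matrices track the molecules each calculator
failed on; combining sets restricts to the intersection of successfully
featurized molecules and concatenates columns with full provenance.

## Models and validation

The primary classifier is a random forest of 500 unpruned trees grown on
bootstrap samples with mtry = √p (⅓·p as the alternative), exactly the
classical construction: out-of-bag (OOB) accuracy as the internal
validation estimate, permutation importance (mean decrease in accuracy,
one permutation per tree on its OOB sample) alongside Gini importance, and
per-prediction probabilities as the vote fraction of the predicted class.
Exact vote ties (possible with an even tree count) resolve to POS: in
photosafety screening a false alarm is cheaper than a miss, so sensitivity
outranks specificity at the margin. Feature selection takes the top-k
columns by permutation importance (Gini available as an alternative),
with ties broken deterministically by column index; both importance
measures are retained because they can rank differently, and
accuracy-based selection is the default.

Classification trees (rpart, cp configurable, 0.05 the documented choice
for dense descriptor blocks) provide the interpretable companion model;
`extractRules()` renders each leaf as the conjunction of its split
conditions. Y-scrambling retrains the forest on uniformly permuted labels
and records OOB accuracy per round — a valid model scores at chance on
scrambled labels while the intact model does not. SVM (radial kernel,
C = 500, γ = 0.004 defaults) and a small feed-forward network are optional
plug-ins; the network implements the fixed 250-250-8-4-1 ReLU/sigmoid
architecture trained with Adam (batch 36, learning rate 0.001, decay 1e-6,
binary cross-entropy, 100 epochs, random-normal initialization) natively in
R. The SVM exposes class output only — no calibrated probability — so it
does not participate in ROC or triage.

Evaluation statistics are computed from confusion counts at full precision
and displayed with half-away-from-zero rounding to two decimals (base R's
round-half-to-even would disagree with conventional table rounding at
values like 0.875). An MCC with a zero marginal is undefined and is
reported as 0 with an explicit flag rather than silently. The ROC sweep
thresholds at every distinct score, groups ties into single steps, and
integrates by trapezoid; the curve is anchored at (0,0) and (1,1).

## Triage and phototoxicity cross-evaluation

Triage selects misclassifications with vote probability *strictly* greater
than 0.8 (a prediction at exactly 0.8 is not "high confidence"). Each entry
is explained by the quality flags of its spectrum record and by a Tanimoto
similarity search against the training set: the top 3 neighbours at
similarity ≥ 0.7 are reported, and a neighbour carrying the label that
matches the wrong prediction is a `training_neighbor_conflict` — the model
plausibly generalised from that neighbour. The 0.7 floor and k = 3 reflect
the similarity range (0.70–0.99) at which such conflicts are typically
informative; both are configurable. Entries with no firing rule are
reported `unexplained` rather than force-fitted.

The phototoxicity module cross-tabulates the spectrum class against 3T3 NRU
outcomes with POS as the toxicity alarm: se_tox = P(POS | toxic),
sp_tox = P(NEG | non-toxic), concordance = toxic∧POS + non-toxic∧NEG.
Undefined rates (empty margin) are flagged, not zeroed. The module predicts
*spectrum features*, not toxicity; the cross-tab quantifies how far the
spectrum class alone carries as an alarm.

## The synthetic study generator

Licensed spectral databases cannot ship with a package, so the generator
emulates the statistical structure the pipeline assumes, with every draw
under one master seed:

* **Structures** from two template families — saturated scaffolds
  (alkanes, alcohols, amines, ethers, cyclohexanes; latent conjugation
  0–2) and conjugated scaffolds (substituted benzenes, styrenes,
  polyene-benzenes, naphthalenes, biphenyls, stilbenes, anthracenes;
  conjugation 6–14) — padded with alkyl tails so every structure is valid,
  standardizable and eligibility-clean. The family mix (36% saturated, the
  rest spread over the conjugated cores) targets an approximately balanced
  class distribution.
* **Spectra**: primary maximum λ = 175 + 17·conjugation + N(0, 12) nm — a
  transparent monotone stand-in for the chromophore-size/wavelength
  relationship, deliberately not an electronic-structure calculation — with
  log-normal MEC (log₁₀ mean 4.2 for conjugated, 2.6 for saturated, sd 0.5)
  and 0–3 secondary maxima at shorter wavelengths.
* **Corruptions**, each with retained ground truth: log-unit MEC recording
  (rate 0.02, applied only where all MECs lie in 10³–10⁵ so the artefact
  lands in the diagnostic [3, 5] band, as a real transcription error
  would), boundary displacement of the primary peak into 281–317 nm (rate
  0.05), and MEC deletion (rate 0.05).
* **Phototoxicity**: Bernoulli outcomes with P(toxic | POS) = 0.55 and
  P(toxic | NEG) = 0.25, reproducing the alarm asymmetry (sensitivity well
  above specificity) seen when spectrum class is used to predict assay
  outcome.

What passing tests on this fixture do show: the labelling rule, descriptor
contracts, forest machinery, triage logic and cross-tab arithmetic are
correct, and the learning problem they compose is solvable end to end. What
they do not show: real-data accuracy. The generator's chemistry space is a
few dozen template families, its structure→spectrum rule is noiseless apart
from Gaussian jitter, and solvent effects, band shapes and literature
curation noise are absent — so held-out accuracies on synthetic studies are
upper bounds with no claim of transfer to licensed-database scale.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run synthetic studies at 1,000
molecules (800/100/100 train/test splits), forests of 500 trees,
Y-scrambling at 5 rounds on the 250 most important fingerprint bits (the
reduced-model protocol), and 10,000-record labelling property sweeps —
sizes chosen so a complete run takes minutes on one CPU while keeping the
chance-level and learnability checks statistically meaningful. Wavelengths
and MECs are compared as floating point with no rounding anywhere in the
labelling path; all display rounding is half-away-from-zero at two
decimals; every stochastic routine takes an explicit integer seed and
derives per-stream sub-seeds from it, so pipeline reruns are byte-identical.

## Known limitations

* Standardization fidelity is bounded by the InChI normalization model;
  exotic tautomeric systems outside InChI's mobile-H perception will not
  collapse.
* Open Babel's ECFP4 bit assignment differs from other toolkits'
  Morgan/ECFP implementations; models and triage similarities are
  internally consistent but bits are not portable across toolkits.
* The Md functional form is one defensible realisation of its recipe;
  absolute bin positions are implementation-specific (the histogram
  contract, not bin identity, is the tested invariant).
* The SVM plug-in provides no probability calibration, and the MLP is a
  minimal trainer intended for the fixed architecture, not a general
  deep-learning backend.
* NEG labels derived from peak lists systematically understate in-window
  absorptivity near the 290 nm edge; the quality flags mark, but cannot
  correct, this censoring.
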