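---
title: "Modeling engineered disulfide bridges from backbone geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling engineered disulfide bridges from backbone geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Introducing a new disulfide bond into a protein — mutating two spatially
close residues to cysteine so that their Sγ atoms can bond — is a standard
route to improved thermal stability, locked conformations, and probes of
dynamics. Most candidate pairs fail: the covalent geometry of a cystine is
strict (S–S ≈ 2.04 Å, Cβ–Sγ–Sγ′ ≈ 104.9°, and a strongly bimodal χ3
torsion), and a pair that looks close in space may be unable to reach it
with any rotamer. `ssbridge` screens every residue pair in a structure for
geometric compatibility with a disulfide, scores each surviving candidate
with a torsional energy function, and ranks candidates for *stabilization*
with a B-factor mobility metric — three separable questions: can the bond
form, how native-like is its geometry, and is it bridging a flexible
region where cross-linking pays off.

## The geometric model

Only backbone atoms (N, Cα, C) are trusted. For every residue the β-carbon
is rebuilt at ideal tetrahedral geometry (1.53 Å from Cα, 110.5° to N and
C, L-chirality), so glycines, alanines and residues with missing side-chain
atoms are handled uniformly and the prediction never peeks at an existing
cysteine's sulfur — which is what makes blind validation against native
disulfides meaningful. (A `use_file_cb` flag reuses deposited Cβ atoms for
users who prefer that.) The file's Cβ *B-factor* is still used in the
mobility metric, where it is observational data, not geometry.

The chirality of the rebuilt Cβ follows real L-amino acids: under this
package's torsion sign convention (standard atan2 convention; the worked
example in `?dihedral` pins it down), the improper torsion N–Cα–C–Cβ of
L-residues in deposited structures measures about −122.5°, and
`construct_cbeta()` selects that branch.

A cysteine side chain modeled on a residue has one degree of freedom, χ1
(N–Cα–Cβ–Sγ); Sγ is placed at 1.81 Å from Cβ with a Cα–Cβ–Sγ angle of
114.6°. For a residue pair, the scan:

1. rejects pairs whose Cβ–Cβ distance is outside [3.0, 5.5] Å (no cystine
   geometry is reachable outside a band around ~4 Å; the interval is
   deliberately generous and configurable);
2. searches the χ1 × χ1′ torus on a 5° grid for poses bringing
   |d(Sγ, Sγ′) − 2.04 Å| to a local minimum, then refines each candidate
   local minimum by pattern search down to a step below 0.01°;
3. keeps poses with S–S deviation ≤ 0.2 Å, χ3 = Cβ–Sγ–Sγ′–Cβ′ inside a
   window (±10° around −87° or +97°), and both Cβ–Sγ–Sγ′ angles within 10°
   of 104.9°;
4. reports, per pair, the surviving pose of lowest energy.

All tolerances live in `scan_config()` and are user-adjustable stringency
settings, not constants; the defaults were chosen to admit near-native
geometry generously. Inter-chain pairs are always eligible; same-chain
pairs must be at least `min_seq_separation = 2` residues apart, because
(i, i+1) bridges are unreachable without severe strain (set 1 to disable).

### Numerical choices

The grid-plus-refinement search was chosen over a closed-form circle–circle
intersection because it is simple, robust to the angular constraints, and
directly checkable against a brute-force oracle: the test suite verifies
that a 1° exhaustive grid with refinement disabled accepts the same pairs
with energies within 0.05 kcal/mol. Candidate poses are the wrap-around
local minima of the S–S deviation over the grid, kept when within the
tolerance plus a slack bound of `4 r sin(step/4)` (r = the Sγ circle
radius), which is the largest displacement a half-step refinement can
recover; refined duplicates are merged at 0.02° resolution. Energy ties are
broken by proximity of χ3 to a window center, then by the lower χ1. Residues
with incomplete backbones are skipped with a warning, never a crash, and a
structure with fewer than two usable residues is an explicit error.

## The energy function

Each candidate is scored with a sum of non-negative strain terms
(kcal/mol, angles in degrees):

- **χ3 term**: `E(χ3) = 4.0 (1 − cos(1.957 (χ3 + 87)))`. Its minima within
  (−180°, 180°] sit at −87° and +96.96°, matching the bimodal χ3
  distribution of native disulfides; its maximum is 8 kcal/mol.
- **χ1 term** per residue: `1.4 (1 + cos 3χ1)`, zero at the canonical
  side-chain rotamers −60°, +60°, 180°.
- **angle term** per sulfur: `0.015 (θ − 104.9)²` on each Cβ–Sγ–Sγ′ angle.

The χ3 constants are the load-bearing, survey-calibrated part of the score.
The χ1 and angle terms are this package's reconstruction of the classic
rotamer/strain penalties used by backbone-threading energy models: a
threefold cosine with minima at canonical rotamers and a harmonic angle
restraint, with amplitudes chosen so that native-like bridge geometries
measured from deposited structures mostly score below ~2.2 kcal/mol (the
90th-percentile guideline for native disulfides). No χ2-dependent term is
included — the score is a function of the angles the scan actually models —
and every constant is exposed in `energy_params()` for recalibration. The
energy is a relative geometry-conformity score for ranking candidates, not
a ΔΔG prediction.

## The ΣB mobility metric and the color scale

Engineered disulfides that stabilize tend to bridge flexible regions. Each
residue contributes the arithmetic mean B-factor of its backbone and
β-carbon atoms; a pair's ΣB is the sum of the two means. The backbone set
is taken as {N, Cα, C, O} — whether the carbonyl O belongs in the average
is a judgment call; including it uses all four deposited backbone
B-factors, and the choice is documented here because other tools may
differ by a per-mille. Glycine contributes its backbone mean only.
B-factors are comparable only *within* a structure, so `bfactor_profile()`
reports the per-structure range and mean, and `colorize_bfactor()`
normalizes residue means to 512 discrete steps between the structure's
minimum and maximum: indices 0–255 on a blue (rigid) scale, 256–511 on a
red (mobile) scale. The midpoint rounds half-up, so an exactly-central
value lands on index 256 (red) — the tie had to fall somewhere and is
documented rather than normative. The mapping is monotone and invariant
under affine rescaling of all B-factors.

## The synthetic generator and what validation shows

`build_ideal_bridge()` inverts the kinematics: given χ1, χ1′, χ3 it
constructs two cysteines realizing those torsions exactly at ideal covalent
geometry, embedded in extended alanine flanks kept > 6 Å from the sulfurs
so they cannot generate additional candidates, with an SSBOND record and
optional seeded Gaussian coordinate noise. `build_survey_set()` draws χ3
uniformly from [−92°, −82°] ∪ [+92°, +102°] — the native bimodal clusters —
and χ1 from the canonical rotamers, at zero noise. The free χ2-like
torsions of the pose are fixed at typical native values (−86°, −75°);
they do not affect any modeled quantity.

`blind_validate()` scans structures with the sulfur positions hidden and
scores recovery (native pair predicted), χ3 chirality agreement (sign
match), the OLS regression of predicted on native χ3 over the
chirality-correct subset, and the pooled per-sulfur distance between
modeled and deposited Sγ positions. On 50 planted ideal bridges the
package achieves 100% recovery, 100% chirality agreement, R² = 1 and
median sulfur displacement at numerical precision; on the real lysozyme
structure shipped with bio3d (four native disulfides, two of which lie
outside the default χ3 windows — widened windows admit all four) it
reaches R² ≈ 0.997 and a median sulfur displacement of ≈ 0.12 Å. These
sizes (50 synthetic structures, one real structure) keep the full
validation under a few seconds while exercising every code path; they are
the package's test surface, not a claim about any particular survey
corpus.

What synthetic validation does **not** show: real backbones are not at
ideal internal coordinates, deposited structures carry alternate
conformations, missing atoms and refinement artifacts, and real engineered
bridges are subject to packing clashes the scan does not model. Perfect
synthetic recovery demonstrates internal consistency of the
generator/scanner pair and correctness of the kinematics; the real-structure
check demonstrates robustness to crystallographic geometry. Expectations on
arbitrary PDB files should be calibrated accordingly.

## Native-bridge extraction and survey filtering

`extract_native()` unions SSBOND-declared pairs with unannotated cysteine
pairs whose deposited Sγ–Sγ distance is below 2.5 Å, deduplicated.
`select_survey_set()` keeps structures with at least one native bridge and
a recorded resolution ≤ 2.0 Å (structures without a recorded resolution
are excluded and reported); sequence-redundancy filtering is left to the
caller, who should supply a pre-clustered list — the package ships no
alignment engine.

The per-sulfur distances are pooled over both sulfurs of each recovered
bridge, since a single summary distance does not dictate a pairing; each
modeled sulfur is compared with the deposited sulfur of its own residue.
The regression is computed over the chirality-correct subset only: a
sign-flipped χ3 is a different, well-separated failure mode, and mixing it
into the regression would measure the failure rate twice.

## Other design decisions

- **Alternate locations** resolve to the highest-occupancy conformer, ties
  to the alphabetically first identifier — deterministic single-conformer
  input, standard practice.
- **HETATM** records are skipped except selenomethionine (MSE), which is
  parsed as methionine with its Se occupying the SD slot; hydrogens are
  dropped (the model uses heavy atoms only).
- **Residue identity** is the triple (chain, number, insertion code),
  preserved verbatim; PDB numbering is not an index.
- **Native cysteines** are scanned like any residue and flagged
  `is_native`, which is exactly what the blind-validation protocol needs;
  in mutant export a selected native cysteine is re-posed (its Sγ moved to
  the modeled position) with a warning.
- **Mutant export** truncates mutated residues beyond Cβ, constructs a Cβ
  for glycine, writes Sγ at the modeled coordinates with occupancy 1.00
  and the Cα B-factor, and emits SSBOND records for each engineered pair;
  untouched residues are written verbatim and the output re-parses
  losslessly to the PDB format's 0.001 Å.
- **No file-size limit**: upload caps belong to web servers, not
  algorithms.

## Known limitations

No clash detection against surrounding side chains; no multi-bridge joint
optimization; no loop-length or ΔΔG stability scoring; no mmCIF input; the
energy constants other than the χ3 term are plausible reconstructions, not
survey-fitted values, and users calibrating against a reference corpus
should adjust `energy_params()` accordingly.
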