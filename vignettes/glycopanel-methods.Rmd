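---
title: "Methods: models, parameters and design choices in glycopanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in glycopanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycopanel)
```

# Scope and assumptions

`glycopanel` models the computational half of an absolute-quantitative
MALDI-TOF glycomics workflow for three glycomes measured in parallel from
cultured cells: N-glycans (released enzymatically, aoWR-labeled by
glycoblotting with on-bead methyl esterification of sialic acids),
O-glycans (released and bis-PMP-labeled by β-elimination in the presence
of pyrazolone), and GSL glycans (released from glycosphingolipids,
aoWR-labeled like N-glycans, with a no-enzyme negative control). Everything
upstream of a centroided monoisotopic peak list — instrument control,
calibration, isotope-pattern peak picking — is out of scope: the package
assumes vendor software has already reduced spectra to `(m/z, area[, S/N])`
rows.

Three assumptions carry the quantitative model:

1. **Singly protonated ions.** Both labels confer high proton affinity, so
   all species are treated as `[M+H]+` (charge 1).
2. **Mass-independent response above ~1 kDa.** Peak area is taken as
   proportional to molar amount, which holds for labeled oligosaccharides
   above roughly 1000 Da; species below that threshold are still
   quantified but flagged `low_mass`, since their amounts may be
   underestimated.
3. **Complete derivatization.** Labeling and (for aoWR) sialic-acid methyl
   esterification are modeled as quantitative; partial esterification is
   not represented.

# Mass model

All masses derive from one elemental table (monoisotopic C, H, N, O and the
proton). Residue masses are dehydro (in-chain) values computed from
molecular formulas — Hex C₆H₁₀O₅, HexNAc C₈H₁₃NO₅, dHex C₆H₁₀O₄, Neu5Ac
C₁₁H₁₇NO₈, Neu5Gc C₁₁H₁₇NO₉ — and label deltas are likewise derived at
build time (aoWR C₂₀H₂₉N₇O₅ minus one water for the oxime condensation;
two PMP units C₁₀H₁₀N₂O minus one water for the bis-adduct) rather than
hard-coded as decimals. Methyl esterification adds one CH₂ per sialic
residue under the aoWR scheme only. m/z is carried at full precision and
rounded to one decimal for display.

Compositions are restricted to the five kinds above; sulfation,
phosphorylation and acetylation are unsupported. Only these five are needed
to represent every species in the shipped database.

One deliberate discrepancy is worth recording: the conventional printed
value for the globo-series diagnostic Y-ion of (Hex)₅(HexNAc)₂ is
m/z 934.9, but the monoisotopic Hex₃ + aoWR fragment computes to 934.4
(934.9 matches the average mass). The package stores and reports the
computed monoisotopic value; MS2 isomer resolution is therefore built on
candidate-unique ladder entries rather than on any fixed printed number.

# Composition search

`enumerate_candidates()` scores every composition inside configurable
per-kind count bounds (defaults Hex ≤ 15, HexNAc ≤ 12, dHex ≤ 6,
Neu5Ac ≤ 8, Neu5Gc ≤ 4) against the query m/z and keeps those within the
tolerance (default ±0.5 Da, boundary inclusive). The grid is materialized
once per bounds vector and cached, which makes the search exhaustive by
construction — no pruning shortcut can skip a boundary case. The defaults
are echoed into output headers because no standard bound set exists; they
comfortably cover every species in the database.

Ranking needed two numerical decisions:

* **Error quantization.** Hex + Neu5Ac and dHex + Neu5Gc have identical
  elemental formulas, so distinct compositions can have *exactly* equal
  masses while their floating-point evaluations differ in the last bits.
  Absolute errors are quantized to 1e-6 Da before ordering (the smallest
  nonzero mass gap between distinct compositions in the default grid is
  0.0126 Da, float noise is ~1e-12), so true ties compare as ties.
* **Tie direction.** Ties break toward fewer residues, then *descending*
  lexicographic counts. Descending matters: ascending order would rank the
  dHex/Neu5Gc twin of every sialylated glycan above the biosynthetically
  common hexose-rich form and no exact-m/z lookup of a sialylated species
  would return itself first.

`annotate_peaklist()` optionally restricts candidates to compositions with
a database record (`require_db_hit`). This mirrors a compositional
database search, and it is what makes annotation robust under m/z jitter:
without it, the chemically implausible penta-fucosyl near-isobar 0.025 Da
from (Hex)₅(HexNAc)₂ outranks the true composition whenever jitter exceeds
~0.013 Da. One composition may match several structures; annotation never
guesses one — ambiguity is preserved for the MS2/digestion evidence layer.

# Quantification

With internal-standard area $A_{IS}$ and spiked amount $Q$ pmol,
$\text{amount} = (A/A_{IS})\cdot Q\cdot(100/\text{protein µg})$ in
pmol per 100 µg protein. The standards are A2GN1
(Hex₅HexNAc₃Neu5Ac₂) for N- and GSL-glycans and "GN4" for O-glycans; since
GN4's exact identity is not standardized, it is a configurable composition
defaulting to HexNAc₄. Spiked amounts are free metadata.

Control subtraction (GSL only) operates on amounts, not areas, so sample
and control may have different internal-standard recoveries; per
composition the amount is clipped at zero and flagged
(`control_subtracted` / `excluded_in_control`). Replicate dispersion
follows reporting convention by n: sample SD (n ≥ 3), half-range tagged
`"range/2"` (n = 2), zero tagged `"single"` (n = 1); a glycan absent from
a replicate is a true zero (detection-limit semantics), not missing data.

# Structural taxonomies

**N-glycans.** PM (pauci-mannose): HexNAc = 2, Hex ≤ 3, dHex ≤ 1, no
sialics; HM (high-mannose): HexNAc = 2, Hex 4–12, no dHex or sialics
(Man₄ counts as HM); CH: everything else. No published boundary exists for
the PM/HM split; this is the common convention and `n_taxonomy()` makes it
overridable. Antennarity is HexNAc − 2 clamped to 1–4 — a bisecting GlcNAc
inflates it, so the bisect flag is reported alongside for discounting.

The composition *signatures* are interpretive. "Contains Hex₂HexNAc₃ or
Hex₃HexNAc₄" taken literally as a componentwise subset would flag nearly
every complex glycan; instead the invariant Hex₃HexNAc₂ core is removed
(ignoring fucose and sialics) and the bisect signature requires the
periphery to *equal* Hex₂HexNAc₃ or Hex₃HexNAc₄, while the tetra-antennary
signature requires it to *dominate* Hex₄HexNAc₄ componentwise (and the
bisect test to have failed). This reading reproduces the canonical
bisected (e.g. Hex₅HexNAc₅) and tetra-antennary (Hex₇HexNAc₆)
compositions; both signature sets are configurable.

**GSL glycans.** Hex₂ alone is the lactosylceramide glycan. Otherwise the
series call is the consensus of isomeric database hits: one series →
unique (`db_unique`); hits spanning ganglio/(neo)lacto or
globo/(neo)lacto → the explicit ambiguity classes `Gg-or-nLc` /
`Gb-or-nLc`, resolvable only by MS2 signature ions or digestion evidence.
The shipped database deliberately omits asialo Gg₃/Gg₄ so the
(Hex)₃(HexNAc)₁ isomer set is exactly {Gb4, nLc4}.

**O-glycans.** Cores from the (Hex, HexNAc) backbone ignoring sialics:
(0,1) Tn; (1,1) core 1; (1,2) core 2 (the branch is diagnostic even
ungalactosylated); (2,2) ambiguous between core 2 and extended core 1
unless β-galactosidase evidence is supplied — a degraded parent
("parent lost") implies the branched core 2, survival implies the linear
extended core 1.

# Fragmentation and digestion

Only Y-type fragments (reducing-end- and label-retaining, single
glycosidic cleavage) are modeled; B/C/X/A ions and double cleavages are
not needed for composition-level isomer logic. A structure's ladder has
one entry per bond. MS2 resolution keeps, per candidate, the *diagnostic*
ions — ladder entries farther than the tolerance from every other
candidate's ladder — and calls the candidate(s) whose diagnostic ions are
observed; both → `mixture` with per-candidate areas, none → `unresolved`,
identical ladders → a refusal (`indistinguishable`) rather than a guess.
Note that distinguishability can be one-way: the core 2 ladder is a subset
of the extended-core-1 ladder, so core 2 can only be implicated by
digestion (which is exactly how the workflow treats it); similarly GM1b
and sialyl-nLc4 share identical composition ladders and are separated by
digestion, not MS2.

Digestion is modeled as complete: an enzyme (a set of removable
(residue, linkage) termini, shipped as editable YAML — α2,3-neuraminidase,
β1,3-, β1,4- and β1-3,6-galactosidase) repeatedly removes cleavable
non-reducing leaves, pass by pass, so a residue uncovered in one pass is
removable in the next; amounts are conserved onto products. The α2,6
sialic-acid proportion is then
$100\cdot\sum(\text{post}\times s)/\sum(\text{pre}\times s)$ over
sialic-acid-weighted amounts, which assumes complete removal of α2,3
linkages — partial-digest kinetics are out of scope.

# Stage profiling

Fold changes across consecutive stage transitions are binned into arrows:
↓↓↓ [0, 0.2), ↓↓ [0.2, 0.5), ↓ [0.5, 0.75), → [0.75, 1.25],
↑ (1.25, 2], ↑↑ (2, 5], ↑↑↑ (5, ∞). The published ranges overlap at their
ends, so boundary placement is a decision: each boundary belongs to the
milder symbol (→ claims both 0.75 and 1.25; a fold of exactly 2 is ↑).
Zero baselines extend the scheme with `new` (0 → positive) and `absent`
(0 → 0) to avoid infinite folds. Both choices are configurable only by
post-processing the numeric fold matrix, which is always exported next to
the symbols.

Clustering uses uncentered Pearson correlation distance
$1 - \sum x y/\sqrt{\sum x^2 \sum y^2}$ with average linkage — the
defaults of the classic Eisen-style clustering tools — on untransformed
absolute amounts; a zero-norm column takes similarity 0 to everything.
Metric (uncentered / centered Pearson / Euclidean) and linkage are
options, because the original tool's exact settings for this kind of
figure are typically unstated; the choice is recorded in the result
object. Agglomeration itself is delegated to `stats::hclust`, and the test
suite checks it against a brute-force re-implementation of average-linkage
merging.

# The synthetic generator

`panel_spec()` plants a ground truth: per glycan, a base amount
(pmol/100 µg) and one positive (or exactly-zero) multiplier per stage
transition; stage amounts are cumulative products, replicates are
identical before noise. `render_peaklist()` renders each sample as a peak
list: m/z gets Gaussian jitter (default SD 0.05 Da, a tenth of the search
tolerance); area is proportional to picomoles deposited with
*multiplicative log-normal* noise (default CV 5 %), reflecting how MALDI
area variability scales with signal (a normal alternative is available by
setting the CV to zero and post-processing); contaminant peaks (default 5)
are uniform over the recorded m/z range; dropout is off by default; the
internal standard is never dropped. All randomness flows from one explicit
seed, and the caller's RNG state is restored afterwards.

`example_gsl_panel_spec()` is an illustrative five-stage GSL story — a
transient GD3 spike (×16) and LacCer rise (×7) at the first transition, a
ganglio-to-globo switch over the next two with an SSEA-4/globo spike at
the third, and a (neo)lacto surge (×16) at the last — with 17 glycans at
amounts between 0.2 and 60 pmol/100 µg, typical of cellular MALDI
glycomics. It is a phenomenological emulation, not a reproduction of
measured values.

What the generator does *not* emulate bounds what green tests can claim
about real data: no isotope envelopes or profile-mode peaks, no
ion-suppression or matrix-cluster chemical noise, no mass-dependent
response roll-off below 1 kDa (the flag is metadata, not a correction),
no partial digestion, and contaminants are uniform rather than chemically
structured. Recovery results on synthetic panels therefore validate the
bookkeeping — search exhaustiveness, ratio arithmetic, conservation,
determinism — not instrument physics.

# Problem sizes and numerical tolerances

The test suite exercises: exhaustive-search equivalence against a naive
quintuple-loop enumerator on 1000 random m/z per scheme over the ~65,000
composition grid; 50-seed noisy recovery on the 17-glycan panel (jitter
0.05 Da, CV 5 %, 5 contaminants) requiring 100 % re-annotation and median
relative quantification error under 10 %; clustering equivalence on 100
random 6 × 20 matrices; and exact (1e-9 relative) round trips for
noiseless quantification, digestion conservation and α2,6 recovery. These
sizes keep the full suite under a minute on one core while leaving each
property no room for coincidence.

# Known limitations

* MS1 composition assignment cannot separate isomers; everything
  structure-level flows through the database, MS2 ladders or digestion.
* The five-residue alphabet excludes modified glycans (sulfo-, phospho-,
  acetyl-).
* Negative-ion mode, multiply charged species and retention/mobility
  evidence are out of scope.
* Arrow bins are descriptive summaries; no statistical test is attached
  to fold changes, and clusters carry no bootstrap support.
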