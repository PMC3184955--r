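---
title: "Methods: chemical-shift structural inference for amelogenin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemical-shift structural inference for amelogenin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amelnmr)
```

`amelnmr` turns the per-residue observables of a solution-NMR study of an
intrinsically flexible, self-assembling protein — chemical shifts, scalar
couplings, heteronuclear NOEs, NOE connectivities, HSQC peak positions
and AUC mass distributions — into secondary-structure calls, assembly
maps and a coarse nanosphere model. This vignette documents the models,
the tunable parameters and their defaults, what the synthetic generators
do and do not emulate, and the design decisions taken where the
underlying methodology leaves choices open.

## Secondary chemical shifts

The zero point of the analysis is a per-amino-acid reference table of
average CA/HA/N/HN shifts (ppm). Throughout the package the sign
convention is fixed numerically:

$$\delta C\alpha = C\alpha_{\text{obs}} - C\alpha_{\text{ref}},\qquad
  \delta H\alpha = H\alpha_{\text{obs}} - H\alpha_{\text{ref}}.$$

All logic is keyed to the numeric sign and thresholds, never to
"upfield/downfield" vocabulary, which is ambiguous between nuclei.
Missing assignments propagate as missing values — never as zeros — since
a flexible protein routinely has unassignable residues (prolines have no
backbone amide at all).

The packaged reference table (`load_reference_shifts()`) is a static
snapshot of database-average values; such statistics drift across
database releases, so the exact numbers are treated as configuration.
Tests inject a synthetic reference table and never depend on the
snapshot.

**Pre-proline rule.** A residue immediately preceding a proline with
$\delta C\alpha < -1.5$ ppm (`threshold_ppm`, config-exposed) is flagged:
proline's ring nitrogen perturbs its predecessor's Cα shift strongly in
the negative direction regardless of conformation, and in practice
nearly all strongly negative δCα values in a proline-rich protein sit
before prolines. Flagged residues are excluded from conformational
interpretation of δCα but are *not* censored from the data.

**Plateau detection.** Helix-like structure appears as a sustained run
of $\delta C\alpha \ge$ `ca_min` (+0.7 ppm) and $\delta H\alpha \le$
`ha_max` (−0.05 ppm) over at least `min_length` (4) residues. The
published analyses report plateaus qualitatively; these cutoffs make the
call testable and are exposed as arguments. Two tolerances reflect how
plateaus behave in proline-containing helical regions: (i) at most one
interior residue per run may fail either cutoff (a single proline
interruption does not split a helix call), applied greedily left to
right so each reported segment contains at most one tolerated failure;
and (ii) pre-proline-flagged residues are exempt from the δCα cutoff,
because the sequence effect drives their δCα negative even inside a
helix. Without exemption, PXX-repeat regions would veto genuine calls.

**Composite deviation.** For comparing observed shifts against
back-predicted shifts the scalar
$\xi = \sqrt{(\Delta\delta HN^2 + \Delta\delta C\alpha^2/4 +
\Delta\delta N^2/25)/3}$ weights each nucleus by its typical dispersion
(factors 2 and 5 on Cα and N). It is non-negative, zero only at exact
agreement, symmetric under sign flips and monotone in each $|\Delta|$.

## Dynamics and NOE evidence

* **³J(HNα)**: values below 7 Hz are `helix_compatible`, at or above 7 Hz
  `extended`. The boundary is assigned to `extended` — a deterministic,
  documented tie-break.
* **Heteronuclear NOE**: the two regimes seen in flexible proteins
  (≈ 0.6 rigid backbone, ≈ 0.3 and below flexible) are separated at
  `rigid_min = 0.45`, the midpoint; the boundary value counts as rigid.
  No numeric cutoff is standard in the literature, so this is a package
  decision, config-exposed. Inputs outside the physical range
  [−1.5, 1.1] are rejected.
* **NOE distance bins**: strong/medium/weak intensities map to 2/4/6 Å
  upper bounds, the manual-classification convention of restraint-based
  structure calculation.
* **Connectivity tabulation**: records are keyed by unordered residue
  pair and class (dNN/dαN/dβN); symmetric duplicates collapse, and
  conflicting intensity bins for the same pair keep the strongest
  (shortest bound) — the conservative restraint, mirroring manual
  practice. Separation categories are $|j-i| = 1, 2, 3$ and $\ge 4$
  (long); counts accumulate at the lower residue index.

## Consensus secondary-structure calls

`call_secondary_structure()` is a deliberately transparent rule cascade,
not a trained model: its testable surface is planted-truth recovery on
synthetic data, not atom-level accuracy. In order:

1. **alpha** — inside a shift plateau with a helix-compatible coupling
   *or* an (i,i+3) NOE; never on a missing δCα unless NOE contacts vouch
   for the residue.
2. **three_ten** — a 2–3 residue run of helix-like δCα without (i,i+3)
   support, flanked by coil. True 3₁₀-helix assignment requires
   calculated structure; this rule is documented as a surrogate.
3. **ppii** — in a proline-rich window (≥ 2 prolines in 5 residues) with
   pre-proline flags within 3 residues and no helix evidence (no plateau,
   no (i,i+3) NOEs). Small J couplings alone are *not* counted against
   PPII, whose couplings are poorly dispersed.
4. **turn** — a 3–5 residue gap between two alpha segments with
   (i,i+2) support.
5. **coil** otherwise.

Confidence counts the agreeing evidence channels (0–4). All window sizes
and thresholds are explicit arguments.

**Fragment stitching.** Overlapping construct tables are mapped into
full-length numbering by per-construct offsets (Amel-N 0, Amel-M 33,
Amel-C 85 for the 1–92 / 34–154 / 86–180 fragment design). Overlap
values agreeing within per-atom tolerances (0.2 ppm for carbons and
nitrogen, 0.02 ppm for protons) are averaged; disagreements are flagged
and resolved by keeping the value from the fragment in which the residue
lies farther from a construct terminus, since terminal residues are the
most perturbed by tags and truncation. Differing amino-acid identity in
an overlap is a hard error (misaligned offsets). Stitching is
commutative in fragment order and idempotent. His-tag leader residues
are stored at indices ≤ 0 and excluded from analyses by default.

## PPII geometry

Backbone dihedrals use the standard four-atom torsion with angles in
(−180°, 180°]; termini and chain breaks carry missing values. Chains are
segmented wherever the consecutive CA–CA distance leaves [2.8, 4.2] Å.

Local helix parameters come from sliding windows of 5 CA positions. The
axis direction is estimated from the bond-difference construction: with
bonds $d_i = CA_{i+1}-CA_i$, the curvature vectors $a_i = d_i - d_{i-1}$
point radially toward the helix axis, so successive cross products
$a_i \times a_{i+1}$ recover the axis direction; the sign is fixed along
chain propagation. Rise per residue is the mean axial bond advance;
twist is the mean signed rotation of successive bond projections about
the axis, with residues per turn $= 360/|\text{twist}|$ and handedness
the sign of the twist (positive = right-handed, looking along the
propagation direction). A total-least-squares axis would be an
acceptable alternative; the bond-difference axis is fixed here and
verified in tests against a brute-force grid search over axis
orientations (agreement within 2% on ideal chains). Collinear and
planar-zig-zag windows (the 2-residue-repeat limit, e.g. a fully
extended chain) are flagged degenerate with undefined handedness.

PPII segments are maximal runs in which every covering window is (i)
left-handed with (ii) residues per turn in [2.6, 3.4] and (iii) rise in
[2.8, 3.4] Å, at least 4 residues long. Per-segment means are reported
with the per-turn length `3 × mean rise` (a 3-residue turn); whether
published per-segment turn lengths are whole-segment or per-window
averages is generally unstated, and this package reports segment means.
Canonical builder dihedrals are PPII (−75°, +145°), α (−57°, −47°), 3₁₀
(−49°, −26°), all trans peptide bonds — the conventional ideal values,
config-exposed because "ideal polyproline helix" is invoked in the field
without numbers. In an ideal PPII helix, residues i and i+3 are related
by one full turn, so proline ring planes one turn apart are co-oriented;
`proline_ring_alignment()` folds the normal-plane angle into [0°, 90°]
and calls ≤ 30° aligned.

## Assembly mapping (CSP)

Peaks of the monomeric fragment are matched to the assembled-protein
spectrum inside a tolerance box of 0.2 ppm (¹⁵N) × 0.02 ppm (¹H), the
empirical reproducibility of well-resolved amide peaks between such
spectra. The distance is the larger tolerance-normalised offset, and
one-to-one matching is greedy in ascending distance: HSQC peak lists of
well-resolved amides are sparse, and tests enforce equality with an
exhaustive optimal assignment on small instances. A fragment peak with
no counterpart is `lost`; a retained peak whose intensity ratio
(full/fragment) falls below `reduced_ratio_max = 0.3` is "dramatically
reduced". Lost or reduced residues are classified assembly-involved;
the 0.3 cutoff is a package decision (no published number exists) and
is config-exposed. Without recorded heights the classification degrades
gracefully to presence/absence. The same matching underlies
`interaction_test()`, which reports residues whose peaks move beyond
tolerance or vanish between two spectra of the same construct.

## Stoichiometry and the nanosphere model

Oligomer counts are the mass quotient rounded half-away-from-zero (the
literature's own worked example, 1046.4/26.1 = 40.09 → 40, does not
discriminate rounding conventions; this one is fixed and documented).
The assembled fraction is the share of total reported c(s) signal in
peaks of n ≥ 2. Upstream c(s) fitting is out of scope: peak masses and
fractions are consumed as input.

The nanosphere model is geometric, not energetic: n = 50 copies (the
major assembly peak mass over the monomer mass) of an 11.9 nm rod-shaped
monomer are placed radially on a sphere of outer diameter 30 nm (the
hydrated-state diameter; 25 nm is accepted via argument), C-termini at
the outer surface and N-termini facing the hollow interior, encoding
N-terminal ipsilateral assembly. Placement directions follow a
deterministic spherical Fibonacci lattice — the arrangement of molecules
on the shell is not specified by any measurement, and the lattice gives
reproducible quasi-uniform coverage without randomness. The cavity
radius is `outer/2 − rod length` (3.1 nm at defaults). Inter-copy bead
clashes below 0.4 nm are reported, never silently repaired. The rod has
18 beads by default, labelled with the four functional domains (TRAP
1–45, coil 46–125, PXX 126–164, C-terminal 165–180) proportionally to
their residue spans.

## Synthetic data: what it does and does not emulate

The generators (`segment_spec`, `make_shift_table`, `make_evidence`,
`make_helix_coordinates`, `make_peak_pair`) are pure functions of
(spec, seed): they save and restore the session RNG. Default effect
sizes are calibrated to the magnitudes reported for helical and
proline-rich regions of amelogenin-like data: helix δCα +2.5 ppm with
δHα −0.3 ppm, pre-proline δCα −2.5 ppm, J regimes 5 ± 1 Hz (helix)
versus 7.5 ± 0.8 Hz (other), hNOE 0.6 ± 0.05 (rigid) versus 0.3 ± 0.1
(flexible), shift noise σ(Cα) = 0.3 ppm and σ(Hα) = 0.03 ppm.
Sequential (i,i+1) NOEs appear chain-wide; (i,i+3) NOEs only inside
alpha segments. The default 180-mer test sequence reproduces the domain
*layout* of mouse amelogenin (helix-prone N-terminus, His/Gln-rich
centre, P-X-Q repeats, charged tail) but is not the real sequence, which
the package does not require.

The generators emulate state-conditional means and Gaussian noise with
planted, non-overlapping segments. They do **not** emulate spectral
overlap, assignment ambiguity, missing-at-random assignments, chemical
exchange, spin diffusion or relaxation physics. Passing recovery tests
therefore demonstrates that the inference rules invert the generative
assumptions at realistic effect sizes — not that they would perform
identically on real spectra, where the hard part (assignment) is
upstream of this package.

Test problem sizes were chosen to make sampling statements stable while
keeping the suite fast: 1000 residues for threshold-accuracy checks,
10 × 1000 residues for the false-involvement rate under jitter at a
quarter of the matching tolerance, 10,000 draws for generator
regime-mean checks, and 200 seeded constructs (~60 residues each, one
alpha, one 3₁₀, one PPII segment) for classifier parameter recovery,
where per-residue accuracy ≥ 90% and segment boundaries within one
residue for ≥ 80% of segments are required.

## Known limitations and recorded discrepancies

* The classifier is a surrogate for restraint-based structure
  calculation; 3₁₀ and turn calls in particular are heuristic.
* Chemical-shift re-referencing is out of scope: inputs are assumed
  DSS-referenced.
* Published helix spans for this system disagree between sources (e.g.
  an abstract-level T21–P33 versus a figure-level K24–I30 for the second
  helix; a PPII span of 118–165 versus a PXX domain of 126–164). Domain
  defaults here follow the four-domain table (1–45 / 46–125 / 126–164 /
  165–180); the discrepancies are inherent to the source data and are
  surfaced, not resolved.
* One published stoichiometry statement ("an additional 10 molecules"
  from a 1240 kDa minor peak) is not reproducible from the printed
  masses (1240/26.1 ≈ 47.5); the package implements only the
  well-defined quotient rule.
* The pre-proline rule has a documented borderline case: a pre-proline
  residue at −0.79 ppm fails the −1.5 ppm threshold by design; softening
  the rule would trade specificity for sensitivity and is left to the
  `threshold_ppm` argument.
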