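---
title: "Protein Block flexibility analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protein Block flexibility analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbflex)
```

## The model

Protein Blocks (PBs) are a structural alphabet: 16 prototypes of local
backbone conformation, labelled *a*–*p*, each defined by eight reference
dihedrals over a five-residue window centred on the assigned residue —
ψ(i−2), φ(i−1), ψ(i−1), φ(i), ψ(i), φ(i+1), ψ(i+1), φ(i+2). PB *m* is the
α-helix core and *d* the central β-strand; *a*–*c* are strand N-caps, *e*–*f*
strand C-caps, *k*–*l* helix N-caps, *n*–*p* helix C-caps, and *a*–*j*
populate coils. The reference table ships as a versioned data file
(`inst/extdata/pb_reference_angles.tsv`) whose header records its
provenance; it is the package's single external constant.

A residue in a frame is assigned the letter whose reference window is
nearest in **angular RMSD**: √(⅛ Σⱼ wrap(θⱼ − refⱼ)²), where `wrap` is the
minimal signed angular difference (360° wraparound). This is the historical
assignment convention; the per-window dissimilarity is exposed as
`pb_distances()` so tests can probe margins directly. Exact ties are broken
alphabetically — a measure-zero event on real data, but determinism matters
for reproducibility. Positions whose window is incomplete (the first two and
last two residues of a chain, or any window containing an undefined
dihedral) receive the sentinel `Z` and are excluded from every downstream
denominator; `Z` is never a 17th category.

Per position, the letter distribution **f** over the assignable frames gives

* `Neq = exp(−Σ fₓ ln fₓ)` — the equivalent number of PBs (natural log,
  0·ln 0 = 0), ranging from 1 (one conformation) to 16 (uniform);
* flexibility classes: Neq > 8 *disordered*, 6 < Neq ≤ 8 *highly flexible*,
  3 ≤ Neq ≤ 6 *flexible*, Neq < 3 *rigid*. The literature describes the
  flexible regime loosely as "around 4"; the explicit [3, 6] band is this
  package's choice of a sharp, testable boundary.

Between two systems A and B at one position,

* `ΔPB = Σₓ |fₓ^A − fₓ^B|` — an L1 distance in [0, 2], symmetric and
  triangle-inequality-satisfying (property-tested), with the per-letter
  terms also reported so statements like "an 80% shift on PB *h*" fall out
  directly;
* `ΔNeq = |Neq_A − Neq_B|`.

Positions with ΔPB > 1 (default) are flagged divergent. The **long-range
call** is deliberately simple: flagged positions are *local* when within ±5
residues of the mutation site, *distant* otherwise, and the headline boolean
is true when a distant position is flagged while the site's own ΔPB stays
below 0.2. The source analyses reason qualitatively about "distant" and
"stable"; the ±5-residue window and the 0.2 bound are this package's
documented defaults, both configurable. The 0.2 bound sits above the
site-stability values the motivating analyses report (ΔPB 0.02–0.07) and
well below the flag threshold.

## Geometry

Backbone dihedrals use the standard four-point torsion (atan2 form, IUPAC
sign, range (−180°, 180°]); the suite cross-checks it against an independent
torsion implementation (`bio3d::torsion.xyz`) and against Biopython-verified
reference cases. φ of the first residue and ψ of the last do not exist and
are `NA` throughout.

RMSD and RMSF operate on Cα atoms. RMSF superposes every frame onto the
ensemble-average structure with one Kabsch pass (via `bio3d::fit.xyz`),
recomputes the mean once, then takes √⟨‖xᵢ − ⟨xᵢ⟩‖²⟩ per atom. The fitting
reference is configurable (`"mean"` default, `"first"` frame optional)
because trajectory tools differ and the convention is rarely stated.
RMSD is recomputed at full precision from the fitted coordinates rather
than taken from `bio3d::rmsd`, which rounds to three decimals. A
configurable burn-in discards leading frames before all statistics
(default 0 for synthetic input; MD protocols typically discard the first
nanoseconds). Units are explicit (Å default, nm on request) rather than
assumed. B-factors for side-by-side comparison use the isotropic relation
B = (8π²/3)·RMSF². Contact persistence is the fraction of frames in which
the minimum site–partner distance is ≤ cutoff; the default 3.0 Å suits
ion–oxygen coordination, and no universal value exists, so it is a
parameter.

## The synthetic generator

`generator_spec()` describes ground truth: a residue range, a target
16-vector of PB frequencies per position, frames per replicate, replicates,
dihedral noise σ, mode and seed. Defaults mirror the sampling design of the
MD campaigns this analysis style is used on: 11 independent replicates and
100 ps frame spacing; σ defaults to 10°. Three modes:

* **string** — letters drawn i.i.d. from each position's target; the exact
  recovery surface. Replicate r uses seed + (r − 1), so pooled runs are
  reproducible and each replicate is independently regenerable.
* **geometry** — each residue's (φ, ψ) set to the drawn letter's *central*
  reference angles plus wrapped Gaussian noise. Because adjacent PB windows
  share dihedrals, arbitrary per-position mixtures are not simultaneously
  realisable; exact assignment recovery is guaranteed only for locally
  consistent label paths (homogeneous segments) at σ = 0, and degrades
  gracefully with σ (property-tested: ≥ 95% recovery of a homogeneous
  β-strand at σ = 10°).
* **coordinate** — geometry mode realised as an actual backbone (N, CA, C)
  via sequential natural-extension (NeRF) chain building with ideal bond
  lengths/angles (N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å; N–CA–C 111.2°,
  CA–C–N 116.2°, C–N–CA 121.7°) and trans peptides (ω = 180°). Building and
  measuring are exact mutual inverses to < 1e-4° in-memory; through a PDB
  file the limit is the format's 0.001 Å coordinate precision.

`inject_variant_effect()` produces a WT/variant spec pair differing only in
one *distant* position's distribution — the canonical fixture for the
long-range call, since the ground-truth answer (exactly that position, site
stable) is known by construction. What passing these tests shows is that the
statistics and the decision rule are implemented correctly; it does **not**
show that real MD ensembles satisfy the generator's assumptions
(i.i.d. frames, no autocorrelation, no window coupling beyond the letter
draw), so effect sizes on real trajectories remain the analyst's judgement.

## Numerical choices and degenerate inputs

* Angles live in (−180°, 180°]; −180° normalises to +180°; all differences
  go through the minimal signed arc.
* Profile rows must sum to 1 within 1e-6 or `neq()`/`delta_pb()` refuse;
  positions with zero assignable frames are flagged empty and excluded,
  and positions with fewer than 10 counted frames (configurable) are marked
  low-confidence.
* A constant track makes a Pearson correlation undefined; it is reported as
  `NA` with a warning, never silently coerced.
* A single-frame ensemble yields an all-zero RMSF with a warning rather
  than an error, so pipelines over degenerate inputs fail loudly but late.
* Multi-model PDB reading pre-scans MODEL blocks and rejects inconsistent
  atom counts naming the first offending model; insertion codes are
  rejected; only the first alternate location is kept.
* All output writers use fixed 6-decimal formatting, so identical inputs
  produce byte-identical files; report JSONs embed the configuration and an
  md5 provenance hash.

## Problem sizes in the test suite

Sampling-based checks use 10,000-frame string-mode ensembles (frequency
recovery within 0.02, Neq within 2% of the analytic target), 1,000-frame
geometry-mode ensembles for noisy assignment, 500-frame Gaussian ensembles
for the RMSF ≈ σ√3 law (5% band, 80–100 atoms so the ~6 fitted degrees of
freedom bias the fluctuation by well under 1%), and 2,000-frame end-to-end
comparisons. These sizes put the sampling error comfortably inside each
assertion band while keeping the full suite under a minute.

## The region registry

The integrin αIIb leg coordinates (author numbering, inclusive) are stored
as printed in the literature: Thigh 452–602, Calf-1 603–743, Calf-2 744–959,
all 9 Calf-1 and 10 Calf-2 loops, and the two modelled Calf-2 loops
(763–775, 840–873). Two source inconsistencies are preserved rather than
corrected: Thigh is quoted as "216 residues" though its interval spans 151
(`region_length` reports 151 and the note records the conflict), and Calf-2
is elsewhere quoted as ending at 952 (the registry follows the 744–959
definition, whose length matches its stated 216). `annotate_positions()`
maps a residue to its most specific region, preferring the canonical
numbered loops over the modelled-region aliases where they overlap.

## Known limitations

* PB assignment is per-frame and per-position; no probabilistic smoothing
  across frames or neighbouring windows.
* No significance testing on ΔPB — the flag threshold is a descriptive
  convention, not an inferential cutoff.
* Long-range means distant *in sequence*; no 3D distance or
  allosteric-pathway inference is attempted.
* Single-chain analyses only; no periodic-boundary unwrapping, solvent or
  mass-weighting in the geometry stage.
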