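# pbflex

Local-backbone flexibility analysis of molecular-dynamics conformational
ensembles with the 16-letter **Protein Blocks** (PB) structural alphabet,
aimed at structural bioinformaticians who want to ask: *does a missense
variant change a protein's local dynamics — and where?*

Global measures such as Cα RMSF often barely move when a point mutation
rewires a protein's dynamics, because the change is local-conformational
rather than amplitudinal. `pbflex` instead assigns every residue of every
trajectory frame one of 16 canonical backbone prototypes (PBs *a*–*p*, each
defined by the φ/ψ dihedrals of a 5-residue window; *m* ≈ α-helix core,
*d* ≈ central β-strand) and summarises the per-position letter distribution
*f* with two statistics:

- **Neq** — the equivalent number of PBs sampled at a position,

  `Neq = exp( − Σₓ fₓ ln fₓ )`,

  the exponential of the Shannon entropy of the PB distribution: 1 when a
  single local conformation is seen (rigid), 16 for a uniform distribution
  over all PBs (fully disordered). Classes: Neq > 8 disordered, 6–8 highly
  flexible, 3–6 flexible, < 3 rigid.

- **ΔPB** — the L1 divergence between two systems' PB distributions at one
  position,

  `ΔPB = Σₓ | fₓ^A − fₓ^B |`,

  0 for identical local-conformation profiles, 2 for disjoint ones;
  positions with ΔPB > 1 are flagged as divergent. Together with
  ΔNeq = |Neq_A − Neq_B| this pinpoints where a wild-type and a variant
  differ, and a *long-range* (allosteric-like) effect is called when the
  mutation site itself stays conformationally stable (site ΔPB below a
  bound, default 0.2) while a distant position diverges.

Around this core the package provides multi-model PDB input/output, backbone
dihedral computation, Kabsch-superposed RMSD/RMSF and B-factor tracks,
contact-persistence fractions (e.g. Ca²⁺ coordination over a trajectory), a
region registry for the integrin αIIb leg domains (Thigh, Calf-1, Calf-2 and
their loops — where many Glanzmann thrombasthenia variants fall), PB-fasta
serialisation, occurrence maps and conservation-logo tables, and a
synthetic-ensemble generator (PB-string, dihedral and backbone-coordinate
modes) that gives every analysis stage a known ground truth.

## Worked example

Simulate a 45-residue wild type whose positions are mostly pure β-strand
(*d*) with one flexible loop, inject a variant whose *distant* position 740
flips to a pure loop conformation (*h*) while the "mutation site" 705 is
untouched, and compare:

```r
library(pbflex)

targets <- lapply(701:745, function(r) {
  if (r %in% 711:715) c(b = 0.5, d = 0.3, h = 0.2) else c(d = 1)
})
wt_spec <- generator_spec(701:745, targets, n_frames = 2000,
                          n_replicates = 1, seed = 7)
pair <- inject_variant_effect(wt_spec, site = 705, distant = 740,
                              effect = c(h = 1))

wt  <- system_run("WT",    generate_string_mode(pair$wt))
var <- system_run("H705P", generate_string_mode(pair$variant))
compare_systems(wt, var, site = 705)
#> pb_comparison: WT vs H705P over 45 positions
#>   Neq correlation: 1.000
#>   positions with dPB > 1 : 1 (2.2% of assignable)
#>   max dPB 2.00 at residue 740
#>   site 705 dPB 0.00 (stable); long-range effect: TRUE
```

The report reads: the two systems' flexibility profiles are globally
indistinguishable (Neq correlation ≈ 1), exactly one position crosses the
ΔPB > 1 divergence threshold — residue 740, with ΔPB = 2 (complete change of
local conformation) — and because the mutation site's own ΔPB is ~0 the
divergence is classified as a long-range effect.

The building blocks are available individually:

```r
neq(pb_target(c(b = 0.6, d = 0.2, h = 0.2)))   # 2.586  (≈2.6 equivalent PBs)
delta_pb(pb_target(c(b = 0.6, d = 0.2, h = 0.2)),
         pb_target(c(h = 1)))$dpb              # 1.6
region_length("Calf-1")                        # 141 residues (603-743)
```

`run_pipeline()` ties the stages together (read/generate → dihedrals → PB
assignment → profiles → Neq/RMSF → comparison) from a list or YAML config
and writes TSV tracks, occurrence-map CSVs and a JSON report;
`inst/scripts/pbflex.R` is a thin shell wrapper around it.

## Scope

`pbflex` analyses conformational ensembles; it does not run molecular
dynamics, complete missing loops, or score variant pathogenicity. The
synthetic generator reproduces the categorical/angular statistics the
analysis consumes, not physics (no force field, solvent or thermodynamics).
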