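# residuekit

Noncanonical amino-acid residue templates for structure prediction, in R.

Modern structure predictors (AlphaFold3 and the ecosystem built on its input
conventions) handle nonstandard residues through Chemical Component
Dictionary (CCD) codes. That works only when the residue is already in the
dictionary. For the many amino-acid-like molecules that are not — designed
side chains, backbone homologues, modified residues — someone has to decide
whether the molecule is even embeddable in a peptide, find the closest
dictionary entry, produce named 3D coordinates that follow residue
conventions, and package everything in the input formats the predictor
expects. `residuekit` automates that pipeline and adds the geometric
validation used to judge the resulting models. It is aimed at peptide-design
and structural-bioinformatics groups who have a SMILES string and want a
residue definition.

## What it does

**Scope classification.** A molecule is a peptide-embeddable residue monomer
when it carries a free amine (a non-amide nitrogen with at least one
hydrogen, excluding nitro/nitrile/quaternary centres), a free carboxyl
(acid or carboxylate), and a shortest backbone path of 2, 3 or 4 bonds
between the amino nitrogen and the carboxyl carbon — alpha, beta and gamma
residues respectively; 5 bonds or more (delta and beyond) are rejected.
Everything else is excluded with machine-readable flags (`oligomer`,
`masked_acid`, `metal_or_coordination`, complexity limits, ...), so batch
screens are auditable.

**Reference-library mapping.** Components are indexed from an SDF by
standard InChIKey. Mapping is two-pass: exact full-key match first, then the
14-character connectivity layer, which tolerates protonation and tautomer
differences while preserving the skeleton. Confidence is `high` only for a
full-key match or graph identity (Tanimoto 1.0); everything else is reported
`ambiguous` with all candidates retained for inspection.

**Similarity search.** Circular Morgan fingerprints (radius 2, 2048 bits)
scored under four coefficients on the on-bit counts |A|, |B| and
intersection c:

    tanimoto   = c / (|A| + |B| - c)        (default ranking)
    dice       = 2c / (|A| + |B|)
    cosine     = c / sqrt(|A| |B|)
    kulczynski = (c/|A| + c/|B|) / 2

A Tanimoto score of 1.0 is treated as an exact structural match; otherwise
the top k (default 10) hits are returned with all four scores.

**Topology building.** One seeded ETKDG conformer (RDKit backend, MMFF
relaxation by default; deterministic for a fixed seed), then rule-based CCD
atom naming: backbone N/CA/C/O with OXT, side chains walked breadth-first
with Greek position letters (CB, CG, CD, ..., NZ, OG1, ...), hydrogens named
after their heavy atom (HB2/HB3 dialect). When a mapped dictionary component
carries atom names, those are adopted; coordinates always come from the
embedder.

**Export.** Residue definitions go to a documented three-section CSV
(metadata / atoms with leaving-atom flags / bonds) and an AlphaFold3-style
JSON job with a namespaced `customComponents` block, validated against a
shipped schema. A `GGXGG` helper embeds one residue at position 3 of a
glycine-flanked pentapeptide, the standard in-chain probe.

**Validation.** Five geometric metrics with fixed reference bands
(d_N_C1 1.382–1.534 Å; d_Ck_Ccarb 1.441–1.609 Å from 1.525 ± 4·0.021;
d_Ccarb_O_mean 1.151–1.311 Å from 1.231 ± 4·0.020; mean ∠Ck–Ccarb–O
114.0–127.6° from 120.8 ± 4·1.7; ∠O–Ccarb–O 110–130°); peptide-bond ω
banding (good: |ω| ≥ 150° or ≤ 30°; borderline: any ω in [120°, 150°) and
none bad; bad: any ω in (30°, 120°) or missing); RMSD
√(1/N ΣᵢΣⱼ (xᵢⱼ_native − xᵢⱼ_model)²) over all-atom/backbone/Cα selections
with optional Kabsch superposition; and chirality-parity agreement between a
definition's stereo and a model's geometry.

## Worked example

```r
library(residuekit)

# a small packaged reference library (12 components) builds in seconds
lib <- read_component_library(mini_component_library(tempdir())$sdf_path)

apply_scope_filters("NCCC(=O)O")
#> <scope_decision> accepted [beta]

# deprotonated beta-alanine: similar components under all four coefficients
search_components("NCCC(=O)[O-]", lib, k = 3)
#>   component_id tanimoto  dice cosine kulczynski  rank exact
#> 1 GLZ             0.524 0.688  0.689      0.690     1 FALSE
#> 2 BAL             0.417 0.588  0.588      0.588     2 FALSE
#> 3 GAB             0.333 0.5    0.501      0.502     3 FALSE

# two-pass InChIKey mapping: the connectivity layer catches the
# protonation variant of the library's beta-alanine entry
glance(map_query_to_ccd("NCCC(=O)[O-]", lib))
#>   mode               confidence n_candidates query_inchikey
#> 1 connectivity_layer ambiguous             1 UCMIRNVEIXFBKS-UHFFFAOYSA-M

# classify -> embed -> name -> definition, in one call
defn <- build_residue("NCCC(=O)O", library = lib, seed = 42)
glance(defn)
#>   component_id residue_class n_atoms n_bonds inchikey
#> 1 ZCA          beta               13      12 UCMIRNVEIXFBKS-UHFFFAOYSA-N

# geometric validation of the embedded conformer
tidy(geometry_metrics(as_coordinate_set(defn), defn$topology$backbone_map))
#>   metric               value  lower  upper in_range
#> 1 d_N_C1                1.46   1.38   1.53 TRUE
#> 2 d_Ck_Ccarb            1.50   1.44   1.61 TRUE
#> 3 d_Ccarb_O_mean        1.28   1.15   1.31 TRUE
#> 4 ang_Ck_Ccarb_O_mean 120.   114    128.   TRUE
#> 5 ang_O1_Ccarb_O2     120.   110    130    TRUE

# export: residue CSV + AlphaFold3-style GGXGG job JSON
write_residue_csv(defn, "ZCA.csv")
ggxgg_job(defn, "job_out")
```

The `rank` column is the position under the ranking coefficient; `exact`
flags Tanimoto 1.0 hits (graph identity). The `in_range` flags compare each
metric against its reference band; `all_pass` (via `glance()`) requires all
five.

A command-line front end over the same functions ships in
`inst/cli/hrb.R` (`classify`, `map`, `search`, `build`, `export`,
`validate`, `fixtures`).

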