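---
title: "Building and validating noncanonical residue templates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and validating noncanonical residue templates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`residuekit` turns amino-acid-like small molecules into residue definitions
usable by AlphaFold3-style structure predictors, and validates the resulting
structures. This vignette is the package's own account of the method: the
model behind each stage, the parameters that matter, the numerical choices,
and what the packaged fixtures can and cannot establish.

## The residue model

A molecule is treated as a peptide-embeddable residue monomer when three
conditions hold:

1. a free amine — a nitrogen that is not part of a nitro or nitrile group,
   is not an amide nitrogen (no neighbouring carbonyl carbon, the
   candidate's own carboxyl excepted), has at most three heavy neighbours,
   and carries at least one hydrogen;
2. a free carboxyl — an sp² carbon bonded to exactly one double-bonded
   terminal oxygen and one single-bonded terminal oxygen (acid or
   carboxylate anion; esters and carbonates do not qualify because their
   single-bonded oxygen bridges to another heavy atom);
3. a shortest path of 2, 3 or 4 bonds between the amino nitrogen and the
   carboxyl carbon, giving the alpha, beta and gamma classes; 5 bonds or
   more is out of scope (`delta_or_longer`).

Classification searches all (nitrogen, carboxyl-carbon) pairs and takes the
minimum bond-count path. Ties among minimal pairs are broken by the
lexicographically smallest (nitrogen index, carbon index) in canonical atom
order, so results do not depend on input atom numbering.

### Exclusion flags and their rationale

Excluded molecules carry non-exclusive machine-readable flags. The
complexity limits are artifact defaults — molecular weight ≤ 600 Da,
rings ≤ 4, heavy atoms ≤ 40, heteroatoms ≤ 12, free acids ≤ 2 — chosen to
keep conformer generation and residue-definition construction robust for
single residues; all are overridable through `scope_limits()`. They are
deliberately conservative rather than tuned to reproduce any particular
database screen.

Two flags needed genuine design decisions:

* **`oligomer`.** "Multiple amide bonds" is the intent, but a literal
  ≥ 2 count misses the glycylglycine dipeptide (one amide bond) while a
  literal ≥ 1 count would reject asparagine-like residues whose side chain
  carries a primary amide. The implemented rule flags a molecule when a
  secondary or tertiary amide bond lies **on** a candidate N→Ccarb shortest
  path, or when two or more amide bonds occur anywhere. This rejects
  peptides and protected intermediates while keeping legitimate side-chain
  amides.
* **`masked_acid`.** Raised when no free carboxyl exists but an
  ester/carbonate carbonyl does — the typical protected-intermediate or
  prodrug pattern. A molecule with both a free acid and an ester is not
  flagged; the free acid makes it a residue candidate.

Salt stripping keeps the largest fragment by heavy-atom count (ties broken
by molecular weight) before any analysis, so screening a hydrochloride
equals screening the free base.

## Reference-library mapping

Components are read from an SDF (optionally gzipped); stored InChIKeys are
trusted when they match the 14-10-1 block syntax and recomputed otherwise.
Key generation runs through the Open Babel InChI backend after salt
stripping; with `standardize = TRUE` the molecule is first routed through
the sanitising parser so the toolkit can repair valence states. Tautomer and
protonation normalisation is not re-implemented: the standard InChI
algorithm's mobile-hydrogen treatment already folds these into the key's
suffix rather than its connectivity layer, which is exactly what the
two-pass lookup exploits — pass 1 matches the full 27-character key, pass 2
only its first 14 characters (the skeleton). Confidence is `high` only for
full-key equality or graph identity (fingerprint Tanimoto 1.0); any other
connectivity-layer hit is `ambiguous` and all key-sharing candidates are
returned sorted by component id, because several dictionary entries can
legitimately share a skeleton.

## Fingerprints and similarity

The package authors its own hashed circular (Morgan) fingerprint: radius 2,
2048 bits, atom invariants combining atomic number, heavy degree, hydrogen
count, formal charge, aromaticity and ring membership, with each iteration
folding in the sorted (bond class, neighbour hash) pairs. Two properties are
contractual and tested: identical molecular graphs give identical vectors
regardless of input atom order (guaranteed by canonical-order parsing plus
order-independent hashing), and the vector length is exactly 2048. Bit
positions are implementation-defined — similarity values are comparable
within the package, not bit-for-bit against other toolkits.

Chirality is intentionally not encoded, so enantiomers score Tanimoto 1.0;
that matches the convention of treating 1.0 as *graph-level* equivalence.
The Kulczynski coefficient is the arithmetic-mean ("Kulczynski II") variant,
the common choice in fingerprint toolkits. Two all-zero fingerprints score 0
by convention. Ranking ties are broken by ascending component id for stable
output.

## Conformers and atom naming

The default conformer engine is seeded distance geometry (ETKDG) with MMFF
relaxation, run through the RDKit Python backend as a subprocess:
deterministic for a fixed (molecule, seed, optimize) triple, with a 3-retry
policy that increments the seed on embedding failure and records the seed
actually used. Open Babel's `--gen3d` is available as an alternative engine
but takes no seed and is not deterministic across calls (its rotor search is
randomised); it exists for cross-checking, not as the default. The embedding
seed defaults to 42 and is recorded in the definition metadata.

Atom naming follows dictionary conventions. For alpha residues the backbone
is N/CA/C/O with the second carboxyl oxygen as OXT (hydrogen HXT). For beta
and gamma residues the carbonyl-adjacent backbone carbon is CA and the walk
toward nitrogen continues CB, CG — the convention of the standard
beta-alanine component — with a `scheme = "sequential"` switch for C1..Ck
naming. Side chains are walked breadth-first from their backbone attachment;
position letters B, G, D, E, Z, H index the depth, names are element symbol
plus letter (CB, OG, NZ), positional ties get numeric suffixes in discovery
order (CG1/CG2), and atoms beyond the Greek range fall back to a
deterministic element+counter scheme under the 4-character limit. Hydrogens
are named after their heavy atom: single hydrogens take the bare stem (HA),
methylenes take the modern PDB suffixes 2/3 (HB2/HB3; a `pdb2` dialect gives
1/2), methyls 1/2/3, and the backbone amine H/H2(/H3). BFS ties are broken
by canonical atom rank, so naming is reproducible.

When a query maps to a dictionary component at full-key confidence and the
component record carries atom names (the packaged fixtures store them in
canonical atom order), those names are adopted verbatim for the matched
atoms — templates donate topology information only; coordinates always come
from the embedder.

## Export formats

The residue CSV is a single RFC-4180 file with a `record` discriminator
column and three sections: `meta` key/value rows (component id, class,
SMILES, InChIKey, seed, optimize, template), `role` rows carrying the
backbone map, `atom` rows (name, element, charge, x/y/z to six decimals,
backbone and leaving flags) and `bond` rows (names, order word, aromatic
flag). Six-decimal fixed formatting makes output byte-deterministic, and
write∘read is the identity on the file bytes. Leaving atoms follow polymer
conventions: OXT, HXT and the last amine hydrogen. The authors' exact
column schema for their patched predictor is unpublished, so this dialect is
defined from the stated content and documented here; byte-for-byte interop
with that patch is not claimed.

The job JSON follows the public AlphaFold3 field names where public (`name`,
`modelSeeds`, `sequences`, `protein`, `modifications`) and carries custom
residues in a namespaced `customComponents` array referencing the CSVs. A
packaged JSON schema plus referential checks (every modification position
inside its sequence, every component id resolvable) define "acceptance" at
the artifact level — a stand-in for the run-without-error criterion that
would require executing the external predictor. Component ids come from the
documented sequence ZCA, ZCB, ..., skipping a packaged list of reserved
standard codes; the 16th assignment in a fresh session is ZCP.

## Validation metrics

Five geometric metrics are evaluated against closed reference intervals:
d_N_C1 ∈ [1.382, 1.534] Å, d_Ck_Ccarb ∈ [1.441, 1.609] Å (1.525 ± 4·0.021),
d_Ccarb_O_mean ∈ [1.151, 1.311] Å (1.231 ± 4·0.020), mean ∠Ck–Ccarb–O ∈
[114.0, 127.6]° (120.8 ± 4·1.7), and ∠O–Ccarb–O ∈ [110, 130]° (a sanity
band around trigonal-planar geometry). Where a (mean, σ) pair exists the
band is *computed* as mean ± 4σ rather than stored, and a test asserts the
printed endpoints are reproduced. Interval endpoints are inclusive. A
missing role atom yields an `NA` metric and a failed flag.

Peptide-bond ω torsions are normalised to (−180°, 180°] and binned on
|ω|: ≤ 30 or ≥ 150 good, strictly between 30 and 120 bad, [120, 150)
borderline, missing values bad; a residue is `good` only when both flanking
torsions are good. The boundary conventions (30 and 150 good, 120
borderline) follow the printed inequalities, whose strictness is mixed; the
grid test pins them. For beta/gamma residues, which have no Cα, the backbone
carbon adjacent to the amide bond substitutes in the torsion via a
configurable role map.

RMSD implements √(1/N ΣΣ(Δx)²) over name-paired atoms in the chosen
selection (all atoms, backbone, Cα). The equation itself has no alignment
step; the default nevertheless superposes first (Kabsch least squares,
implemented via SVD with a reflection guard and cross-checked against an
independent implementation in the tests) because structure-comparison tables
conventionally superpose — `superpose = FALSE` gives the raw evaluation.
This is recorded as an interpretation, not a fact about the original
computation.

Chirality agreement perceives stereocentres from the definition's bond
graph — carbons with four pairwise-distinguishable branches, using hashed
branch signatures — and compares parity between the definition's embedded
conformer (which realises the input stereo-SMILES; the embedder enforces
it) and the model's geometry, via the signed volume of the three
highest-priority substituents around the centre. Labels are mapped onto
"R"/"S" under a fixed internal priority convention; they are consistent
parity labels, not full CIP assignments, and agreement — the reported
quantity — is invariant to the convention. Molecules without perceivable
centres report accuracy `NA`, treated as vacuously agreeing in aggregates;
hash collisions between genuinely different branches would make a centre
drop out conservatively rather than mislabel.

## Synthetic fixtures: what they do and do not show

All tests run offline on fixtures generated in code:

* a 24-molecule labelled panel spanning every class and flag;
* a 12-component reference SDF (standard residues with real dictionary
  codes, a beta and a gamma acid, a glycine/glycinate protonation pair
  sharing a connectivity layer, aromatic decoys) plus a 20-component decoy
  library for ranking tests — entries that are not real dictionary
  components carry synthetic codes and are documented as such;
* an ideal alpha backbone placed by internal-coordinate construction at the
  band means (reproducing the specified internal coordinates to 10⁻⁶), with
  optional seeded Gaussian coordinate noise (σ = 0.5 Å at seed 7 is the
  documented perturbed case, which breaks at least one band);
* a seven-atom tripeptide trace with exactly prescribed ω torsions.

These establish the algorithmic contracts: classification equals a
brute-force path search, banding equals the printed inequalities, round
trips are identities, metrics are rigid-motion invariant. They do not
establish anything about predictor behaviour on real structures — the
published end-to-end rates (predictor acceptance, fraction of monomers
passing all five bands, ω quality over motif peptides, chirality accuracy
of predictions) depend on running the external predictor with its weights
and on a specific database snapshot, both outside this package's scope.
Problem sizes in the test suite (a dozen-component library, a two-dozen
molecule panel, five-atom geometry fixtures) were chosen as the smallest
sets that exercise every code path and tie-break.

## Known limitations

* The SMILES front end covers organic chemistry as emitted by the Open
  Babel canonical writer; exotic inputs (polymeric markers, reaction
  SMILES) are out of scope.
* Aromatic perception follows the canonical-SMILES lowercase convention;
  no independent Hückel analysis is performed.
* The component index is an in-memory tibble keyed by full key and prefix;
  it is sized for curated libraries (10²–10⁴ components), not for indexing
  the full dictionary.
* Enantiomers are indistinguishable to the fingerprints by design; the
  chirality module, not the similarity module, is responsible for stereo.
* `embed_conformer()` produces a single conformer; ensembles and ring
  sampling are out of scope.
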