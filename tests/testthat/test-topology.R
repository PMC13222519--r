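test_that("conformer embedding is finite, deterministic and seed-sensitive", {
  mol <- parse_molecule("NCC(=O)O")
  c1 <- embed_conformer(mol, seed = 42)
  expect_equal(dim(c1), c(10, 3))
  expect_true(all(is.finite(c1)))
  c2 <- embed_conformer(mol, seed = 42)
  expect_identical(c1[, ], c2[, ])
  expect_equal(attr(c1, "seed_used"), 42L)
  c3 <- embed_conformer(mol, seed = 7)
  expect_false(identical(c1[, ], c3[, ]))
  # optimized geometry: N-CA bond near its force-field equilibrium
  bb <- recognize_backbone(mol)
  d <- sqrt(sum((c1[bb[["N"]], ] - c1[bb[["C1"]], ])^2))
  expect_gte(d, 1.40)
  expect_lte(d, 1.55)
})

test_that("backbone roles follow the classification path", {
  bb_gly <- recognize_backbone(parse_molecule("NCC(=O)O"))
  expect_named(bb_gly, c("N", "C1", "Ccarb", "O1", "O2"))
  bb_bal <- recognize_backbone(parse_molecule("NCCC(=O)O"))
  expect_named(bb_bal, c("N", "C1", "C2", "Ccarb", "O1", "O2"))
  bb_gab <- recognize_backbone(parse_molecule("NCCCC(=O)O"))
  expect_named(bb_gab, c("N", "C1", "C2", "C3", "Ccarb", "O1", "O2"))
  expect_error(recognize_backbone(parse_molecule("CCO")),
               class = "residuekit_topology_error")
})

test_that("alanine names agree with the bundled reference component entry", {
  defn <- fx_defn_ala()
  lib <- fx_library()
  ref <- lib$components$atom_names[[
    which(lib$components$component_id == "ALA")]]
  mol <- parse_molecule("N[C@@H](C)C(=O)O")
  ours <- defn$topology$atoms$name[defn$topology$atoms$element != "H"]
  # both are in canonical atom order, so they compare element-wise
  expect_identical(ours, ref)
  # hydrogens follow their heavy atoms with the modern suffix dialect
  h <- defn$topology$atoms[defn$topology$atoms$element == "H", ]
  expect_setequal(h$name, c("H", "H2", "HA", "HB1", "HB2", "HB3", "HXT"))
  expect_setequal(h$parent_heavy[h$name %in% c("HB1", "HB2", "HB3")], "CB")
})

test_that("side chains are walked breadth-first with Greek position letters", {
  lys <- build_residue("NC(CCCCN)C(=O)O")
  heavy <- lys$topology$atoms[lys$topology$atoms$element != "H", ]
  expect_setequal(heavy$name,
                  c("N", "CA", "C", "O", "OXT", "CB", "CG", "CD", "CE", "NZ"))
  # path order from CA outward
  bonds <- lys$topology$bonds
  bonded <- function(a, b) any((bonds$atom1 == a & bonds$atom2 == b) |
                                 (bonds$atom1 == b & bonds$atom2 == a))
  for (pair in list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"),
                    c("CD", "CE"), c("CE", "NZ"))) {
    expect_true(bonded(pair[1], pair[2]), info = paste(pair, collapse = "-"))
  }
  # serine: the side-chain oxygen takes the gamma position
  ser <- assign_atom_names(parse_molecule("NC(CO)C(=O)O"),
                           recognize_backbone(parse_molecule("NC(CO)C(=O)O")))
  expect_true("OG" %in% ser$name)
  # valine-like branch: positional ties get numeric suffixes
  val <- assign_atom_names(parse_molecule("CC(C)C(N)C(=O)O"),
                           recognize_backbone(parse_molecule("CC(C)C(N)C(=O)O")))
  expect_true(all(c("CG1", "CG2") %in% val$name))
})

test_that("beta and gamma backbones use the beta-alanine naming convention", {
  bal <- build_residue("NCCC(=O)O")
  expect_identical(unname(bal$topology$backbone_map[c("C1", "C2")]),
                   c("CB", "CA"))
  gab <- build_residue("NCCCC(=O)O")
  expect_identical(unname(gab$topology$backbone_map[c("C1", "C2", "C3")]),
                   c("CG", "CB", "CA"))
  # sequential scheme override
  mol <- parse_molecule("NCCC(=O)O")
  seqn <- assign_atom_names(mol, recognize_backbone(mol),
                            scheme = "sequential")
  expect_true(all(c("C1", "C2") %in% seqn$name))
})

test_that("atom naming is a bijection with unique names on every accepted molecule", {
  panel <- toy_molecule_set()
  accepted <- panel[panel$accepted, ]
  for (i in seq_len(nrow(accepted))) {
    mol <- parse_molecule(accepted$smiles[i])
    named <- assign_atom_names(mol, recognize_backbone(mol))
    expect_equal(nrow(named), nrow(mol$atoms), info = accepted$id[i])
    expect_false(anyNA(named$name), info = accepted$id[i])
    expect_false(anyDuplicated(named$name) > 0, info = accepted$id[i])
    expect_true(all(nchar(named$name) <= 4), info = accepted$id[i])
    expect_identical(named$idx, mol$atoms$idx)
  }
})

test_that("topology construction validates its invariants", {
  gly <- fx_defn_gly()
  expect_equal(nrow(gly$topology$atoms), 10)
  expect_equal(nrow(gly$topology$bonds), 9)
  expect_identical(sort(unname(gly$topology$backbone_map)),
                   sort(c("N", "CA", "C", "O", "OXT")))
  # aromatic side-chain bonds are flagged
  phe_mol <- parse_molecule("N[C@@H](Cc1ccccc1)C(=O)O")
  phe_named <- assign_atom_names(phe_mol, recognize_backbone(phe_mol))
  phe_topo <- build_topology(phe_mol, phe_named,
                             recognize_backbone(phe_mol), "alpha")
  expect_equal(sum(phe_topo$bonds$aromatic), 6)
  # injected inconsistencies are rejected with a structured error
  broken <- gly$topology$atoms
  broken$name[broken$name == "OXT"] <- "O"  # duplicate name
  expect_error(
    build_topology(parse_molecule("NCC(=O)O"), broken,
                   recognize_backbone(parse_molecule("NCC(=O)O")), "alpha"),
    class = "residuekit_topology_error"
  )
})

test_that("a full-key library match donates its template atom names", {
  lib <- fx_library()
  defn <- build_residue("N[C@@H](C)C(=O)O", library = lib)
  expect_identical(defn$metadata$template_id, "ALA")
  ref <- lib$components$atom_names[[
    which(lib$components$component_id == "ALA")]]
  ours <- defn$topology$atoms$name[defn$topology$atoms$element != "H"]
  expect_identical(ours, ref)
  # absent from the library: no template recorded
  plain <- fx_defn_ala()
  expect_true(is.na(plain$metadata$template_id))
})

test_that("out-of-scope molecules are refused by the one-call builder", {
  expect_error(build_residue("NCC(=O)NCC(=O)O"),
               class = "residuekit_scope_error")
})
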