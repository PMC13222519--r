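#' Labelled toy molecule panel
#'
#' A ground-truth-annotated panel of small molecules covering every
#' classification outcome and exclusion flag: alpha/beta/gamma residues,
#' a dipeptide, a masked (esterified) acid, nitrile and nitro decoys, a
#' quaternary ammonium zwitterion, a delta amino acid, a covalent metal
#' adduct, a multi-acid, and molecules tripping each complexity limit.
#' `label` is the expected backbone classification, `accepted` the expected
#' scope decision, and `flags_expected` the flags every screening run must
#' at least raise (flags are non-exclusive).
#'
#' @return A tibble with columns `id`, `smiles`, `label`, `accepted`,
#'   `flags_expected` (list column).
#' @export
toy_molecule_set <- function() {
  tibble::tribble(
    ~id,              ~smiles,                                   ~label,     ~accepted, ~flags_expected,
    "glycine",        "NCC(=O)O",                                "alpha",    TRUE,  character(),
    "l_alanine",      "N[C@@H](C)C(=O)O",                        "alpha",    TRUE,  character(),
    "phenylglycine",  "NC(c1ccccc1)C(=O)O",                      "alpha",    TRUE,  character(),
    "serine",         "NC(CO)C(=O)O",                            "alpha",    TRUE,  character(),
    "proline",        "OC(=O)C1CCCN1",                           "alpha",    TRUE,  character(),
    "phenylalanine",  "N[C@@H](Cc1ccccc1)C(=O)O",                "alpha",    TRUE,  character(),
    "aspartic",       "NC(CC(=O)O)C(=O)O",                       "alpha",    TRUE,  character(),
    "lysine",         "NC(CCCCN)C(=O)O",                         "alpha",    TRUE,  character(),
    "beta_alanine",   "NCCC(=O)O",                               "beta",     TRUE,  character(),
    "aminobutanoic3", "CC(N)CC(=O)O",                            "beta",     TRUE,  character(),
    "gaba",           "NCCCC(=O)O",                              "gamma",    TRUE,  character(),
    "gabob",          "NCC(O)CC(=O)O",                           "gamma",    TRUE,  character(),
    "gly_gly",        "NCC(=O)NCC(=O)O",                         "rejected", FALSE, c("oligomer"),
    "gly_ester",      "COC(=O)CN",                               "rejected", FALSE, c("masked_acid"),
    "delta_amino",    "NCCCCC(=O)O",                             "rejected", FALSE, c("delta_or_longer"),
    "cyanopropanoic", "N#CCCC(=O)O",                             "rejected", FALSE, c("no_amine"),
    "nitrobenzoic",   "O=[N+]([O-])c1ccc(C(=O)O)cc1",            "rejected", FALSE, c("no_amine"),
    "betaine",        "C[N+](C)(C)CC(=O)[O-]",                   "rejected", FALSE, c("no_amine"),
    "ethanol",        "CCO",                                     "rejected", FALSE, c("no_carboxyl", "no_amine"),
    "sodium_adduct",  "NCC(=O)O[Na]",                            "rejected", FALSE, c("metal_or_coordination"),
    "citric",         "OC(=O)CC(O)(CC(=O)O)C(=O)O",              "rejected", FALSE, c("multi_acid_above_limit", "no_amine"),
    "heavy_chain",    paste0("NC(", strrep("C", 40), ")C(=O)O"), "alpha",    FALSE, c("mw_above_threshold", "heavy_atom_count_above_threshold"),
    "pentaring",      "NC(C(=O)O)C(C1CC1)(C1CC1)C(C1CC1)(C1CC1)C1CC1", "alpha", FALSE, c("ring_count_above_threshold"),
    "perfluoro",      "NC(C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F)C(=O)O", "alpha", FALSE, c("hetero_atom_count_above_threshold")
  )
}

# component table behind the packaged mini reference library; entries that do
# not correspond to a real dictionary component (the gamma acid, the
# glycinate protonation variant, decoys) carry synthetic codes and are
# documented as such
mini_component_table <- function() {
  tibble::tribble(
    ~component_id, ~code, ~smiles,
    "GLY", "GLY", "NCC(=O)O",
    "ALA", "ALA", "N[C@@H](C)C(=O)O",
    "LYS", "LYS", "N[C@@H](CCCCN)C(=O)O",
    "SER", "SER", "N[C@@H](CO)C(=O)O",
    "PRO", "PRO", "OC(=O)[C@@H]1CCCN1",
    "PHE", "PHE", "N[C@@H](Cc1ccccc1)C(=O)O",
    "ASP", "ASP", "N[C@@H](CC(=O)O)C(=O)O",
    "BAL", "BAL", "NCCC(=O)O",
    "GAB", "GAB", "NCCCC(=O)O",
    "GLZ", "GLZ", "NCC(=O)[O-]",
    "BNZ", "BNZ", "c1ccccc1",
    "TOL", "TOL", "Cc1ccccc1"
  )
}

# Reference atom names for library entries, assigned by bespoke per-molecule
# structural rules (independent of the production naming code): returns the
# heavy-atom names of `smiles` in canonical atom order, or NULL.
reference_atom_names <- function(component_id, smiles) {
  if (!component_id %in% c("GLY", "ALA", "BAL")) return(NULL)
  mol <- parse_molecule(smiles)
  a <- mol$atoms[mol$atoms$heavy, ]
  nm <- rep(NA_character_, nrow(a))
  site <- find_carboxyl_sites(mol)
  nm[site$carbon_index] <- "C"
  nm[site$o_double_index] <- "O"
  nm[site$o_single_index] <- "OXT"
  n_idx <- which(mol$atoms$element == "N")[1]
  nm[n_idx] <- "N"
  carbons <- setdiff(which(a$element == "C"), site$carbon_index)
  if (component_id == "GLY") {
    nm[carbons] <- "CA"
  } else if (component_id == "ALA") {
    # CA bonded to both N and the carboxyl carbon; the remaining C is CB
    ca <- carbons[vapply(carbons, function(i) {
      nb <- atom_neighbors(mol, i, heavy_only = TRUE)
      n_idx %in% nb && site$carbon_index %in% nb
    }, logical(1))]
    nm[ca] <- "CA"
    nm[setdiff(carbons, ca)] <- "CB"
  } else if (component_id == "BAL") {
    ca <- carbons[vapply(carbons, function(i)
      site$carbon_index %in% atom_neighbors(mol, i, heavy_only = TRUE),
      logical(1))]
    nm[ca] <- "CA"
    nm[setdiff(carbons, ca)] <- "CB"
  }
  nm
}

#' Materialise the packaged mini component library
#'
#' Writes a small synthetic SDF reference library (12 components: standard
#' residues, a beta and a gamma acid, an acid/conjugate-base pair sharing a
#' connectivity layer, and non-residue decoys) together with the reserved
#' three-letter code list. Output is byte-deterministic.
#'
#' @param out_dir Directory to write into.
#' @param gzip Also write a gzipped copy of the SDF?
#' @return A list with `sdf_path`, `sdf_gz_path` (or `NA`), `code_list_path`
#'   and the `components` tibble.
#' @export
mini_component_library <- function(out_dir = tempdir(), gzip = FALSE) {
  comp <- mini_component_table()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sdf_path <- file.path(out_dir, "mini_components.sdf")
  writeLines(build_sdf_records(comp), sdf_path)
  gz_path <- NA_character_
  if (gzip) {
    gz_path <- paste0(sdf_path, ".gz")
    con <- gzfile(gz_path, "wb")
    writeLines(readLines(sdf_path), con)
    close(con)
  }
  code_path <- file.path(out_dir, "standard_codes.txt")
  writeLines(standard_codes(), code_path)
  list(sdf_path = sdf_path, sdf_gz_path = gz_path,
       code_list_path = code_path, components = comp)
}

#' A decoy-only search library
#'
#' Twenty structurally diverse small molecules, none an amino acid, used to
#' exercise ranking and truncation behaviour without exact matches.
#'
#' @param out_dir Directory to write the SDF into.
#' @return Path of the written SDF.
#' @export
decoy_component_library <- function(out_dir = tempdir()) {
  decoys <- tibble::tibble(
    component_id = sprintf("D%02d", 1:20),
    code = sprintf("D%02d", 1:20),
    smiles = c(
      "CCO", "CCCO", "CCCCO", "CCOC", "CCOCC",
      "CCN", "CCCN", "CCNCC", "c1ccccc1", "Cc1ccccc1",
      "Oc1ccccc1", "Nc1ccccc1", "CC(C)O", "CC(C)N", "CCC(=O)C",
      "CC(=O)OC", "C1CCCCC1", "C1CCNCC1", "C1CCOCC1", "CC(C)(C)O"
    )
  )
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(out_dir, "decoy_components.sdf")
  writeLines(build_sdf_records(decoys), path)
  path
}

# render component rows as SDF text (molblock + data fields); molblock
# timestamps are normalised so output bytes depend only on the structures
build_sdf_records <- function(comp) {
  keys <- vapply(comp$smiles, function(s)
    ob_cli_inchikey(parse_molecule(s)$smiles), character(1))
  recs <- character()
  for (i in seq_len(nrow(comp))) {
    molblock <- ob_smiles_to_sdf(parse_molecule(comp$smiles[i])$smiles,
                                 hydrogens = FALSE)
    lines <- strsplit(molblock, "\n", fixed = TRUE)[[1]]
    lines <- lines[!grepl("^\\${4}", lines)]
    lines <- lines[seq_len(max(grep("^M  END", lines)))]
    lines[1] <- comp$component_id[i]
    lines[2] <- "  residuekit 2D"
    fields <- c(
      "> <component_id>", comp$component_id[i], "",
      "> <three_letter_code>", comp$code[i], "",
      "> <InChIKey>", keys[i], ""
    )
    an <- reference_atom_names(comp$component_id[i], comp$smiles[i])
    if (!is.null(an)) {
      fields <- c(fields, "> <ATOM_NAMES>", paste(an, collapse = " "), "")
    }
    recs <- c(recs, lines, fields, "$$$$")
  }
  recs
}

#' Internal-coordinate specification of an ideal alpha backbone
#'
#' Defaults realise the tabulated mean bond geometry (Ck-Ccarb 1.525 A,
#' Ccarb-O 1.231 A, Ck-Ccarb-O 120.8 deg on both oxygens, planar carboxyl)
#' with an N-C1 distance at its band midpoint.
#'
#' @param d_N_C1,d_Ck_Ccarb,d_Ccarb_O Bond lengths in angstrom.
#' @param ang_N_C1_Ck Backbone angle in degrees (not a validated metric).
#' @param ang_Ck_Ccarb_O Carboxyl substituent angle in degrees (both
#'   oxygens).
#' @return A named list.
#' @export
ideal_geometry_spec <- function(d_N_C1 = 1.458, d_Ck_Ccarb = 1.525,
                                d_Ccarb_O = 1.231, ang_N_C1_Ck = 110.5,
                                ang_Ck_Ccarb_O = 120.8) {
  list(d_N_C1 = d_N_C1, d_Ck_Ccarb = d_Ck_Ccarb, d_Ccarb_O = d_Ccarb_O,
       ang_N_C1_Ck = ang_N_C1_Ck, ang_Ck_Ccarb_O = ang_Ck_Ccarb_O)
}

#' Ideal (optionally perturbed) alpha-residue backbone coordinates
#'
#' Places N, CA, C, O, OXT so that the internal coordinates reproduce `spec`
#' exactly (the carboxyl is planar: O and OXT at the specified angle on
#' opposite sides, giving an O-Ccarb-O angle of 360 - 2*ang). With `perturb`
#' set, seeded isotropic Gaussian noise of that standard deviation (angstrom)
#' is added to every coordinate.
#'
#' @param spec An [ideal_geometry_spec()].
#' @param perturb Optional coordinate noise sigma in angstrom.
#' @param seed RNG seed used when `perturb` is set.
#' @return A list: `coords` (a `coordinate_set`) and `backbone_map`.
#' @export
ideal_alpha_coordinates <- function(spec = ideal_geometry_spec(),
                                    perturb = NULL, seed = 1L) {
  n <- c(0, 0, 0)
  ca <- c(spec$d_N_C1, 0, 0)
  # place C in the xy-plane at the backbone angle
  ang <- spec$ang_N_C1_Ck * pi / 180
  cc <- ca + spec$d_Ck_Ccarb * c(-cos(ang), sin(ang), 0)
  o1 <- place_atom(n, ca, cc, spec$d_Ccarb_O, spec$ang_Ck_Ccarb_O, 0)
  o2 <- place_atom(n, ca, cc, spec$d_Ccarb_O, spec$ang_Ck_Ccarb_O, 180)
  m <- rbind(n, ca, cc, o1, o2)
  if (!is.null(perturb)) {
    set.seed(seed)
    m <- m + matrix(stats::rnorm(length(m), sd = perturb), nrow(m), 3)
  }
  coords <- coordinate_set(tibble::tibble(
    name = c("N", "CA", "C", "O", "OXT"),
    element = c("N", "C", "C", "O", "O"),
    x = m[, 1], y = m[, 2], z = m[, 3]
  ))
  list(coords = coords,
       backbone_map = c(N = "N", C1 = "CA", Ccarb = "C",
                        O1 = "O", O2 = "OXT"))
}

#' Synthetic tripeptide backbone with prescribed omega torsions
#'
#' Builds the minimal seven-atom CA/C/N trace of residues i-1, i, i+1 with
#' the two peptide-bond torsions around residue i set exactly to
#' `omega_prev` and `omega_next`; used to exercise the omega banding rules.
#'
#' @param omega_prev,omega_next Peptide-bond torsions in degrees; pass `NA`
#'   to omit the corresponding flanking atoms (missing-value case).
#' @param phi,psi Intervening backbone torsions (degrees, defaults typical of
#'   an extended chain).
#' @return A `coordinate_set` with `resno` 1..3 and names CA/C/N.
#' @export
omega_fixture <- function(omega_prev = 180, omega_next = 180,
                          phi = -120, psi = 130) {
  d_can <- 1.33   # C-N peptide bond
  d_nca <- 1.46
  d_cac <- 1.52
  a_cacn <- 116
  a_cnca <- 121.7
  a_ncac <- 111
  p1 <- c(0, 0, 0)                 # CA(i-1)
  p2 <- c(d_cac, 0, 0)             # C(i-1)
  p3 <- place_atom(c(-1, 1, 0), p1, p2, d_can, a_cacn, 55)  # N(i)
  atoms <- list(
    list("CA", 1L, p1), list("C", 1L, p2), list("N", 2L, p3)
  )
  if (!is.na(omega_prev)) {
    p4 <- place_atom(p1, p2, p3, d_nca, a_cnca, omega_prev)  # CA(i)
    p5 <- place_atom(p2, p3, p4, d_cac, a_ncac, phi)         # C(i)
    atoms <- c(atoms, list(list("CA", 2L, p4), list("C", 2L, p5)))
    if (!is.na(omega_next)) {
      p6 <- place_atom(p3, p4, p5, d_can, a_cacn, psi)       # N(i+1)
      p7 <- place_atom(p4, p5, p6, d_nca, a_cnca, omega_next) # CA(i+1)
      atoms <- c(atoms, list(list("N", 3L, p6), list("CA", 3L, p7)))
    }
  }
  coordinate_set(tibble::tibble(
    name = vapply(atoms, `[[`, character(1), 1),
    element = substr(vapply(atoms, `[[`, character(1), 1), 1, 1),
    resno = vapply(atoms, `[[`, integer(1), 2),
    x = vapply(atoms, function(a) a[[3]][1], numeric(1)),
    y = vapply(atoms, function(a) a[[3]][2], numeric(1)),
    z = vapply(atoms, function(a) a[[3]][3], numeric(1))
  ))
}

#' Write every packaged fixture into a directory
#'
#' @param out_dir Target directory.
#' @return Invisibly, a list of the written paths.
#' @export
write_fixtures <- function(out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  lib <- mini_component_library(out_dir, gzip = TRUE)
  decoys <- decoy_component_library(out_dir)
  panel_path <- file.path(out_dir, "toy_molecules.smi")
  panel <- toy_molecule_set()
  writeLines(paste(panel$smiles, panel$id), panel_path)
  invisible(list(library = lib, decoys = decoys, panel = panel_path))
}
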