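#' Generate a 3D conformer for an accepted residue molecule
#'
#' Embeds one conformer with seeded distance geometry (ETKDG through the
#' RDKit backend, the default) followed by optional force-field relaxation
#' (MMFF94, falling back to UFF). Deterministic for a fixed (molecule, seed,
#' optimize) triple. On embedding failure the seed is incremented and retried
#' up to 3 times before erroring. The alternative `"openbabel"` engine
#' (`--gen3d`) is provided for cross-checking; it does not take a seed and is
#' documented as non-deterministic.
#'
#' @param mol An `rk_mol` or SMILES string.
#' @param seed Integer random seed for the distance-geometry embedding.
#' @param optimize Apply force-field relaxation? Default `TRUE`.
#' @param engine `"rdkit"` (default, seeded) or `"openbabel"`.
#' @return A numeric matrix (atoms x 3, rows aligned with `mol$atoms`) with
#'   attributes `seed_used`, `optimized`, `engine`.
#' @examples
#' \dontrun{
#' mol <- parse_molecule("NCC(=O)O")
#' xyz <- embed_conformer(mol, seed = 42)
#' }
#' @export
embed_conformer <- function(mol, seed = 42L, optimize = TRUE,
                            engine = c("rdkit", "openbabel")) {
  engine <- match.arg(engine)
  mol <- as_rk_mol(mol)
  if (engine == "rdkit") {
    embed_rdkit(mol, seed, optimize)
  } else {
    embed_openbabel(mol, optimize)
  }
}

embed_rdkit <- function(mol, seed, optimize) {
  script <- system.file("python", "embed_conformer.py", package = "residuekit")
  if (!nzchar(script)) {
    # during in-source development
    script <- file.path("inst", "python", "embed_conformer.py")
  }
  python <- Sys.which("python")
  if (!nzchar(python)) python <- Sys.which("python3")
  if (!nzchar(python)) {
    rk_abort("No python interpreter found for the RDKit conformer engine",
             class = "residuekit_dependency_error")
  }
  out <- suppressWarnings(system2(
    python,
    c(shQuote(script), shQuote(mol$smiles), as.integer(seed),
      if (optimize) "1" else "0"),
    stdout = TRUE, stderr = FALSE
  ))
  status <- attr(out, "status") %||% 0L
  if (status != 0 || length(out) < 2) {
    rk_abort(paste0("Conformer embedding failed for '", mol$smiles,
                    "' (3 attempts, seeds ", seed, "-", seed + 2, ")"),
             class = "residuekit_embedding_error", smiles = mol$smiles)
  }
  seed_used <- as.integer(sub("^SEED_USED ", "", out[1]))
  parsed <- parse_molblock(paste(out[-1], collapse = "\n"))
  coords <- align_conformer_atoms(mol, parsed)
  structure(coords, seed_used = seed_used, optimized = optimize,
            engine = "rdkit")
}

embed_openbabel <- function(mol, optimize) {
  sdf <- ob_smiles_to_sdf(mol$smiles, hydrogens = TRUE, gen3d = TRUE)
  parsed <- parse_molblock(sdf)
  coords <- align_conformer_atoms(mol, parsed)
  structure(coords, seed_used = NA_integer_, optimized = optimize,
            engine = "openbabel")
}

# Both engines parse the same canonical SMILES, so heavy atoms correspond
# positionally; explicit hydrogens are re-associated through their heavy
# parent (k-th hydrogen of heavy atom j on either side).
align_conformer_atoms <- function(mol, parsed) {
  n <- nrow(mol$atoms)
  if (nrow(parsed$atoms) != n) {
    rk_abort("Conformer atom count does not match molecule",
             class = "residuekit_embedding_error")
  }
  heavy_ours <- which(mol$atoms$heavy)
  heavy_theirs <- which(parsed$atoms$element != "H")
  if (!identical(mol$atoms$element[heavy_ours],
                 parsed$atoms$element[heavy_theirs])) {
    rk_abort("Conformer heavy-atom elements do not match molecule",
             class = "residuekit_embedding_error")
  }
  coords <- matrix(NA_real_, n, 3)
  coords[heavy_ours, ] <- as.matrix(
    parsed$atoms[heavy_theirs, c("x", "y", "z")]
  )
  # hydrogens by parent correspondence
  h_parent <- function(atoms, bonds, h) {
    nb <- c(bonds$a2[bonds$a1 == h], bonds$a1[bonds$a2 == h])
    nb[1]
  }
  ours_h <- setdiff(seq_len(n), heavy_ours)
  theirs_h <- setdiff(seq_len(n), heavy_theirs)
  our_parents <- vapply(ours_h, function(h)
    match(h_parent(mol$atoms, mol$bonds, h), heavy_ours), integer(1))
  their_parents <- vapply(theirs_h, function(h)
    match(h_parent(parsed$atoms, parsed$bonds, h), heavy_theirs), integer(1))
  for (p in unique(our_parents)) {
    mine <- ours_h[our_parents == p]
    theirs <- theirs_h[their_parents == p]
    if (length(mine) != length(theirs)) {
      rk_abort("Hydrogen layout mismatch between molecule and conformer",
               class = "residuekit_embedding_error")
    }
    coords[mine, ] <- as.matrix(
      parsed$atoms[theirs, c("x", "y", "z")]
    )
  }
  colnames(coords) <- c("x", "y", "z")
  coords
}

#' Assign backbone roles from a classification
#'
#' Maps the stored N -> Ccarb shortest path onto the roles N, C1..Ck, Ccarb
#' and assigns the carboxyl oxygens O1 (double-bonded) and O2 (single-bonded).
#'
#' @param mol An `rk_mol` or SMILES string.
#' @param cls A [classify_backbone()] result with label alpha/beta/gamma.
#' @return Named integer vector of atom indices with names `N`, `C1`..`Ck`,
#'   `Ccarb`, `O1`, `O2`.
#' @export
recognize_backbone <- function(mol, cls = NULL) {
  mol <- as_rk_mol(mol)
  cls <- cls %||% classify_backbone(mol)
  if (!cls$label %in% c("alpha", "beta", "gamma")) {
    rk_abort("Backbone roles require an accepted alpha/beta/gamma molecule",
             class = "residuekit_topology_error")
  }
  path <- cls$path_atoms
  k <- length(path) - 2  # backbone carbons between N and Ccarb
  roles <- c(path[1], path[2:(1 + k)], cls$ccarb_index,
             cls$o_double_index, cls$o_single_index)
  names(roles) <- c("N", paste0("C", seq_len(k)), "Ccarb", "O1", "O2")
  roles
}

# Greek position letters used for CCD-style side-chain names
GREEK_POSITIONS <- c("B", "G", "D", "E", "Z", "H")

#' Convert atom indices to CCD-style residue atom names
#'
#' Backbone atoms receive the conventional labels (alpha residues: N, CA, C,
#' O, with the second carboxyl oxygen as OXT; beta/gamma residues follow the
#' beta-alanine convention where the carbonyl-adjacent carbon is CA and the
#' nitrogen-adjacent carbon CB/CG). Side chains are walked breadth-first from
#' their backbone attachment and named element symbol + Greek position letter
#' (CB, CG, CD, ..., NZ, OG, ...) with numeric suffixes when several atoms
#' share a position; atoms beyond the Greek range or clashing after
#' suffixing fall back to a deterministic element+counter scheme. Hydrogens
#' are named after their heavy atom (HA; HB2/HB3 for methylenes under the
#' default modern-PDB dialect; H/H2/H3 on the backbone nitrogen; HXT on the
#' acid oxygen).
#'
#' @param mol An `rk_mol` or SMILES string.
#' @param backbone_map A [recognize_backbone()] role vector.
#' @param coords Optional conformer matrix from [embed_conformer()].
#' @param scheme `"ccd"` (default, Greek convention) or `"sequential"`
#'   (backbone carbons named C1..Ck).
#' @param dialect Hydrogen suffix dialect: `"pdb3"` (modern, HB2/HB3) or
#'   `"pdb2"` (HB1/HB2).
#' @param template_names Optional character vector of heavy-atom names in
#'   canonical atom order, adopted verbatim (coordinates remain the
#'   embedder's); used when a mapped reference component provides topology
#'   names.
#' @return A tibble of named atoms: `idx`, `element`, `name`, `charge`,
#'   `x`, `y`, `z`, `is_backbone`, `parent_heavy`.
#' @export
assign_atom_names <- function(mol, backbone_map, coords = NULL,
                              scheme = c("ccd", "sequential"),
                              dialect = c("pdb3", "pdb2"),
                              template_names = NULL) {
  scheme <- match.arg(scheme)
  dialect <- match.arg(dialect)
  mol <- as_rk_mol(mol)
  a <- mol$atoms
  n <- nrow(a)
  heavy_idx <- which(a$heavy)
  name <- rep(NA_character_, n)
  used <- character()

  claim <- function(proposal, element) {
    # enforce uniqueness and the 4-character limit deterministically
    if (nchar(proposal) <= 4 && !proposal %in% used) return(proposal)
    k <- 1
    repeat {
      cand <- paste0(element, k)
      if (nchar(cand) <= 4 && !cand %in% used) return(cand)
      k <- k + 1
    }
  }

  if (!is.null(template_names)) {
    if (length(template_names) != length(heavy_idx)) {
      rk_abort("template_names length must equal the heavy-atom count",
               class = "residuekit_topology_error")
    }
    for (i in seq_along(heavy_idx)) {
      nm <- claim(template_names[i], a$element[heavy_idx[i]])
      name[heavy_idx[i]] <- nm
      used <- c(used, nm)
    }
  } else {
    carbons <- grep("^C[0-9]+$", names(backbone_map), value = TRUE)
    k <- length(carbons)
    bb_names <- c(N = "N", Ccarb = "C", O1 = "O", O2 = "OXT")
    if (scheme == "ccd") {
      # carbonyl-adjacent carbon is CA; walking toward N: CB, CG
      pos <- c("CA", "CB", "CG")
      for (j in seq_len(k)) bb_names[paste0("C", j)] <- pos[k - j + 1]
    } else {
      for (j in seq_len(k)) bb_names[paste0("C", j)] <- paste0("C", j)
    }
    for (role in names(backbone_map)) {
      nm <- claim(bb_names[[role]], a$element[backbone_map[[role]]])
      name[backbone_map[[role]]] <- nm
      used <- c(used, nm)
    }

    # breadth-first walk of the side chains from the backbone attachments;
    # all backbone atoms (including the carboxyl oxygens) are marked visited
    sources <- backbone_map[setdiff(names(backbone_map), c("O1", "O2"))]
    depth <- rep(NA_integer_, n)
    depth[as.integer(backbone_map)] <- 0L
    frontier <- as.integer(sources)
    order_found <- integer()
    while (length(frontier) > 0) {
      nxt <- integer()
      for (i in sort(frontier)) {
        for (nb in sort(atom_neighbors(mol, i, heavy_only = TRUE))) {
          if (is.na(depth[nb])) {
            depth[nb] <- depth[i] + 1L
            order_found <- c(order_found, nb)
            nxt <- c(nxt, nb)
          }
        }
      }
      frontier <- nxt
    }
    side <- order_found
    # group by (element, depth) to decide numeric suffixes
    grp_key <- paste(a$element[side], depth[side])
    grp_n <- table(grp_key)
    grp_seen <- stats::setNames(rep(0L, length(grp_n)), names(grp_n))
    for (i in side) {
      key <- paste(a$element[i], depth[i])
      grp_seen[key] <- grp_seen[key] + 1L
      d <- depth[i]
      proposal <- if (d >= 1 && d <= length(GREEK_POSITIONS)) {
        base <- paste0(a$element[i], GREEK_POSITIONS[d])
        if (grp_n[key] > 1) paste0(base, grp_seen[key]) else base
      } else {
        paste0(a$element[i], "X")  # forces the element+counter fallback
      }
      nm <- claim(proposal, a$element[i])
      name[i] <- nm
      used <- c(used, nm)
    }
    # disconnected heavy atoms (should not occur for accepted molecules)
    for (i in heavy_idx[is.na(name[heavy_idx])]) {
      nm <- claim(paste0(a$element[i], "X"), a$element[i])
      name[i] <- nm
      used <- c(used, nm)
    }
  }

  # hydrogens: named after their heavy atom
  parent_heavy <- rep(NA_character_, n)
  h_idx <- which(!a$heavy)
  suffix2 <- if (dialect == "pdb3") c("2", "3") else c("1", "2")
  for (p in heavy_idx) {
    hs <- intersect(atom_neighbors(mol, p), h_idx)
    if (length(hs) == 0) next
    stem <- sub(paste0("^", a$element[p]), "", name[p])
    base <- paste0("H", stem)
    proposals <- if (length(hs) == 1) {
      base
    } else if (nzchar(stem) && length(hs) == 2) {
      paste0(base, suffix2)
    } else if (nzchar(stem)) {
      paste0(base, seq_along(hs))
    } else {
      # backbone-nitrogen style: H, H2, H3
      c(base, paste0(base, 1 + seq_len(length(hs) - 1)))
    }
    for (j in seq_along(hs)) {
      nm <- claim(proposals[j], "H")
      name[hs[j]] <- nm
      used <- c(used, nm)
      parent_heavy[hs[j]] <- name[p]
    }
  }

  xyz <- if (is.null(coords)) {
    matrix(NA_real_, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  } else {
    coords
  }
  tibble::tibble(
    idx = a$idx,
    element = a$element,
    name = name,
    charge = a$charge,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    is_backbone = a$idx %in% as.integer(backbone_map),
    parent_heavy = parent_heavy
  )
}

#' Build a validated residue topology
#'
#' Converts the bond table into atom-name space, carries the backbone role
#' map, and checks the structural invariants (name uniqueness, bond
#' referential integrity, connectivity, role completeness).
#'
#' @param mol An `rk_mol` or SMILES string.
#' @param named_atoms Output of [assign_atom_names()].
#' @param backbone_map A [recognize_backbone()] role vector.
#' @param residue_class `"alpha"`, `"beta"` or `"gamma"`.
#' @return A `residue_topology`: list with `residue_class`, `atoms`, `bonds`
#'   (tibble: `atom1`, `atom2`, `order` in single/double/triple, `aromatic`)
#'   and `backbone_map` (roles to atom names).
#' @export
build_topology <- function(mol, named_atoms, backbone_map, residue_class) {
  mol <- as_rk_mol(mol)
  stopifnot(residue_class %in% c("alpha", "beta", "gamma"))
  nm <- named_atoms$name
  bonds <- tibble::tibble(
    atom1 = nm[mol$bonds$a1],
    atom2 = nm[mol$bonds$a2],
    order = c("single", "double", "triple")[mol$bonds$order],
    aromatic = mol$bonds$aromatic
  )
  role_names <- stats::setNames(nm[as.integer(backbone_map)],
                                names(backbone_map))
  topo <- structure(
    list(residue_class = residue_class,
         atoms = named_atoms,
         bonds = bonds,
         backbone_map = role_names),
    class = "residue_topology"
  )
  validate_topology(topo)
  topo
}

#' @export
print.residue_topology <- function(x, ...) {
  cat("<residue_topology> ", x$residue_class, " residue, ",
      nrow(x$atoms), " atoms, ", nrow(x$bonds), " bonds\n", sep = "")
  cat("  backbone:", paste(names(x$backbone_map), x$backbone_map,
                           sep = "=", collapse = " "), "\n")
  invisible(x)
}

validate_topology <- function(topo) {
  atoms <- topo$atoms
  bonds <- topo$bonds
  problems <- character()
  if (anyNA(atoms$name)) problems <- c(problems, "unnamed atoms present")
  if (anyDuplicated(atoms$name)) {
    problems <- c(problems, paste("duplicate atom names:",
      paste(unique(atoms$name[duplicated(atoms$name)]), collapse = ", ")))
  }
  bad_ref <- unique(c(bonds$atom1, bonds$atom2))
  bad_ref <- bad_ref[!bad_ref %in% atoms$name]
  if (length(bad_ref)) {
    problems <- c(problems, paste("bonds reference unknown atoms:",
                                  paste(bad_ref, collapse = ", ")))
  }
  if (any(bonds$atom1 == bonds$atom2)) {
    problems <- c(problems, "self-bonds present")
  }
  key <- paste(pmin(bonds$atom1, bonds$atom2), pmax(bonds$atom1, bonds$atom2))
  if (anyDuplicated(key)) problems <- c(problems, "duplicate bonds present")
  expected_roles <- c("N", "Ccarb", "O1", "O2",
    paste0("C", seq_len(switch(topo$residue_class,
                               alpha = 1, beta = 2, gamma = 3))))
  missing_roles <- setdiff(expected_roles, names(topo$backbone_map))
  if (length(missing_roles)) {
    problems <- c(problems, paste("missing backbone roles:",
                                  paste(missing_roles, collapse = ", ")))
  }
  if (length(problems) == 0 && nrow(atoms) > 1) {
    g <- igraph::graph_from_data_frame(
      bonds[, c("atom1", "atom2")], directed = FALSE,
      vertices = data.frame(name = atoms$name)
    )
    if (igraph::count_components(g) != 1) {
      problems <- c(problems, "bond graph is disconnected")
    }
  }
  if (length(problems)) {
    rk_abort(paste0("Invalid residue topology: ",
                    paste(problems, collapse = "; ")),
             class = "residuekit_topology_error", problems = problems)
  }
  invisible(topo)
}

#' One-call residue construction from SMILES
#'
#' Convenience wrapper: classify, check scope, embed, name and build, with
#' optional topology-template adoption from a mapped reference component.
#'
#' @param smiles Input SMILES.
#' @param library Optional [read_component_library()] index; when the query
#'   maps with high confidence to a component carrying atom names, those are
#'   adopted for the matched atoms.
#' @param seed,optimize Passed to [embed_conformer()].
#' @param ... Passed to [assign_atom_names()].
#' @return A `residue_definition`, see [new_residue_definition()].
#' @export
build_residue <- function(smiles, library = NULL, seed = 42L,
                          optimize = TRUE, ...) {
  mol <- as_rk_mol(smiles)
  decision <- apply_scope_filters(mol)
  if (!decision$accepted) {
    rk_abort(paste0("Molecule out of residue scope: ",
                    paste(decision$exclusion_flags, collapse = ";")),
             class = "residuekit_scope_error",
             flags = decision$exclusion_flags)
  }
  cls <- decision$classification
  bb <- recognize_backbone(mol, cls)
  coords <- embed_conformer(mol, seed = seed, optimize = optimize)

  template_names <- NULL
  template_id <- NA_character_
  if (!is.null(library)) {
    mapping <- map_query_to_ccd(mol, library)
    if (mapping$mode == "full_key" && nrow(mapping$candidates) > 0) {
      cand_id <- mapping$candidates$component_id[1]
      comp <- library$components
      row <- comp[comp$component_id == cand_id, ]
      tn <- row$atom_names[[1]]
      if (!is.null(tn) && length(tn) == mol$n_heavy &&
          identical(row$smiles, mol$smiles)) {
        template_names <- tn
        template_id <- cand_id
      }
    }
  }
  named <- assign_atom_names(mol, bb, coords = coords,
                             template_names = template_names, ...)
  topo <- build_topology(mol, named, bb, cls$label)
  new_residue_definition(
    topology = topo, mol = mol,
    seed = attr(coords, "seed_used"),
    optimize = attr(coords, "optimized"),
    template_id = template_id
  )
}
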