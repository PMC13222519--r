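#' Parse a SMILES string into a query molecule
#'
#' Parses a SMILES string through Open Babel, optionally strips salts/counter
#' ions by keeping the largest organic fragment, and normalises the molecule to
#' canonical-SMILES atom order with explicit hydrogens appended after the heavy
#' atoms. The canonical-order convention means two inputs describing the same
#' molecular graph yield atom tables in the same order, which downstream code
#' (fingerprints, template-name adoption) relies on.
#'
#' @param smiles A single SMILES string.
#' @param strip_salt Keep only the largest fragment (by heavy-atom count, ties
#'   broken by molecular weight)? Default `TRUE`.
#' @return An object of class `rk_mol`: a list with elements
#'   \describe{
#'     \item{source_smiles}{the input string}
#'     \item{smiles}{canonical SMILES of the retained fragment}
#'     \item{atoms}{tibble with columns `idx`, `element`, `charge`,
#'       `aromatic`, `heavy`, `h_count`}
#'     \item{bonds}{tibble with columns `a1`, `a2`, `order`, `aromatic`,
#'       `in_ring`}
#'   }
#' @examples
#' \dontrun{
#' mol <- parse_molecule("NCC(=O)O")
#' mol$atoms
#' }
#' @export
parse_molecule <- function(smiles, strip_salt = TRUE) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  can0 <- ob_canonical(smiles)
  if (is.na(can0) || !nzchar(can0)) {
    rk_abort(paste0("Could not parse SMILES: '", smiles, "'"),
             class = "residuekit_parse_error", smiles = smiles)
  }
  frags <- strsplit(can0, ".", fixed = TRUE)[[1]]
  if (length(frags) > 1 && strip_salt) {
    keep <- pick_largest_fragment(frags)
    can <- ob_canonical(keep)
  } else {
    can <- can0
  }
  sdf_text <- ob_smiles_to_sdf(can, hydrogens = TRUE)
  parsed <- parse_molblock(sdf_text)
  atoms <- parsed$atoms
  bonds <- parsed$bonds

  # aromatic perception from the canonical SMILES the SDF was generated from:
  # heavy atoms appear in SMILES order, explicit hydrogens follow.
  flags <- smiles_atom_flags(can)
  n_heavy <- nrow(flags)
  if (n_heavy > sum(atoms$element != "H")) {
    # explicit [H] atoms written in the SMILES: treat every lexer atom in order
    n_heavy <- sum(atoms$element != "H")
  }
  atoms$aromatic <- FALSE
  atoms$aromatic[seq_len(n_heavy)] <- flags$aromatic[seq_len(n_heavy)]
  atoms$heavy <- atoms$element != "H"

  # ring bonds: edges not bridging the bond graph
  g <- igraph::graph_from_data_frame(
    bonds[, c("a1", "a2")], directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(atoms)))
  )
  bridge_ids <- igraph::bridges(g)
  bonds$in_ring <- !seq_len(nrow(bonds)) %in% as.integer(bridge_ids)
  bonds$aromatic <- bonds$in_ring &
    atoms$aromatic[bonds$a1] & atoms$aromatic[bonds$a2]

  # hydrogen counts on heavy atoms (explicit H were added before parsing)
  h_idx <- which(!atoms$heavy)
  atoms$h_count <- vapply(seq_len(nrow(atoms)), function(i) {
    nb <- c(bonds$a2[bonds$a1 == i], bonds$a1[bonds$a2 == i])
    sum(nb %in% h_idx)
  }, integer(1))

  structure(
    list(
      source_smiles = smiles,
      smiles = can,
      atoms = atoms,
      bonds = bonds,
      n_heavy = sum(atoms$heavy)
    ),
    class = "rk_mol"
  )
}

#' @export
print.rk_mol <- function(x, ...) {
  cat("<rk_mol> ", x$smiles, "\n", sep = "")
  cat("  atoms: ", nrow(x$atoms), " (", x$n_heavy, " heavy), bonds: ",
      nrow(x$bonds), "\n", sep = "")
  invisible(x)
}

# coerce SMILES-or-mol arguments
as_rk_mol <- function(x, strip_salt = TRUE) {
  if (inherits(x, "rk_mol")) return(x)
  parse_molecule(x, strip_salt = strip_salt)
}

#' Basic molecular properties used by the scope filters
#'
#' @param mol An `rk_mol` or SMILES string.
#' @return A one-row tibble with `mw`, `heavy_atoms`, `heteroatoms`,
#'   `ring_count` (graph cycle rank, equal to the SSSR size), and
#'   `elements` (list column).
#' @export
molecular_properties <- function(mol) {
  mol <- as_rk_mol(mol)
  heavy <- mol$atoms[mol$atoms$heavy, ]
  hb <- mol$bonds[mol$bonds$a1 %in% heavy$idx & mol$bonds$a2 %in% heavy$idx, ]
  comp <- igraph::count_components(heavy_graph(mol))
  tibble::tibble(
    mw = ob_molecular_weight(mol$smiles),
    heavy_atoms = nrow(heavy),
    heteroatoms = sum(!heavy$element %in% c("C", "H")),
    ring_count = nrow(hb) - nrow(heavy) + comp,
    elements = list(sort(unique(mol$atoms$element)))
  )
}

# igraph over heavy atoms only, vertex names = atom idx
heavy_graph <- function(mol) {
  heavy <- mol$atoms$idx[mol$atoms$heavy]
  hb <- mol$bonds[mol$bonds$a1 %in% heavy & mol$bonds$a2 %in% heavy, ]
  igraph::graph_from_data_frame(
    data.frame(from = as.character(hb$a1), to = as.character(hb$a2)),
    directed = FALSE,
    vertices = data.frame(name = as.character(heavy))
  )
}

# neighbours (atom indices) of atom i, optionally restricted to heavy atoms
atom_neighbors <- function(mol, i, heavy_only = FALSE) {
  b <- mol$bonds
  nb <- c(b$a2[b$a1 == i], b$a1[b$a2 == i])
  if (heavy_only) nb <- nb[mol$atoms$heavy[nb]]
  nb
}

# bond order between atoms i and j (0 when not bonded)
bond_order <- function(mol, i, j) {
  b <- mol$bonds
  hit <- (b$a1 == i & b$a2 == j) | (b$a1 == j & b$a2 == i)
  if (!any(hit)) return(0L)
  b$order[which(hit)[1]]
}

## ---- Open Babel wrappers -------------------------------------------------

ob_options <- function(...) {
  nm <- c(...)
  if (length(nm) == 0) {
    data.frame(names = character(), args = character())
  } else {
    data.frame(names = nm, args = rep("", length(nm)))
  }
}

# Canonical SMILES (retains stereo); returns NA on parse failure.
ob_canonical <- function(smiles) {
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", smiles, options = ob_options()),
    error = function(e) ""
  )
  out <- sub("[\t\n ].*$", "", out)
  if (!nzchar(out)) NA_character_ else out
}

# SMILES -> single V2000 molblock with explicit hydrogens and 2D layout.
ob_smiles_to_sdf <- function(smiles, hydrogens = TRUE, gen3d = FALSE) {
  opts <- if (gen3d) {
    ob_options(if (hydrogens) "h", "gen3D")
  } else {
    ob_options(if (hydrogens) "h", "gen2D")
  }
  ChemmineOB::convertFormat("SMI", "SDF", smiles, options = opts)
}

ob_sdf_to_canonical <- function(sdf_text) {
  out <- tryCatch(
    ChemmineOB::convertFormat("SDF", "CAN", sdf_text, options = ob_options()),
    error = function(e) ""
  )
  out <- sub("[\t\n ].*$", "", out)
  if (!nzchar(out)) NA_character_ else out
}

ob_molecular_weight <- function(smiles) {
  props <- ChemmineOB::forEachMol("SMILES", smiles, function(m) {
    ChemmineOB::prop_OB(c(m))
  })
  as.numeric(props[[1]]$MW)
}

## ---- molblock parsing ----------------------------------------------------

# Parse a single V2000 molblock (as emitted by Open Babel) into atom and bond
# tibbles. Formal charges are taken from M CHG lines.
parse_molblock <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  n_atoms <- as.integer(substr(counts, 1, 3))
  n_bonds <- as.integer(substr(counts, 4, 6))
  if (is.na(n_atoms) || n_atoms < 1) {
    rk_abort("Empty or malformed molblock", class = "residuekit_parse_error")
  }
  atom_lines <- lines[5:(4 + n_atoms)]
  bond_lines <- if (n_bonds > 0) lines[(5 + n_atoms):(4 + n_atoms + n_bonds)] else character()

  atoms <- tibble::tibble(
    idx = seq_len(n_atoms),
    element = trimws(substr(atom_lines, 32, 34)),
    x = as.numeric(substr(atom_lines, 1, 10)),
    y = as.numeric(substr(atom_lines, 11, 20)),
    z = as.numeric(substr(atom_lines, 21, 30)),
    charge = 0L
  )
  bonds <- tibble::tibble(
    a1 = as.integer(substr(bond_lines, 1, 3)),
    a2 = as.integer(substr(bond_lines, 4, 6)),
    order = as.integer(substr(bond_lines, 7, 9))
  )
  for (chg_line in grep("^M  CHG", lines, value = TRUE)) {
    flds <- as.integer(strsplit(trimws(sub("^M  CHG", "", chg_line)),
                                "\\s+")[[1]])
    n <- flds[1]
    for (k in seq_len(n)) {
      atoms$charge[flds[2 * k]] <- flds[2 * k + 1]
    }
  }
  list(atoms = atoms, bonds = bonds)
}

## ---- SMILES atom lexer ---------------------------------------------------

# Walk a SMILES string and return, per atom in order of appearance, the
# element symbol and whether it was written in aromatic (lowercase) form.
# Only needs to cover what Open Babel canonical SMILES emits.
smiles_atom_flags <- function(smiles) {
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)
  elements <- character()
  aromatic <- logical()
  i <- 1
  two_letter_aromatic <- c("se", "as", "te", "si")
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1
      content <- paste(chars[(i + 1):(j - 1)], collapse = "")
      content <- sub("^[0-9]*", "", content)  # isotope
      m <- regmatches(content, regexpr("^[A-Za-z][a-z]?", content))[1]
      if (grepl("^[a-z]", m)) {
        sym <- if (m %in% two_letter_aromatic) m else substr(m, 1, 1)
        el <- paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
        elements <- c(elements, el)
        aromatic <- c(aromatic, TRUE)
      } else {
        # the H-count marker inside brackets is uppercase, so ^[A-Z][a-z]?
        # never absorbs it; a 2-char match is taken only if it is an element
        el <- if (m %in% ELEMENT_SYMBOLS) m else substr(m, 1, 1)
        elements <- c(elements, el)
        aromatic <- c(aromatic, FALSE)
      }
      i <- j + 1
    } else if (ch %in% c("C", "B", "N", "O", "P", "S", "F", "I")) {
      if (ch == "C" && i < n && chars[i + 1] == "l") {
        elements <- c(elements, "Cl"); aromatic <- c(aromatic, FALSE); i <- i + 2
      } else if (ch == "B" && i < n && chars[i + 1] == "r") {
        elements <- c(elements, "Br"); aromatic <- c(aromatic, FALSE); i <- i + 2
      } else {
        elements <- c(elements, ch); aromatic <- c(aromatic, FALSE); i <- i + 1
      }
    } else if (ch %in% c("c", "b", "n", "o", "p", "s")) {
      elements <- c(elements, toupper(ch)); aromatic <- c(aromatic, TRUE); i <- i + 1
    } else if (ch == "%") {
      i <- i + 3  # two-digit ring closure
    } else {
      i <- i + 1  # bonds, branches, ring digits, dots, stereo marks
    }
  }
  tibble::tibble(element = elements, aromatic = aromatic)
}
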