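#' Default complexity and robustness limits for residue screening
#'
#' Thresholds applied by [apply_scope_filters()]. The defaults are artifact
#' choices documented in the methods vignette: molecular weight <= 600 Da,
#' rings <= 4, heavy atoms <= 40, heteroatoms <= 12, free acids <= 2.
#'
#' @param max_mw Maximum molecular weight (Da).
#' @param max_rings Maximum ring count (SSSR size).
#' @param max_heavy_atoms Maximum heavy-atom count.
#' @param max_heteroatoms Maximum heteroatom (non C/H) count.
#' @param max_acids Maximum number of free carboxyl groups.
#' @return A named list of limits.
#' @export
scope_limits <- function(max_mw = 600, max_rings = 4, max_heavy_atoms = 40,
                         max_heteroatoms = 12, max_acids = 2) {
  list(max_mw = max_mw, max_rings = max_rings,
       max_heavy_atoms = max_heavy_atoms,
       max_heteroatoms = max_heteroatoms, max_acids = max_acids)
}

#' Locate free carboxyl groups
#'
#' Finds every carbon bonded to exactly one double-bonded terminal oxygen and
#' one single-bonded terminal oxygen (free acid or carboxylate anion). Ester
#' and carbonate carbons, whose single-bonded oxygen carries another heavy
#' atom, are not sites.
#'
#' @param mol An `rk_mol` or SMILES string.
#' @return A tibble with one row per site: `carbon_index`, `o_double_index`,
#'   `o_single_index`.
#' @examples
#' \dontrun{
#' find_carboxyl_sites("CC(=O)O")            # 1 site
#' find_carboxyl_sites("NC(CC(=O)O)C(=O)O")  # 2 sites
#' }
#' @export
find_carboxyl_sites <- function(mol) {
  mol <- as_rk_mol(mol)
  a <- mol$atoms
  out <- list()
  for (c_idx in a$idx[a$element == "C"]) {
    nb <- atom_neighbors(mol, c_idx, heavy_only = TRUE)
    o_nb <- nb[a$element[nb] == "O"]
    if (length(o_nb) < 2) next
    term <- vapply(o_nb, function(o) {
      length(atom_neighbors(mol, o, heavy_only = TRUE)) == 1
    }, logical(1))
    o_double <- o_nb[term & vapply(o_nb, function(o)
      bond_order(mol, c_idx, o) == 2L, logical(1))]
    o_single <- o_nb[term & vapply(o_nb, function(o)
      bond_order(mol, c_idx, o) == 1L, logical(1))]
    if (length(o_double) == 1 && length(o_single) >= 1) {
      out[[length(out) + 1]] <- tibble::tibble(
        carbon_index = c_idx,
        o_double_index = o_double[1],
        o_single_index = min(o_single)
      )
    }
  }
  if (length(out) == 0) {
    tibble::tibble(carbon_index = integer(), o_double_index = integer(),
                   o_single_index = integer())
  } else {
    dplyr::bind_rows(out)
  }
}

#' Locate candidate amino nitrogens
#'
#' Collects all nitrogens except those in nitro and nitrile groups, annotating
#' each with its hydrogen count, amide status and heavy-atom degree. Under the
#' default flags, amide nitrogens, nitrogens with heavy degree > 3 and
#' nitrogens without hydrogens are removed, matching the free-amine scope rule
#' (a nonamide N with at least one H).
#'
#' @param mol An `rk_mol` or SMILES string.
#' @param allow_amide Keep amide nitrogens?
#' @param allow_quaternary Keep quaternary / H-free nitrogen centres?
#' @return A tibble with columns `nitrogen_index`, `h_count`, `is_amide`,
#'   `heavy_degree`.
#' @export
find_amine_sites <- function(mol, allow_amide = FALSE,
                             allow_quaternary = FALSE) {
  mol <- as_rk_mol(mol)
  a <- mol$atoms
  acid_carbons <- find_carboxyl_sites(mol)$carbon_index
  rows <- list()
  for (n_idx in a$idx[a$element == "N"]) {
    nb <- atom_neighbors(mol, n_idx, heavy_only = TRUE)
    # nitro: N with >= 2 terminal oxygens
    o_term <- sum(a$element[nb] == "O" & vapply(nb, function(o)
      length(atom_neighbors(mol, o, heavy_only = TRUE)) == 1, logical(1)))
    if (o_term >= 2) next
    # nitrile: N in a triple bond
    if (any(vapply(nb, function(x)
      bond_order(mol, n_idx, x) == 3L, logical(1)))) next
    is_amide <- any(vapply(nb, function(cn) {
      if (a$element[cn] != "C" || cn %in% acid_carbons) return(FALSE)
      cnb <- atom_neighbors(mol, cn, heavy_only = TRUE)
      any(a$element[cnb] == "O" &
            vapply(cnb, function(o) bond_order(mol, cn, o) == 2L, logical(1)))
    }, logical(1)))
    rows[[length(rows) + 1]] <- tibble::tibble(
      nitrogen_index = n_idx,
      h_count = a$h_count[n_idx],
      is_amide = is_amide,
      heavy_degree = length(nb)
    )
  }
  sites <- if (length(rows) == 0) {
    tibble::tibble(nitrogen_index = integer(), h_count = integer(),
                   is_amide = logical(), heavy_degree = integer())
  } else {
    dplyr::bind_rows(rows)
  }
  if (!allow_amide) sites <- sites[!sites$is_amide, ]
  if (!allow_quaternary) {
    sites <- sites[sites$heavy_degree <= 3 & sites$h_count >= 1, ]
  }
  sites
}

#' Classify the amino-acid backbone as alpha, beta or gamma
#'
#' Computes bond-count shortest paths between every free carboxyl carbon and
#' every candidate amino nitrogen; the minimum path length determines the
#' class (2 bonds = alpha, 3 = beta, 4 = gamma, 5 or more = rejected). Ties
#' among minimal pairs are broken by the lexicographically smallest
#' (nitrogen index, carboxyl-carbon index).
#'
#' @param mol An `rk_mol` or SMILES string.
#' @param carboxyls Optional precomputed [find_carboxyl_sites()] table.
#' @param amines Optional precomputed [find_amine_sites()] table.
#' @return A `backbone_classification` list: `label`, `path_length_bonds`,
#'   `n_index`, `ccarb_index`, `path_atoms`, `o_double_index`,
#'   `o_single_index`.
#' @examples
#' \dontrun{
#' classify_backbone("NCC(=O)O")$label     # "alpha"
#' classify_backbone("NCCC(=O)O")$label    # "beta"
#' }
#' @export
classify_backbone <- function(mol, carboxyls = NULL, amines = NULL) {
  mol <- as_rk_mol(mol)
  carboxyls <- carboxyls %||% find_carboxyl_sites(mol)
  amines <- amines %||% find_amine_sites(mol)
  rejected <- function(len = NA_real_) {
    structure(list(label = "rejected", path_length_bonds = len,
                   n_index = NA_integer_, ccarb_index = NA_integer_,
                   path_atoms = integer(), o_double_index = NA_integer_,
                   o_single_index = NA_integer_),
              class = "backbone_classification")
  }
  if (nrow(carboxyls) == 0 || nrow(amines) == 0) return(rejected())

  g <- heavy_graph(mol)
  dmat <- igraph::distances(
    g,
    v = as.character(amines$nitrogen_index),
    to = as.character(carboxyls$carbon_index)
  )
  best <- Inf
  best_pair <- NULL
  for (i in order(amines$nitrogen_index)) {
    for (j in order(carboxyls$carbon_index)) {
      d <- dmat[i, j]
      if (d < best) {
        best <- d
        best_pair <- c(i, j)
      }
    }
  }
  if (!is.finite(best) || best >= 5) {
    return(rejected(if (is.finite(best)) best else Inf))
  }
  n_idx <- amines$nitrogen_index[best_pair[1]]
  site <- carboxyls[best_pair[2], ]
  sp <- igraph::shortest_paths(g, from = as.character(n_idx),
                               to = as.character(site$carbon_index))
  path_atoms <- as.integer(names(sp$vpath[[1]]))
  label <- c(`2` = "alpha", `3` = "beta", `4` = "gamma")[[as.character(best)]]
  structure(
    list(label = label, path_length_bonds = as.numeric(best),
         n_index = n_idx, ccarb_index = site$carbon_index,
         path_atoms = path_atoms,
         o_double_index = site$o_double_index,
         o_single_index = site$o_single_index),
    class = "backbone_classification"
  )
}

#' @export
print.backbone_classification <- function(x, ...) {
  cat("<backbone_classification> ", x$label,
      " (path ", x$path_length_bonds, " bonds)\n", sep = "")
  invisible(x)
}

#' Decide whether a classified molecule is in residue scope
#'
#' Evaluates the complexity/robustness limits and structural exclusion rules
#' and returns the accept/reject decision with machine-readable,
#' non-exclusive flags.
#'
#' @param mol An `rk_mol` or SMILES string.
#' @param cls Optional precomputed [classify_backbone()] result.
#' @param limits A [scope_limits()] list.
#' @return A `scope_decision` list: `accepted`, `classification`,
#'   `exclusion_flags` (character vector).
#' @export
apply_scope_filters <- function(mol, cls = NULL, limits = scope_limits()) {
  mol <- as_rk_mol(mol)
  carboxyls <- find_carboxyl_sites(mol)
  amines <- find_amine_sites(mol)
  cls <- cls %||% classify_backbone(mol, carboxyls, amines)
  flags <- character()

  props <- molecular_properties(mol)
  if (props$mw > limits$max_mw) flags <- c(flags, "mw_above_threshold")
  if (props$ring_count > limits$max_rings) {
    flags <- c(flags, "ring_count_above_threshold")
  }
  if (props$heavy_atoms > limits$max_heavy_atoms) {
    flags <- c(flags, "heavy_atom_count_above_threshold")
  }
  if (props$heteroatoms > limits$max_heteroatoms) {
    flags <- c(flags, "hetero_atom_count_above_threshold")
  }
  if (nrow(carboxyls) > limits$max_acids) {
    flags <- c(flags, "multi_acid_above_limit")
  }
  if (nrow(carboxyls) == 0) {
    flags <- c(flags, if (has_masked_acid(mol)) "masked_acid" else "no_carboxyl")
  }
  if (nrow(amines) == 0) flags <- c(flags, "no_amine")
  if (cls$label == "rejected" && nrow(carboxyls) > 0 && nrow(amines) > 0) {
    flags <- c(flags, "delta_or_longer")
  }
  if (is_oligomer(mol, carboxyls, amines)) flags <- c(flags, "oligomer")
  if (!all(props$elements[[1]] %in% ORGANIC_ELEMENTS)) {
    flags <- c(flags, "metal_or_coordination")
  }

  structure(
    list(
      accepted = length(flags) == 0 &&
        cls$label %in% c("alpha", "beta", "gamma"),
      classification = cls,
      exclusion_flags = flags
    ),
    class = "scope_decision"
  )
}

#' @export
print.scope_decision <- function(x, ...) {
  cat("<scope_decision> ", if (x$accepted) "accepted" else "rejected",
      " [", x$classification$label, "]", sep = "")
  if (length(x$exclusion_flags)) {
    cat(" flags:", paste(x$exclusion_flags, collapse = ";"))
  }
  cat("\n")
  invisible(x)
}

# ester / carbonate carbonyl whose single-bonded oxygen carries another heavy
# atom; used for the masked_acid flag when no free acid is present
has_masked_acid <- function(mol) {
  a <- mol$atoms
  for (c_idx in a$idx[a$element == "C"]) {
    nb <- atom_neighbors(mol, c_idx, heavy_only = TRUE)
    o_nb <- nb[a$element[nb] == "O"]
    if (length(o_nb) < 2) next
    has_dbl_term <- any(vapply(o_nb, function(o) {
      bond_order(mol, c_idx, o) == 2L &&
        length(atom_neighbors(mol, o, heavy_only = TRUE)) == 1
    }, logical(1)))
    has_single_bridging <- any(vapply(o_nb, function(o) {
      bond_order(mol, c_idx, o) == 1L &&
        length(atom_neighbors(mol, o, heavy_only = TRUE)) > 1
    }, logical(1)))
    if (has_dbl_term && has_single_bridging) return(TRUE)
  }
  FALSE
}

# amide bonds: C-N single bonds where the carbon also bears a double-bonded
# terminal oxygen; secondary = the nitrogen has >= 2 heavy neighbours
amide_bonds <- function(mol) {
  a <- mol$atoms
  out <- list()
  for (k in seq_len(nrow(mol$bonds))) {
    b <- mol$bonds[k, ]
    if (b$order != 1L) next
    pair <- c(b$a1, b$a2)
    c_idx <- pair[a$element[pair] == "C"]
    n_idx <- pair[a$element[pair] == "N"]
    if (length(c_idx) != 1 || length(n_idx) != 1) next
    cnb <- atom_neighbors(mol, c_idx, heavy_only = TRUE)
    carbonyl <- any(a$element[cnb] == "O" & vapply(cnb, function(o) {
      bond_order(mol, c_idx, o) == 2L &&
        length(atom_neighbors(mol, o, heavy_only = TRUE)) == 1
    }, logical(1)))
    if (!carbonyl) next
    out[[length(out) + 1]] <- tibble::tibble(
      c_index = c_idx, n_index = n_idx,
      secondary = length(atom_neighbors(mol, n_idx, heavy_only = TRUE)) >= 2
    )
  }
  if (length(out) == 0) {
    tibble::tibble(c_index = integer(), n_index = integer(),
                   secondary = logical())
  } else {
    dplyr::bind_rows(out)
  }
}

# oligomer rule: a secondary/tertiary amide on a candidate N->Ccarb shortest
# path, or >= 2 amide bonds anywhere (see methods vignette for the rationale)
is_oligomer <- function(mol, carboxyls, amines) {
  ab <- amide_bonds(mol)
  if (nrow(ab) >= 2) return(TRUE)
  if (nrow(ab) == 0 || !any(ab$secondary)) return(FALSE)
  if (nrow(carboxyls) == 0 || nrow(amines) == 0) return(FALSE)
  g <- heavy_graph(mol)
  for (n_idx in amines$nitrogen_index) {
    for (c_idx in carboxyls$carbon_index) {
      sp <- suppressWarnings(igraph::shortest_paths(
        g, from = as.character(n_idx), to = as.character(c_idx)
      ))
      path <- as.integer(names(sp$vpath[[1]]))
      if (length(path) < 2) next
      on_path <- ab$secondary &
        ab$c_index %in% path & ab$n_index %in% path
      if (any(on_path)) return(TRUE)
    }
  }
  FALSE
}

#' Screen a batch of SMILES for residue scope
#'
#' Applies the full scope decision to each input SMILES. Unparseable records
#' are kept as rows flagged `parse_error`; blank lines are skipped.
#'
#' @param smiles Character vector of SMILES, or the path of a file with one
#'   SMILES per line (optionally followed by whitespace and an identifier).
#' @param limits A [scope_limits()] list.
#' @param ... Passed to [find_amine_sites()] via the classification (reserved).
#' @return A tibble with columns `id`, `smiles`, `label`, `path_length`,
#'   `accepted`, `flags` (semicolon-joined).
#' @examples
#' \dontrun{
#' screen_batch(c("NCC(=O)O", "NCCC(=O)O", "CCO"))
#' }
#' @export
screen_batch <- function(smiles, limits = scope_limits(), ...) {
  if (length(smiles) == 1 && file.exists(smiles)) {
    lines <- trimws(readLines(smiles, warn = FALSE))
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\\s+")
    smi <- vapply(parts, `[[`, character(1), 1)
    ids <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_,
                  character(1))
  } else {
    smi <- smiles
    ids <- names(smiles) %||% rep(NA_character_, length(smiles))
  }
  if (length(smi) == 0) {
    return(tibble::tibble(id = character(), smiles = character(),
                          label = character(), path_length = numeric(),
                          accepted = logical(), flags = character()))
  }
  ids <- ifelse(is.na(ids) | !nzchar(ids), paste0("mol", seq_along(smi)), ids)
  purrr::map2_dfr(smi, ids, function(s, id) {
    dec <- tryCatch(apply_scope_filters(s, limits = limits),
                    residuekit_parse_error = function(e) NULL)
    if (is.null(dec)) {
      tibble::tibble(id = id, smiles = s, label = NA_character_,
                     path_length = NA_real_, accepted = FALSE,
                     flags = "parse_error")
    } else {
      tibble::tibble(
        id = id, smiles = s,
        label = dec$classification$label,
        path_length = dec$classification$path_length_bonds,
        accepted = dec$accepted,
        flags = paste(dec$exclusion_flags, collapse = ";")
      )
    }
  })
}

#' Summarise a screening table
#'
#' @param screened Output of [screen_batch()].
#' @return A list with `by_label` (tibble of label counts; parse failures are
#'   counted as rejected) and `by_flag` (tibble of non-exclusive flag counts).
#' @export
screen_summary <- function(screened) {
  lab <- ifelse(is.na(screened$label), "rejected", screened$label)
  by_label <- dplyr::count(tibble::tibble(label = lab), .data$label,
                           name = "n")
  flags <- unlist(strsplit(screened$flags[nzchar(screened$flags)], ";"))
  by_flag <- if (length(flags) == 0) {
    tibble::tibble(flag = character(), n = integer())
  } else {
    dplyr::count(tibble::tibble(flag = flags), .data$flag, name = "n")
  }
  list(by_label = by_label, by_flag = by_flag)
}
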