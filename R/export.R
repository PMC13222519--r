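#' Packaged list of standard residue codes
#'
#' A curated subset of three-letter codes already in use for standard and
#' common modified residues, used to avoid collisions when assigning custom
#' component IDs. Full-dictionary collision checking would require the
#' complete reference dictionary and is intentionally out of scope.
#'
#' @return Character vector of reserved codes.
#' @export
standard_codes <- function() {
  c(
    # the twenty standard amino acids
    "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
    "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
    # frequent modified/special residues
    "MSE", "SEP", "TPO", "PTR", "CSO", "HYP", "MLY", "PCA", "KCX", "CME",
    "DAL", "DAR", "DSG", "DCY", "DGL", "DHI", "DIL", "DLE", "DLY", "DPR",
    "ABA", "AIB", "BAL", "DAB", "DPP", "GHP", "HCS", "NLE", "NVA", "ORN",
    "SAR", "UNK", "ACE", "NH2", "NME", "FOR"
  )
}

#' Assign the next free custom component ID
#'
#' Custom residues receive three-letter codes from the documented sequence
#' ZCA, ZCB, ..., ZCZ, ZDA, ... skipping any code present in the packaged
#' standard-code list or in `existing`. A fresh session therefore starts at
#' "ZCA"; the 16th assignment is "ZCP".
#'
#' @param existing Character vector of codes already used in this session.
#' @return A single unused three-letter code.
#' @examples
#' assign_component_id()             # "ZCA"
#' assign_component_id("ZCA")        # "ZCB"
#' @export
assign_component_id <- function(existing = character()) {
  reserved <- c(standard_codes(), toupper(existing))
  for (l2 in LETTERS[3:26]) {
    for (l3 in LETTERS) {
      code <- paste0("Z", l2, l3)
      if (!code %in% reserved) return(code)
    }
  }
  rk_abort("Custom component ID sequence exhausted",
           class = "residuekit_export_error")
}

#' Construct a residue definition
#'
#' Bundles a validated topology with its provenance metadata and a custom
#' component ID into the exportable unit consumed by the CSV and JSON
#' writers.
#'
#' @param topology A [build_topology()] result.
#' @param mol The source `rk_mol` (for SMILES/InChIKey metadata); optional
#'   when `metadata` is supplied directly.
#' @param component_id Three-letter code; assigned from the session sequence
#'   when `NULL`.
#' @param seed,optimize Conformer-generation parameters to record.
#' @param template_id Mapped reference component, or `NA`.
#' @param existing_ids Codes already used in this session.
#' @param metadata Full metadata list (overrides the other metadata args).
#' @return A `residue_definition`.
#' @export
new_residue_definition <- function(topology, mol = NULL, component_id = NULL,
                                   seed = NA_integer_, optimize = NA,
                                   template_id = NA_character_,
                                   existing_ids = character(),
                                   metadata = NULL) {
  stopifnot(inherits(topology, "residue_topology"))
  validate_topology(topology)
  component_id <- component_id %||% assign_component_id(existing_ids)
  if (!grepl("^[A-Z0-9]{3}$", component_id)) {
    rk_abort("component_id must be 3 uppercase alphanumerics",
             class = "residuekit_export_error")
  }
  if (component_id %in% standard_codes()) {
    rk_abort(paste0("component_id '", component_id,
                    "' collides with a standard code"),
             class = "residuekit_export_error")
  }
  metadata <- metadata %||% list(
    source_smiles = mol$smiles,
    inchikey = standard_inchikey(mol),
    residue_class = topology$residue_class,
    seed = seed,
    optimize = isTRUE(optimize),
    template_id = template_id
  )
  structure(
    list(component_id = component_id, topology = topology,
         metadata = metadata),
    class = "residue_definition"
  )
}

#' @export
print.residue_definition <- function(x, ...) {
  cat("<residue_definition> ", x$component_id, " (",
      x$topology$residue_class, "), ", nrow(x$topology$atoms), " atoms\n",
      sep = "")
  invisible(x)
}

# leaving atoms under polymer conventions: the acid oxygen O2 (OXT), its
# hydrogen, and the last hydrogen on the backbone nitrogen
leaving_atoms <- function(defn) {
  topo <- defn$topology
  atoms <- topo$atoms
  o2 <- topo$backbone_map[["O2"]]
  nb <- topo$backbone_map[["N"]]
  out <- o2
  out <- c(out, atoms$name[!is.na(atoms$parent_heavy) &
                             atoms$parent_heavy == o2])
  n_h <- atoms$name[!is.na(atoms$parent_heavy) & atoms$parent_heavy == nb]
  if (length(n_h) > 0) out <- c(out, n_h[length(n_h)])
  out
}

## ---- CSV residue-definition dialect --------------------------------------

# One UTF-8 RFC-4180 file, a single header row `record,f1..f8`, then three
# sections distinguished by the first column:
#   meta,<key>,<value>
#   role,<backbone role>,<atom name>
#   atom,<name>,<element>,<charge>,<x>,<y>,<z>,<is_backbone>,<is_leaving>
#   bond,<atom1>,<atom2>,<order>,<aromatic>
# Coordinates are fixed to 6 decimals so output is byte-deterministic.

#' Write a residue definition to CSV
#'
#' @param defn A [new_residue_definition()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_residue_csv <- function(defn, path) {
  stopifnot(inherits(defn, "residue_definition"))
  validate_topology(defn$topology)
  topo <- defn$topology
  atoms <- topo$atoms
  leaving <- leaving_atoms(defn)
  md <- defn$metadata

  fmt <- function(x) {
    ifelse(is.na(x), "", formatC(x, format = "f", digits = 6))
  }
  csv_field <- function(x) {
    x <- as.character(x)
    x[is.na(x)] <- ""
    needs <- grepl('[",\n]', x)
    x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
    x
  }
  row <- function(...) {
    vals <- csv_field(c(...))
    paste(c(vals, rep("", 9 - length(vals))), collapse = ",")
  }

  lines <- c(
    row("record", paste0("f", 1:8)),
    row("meta", "component_id", defn$component_id),
    row("meta", "residue_class", topo$residue_class),
    row("meta", "source_smiles", md$source_smiles),
    row("meta", "inchikey", md$inchikey),
    row("meta", "seed", md$seed),
    row("meta", "optimize", tolower(isTRUE(md$optimize))),
    row("meta", "template_id", md$template_id),
    vapply(names(topo$backbone_map), function(r)
      row("role", r, topo$backbone_map[[r]]), character(1)),
    vapply(seq_len(nrow(atoms)), function(i) {
      row("atom", atoms$name[i], atoms$element[i], atoms$charge[i],
          fmt(atoms$x[i]), fmt(atoms$y[i]), fmt(atoms$z[i]),
          tolower(atoms$is_backbone[i]),
          tolower(atoms$name[i] %in% leaving))
    }, character(1)),
    vapply(seq_len(nrow(topo$bonds)), function(i) {
      row("bond", topo$bonds$atom1[i], topo$bonds$atom2[i],
          topo$bonds$order[i], tolower(topo$bonds$aromatic[i]))
    }, character(1))
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\r\n", useBytes = TRUE)
  invisible(path)
}

#' Read a residue definition from CSV
#'
#' Inverse of [write_residue_csv()]; schema violations are reported with the
#' offending row number.
#'
#' @param path File in the documented residue-CSV dialect.
#' @return A `residue_definition`.
#' @export
read_residue_csv <- function(path) {
  if (!file.exists(path)) {
    rk_abort(paste0("Residue CSV not found: ", path),
             class = "residuekit_io_error")
  }
  tab <- utils::read.csv(path, header = TRUE, colClasses = "character",
                         col.names = c("record", paste0("f", 1:8)))
  die <- function(msg, rown = NULL) {
    rk_abort(paste0("Residue CSV parse error",
                    if (!is.null(rown)) paste0(" (row ", rown + 1, ")"),
                    ": ", msg),
             class = "residuekit_csv_error")
  }
  known <- c("meta", "role", "atom", "bond")
  bad <- which(!tab$record %in% known)
  if (length(bad)) die(paste0("unknown record type '", tab$record[bad[1]], "'"),
                       bad[1])
  for (section in c("meta", "role", "atom", "bond")) {
    if (!any(tab$record == section)) {
      die(paste0("missing section '", section, "'"))
    }
  }
  meta_rows <- tab[tab$record == "meta", ]
  md0 <- stats::setNames(as.list(meta_rows$f2), meta_rows$f1)
  for (need in c("component_id", "residue_class")) {
    if (is.null(md0[[need]])) die(paste0("missing meta key '", need, "'"))
  }
  num_or_na <- function(x) ifelse(nzchar(x), suppressWarnings(as.numeric(x)),
                                  NA_real_)
  atom_rows <- which(tab$record == "atom")
  atoms <- tibble::tibble(
    idx = seq_along(atom_rows),
    element = tab$f2[atom_rows],
    name = tab$f1[atom_rows],
    charge = as.integer(num_or_na(tab$f3[atom_rows])),
    x = num_or_na(tab$f4[atom_rows]),
    y = num_or_na(tab$f5[atom_rows]),
    z = num_or_na(tab$f6[atom_rows]),
    is_backbone = tab$f7[atom_rows] == "true"
  )
  bond_rows <- which(tab$record == "bond")
  bonds <- tibble::tibble(
    atom1 = tab$f1[bond_rows],
    atom2 = tab$f2[bond_rows],
    order = tab$f3[bond_rows],
    aromatic = tab$f4[bond_rows] == "true"
  )
  bad_order <- which(!bonds$order %in% c("single", "double", "triple"))
  if (length(bad_order)) {
    die(paste0("invalid bond order '", bonds$order[bad_order[1]], "'"),
        bond_rows[bad_order[1]])
  }
  bad_ref <- which(!(bonds$atom1 %in% atoms$name &
                       bonds$atom2 %in% atoms$name))
  if (length(bad_ref)) {
    die("bond references unknown atom name", bond_rows[bad_ref[1]])
  }
  # reconstruct hydrogen parents from the bond table
  atoms$parent_heavy <- NA_character_
  h <- atoms$element == "H"
  for (i in which(h)) {
    nb <- c(bonds$atom2[bonds$atom1 == atoms$name[i]],
            bonds$atom1[bonds$atom2 == atoms$name[i]])
    if (length(nb) > 0) atoms$parent_heavy[i] <- nb[1]
  }
  role_rows <- tab[tab$record == "role", ]
  backbone_map <- stats::setNames(role_rows$f2, role_rows$f1)
  topo <- structure(
    list(residue_class = md0$residue_class,
         atoms = atoms, bonds = bonds, backbone_map = backbone_map),
    class = "residue_topology"
  )
  validate_topology(topo)
  new_residue_definition(
    topology = topo,
    component_id = md0$component_id,
    metadata = list(
      source_smiles = md0$source_smiles %||% NA_character_,
      inchikey = md0$inchikey %||% NA_character_,
      residue_class = md0$residue_class,
      seed = as.integer(num_or_na(md0$seed %||% "")),
      optimize = identical(md0$optimize, "true"),
      template_id = if (is.null(md0$template_id) ||
                          !nzchar(md0$template_id)) NA_character_
                    else md0$template_id
    )
  )
}

## ---- AlphaFold3-style job JSON -------------------------------------------

#' Build an AlphaFold3-style job specification
#'
#' Writes the JSON job file plus one residue-definition CSV per custom
#' component. Field names follow the public AlphaFold3 input format where
#' they are public (`name`, `modelSeeds`, `sequences`, `protein`,
#' `modifications`); the custom-component extension is carried in the
#' namespaced `customComponents` block, which accepts either individual CSV
#' file references or a components folder.
#'
#' @param chains Character vector of one-letter sequences (use `X` at
#'   positions modified by a custom component).
#' @param modifications Tibble/data frame with columns `chain` (1-based chain
#'   index), `position` (1-based), `component_id`.
#' @param definitions List of `residue_definition` objects (may be empty when
#'   all modifications use standard codes).
#' @param out_dir Output directory (created if needed).
#' @param name Job name.
#' @param model_seeds Integer vector for the `modelSeeds` field.
#' @return Path of the written job JSON, invisibly; component CSVs are
#'   placed in `out_dir/components/`.
#' @export
build_af3_json <- function(chains, modifications, definitions, out_dir,
                           name = "residuekit_job", model_seeds = 1L) {
  stopifnot(length(chains) >= 1)
  if (is.null(modifications)) {
    modifications <- tibble::tibble(chain = integer(), position = integer(),
                                    component_id = character())
  }
  defs <- stats::setNames(
    definitions,
    vapply(definitions, function(d) d$component_id, character(1))
  )
  known <- c(names(defs), standard_codes())
  for (i in seq_len(nrow(modifications))) {
    m <- modifications[i, ]
    if (m$chain < 1 || m$chain > length(chains)) {
      rk_abort(paste0("modification ", i, ": chain index out of range"),
               class = "residuekit_export_error")
    }
    if (m$position < 1 || m$position > nchar(chains[m$chain])) {
      rk_abort(paste0("modification ", i, ": position ", m$position,
                      " outside sequence of length ", nchar(chains[m$chain])),
               class = "residuekit_export_error")
    }
    if (!m$component_id %in% known) {
      rk_abort(paste0("modification ", i, ": component '", m$component_id,
                      "' has no definition and is not a standard code"),
               class = "residuekit_export_error")
    }
  }

  dir.create(file.path(out_dir, "components"), recursive = TRUE,
             showWarnings = FALSE)
  comp_refs <- list()
  for (id in names(defs)) {
    rel <- file.path("components", paste0(id, ".csv"))
    write_residue_csv(defs[[id]], file.path(out_dir, rel))
    comp_refs[[length(comp_refs) + 1]] <-
      list(componentId = id, csv = rel)
  }

  sequences <- purrr::imap(chains, function(seq, ci) {
    mods <- modifications[modifications$chain == ci, ]
    entry <- list(id = LETTERS[ci], sequence = seq)
    if (nrow(mods) > 0) {
      entry$modifications <- purrr::map(seq_len(nrow(mods)), function(i) {
        list(position = as.integer(mods$position[i]),
             componentId = mods$component_id[i])
      })
    }
    list(protein = entry)
  })
  job <- list(
    name = name,
    modelSeeds = as.list(as.integer(model_seeds)),
    sequences = sequences,
    customComponents = comp_refs
  )
  problems <- validate_af3_job(job)
  if (length(problems)) {
    rk_abort(paste0("Job spec failed schema validation: ",
                    paste(problems, collapse = "; ")),
             class = "residuekit_export_error")
  }
  json_path <- file.path(out_dir, paste0(name, ".json"))
  jsonlite::write_json(job, json_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(json_path)
}

#' Emit the five-residue GGXGG motif job for one custom residue
#'
#' The residue of interest is embedded at position 3 of a GGXGG peptide
#' (glycine flanks), the standard probe for in-chain behaviour.
#'
#' @param defn A `residue_definition`.
#' @param out_dir Output directory.
#' @param name Job name.
#' @return Path of the job JSON, invisibly.
#' @export
ggxgg_job <- function(defn, out_dir, name = NULL) {
  stopifnot(inherits(defn, "residue_definition"))
  name <- name %||% paste0("ggxgg_", tolower(defn$component_id))
  build_af3_json(
    chains = "GGXGG",
    modifications = tibble::tibble(chain = 1L, position = 3L,
                                   component_id = defn$component_id),
    definitions = list(defn),
    out_dir = out_dir,
    name = name
  )
}

#' Validate a job specification against the packaged schema
#'
#' Structural validation (types, required fields, patterns) against the JSON
#' schema shipped in `inst/schema/af3_job.schema.json`, plus referential
#' checks: every modification position must lie within its sequence and every
#' referenced custom component must appear in `customComponents`.
#'
#' @param job A job list (as built by [build_af3_json()]) or the path of a
#'   job JSON file.
#' @return Character vector of problems; empty when valid.
#' @export
validate_af3_job <- function(job) {
  if (is.character(job)) {
    job <- jsonlite::read_json(job)
  }
  schema_path <- system.file("schema", "af3_job.schema.json",
                             package = "residuekit")
  if (!nzchar(schema_path)) {
    schema_path <- file.path("inst", "schema", "af3_job.schema.json")
  }
  schema <- jsonlite::read_json(schema_path)
  problems <- check_schema(job, schema, "$")

  custom_ids <- vapply(job$customComponents %||% list(),
                       function(x) x$componentId %||% "", character(1))
  for (s in job$sequences %||% list()) {
    p <- s$protein
    if (is.null(p)) next
    for (m in p$modifications %||% list()) {
      if (!is.null(m$position) && !is.null(p$sequence) &&
          (m$position < 1 || m$position > nchar(p$sequence))) {
        problems <- c(problems, paste0("modification position ", m$position,
                                       " outside sequence ", p$id %||% "?"))
      }
      cid <- m$componentId %||% ""
      if (!cid %in% c(custom_ids, standard_codes())) {
        problems <- c(problems,
                      paste0("unresolved componentId '", cid, "'"))
      }
    }
  }
  problems
}

# Minimal JSON-schema checker covering the subset used by the packaged
# schema: type, required, properties, items, enum, pattern, minItems.
check_schema <- function(x, schema, path) {
  problems <- character()
  ty <- schema$type
  if (!is.null(ty)) {
    ok <- switch(ty,
      object = is.list(x),
      array = is.list(x) && (length(x) == 0 || is.null(names(x))),
      string = is.character(x) && length(x) == 1,
      integer = is.numeric(x) && length(x) == 1 && x == as.integer(x),
      number = is.numeric(x) && length(x) == 1,
      boolean = is.logical(x) && length(x) == 1,
      TRUE
    )
    if (!isTRUE(ok)) {
      return(paste0(path, ": expected ", ty))
    }
  }
  for (req in schema$required %||% list()) {
    if (is.null(x[[req]])) {
      problems <- c(problems, paste0(path, ": missing required '", req, "'"))
    }
  }
  props <- schema$properties %||% list()
  for (nm in names(props)) {
    if (!is.null(x[[nm]])) {
      problems <- c(problems,
                    check_schema(x[[nm]], props[[nm]],
                                 paste0(path, ".", nm)))
    }
  }
  if (!is.null(schema$items) && is.list(x)) {
    if (!is.null(schema$minItems) && length(x) < schema$minItems) {
      problems <- c(problems, paste0(path, ": fewer than ", schema$minItems,
                                     " items"))
    }
    for (i in seq_along(x)) {
      problems <- c(problems,
                    check_schema(x[[i]], schema$items,
                                 paste0(path, "[", i, "]")))
    }
  }
  if (!is.null(schema$enum) && length(x) == 1 && !x %in% unlist(schema$enum)) {
    problems <- c(problems, paste0(path, ": value not in enum"))
  }
  if (!is.null(schema$pattern) && is.character(x) &&
      !grepl(schema$pattern, x)) {
    problems <- c(problems, paste0(path, ": does not match pattern"))
  }
  problems
}
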