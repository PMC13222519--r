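#' Load a component reference library from an SDF file
#'
#' Reads a Chemical-Component-Dictionary style SDF (optionally gzipped) into a
#' searchable index. Each record contributes an identifier, a 1-3 character
#' code, a canonical structure and an InChIKey; keys stored in data fields are
#' trusted when syntactically valid and recomputed through the InChI backend
#' otherwise. Unparseable records are skipped with a message, never fatal.
#'
#' @param sdf_path Path to an SDF or SDF.gz file.
#' @param id_field Data-field name holding the component identifier; falls
#'   back to the molblock title line.
#' @param code_field Data-field name holding the short code; falls back to the
#'   identifier when it is 3 characters or fewer.
#' @param key_fields Candidate data-field names for a stored InChIKey, tried
#'   in order.
#' @return A `component_library`: list with `components` (tibble:
#'   `component_id`, `code`, `inchikey`, `prefix14`, `smiles`, `fp` list
#'   column of Morgan fingerprints, `atom_names` list column when the record
#'   carries canonical-order atom names), `n_skipped`, `source`.
#' @examples
#' \dontrun{
#' lib <- read_component_library(mini_component_library(tempdir())$sdf_path)
#' lib$components
#' }
#' @export
read_component_library <- function(sdf_path,
                                   id_field = "component_id",
                                   code_field = "three_letter_code",
                                   key_fields = c("InChIKey", "INCHIKEY",
                                                  "InChI_Key", "inchikey")) {
  if (!file.exists(sdf_path)) {
    rk_abort(paste0("Component SDF not found: ", sdf_path),
             class = "residuekit_io_error")
  }
  path <- sdf_path
  if (grepl("\\.gz$", sdf_path)) {
    path <- tempfile(fileext = ".sdf")
    writeLines(readLines(gzfile(sdf_path), warn = FALSE), path)
  }
  records <- split_sdf_records(path)
  if (length(records) == 0) {
    rk_abort("No records found in component SDF",
             class = "residuekit_empty_library_error")
  }

  rows <- list()
  n_skipped <- 0
  for (rec in records) {
    parsed <- tryCatch(parse_sdf_record(rec, id_field, code_field, key_fields),
                       error = function(e) NULL)
    if (is.null(parsed)) {
      n_skipped <- n_skipped + 1
      next
    }
    rows[[length(rows) + 1]] <- parsed
  }
  if (length(rows) == 0) {
    rk_abort("No parseable records in component SDF",
             class = "residuekit_empty_library_error")
  }
  if (n_skipped > 0) {
    message(n_skipped, " unparseable SDF record(s) skipped")
  }
  components <- dplyr::bind_rows(rows)

  # recompute missing/invalid keys in one InChI backend call
  need <- !is_valid_inchikey(components$inchikey)
  if (any(need)) {
    keys <- vapply(components$smiles[need], ob_cli_inchikey, character(1))
    components$inchikey[need] <- keys
  }
  components$prefix14 <- inchikey_prefix(components$inchikey)
  components$fp <- purrr::map(components$smiles, morgan_fingerprint)

  structure(
    list(components = components, n_skipped = n_skipped, source = sdf_path),
    class = "component_library"
  )
}

#' @export
print.component_library <- function(x, ...) {
  cat("<component_library> ", nrow(x$components), " components",
      if (x$n_skipped > 0) paste0(" (", x$n_skipped, " skipped)"), "\n",
      sep = "")
  invisible(x)
}

# split an SDF file into per-record character blocks on $$$$ delimiters
split_sdf_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) return(list())
  idx <- cumsum(c(0, head(grepl("^\\${4}", lines), -1)))
  recs <- split(lines, idx)
  recs <- purrr::map(recs, function(r) r[!grepl("^\\${4}", r)])
  recs[purrr::map_lgl(recs, function(r) any(nzchar(trimws(r))))]
}

parse_sdf_record <- function(lines, id_field, code_field, key_fields) {
  mend <- grep("^M  END", lines)
  if (length(mend) == 0) stop("no M END")
  molblock <- paste(c(lines[1:mend[1]], "$$$$"), collapse = "\n")
  fields <- parse_sdf_datafields(lines[-(1:mend[1])])

  smiles <- ob_sdf_to_canonical(molblock)
  if (is.na(smiles)) stop("unparseable structure")
  # light sanitization: re-parse from canonical SMILES (valence repair by the
  # toolkit), keep the largest fragment
  mol <- parse_molecule(smiles)

  id <- fields[[id_field]] %||% trimws(lines[1])
  if (is.null(id) || !nzchar(id)) stop("record without identifier")
  code <- fields[[code_field]] %||%
    (if (nchar(id) <= 3) toupper(id) else NA_character_)
  key <- NA_character_
  for (kf in key_fields) {
    if (!is.null(fields[[kf]]) && is_valid_inchikey(fields[[kf]])) {
      key <- fields[[kf]]
      break
    }
  }
  names_field <- fields[["ATOM_NAMES"]]
  tibble::tibble(
    component_id = id,
    code = code,
    inchikey = key,
    smiles = mol$smiles,
    atom_names = list(if (is.null(names_field)) NULL else
      strsplit(trimws(names_field), "\\s+")[[1]])
  )
}

parse_sdf_datafields <- function(lines) {
  out <- list()
  i <- 1
  while (i <= length(lines)) {
    m <- regmatches(lines[i], regexec("^>\\s*<([^>]+)>", lines[i]))[[1]]
    if (length(m) == 2) {
      vals <- character()
      j <- i + 1
      while (j <= length(lines) && nzchar(trimws(lines[j]))) {
        vals <- c(vals, lines[j])
        j <- j + 1
      }
      out[[m[2]]] <- paste(vals, collapse = "\n")
      i <- j
    } else {
      i <- i + 1
    }
  }
  out
}

#' Map a query molecule to reference components by InChIKey
#'
#' Two-pass mapping: an exact full-key lookup first, then a fallback on the
#' 14-character connectivity layer, which tolerates protonation and tautomer
#' differences while preserving the molecular skeleton. Confidence is `high`
#' only for a full-key match or graph identity (Tanimoto 1.0 between query and
#' candidate fingerprints); other connectivity-layer matches are `ambiguous`.
#'
#' @param mol An `rk_mol` or SMILES string.
#' @param library A [read_component_library()] index.
#' @param retain_all Keep all key-sharing candidates (default) or only the
#'   first by component id?
#' @param standardize Passed to [standard_inchikey()].
#' @return A `mapping_result`: list with `mode` (`full_key`,
#'   `connectivity_layer` or `none`), `candidates` (tibble sorted by
#'   `component_id`), `confidence` (`high`, `ambiguous`, `none`) and
#'   `query_inchikey`.
#' @export
map_query_to_ccd <- function(mol, library, retain_all = TRUE,
                             standardize = TRUE) {
  stopifnot(inherits(library, "component_library"))
  mol <- as_rk_mol(mol)
  key <- standard_inchikey(mol, standardize = standardize)
  comp <- library$components

  hits <- comp[!is.na(comp$inchikey) & comp$inchikey == key, ]
  mode <- "full_key"
  if (nrow(hits) == 0) {
    hits <- comp[!is.na(comp$prefix14) &
                   comp$prefix14 == inchikey_prefix(key), ]
    mode <- if (nrow(hits) > 0) "connectivity_layer" else "none"
  }
  hits <- hits[order(hits$component_id), ]
  if (!retain_all && nrow(hits) > 1) hits <- hits[1, , drop = FALSE]

  confidence <- "none"
  if (mode == "full_key") {
    confidence <- "high"
  } else if (mode == "connectivity_layer") {
    qfp <- morgan_fingerprint(mol)
    identical_graph <- purrr::map_lgl(hits$fp, function(f) {
      similarity_score(qfp, f, "tanimoto") == 1
    })
    confidence <- if (any(identical_graph)) "high" else "ambiguous"
  }

  structure(
    list(mode = mode,
         candidates = hits[, c("component_id", "code", "inchikey", "smiles")],
         confidence = confidence,
         query_inchikey = key),
    class = "mapping_result"
  )
}

#' @export
print.mapping_result <- function(x, ...) {
  cat("<mapping_result> mode=", x$mode, " confidence=", x$confidence,
      " candidates=", nrow(x$candidates), "\n", sep = "")
  invisible(x)
}
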