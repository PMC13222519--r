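#' Standard InChIKey of a molecule
#'
#' Generates the 27-character standard InChIKey through the Open Babel
#' `obabel` command-line InChI backend. Salts/counter-ions are stripped first
#' (largest fragment kept). With `standardize = TRUE` (default) the molecule is
#' additionally routed through the package's sanitising parser, which lets
#' Open Babel repair valence states before key generation; mobile-hydrogen
#' (tautomer/protonation) normalisation is inherent to the standard InChI
#' algorithm itself and is reflected in the key's protonation flag rather than
#' the connectivity layer.
#'
#' @param mol An `rk_mol` object or a SMILES string.
#' @param standardize Apply sanitising canonicalization before key generation?
#' @return A single InChIKey string (format `XXXXXXXXXXXXXX-XXXXXXXXXX-X`).
#' @examples
#' \dontrun{
#' standard_inchikey("NCC(=O)O")       # glycine
#' standard_inchikey("NCC(=O)O.Cl")    # same key: the salt is stripped
#' }
#' @export
standard_inchikey <- function(mol, standardize = TRUE) {
  if (inherits(mol, "rk_mol")) {
    smi <- mol$smiles
  } else if (standardize) {
    smi <- parse_molecule(mol)$smiles
  } else {
    frags <- strsplit(mol, ".", fixed = TRUE)[[1]]
    smi <- if (length(frags) > 1) pick_largest_fragment(frags) else mol
  }
  key <- ob_cli_inchikey(smi)
  if (is.na(key)) {
    rk_abort(paste0("InChIKey generation failed for SMILES: '", smi, "'"),
             class = "residuekit_inchi_error", smiles = smi)
  }
  key
}

#' Validate InChIKey syntax
#'
#' @param key Character vector of candidate keys.
#' @return Logical vector: `TRUE` where the value matches the 14-10-1 block
#'   layout of a standard InChIKey.
#' @export
is_valid_inchikey <- function(key) {
  !is.na(key) & grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", key)
}

#' Connectivity layer (first 14 characters) of an InChIKey
#'
#' @param key Character vector of InChIKeys.
#' @return Character vector of 14-character connectivity-layer prefixes.
#' @export
inchikey_prefix <- function(key) {
  substr(key, 1L, INCHIKEY_PREFIX_LENGTH)
}

# The connectivity layer of a standard InChIKey is its first 14 characters.
INCHIKEY_PREFIX_LENGTH <- 14L

# largest fragment by heavy atoms, ties by molecular weight
pick_largest_fragment <- function(frags) {
  counts <- vapply(frags, function(f) {
    fl <- smiles_atom_flags(f)
    sum(fl$element != "H")
  }, integer(1))
  best <- which(counts == max(counts))
  if (length(best) > 1) {
    mws <- vapply(frags[best], ob_molecular_weight, numeric(1))
    best <- best[which.max(mws)]
  }
  frags[best[1]]
}

## ---- obabel CLI ----------------------------------------------------------

obabel_path <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p)) {
    rk_abort("The 'obabel' executable was not found on PATH",
             class = "residuekit_dependency_error")
  }
  p
}

# one SMILES -> one InChIKey (NA on failure); the in-process ChemmineOB route
# is avoided here because it drops tetrahedral stereo from SMILES input
ob_cli_inchikey <- function(smiles) {
  out <- suppressWarnings(system2(
    obabel_path(), c(paste0("-:", shQuote(smiles)), "-oinchikey"),
    stdout = TRUE, stderr = FALSE
  ))
  out <- out[is_valid_inchikey(out)]
  if (length(out) == 0) NA_character_ else out[1]
}

# batch: SDF file (one or more records) -> vector of keys, NA where absent.
# Records must all be parseable by Open Babel (callers filter beforehand).
ob_cli_inchikey_sdf <- function(sdf_path) {
  out <- suppressWarnings(system2(
    obabel_path(), c(shQuote(sdf_path), "-oinchikey"),
    stdout = TRUE, stderr = FALSE
  ))
  out[is_valid_inchikey(out)]
}
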