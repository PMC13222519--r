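#' Circular (Morgan) fingerprint of a molecule
#'
#' Hashed circular fingerprint over heavy-atom environments, radius 2 and
#' 2048 bits by default, matching the parameters used for the reference
#' library. The initial atom invariant combines atomic number, heavy degree,
#' hydrogen count, formal charge, aromaticity and ring membership; each
#' iteration folds in the sorted (bond class, neighbour hash) pairs, so the
#' result is independent of input atom order. Chirality is not encoded:
#' enantiomers share a fingerprint, consistent with treating Tanimoto 1.0 as
#' graph-level equivalence.
#'
#' @param mol An `rk_mol` or SMILES string.
#' @param radius Neighbourhood radius (default 2).
#' @param nbits Fingerprint length in bits (default 2048).
#' @return A logical vector of class `morgan_fp` and length `nbits`.
#' @examples
#' \dontrun{
#' fp <- morgan_fingerprint("NCC(=O)O")
#' sum(fp)  # number of set bits
#' }
#' @export
morgan_fingerprint <- function(mol, radius = 2L, nbits = 2048L) {
  mol <- as_rk_mol(mol)
  heavy <- which(mol$atoms$heavy)
  if (length(heavy) == 0) {
    rk_abort("Cannot fingerprint an empty molecule",
             class = "residuekit_fingerprint_error")
  }
  a <- mol$atoms
  ring_atom <- rep(FALSE, nrow(a))
  rb <- mol$bonds[mol$bonds$in_ring, ]
  ring_atom[c(rb$a1, rb$a2)] <- TRUE

  # neighbour lists restricted to heavy atoms, with bond classes
  nbrs <- purrr::map(heavy, function(i) {
    b <- mol$bonds
    sel <- (b$a1 == i | b$a2 == i)
    other <- ifelse(b$a1[sel] == i, b$a2[sel], b$a1[sel])
    keep <- a$heavy[other]
    cls <- ifelse(b$aromatic[sel], 4L, b$order[sel])
    list(atoms = match(other[keep], heavy), class = cls[keep])
  })

  inv <- vapply(heavy, function(i) {
    hash_ints(c(atomic_number(a$element[i]),
                length(atom_neighbors(mol, i, heavy_only = TRUE)),
                a$h_count[i],
                a$charge[i] + 16L,
                as.integer(a$aromatic[i]),
                as.integer(ring_atom[i])))
  }, integer(1))

  bits_on <- inv %% nbits
  for (r in seq_len(radius)) {
    inv <- vapply(seq_along(heavy), function(k) {
      nb <- nbrs[[k]]
      if (length(nb$atoms) == 0) return(hash_ints(c(r, inv[k])))
      pairs <- cbind(nb$class, inv[nb$atoms])
      ord <- order(pairs[, 1], pairs[, 2])
      hash_ints(c(r, inv[k], as.vector(t(pairs[ord, , drop = FALSE]))))
    }, integer(1))
    bits_on <- c(bits_on, inv %% nbits)
  }

  bits <- rep(FALSE, nbits)
  bits[bits_on + 1L] <- TRUE
  structure(bits, class = "morgan_fp", radius = radius, nbits = nbits)
}

#' @export
print.morgan_fp <- function(x, ...) {
  cat("<morgan_fp> ", attr(x, "nbits"), " bits, radius ", attr(x, "radius"),
      ", ", sum(x), " on\n", sep = "")
  invisible(x)
}

#' Similarity between two binary fingerprints
#'
#' Set-overlap coefficients on the on-bit counts `|A|`, `|B|` and the
#' intersection `c`:
#' Tanimoto `c/(|A|+|B|-c)`, Dice `2c/(|A|+|B|)`, cosine `c/sqrt(|A||B|)`,
#' Kulczynski `(c/|A| + c/|B|)/2` (the arithmetic-mean "Kulczynski II"
#' variant). Two all-zero fingerprints score 0 by convention.
#'
#' @param a,b Equal-length logical bit vectors (e.g. [morgan_fingerprint()]).
#' @param coefficient One of `"tanimoto"`, `"dice"`, `"cosine"`,
#'   `"kulczynski"`.
#' @return A similarity value in `[0, 1]`.
#' @export
similarity_score <- function(a, b,
                             coefficient = c("tanimoto", "dice", "cosine",
                                             "kulczynski")) {
  coefficient <- match.arg(coefficient)
  if (length(a) != length(b)) {
    rk_abort("Fingerprint lengths differ",
             class = "residuekit_fingerprint_error")
  }
  na <- sum(a)
  nb <- sum(b)
  cc <- sum(a & b)
  if (na == 0 && nb == 0) return(0)
  if (na == 0 || nb == 0) return(0)
  switch(coefficient,
    tanimoto = cc / (na + nb - cc),
    dice = 2 * cc / (na + nb),
    cosine = cc / sqrt(na * nb),
    kulczynski = (cc / na + cc / nb) / 2
  )
}

#' Rank reference components by fingerprint similarity
#'
#' Scores every library component against the query under all four
#' coefficients and returns the hits ranked by the chosen coefficient
#' (descending, ties broken by ascending component id). A Tanimoto score of
#' 1.0 marks graph-level equivalence and is flagged as an exact structural
#' match; otherwise the top `k` hits are returned.
#'
#' @param query An `rk_mol` or SMILES string.
#' @param library A [read_component_library()] index.
#' @param coefficient Ranking coefficient, default `"tanimoto"`.
#' @param k Number of hits to return (default 10; truncated to library size).
#' @return A tibble of class `similarity_hits` with columns `component_id`,
#'   `code`, `inchikey`, the four coefficient columns, `score` (ranking
#'   coefficient), `rank` and `exact`. Attribute `exact_match` is `TRUE` when
#'   an exact structural match is present.
#' @examples
#' \dontrun{
#' lib <- read_component_library(mini_component_library(tempdir())$sdf_path)
#' search_components("NCC(=O)O", lib)
#' }
#' @export
search_components <- function(query, library,
                              coefficient = c("tanimoto", "dice", "cosine",
                                              "kulczynski"),
                              k = 10L) {
  coefficient <- match.arg(coefficient)
  stopifnot(inherits(library, "component_library"), k >= 1)
  comp <- library$components
  if (nrow(comp) == 0) {
    warning("empty component library")
    return(tibble::tibble())
  }
  qfp <- morgan_fingerprint(as_rk_mol(query))
  scores <- purrr::map_dfr(comp$fp, function(f) {
    tibble::tibble(
      tanimoto = similarity_score(qfp, f, "tanimoto"),
      dice = similarity_score(qfp, f, "dice"),
      cosine = similarity_score(qfp, f, "cosine"),
      kulczynski = similarity_score(qfp, f, "kulczynski")
    )
  })
  hits <- dplyr::bind_cols(
    comp[, c("component_id", "code", "inchikey")], scores
  )
  hits$score <- hits[[coefficient]]
  hits <- dplyr::arrange(hits, dplyr::desc(.data$score), .data$component_id)
  hits$rank <- seq_len(nrow(hits))
  hits$exact <- hits$tanimoto == 1
  hits <- utils::head(hits, min(k, nrow(hits)))
  structure(hits,
            class = c("similarity_hits", class(tibble::tibble())),
            coefficient = coefficient,
            exact_match = any(hits$exact))
}
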