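#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname tidy.geometry_report
#' @export
tidy.scope_decision <- function(x, ...) {
  tibble::tibble(
    label = x$classification$label,
    path_length = x$classification$path_length_bonds,
    accepted = x$accepted,
    flag = if (length(x$exclusion_flags)) x$exclusion_flags else NA_character_
  )
}

#' @rdname tidy.geometry_report
#' @export
glance.scope_decision <- function(x, ...) {
  tibble::tibble(
    label = x$classification$label,
    accepted = x$accepted,
    n_flags = length(x$exclusion_flags)
  )
}

#' Tidiers for residuekit report objects
#'
#' broom-style [generics::tidy()] and [generics::glance()] methods turning
#' the package's report objects into tibbles: one row per metric, omega
#' torsion, mapping candidate, stereocentre or exclusion flag for `tidy()`,
#' and a one-row summary for `glance()`.
#'
#' @param x A report object produced by this package.
#' @param ... Unused, for generic consistency.
#' @return A tibble.
#' @export
tidy.geometry_report <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.geometry_report
#' @export
glance.geometry_report <- function(x, ...) {
  tibble::tibble(
    n_metrics = nrow(x),
    n_pass = sum(x$in_range),
    all_pass = attr(x, "all_pass")
  )
}

#' @rdname tidy.geometry_report
#' @export
tidy.omega_report <- function(x, ...) {
  tibble::tibble(
    torsion = c("omega_prev", "omega_next"),
    value = c(x$omega_prev, x$omega_next),
    category = x$category
  )
}

#' @rdname tidy.geometry_report
#' @export
glance.omega_report <- function(x, ...) {
  tibble::tibble(omega_prev = x$omega_prev, omega_next = x$omega_next,
                 category = x$category)
}

#' @rdname tidy.geometry_report
#' @export
tidy.mapping_result <- function(x, ...) {
  out <- x$candidates
  if (nrow(out) == 0) return(out)
  out$mode <- x$mode
  out$confidence <- x$confidence
  out
}

#' @rdname tidy.geometry_report
#' @export
glance.mapping_result <- function(x, ...) {
  tibble::tibble(mode = x$mode, confidence = x$confidence,
                 n_candidates = nrow(x$candidates),
                 query_inchikey = x$query_inchikey)
}

#' @rdname tidy.geometry_report
#' @export
tidy.rmsd_result <- function(x, ...) {
  tibble::tibble(value = x$value, selection = x$selection,
                 superposed = x$superposed, n_atoms = x$n_atoms)
}

#' @rdname tidy.geometry_report
#' @export
tidy.chirality_report <- function(x, ...) {
  x$centers
}

#' @rdname tidy.geometry_report
#' @export
glance.chirality_report <- function(x, ...) {
  tibble::tibble(n_centers = nrow(x$centers), accuracy = x$accuracy)
}

#' @rdname tidy.geometry_report
#' @export
tidy.residue_definition <- function(x, ...) {
  x$topology$atoms
}

#' @rdname tidy.geometry_report
#' @export
glance.residue_definition <- function(x, ...) {
  tibble::tibble(
    component_id = x$component_id,
    residue_class = x$topology$residue_class,
    n_atoms = nrow(x$topology$atoms),
    n_bonds = nrow(x$topology$bonds),
    inchikey = x$metadata$inchikey %||% NA_character_
  )
}
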