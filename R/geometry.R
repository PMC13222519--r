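#' Construct a coordinate set
#'
#' The common container for validation inputs: an ordered atom table with
#' unique names and finite coordinates, optionally with residue numbers for
#' peptide-level checks.
#'
#' @param atoms Data frame with columns `name`, `element`, `x`, `y`, `z`, and
#'   optionally `resno` and `is_backbone`.
#' @return A `coordinate_set`.
#' @export
coordinate_set <- function(atoms) {
  atoms <- tibble::as_tibble(atoms)
  stopifnot(all(c("name", "element", "x", "y", "z") %in% names(atoms)))
  if (!"resno" %in% names(atoms)) atoms$resno <- 1L
  key <- paste(atoms$resno, atoms$name)
  if (anyDuplicated(key)) {
    rk_abort("Atom names must be unique within a residue",
             class = "residuekit_geometry_error")
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    rk_abort("Coordinates must be finite",
             class = "residuekit_geometry_error")
  }
  structure(list(atoms = atoms), class = "coordinate_set")
}

#' @export
print.coordinate_set <- function(x, ...) {
  cat("<coordinate_set> ", nrow(x$atoms), " atoms, ",
      length(unique(x$atoms$resno)), " residue(s)\n", sep = "")
  invisible(x)
}

#' Coordinate set of a residue definition's conformer
#'
#' @param defn A `residue_definition` whose topology carries coordinates.
#' @param heavy_only Drop hydrogens?
#' @return A `coordinate_set`.
#' @export
as_coordinate_set <- function(defn, heavy_only = FALSE) {
  atoms <- defn$topology$atoms
  if (heavy_only) atoms <- atoms[atoms$element != "H", ]
  if (anyNA(atoms$x)) {
    rk_abort("Definition has no embedded coordinates",
             class = "residuekit_geometry_error")
  }
  coordinate_set(atoms[, c("name", "element", "x", "y", "z",
                           "is_backbone")])
}

#' Read a structure file into a coordinate set
#'
#' PDB and mmCIF files are parsed with bio3d.
#'
#' @param path Structure file (`.pdb`, `.cif`).
#' @return A `coordinate_set` with residue numbers.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) {
    rk_abort(paste0("Structure file not found: ", path),
             class = "residuekit_io_error")
  }
  obj <- if (grepl("\\.cif$", path, ignore.case = TRUE)) {
    bio3d::read.cif(path)
  } else {
    bio3d::read.pdb(path)
  }
  a <- obj$atom
  coordinate_set(tibble::tibble(
    name = a$elety,
    element = ifelse(is.na(a$elesy) | !nzchar(a$elesy),
                     substr(trimws(a$elety), 1, 1), trimws(a$elesy)),
    x = a$x, y = a$y, z = a$z,
    resno = a$resno
  ))
}

#' Reference bands for the five geometric validity metrics
#'
#' Three bands are reconstructed as mean +/- 4*sigma from the tabulated
#' (mean, sigma) pairs (Ck-Ccarb 1.525 +/- 0.021 A; Ccarb-O 1.231 +/- 0.020 A;
#' Ck-Ccarb-O 120.8 +/- 1.7 deg); the N-C1 band and the O-Ccarb-O sanity band
#' are stated directly as interval endpoints.
#'
#' @return A tibble with columns `metric`, `mean`, `sigma`, `lower`, `upper`,
#'   `units`.
#' @export
reference_bands <- function() {
  tb <- tibble::tribble(
    ~metric,                ~mean, ~sigma, ~lower, ~upper, ~units,
    "d_N_C1",                  NA,     NA,  1.382,  1.534, "angstrom",
    "d_Ck_Ccarb",           1.525,  0.021,     NA,     NA, "angstrom",
    "d_Ccarb_O_mean",       1.231,  0.020,     NA,     NA, "angstrom",
    "ang_Ck_Ccarb_O_mean",  120.8,    1.7,     NA,     NA, "degree",
    "ang_O1_Ccarb_O2",         NA,     NA,  110.0,  130.0, "degree"
  )
  has_ms <- !is.na(tb$mean)
  tb$lower[has_ms] <- tb$mean[has_ms] - 4 * tb$sigma[has_ms]
  tb$upper[has_ms] <- tb$mean[has_ms] + 4 * tb$sigma[has_ms]
  tb
}

#' Compute the five geometric validity metrics
#'
#' Evaluates the backbone N-C1 distance, the terminal-backbone-carbon to
#' carboxyl-carbon distance, the mean carboxyl C-O distance, the mean
#' Ck-Ccarb-O angle and the O-Ccarb-O angle, each flagged against its closed
#' reference interval. A missing role atom yields an `NA` metric and a failed
#' flag.
#'
#' @param coords A `coordinate_set`.
#' @param backbone_map Named character vector mapping roles `N`, `C1`..`Ck`,
#'   `Ccarb`, `O1`, `O2` to atom names (e.g. `residue_topology$backbone_map`).
#' @return A `geometry_report` tibble (`metric`, `value`, `lower`, `upper`,
#'   `in_range`) with attribute `all_pass`.
#' @export
geometry_metrics <- function(coords, backbone_map) {
  stopifnot(inherits(coords, "coordinate_set"))
  atoms <- coords$atoms
  xyz <- function(role) {
    nm <- backbone_map[[role]]
    if (is.null(nm) || is.na(nm)) return(NULL)
    i <- which(atoms$name == nm)
    if (length(i) != 1) return(NULL)
    c(atoms$x[i], atoms$y[i], atoms$z[i])
  }
  carbons <- grep("^C[0-9]+$", names(backbone_map), value = TRUE)
  ck_role <- carbons[which.max(as.integer(sub("^C", "", carbons)))]
  p <- list(N = xyz("N"), C1 = xyz("C1"), Ck = xyz(ck_role),
            Ccarb = xyz("Ccarb"), O1 = xyz("O1"), O2 = xyz("O2"))

  val <- c(
    d_N_C1 = if (!is.null(p$N) && !is.null(p$C1)) vec_dist(p$N, p$C1)
             else NA_real_,
    d_Ck_Ccarb = if (!is.null(p$Ck) && !is.null(p$Ccarb))
      vec_dist(p$Ck, p$Ccarb) else NA_real_,
    d_Ccarb_O_mean = if (!is.null(p$Ccarb) && !is.null(p$O1) &&
                           !is.null(p$O2))
      mean(c(vec_dist(p$Ccarb, p$O1), vec_dist(p$Ccarb, p$O2)))
      else NA_real_,
    ang_Ck_Ccarb_O_mean = if (!is.null(p$Ck) && !is.null(p$Ccarb) &&
                                !is.null(p$O1) && !is.null(p$O2))
      mean(c(vec_angle(p$Ck, p$Ccarb, p$O1), vec_angle(p$Ck, p$Ccarb, p$O2)))
      else NA_real_,
    ang_O1_Ccarb_O2 = if (!is.null(p$O1) && !is.null(p$Ccarb) &&
                            !is.null(p$O2))
      vec_angle(p$O1, p$Ccarb, p$O2) else NA_real_
  )
  bands <- reference_bands()
  report <- tibble::tibble(
    metric = bands$metric,
    value = as.numeric(val[bands$metric]),
    lower = bands$lower,
    upper = bands$upper,
    in_range = !is.na(val[bands$metric]) &
      val[bands$metric] >= bands$lower & val[bands$metric] <= bands$upper
  )
  structure(report,
            class = c("geometry_report", class(tibble::tibble())),
            all_pass = all(report$in_range))
}

#' Classify the peptide-bond omega dihedrals around a residue
#'
#' Evaluates the two peptide-bond torsions flanking residue `residue_index`
#' (omega_prev over the (i-1) -> i bond, omega_next over i -> (i+1)) and bins
#' the residue: `good` when both present torsions satisfy |omega| >= 150 or
#' |omega| <= 30 degrees; `borderline` when at least one lies in
#' [120, 150) and none in the bad zone; `bad` for any |omega| strictly
#' between 30 and 120 degrees or a missing value. For residues without an
#' alpha carbon the backbone carbon adjacent to the amide bond substitutes
#' for it via the `roles` map.
#'
#' @param structure A `coordinate_set` with residue numbers.
#' @param residue_index Residue number of the residue of interest.
#' @param roles Named map of the per-residue backbone atom names used in the
#'   torsions (`N`, `C1` = alpha-carbon equivalent, `Ccarb` = carbonyl
#'   carbon). Can be a function(resno) returning such a map for
#'   heterogeneous chains.
#' @return An `omega_report`: list with `omega_prev`, `omega_next` (degrees
#'   or `NA`) and `category`.
#' @export
classify_omega <- function(structure, residue_index,
                           roles = c(N = "N", C1 = "CA", Ccarb = "C")) {
  stopifnot(inherits(structure, "coordinate_set"))
  atoms <- structure$atoms
  role_for <- if (is.function(roles)) roles else function(resno) roles
  at <- function(resno, role) {
    nm <- role_for(resno)[[role]]
    i <- which(atoms$resno == resno & atoms$name == nm)
    if (length(i) != 1) return(NULL)
    c(atoms$x[i], atoms$y[i], atoms$z[i])
  }
  dihedral_or_na <- function(p1, p2, p3, p4) {
    if (is.null(p1) || is.null(p2) || is.null(p3) || is.null(p4)) {
      return(NA_real_)
    }
    vec_dihedral(p1, p2, p3, p4)
  }
  i <- residue_index
  omega_prev <- dihedral_or_na(at(i - 1, "C1"), at(i - 1, "Ccarb"),
                               at(i, "N"), at(i, "C1"))
  omega_next <- dihedral_or_na(at(i, "C1"), at(i, "Ccarb"),
                               at(i + 1, "N"), at(i + 1, "C1"))
  structure(
    list(omega_prev = omega_prev, omega_next = omega_next,
         category = omega_category(c(omega_prev, omega_next))),
    class = "omega_report"
  )
}

# band rules on |omega|: <=30 or >=150 good; (30,120) bad; [120,150)
# borderline; missing values are bad
omega_category <- function(omegas) {
  if (any(is.na(omegas))) return("bad")
  a <- abs(omegas)
  if (any(a > 30 & a < 120)) return("bad")
  if (any(a >= 120 & a < 150)) return("borderline")
  "good"
}

#' @export
print.omega_report <- function(x, ...) {
  cat("<omega_report> prev=", round(x$omega_prev, 1), " next=",
      round(x$omega_next, 1), " -> ", x$category, "\n", sep = "")
  invisible(x)
}

#' Root mean square deviation between two coordinate sets
#'
#' Atoms are paired by name over the chosen selection and the deviation is
#' evaluated as sqrt(1/N * sum of squared coordinate differences). With
#' `superpose = TRUE` (default) an optimal least-squares rigid-body
#' superposition (Kabsch) is applied first.
#'
#' @param native,model `coordinate_set` objects.
#' @param selection `"all"`, `"backbone"` (N, CA, C, O, OXT or tagged
#'   backbone atoms) or `"calpha"`.
#' @param superpose Superpose before evaluating?
#' @return An `rmsd_result`: list with `value` (angstrom), `selection`,
#'   `superposed`, `n_atoms`.
#' @export
rmsd <- function(native, model, selection = c("all", "backbone", "calpha"),
                 superpose = TRUE) {
  selection <- match.arg(selection)
  stopifnot(inherits(native, "coordinate_set"),
            inherits(model, "coordinate_set"))
  pick <- function(cs) {
    a <- cs$atoms
    a <- switch(selection,
      all = a,
      backbone = if ("is_backbone" %in% names(a) && any(a$is_backbone)) {
        a[a$is_backbone, ]
      } else {
        a[a$name %in% c("N", "CA", "C", "O", "OXT"), ]
      },
      calpha = a[a$name == "CA", ]
    )
    a$key <- paste(a$resno, a$name)
    a
  }
  na <- pick(native)
  ma <- pick(model)
  common <- intersect(na$key, ma$key)
  if (length(common) == 0) {
    rk_abort("No atom-name correspondence between native and model",
             class = "residuekit_geometry_error")
  }
  only_native <- setdiff(na$key, ma$key)
  only_model <- setdiff(ma$key, na$key)
  if (length(only_native) || length(only_model)) {
    warning("unmatched atoms dropped: ",
            paste(c(only_native, only_model), collapse = ", "))
  }
  P <- as.matrix(na[match(common, na$key), c("x", "y", "z")])
  Q <- as.matrix(ma[match(common, ma$key), c("x", "y", "z")])
  if (superpose) Q <- kabsch_superpose(Q, P)
  value <- sqrt(sum((P - Q)^2) / nrow(P))
  structure(
    list(value = value, selection = selection, superposed = superpose,
         n_atoms = nrow(P)),
    class = "rmsd_result"
  )
}

#' @export
print.rmsd_result <- function(x, ...) {
  cat("<rmsd_result> ", format(round(x$value, 4), nsmall = 4), " A (",
      x$selection, ", ", x$n_atoms, " atoms, ",
      if (x$superposed) "superposed" else "raw", ")\n", sep = "")
  invisible(x)
}

# Kabsch: rigid-body transform of P that minimises RMSD onto Q
kabsch_superpose <- function(P, Q) {
  pc <- colMeans(P)
  qc <- colMeans(Q)
  P0 <- sweep(P, 2, pc)
  Q0 <- sweep(Q, 2, qc)
  s <- svd(crossprod(P0, Q0))
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  sweep(P0 %*% R, 2, qc, `+`)
}

#' Chirality-parity agreement between a definition and a model
#'
#' Perceives tetrahedral stereocentres from the definition's bond graph
#' (carbons whose four branches are pairwise distinguishable), derives the
#' expected parity label from the definition's own embedded conformer (which
#' realises the input stereo-SMILES), the observed label from the model
#' coordinates, and reports per-centre agreement. Labels are signed-volume
#' parity labels mapped onto "R"/"S" under a fixed internal branch-priority
#' convention (not full CIP); agreement is invariant to that convention.
#'
#' @param defn A `residue_definition` with embedded coordinates.
#' @param model A `coordinate_set` with atoms named as in the definition.
#' @return A `chirality_report`: list with `centers` (tibble: `atom`,
#'   `expected`, `observed`, `agree`) and `accuracy` (fraction agreeing;
#'   `NA` when the molecule has no perceivable centre, treated as vacuously
#'   agreeing in aggregate statistics).
#' @export
chirality_agreement <- function(defn, model) {
  stopifnot(inherits(defn, "residue_definition"),
            inherits(model, "coordinate_set"))
  topo <- defn$topology
  atoms <- topo$atoms
  bonds <- topo$bonds
  nbrs <- function(nm) {
    c(bonds$atom2[bonds$atom1 == nm], bonds$atom1[bonds$atom2 == nm])
  }
  branch_sig <- function(center, start) {
    # graph-only branch signature: BFS away from the centre, hashing the
    # sorted (depth, element, charge) multiset
    seen <- c(center, start)
    frontier <- start
    feats <- list(c(1L, atomic_number(atoms$element[atoms$name == start]),
                    atoms$charge[atoms$name == start]))
    depth <- 1L
    while (length(frontier) > 0) {
      depth <- depth + 1L
      nxt <- character()
      for (nm in frontier) {
        for (nb in nbrs(nm)) {
          if (!nb %in% seen) {
            seen <- c(seen, nb)
            nxt <- c(nxt, nb)
            feats[[length(feats) + 1]] <-
              c(depth, atomic_number(atoms$element[atoms$name == nb]),
                atoms$charge[atoms$name == nb])
          }
        }
      }
      frontier <- nxt
    }
    m <- do.call(rbind, feats)
    m <- m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
    hash_ints(as.vector(t(m)))
  }
  parity <- function(tbl, center, ordered_nbrs) {
    pc <- unlist(tbl[tbl$name == center, c("x", "y", "z")])
    ps <- lapply(ordered_nbrs[1:3], function(nm)
      unlist(tbl[tbl$name == nm, c("x", "y", "z")]))
    if (any(vapply(ps, length, integer(1)) != 3) || length(pc) != 3) {
      return(NA_character_)
    }
    v <- vapply(ps, function(p) p - pc, numeric(3))
    if (det(v) > 0) "R" else "S"
  }

  centers <- list()
  for (nm in atoms$name[atoms$element == "C"]) {
    nb <- nbrs(nm)
    if (length(nb) != 4) next
    sigs <- vapply(nb, function(s) branch_sig(nm, s), integer(1))
    if (anyDuplicated(sigs)) next
    ord <- nb[order(-sigs)]
    expected <- parity(atoms, nm, ord)
    observed <- parity(model$atoms, nm, ord)
    centers[[length(centers) + 1]] <- tibble::tibble(
      atom = nm, expected = expected, observed = observed,
      agree = !is.na(expected) && !is.na(observed) && expected == observed,
      note = if (is.na(observed)) "model atoms missing" else NA_character_
    )
  }
  centers <- if (length(centers) == 0) {
    tibble::tibble(atom = character(), expected = character(),
                   observed = character(), agree = logical(),
                   note = character())
  } else {
    dplyr::bind_rows(centers)
  }
  usable <- centers[!is.na(centers$expected) & !is.na(centers$observed), ]
  structure(
    list(centers = centers,
         accuracy = if (nrow(usable) == 0) NA_real_
                    else mean(usable$agree)),
    class = "chirality_report"
  )
}

#' @export
print.chirality_report <- function(x, ...) {
  cat("<chirality_report> ", nrow(x$centers), " centre(s), accuracy ",
      if (is.na(x$accuracy)) "n/a (no centres)" else
        format(round(x$accuracy, 3)), "\n", sep = "")
  invisible(x)
}
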