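test_that("reference bands reconstruct from the tabulated mean and sigma", {
  bands <- reference_bands()
  b <- function(m) bands[bands$metric == m, ]
  expect_equal(b("d_Ck_Ccarb")$lower, 1.441)
  expect_equal(b("d_Ck_Ccarb")$upper, 1.609)
  expect_equal(b("d_Ccarb_O_mean")$lower, 1.151)
  expect_equal(b("d_Ccarb_O_mean")$upper, 1.311)
  expect_equal(b("ang_Ck_Ccarb_O_mean")$lower, 114.0)
  expect_equal(b("ang_Ck_Ccarb_O_mean")$upper, 127.6)
  expect_equal(b("d_N_C1")[, c("lower", "upper")],
               tibble::tibble(lower = 1.382, upper = 1.534))
  expect_equal(b("ang_O1_Ccarb_O2")[, c("lower", "upper")],
               tibble::tibble(lower = 110, upper = 130))
})

test_that("the ideal alpha fixture reproduces its internal coordinates and passes", {
  ia <- ideal_alpha_coordinates()
  a <- ia$coords$atoms
  p <- function(nm) unlist(a[a$name == nm, c("x", "y", "z")])
  expect_equal(sqrt(sum((p("N") - p("CA"))^2)), 1.458, tolerance = 1e-6)
  expect_equal(sqrt(sum((p("CA") - p("C"))^2)), 1.525, tolerance = 1e-6)
  expect_equal(sqrt(sum((p("C") - p("O"))^2)), 1.231, tolerance = 1e-6)
  expect_equal(sqrt(sum((p("C") - p("OXT"))^2)), 1.231, tolerance = 1e-6)
  rep <- geometry_metrics(ia$coords, ia$backbone_map)
  expect_true(attr(rep, "all_pass"))
  expect_equal(sum(rep$in_range), 5)
})

test_that("out-of-band and missing geometry is flagged", {
  bad <- ideal_alpha_coordinates(ideal_geometry_spec(d_N_C1 = 1.30))
  rep <- geometry_metrics(bad$coords, bad$backbone_map)
  expect_false(rep$in_range[rep$metric == "d_N_C1"])
  expect_false(attr(rep, "all_pass"))
  expect_true(all(rep$in_range[rep$metric != "d_N_C1"]))
  # missing role atom: NA value, failed flag
  amputated <- bad$coords
  amputated$atoms <- amputated$atoms[amputated$atoms$name != "OXT", ]
  rep2 <- geometry_metrics(coordinate_set(amputated$atoms), bad$backbone_map)
  expect_true(is.na(rep2$value[rep2$metric == "ang_O1_Ccarb_O2"]))
  expect_false(attr(rep2, "all_pass"))
  # the O-angle mean is the arithmetic mean of the two substituent angles
  asym <- ideal_alpha_coordinates(ideal_geometry_spec())
  o1 <- asym$coords$atoms$name == "O"
  rep3 <- geometry_metrics(asym$coords, asym$backbone_map)
  expect_equal(rep3$value[rep3$metric == "ang_Ck_Ccarb_O_mean"], 120.8,
               tolerance = 1e-6)
})

test_that("perturbed fixtures break at least one band at the documented seed", {
  noisy <- ideal_alpha_coordinates(perturb = 0.5, seed = 7)
  rep <- geometry_metrics(noisy$coords, noisy$backbone_map)
  expect_false(attr(rep, "all_pass"))
})

test_that("omega classification matches the printed band rules", {
  r <- classify_omega(omega_fixture(179.2, -178.0), 2)
  expect_identical(r$category, "good")
  expect_equal(r$omega_prev, 179.2, tolerance = 1e-6)
  expect_equal(r$omega_next, -178.0, tolerance = 1e-6)
  expect_identical(classify_omega(omega_fixture(140, 165), 2)$category,
                   "borderline")
  expect_identical(classify_omega(omega_fixture(60, 175), 2)$category, "bad")
  expect_identical(classify_omega(omega_fixture(2, -179), 2)$category,
                   "good")  # cis peptide bonds are good
  # missing flanking atoms mean a missing omega, which is bad
  r_miss <- classify_omega(omega_fixture(180, NA), 2)
  expect_true(is.na(r_miss$omega_next))
  expect_identical(r_miss$category, "bad")
})

test_that("omega banding partitions |omega| exactly as the brute-force scan", {
  for (deg in 0:180) {
    expect_identical(residuekit:::omega_category(c(deg, deg)),
                     oracle_omega_band(c(deg, deg)), info = deg)
    expect_identical(residuekit:::omega_category(c(-deg, deg)),
                     oracle_omega_band(c(deg, deg)), info = -deg)
  }
  # zone boundaries: 30 and 150 are good, 120 is borderline
  expect_identical(residuekit:::omega_category(c(30, 30)), "good")
  expect_identical(residuekit:::omega_category(c(150, 150)), "good")
  expect_identical(residuekit:::omega_category(c(120, 180)), "borderline")
})

test_that("geometry metrics and omega are rigid-motion invariant", {
  ia <- ideal_alpha_coordinates()
  base <- geometry_metrics(ia$coords, ia$backbone_map)
  om <- omega_fixture(165, -140)
  base_om <- classify_omega(om, 2)
  for (seed in 1:5) {
    moved <- geometry_metrics(rigid_motion(ia$coords, seed), ia$backbone_map)
    expect_equal(moved$value, base$value, tolerance = 1e-6)
    moved_om <- classify_omega(rigid_motion(om, seed), 2)
    expect_equal(moved_om$omega_prev, base_om$omega_prev, tolerance = 1e-6)
    expect_equal(moved_om$omega_next, base_om$omega_next, tolerance = 1e-6)
  }
})

test_that("rmsd matches closed forms and the superposition inequality", {
  ia <- ideal_alpha_coordinates()$coords
  expect_equal(rmsd(ia, ia, superpose = FALSE)$value, 0)
  expect_equal(rmsd(ia, ia, superpose = TRUE)$value, 0, tolerance = 1e-9)
  # uniform translation by (1, 0, 0): raw RMSD exactly 1 A
  shifted <- ia
  shifted$atoms$x <- shifted$atoms$x + 1
  expect_equal(rmsd(ia, shifted, superpose = FALSE)$value, 1.0)
  expect_lt(rmsd(ia, shifted, superpose = TRUE)$value, 1e-9)
  # two-atom toy from direct evaluation of the equation
  toy_n <- coordinate_set(tibble::tibble(
    name = c("A1", "A2"), element = "C", x = c(0, 1), y = 0, z = 0))
  toy_m <- coordinate_set(tibble::tibble(
    name = c("A1", "A2"), element = "C", x = c(0, 2), y = 0, z = 0))
  expect_equal(rmsd(toy_n, toy_m, superpose = FALSE)$value, sqrt(1 / 2))
})

test_that("superposed rmsd never exceeds raw rmsd and matches bio3d", {
  ia <- ideal_alpha_coordinates()$coords
  for (seed in 1:5) {
    set.seed(seed)
    noisy <- ia
    noisy$atoms$x <- noisy$atoms$x + stats::rnorm(5, sd = 0.3)
    noisy$atoms$y <- noisy$atoms$y + stats::rnorm(5, sd = 0.3)
    noisy$atoms$z <- noisy$atoms$z + stats::rnorm(5, sd = 0.3)
    moved <- rigid_motion(noisy, seed + 100)
    raw <- rmsd(ia, moved, superpose = FALSE)$value
    sup <- rmsd(ia, moved, superpose = TRUE)$value
    expect_lte(sup, raw + 1e-12)
    # independent cross-check: bio3d's Kabsch fit on the same pairing
    ref <- bio3d::rmsd(
      as.vector(t(as.matrix(ia$atoms[, c("x", "y", "z")]))),
      as.vector(t(as.matrix(moved$atoms[, c("x", "y", "z")]))),
      fit = TRUE
    )
    expect_lt(abs(sup - ref), 5e-4)  # bio3d prints rounded to 3 decimals
  }
})

test_that("rmsd selections pair atoms by name and flag mismatches", {
  gly <- fx_defn_gly()
  cs <- as_coordinate_set(gly)
  expect_equal(rmsd(cs, cs)$value, 0, tolerance = 1e-9)
  bb <- rmsd(cs, cs, selection = "backbone")
  expect_equal(bb$n_atoms, 5)
  ca <- rmsd(cs, cs, selection = "calpha")
  expect_equal(ca$n_atoms, 1)
  other <- cs
  other$atoms$name[other$atoms$name == "HXT"] <- "HQQ"
  expect_warning(rmsd(cs, other), "unmatched")
  renamed <- cs
  renamed$atoms$name <- paste0("Q", seq_len(nrow(renamed$atoms)))
  expect_error(rmsd(cs, renamed), class = "residuekit_geometry_error")
})

test_that("chirality agreement is exact on self-comparison and halves on a flip", {
  thr <- fx_defn_thr()
  cs <- as_coordinate_set(thr)
  self <- chirality_agreement(thr, cs)
  expect_equal(nrow(self$centers), 2)
  expect_equal(self$accuracy, 1.0)
  # invert one of two centres by swapping two substituent positions
  a <- cs$atoms
  i1 <- which(a$name == "OG")
  i2 <- which(a$name == "CG")
  stopifnot(length(i1) == 1, length(i2) == 1)
  tmp <- a[i1, c("x", "y", "z")]
  a[i1, c("x", "y", "z")] <- a[i2, c("x", "y", "z")]
  a[i2, c("x", "y", "z")] <- tmp
  flipped <- chirality_agreement(thr, coordinate_set(a))
  expect_equal(flipped$accuracy, 0.5)
  expect_equal(sum(flipped$centers$agree), 1)
  # enantiomeric definitions disagree at every centre against each other's
  # conformer: a global mirror flips both labels
  mirrored <- cs
  mirrored$atoms$x <- -mirrored$atoms$x
  expect_equal(chirality_agreement(thr, mirrored)$accuracy, 0)
})

test_that("achiral residues report no centres with the documented convention", {
  gly <- fx_defn_gly()
  rep <- chirality_agreement(gly, as_coordinate_set(gly))
  expect_equal(nrow(rep$centers), 0)
  expect_true(is.na(rep$accuracy))
})

test_that("structure files round-trip through the PDB reader", {
  ia <- ideal_alpha_coordinates()$coords
  pdb <- tempfile(fileext = ".pdb")
  a <- ia$atoms
  lines <- vapply(seq_len(nrow(a)), function(i) {
    sprintf("ATOM  %5d %-4s GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            i, a$name[i], 1L, a$x[i], a$y[i], a$z[i], a$element[i])
  }, character(1))
  write_text(c(lines, "END"), pdb)
  cs <- read_structure(pdb)
  expect_equal(nrow(cs$atoms), 5)
  expect_setequal(cs$atoms$name, c("N", "CA", "C", "O", "OXT"))
  rep <- geometry_metrics(cs, c(N = "N", C1 = "CA", Ccarb = "C",
                                O1 = "O", O2 = "OXT"))
  expect_true(attr(rep, "all_pass"))
})
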