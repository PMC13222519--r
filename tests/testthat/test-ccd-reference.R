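test_that("the fixture SDF loads with both key maps populated", {
  lib <- fx_library()
  expect_s3_class(lib, "component_library")
  expect_equal(nrow(lib$components), 12)
  expect_true(all(is_valid_inchikey(lib$components$inchikey)))
  expect_true(all(nchar(lib$components$prefix14) == 14))
  expect_false(anyDuplicated(lib$components$component_id) > 0)
  # an acid / conjugate-base pair shares a connectivity layer
  expect_gt(sum(duplicated(lib$components$prefix14)), 0)
})

test_that("corrupt records are skipped, empty libraries are fatal", {
  src <- readLines(file.path(fx_library_dir(), "mini_components.sdf"))
  corrupt <- c("BADREC", "  residuekit 2D", "", "garbage counts line",
               "M  END", "$$$$", src)
  path <- write_text(corrupt, tempfile(fileext = ".sdf"))
  expect_message(lib <- read_component_library(path), "skipped")
  expect_equal(nrow(lib$components), 12)
  expect_equal(lib$n_skipped, 1)

  empty <- write_text(c("JUNK", "no structure here", "$$$$"),
                      tempfile(fileext = ".sdf"))
  expect_error(suppressMessages(read_component_library(empty)),
               class = "residuekit_empty_library_error")
  expect_error(read_component_library(tempfile()),
               class = "residuekit_io_error")
})

test_that("gzip compression is transparent and loading is deterministic", {
  plain <- fx_library()
  gz <- suppressMessages(read_component_library(
    file.path(fx_library_dir(), "mini_components.sdf.gz")
  ))
  expect_identical(plain$components, gz$components)
  again <- suppressMessages(read_component_library(
    file.path(fx_library_dir(), "mini_components.sdf")
  ))
  expect_identical(plain$components, again$components)
})

test_that("invalid stored keys are recomputed from the structure", {
  src <- readLines(file.path(fx_library_dir(), "mini_components.sdf"))
  gly_key <- "DHMQDGOQFOQNFH-UHFFFAOYSA-N"
  stopifnot(any(src == gly_key))
  src[src == gly_key] <- "NOT-A-VALID-KEY"
  path <- write_text(src, tempfile(fileext = ".sdf"))
  lib <- suppressMessages(read_component_library(path))
  expect_true(all(is_valid_inchikey(lib$components$inchikey)))
  expect_identical(
    lib$components$inchikey[lib$components$component_id == "GLY"], gly_key
  )
})

test_that("InChIKeys have the expected frozen values and stereo behaviour", {
  # values verified against an independent InChI implementation
  expect_identical(standard_inchikey("NCC(=O)O"),
                   "DHMQDGOQFOQNFH-UHFFFAOYSA-N")
  expect_identical(standard_inchikey("NCC(=O)O.Cl"),
                   "DHMQDGOQFOQNFH-UHFFFAOYSA-N")
  l_ala <- standard_inchikey("N[C@@H](C)C(=O)O")
  d_ala <- standard_inchikey("N[C@H](C)C(=O)O")
  expect_identical(l_ala, "QNAYBMKLOCPYGJ-REOHCLBHSA-N")
  expect_identical(d_ala, "QNAYBMKLOCPYGJ-UWTATZPHSA-N")
  # stereo lives outside the connectivity layer
  expect_identical(inchikey_prefix(l_ala), inchikey_prefix(d_ala))
  expect_false(l_ala == d_ala)
  expect_equal(nchar(inchikey_prefix(l_ala)), 14)
})

test_that("every library member round-trips to itself with a full-key match", {
  lib <- fx_library()
  for (i in seq_len(nrow(lib$components))) {
    m <- map_query_to_ccd(lib$components$smiles[i], lib)
    expect_identical(m$mode, "full_key", info = lib$components$component_id[i])
    expect_identical(m$confidence, "high")
    expect_true(lib$components$component_id[i] %in%
                  m$candidates$component_id)
  }
})

test_that("connectivity-layer matching catches protonation variants (pass 2)", {
  lib <- fx_library()
  # deprotonated beta-alanine: full key differs, 14-char prefix matches BAL
  m <- map_query_to_ccd("NCCC(=O)[O-]", lib)
  expect_identical(m$mode, "connectivity_layer")
  expect_true("BAL" %in% m$candidates$component_id)
  expect_identical(
    inchikey_prefix(m$query_inchikey),
    lib$components$prefix14[lib$components$component_id == "BAL"]
  )
  # full-key candidates are a subset of connectivity-layer candidates
  full <- lib$components$component_id[
    lib$components$inchikey == m$query_inchikey]
  conn <- lib$components$component_id[
    lib$components$prefix14 == inchikey_prefix(m$query_inchikey)]
  expect_true(all(full %in% conn))
})

test_that("absent queries return mode none and retain_all is honoured", {
  lib <- fx_library()
  m <- map_query_to_ccd("CCCCCCCCBr", lib)
  expect_identical(m$mode, "none")
  expect_identical(m$confidence, "none")
  expect_equal(nrow(m$candidates), 0)
  # GLY and GLZ share a connectivity layer: querying the shared skeleton in a
  # third protonation-ish spelling keeps all candidates, or the first only
  m_all <- map_query_to_ccd("NCC(=O)O", lib)
  expect_identical(m_all$mode, "full_key")
  m_first <- map_query_to_ccd("NCC(=O)[O-]", lib, retain_all = FALSE)
  expect_lte(nrow(m_first$candidates), 1)
})
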