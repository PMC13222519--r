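test_that("component IDs follow the documented sequence and avoid collisions", {
  expect_identical(assign_component_id(), "ZCA")
  expect_identical(assign_component_id("ZCA"), "ZCB")
  used <- vapply(0:14, function(i) paste0("ZC", LETTERS[i + 1]), character(1))
  expect_identical(assign_component_id(used), "ZCP")  # 16th in the sequence
  # sequence wraps past ZCZ into ZDA and skips reserved codes
  all_zc <- paste0("ZC", LETTERS)
  expect_identical(assign_component_id(all_zc), "ZDA")
  # injectivity within a session
  session <- character()
  for (i in 1:30) session <- c(session, assign_component_id(session))
  expect_false(anyDuplicated(session) > 0)
  expect_false(any(session %in% standard_codes()))
})

test_that("definitions refuse invalid or colliding component IDs", {
  defn <- fx_defn_gly()
  expect_error(
    new_residue_definition(defn$topology, component_id = "ALA",
                           metadata = defn$metadata),
    class = "residuekit_export_error"
  )
  expect_error(
    new_residue_definition(defn$topology, component_id = "zc1",
                           metadata = defn$metadata),
    class = "residuekit_export_error"
  )
})

test_that("residue CSV writes the documented three-section dialect", {
  defn <- fx_defn_gly()
  path <- tempfile(fileext = ".csv")
  write_residue_csv(defn, path)
  lines <- readLines(path)
  expect_equal(sum(grepl("^atom,", lines)), 10)
  expect_equal(sum(grepl("^bond,", lines)), 9)
  expect_gt(sum(grepl("^meta,", lines)), 0)
  expect_gt(sum(grepl("^role,", lines)), 0)
  # leaving atoms are flagged for polymerisation: OXT, HXT, one amine H
  atom_lines <- lines[grepl("^atom,", lines)]
  leaving <- vapply(strsplit(atom_lines, ","), function(f)
    if (f[9] == "true") f[2] else NA_character_, character(1))
  expect_setequal(stats::na.omit(leaving), c("OXT", "HXT", "H2"))
})

test_that("CSV round trip is the identity on residue definitions", {
  for (defn in list(fx_defn_gly(), fx_defn_ala())) {
    path <- tempfile(fileext = ".csv")
    write_residue_csv(defn, path)
    back <- read_residue_csv(path)
    expect_identical(back$component_id, defn$component_id)
    expect_identical(back$topology$residue_class,
                     defn$topology$residue_class)
    shared <- c("element", "name", "charge", "is_backbone", "parent_heavy")
    expect_identical(as.data.frame(back$topology$atoms[, shared]),
                     as.data.frame(defn$topology$atoms[, shared]))
    expect_equal(back$topology$atoms$x, defn$topology$atoms$x,
                 tolerance = 1e-6)
    expect_identical(as.data.frame(back$topology$bonds),
                     as.data.frame(defn$topology$bonds))
    expect_identical(back$topology$backbone_map, defn$topology$backbone_map)
    expect_identical(back$metadata$inchikey, defn$metadata$inchikey)
    # writing the read-back definition reproduces the bytes exactly
    path2 <- tempfile(fileext = ".csv")
    write_residue_csv(back, path2)
    expect_identical(readBin(path, "raw", file.size(path) + 10),
                     readBin(path2, "raw", file.size(path2) + 10))
  }
})

test_that("malformed residue CSVs are rejected with located errors", {
  defn <- fx_defn_gly()
  path <- tempfile(fileext = ".csv")
  write_residue_csv(defn, path)
  lines <- readLines(path)

  no_bonds <- write_text(lines[!grepl("^bond,", lines)],
                         tempfile(fileext = ".csv"))
  expect_error(read_residue_csv(no_bonds), "bond",
               class = "residuekit_csv_error")

  bad_ref <- write_text(
    c(lines, "bond,QQ,ZZ,single,false"), tempfile(fileext = ".csv")
  )
  err <- tryCatch(read_residue_csv(bad_ref), error = function(e) e)
  expect_s3_class(err, "residuekit_csv_error")
  expect_match(conditionMessage(err), "row [0-9]+")

  dup <- gsub("OXT", "O", lines)  # collapses OXT onto O: duplicate name
  expect_error(read_residue_csv(write_text(dup, tempfile(fileext = ".csv"))),
               class = "residuekit_topology_error")
  # a definition with duplicate names also refuses to write
  broken <- defn
  broken$topology$atoms$name[broken$topology$atoms$name == "OXT"] <- "O"
  expect_error(write_residue_csv(broken, tempfile(fileext = ".csv")),
               class = "residuekit_topology_error")
})

test_that("the GGXGG helper emits a valid five-residue job", {
  defn <- fx_defn_gly()
  out <- tempfile()
  path <- ggxgg_job(defn, out)
  job <- jsonlite::read_json(path)
  expect_length(validate_af3_job(path), 0)
  prot <- job$sequences[[1]]$protein
  expect_identical(prot$sequence, "GGXGG")
  expect_length(prot$modifications, 1)
  expect_equal(prot$modifications[[1]]$position, 3)
  expect_identical(prot$modifications[[1]]$componentId, defn$component_id)
  expect_length(job$customComponents, 1)
  csv_rel <- job$customComponents[[1]]$csv
  expect_true(file.exists(file.path(out, csv_rel)))
  # the referenced CSV reconstructs the definition
  back <- read_residue_csv(file.path(out, csv_rel))
  expect_identical(back$component_id, defn$component_id)
})

test_that("multi-chain jobs with several custom residues validate", {
  defns <- list(fx_defn_gly(), fx_defn_ala())
  defns[[1]]$component_id <- "ZCA"
  defns[[2]]$component_id <- "ZCB"
  out <- tempfile()
  path <- build_af3_json(
    chains = "GSXAXG",
    modifications = tibble::tibble(chain = c(1L, 1L), position = c(3L, 5L),
                                   component_id = c("ZCA", "ZCB")),
    definitions = defns, out_dir = out, name = "two_mods"
  )
  expect_length(validate_af3_job(path), 0)
  expect_true(file.exists(file.path(out, "components", "ZCA.csv")))
  expect_true(file.exists(file.path(out, "components", "ZCB.csv")))
})

test_that("unresolvable components and bad positions are refused", {
  defn <- fx_defn_gly()
  expect_error(
    build_af3_json("GGXGG",
                   tibble::tibble(chain = 1L, position = 3L,
                                  component_id = "ZZZ"),
                   definitions = list(), out_dir = tempfile()),
    class = "residuekit_export_error"
  )
  expect_error(
    build_af3_json("GGXGG",
                   tibble::tibble(chain = 1L, position = 9L,
                                  component_id = defn$component_id),
                   definitions = list(defn), out_dir = tempfile()),
    class = "residuekit_export_error"
  )
  # hand-corrupted job JSON fails schema validation
  out <- tempfile()
  path <- ggxgg_job(defn, out)
  job <- jsonlite::read_json(path)
  job$sequences[[1]]$protein$sequence <- NULL
  expect_gt(length(validate_af3_job(job)), 0)
})
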