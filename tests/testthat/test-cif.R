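test_that("a minimal comp block parses into one monomer", {
  doc <- c(
    "data_comp_EX1",
    "loop_",
    "_chem_comp_atom.comp_id",
    "_chem_comp_atom.atom_id",
    "_chem_comp_atom.type_symbol",
    "_chem_comp_atom.type_energy",
    "_chem_comp_atom.partial_charge",
    "EX1 C1 C . 0",
    "EX1 C2 C . 0",
    "loop_",
    "_chem_comp_bond.comp_id",
    "_chem_comp_bond.atom_id_1",
    "_chem_comp_bond.atom_id_2",
    "_chem_comp_bond.type",
    "_chem_comp_bond.value_dist",
    "_chem_comp_bond.value_dist_esd",
    "EX1 C1 C2 single . .")
  lib <- read_library(doc)
  expect_length(lib$monomers, 1L)
  expect_length(lib$modifications, 0L)
  expect_length(lib$links, 0L)
  expect_equal(lib$monomers$EX1$atoms$name, c("C1", "C2"))
  expect_equal(lib$monomers$EX1$level, "minimal")
})

test_that("fixture library round-trips semantically and byte-stably", {
  lib <- FIXTURE_LIB
  doc1 <- write_library(lib)
  lib2 <- read_library(doc1)
  doc2 <- write_library(lib2)
  expect_identical(doc1, doc2)
  expect_setequal(names(lib2$monomers), names(lib$monomers))
  expect_setequal(names(lib2$modifications), names(lib$modifications))
  expect_setequal(names(lib2$links), names(lib$links))
  for (code in names(lib$monomers)) {
    a <- lib$monomers[[code]]; b <- lib2$monomers[[code]]
    expect_equal(sort(a$atoms$name), sort(b$atoms$name), info = code)
    expect_equal(nrow(a$bonds), nrow(b$bonds), info = code)
    expect_equal(nrow(a$angles), nrow(b$angles), info = code)
    ca <- canonical_order <- linksmith:::canonicalize_description(a)
    cb <- linksmith:::canonicalize_description(b)
    expect_equal(cb$bonds$target, round(ca$bonds$target, 3), info = code)
    expect_equal(cb$angles$target, round(ca$angles$target, 2), info = code)
    expect_equal(cb$chirals$sign, ca$chirals$sign, info = code)
  }
})

test_that("random-molecule libraries double round-trip byte-identically", {
  mons <- lapply(1:50, function(s)
    complete_description(random_molecule(s, n_heavy = 3L + s %% 8L,
                                         code = sprintf("R%02d", s)),
                         PARAM_TABLE))
  names(mons) <- vapply(mons, `[[`, character(1), "code")
  lib <- restraint_library(monomers = mons)
  doc1 <- write_library(lib)
  doc2 <- write_library(read_library(doc1))
  expect_identical(doc1, doc2)
})

test_that("the shipped fragments file reads back as the built-in library", {
  path <- system.file("extdata", "fragments.cif", package = "linksmith")
  skip_if(path == "", "installed extdata not found")
  lib <- read_library(path)
  expect_setequal(names(lib$monomers),
                  c("GLY", "ALA", "CYS", "LYS", "PLP", "GLC"))
  expect_true("DEL-OXT" %in% names(lib$modifications))
  expect_true("TRANS" %in% names(lib$links))
})

test_that("parse and consistency errors are raised with context", {
  bad_loop <- c("data_comp_Z", "loop_", "_chem_comp_atom.comp_id",
                "_chem_comp_atom.atom_id", "Z C1 Z")
  expect_error(read_library(bad_loop), "malformed loop")

  missing_entry <- c("data_mod_list", "loop_", "_chem_mod.id",
                     "_chem_mod.name", "_chem_mod.comp_id",
                     "_chem_mod.group_id", "GONE . . peptide")
  expect_error(read_library(missing_entry), "GONE")

  dangling <- FIXTURE_LIB
  dangling$monomers$GLY$bonds$atom1[1] <- "ZZ"
  expect_error(write_library(dangling), "GLY")
})

test_that("missing esd fields read as documented defaults and are flagged", {
  doc <- c(
    "data_comp_EX2",
    "loop_",
    "_chem_comp_atom.comp_id", "_chem_comp_atom.atom_id",
    "_chem_comp_atom.type_symbol", "_chem_comp_atom.type_energy",
    "_chem_comp_atom.partial_charge",
    "EX2 C1 C CH3 0", "EX2 C2 C CH3 0",
    "loop_",
    "_chem_comp_bond.comp_id", "_chem_comp_bond.atom_id_1",
    "_chem_comp_bond.atom_id_2", "_chem_comp_bond.type",
    "_chem_comp_bond.value_dist", "_chem_comp_bond.value_dist_esd",
    "EX2 C1 C2 single 1.530 .")
  lib <- read_library(doc)
  m <- lib$monomers$EX2
  expect_equal(m$bonds$sigma, 0.02)
  expect_true("bond esd defaulted" %in% attr(m, "flagged_defaults"))
})

test_that("merging keeps additional entries where ids collide", {
  add <- restraint_library(
    monomers = list(GLY = apply_edit(FIXTURE_LIB$monomers$GLY,
                                     graph_edit("change_atom", name = "O",
                                                energy_type = "OC"))),
    provenance = "additional")
  merged <- merge_libraries(FIXTURE_LIB, add)
  gly <- merged$monomers$GLY
  expect_equal(gly$atoms$energy_type[gly$atoms$name == "O"], "OC")
  expect_equal(attr(merged, "shadowed"), "GLY")
  expect_equal(unname(merged$provenance["GLY"]), "additional")
})
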