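test_that("the built-in library is complete, valid and self-consistent", {
  lib <- FIXTURE_LIB
  expect_setequal(names(lib$monomers),
                  c("GLY", "ALA", "CYS", "LYS", "PLP", "GLC"))
  for (code in names(lib$monomers)) {
    m <- lib$monomers[[code]]
    expect_equal(m$level, "complete", info = code)
    expect_equal(nrow(validate_monomer(m)), 0L, info = code)
    expect_true(all(!is.na(m$bonds$target)), info = code)
  }

  # PLP carries the aldehyde oxygen double-bonded to C4A
  plp <- lib$monomers$PLP
  k <- linksmith:::bond_between(plp, "O4A", "C4A")
  expect_length(k, 1L)
  expect_equal(plp$bonds$order[k], "double")

  # the anomeric modification removes O1 and HO1 from the pyranose
  d <- lib$modifications$`DEL-O1`
  expect_setequal(d$atoms$atom_id[d$atoms$fun == "delete"], c("O1", "HO1"))
  expect_equal(d$group, "pyranose")

  expect_length(resolve_references(lib), 0L)
})

test_that("the parameter table resolves symmetrically with fallbacks", {
  tbl <- PARAM_TABLE
  amide <- lookup_bond(tbl, "C", "NH1", "C", "N", "single")
  expect_equal(amide$level, "typed")
  expect_gt(amide$sigma, 0)
  rev <- lookup_bond(tbl, "NH1", "C", "N", "C", "single")
  expect_equal(rev$target, amide$target)

  unknown <- lookup_bond(tbl, "QQ1", "QQ2", "C", "S", "single")
  expect_equal(unknown$level, "element")
  madeup <- lookup_bond(tbl, "QQ1", "QQ2", "Se", "Br", "single")
  expect_equal(madeup$level, "radii")
  expect_equal(madeup$target, 1.20 + 1.20, tolerance = 1e-9)

  ang <- lookup_angle(tbl, "ZZ", "ZZ", "ZZ", hyb2 = "sp2")
  expect_equal(ang$target, 120)
  expect_equal(ang$level, "hybrid")
})

test_that("the random-molecule generator is deterministic and valid", {
  a <- random_molecule(1, 8)
  b <- random_molecule(1, 8)
  expect_identical(a$atoms, b$atoms)
  expect_identical(a$bonds, b$bonds)

  for (seed in 1:100) {
    m <- random_molecule(seed, 2L + seed %% 12L)
    expect_equal(nrow(validate_monomer(m)), 0L, info = paste("seed", seed))
  }

  tiny <- random_molecule(3, 2)
  expect_equal(sum(tiny$atoms$element != "H"), 2L)
  heavy <- tiny$atoms$name[tiny$atoms$element != "H"]
  expect_length(linksmith:::bond_between(tiny, heavy[1], heavy[2]), 1L)
})

test_that("design-scheme entry counts follow the two library designs", {
  expect_equal(count_design_entries(design_scheme("monomer_only", 20, 3, 2)),
               120L)
  expect_equal(count_design_entries(design_scheme("monomer_only", 1, 3, 2)),
               6L)
  expect_equal(count_design_entries(
    design_scheme("link_mod", 20, n_generic_mods = 2, n_generic_links = 2)),
    24L)

  set.seed(31)
  for (i in 1:20) {
    n <- sample(1:30, 1); p <- sample(1:4, 1); c2 <- sample(1:3, 1)
    expect_equal(count_design_entries(design_scheme("monomer_only", n, p, c2)),
                 n * p * c2)
    gm <- sample(0:5, 1); gl <- sample(0:5, 1)
    expect_equal(count_design_entries(
      design_scheme("link_mod", n, n_generic_mods = gm, n_generic_links = gl)),
      n + gm + gl)
  }
  expect_error(design_scheme("monomer_only", 20, 0, 0))
})

test_that("fixture mods and links assemble a dipeptide that matches the table", {
  gly <- FIXTURE_LIB$monomers$GLY
  out <- apply_link(gly, gly, FIXTURE_LIB$modifications$`DEL-OXT`,
                    FIXTURE_LIB$modifications$NH1, FIXTURE_LIB$links$TRANS)
  expect_equal(nrow(validate_monomer(out$desc)), 0L)
  # 2 glycines - OXT - HXT - H2 + nothing = 10 + 10 - 3
  expect_equal(nrow(out$desc$atoms), 17L)
})
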