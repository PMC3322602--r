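lysplp_session <- local({
  lys <- FIXTURE_LIB$monomers$LYS
  plp0 <- FIXTURE_LIB$monomers$PLP
  plp <- apply_edit(plp0, graph_edit("delete_atom", name = "O4A"))
  ses <- compose_session(lys, plp, list("NZ", "C4A", "double"),
                         parentA = lys, parentB = plp0)
  regularize_session(ses, PARAM_TABLE, seed = 1)
})

test_that("composition validates endpoints and keeps copies distinct", {
  lys <- FIXTURE_LIB$monomers$LYS
  plp <- FIXTURE_LIB$monomers$PLP
  ses <- compose_session(lys, plp, list("NZ", "C4A", "double"))
  expect_s3_class(ses, "composite_session")
  expect_false(ses$regularized)

  cys <- FIXTURE_LIB$monomers$CYS
  ss <- compose_session(cys, cys, list("SG", "SG", "single"))
  ss <- make_unique_names(ss)
  expect_equal(sum(ss$map$orig == "SG"), 2L)
  expect_equal(anyDuplicated(ss$map$unique), 0L)

  expect_error(compose_session(lys, plp, list("QQ", "C4A", "single")), "QQ")
  expect_error(compose_session(lys, plp, list("NZ", "C4A", "quadruple")),
               "order")
})

test_that("unique naming is bijective and restorable", {
  cys <- FIXTURE_LIB$monomers$CYS
  ses <- make_unique_names(compose_session(cys, cys, list("SG", "SG", "single")))
  map <- ses$map
  expect_equal(anyDuplicated(map$unique), 0L)
  expect_equal(anyDuplicated(paste(map$side, map$orig)), 0L)
  # restoring through the map is the identity per side
  for (s in 1:2) {
    side <- map[map$side == s, ]
    back <- stats::setNames(side$orig, side$unique)
    expect_setequal(unname(back[side$unique]),
                    FIXTURE_LIB$monomers$CYS$atoms$name)
  }

  # no collisions: names pass through unchanged
  lys <- FIXTURE_LIB$monomers$LYS
  plp <- FIXTURE_LIB$monomers$PLP
  m2 <- make_unique_names(compose_session(lys, plp,
                                          list("NZ", "C4A", "double")))$map
  shared <- intersect(lys$atoms$name, plp$atoms$name)
  keep <- !m2$orig %in% shared
  expect_equal(m2$orig[keep], m2$unique[keep])

  # random molecule pairs: rename/restore round-trips
  for (seed in 1:6) {
    a <- random_molecule(seed, 6); b <- random_molecule(seed + 50, 6)
    cn <- linksmith:::canonical_composite_names(a$atoms$name, b$atoms$name)
    expect_equal(anyDuplicated(c(cn$side1, cn$side2)), 0L)
    expect_equal(names(cn$side1), a$atoms$name)
    expect_equal(names(cn$side2), b$atoms$name)
  }
})

test_that("regularizing the composite adjusts hydrogens across the bond", {
  ses <- lysplp_session
  expect_true(ses$regularized)
  expect_true(ses$report$converged)
  # the imine nitrogen keeps exactly one of its three hydrogens
  expect_equal(sum(grepl("^HZ", ses$map$orig[ses$map$side == 1])), 1L)
  # both original names are restorable through the map
  expect_equal(anyDuplicated(ses$map$unique), 0L)

  # the glycine dipeptide case: amide forms, composite converges
  gly <- FIXTURE_LIB$monomers$GLY
  g1 <- apply_edit(apply_edit(gly, graph_edit("delete_atom", name = "OXT")),
                   graph_edit("delete_atom", name = "HXT"))
  dip <- regularize_session(
    compose_session(g1, gly, list("C", "N", "single"),
                    parentA = gly, parentB = gly),
    PARAM_TABLE, seed = 2)
  expect_true(dip$report$converged)
  expect_lte(dip$report$max$bond, 0.01)

  # leaving the aldehyde oxygen in place violates the valence at C4A
  lys <- FIXTURE_LIB$monomers$LYS
  plp0 <- FIXTURE_LIB$monomers$PLP
  expect_error(
    regularize_session(compose_session(lys, plp0, list("NZ", "C4A", "double")),
                       PARAM_TABLE),
    "C4A")
})

test_that("splitting yields the expected link and modification content", {
  expect_error(split_session(compose_session(FIXTURE_LIB$monomers$GLY,
                                             FIXTURE_LIB$monomers$ALA,
                                             list("C", "N", "single"))),
               "before regularization")

  parts <- split_session(lysplp_session, PARAM_TABLE)
  expect_equal(parts$mod1$id, "LYSmod1")
  expect_equal(parts$mod2$id, "PLPmod1")
  expect_equal(parts$link$id, "LYS-PLP")

  # link carries the NZ-C4A bond and every angle spanning it
  lb <- parts$link$bonds
  expect_equal(nrow(lb), 1L)
  expect_setequal(c(lb$atom1, lb$atom2), c("NZ", "C4A"))
  expect_equal(lb$order, "double")
  expect_gt(nrow(parts$link$angles), 0L)
  span_ok <- apply(parts$link$angles[, c("comp1", "comp2", "comp3")], 1,
                   function(r) length(unique(r)) > 1)
  expect_true(all(span_ok))

  # PLP modification deletes the aldehyde oxygen; LYS loses two hydrogens
  del2 <- parts$mod2$atoms[parts$mod2$atoms$fun == "delete", "atom_id"]
  expect_true("O4A" %in% del2)
  del1 <- parts$mod1$atoms[parts$mod1$atoms$fun == "delete", "atom_id"]
  expect_equal(sort(grep("^HZ", del1, value = TRUE)), c("HZ2", "HZ3"))
})

test_that("every link restraint references both sides", {
  for (seed in c(3, 8)) {
    case <- sample_composition(seed)
    ses <- regularize_session(
      compose_session(case$monA, case$monB, case$bond), PARAM_TABLE,
      seed = seed)
    parts <- split_session(ses, PARAM_TABLE)
    l <- parts$link
    expect_gte(nrow(l$bonds), 1L)
    expect_true(all(apply(l$bonds[, c("comp1", "comp2")], 1,
                          function(r) length(unique(r)) > 1)))
    if (nrow(l$torsions))
      expect_true(all(apply(l$torsions[, c("comp1", "comp2", "comp3", "comp4")],
                            1, function(r) length(unique(r)) > 1)))
    if (nrow(l$planes)) {
      by_plane <- split(l$planes$comp, l$planes$plane_id)
      expect_true(all(vapply(by_plane, function(x)
        length(unique(x)) > 1, logical(1))))
    }
  }
})

test_that("change detection follows the declared-sigma threshold", {
  ref <- complete_description(FIXTURE_LIB$monomers$GLY, PARAM_TABLE)
  sub <- ref
  k <- which(sub$bonds$atom1 == "CA" & sub$bonds$atom2 == "C" |
               sub$bonds$atom1 == "C" & sub$bonds$atom2 == "CA")
  sigma <- sub$bonds$sigma[k]

  sub_small <- sub
  sub_small$bonds$target[k] <- sub$bonds$target[k] + 0.5 * sigma
  m_small <- linksmith:::diff_modification(ref, sub_small, "Gm1")
  expect_equal(nrow(m_small$bonds), 0L)

  sub_big <- sub
  sub_big$bonds$target[k] <- sub$bonds$target[k] + 2 * sigma
  m_big <- linksmith:::diff_modification(ref, sub_big, "Gm2")
  expect_equal(nrow(m_big$bonds), 1L)
  expect_equal(m_big$bonds$fun, "change")
  expect_equal(m_big$bonds$new_target, sub_big$bonds$target[k])

  # multiplier 0 records even the sub-sigma change (lossless split)
  m_zero <- linksmith:::diff_modification(ref, sub_small, "Gm3",
                                          sigma_multiplier = 0)
  expect_equal(nrow(m_zero$bonds), 1L)
})

test_that("modifications apply in delete-change-add order with checks", {
  ala <- FIXTURE_LIB$monomers$ALA
  del_oxt <- FIXTURE_LIB$modifications$`DEL-OXT`
  out <- apply_modification(ala, del_oxt)
  expect_false("OXT" %in% out$atoms$name)
  expect_false("HXT" %in% out$atoms$name)
  expect_false("OXT" %in% out$planes$atom_id)
  # the carboxyl plane survives with its remaining three atoms
  expect_true(all(c("C", "CA", "O") %in% out$planes$atom_id))

  empty <- modification_entry("NOP", parent = "ALA")
  same <- apply_modification(ala, empty)
  expect_equal(same$atoms, ala$atoms)
  expect_equal(same$bonds, ala$bonds)

  expect_error(apply_modification(FIXTURE_LIB$monomers$PLP, del_oxt),
               "group 'peptide'")
  expect_error(apply_modification(FIXTURE_LIB$monomers$GLY,
                                  FIXTURE_LIB$modifications$`DEL-O1`),
               "pyranose")
  bad <- modification_entry("BADM", parent = "GLY",
                            atoms = data.frame(fun = "delete", atom_id = "ZZ",
                                               new_atom_id = NA,
                                               new_type_symbol = NA,
                                               new_type_energy = NA,
                                               new_charge = NA))
  expect_error(apply_modification(FIXTURE_LIB$monomers$GLY, bad), "ZZ")
})

test_that("diff of an applied modification reproduces the modification", {
  ref <- complete_description(FIXTURE_LIB$monomers$ALA, PARAM_TABLE)
  mod <- FIXTURE_LIB$modifications$`DEL-OXT`
  sub <- apply_modification(ref, mod)
  rec <- linksmith:::diff_modification(ref, sub, "ALAmod1")
  expect_setequal(rec$atoms$atom_id[rec$atoms$fun == "delete"],
                  c("OXT", "HXT"))
  expect_equal(nrow(rec$atoms[rec$atoms$fun == "add", ]), 0L)
})

test_that("generic links check groups and build the amide correctly", {
  gly <- FIXTURE_LIB$monomers$GLY
  trans <- FIXTURE_LIB$links$TRANS
  out <- apply_link(gly, gly,
                    FIXTURE_LIB$modifications$`DEL-OXT`,
                    FIXTURE_LIB$modifications$NH1, trans)
  # one amide bond between side-1 C and side-2 N at the table target
  amide <- lookup_bond(PARAM_TABLE, "C", "NH1", "C", "N", "single")
  mp <- stats::setNames(out$map$unique, paste(out$map$side, out$map$orig))
  cn <- out$desc$bonds[
    (out$desc$bonds$atom1 == mp[["1 C"]] & out$desc$bonds$atom2 == mp[["2 N"]]) |
      (out$desc$bonds$atom2 == mp[["1 C"]] & out$desc$bonds$atom1 == mp[["2 N"]]), ]
  expect_equal(nrow(cn), 1L)
  expect_equal(cn$target, amide$target)
  expect_equal(nrow(validate_monomer(out$desc)), 0L)

  # a pyranose-only link refuses a peptide on side 2
  expect_error(
    apply_link(FIXTURE_LIB$monomers$GLC, gly,
               FIXTURE_LIB$modifications$`DEL-O1`,
               FIXTURE_LIB$modifications$`DEL-HO4`,
               FIXTURE_LIB$links$`ALPHA1-4`),
    "group")
})

test_that("apply_link over a lossless split reproduces the composite", {
  parts <- split_session(lysplp_session, PARAM_TABLE, sigma_multiplier = 0)
  out <- apply_link(complete_description(FIXTURE_LIB$monomers$LYS, PARAM_TABLE),
                    complete_description(FIXTURE_LIB$monomers$PLP, PARAM_TABLE),
                    parts$mod1, parts$mod2, parts$link)
  expect_true(isTRUE(composites_equal(lysplp_session$composite,
                                      lysplp_session$map,
                                      out$desc, out$map)))
})

test_that("saving as an additional library writes the documented blocks", {
  f <- withr::local_tempfile(fileext = ".cif")
  save_additional_library(lysplp_session, f, base = FIXTURE_LIB,
                          table = PARAM_TABLE)
  expect_equal(count_cif_blocks(f), 5L)
  lines <- readLines(f)
  expect_true("data_mod_LYSmod1" %in% lines)
  expect_true("data_mod_PLPmod1" %in% lines)
  expect_true("data_link_LYS-PLP" %in% lines)
  back <- read_library(f, provenance = "additional")
  expect_length(back$monomers, 0L)
  expect_setequal(names(back$modifications), c("LYSmod1", "PLPmod1"))
  expect_equal(names(back$links), "LYS-PLP")
  bb <- back$links$`LYS-PLP`$bonds
  expect_setequal(c(bb$atom1, bb$atom2), c("NZ", "C4A"))

  # a parent missing from the base library is written as a monomer block
  smaller <- FIXTURE_LIB
  smaller$monomers$PLP <- NULL
  f2 <- withr::local_tempfile(fileext = ".cif")
  save_additional_library(lysplp_session, f2, base = smaller,
                          table = PARAM_TABLE)
  expect_equal(count_cif_blocks(f2), 6L)
  expect_true("data_comp_PLP" %in% readLines(f2))

  # forcing a monomer that shadows a base entry warns (the name-shadowing
  # pitfall) and appending an existing id warns with precedence to the new
  f3 <- withr::local_tempfile(fileext = ".cif")
  w <- testthat::capture_warnings(
    save_additional_library(lysplp_session, f3, base = FIXTURE_LIB,
                            table = PARAM_TABLE, force_monomers = TRUE))
  expect_true(any(grepl("shadows", w)))
  expect_warning(save_additional_library(lysplp_session, f, mode = "append",
                                         base = FIXTURE_LIB,
                                         table = PARAM_TABLE),
                 "precedence")
})

test_that("splitting is deterministic: same session writes identical files", {
  f1 <- withr::local_tempfile(fileext = ".cif")
  f2 <- withr::local_tempfile(fileext = ".cif")
  save_additional_library(lysplp_session, f1, base = FIXTURE_LIB,
                          table = PARAM_TABLE)
  save_additional_library(lysplp_session, f2, base = FIXTURE_LIB,
                          table = PARAM_TABLE)
  expect_identical(readLines(f1), readLines(f2))
})
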