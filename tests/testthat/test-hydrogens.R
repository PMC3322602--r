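test_that("hydrogen counts follow valence minus bond orders", {
  # sp3 carbon with three heavy single bonds gains one H named from itself
  d <- monomer_description(
    "NEO", "neopentane core",
    atoms = data.frame(name = c("CA", "CB1", "CB2", "CB3"), element = "C",
                       stringsAsFactors = FALSE),
    bonds = data.frame(atom1 = "CA", atom2 = c("CB1", "CB2", "CB3"),
                       order = "single", target = NA_real_, sigma = NA_real_,
                       stringsAsFactors = FALSE))
  out <- adjust_hydrogens(d)
  ha <- out$desc$atoms$name[out$desc$atoms$element == "H" &
                              out$desc$atoms$name %in%
                                c(out$desc$bonds$atom1[out$desc$bonds$atom2 == "CA"],
                                  out$desc$bonds$atom2[out$desc$bonds$atom1 == "CA"])]
  expect_equal(ha, "HA")
  # each CB ends up with 3 hydrogens
  hb <- grep("^HB1", out$desc$atoms$name, value = TRUE)
  expect_length(hb, 3L)

  # nitrogen with two heavy single bonds keeps exactly one H
  d2 <- monomer_description(
    "AMD", "secondary amine",
    atoms = data.frame(name = c("N", "C1", "C2", "H1", "H2"),
                       element = c("N", "C", "C", "H", "H"),
                       stringsAsFactors = FALSE),
    bonds = data.frame(atom1 = c("N", "N", "N", "N"),
                       atom2 = c("C1", "C2", "H1", "H2"),
                       order = "single", target = NA_real_, sigma = NA_real_,
                       stringsAsFactors = FALSE))
  out2 <- adjust_hydrogens(d2)
  hn <- sum(out2$desc$atoms$element == "H" &
              out2$desc$atoms$name %in%
                c(out2$desc$bonds$atom1[out2$desc$bonds$atom2 == "N"],
                  out2$desc$bonds$atom2[out2$desc$bonds$atom1 == "N"]))
  expect_equal(hn, 1L)
  expect_true(any(vapply(out2$edits, function(e)
    e$kind == "delete_atom", logical(1))))

  # saturated ether oxygen: nothing to do, empty edit list
  eth <- make_ethanol()
  out3 <- adjust_hydrogens(eth)
  expect_length(out3$edits, 0L)
  expect_equal(out3$desc$atoms$name, eth$atoms$name)
})

test_that("adjust_hydrogens is idempotent and errors on over-valence", {
  for (seed in 1:6) {
    d <- random_molecule(seed, n_heavy = 7)
    once <- adjust_hydrogens(d)
    twice <- adjust_hydrogens(once$desc)
    expect_length(twice$edits, 0L)
    expect_equal(twice$desc$atoms, once$desc$atoms)
  }

  bad <- monomer_description(
    "BAD", "pentavalent carbon",
    atoms = data.frame(name = c("C0", paste0("C", 1:5)), element = "C",
                       stringsAsFactors = FALSE),
    bonds = data.frame(atom1 = "C0", atom2 = paste0("C", 1:5),
                       order = "single", target = NA_real_, sigma = NA_real_,
                       stringsAsFactors = FALSE))
  expect_error(adjust_hydrogens(bad), "C0")
})

test_that("formal charge shifts the hydrogen count", {
  lys <- FIXTURE_LIB$monomers$LYS
  nz_h <- grep("^HZ", lys$atoms$name, value = TRUE)
  expect_length(nz_h, 3L)   # NH3+ retains three hydrogens under +1 charge
  out <- adjust_hydrogens(lys)
  expect_length(out$edits, 0L)
})
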