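test_that("graph edits apply, journal, and reject bad payloads", {
  plp <- FIXTURE_LIB$monomers$PLP
  n0 <- nrow(plp$atoms)
  ed <- apply_edit(plp, graph_edit("delete_atom", name = "O4A"))
  expect_equal(nrow(ed$atoms), n0 - 1L)
  expect_false("O4A" %in% unlist(ed$bonds[c("atom1", "atom2")]))
  expect_false("O4A" %in% unlist(ed$angles[c("atom1", "atom2", "atom3")]))
  expect_false("O4A" %in% ed$planes$atom_id)
  expect_equal(ed$journal[[length(ed$journal)]]$kind, "delete_atom")

  gly <- FIXTURE_LIB$monomers$GLY
  ed2 <- apply_edit(gly, graph_edit("delete_atom", name = "OXT"))
  expect_true(any(vapply(ed2$journal, function(e)
    e$kind == "delete_atom" && e$name == "OXT", logical(1))))

  # add then delete is the identity on the graph
  d <- make_ethanol()
  d2 <- apply_edit(d, graph_edit("add_atom", name = "X", element = "C"))
  d2 <- apply_edit(d2, graph_edit("delete_atom", name = "X"))
  expect_equal(d2$atoms$name, d$atoms$name)
  expect_equal(d2$bonds, d$bonds)

  expect_error(apply_edit(d, graph_edit("delete_atom", name = "QQ")), "QQ")
  expect_error(apply_edit(d, graph_edit("add_atom", name = "C1", element = "C")),
               "duplicate")
  expect_error(apply_edit(d, graph_edit("add_bond", atom1 = "C1", atom2 = "C1")),
               "itself")
})

test_that("replaying the journal reproduces the edited monomer", {
  set.seed(11)
  for (trial in 1:8) {
    d0 <- random_molecule(seed = trial, n_heavy = sample(4:10, 1))
    d <- d0
    heavy <- d$atoms$name[d$atoms$element != "H"]
    for (k in 1:4) {
      kind <- sample(c("add_atom", "delete_atom", "change_atom"), 1)
      e <- switch(kind,
        add_atom = graph_edit("add_atom", name = paste0("X", k), element = "C"),
        delete_atom = graph_edit("delete_atom",
                                 name = sample(setdiff(d$atoms$name, heavy[1]), 1)),
        change_atom = graph_edit("change_atom", name = heavy[1],
                                 energy_type = paste0("T", k)))
      d <- tryCatch(apply_edit(d, e), error = function(err) d)
    }
    replay <- d0
    for (e in d$journal) replay <- apply_edit(replay, e)
    expect_equal(replay$atoms, d$atoms)
    expect_equal(replay$bonds, d$bonds)
  }
})

test_that("chiral volume follows the determinant and its permutation parity", {
  ctr <- c(0, 0, 0)
  expect_equal(chiral_volume(ctr, c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)), 1)
  expect_equal(chiral_volume(ctr, c(0, 1, 0), c(1, 0, 0), c(0, 0, 1)), -1)
  expect_equal(chiral_volume(ctr, c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)), 0)
  expect_equal(chirality_sign(0.05), "degenerate")
  expect_equal(chirality_sign(0.5), "positive")
  expect_equal(chirality_sign(-0.5), "negative")

  set.seed(7)
  for (i in 1:25) {
    pts <- matrix(rnorm(12), 4, 3)
    v <- chiral_volume(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    # even permutation preserves, odd flips
    expect_equal(chiral_volume(pts[1, ], pts[3, ], pts[4, ], pts[2, ]), v)
    expect_equal(chiral_volume(pts[1, ], pts[3, ], pts[2, ], pts[4, ]), -v)
  }
})

test_that("validate reports defects and passes clean fixtures", {
  for (code in names(FIXTURE_LIB$monomers))
    expect_equal(nrow(validate_monomer(FIXTURE_LIB$monomers[[code]])), 0L)

  d <- make_ethanol()
  d$bonds <- rbind(d$bonds, data.frame(atom1 = "C1", atom2 = "XX",
                                       order = "single", target = NA_real_,
                                       sigma = NA_real_))
  rep <- validate_monomer(d)
  expect_true(any(rep$class == "dangling_reference" & rep$id == "XX"))

  d2 <- make_ethanol()
  d2$atoms$name[2] <- "C1"
  rep2 <- validate_monomer(d2)
  expect_true(any(rep2$class == "duplicate_atom" & rep2$id == "C1"))
})
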