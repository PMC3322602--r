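test_that("energy typing is deterministic and tracks hybridization", {
  gly <- assign_energy_types(FIXTURE_LIB$monomers$GLY)
  ty <- function(d, a) d$atoms$energy_type[d$atoms$name == a]
  expect_equal(ty(gly, "C"), "C")       # carbonyl carbon
  expect_equal(ty(gly, "CA"), "CH2")
  expect_equal(ty(gly, "O"), "O")
  expect_equal(ty(gly, "OXT"), "OH1")

  # PLP C4A is a carbonyl carbon with the aldehyde oxygen, and becomes a
  # plain sp2 carbon once the oxygen is swapped for the imine nitrogen
  plp <- assign_energy_types(FIXTURE_LIB$monomers$PLP)
  expect_equal(ty(plp, "C4A"), "C")
  expect_equal(ty(plp, "N1"), "NR")
  expect_equal(ty(plp, "P"), "P")
  schiff <- apply_edit(plp, graph_edit("delete_atom", name = "O4A"))
  schiff <- apply_edit(schiff, graph_edit("add_atom", name = "NX", element = "N"))
  schiff <- apply_edit(schiff, graph_edit("add_bond", atom1 = "C4A",
                                          atom2 = "NX", order = "double"))
  schiff <- assign_energy_types(schiff)
  expect_equal(ty(schiff, "C4A"), "C2")

  expect_identical(assign_energy_types(plp)$atoms, plp$atoms)
})

test_that("angle enumeration equals brute force over bonded triples", {
  brute_count <- function(d) {
    nm <- d$atoms$name
    bonded <- function(x, y) length(linksmith:::bond_between(d, x, y)) > 0
    n <- 0L
    for (b in nm) for (a in nm) for (c in nm) {
      if (a < c && a != b && c != b && bonded(a, b) && bonded(c, b))
        n <- n + 1L
    }
    n
  }
  d <- complete_description(make_chain3(), PARAM_TABLE)
  expect_equal(nrow(d$angles), 1L)
  expect_equal(d$angles$atom2, "B")

  for (seed in 1:12) {
    m <- random_molecule(seed, n_heavy = 3L + seed %% 6L)
    cd <- complete_description(m, PARAM_TABLE)
    expect_equal(nrow(cd$angles), brute_count(m), info = paste("seed", seed))
    # closed form for trees: sum over atoms of deg*(deg-1)/2
    deg <- table(factor(c(m$bonds$atom1, m$bonds$atom2),
                        levels = m$atoms$name))
    expect_equal(nrow(cd$angles), sum(deg * (deg - 1) / 2))
  }
})

test_that("completion builds planes, chirals and targets with fallbacks", {
  gly <- FIXTURE_LIB$monomers$GLY
  expect_equal(gly$level, "complete")
  # carboxylate sp2 carbon and its three neighbours share a plane
  pl <- split(gly$planes$atom_id, gly$planes$plane_id)
  expect_true(any(vapply(pl, function(x)
    all(c("C", "CA", "O", "OXT") %in% x), logical(1))))
  expect_true(all(!is.na(gly$bonds$target)))
  expect_true(all(gly$bonds$sigma > 0))
  expect_true(all(!is.na(gly$angles$target)))

  ala <- FIXTURE_LIB$monomers$ALA
  expect_equal(ala$chirals$centre, "CA")
  expect_equal(ala$chirals$sign, "negative")

  # restraint set is independent of atom insertion order
  plp <- fixture_plp <- FIXTURE_LIB$monomers$PLP
  shuf <- plp
  set.seed(2)
  perm <- sample(nrow(shuf$atoms))
  shuf$atoms <- shuf$atoms[perm, ]
  shuf$level <- "minimal"
  redo <- complete_description(
    monomer_description(plp$code, plp$name, plp$group,
                        atoms = shuf$atoms, bonds = plp$bonds,
                        chirals = plp$chirals),
    PARAM_TABLE)
  expect_equal(redo$angles, plp$angles)
  expect_equal(redo$bonds, plp$bonds)
  expect_equal(redo$planes, plp$planes)
})

test_that("bond perception follows the covalent-radius rule", {
  two_c <- function(dist)
    data.frame(name = c("C1", "C2"), element = "C",
               x = c(0, dist), y = 0, z = 0, stringsAsFactors = FALSE)
  expect_equal(nrow(perceive_graph(two_c(1.53))$bonds), 1L)
  expect_equal(nrow(perceive_graph(two_c(3.0))$bonds), 0L)
  expect_error(perceive_graph(two_c(0.3)), "overlapping")

  # idealized fixture coordinates recover the bond set exactly
  for (code in c("GLY", "ALA", "GLC")) {
    m <- FIXTURE_LIB$monomers[[code]]
    xyz <- regularize(m, embed_coordinates(m, seed = 3))$coords
    at <- data.frame(name = rownames(xyz),
                     element = m$atoms$element[match(rownames(xyz), m$atoms$name)],
                     x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                     stringsAsFactors = FALSE)
    p <- perceive_graph(at, code = code)
    key <- function(d) sort(apply(d$bonds[, 1:2], 1,
                                  function(r) paste(sort(r), collapse = "-")))
    expect_equal(key(p), key(m), info = code)
  }
})

test_that("perceived orders and chirality come from the coordinates", {
  m <- FIXTURE_LIB$monomers$ALA
  xyz <- regularize(m, embed_coordinates(m, seed = 5))$coords
  at <- data.frame(name = rownames(xyz),
                   element = m$atoms$element[match(rownames(xyz), m$atoms$name)],
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   stringsAsFactors = FALSE)
  p <- perceive_graph(at, code = "ALA")
  # carbonyl C=O promoted to double (shortest eligible bond first)
  co <- p$bonds[p$bonds$atom1 %in% c("C", "O") & p$bonds$atom2 %in% c("C", "O"), ]
  expect_equal(co$order, "double")
  # CA handedness recovered with the declared sign under sorted neighbours
  ch <- linksmith:::canonical_chirals(p$chirals)
  expect_equal(ch$sign[ch$centre == "CA"],
               linksmith:::canonical_chirals(m$chirals)$sign)
})

test_that("as-is targets equal the observed geometry", {
  m <- FIXTURE_LIB$monomers$GLY
  xyz <- regularize(m, embed_coordinates(m, seed = 2))$coords
  tf <- targets_from_coordinates(m, xyz, PARAM_TABLE)
  res <- restraint_residuals(tf, xyz)
  expect_lt(max(abs(res$bonds$deviation)), 1e-9)
  expect_lt(max(abs(res$angles$deviation)), 1e-9)
  expect_equal(tf$bonds$sigma, rep(0.02, nrow(tf$bonds)))

  # collinear triple reads 180 degrees
  coords <- rbind(A = c(0, 0, 0), B = c(1.5, 0, 0), C = c(3.0, 0, 0))
  chain <- targets_from_coordinates(make_chain3(), coords, PARAM_TABLE)
  expect_equal(chain$angles$target, 180)

  expect_error(targets_from_coordinates(m, xyz[-1, , drop = FALSE]),
               rownames(xyz)[1])
})
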