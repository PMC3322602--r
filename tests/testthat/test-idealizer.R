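test_that("embedding is deterministic, seed-sensitive and clash-free", {
  single <- complete_description(monomer_description(
    "ONE", "atom", atoms = data.frame(name = "X", element = "C",
                                      stringsAsFactors = FALSE)), PARAM_TABLE)
  expect_equal(unname(embed_coordinates(single, 1)[1, ]), c(0, 0, 0))

  m <- FIXTURE_LIB$monomers$LYS
  a <- embed_coordinates(m, seed = 1)
  b <- embed_coordinates(m, seed = 1)
  c2 <- embed_coordinates(m, seed = 2)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a, c2)))
  expect_gt(min(dist(a)), 0.7)
  expect_gt(min(dist(c2)), 0.7)

  disco <- monomer_description(
    "DIS", "two parts",
    atoms = data.frame(name = c("A", "B"), element = "C",
                       stringsAsFactors = FALSE))
  disco$level <- "complete"
  expect_error(embed_coordinates(disco), "disconnected")
})

test_that("residual evaluation is pure and reports exact deviations", {
  m <- FIXTURE_LIB$monomers$GLY
  ideal <- regularize(m, embed_coordinates(m, seed = 4))$coords

  # stretch one bond by +0.1 and read it back
  shifted <- ideal
  b1 <- m$bonds[1, ]
  dir <- shifted[b1$atom2, ] - shifted[b1$atom1, ]
  dir <- dir / sqrt(sum(dir^2))
  moved <- b1$atom2
  # move the atom and everything beyond it? only the atom: other restraints
  # change too, but the stretched bond row must read exactly +0.1
  shifted[moved, ] <- shifted[moved, ] + 0.1 * dir
  res <- restraint_residuals(m, shifted)
  row <- res$bonds[res$bonds$atom1 == b1$atom1 & res$bonds$atom2 == b1$atom2, ]
  expect_equal(row$deviation,
               restraint_residuals(m, ideal)$bonds[1, "deviation"] + 0.1,
               tolerance = 1e-9)

  # maxima equal the max over rows for random perturbations
  set.seed(9)
  for (i in 1:5) {
    pert <- ideal + matrix(rnorm(length(ideal), 0, 0.05), nrow(ideal), 3)
    r <- restraint_residuals(m, pert)
    expect_equal(r$max$bond, max(abs(r$bonds$deviation)))
    expect_equal(r$max$angle, max(abs(r$angles$deviation)))
    expect_equal(r$max$plane, max(abs(r$planes$deviation)))
  }
  expect_error(restraint_residuals(m, ideal[-1, , drop = FALSE]),
               rownames(ideal)[1])
})

test_that("regularization is a fixed point on ideal coordinates", {
  m <- FIXTURE_LIB$monomers$ALA
  ideal <- regularize(m, embed_coordinates(m, seed = 1))$coords
  again <- regularize(m, ideal)
  expect_true(again$report$converged)
  expect_lt(max(abs(again$coords - ideal)), 1e-4)
})

test_that("the objective is invariant under rigid motions", {
  m <- FIXTURE_LIB$monomers$CYS
  ri <- linksmith:::restraint_index(m)
  xyz <- embed_coordinates(m, seed = 2)
  f0 <- linksmith:::objective_gradient(as.numeric(xyz), ri, grad = FALSE)$f
  set.seed(4)
  for (i in 1:5) {
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    moved <- xyz %*% q + matrix(rnorm(3), nrow(xyz), 3, byrow = TRUE)
    f1 <- linksmith:::objective_gradient(as.numeric(moved), ri, grad = FALSE)$f
    expect_equal(f1, f0, tolerance = 1e-8)
  }
})

test_that("analytic gradients match finite differences", {
  m <- FIXTURE_LIB$monomers$PLP
  ri <- linksmith:::restraint_index(m)
  set.seed(12)
  x <- as.numeric(embed_coordinates(m, seed = 3)) +
    rnorm(3 * nrow(m$atoms), 0, 0.08)
  g <- linksmith:::objective_gradient(x, ri)$g
  idx <- sample(seq_along(x), 20)
  for (i in idx) {
    h <- 1e-6
    xp <- x; xm <- x; xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
    fd <- (linksmith:::objective_gradient(xp, ri, grad = FALSE)$f -
             linksmith:::objective_gradient(xm, ri, grad = FALSE)$f) / (2 * h)
    expect_equal(g[i], fd, tolerance = 1e-4)
  }
})

test_that("a declared chirality is enforced from a wrong-handed start", {
  m <- FIXTURE_LIB$monomers$ALA
  ideal <- regularize(m, embed_coordinates(m, seed = 1))$coords
  ch <- m$chirals[1, ]
  vol <- function(X) chiral_volume(X[ch$centre, ], X[ch$atom1, ],
                                   X[ch$atom2, ], X[ch$atom3, ])
  mirrored <- ideal
  mirrored[, 1] <- -mirrored[, 1]
  expect_true(sign(vol(mirrored)) != sign(vol(ideal)))
  fixed <- regularize(m, mirrored)
  expect_true(fixed$report$max$chiral_ok)
  expect_equal(sign(vol(fixed$coords)), if (ch$sign == "positive") 1 else -1)
})

test_that("idealized coordinates serialize as HETATM records", {
  m <- FIXTURE_LIB$monomers$GLY
  xyz <- regularize(m, embed_coordinates(m, seed = 1))$coords
  f <- withr::local_tempfile(fileext = ".pdb")
  write_idealized_pdb(m, xyz, f)
  lines <- readLines(f)
  expect_equal(sum(startsWith(lines, "HETATM")), nrow(m$atoms))
  expect_true(all(grepl(" 1\\.00 20\\.00", lines[startsWith(lines, "HETATM")])))
  back <- read_pdb_atoms(f)
  expect_setequal(back$name, m$atoms$name)
  expect_lt(max(abs(as.matrix(back[match(rownames(xyz), back$name),
                                   c("x", "y", "z")]) - xyz)), 1e-3)
})
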