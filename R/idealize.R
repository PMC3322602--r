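# ---- coordinate embedding ---------------------------------------------------

#' Generate starting coordinates for a complete description
#'
#' Breadth-first placement: atoms are positioned one at a time from bond and
#' angle targets (NeRF-style internal-to-Cartesian construction) with
#' dihedral choices drawn from a seeded generator - near 0/180 degrees
#' across conjugated (sp2-sp2) bonds and near staggered positions
#' otherwise.  Ring-closure bonds are ignored during placement and pulled
#' in by the subsequent minimization.  Deterministic for a fixed seed.
#'
#' @param desc A complete, connected [monomer_description()].
#' @param seed Integer seed for the dihedral choices.
#' @return Numeric matrix (atoms x 3) with atom-name rownames; no two atoms
#'   closer than 0.7 angstrom (enforced by jittered retries).
#' @export
embed_coordinates <- function(desc, seed = 1L) {
  stopifnot(desc$level == "complete")
  nm <- desc$atoms$name
  if (nrow(desc$atoms) > 1L) {
    comp <- connected_components(nm, desc$bonds)
    if (length(unique(comp)) > 1L)
      stop("cannot embed '", desc$code, "': graph is disconnected")
  }
  rng <- local_rng(seed)
  env <- atom_environment(desc)
  xyz <- matrix(NA_real_, nrow = length(nm), ncol = 3L,
                dimnames = list(nm, c("x", "y", "z")))
  if (length(nm) == 1L) { xyz[1, ] <- 0; return(xyz) }

  bt <- function(a1, a2) {
    k <- bond_between(desc, a1, a2)
    t <- desc$bonds$target[k[1]]
    if (is.na(t)) 1.5 else t
  }
  at <- function(a1, a2, a3) {
    A <- desc$angles
    k <- which(A$atom2 == a2 & (A$atom1 == a1 & A$atom3 == a3 |
                                  A$atom1 == a3 & A$atom3 == a1))
    if (length(k)) A$target[k[1]] else 109.47
  }

  root <- nm[order(-env$degree, nm)][1]
  placed <- character(0)
  parent <- setNames(rep(NA_character_, length(nm)), nm)
  queue <- root
  order_out <- character(0)
  seen <- root
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    order_out <- c(order_out, cur)
    for (nb in sort(neighbours_of(desc, cur))) {
      if (!nb %in% seen) {
        seen <- c(seen, nb); parent[nb] <- cur; queue <- c(queue, nb)
      }
    }
  }

  for (a in order_out) {
    p <- parent[[a]]
    if (is.na(p)) { xyz[a, ] <- c(0, 0, 0); placed <- c(placed, a); next }
    if (is.na(parent[[p]])) {
      sibs <- placed[!is.na(parent[placed]) & parent[placed] == p]
      if (!length(sibs)) { xyz[a, ] <- xyz[p, ] + c(bt(a, p), 0, 0) }
      else {
        g <- sibs[1]
        xyz[a, ] <- place_nerf(xyz[p, ], xyz[g, ],
                               xyz[g, ] + c(0, 0, 1),
                               bt(a, p), at(a, p, g),
                               pick_dihedral(rng, env, p, g))
      }
      placed <- c(placed, a); next
    }
    g <- parent[[p]]
    gg <- if (!is.na(parent[[g]])) parent[[g]] else {
      alt <- setdiff(placed[!is.na(parent[placed]) & parent[placed] == g], p)
      if (length(alt)) alt[1] else NA_character_
    }
    ref <- if (!is.na(gg)) xyz[gg, ] else xyz[g, ] + c(0, 0, 1)
    xyz[a, ] <- place_nerf(xyz[p, ], xyz[g, ], ref, bt(a, p), at(a, p, g),
                           pick_dihedral(rng, env, p, g))
    # keep placements apart; jitter the dihedral on clashes
    tries <- 0L
    while (min_dist(xyz, placed, a) < 0.7 && tries < 24L) {
      xyz[a, ] <- place_nerf(xyz[p, ], xyz[g, ], ref, bt(a, p), at(a, p, g),
                             rng(1) * 360)
      tries <- tries + 1L
    }
    placed <- c(placed, a)
  }
  untangle(desc, xyz)
}

# Distance-geometry clean-up of the sequential placement: minimize bond
# targets, 1-3 distances implied by the angle targets, and a soft overlap
# repulsion between all other pairs.  This prevents rings from collapsing
# onto themselves and tetrahedral centres from flattening before the real
# restraint minimization takes over; the repulsion exists only here, not in
# the regularization objective.
untangle <- function(desc, xyz) {
  nm <- desc$atoms$name
  n <- length(nm)
  if (n < 3L) return(xyz)
  idx <- function(a) match(a, nm)
  bi <- idx(desc$bonds$atom1); bj <- idx(desc$bonds$atom2)
  bt <- ifelse(is.na(desc$bonds$target), 1.5, desc$bonds$target)
  blen <- function(i, j) {
    k <- which((bi == i & bj == j) | (bi == j & bj == i))
    if (length(k)) bt[k[1]] else 1.5
  }
  ti <- integer(0); tj <- integer(0); tt <- numeric(0)
  for (r in seq_len(nrow(desc$angles))) {
    i <- idx(desc$angles$atom1[r]); v <- idx(desc$angles$atom2[r])
    j <- idx(desc$angles$atom3[r])
    r1 <- blen(i, v); r2 <- blen(j, v)
    th <- desc$angles$target[r]
    if (is.na(th)) th <- 109.47
    ti <- c(ti, i); tj <- c(tj, j)
    tt <- c(tt, sqrt(r1^2 + r2^2 - 2 * r1 * r2 * cos(th * pi / 180)))
  }
  close_key <- c(paste(pmin(bi, bj), pmax(bi, bj)),
                 paste(pmin(ti, tj), pmax(ti, tj)))
  heavy <- desc$atoms$element != "H"
  ri <- integer(0); rj <- integer(0); rd <- numeric(0)
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    if (paste(i, j) %in% close_key) next
    ri <- c(ri, i); rj <- c(rj, j)
    rd <- c(rd, if (heavy[i] && heavy[j]) 2.2 else 1.7)
  }
  pr_i <- c(bi, ti); pr_j <- c(bj, tj); pr_t <- c(bt, tt)
  pr_w <- c(rep(100, length(bi)), rep(20, length(ti)))
  fg <- function(x, grad = TRUE) {
    X <- matrix(x, ncol = 3L)
    dv <- X[pr_i, , drop = FALSE] - X[pr_j, , drop = FALSE]
    d <- sqrt(rowSums(dv^2))
    f <- sum(pr_w * (d - pr_t)^2)
    rv <- X[ri, , drop = FALSE] - X[rj, , drop = FALSE]
    rdi <- sqrt(rowSums(rv^2))
    viol <- rdi < rd
    f <- f + 10 * sum((rd[viol] - rdi[viol])^2)
    if (!grad) return(list(f = f))
    G <- matrix(0, n, 3L)
    coef <- 2 * pr_w * (d - pr_t) / pmax(d, 1e-8)
    gi <- dv * coef
    G <- G + acc_rows(gi, pr_i, n) - acc_rows(gi, pr_j, n)
    if (any(viol)) {
      coef <- -20 * (rd[viol] - rdi[viol]) / pmax(rdi[viol], 1e-8)
      gi <- rv[viol, , drop = FALSE] * coef
      G <- G + acc_rows(gi, ri[viol], n) - acc_rows(gi, rj[viol], n)
    }
    list(f = f, g = as.numeric(G))
  }
  fit <- stats::optim(as.numeric(xyz), function(p) fg(p, FALSE)$f,
                      function(p) fg(p)$g, method = "BFGS",
                      control = list(maxit = 500L, reltol = 1e-12))
  matrix(fit$par, ncol = 3L, dimnames = dimnames(xyz))
}

min_dist <- function(xyz, placed, a) {
  others <- setdiff(placed, a)
  if (!length(others)) return(Inf)
  min(sqrt(rowSums((xyz[others, , drop = FALSE] -
                      matrix(xyz[a, ], length(others), 3, byrow = TRUE))^2)))
}

pick_dihedral <- function(rng, env, p, g) {
  sp2 <- env$hyb[match(p, env$name)] == "sp2" && env$hyb[match(g, env$name)] == "sp2"
  base <- if (sp2) c(0, 180) else c(60, 180, 300)
  base[1L + floor(rng(1) * length(base))] + (rng(1) - 0.5) * 10
}

# uniform(0,1) generator that neither disturbs nor depends on the caller's
# .Random.seed
local_rng <- function(seed) {
  rng_state <- NULL
  function(n) {
    glob <- globalenv()
    old <- if (exists(".Random.seed", envir = glob, inherits = FALSE))
      get(".Random.seed", envir = glob) else NULL
    if (is.null(rng_state)) set.seed(as.integer(seed))
    else assign(".Random.seed", rng_state, envir = glob)
    out <- stats::runif(n)
    rng_state <<- get(".Random.seed", envir = glob)
    if (is.null(old)) rm(".Random.seed", envir = glob)
    else assign(".Random.seed", old, envir = glob)
    out
  }
}

place_nerf <- function(p, g, ref, dist, angle, dihedral) {
  ang <- angle * pi / 180; tor <- dihedral * pi / 180
  bc <- p - g; bc <- bc / sqrt(sum(bc^2))
  ab <- g - ref
  n <- cross3(ab, bc)
  if (sum(n^2) < 1e-12) n <- cross3(c(1, 0, 0), bc)
  if (sum(n^2) < 1e-12) n <- cross3(c(0, 1, 0), bc)
  n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d2 <- c(-dist * cos(ang), dist * sin(ang) * cos(tor), dist * sin(ang) * sin(tor))
  p + d2[1] * bc + d2[2] * m + d2[3] * n
}

# ---- objective and gradient -------------------------------------------------

# Pre-index a description's restraints against a fixed atom order.
restraint_index <- function(desc) {
  nm <- desc$atoms$name
  idx <- function(a) match(a, nm)
  list(
    nm = nm,
    bonds = list(i = idx(desc$bonds$atom1), j = idx(desc$bonds$atom2),
                 t = desc$bonds$target, s = desc$bonds$sigma),
    angles = list(i = idx(desc$angles$atom1), j = idx(desc$angles$atom2),
                  k = idx(desc$angles$atom3), t = desc$angles$target,
                  s = desc$angles$sigma),
    torsions = list(i = idx(desc$torsions$atom1), j = idx(desc$torsions$atom2),
                    k = idx(desc$torsions$atom3), l = idx(desc$torsions$atom4),
                    t = desc$torsions$target, s = desc$torsions$sigma,
                    p = desc$torsions$period),
    chirals = list(c = idx(desc$chirals$centre), i = idx(desc$chirals$atom1),
                   j = idx(desc$chirals$atom2), k = idx(desc$chirals$atom3),
                   sign = desc$chirals$sign),
    planes = lapply(split(desc$planes, desc$planes$plane_id), function(pl)
      list(i = idx(pl$atom_id), w = 1 / pl$dist_esd^2)),
    floor = contact_floor_pairs(desc)
  )
}

# Anti-collapse floor: atom pairs at graph distance >= 3 must stay outside
# the covalent-radius sum plus a margin.  This is not a van der Waals term
# - it only activates far inside any physical conformation - but it keeps
# rotatable arms from folding through each other into geometries where
# bond perception from the idealized coordinates would invent bonds.
contact_floor_pairs <- function(desc, margin = 0.55) {
  nm <- desc$atoms$name
  n <- length(nm)
  if (n < 4L) return(list(i = integer(), j = integer(), d = numeric()))
  adj <- matrix(FALSE, n, n)
  bi <- match(desc$bonds$atom1, nm); bj <- match(desc$bonds$atom2, nm)
  adj[cbind(bi, bj)] <- TRUE; adj[cbind(bj, bi)] <- TRUE
  # graph distance < 3 <=> bonded or sharing a neighbour
  two <- adj %*% adj > 0
  near <- adj | two
  radii <- vapply(desc$atoms$element, covalent_radius, numeric(1))
  pairs <- which(upper.tri(near) & !near, arr.ind = TRUE)
  list(i = pairs[, 1], j = pairs[, 2],
       d = radii[pairs[, 1]] + radii[pairs[, 2]] + margin)
}

FLOOR_WEIGHT <- 20

CHIRAL_MARGIN <- 0.1   # angstrom^3 hinge margin
CHIRAL_WEIGHT <- 25

objective_gradient <- function(x, ri, grad = TRUE) {
  X <- matrix(x, ncol = 3L)
  G <- if (grad) matrix(0, nrow(X), 3L) else NULL
  f <- 0

  b <- ri$bonds
  if (length(b$i)) {
    dvec <- X[b$i, , drop = FALSE] - X[b$j, , drop = FALSE]
    d <- sqrt(rowSums(dvec^2))
    dev <- (d - b$t) / b$s
    f <- f + sum(dev^2)
    if (grad) {
      coef <- 2 * dev / (b$s * pmax(d, 1e-8))
      gi <- dvec * coef
      G <- G + acc_rows(gi, b$i, nrow(X)) - acc_rows(gi, b$j, nrow(X))
    }
  }

  a <- ri$angles
  if (length(a$i)) {
    U <- X[a$i, , drop = FALSE] - X[a$j, , drop = FALSE]
    V <- X[a$k, , drop = FALSE] - X[a$j, , drop = FALSE]
    lu <- sqrt(rowSums(U^2)); lv <- sqrt(rowSums(V^2))
    cosv <- pmax(-1, pmin(1, rowSums(U * V) / (lu * lv)))
    th <- acos(cosv) * 180 / pi
    dev <- (th - a$t) / a$s
    f <- f + sum(dev^2)
    if (grad) {
      sinv <- sqrt(pmax(1 - cosv^2, 1e-8))
      Uh <- U / lu; Vh <- V / lv
      da <- -(Vh - cosv * Uh) / (lu * sinv) * 180 / pi
      dc <- -(Uh - cosv * Vh) / (lv * sinv) * 180 / pi
      coef <- 2 * dev / a$s
      Ga <- da * coef; Gc <- dc * coef
      G <- G + acc_rows(Ga, a$i, nrow(X)) + acc_rows(Gc, a$k, nrow(X)) -
        acc_rows(Ga + Gc, a$j, nrow(X))
    }
  }

  tr <- ri$torsions
  if (length(tr$i)) {
    B1 <- X[tr$j, , drop = FALSE] - X[tr$i, , drop = FALSE]
    B2 <- X[tr$k, , drop = FALSE] - X[tr$j, , drop = FALSE]
    B3 <- X[tr$l, , drop = FALSE] - X[tr$k, , drop = FALSE]
    N1 <- crossm(B1, B2); N2 <- crossm(B2, B3)
    lb2 <- sqrt(rowSums(B2^2))
    n1sq <- rowSums(N1^2); n2sq <- rowSums(N2^2)
    okt <- n1sq > 1e-10 & n2sq > 1e-10
    M1 <- crossm(N1, B2 / lb2)
    th <- atan2(rowSums(M1 * N2), rowSums(N1 * N2)) * 180 / pi
    span <- 360 / pmax(1L, tr$p)
    delta <- th - tr$t
    delta <- delta - span * round(delta / span)
    dev <- ifelse(okt, delta / tr$s, 0)
    f <- f + sum(dev^2)
    if (grad) {
      da <- (lb2 / n1sq) * N1 * 180 / pi
      dd <- -(lb2 / n2sq) * N2 * 180 / pi
      c1 <- rowSums(B1 * B2) / lb2^2; c2 <- rowSums(B3 * B2) / lb2^2
      db <- -(1 + c1) * da + c2 * dd
      dc <- c1 * da - (1 + c2) * dd
      coef <- ifelse(okt, 2 * dev / tr$s, 0)
      G <- G + acc_rows(da * coef, tr$i, nrow(X)) +
        acc_rows(db * coef, tr$j, nrow(X)) +
        acc_rows(dc * coef, tr$k, nrow(X)) +
        acc_rows(dd * coef, tr$l, nrow(X))
    }
  }

  ch <- ri$chirals
  for (r in seq_along(ch$c)) {
    if (ch$sign[r] == "both") next
    cc <- ch$c[r]; i1 <- ch$i[r]; i2 <- ch$j[r]; i3 <- ch$k[r]
    v1 <- X[i1, ] - X[cc, ]; v2 <- X[i2, ] - X[cc, ]; v3 <- X[i3, ] - X[cc, ]
    V <- det(cbind(v1, v2, v3))
    s <- if (ch$sign[r] == "positive") 1 else -1
    h <- CHIRAL_MARGIN - s * V
    if (h > 0) {
      f <- f + CHIRAL_WEIGHT * h^2
      if (grad) {
        dV1 <- cross3(v2, v3); dV2 <- cross3(v3, v1); dV3 <- cross3(v1, v2)
        coef <- -2 * CHIRAL_WEIGHT * h * s
        G[i1, ] <- G[i1, ] + coef * dV1
        G[i2, ] <- G[i2, ] + coef * dV2
        G[i3, ] <- G[i3, ] + coef * dV3
        G[cc, ] <- G[cc, ] - coef * (dV1 + dV2 + dV3)
      }
    }
  }

  fl <- ri$floor
  if (length(fl$i)) {
    dvec <- X[fl$i, , drop = FALSE] - X[fl$j, , drop = FALSE]
    d <- sqrt(rowSums(dvec^2))
    viol <- d < fl$d
    if (any(viol)) {
      gap <- fl$d[viol] - d[viol]
      f <- f + FLOOR_WEIGHT * sum(gap^2)
      if (grad) {
        coef <- -2 * FLOOR_WEIGHT * gap / pmax(d[viol], 1e-8)
        gi <- dvec[viol, , drop = FALSE] * coef
        G <- G + acc_rows(gi, fl$i[viol], nrow(X)) -
          acc_rows(gi, fl$j[viol], nrow(X))
      }
    }
  }

  for (pl in ri$planes) {
    P <- X[pl$i, , drop = FALSE]
    w <- pl$w
    ctr <- colSums(P * w) / sum(w)
    Pc <- sweep(P, 2L, ctr)
    M <- t(Pc * w) %*% Pc
    ev <- eigen(M, symmetric = TRUE)
    nrm <- ev$vectors[, 3L]
    dists <- as.numeric(Pc %*% nrm)
    f <- f + sum(w * dists^2)
    if (grad) {
      # envelope: centre and normal are the weighted least-squares optimum,
      # so the partial through them vanishes
      gi <- 2 * w * dists
      G[pl$i, ] <- G[pl$i, ] + outer(gi, nrm)
    }
  }

  list(f = f, g = if (grad) as.numeric(G) else NULL)
}

# accumulate rows of an m x 3 matrix into an n x 3 matrix by atom index
acc_rows <- function(M, idx, n) {
  rs <- rowsum(M, idx)
  out <- matrix(0, n, 3L)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

# ---- regularization ---------------------------------------------------------

#' Idealize coordinates against a complete description
#'
#' Quasi-Newton (BFGS) minimization of the weighted restraint objective
#' sum over bonds, angles, torsions, planar groups and chiral-volume
#' hinges, with weights 1/sigma^2.  Chiral centres that end up with the
#' wrong handedness after a minimization round are reflected through the
#' plane of their neighbours and the minimization is repeated, which
#' resolves mirror-image traps without touching correctly signed centres.
#' Non-convergence is reported, not raised.
#'
#' @param desc Complete [monomer_description()].
#' @param coords Starting coordinates (atoms x 3 with rownames), e.g. from
#'   [embed_coordinates()].
#' @param max_iter Iteration cap handed to the minimizer per round.
#' @param max_rounds Reflection/polish rounds.
#' @param step_tol,grad_tol Convergence thresholds: max coordinate change
#'   between rounds (angstrom) and max absolute gradient component.
#' @return List with `coords` (idealized) and `report` (a residual report;
#'   see [restraint_residuals()]), the report extended with `iterations`,
#'   `objective` and `converged`.
#' @export
regularize <- function(desc, coords, max_iter = 2000L, max_rounds = 12L,
                       step_tol = 1e-4, grad_tol = 1e-6) {
  stopifnot(desc$level == "complete")
  coords <- coords[desc$atoms$name, , drop = FALSE]
  ri <- restraint_index(desc)
  x <- as.numeric(coords)
  total_it <- 0L
  converged <- FALSE
  best_x <- NULL
  best_score <- Inf
  rng <- local_rng(97L)
  og <- function(p) objective_gradient(p, ri, grad = FALSE)$f
  gr <- function(p) objective_gradient(p, ri, grad = TRUE)$g
  for (round in seq_len(max_rounds)) {
    fit <- stats::optim(x, og, gr, method = "BFGS",
                        control = list(maxit = max_iter, reltol = 1e-14))
    total_it <- total_it + fit$counts[["function"]]
    step <- max(abs(fit$par - x))
    x <- fit$par
    gmax <- max(abs(gr(x)))
    settled <- gmax < grad_tol || step < step_tol

    fixed <- fix_wrong_chirals(x, ri)
    if (!identical(fixed, x)) {        # wrong handedness: reflect and redo
      x <- fixed
      next
    }
    out <- matrix(x, ncol = 3L,
                  dimnames = list(desc$atoms$name, c("x", "y", "z")))
    rep0 <- restraint_residuals(desc, out)
    # entangled conformations show up as deep anti-collapse violations
    fl <- ri$floor
    clash <- character(0)
    if (length(fl$i)) {
      dfl <- sqrt(rowSums((out[fl$i, , drop = FALSE] -
                             out[fl$j, , drop = FALSE])^2))
      deep <- which(fl$d - dfl > 0.3)
      clash <- desc$atoms$name[unique(c(fl$i[deep], fl$j[deep]))]
    }
    # rank settled states: clash-free conformers first, then by residual
    score <- 1000 * length(clash) + 100 * rep0$max$bond + rep0$max$angle
    if (settled && score < best_score) { best_score <- score; best_x <- x }
    # strict residual bar first; accept a best-effort conformer only after
    # the restart budget is mostly spent
    angle_bar <- if (round <= max_rounds - 3L) 1 else 5
    if (rep0$max$bond <= 0.01 && rep0$max$angle <= angle_bar &&
          !length(clash) && settled) {
      converged <- TRUE
      break
    }
    if (round == max_rounds) break
    # escape flattened / entangled local minima: kick the atoms involved in
    # the residuals; if the basin survives kicking (a wedged conformation
    # needs a concerted move), restart from a fresh deterministic embedding
    bad <- unique(c(
      unlist(rep0$bonds[abs(rep0$bonds$deviation) > 0.02,
                        c("atom1", "atom2")]),
      unlist(rep0$angles[abs(rep0$angles$deviation) > 5,
                         c("atom1", "atom2", "atom3")]),
      clash))
    # a clean but unaccepted state is a strained conformer: only a fresh
    # fold can improve it, so restart; otherwise alternate kicks/restarts
    if (!length(bad) || round %% 3L == 0L) {
      fresh <- try(embed_coordinates(desc, seed = 7919L + 101L * round),
                   silent = TRUE)
      if (!inherits(fresh, "try-error")) {
        x <- as.numeric(fresh[desc$atoms$name, , drop = FALSE])
        next
      }
    }
    if (!length(bad)) next
    ki <- match(bad, desc$atoms$name)
    X <- matrix(x, ncol = 3L)
    X[ki, ] <- X[ki, ] + (matrix(rng(3 * length(ki)), ncol = 3L) - 0.5) * 1.6
    x <- as.numeric(X)
  }
  if (!converged && !is.null(best_x)) {
    converged <- TRUE          # settled, best-effort conformer
    x <- best_x
  }
  out <- matrix(x, ncol = 3L, dimnames = list(desc$atoms$name, c("x", "y", "z")))
  rep <- restraint_residuals(desc, out)
  rep$iterations <- total_it
  rep$objective <- objective_gradient(x, ri, grad = FALSE)$f
  rep$converged <- converged
  list(coords = out, report = rep)
}

# Reflect wrongly signed chiral centres through the plane of the three
# reference neighbours.  The centre's remaining substituents (typically its
# hydrogen) are carried through the mirror with it, otherwise the next
# minimization simply pulls the centre back.
fix_wrong_chirals <- function(x, ri) {
  X <- matrix(x, ncol = 3L)
  ch <- ri$chirals
  for (r in seq_along(ch$c)) {
    if (ch$sign[r] == "both") next
    cc <- ch$c[r]
    trip <- c(ch$i[r], ch$j[r], ch$k[r])
    v1 <- X[trip[1], ] - X[cc, ]; v2 <- X[trip[2], ] - X[cc, ]
    v3 <- X[trip[3], ] - X[cc, ]
    V <- det(cbind(v1, v2, v3))
    s <- if (ch$sign[r] == "positive") 1 else -1
    if (s * V < 0) {
      n <- cross3(X[trip[2], ] - X[trip[1], ], X[trip[3], ] - X[trip[1], ])
      if (sum(n^2) < 1e-10) next
      n <- n / sqrt(sum(n^2))
      nb <- c(ri$bonds$j[ri$bonds$i == cc], ri$bonds$i[ri$bonds$j == cc])
      movers <- c(cc, setdiff(nb, trip))
      for (m in movers) {
        d <- sum((X[m, ] - X[trip[1], ]) * n)
        X[m, ] <- X[m, ] - 2 * d * n
      }
    }
  }
  as.numeric(X)
}

#' Evaluate restraint residuals
#'
#' Pure evaluation of per-restraint deviations of a coordinate set against
#' a complete description; no coordinates are modified.
#'
#' @param desc Complete [monomer_description()].
#' @param coords Numeric matrix (atoms x 3, rownames = atom names).
#' @return List of class `residual_report`: data frames `bonds`, `angles`,
#'   `torsions`, `chirals` (per-restraint deviation and deviation/sigma),
#'   `planes` (per-atom distance to the best-fit plane), and `max` - the
#'   per-class maxima of the absolute deviations.
#' @export
restraint_residuals <- function(desc, coords) {
  missing <- setdiff(desc$atoms$name, rownames(coords))
  if (length(missing))
    stop("missing coordinates for atom(s): ", paste(missing, collapse = ", "))
  X <- coords[desc$atoms$name, , drop = FALSE]

  b <- desc$bonds
  b$observed <- vapply(seq_len(nrow(b)), function(k)
    sqrt(sum((X[b$atom1[k], ] - X[b$atom2[k], ])^2)), numeric(1))
  b$deviation <- b$observed - b$target
  b$dev_over_sigma <- b$deviation / b$sigma

  a <- desc$angles
  a$observed <- vapply(seq_len(nrow(a)), function(k)
    angle_deg(X[a$atom1[k], ], X[a$atom2[k], ], X[a$atom3[k], ]), numeric(1))
  a$deviation <- a$observed - a$target
  a$dev_over_sigma <- a$deviation / a$sigma

  tr <- desc$torsions
  tr$observed <- vapply(seq_len(nrow(tr)), function(k)
    dihedral_deg(X[tr$atom1[k], ], X[tr$atom2[k], ], X[tr$atom3[k], ],
                 X[tr$atom4[k], ]), numeric(1))
  tr$deviation <- vapply(seq_len(nrow(tr)), function(k) {
    span <- 360 / max(1L, tr$period[k])
    d <- tr$observed[k] - tr$target[k]
    d - span * round(d / span)
  }, numeric(1))
  tr$dev_over_sigma <- tr$deviation / tr$sigma

  ch <- desc$chirals
  ch$volume <- vapply(seq_len(nrow(ch)), function(k)
    chiral_volume(X[ch$centre[k], ], X[ch$atom1[k], ], X[ch$atom2[k], ],
                  X[ch$atom3[k], ]), numeric(1))
  ch$observed_sign <- vapply(ch$volume, chirality_sign, character(1))
  ch$ok <- ch$sign == "both" | ch$sign == ch$observed_sign

  pl_rows <- list()
  for (pid in unique(desc$planes$plane_id)) {
    pl <- desc$planes[desc$planes$plane_id == pid, ]
    P <- X[pl$atom_id, , drop = FALSE]
    w <- 1 / pl$dist_esd^2
    ctr <- colSums(P * w) / sum(w)
    Pc <- sweep(P, 2L, ctr)
    ev <- eigen(t(Pc * w) %*% Pc, symmetric = TRUE)
    dists <- as.numeric(Pc %*% ev$vectors[, 3L])
    pl_rows[[pid]] <- data.frame(plane_id = pid, atom_id = pl$atom_id,
                                 deviation = dists,
                                 dev_over_sigma = dists / pl$dist_esd,
                                 stringsAsFactors = FALSE)
  }
  planes <- if (length(pl_rows)) do.call(rbind, pl_rows) else
    data.frame(plane_id = character(), atom_id = character(),
               deviation = numeric(), dev_over_sigma = numeric())
  rownames(planes) <- NULL

  maxes <- list(
    bond = if (nrow(b)) max(abs(b$deviation)) else 0,
    angle = if (nrow(a)) max(abs(a$deviation)) else 0,
    torsion = if (nrow(tr)) max(abs(tr$deviation)) else 0,
    plane = if (nrow(planes)) max(abs(planes$deviation)) else 0,
    chiral_ok = if (nrow(ch)) all(ch$ok) else TRUE)

  structure(list(bonds = b, angles = a, torsions = tr, chirals = ch,
                 planes = planes, max = maxes),
            class = "residual_report")
}

#' @export
print.residual_report <- function(x, ...) {
  cat(sprintf("<residual report> max |bond dev| %.4f A, max |angle dev| %.3f deg, max |plane dev| %.4f A, chirals %s\n",
              x$max$bond, x$max$angle, x$max$plane,
              if (isTRUE(x$max$chiral_ok)) "ok" else "WRONG SIGN"))
  if (!is.null(x$converged))
    cat(sprintf("  objective %.6g after %d evaluations; converged: %s\n",
                x$objective, x$iterations, x$converged))
  invisible(x)
}

# ---- PDB output -------------------------------------------------------------

#' Write idealized coordinates as a PDB file
#'
#' Emits HETATM records (occupancy 1.00, B-factor 20.00, element columns
#' filled) for one residue, PDB v3.3 fixed columns.
#'
#' @param desc A [monomer_description()] (for names/elements and residue id).
#' @param coords Coordinates matrix with atom-name rownames.
#' @param path Output file.
#' @export
write_idealized_pdb <- function(desc, coords, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nm <- desc$atoms$name
  for (i in seq_along(nm)) {
    el <- toupper(desc$atoms$element[i])
    aname <- if (nchar(nm[i]) >= 4L) substr(nm[i], 1, 4) else paste0(" ", nm[i])
    aname <- formatC(aname, width = -4)
    writeLines(sprintf("HETATM%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                       i, aname, "", substr(desc$code, 1, 3), "A", 1L, "",
                       coords[nm[i], 1], coords[nm[i], 2], coords[nm[i], 3],
                       1.00, 20.00, el), con)
  }
  writeLines("END", con)
  invisible(path)
}
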