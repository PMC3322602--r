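# ---- restraint enumeration and completion -----------------------------------

#' Complete a minimal description
#'
#' Extends a minimal description to a complete one: assigns energy types
#' where missing, enumerates one angle restraint per bonded path of length
#' two, one torsion per rotatable (non-ring, non-terminal) bond, chiral
#' centres at tetravalent atoms with at least three heavy substituents, and
#' planar groups over every sp2 atom plus its bonded neighbours (groups
#' sharing two or more atoms are merged).  Every bond and angle receives a
#' target and sigma from the parameter table via its fallback chain; torsion
#' targets follow the hybridization of the central bond (180 deg, period 2
#' between sp2 atoms, period 3 otherwise).
#'
#' The restraint set is canonical: independent of atom insertion order.
#' Chiral signs already declared on the input are kept; newly detected
#' centres are declared "both" (no handedness imposed).
#'
#' @param desc A valid [monomer_description()].
#' @param table A [parameter_table()].
#' @return A complete description.  Attribute `fallbacks` lists every
#'   lookup that resolved below the typed level.
#' @export
complete_description <- function(desc, table = builtin_parameter_table()) {
  rep <- validate_monomer(desc)
  if (nrow(rep))
    stop("cannot complete '", desc$code, "': ", rep$message[1])
  desc <- assign_energy_types(desc, overwrite = FALSE)
  env <- atom_environment(desc)
  fallbacks <- character(0)
  typ <- function(a) desc$atoms$energy_type[match(a, desc$atoms$name)]
  ele <- function(a) desc$atoms$element[match(a, desc$atoms$name)]
  hyb <- function(a) env$hyb[match(a, env$name)]

  # bond targets
  b <- desc$bonds
  for (k in seq_len(nrow(b))) {
    lk <- lookup_bond(table, typ(b$atom1[k]), typ(b$atom2[k]),
                      ele(b$atom1[k]), ele(b$atom2[k]), b$order[k])
    b$target[k] <- lk$target; b$sigma[k] <- lk$sigma
    if (lk$level != "typed")
      fallbacks <- c(fallbacks, sprintf("bond %s-%s (%s)", b$atom1[k], b$atom2[k], lk$level))
  }
  desc$bonds <- b

  # angles: one per bonded path of length 2
  ang <- list()
  for (v in desc$atoms$name) {
    nb <- sort(neighbours_of(desc, v))
    if (length(nb) < 2L) next
    for (i in seq_len(length(nb) - 1L)) for (j in seq((i + 1L), length(nb))) {
      lk <- lookup_angle(table, typ(nb[i]), typ(v), typ(nb[j]), hyb(v))
      if (lk$level != "typed")
        fallbacks <- c(fallbacks, sprintf("angle %s-%s-%s (%s)", nb[i], v, nb[j], lk$level))
      ang[[length(ang) + 1L]] <- data.frame(
        atom1 = nb[i], atom2 = v, atom3 = nb[j],
        target = lk$target, sigma = lk$sigma, stringsAsFactors = FALSE)
    }
  }
  desc$angles <- if (length(ang)) do.call(rbind, ang) else empty_angles()

  # torsions: one per rotatable central bond
  ring_bond <- ring_bond_flags(desc)
  tor <- list()
  for (k in seq_len(nrow(desc$bonds))) {
    if (ring_bond[k]) next
    bt <- desc$bonds$atom1[k]; ct <- desc$bonds$atom2[k]
    ea <- torsion_end(desc, bt, ct)
    ed <- torsion_end(desc, ct, bt)
    if (is.na(ea) || is.na(ed)) next
    sp2sp2 <- hyb(bt) == "sp2" && hyb(ct) == "sp2"
    tor[[length(tor) + 1L]] <- data.frame(
      id = "", atom1 = ea, atom2 = bt, atom3 = ct, atom4 = ed,
      target = 180, sigma = table$defaults$torsion_sigma,
      period = if (sp2sp2) 2L else 3L, stringsAsFactors = FALSE)
  }
  desc$torsions <- if (length(tor)) do.call(rbind, tor) else empty_torsions()

  # chiral centres: tetravalent atoms with >= 3 distinct heavy substituents
  declared <- desc$chirals
  ch <- list()
  for (i in seq_len(nrow(env))) {
    if (env$degree[i] != 4L) next
    heavy <- Filter(function(a) ele(a) != "H", neighbours_of(desc, env$name[i]))
    if (length(heavy) < 3L) next
    j <- match(env$name[i], declared$centre)
    if (!is.na(j)) { ch[[length(ch) + 1L]] <- declared[j, ]; next }
    nb <- sort(heavy)[1:3]
    ch[[length(ch) + 1L]] <- data.frame(
      id = paste0("chir_", env$name[i]), centre = env$name[i],
      atom1 = nb[1], atom2 = nb[2], atom3 = nb[3], sign = "both",
      stringsAsFactors = FALSE)
  }
  desc$chirals <- if (length(ch)) do.call(rbind, ch) else empty_chirals()

  # planes: sp2 atoms with their neighbours, merged on >= 2 shared atoms
  desc$planes <- build_planes(desc, env, table$defaults$plane_esd)

  desc$level <- "complete"
  desc <- canonicalize_description(desc)
  # torsion ids after canonical sorting so they are insertion-order free
  if (nrow(desc$torsions))
    desc$torsions$id <- sprintf("tor_%d", seq_len(nrow(desc$torsions)))
  attr(desc, "fallbacks") <- fallbacks
  desc
}

ring_bond_flags <- function(desc) {
  nm <- desc$atoms$name
  vapply(seq_len(nrow(desc$bonds)), function(k) {
    rest <- desc$bonds[-k, , drop = FALSE]
    comp <- connected_components(nm, rest)
    comp[match(desc$bonds$atom1[k], nm)] == comp[match(desc$bonds$atom2[k], nm)]
  }, logical(1))
}

# Reference end atom for a torsion about bond b-c: the neighbour of b
# (excluding c) with the highest atomic priority, ties broken by name.
torsion_end <- function(desc, b, cexcl) {
  nb <- setdiff(neighbours_of(desc, b), cexcl)
  if (!length(nb)) return(NA_character_)
  el <- desc$atoms$element[match(nb, desc$atoms$name)]
  z <- vapply(el, function(e) match(toupper(e), names(COVALENT_RADII)), integer(1))
  zval <- c(1, 6, 7, 8, 15, 16, 34, 9, 17, 35, 53)[z]
  nb[order(-zval, nb)][1]
}

build_planes <- function(desc, env, esd) {
  groups <- list()
  for (i in which(env$hyb == "sp2" & env$element != "H")) {
    groups[[length(groups) + 1L]] <-
      c(env$name[i], neighbours_of(desc, env$name[i]))
  }
  if (!length(groups)) return(empty_planes())
  # merge groups sharing >= 2 atoms until stable
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (i in seq_along(groups)) {
      if (is.null(groups[[i]])) next
      for (j in seq_along(groups)) {
        if (j <= i || is.null(groups[[j]])) next
        if (length(intersect(groups[[i]], groups[[j]])) >= 2L) {
          groups[[i]] <- union(groups[[i]], groups[[j]])
          groups[j] <- list(NULL)
          changed <- TRUE
        }
      }
    }
  }
  groups <- Filter(function(g) !is.null(g) && length(g) >= 3L, groups)
  groups <- lapply(groups, sort)
  groups <- groups[order(vapply(groups, function(g) g[1], character(1)))]
  if (!length(groups)) return(empty_planes())
  do.call(rbind, lapply(seq_along(groups), function(i)
    data.frame(plane_id = sprintf("plan-%d", i), atom_id = groups[[i]],
               dist_esd = esd, stringsAsFactors = FALSE)))
}

# ---- graph perception from coordinates --------------------------------------

#' Perceive a molecular graph from coordinates
#'
#' Places a bond between atoms i and j whenever their distance does not
#' exceed the sum of covalent radii plus `tolerance`.  Bond orders are then
#' raised greedily (shortest bond first) while both endpoints have free
#' valence; a nitrogen whose perceived bonds exceed its neutral valence is
#' assigned a +1 formal charge.  Chiralities are read from the coordinates
#' via [chiral_volume()].
#'
#' @param atoms Data frame with columns `name`, `element`, `x`, `y`, `z`
#'   (angstrom), e.g. from [read_pdb_atoms()].
#' @param code,group Passed to the resulting description.
#' @param tolerance Distance slack over the covalent-radius sum.
#' @return A minimal [monomer_description()].
#' @export
perceive_graph <- function(atoms, code = "UNL", group = "non-polymer",
                           tolerance = 0.45) {
  stopifnot(nrow(atoms) >= 1L,
            all(c("name", "element", "x", "y", "z") %in% names(atoms)))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(atoms)
  d <- as.matrix(stats::dist(xyz))
  if (n > 1L && any(d[upper.tri(d)] < 0.5))
    stop("overlapping atoms: interatomic distance below 0.5 angstrom")
  radii <- vapply(atoms$element, covalent_radius, numeric(1))
  bonds <- empty_bonds()
  for (i in seq_len(max(0L, n - 1L))) for (j in seq((i + 1L), n)) {
    if (d[i, j] <= radii[i] + radii[j] + tolerance)
      bonds <- rbind(bonds, data.frame(atom1 = atoms$name[i], atom2 = atoms$name[j],
                                       order = "single", target = NA_real_,
                                       sigma = NA_real_, stringsAsFactors = FALSE))
  }
  desc <- monomer_description(code = code, group = group, atoms = data.frame(
    name = atoms$name, element = atoms$element, stringsAsFactors = FALSE),
    bonds = bonds)
  desc <- infer_charges(desc)
  desc <- promote_orders(desc, d)
  desc <- perceive_chirals(desc, xyz)
  desc
}

infer_charges <- function(desc) {
  for (i in seq_len(nrow(desc$atoms))) {
    el <- toupper(desc$atoms$element[i])
    if (!el %in% c("N", "P")) next
    a <- desc$atoms$name[i]
    tot <- sum(order_value(desc$bonds$order[desc$bonds$atom1 == a | desc$bonds$atom2 == a]))
    base <- VALENCE[[el]]
    if (tot > base) desc$atoms$charge[i] <- as.integer(min(tot - base, 1L))
  }
  desc
}

promote_orders <- function(desc, d) {
  free <- function() {
    vapply(seq_len(nrow(desc$atoms)), function(i) {
      a <- desc$atoms$name[i]
      cap <- effective_valence(desc$atoms$element[i], desc$atoms$charge[i])
      cap - sum(order_value(desc$bonds$order[desc$bonds$atom1 == a | desc$bonds$atom2 == a]))
    }, numeric(1))
  }
  repeat {
    f <- free()
    names(f) <- desc$atoms$name
    cand <- which(desc$bonds$order %in% c("single", "double") &
                    f[desc$bonds$atom1] >= 1 & f[desc$bonds$atom2] >= 1)
    cand <- cand[desc$atoms$element[match(desc$bonds$atom1[cand], desc$atoms$name)] != "H" &
                   desc$atoms$element[match(desc$bonds$atom2[cand], desc$atoms$name)] != "H"]
    if (!length(cand)) break
    lens <- d[cbind(match(desc$bonds$atom1[cand], desc$atoms$name),
                    match(desc$bonds$atom2[cand], desc$atoms$name))]
    k <- cand[which.min(lens)]
    desc$bonds$order[k] <- if (desc$bonds$order[k] == "single") "double" else "triple"
  }
  desc
}

perceive_chirals <- function(desc, xyz) {
  rownames(xyz) <- desc$atoms$name
  env <- atom_environment(desc)
  ch <- list()
  for (i in which(env$degree == 4L)) {
    a <- env$name[i]
    heavy <- Filter(function(x) desc$atoms$element[match(x, desc$atoms$name)] != "H",
                    neighbours_of(desc, a))
    if (length(heavy) < 3L) next
    nb <- sort(heavy)[1:3]
    v <- chiral_volume(xyz[a, ], xyz[nb[1], ], xyz[nb[2], ], xyz[nb[3], ])
    sgn <- chirality_sign(v)
    if (sgn == "degenerate") sgn <- "both"
    ch[[length(ch) + 1L]] <- data.frame(
      id = paste0("chir_", a), centre = a, atom1 = nb[1], atom2 = nb[2],
      atom3 = nb[3], sign = sgn, stringsAsFactors = FALSE)
  }
  desc$chirals <- if (length(ch)) do.call(rbind, ch) else empty_chirals()
  desc
}

# ---- targets from coordinates ----------------------------------------------

#' Derive restraint targets directly from coordinates
#'
#' The "as-is" completion mode: the molecular graph is left untouched and
#' the observed geometry is adopted as the restraint targets - bond targets
#' become the observed distances and angle targets the observed angles,
#' with sigmas from the table defaults.  Intended for high-precision input
#' coordinates (small-molecule crystallography, force-field minimised
#' models); with imprecise coordinates it produces modifications with many
#' spurious edits, which is why it is not the default route.
#'
#' @param desc A [monomer_description()]; restraints are enumerated first if
#'   absent.
#' @param coords Numeric matrix (atoms x 3) with rownames covering every
#'   atom of `desc`.
#' @param table A [parameter_table()] (sigma defaults only).
#' @return A complete description with observed targets.
#' @export
targets_from_coordinates <- function(desc, coords,
                                     table = builtin_parameter_table()) {
  missing <- setdiff(desc$atoms$name, rownames(coords))
  if (length(missing))
    stop("missing coordinates for atom(s): ", paste(missing, collapse = ", "))
  if (desc$level != "complete") desc <- complete_description(desc, table)
  b <- desc$bonds
  for (k in seq_len(nrow(b))) {
    b$target[k] <- sqrt(sum((coords[b$atom1[k], ] - coords[b$atom2[k], ])^2))
    b$sigma[k] <- table$defaults$bond_sigma
  }
  desc$bonds <- b
  a <- desc$angles
  for (k in seq_len(nrow(a))) {
    a$target[k] <- angle_deg(coords[a$atom1[k], ], coords[a$atom2[k], ],
                             coords[a$atom3[k], ])
    a$sigma[k] <- table$defaults$angle_sigma
  }
  desc$angles <- a
  tr <- desc$torsions
  for (k in seq_len(nrow(tr))) {
    tr$target[k] <- dihedral_deg(coords[tr$atom1[k], ], coords[tr$atom2[k], ],
                                 coords[tr$atom3[k], ], coords[tr$atom4[k], ])
    tr$period[k] <- 1L
  }
  desc$torsions <- tr
  for (k in seq_len(nrow(desc$chirals))) {
    v <- chiral_volume(coords[desc$chirals$centre[k], ],
                       coords[desc$chirals$atom1[k], ],
                       coords[desc$chirals$atom2[k], ],
                       coords[desc$chirals$atom3[k], ])
    sgn <- chirality_sign(v)
    if (sgn != "degenerate") desc$chirals$sign[k] <- sgn
  }
  desc
}

angle_deg <- function(a, b, c) {
  u <- a - b; v <- c - b
  cosv <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(max(-1, min(1, cosv))) * 180 / pi
}

dihedral_deg <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# row-wise cross product of two n x 3 matrices
crossm <- function(A, B) {
  cbind(A[, 2] * B[, 3] - A[, 3] * B[, 2],
        A[, 3] * B[, 1] - A[, 1] * B[, 3],
        A[, 1] * B[, 2] - A[, 2] * B[, 1])
}

# ---- PDB coordinate input ---------------------------------------------------

#' Read atoms from a PDB coordinate file
#'
#' Thin wrapper over [bio3d::read.pdb()] returning the columns the graph
#' perception needs.  The element is taken from the element columns of the
#' record, falling back to the leading letter of the atom name.
#'
#' @param path PDB file with ATOM/HETATM records.
#' @return Data frame with columns `name`, `element`, `x`, `y`, `z`.
#' @export
read_pdb_atoms <- function(path) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  elem <- at$elesy
  fix <- is.na(elem) | !nzchar(trimws(elem))
  elem[fix] <- substr(gsub("[^A-Za-z].*$", "", at$elety[fix]), 1L, 1L)
  data.frame(name = trimws(at$elety), element = normalize_element(trimws(elem)),
             x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
}

normalize_element <- function(el) {
  el <- toupper(el)
  paste0(substr(el, 1, 1), tolower(substring(el, 2)))
}
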