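# ---- composite sessions: compose, rename, regularize, split -----------------

# Deterministic unique naming for the union of two monomers' atom sets:
# names unique to one side are kept; colliding names get a side suffix
# ("1"/"2"), truncated to fit four characters and bumped numerically on
# residual collisions.
canonical_composite_names <- function(namesA, namesB) {
  clash <- intersect(namesA, namesB)
  taken <- union(namesA, namesB)
  assign_side <- function(names, digit) {
    out <- stats::setNames(names, names)
    for (nm in names) {
      if (!nm %in% clash) next
      base <- nm
      cand <- paste0(base, digit)
      while (nchar(cand) > 4L && nzchar(base)) {
        base <- substr(base, 1L, nchar(base) - 1L)
        cand <- paste0(base, digit)
      }
      k <- 0L
      while (cand %in% taken) {
        k <- k + 1L
        cand <- paste0(substr(base, 1L, 4L - nchar(digit) - nchar(as.character(k))),
                       digit, k)
      }
      taken <<- c(taken, cand)
      out[nm] <- cand
    }
    out
  }
  list(side1 = assign_side(namesA, "1"), side2 = assign_side(namesB, "2"))
}

#' Compose two monomers with a covalent link bond
#'
#' Starts a composite session from deep copies of two (possibly pre-edited)
#' monomers joined by one inter-monomer bond.  The two may be copies of the
#' same compound (disulfide-style links).  `parentA`/`parentB` name the
#' pristine library descriptions the eventual modification entries are
#' diffed against; they default to the monomers as given.  After
#' composition the monomer interiors are treated as fixed - the only
#' editable property is the link-bond order, via [set_link_bond_order()].
#'
#' @param monA,monB [monomer_description()]s (minimal or complete).
#' @param bond List or vector `(atomA, atomB, order)`; order defaults to
#'   "single".
#' @param parentA,parentB Pristine parents for diffing.
#' @return An object of class `composite_session`.
#' @export
compose_session <- function(monA, monB, bond, parentA = monA, parentB = monB) {
  stopifnot(inherits(monA, "monomer_description"),
            inherits(monB, "monomer_description"))
  bond <- as.list(bond)
  if (length(bond) < 3L) bond[[3]] <- "single"
  names(bond) <- c("atomA", "atomB", "order")[seq_along(bond)]
  if (!bond$atomA %in% monA$atoms$name)
    stop("link bond endpoint '", bond$atomA, "' not found in ", monA$code)
  if (!bond$atomB %in% monB$atoms$name)
    stop("link bond endpoint '", bond$atomB, "' not found in ", monB$code)
  if (!bond$order %in% BOND_ORDERS)
    stop("unknown link bond order '", bond$order, "'")
  structure(list(monA = monA, monB = monB,
                 parentA = parentA, parentB = parentB,
                 bond = bond, map = NULL, composite = NULL, side = NULL,
                 coords = NULL, report = NULL, regularized = FALSE),
            class = "composite_session")
}

#' @export
print.composite_session <- function(x, ...) {
  cat(sprintf("<composite session> %s(%s) %s %s(%s), %s bond%s\n",
              x$monA$code, x$bond$atomA,
              if (x$regularized) "=" else "~", x$monB$code, x$bond$atomB,
              x$bond$order, if (x$regularized) " (regularized)" else ""))
  invisible(x)
}

#' Change the order of the link bond of a session
#'
#' The one edit allowed after composition.  Clears any regularization
#' result, which must be recomputed.
#'
#' @param session A `composite_session`.
#' @param order New bond order.
#' @return The updated session.
#' @export
set_link_bond_order <- function(session, order) {
  if (!order %in% BOND_ORDERS) stop("unknown bond order '", order, "'")
  session$bond$order <- order
  session$composite <- session$coords <- session$report <- session$map <- NULL
  session$regularized <- FALSE
  session
}

#' Assign unique atom names across a composite
#'
#' Gives every atom of the two-monomer composite a unique working name and
#' records the bijective map back to the original per-side names.  The map
#' is extended later for hydrogens added automatically during
#' regularization (named from the original name of the heavy atom they bind
#' to).
#'
#' @param session A `composite_session`.
#' @return The session with `$map`: a data frame (side, orig, unique,
#'   added).
#' @export
make_unique_names <- function(session) {
  nmA <- session$monA$atoms$name
  nmB <- session$monB$atoms$name
  cn <- canonical_composite_names(nmA, nmB)
  session$map <- rbind(
    data.frame(side = 1L, orig = nmA, unique = unname(cn$side1[nmA]),
               added = FALSE, stringsAsFactors = FALSE),
    data.frame(side = 2L, orig = nmB, unique = unname(cn$side2[nmB]),
               added = FALSE, stringsAsFactors = FALSE))
  session
}

rename_frame <- function(df, cols, map) {
  for (col in cols) df[[col]] <- unname(map[df[[col]]])
  df
}

# Merge the two (renamed) monomer graphs and the link bond into one minimal
# description.  Energy types are wiped: the composite is retyped from
# scratch so that hybridization changes at the junction propagate.
build_composite_graph <- function(session) {
  mapA <- stats::setNames(session$map$unique[session$map$side == 1L],
                          session$map$orig[session$map$side == 1L])
  mapB <- stats::setNames(session$map$unique[session$map$side == 2L],
                          session$map$orig[session$map$side == 2L])
  ren <- function(m, mp) {
    at <- m$atoms
    at$parent_ref <- at$name           # orig-space name survives renaming
    at$name <- unname(mp[at$name])
    at$energy_type <- NA_character_
    list(atoms = at,
         bonds = rename_frame(m$bonds, c("atom1", "atom2"), mp),
         chirals = rename_frame(m$chirals, c("centre", "atom1", "atom2", "atom3"), mp))
  }
  A <- ren(session$monA, mapA); B <- ren(session$monB, mapB)
  bonds <- rbind(A$bonds, B$bonds)
  bonds$target <- NA_real_; bonds$sigma <- NA_real_
  link_row <- data.frame(atom1 = unname(mapA[session$bond$atomA]),
                         atom2 = unname(mapB[session$bond$atomB]),
                         order = session$bond$order, target = NA_real_,
                         sigma = NA_real_, stringsAsFactors = FALSE)
  desc <- monomer_description(
    code = paste0(session$monA$code, "-", session$monB$code),
    name = "composite", group = "non-polymer", level = "minimal",
    atoms = rbind(A$atoms, B$atoms), bonds = rbind(bonds, link_row),
    chirals = rbind(A$chirals, B$chirals))
  side <- stats::setNames(session$map$side, session$map$unique)
  list(desc = desc, side = side)
}

#' Regularize a composite session
#'
#' The full junction pipeline: unique names are assigned, the two graphs
#' are merged with the link bond, hydrogens are re-adjusted across the new
#' bond (the automatic edits become part of the eventual modifications),
#' the composite is retyped and completed against the parameter table, and
#' coordinates are embedded and idealized.  A valence violation at the link
#' bond - typically a doubly bonded substituent that should have been
#' deleted first - is reported as an error naming the offending atom.
#'
#' @param session A `composite_session`.
#' @param table A [parameter_table()].
#' @param seed Seed for the coordinate embedding.
#' @return The session with `$composite` (complete description in unique
#'   names), `$coords`, `$report`, `$map` (including automatic hydrogens)
#'   and `$regularized = TRUE`.
#' @export
regularize_session <- function(session, table = builtin_parameter_table(),
                               seed = 1L) {
  if (is.null(session$map)) session <- make_unique_names(session)
  bg <- build_composite_graph(session)
  desc <- bg$desc; side <- bg$side

  adj <- tryCatch(adjust_hydrogens(desc), error = function(e) e)
  if (inherits(adj, "error"))
    stop(conditionMessage(adj),
         "; delete the offending substituent (e.g. a doubly bonded atom on ",
         "the link atom) before regularizing the composite")
  desc <- adj$desc

  # book-keep the automatic hydrogen edits into the name map
  for (e in adj$edits) {
    if (e$kind == "delete_atom") {
      session$map <- session$map[session$map$unique != e$name, , drop = FALSE]
      side <- side[names(side) != e$name]
    } else if (e$kind == "add_bond") {
      h <- if (e$atom1 %in% desc$atoms$name &&
                 is_hydrogen(desc, e$atom1)) e$atom1 else e$atom2
      heavy <- setdiff(c(e$atom1, e$atom2), h)
      s <- side[[heavy]]
      heavy_orig <- session$map$orig[session$map$unique == heavy]
      taken <- session$map$orig[session$map$side == s]
      orig_h <- hydrogen_names_for(heavy_orig,
                                   desc$atoms$element[match(heavy, desc$atoms$name)],
                                   1L, taken)
      session$map <- rbind(session$map, data.frame(
        side = s, orig = orig_h, unique = h, added = TRUE,
        stringsAsFactors = FALSE))
      side[h] <- s
    }
  }

  desc <- complete_description(desc, table)
  coords <- embed_coordinates(desc, seed = seed)
  reg <- regularize(desc, coords)

  session$composite <- desc
  session$side <- side
  session$coords <- reg$coords
  session$report <- reg$report
  session$h_edits <- adj$edits
  session$regularized <- TRUE
  session
}

# ---- splitting --------------------------------------------------------------

sides_of <- function(session, atoms) unname(session$side[atoms])

orig_of <- function(session, atoms) {
  m <- match(atoms, session$map$unique)
  session$map$orig[m]
}

# Side-internal part of the regularized composite, translated back to the
# original per-side atom names.
side_subdescription <- function(session, s) {
  comp <- session$composite
  keep <- names(session$side)[session$side == s]
  mp <- stats::setNames(orig_of(session, keep), keep)
  at <- comp$atoms[comp$atoms$name %in% keep, , drop = FALSE]
  added <- session$map$added[match(at$name, session$map$unique)]
  at$name <- unname(mp[at$name])
  at$parent_ref <- ifelse(added, NA_character_, at$name)
  all_in <- function(...) {
    cols <- list(...)
    Reduce(`&`, lapply(cols, function(x) x %in% keep))
  }
  b <- comp$bonds[all_in(comp$bonds$atom1, comp$bonds$atom2), , drop = FALSE]
  a <- comp$angles[all_in(comp$angles$atom1, comp$angles$atom2, comp$angles$atom3), , drop = FALSE]
  tr <- comp$torsions[all_in(comp$torsions$atom1, comp$torsions$atom2,
                             comp$torsions$atom3, comp$torsions$atom4), , drop = FALSE]
  ch <- comp$chirals[all_in(comp$chirals$centre, comp$chirals$atom1,
                            comp$chirals$atom2, comp$chirals$atom3), , drop = FALSE]
  pl_keep <- !vapply(split(comp$planes$atom_id, comp$planes$plane_id),
                     function(x) any(!x %in% keep), logical(1))
  pl <- comp$planes[comp$planes$plane_id %in%
                      names(pl_keep)[pl_keep], , drop = FALSE]
  parent <- if (s == 1L) session$parentA else session$parentB
  monomer_description(
    code = parent$code, name = parent$name, group = parent$group,
    level = "complete", atoms = at,
    bonds = rename_frame(b, c("atom1", "atom2"), mp),
    angles = rename_frame(a, c("atom1", "atom2", "atom3"), mp),
    torsions = rename_frame(tr, c("atom1", "atom2", "atom3", "atom4"), mp),
    chirals = rename_frame(ch, c("centre", "atom1", "atom2", "atom3"), mp),
    planes = rename_frame(pl, "atom_id", mp))
}

bond_key <- function(a1, a2) paste(pmin(a1, a2), pmax(a1, a2))
angle_key <- function(a1, a2, a3) paste(a2, pmin(a1, a3), pmax(a1, a3))
torsion_key <- function(a1, a2, a3, a4)
  pmin(paste(a1, a2, a3, a4), paste(a4, a3, a2, a1))

# Diff a side-internal composite description against the completed pristine
# parent, producing a modification entry.  `sigma_multiplier` scales the
# change-detection threshold: a surviving restraint is recorded as changed
# when its type changed or its target moved by more than
# sigma_multiplier * declared sigma (0 makes the split lossless).
diff_modification <- function(ref, sub, id, sigma_multiplier = 1) {
  thr <- function(delta, sigma) abs(delta) > sigma_multiplier * sigma + 1e-9

  atoms <- empty_mod_atoms()
  deleted <- setdiff(ref$atoms$name, sub$atoms$name)
  for (d in deleted)
    atoms <- rbind(atoms, data.frame(fun = "delete", atom_id = d,
                                     new_atom_id = NA, new_type_symbol = NA,
                                     new_type_energy = NA, new_charge = NA,
                                     stringsAsFactors = FALSE))
  added_at <- sub$atoms[is.na(sub$atoms$parent_ref), , drop = FALSE]
  for (i in seq_len(nrow(added_at)))
    atoms <- rbind(atoms, data.frame(fun = "add", atom_id = added_at$name[i],
                                     new_atom_id = NA,
                                     new_type_symbol = added_at$element[i],
                                     new_type_energy = added_at$energy_type[i],
                                     new_charge = added_at$charge[i],
                                     stringsAsFactors = FALSE))
  common <- intersect(ref$atoms$name, sub$atoms$name)
  for (nm in common) {
    i <- match(nm, ref$atoms$name); j <- match(nm, sub$atoms$name)
    type_chg <- !identical(ref$atoms$energy_type[i], sub$atoms$energy_type[j])
    chg_chg <- ref$atoms$charge[i] != sub$atoms$charge[j]
    if (type_chg || chg_chg)
      atoms <- rbind(atoms, data.frame(fun = "change", atom_id = nm,
                                       new_atom_id = NA,
                                       new_type_symbol = sub$atoms$element[j],
                                       new_type_energy = sub$atoms$energy_type[j],
                                       new_charge = sub$atoms$charge[j],
                                       stringsAsFactors = FALSE))
  }

  bonds <- empty_mod_bonds()
  rb <- ref$bonds; sb <- sub$bonds
  rk <- bond_key(rb$atom1, rb$atom2); sk <- bond_key(sb$atom1, sb$atom2)
  for (i in which(!rk %in% sk)) {
    if (rb$atom1[i] %in% deleted || rb$atom2[i] %in% deleted) next  # implied
    bonds <- rbind(bonds, data.frame(fun = "delete", atom1 = rb$atom1[i],
                                     atom2 = rb$atom2[i], new_order = NA,
                                     new_target = NA, new_sigma = NA,
                                     stringsAsFactors = FALSE))
  }
  for (i in which(!sk %in% rk))
    bonds <- rbind(bonds, data.frame(fun = "add", atom1 = sb$atom1[i],
                                     atom2 = sb$atom2[i],
                                     new_order = sb$order[i],
                                     new_target = sb$target[i],
                                     new_sigma = sb$sigma[i],
                                     stringsAsFactors = FALSE))
  for (i in which(sk %in% rk)) {
    j <- match(sk[i], rk)
    if (rb$order[j] != sb$order[i] ||
          thr(sb$target[i] - rb$target[j], rb$sigma[j]))
      bonds <- rbind(bonds, data.frame(fun = "change", atom1 = sb$atom1[i],
                                       atom2 = sb$atom2[i],
                                       new_order = sb$order[i],
                                       new_target = sb$target[i],
                                       new_sigma = sb$sigma[i],
                                       stringsAsFactors = FALSE))
  }

  angles <- empty_mod_angles()
  ra <- ref$angles; sa <- sub$angles
  rk <- angle_key(ra$atom1, ra$atom2, ra$atom3)
  sk <- angle_key(sa$atom1, sa$atom2, sa$atom3)
  for (i in which(!rk %in% sk)) {
    if (any(c(ra$atom1[i], ra$atom2[i], ra$atom3[i]) %in% deleted)) next
    angles <- rbind(angles, data.frame(fun = "delete", atom1 = ra$atom1[i],
                                       atom2 = ra$atom2[i], atom3 = ra$atom3[i],
                                       new_target = NA, new_sigma = NA,
                                       stringsAsFactors = FALSE))
  }
  for (i in which(!sk %in% rk))
    angles <- rbind(angles, data.frame(fun = "add", atom1 = sa$atom1[i],
                                       atom2 = sa$atom2[i], atom3 = sa$atom3[i],
                                       new_target = sa$target[i],
                                       new_sigma = sa$sigma[i],
                                       stringsAsFactors = FALSE))
  for (i in which(sk %in% rk)) {
    j <- match(sk[i], rk)
    if (thr(sa$target[i] - ra$target[j], ra$sigma[j]))
      angles <- rbind(angles, data.frame(fun = "change", atom1 = sa$atom1[i],
                                         atom2 = sa$atom2[i], atom3 = sa$atom3[i],
                                         new_target = sa$target[i],
                                         new_sigma = sa$sigma[i],
                                         stringsAsFactors = FALSE))
  }

  torsions <- empty_mod_torsions()
  rt <- ref$torsions; st <- sub$torsions
  rk <- torsion_key(rt$atom1, rt$atom2, rt$atom3, rt$atom4)
  sk <- torsion_key(st$atom1, st$atom2, st$atom3, st$atom4)
  for (i in which(!rk %in% sk)) {
    if (any(c(rt$atom1[i], rt$atom2[i], rt$atom3[i], rt$atom4[i]) %in% deleted)) next
    torsions <- rbind(torsions, data.frame(
      fun = "delete", id = rt$id[i], atom1 = rt$atom1[i], atom2 = rt$atom2[i],
      atom3 = rt$atom3[i], atom4 = rt$atom4[i], new_target = NA,
      new_sigma = NA, new_period = NA, stringsAsFactors = FALSE))
  }
  for (i in which(!sk %in% rk))
    torsions <- rbind(torsions, data.frame(
      fun = "add", id = st$id[i], atom1 = st$atom1[i], atom2 = st$atom2[i],
      atom3 = st$atom3[i], atom4 = st$atom4[i], new_target = st$target[i],
      new_sigma = st$sigma[i], new_period = st$period[i],
      stringsAsFactors = FALSE))
  for (i in which(sk %in% rk)) {
    j <- match(sk[i], rk)
    span <- 360 / max(1L, rt$period[j])
    d <- st$target[i] - rt$target[j]
    d <- d - span * round(d / span)
    if (st$period[i] != rt$period[j] || thr(d, rt$sigma[j]))
      torsions <- rbind(torsions, data.frame(
        fun = "change", id = rt$id[j], atom1 = st$atom1[i], atom2 = st$atom2[i],
        atom3 = st$atom3[i], atom4 = st$atom4[i], new_target = st$target[i],
        new_sigma = st$sigma[i], new_period = st$period[i],
        stringsAsFactors = FALSE))
  }

  chirals <- empty_mod_chirals()
  rc <- canonical_chirals(ref$chirals); sc <- canonical_chirals(sub$chirals)
  for (i in which(!rc$centre %in% sc$centre)) {
    if (any(c(rc$centre[i], rc$atom1[i], rc$atom2[i], rc$atom3[i]) %in% deleted)) next
    chirals <- rbind(chirals, data.frame(
      fun = "delete", id = rc$id[i], centre = rc$centre[i], atom1 = rc$atom1[i],
      atom2 = rc$atom2[i], atom3 = rc$atom3[i], new_sign = NA,
      stringsAsFactors = FALSE))
  }
  for (i in which(!sc$centre %in% rc$centre))
    chirals <- rbind(chirals, data.frame(
      fun = "add", id = sc$id[i], centre = sc$centre[i], atom1 = sc$atom1[i],
      atom2 = sc$atom2[i], atom3 = sc$atom3[i], new_sign = sc$sign[i],
      stringsAsFactors = FALSE))
  for (i in which(sc$centre %in% rc$centre)) {
    j <- match(sc$centre[i], rc$centre)
    if (sc$sign[i] != rc$sign[j] ||
          !identical(c(sc$atom1[i], sc$atom2[i], sc$atom3[i]),
                     c(rc$atom1[j], rc$atom2[j], rc$atom3[j])))
      chirals <- rbind(chirals, data.frame(
        fun = "change", id = rc$id[j], centre = sc$centre[i],
        atom1 = sc$atom1[i], atom2 = sc$atom2[i], atom3 = sc$atom3[i],
        new_sign = sc$sign[i], stringsAsFactors = FALSE))
  }

  planes <- empty_mod_planes()
  ref_planes <- split(ref$planes, ref$planes$plane_id)
  sub_planes <- split(sub$planes, sub$planes$plane_id)
  matched_ref <- character(0)
  for (sid in names(sub_planes)) {
    sp <- sub_planes[[sid]]
    best <- NULL; best_n <- 1L
    for (rid in setdiff(names(ref_planes), matched_ref)) {
      n <- length(intersect(sp$atom_id, ref_planes[[rid]]$atom_id))
      if (n >= 2L && n > best_n) { best <- rid; best_n <- n }
    }
    if (is.null(best)) {
      for (i in seq_len(nrow(sp)))
        planes <- rbind(planes, data.frame(fun = "add", plane_id = sid,
                                           atom_id = sp$atom_id[i],
                                           new_dist_esd = sp$dist_esd[i],
                                           stringsAsFactors = FALSE))
    } else {
      matched_ref <- c(matched_ref, best)
      rp <- ref_planes[[best]]
      for (a in setdiff(sp$atom_id, rp$atom_id))
        planes <- rbind(planes, data.frame(fun = "add", plane_id = best,
                                           atom_id = a,
                                           new_dist_esd = sp$dist_esd[match(a, sp$atom_id)],
                                           stringsAsFactors = FALSE))
      for (a in setdiff(rp$atom_id, sp$atom_id)) {
        if (a %in% deleted) next
        planes <- rbind(planes, data.frame(fun = "delete", plane_id = best,
                                           atom_id = a, new_dist_esd = NA,
                                           stringsAsFactors = FALSE))
      }
    }
  }
  for (rid in setdiff(names(ref_planes), matched_ref)) {
    rp <- ref_planes[[rid]]
    for (a in setdiff(rp$atom_id, deleted))
      planes <- rbind(planes, data.frame(fun = "delete", plane_id = rid,
                                         atom_id = a, new_dist_esd = NA,
                                         stringsAsFactors = FALSE))
  }

  modification_entry(id = id, parent = ref$code, group = ref$group,
                     name = paste("modification of", ref$code),
                     atoms = atoms, bonds = bonds, angles = angles,
                     torsions = torsions, chirals = chirals, planes = planes)
}

#' Split a regularized composite into two modifications and a link
#'
#' The junction algorithm: every template restraint involving atoms of both
#' monomers is moved to the link entry; what remains on each side is diffed
#' against the completed pristine parent monomer using the per-atom parent
#' references - deletions and additions are read off directly, and
#' surviving atoms/restraints are recorded as changed when their type
#' changed or their target moved by more than `sigma_multiplier` times the
#' declared sigma.
#'
#' @param session A regularized `composite_session`.
#' @param table Parameter table used to complete the pristine parents.
#' @param sigma_multiplier Change-detection threshold multiplier (1 =
#'   declared sigma; 0 makes the split lossless, which is what the
#'   apply/split round-trip oracle uses).
#' @return `list(mod1, mod2, link)`: two [modification_entry()]s and a
#'   [link_entry()].  Mod ids follow the `<CODE>mod<n>` convention and the
#'   link id is `<CODE1>-<CODE2>`.
#' @export
split_session <- function(session, table = builtin_parameter_table(),
                          sigma_multiplier = 1) {
  if (!isTRUE(session$regularized))
    stop("split requested before regularization: regularize the composite first")
  comp <- session$composite
  s_of <- function(a) unname(session$side[a])
  o_of <- function(a) orig_of(session, a)

  spans <- function(...) {
    cols <- list(...)
    if (!length(cols[[1]])) return(logical(0))
    m <- do.call(cbind, lapply(cols, s_of))
    apply(m, 1L, function(r) length(unique(r)) > 1L)
  }

  b <- comp$bonds
  bi <- spans(b$atom1, b$atom2)
  link_bonds <- data.frame(comp1 = s_of(b$atom1[bi]), atom1 = o_of(b$atom1[bi]),
                           comp2 = s_of(b$atom2[bi]), atom2 = o_of(b$atom2[bi]),
                           order = b$order[bi], target = b$target[bi],
                           sigma = b$sigma[bi], stringsAsFactors = FALSE)
  a <- comp$angles
  ai <- spans(a$atom1, a$atom2, a$atom3)
  link_angles <- data.frame(comp1 = s_of(a$atom1[ai]), atom1 = o_of(a$atom1[ai]),
                            comp2 = s_of(a$atom2[ai]), atom2 = o_of(a$atom2[ai]),
                            comp3 = s_of(a$atom3[ai]), atom3 = o_of(a$atom3[ai]),
                            target = a$target[ai], sigma = a$sigma[ai],
                            stringsAsFactors = FALSE)
  tr <- comp$torsions
  ti <- spans(tr$atom1, tr$atom2, tr$atom3, tr$atom4)
  link_torsions <- data.frame(
    id = tr$id[ti],
    comp1 = s_of(tr$atom1[ti]), atom1 = o_of(tr$atom1[ti]),
    comp2 = s_of(tr$atom2[ti]), atom2 = o_of(tr$atom2[ti]),
    comp3 = s_of(tr$atom3[ti]), atom3 = o_of(tr$atom3[ti]),
    comp4 = s_of(tr$atom4[ti]), atom4 = o_of(tr$atom4[ti]),
    target = tr$target[ti], sigma = tr$sigma[ti], period = tr$period[ti],
    stringsAsFactors = FALSE)
  ch <- comp$chirals
  ci <- spans(ch$centre, ch$atom1, ch$atom2, ch$atom3)
  link_chirals <- data.frame(
    id = ch$id[ci], comp_centre = s_of(ch$centre[ci]), centre = o_of(ch$centre[ci]),
    comp1 = s_of(ch$atom1[ci]), atom1 = o_of(ch$atom1[ci]),
    comp2 = s_of(ch$atom2[ci]), atom2 = o_of(ch$atom2[ci]),
    comp3 = s_of(ch$atom3[ci]), atom3 = o_of(ch$atom3[ci]),
    sign = ch$sign[ci], stringsAsFactors = FALSE)
  pl <- comp$planes
  pspan <- vapply(split(pl$atom_id, pl$plane_id),
                  function(x) length(unique(s_of(x))) > 1L, logical(1))
  pli <- pl$plane_id %in% names(pspan)[pspan]
  link_planes <- data.frame(plane_id = pl$plane_id[pli], comp = s_of(pl$atom_id[pli]),
                            atom_id = o_of(pl$atom_id[pli]),
                            dist_esd = pl$dist_esd[pli], stringsAsFactors = FALSE)

  codeA <- session$parentA$code; codeB <- session$parentB$code
  idA <- paste0(codeA, "mod1")
  idB <- paste0(codeB, if (codeA == codeB) "mod2" else "mod1")

  refA <- complete_description(session$parentA, table)
  refB <- complete_description(session$parentB, table)
  subA <- side_subdescription(session, 1L)
  subB <- side_subdescription(session, 2L)
  modA <- diff_modification(refA, subA, idA, sigma_multiplier)
  modB <- diff_modification(refB, subB, idB, sigma_multiplier)

  link <- link_entry(
    id = paste0(codeA, "-", codeB),
    comp1 = codeA, mod1 = idA, group1 = session$parentA$group,
    comp2 = codeB, mod2 = idB, group2 = session$parentB$group,
    name = paste("link", codeA, codeB),
    bonds = link_bonds, angles = link_angles, torsions = link_torsions,
    chirals = link_chirals, planes = link_planes)
  list(mod1 = modA, mod2 = modB, link = link)
}
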