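# ---- applying modifications and links ---------------------------------------

#' Apply a modification entry to a monomer
#'
#' Edits are applied in the order delete, change, add.  Deleting an atom
#' removes its bonds and restraints implicitly, mirroring how the entries
#' are generated.  A delete referencing an absent atom signals a
#' modification/monomer mismatch.
#'
#' @param mon A [monomer_description()] whose code matches the
#'   modification's parent, or whose group matches for a generic
#'   modification (parent ".").
#' @param mod A [modification_entry()].
#' @return The modified description.
#' @export
apply_modification <- function(mon, mod) {
  stopifnot(inherits(mon, "monomer_description"),
            inherits(mod, "modification_entry"))
  if (!mod$parent %in% c(".", "")) {
    if (mod$parent != mon$code)
      stop("modification ", mod$id, " applies to ", mod$parent,
           ", not ", mon$code)
  } else if (!is.na(mod$group) && nzchar(mod$group) && mod$group != mon$group) {
    stop("generic modification ", mod$id, " applies to group '", mod$group,
         "', not '", mon$group, "'")
  }

  # deletes
  for (a in mod$atoms$atom_id[mod$atoms$fun == "delete"]) {
    if (!a %in% mon$atoms$name)
      stop("modification ", mod$id, " deletes atom '", a,
           "' absent from ", mon$code, " (mismatched monomer?)")
    mon <- apply_edit(mon, graph_edit("delete_atom", name = a))
  }
  del_rows <- function(df, fun) df[df$fun == fun, , drop = FALSE]
  b <- del_rows(mod$bonds, "delete")
  for (i in seq_len(nrow(b)))
    mon <- apply_edit(mon, graph_edit("delete_bond", atom1 = b$atom1[i],
                                      atom2 = b$atom2[i]))
  a <- del_rows(mod$angles, "delete")
  for (i in seq_len(nrow(a))) {
    k <- which(mon$angles$atom2 == a$atom2[i] &
                 (mon$angles$atom1 == a$atom1[i] & mon$angles$atom3 == a$atom3[i] |
                    mon$angles$atom1 == a$atom3[i] & mon$angles$atom3 == a$atom1[i]))
    if (length(k)) mon$angles <- mon$angles[-k[1], , drop = FALSE]
  }
  tr <- del_rows(mod$torsions, "delete")
  if (nrow(tr)) {
    drop <- torsion_key(mon$torsions$atom1, mon$torsions$atom2,
                        mon$torsions$atom3, mon$torsions$atom4) %in%
      torsion_key(tr$atom1, tr$atom2, tr$atom3, tr$atom4)
    mon$torsions <- mon$torsions[!drop, , drop = FALSE]
  }
  ch <- del_rows(mod$chirals, "delete")
  if (nrow(ch))
    mon$chirals <- mon$chirals[!mon$chirals$centre %in% ch$centre, , drop = FALSE]
  pl <- del_rows(mod$planes, "delete")
  for (i in seq_len(nrow(pl))) {
    hit <- which(mon$planes$atom_id == pl$atom_id[i])
    if (length(hit)) {
      # match by atom within the overlapping plane
      pid <- if (pl$plane_id[i] %in% mon$planes$plane_id) pl$plane_id[i] else
        mon$planes$plane_id[hit[1]]
      k <- which(mon$planes$plane_id == pid & mon$planes$atom_id == pl$atom_id[i])
      if (length(k)) mon$planes <- mon$planes[-k[1], , drop = FALSE]
    }
  }
  tab <- table(mon$planes$plane_id)
  mon$planes <- mon$planes[mon$planes$plane_id %in% names(tab)[tab >= 3L], , drop = FALSE]

  # changes
  at <- mod$atoms[mod$atoms$fun == "change", , drop = FALSE]
  for (i in seq_len(nrow(at))) {
    args <- list("change_atom", name = at$atom_id[i])
    if (!is.na(at$new_atom_id[i])) args$new_name <- at$new_atom_id[i]
    if (!is.na(at$new_type_symbol[i])) args$element <- at$new_type_symbol[i]
    if (!is.na(at$new_type_energy[i])) args$energy_type <- at$new_type_energy[i]
    if (!is.na(at$new_charge[i])) args$charge <- at$new_charge[i]
    mon <- apply_edit(mon, do.call(graph_edit, args))
  }
  b <- mod$bonds[mod$bonds$fun == "change", , drop = FALSE]
  for (i in seq_len(nrow(b))) {
    args <- list("change_bond", atom1 = b$atom1[i], atom2 = b$atom2[i])
    if (!is.na(b$new_order[i])) args$order <- b$new_order[i]
    if (!is.na(b$new_target[i])) args$target <- b$new_target[i]
    if (!is.na(b$new_sigma[i])) args$sigma <- b$new_sigma[i]
    mon <- apply_edit(mon, do.call(graph_edit, args))
  }
  a <- mod$angles[mod$angles$fun == "change", , drop = FALSE]
  for (i in seq_len(nrow(a))) {
    k <- which(mon$angles$atom2 == a$atom2[i] &
                 (mon$angles$atom1 == a$atom1[i] & mon$angles$atom3 == a$atom3[i] |
                    mon$angles$atom1 == a$atom3[i] & mon$angles$atom3 == a$atom1[i]))
    if (!length(k))
      stop("modification ", mod$id, " changes an angle absent from ", mon$code)
    if (!is.na(a$new_target[i])) mon$angles$target[k[1]] <- a$new_target[i]
    if (!is.na(a$new_sigma[i])) mon$angles$sigma[k[1]] <- a$new_sigma[i]
  }
  tr <- mod$torsions[mod$torsions$fun == "change", , drop = FALSE]
  for (i in seq_len(nrow(tr))) {
    k <- which(torsion_key(mon$torsions$atom1, mon$torsions$atom2,
                           mon$torsions$atom3, mon$torsions$atom4) ==
                 torsion_key(tr$atom1[i], tr$atom2[i], tr$atom3[i], tr$atom4[i]))
    if (!length(k))
      stop("modification ", mod$id, " changes a torsion absent from ", mon$code)
    if (!is.na(tr$new_target[i])) mon$torsions$target[k[1]] <- tr$new_target[i]
    if (!is.na(tr$new_sigma[i])) mon$torsions$sigma[k[1]] <- tr$new_sigma[i]
    if (!is.na(tr$new_period[i])) mon$torsions$period[k[1]] <- tr$new_period[i]
  }
  ch <- mod$chirals[mod$chirals$fun == "change", , drop = FALSE]
  for (i in seq_len(nrow(ch))) {
    k <- match(ch$centre[i], mon$chirals$centre)
    if (is.na(k))
      stop("modification ", mod$id, " changes a chiral centre absent from ", mon$code)
    mon$chirals[k, c("atom1", "atom2", "atom3")] <-
      c(ch$atom1[i], ch$atom2[i], ch$atom3[i])
    if (!is.na(ch$new_sign[i])) mon$chirals$sign[k] <- ch$new_sign[i]
  }

  # adds
  at <- mod$atoms[mod$atoms$fun == "add", , drop = FALSE]
  for (i in seq_len(nrow(at)))
    mon <- apply_edit(mon, graph_edit("add_atom", name = at$atom_id[i],
                                      element = at$new_type_symbol[i],
                                      energy_type = at$new_type_energy[i],
                                      charge = if (is.na(at$new_charge[i])) 0L
                                               else at$new_charge[i]))
  b <- mod$bonds[mod$bonds$fun == "add", , drop = FALSE]
  for (i in seq_len(nrow(b)))
    mon <- apply_edit(mon, graph_edit("add_bond", atom1 = b$atom1[i],
                                      atom2 = b$atom2[i],
                                      order = if (is.na(b$new_order[i])) "single"
                                              else b$new_order[i],
                                      target = b$new_target[i],
                                      sigma = b$new_sigma[i]))
  a <- mod$angles[mod$angles$fun == "add", , drop = FALSE]
  if (nrow(a))
    mon$angles <- rbind(mon$angles, data.frame(
      atom1 = a$atom1, atom2 = a$atom2, atom3 = a$atom3,
      target = a$new_target, sigma = a$new_sigma, stringsAsFactors = FALSE))
  tr <- mod$torsions[mod$torsions$fun == "add", , drop = FALSE]
  if (nrow(tr))
    mon$torsions <- rbind(mon$torsions, data.frame(
      id = tr$id, atom1 = tr$atom1, atom2 = tr$atom2, atom3 = tr$atom3,
      atom4 = tr$atom4, target = tr$new_target, sigma = tr$new_sigma,
      period = tr$new_period, stringsAsFactors = FALSE))
  ch <- mod$chirals[mod$chirals$fun == "add", , drop = FALSE]
  if (nrow(ch))
    mon$chirals <- rbind(mon$chirals, data.frame(
      id = ch$id, centre = ch$centre, atom1 = ch$atom1, atom2 = ch$atom2,
      atom3 = ch$atom3, sign = ch$new_sign, stringsAsFactors = FALSE))
  pl <- mod$planes[mod$planes$fun == "add", , drop = FALSE]
  if (nrow(pl))
    mon$planes <- rbind(mon$planes, data.frame(
      plane_id = pl$plane_id, atom_id = pl$atom_id,
      dist_esd = pl$new_dist_esd, stringsAsFactors = FALSE))
  mon
}

#' Apply a link entry to two monomers
#'
#' Checks the side constraints (specific compound code, or group membership
#' for generic sides), applies the two modifications, merges the modified
#' monomers under the canonical composite naming scheme and appends the
#' link's cross-monomer restraints.
#'
#' @param monA,monB Monomer descriptions for sides 1 and 2.
#' @param modA,modB Modifications for the two sides (NULL to skip).
#' @param link A [link_entry()].
#' @return List with `desc` (the combined [monomer_description()], unique
#'   working names) and `map` (data frame side/orig/unique).
#' @export
apply_link <- function(monA, monB, modA = NULL, modB = NULL, link) {
  check_side <- function(mon, comp, group, side) {
    if (nzchar(comp) && comp != "." && comp != mon$code)
      stop("link ", link$id, " side ", side, " requires monomer ", comp,
           ", got ", mon$code)
    if ((!nzchar(comp) || comp == ".") && nzchar(group) && group != mon$group)
      stop("link ", link$id, " side ", side, " requires group '", group,
           "', got '", mon$group, "'")
  }
  check_side(monA, link$comp1, link$group1, 1L)
  check_side(monB, link$comp2, link$group2, 2L)
  A <- if (is.null(modA)) monA else apply_modification(monA, modA)
  B <- if (is.null(modB)) monB else apply_modification(monB, modB)

  cn <- canonical_composite_names(A$atoms$name, B$atoms$name)
  mapA <- cn$side1; mapB <- cn$side2
  renA <- rename_all(A, mapA); renB <- rename_all(B, mapB)
  if (nrow(renA$planes)) renA$planes$plane_id <- paste0("1-", renA$planes$plane_id)
  if (nrow(renB$planes)) renB$planes$plane_id <- paste0("2-", renB$planes$plane_id)

  atoms <- rbind(renA$atoms, renB$atoms)
  desc <- monomer_description(
    code = paste0(monA$code, "-", monB$code), name = link$id,
    group = "non-polymer", level = "complete", atoms = atoms,
    bonds = rbind(renA$bonds, renB$bonds),
    angles = rbind(renA$angles, renB$angles),
    torsions = rbind(renA$torsions, renB$torsions),
    chirals = rbind(renA$chirals, renB$chirals),
    planes = rbind(renA$planes, renB$planes))

  res <- function(side, atom) {
    mp <- if (side == 1L) mapA else mapB
    v <- mp[atom]
    if (anyNA(v)) stop("link ", link$id, " references atom '",
                       atom[is.na(v)][1], "' missing on side ", side)
    unname(v)
  }
  lb <- link$bonds
  for (i in seq_len(nrow(lb)))
    desc <- apply_edit(desc, graph_edit(
      "add_bond", atom1 = res(lb$comp1[i], lb$atom1[i]),
      atom2 = res(lb$comp2[i], lb$atom2[i]), order = lb$order[i],
      target = lb$target[i], sigma = lb$sigma[i]))
  la <- link$angles
  if (nrow(la))
    desc$angles <- rbind(desc$angles, data.frame(
      atom1 = mapply(res, la$comp1, la$atom1),
      atom2 = mapply(res, la$comp2, la$atom2),
      atom3 = mapply(res, la$comp3, la$atom3),
      target = la$target, sigma = la$sigma, stringsAsFactors = FALSE))
  lt <- link$torsions
  if (nrow(lt))
    desc$torsions <- rbind(desc$torsions, data.frame(
      id = lt$id,
      atom1 = mapply(res, lt$comp1, lt$atom1),
      atom2 = mapply(res, lt$comp2, lt$atom2),
      atom3 = mapply(res, lt$comp3, lt$atom3),
      atom4 = mapply(res, lt$comp4, lt$atom4),
      target = lt$target, sigma = lt$sigma, period = lt$period,
      stringsAsFactors = FALSE))
  lc <- link$chirals
  if (nrow(lc))
    desc$chirals <- rbind(desc$chirals, data.frame(
      id = lc$id, centre = mapply(res, lc$comp_centre, lc$centre),
      atom1 = mapply(res, lc$comp1, lc$atom1),
      atom2 = mapply(res, lc$comp2, lc$atom2),
      atom3 = mapply(res, lc$comp3, lc$atom3),
      sign = lc$sign, stringsAsFactors = FALSE))
  lp <- link$planes
  if (nrow(lp))
    desc$planes <- rbind(desc$planes, data.frame(
      plane_id = paste0("l-", lp$plane_id),
      atom_id = mapply(res, lp$comp, lp$atom_id),
      dist_esd = lp$dist_esd, stringsAsFactors = FALSE))

  map <- rbind(
    data.frame(side = 1L, orig = names(mapA), unique = unname(mapA),
               stringsAsFactors = FALSE),
    data.frame(side = 2L, orig = names(mapB), unique = unname(mapB),
               stringsAsFactors = FALSE))
  list(desc = desc, map = map)
}

rename_all <- function(m, mp) {
  m$atoms$name <- unname(mp[m$atoms$name])
  m$bonds <- rename_frame(m$bonds, c("atom1", "atom2"), mp)
  m$angles <- rename_frame(m$angles, c("atom1", "atom2", "atom3"), mp)
  m$torsions <- rename_frame(m$torsions, c("atom1", "atom2", "atom3", "atom4"), mp)
  m$chirals <- rename_frame(m$chirals, c("centre", "atom1", "atom2", "atom3"), mp)
  m$planes <- rename_frame(m$planes, "atom_id", mp)
  m
}

# ---- composite comparison ---------------------------------------------------

# Canonical, naming-scheme-independent signature of a composite: every atom
# is identified as "side:original-name".  Used by the apply/split
# round-trip oracle.
composite_signature <- function(desc, map, digits = 6) {
  mp <- stats::setNames(paste0(map$side, ":", map$orig), map$unique)
  d <- desc
  d$atoms$name <- unname(mp[d$atoms$name])
  d$bonds <- rename_frame(d$bonds, c("atom1", "atom2"), mp)
  d$angles <- rename_frame(d$angles, c("atom1", "atom2", "atom3"), mp)
  d$torsions <- rename_frame(d$torsions, c("atom1", "atom2", "atom3", "atom4"), mp)
  d$chirals <- rename_frame(d$chirals, c("centre", "atom1", "atom2", "atom3"), mp)
  d$planes <- rename_frame(d$planes, "atom_id", mp)
  d <- canonicalize_description(d)
  rnd <- function(x) round(x, digits)
  list(
    atoms = paste(d$atoms$name, d$atoms$element, d$atoms$energy_type,
                  d$atoms$charge),
    bonds = paste(d$bonds$atom1, d$bonds$atom2, d$bonds$order,
                  rnd(d$bonds$target)),
    angles = paste(d$angles$atom1, d$angles$atom2, d$angles$atom3,
                   rnd(d$angles$target)),
    torsions = paste(d$torsions$atom1, d$torsions$atom2, d$torsions$atom3,
                     d$torsions$atom4, rnd(d$torsions$target), d$torsions$period),
    chirals = paste(d$chirals$centre, d$chirals$atom1, d$chirals$atom2,
                    d$chirals$atom3, d$chirals$sign),
    planes = sort(unname(vapply(
      split(paste(d$planes$atom_id, rnd(d$planes$dist_esd)),
            d$planes$plane_id),
      function(x) paste(sort(x), collapse = "|"), character(1))),
      method = "radix"))
}

#' Compare two composites for semantic equality
#'
#' Compares atoms, bonds, angle/torsion/chiral/plane restraints and their
#' targets (to `digits` decimal places) in the side-qualified original name
#' space, so the comparison is independent of the unique-renaming scheme.
#'
#' @param descA,descB Composite descriptions.
#' @param mapA,mapB Their side/orig/unique name maps.
#' @param digits Rounding applied to targets before comparison.
#' @return TRUE or a character vector describing the first differences.
#' @export
composites_equal <- function(descA, mapA, descB, mapB, digits = 6) {
  sa <- composite_signature(descA, mapA, digits)
  sb <- composite_signature(descB, mapB, digits)
  diffs <- character(0)
  for (part in names(sa)) {
    a <- sort(sa[[part]], method = "radix")
    b <- sort(sb[[part]], method = "radix")
    if (!identical(a, b)) {
      d1 <- setdiff(a, b); d2 <- setdiff(b, a)
      diffs <- c(diffs, sprintf("%s: only in first {%s} only in second {%s}",
                                part, paste(utils::head(d1, 3), collapse = "; "),
                                paste(utils::head(d2, 3), collapse = "; ")))
    }
  }
  if (length(diffs)) diffs else TRUE
}

# ---- saving the additional library ------------------------------------------

#' Save a split composite as an additional library
#'
#' Emits the modification list, link list, the two modification blocks and
#' the link block.  Monomer blocks are included only for sides whose parent
#' compound is not resolvable in the base library; including one that *is*
#' resolvable would shadow the standard entry during refinement, so doing
#' it via `force_monomers` triggers a shadowing warning.  In append mode
#' the file's existing entries are merged in with precedence to the new
#' ones (a warning reports each shadowed id).
#'
#' @param session A regularized `composite_session`.
#' @param path Output CIF file.
#' @param mode "new" or "append".
#' @param base Base [restraint_library()] used to decide monomer inclusion.
#' @param table,sigma_multiplier Passed to [split_session()].
#' @param force_monomers Include the parent monomer blocks regardless.
#' @return The written [restraint_library()], invisibly.
#' @export
save_additional_library <- function(session, path, mode = c("new", "append"),
                                    base = NULL,
                                    table = builtin_parameter_table(),
                                    sigma_multiplier = 1,
                                    force_monomers = FALSE) {
  mode <- match.arg(mode)
  parts <- split_session(session, table, sigma_multiplier)
  mods <- list(parts$mod1, parts$mod2)
  names(mods) <- vapply(mods, `[[`, character(1), "id")
  if (anyDuplicated(names(mods)))
    stop("id collision among entries to be written: ", names(mods)[1])
  links <- stats::setNames(list(parts$link), parts$link$id)

  monomers <- list()
  for (parent in list(session$parentA, session$parentB)) {
    in_base <- !is.null(base) && parent$code %in% names(base$monomers)
    if (force_monomers || !in_base) {
      if (in_base)
        warning("monomer block '", parent$code, "' shadows a base-library ",
                "entry of the same name; refinement will no longer see the ",
                "base description")
      monomers[[parent$code]] <- complete_description(parent, table)
    }
  }

  lib <- restraint_library(monomers = monomers, modifications = mods,
                           links = links, provenance = "additional")
  if (mode == "append" && file.exists(path)) {
    old <- read_library(path, provenance = "additional")
    merged <- merge_libraries(old, lib)
    shadowed <- attr(merged, "shadowed")
    if (length(shadowed))
      warning("append: new entries take precedence over existing id(s): ",
              paste(shadowed, collapse = ", "))
    lib <- merged
  }
  write_library(lib, path = path, lists = "mod_link")
  invisible(lib)
}

#' Count data blocks in a CIF document
#'
#' @param text File path, string or lines.
#' @return Integer number of `data_` blocks.
#' @export
count_cif_blocks <- function(text) {
  lines <- if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    readLines(text) else if (length(text) == 1L) strsplit(text, "\n")[[1]] else text
  sum(grepl("^data_", lines))
}
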