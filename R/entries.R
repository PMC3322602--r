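# ---- modification / link / library containers -------------------------------

empty_mod_atoms <- function() {
  data.frame(fun = character(), atom_id = character(),
             new_atom_id = character(), new_type_symbol = character(),
             new_type_energy = character(), new_charge = integer(),
             stringsAsFactors = FALSE)
}

empty_mod_bonds <- function() {
  data.frame(fun = character(), atom1 = character(), atom2 = character(),
             new_order = character(), new_target = numeric(),
             new_sigma = numeric(), stringsAsFactors = FALSE)
}

empty_mod_angles <- function() {
  data.frame(fun = character(), atom1 = character(), atom2 = character(),
             atom3 = character(), new_target = numeric(), new_sigma = numeric(),
             stringsAsFactors = FALSE)
}

empty_mod_torsions <- function() {
  data.frame(fun = character(), id = character(), atom1 = character(),
             atom2 = character(), atom3 = character(), atom4 = character(),
             new_target = numeric(), new_sigma = numeric(),
             new_period = integer(), stringsAsFactors = FALSE)
}

empty_mod_chirals <- function() {
  data.frame(fun = character(), id = character(), centre = character(),
             atom1 = character(), atom2 = character(), atom3 = character(),
             new_sign = character(), stringsAsFactors = FALSE)
}

empty_mod_planes <- function() {
  data.frame(fun = character(), plane_id = character(), atom_id = character(),
             new_dist_esd = numeric(), stringsAsFactors = FALSE)
}

#' Construct a modification entry
#'
#' A modification records add/delete/change edits against a named parent
#' monomer (or against any member of a monomer group when `parent` is ".").
#' Deleting an atom implies deletion of its bonds and restraints, so
#' restraint edit tables list only edits between surviving atoms.
#'
#' @param id Modification id (e.g. "LYSmod1", "DEL-OXT").
#' @param parent Parent compound code, or "." for group-generic.
#' @param group Monomer group a generic modification applies to.
#' @param name Free-text name.
#' @param atoms,bonds,angles,torsions,chirals,planes Edit tables; see the
#'   `empty_mod_*` shapes in the source.
#' @return Object of class `modification_entry`.
#' @export
modification_entry <- function(id, parent = ".", group = NA_character_,
                               name = "",
                               atoms = empty_mod_atoms(),
                               bonds = empty_mod_bonds(),
                               angles = empty_mod_angles(),
                               torsions = empty_mod_torsions(),
                               chirals = empty_mod_chirals(),
                               planes = empty_mod_planes()) {
  structure(list(id = id, parent = parent, group = group, name = name,
                 atoms = atoms, bonds = bonds, angles = angles,
                 torsions = torsions, chirals = chirals, planes = planes),
            class = "modification_entry")
}

#' @export
print.modification_entry <- function(x, ...) {
  cat(sprintf("<modification %s on %s%s> %d atom, %d bond, %d angle, %d torsion, %d chiral, %d plane edits\n",
              x$id, x$parent,
              if (!is.na(x$group)) paste0(" (group ", x$group, ")") else "",
              nrow(x$atoms), nrow(x$bonds), nrow(x$angles), nrow(x$torsions),
              nrow(x$chirals), nrow(x$planes)))
  invisible(x)
}

empty_link_bonds <- function() {
  data.frame(comp1 = integer(), atom1 = character(), comp2 = integer(),
             atom2 = character(), order = character(), target = numeric(),
             sigma = numeric(), stringsAsFactors = FALSE)
}

empty_link_angles <- function() {
  data.frame(comp1 = integer(), atom1 = character(), comp2 = integer(),
             atom2 = character(), comp3 = integer(), atom3 = character(),
             target = numeric(), sigma = numeric(), stringsAsFactors = FALSE)
}

empty_link_torsions <- function() {
  data.frame(id = character(), comp1 = integer(), atom1 = character(),
             comp2 = integer(), atom2 = character(), comp3 = integer(),
             atom3 = character(), comp4 = integer(), atom4 = character(),
             target = numeric(), sigma = numeric(), period = integer(),
             stringsAsFactors = FALSE)
}

empty_link_chirals <- function() {
  data.frame(id = character(), comp_centre = integer(), centre = character(),
             comp1 = integer(), atom1 = character(), comp2 = integer(),
             atom2 = character(), comp3 = integer(), atom3 = character(),
             sign = character(), stringsAsFactors = FALSE)
}

empty_link_planes <- function() {
  data.frame(plane_id = character(), comp = integer(), atom_id = character(),
             dist_esd = numeric(), stringsAsFactors = FALSE)
}

#' Construct a link entry
#'
#' A link carries the cross-monomer restraints (at least one bond, plus the
#' angles, torsions, chiral centres and planar groups that span the
#' junction) joining two possibly modified monomers.  Each side names a
#' specific compound code or, for generic links, a monomer group, together
#' with the modification applied to that side.
#'
#' @param id Link id (e.g. "LYS-PLP", "TRANS").
#' @param comp1,comp2 Compound codes ("" when the side is generic).
#' @param group1,group2 Group constraint for generic sides.
#' @param mod1,mod2 Modification ids applied to each side.
#' @param name Free-text name.
#' @param bonds,angles,torsions,chirals,planes Restraint tables with a side
#'   discriminator (1 or 2) per atom; see `empty_link_*` in the source.
#' @return Object of class `link_entry`.
#' @export
link_entry <- function(id, comp1 = "", mod1 = "", group1 = "",
                       comp2 = "", mod2 = "", group2 = "", name = "",
                       bonds = empty_link_bonds(),
                       angles = empty_link_angles(),
                       torsions = empty_link_torsions(),
                       chirals = empty_link_chirals(),
                       planes = empty_link_planes()) {
  structure(list(id = id, comp1 = comp1, mod1 = mod1, group1 = group1,
                 comp2 = comp2, mod2 = mod2, group2 = group2, name = name,
                 bonds = bonds, angles = angles, torsions = torsions,
                 chirals = chirals, planes = planes),
            class = "link_entry")
}

#' @export
print.link_entry <- function(x, ...) {
  side <- function(comp, grp, mod)
    paste0(if (nzchar(comp)) comp else paste0("group:", grp),
           if (nzchar(mod)) paste0(" + ", mod) else "")
  cat(sprintf("<link %s> %s -- %s: %d bonds, %d angles, %d torsions, %d chirals, %d plane rows\n",
              x$id, side(x$comp1, x$group1, x$mod1),
              side(x$comp2, x$group2, x$mod2),
              nrow(x$bonds), nrow(x$angles), nrow(x$torsions),
              nrow(x$chirals), nrow(x$planes)))
  invisible(x)
}

#' Construct a restraint library
#'
#' A library is a set of monomer, modification and link entries, each with a
#' provenance label ("standard" or "additional").  Additional entries shadow
#' standard entries with the same id when libraries are merged.
#'
#' @param monomers Named list of [monomer_description()]s.
#' @param modifications Named list of [modification_entry()]s.
#' @param links Named list of [link_entry()]s.
#' @param provenance Source label applied to all entries.
#' @return Object of class `restraint_library`.
#' @export
restraint_library <- function(monomers = list(), modifications = list(),
                              links = list(), provenance = "standard") {
  if (length(monomers) && is.null(names(monomers)))
    names(monomers) <- vapply(monomers, function(m) m$code, character(1))
  if (length(modifications) && is.null(names(modifications)))
    names(modifications) <- vapply(modifications, function(m) m$id, character(1))
  if (length(links) && is.null(names(links)))
    names(links) <- vapply(links, function(l) l$id, character(1))
  stopifnot(!anyDuplicated(names(monomers)), !anyDuplicated(names(modifications)),
            !anyDuplicated(names(links)))
  prov <- c(stats::setNames(rep(provenance, length(monomers)), names(monomers)),
            stats::setNames(rep(provenance, length(modifications)), names(modifications)),
            stats::setNames(rep(provenance, length(links)), names(links)))
  structure(list(monomers = monomers, modifications = modifications,
                 links = links, provenance = prov, opaque = list()),
            class = "restraint_library")
}

#' @export
print.restraint_library <- function(x, ...) {
  cat(sprintf("<restraint library> %d monomers, %d modifications, %d links\n",
              length(x$monomers), length(x$modifications), length(x$links)))
  invisible(x)
}

#' Merge two restraint libraries with additional-library precedence
#'
#' Entries of `additional` win wherever ids collide with `standard`, which
#' is the refinement-time semantics of a user's additional library: a
#' same-named entry shadows the standard one.
#'
#' @param standard,additional [restraint_library()] objects.
#' @return Merged library; shadowed ids are reported via a warning-free
#'   attribute `shadowed`.
#' @export
merge_libraries <- function(standard, additional) {
  out <- standard
  shadowed <- character(0)
  for (slot in c("monomers", "modifications", "links")) {
    for (id in names(additional[[slot]])) {
      if (id %in% names(out[[slot]])) shadowed <- c(shadowed, id)
      out[[slot]][[id]] <- additional[[slot]][[id]]
      out$provenance[id] <- "additional"
    }
  }
  attr(out, "shadowed") <- shadowed
  out
}

#' Check that modification and link references resolve
#'
#' Every modification's parent code and every link's side compounds and
#' modification ids must resolve within the union of `lib` and `base`;
#' generic references (".", "", or group names) are exempt.
#'
#' @param lib Library to check.
#' @param base Optional base library forming the resolution scope.
#' @return Character vector of unresolved references (empty when clean).
#' @export
resolve_references <- function(lib, base = NULL) {
  mons <- names(lib$monomers)
  mods <- names(lib$modifications)
  if (!is.null(base)) {
    mons <- union(mons, names(base$monomers))
    mods <- union(mods, names(base$modifications))
  }
  bad <- character(0)
  for (m in lib$modifications) {
    if (!m$parent %in% c(".", "") && !m$parent %in% mons)
      bad <- c(bad, sprintf("modification %s: parent monomer '%s'", m$id, m$parent))
  }
  for (l in lib$links) {
    for (side in 1:2) {
      comp <- l[[paste0("comp", side)]]; mod <- l[[paste0("mod", side)]]
      if (nzchar(comp) && comp != "." && !comp %in% mons)
        bad <- c(bad, sprintf("link %s: side-%d monomer '%s'", l$id, side, comp))
      if (nzchar(mod) && mod != "." && !mod %in% mods)
        bad <- c(bad, sprintf("link %s: side-%d modification '%s'", l$id, side, mod))
    }
  }
  bad
}
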