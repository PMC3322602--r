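# ---- empty restraint frames -------------------------------------------------

empty_atoms <- function() {
  data.frame(name = character(), element = character(),
             energy_type = character(), charge = integer(),
             parent_ref = character(), stringsAsFactors = FALSE)
}

empty_bonds <- function() {
  data.frame(atom1 = character(), atom2 = character(), order = character(),
             target = numeric(), sigma = numeric(), stringsAsFactors = FALSE)
}

empty_angles <- function() {
  data.frame(atom1 = character(), atom2 = character(), atom3 = character(),
             target = numeric(), sigma = numeric(), stringsAsFactors = FALSE)
}

empty_torsions <- function() {
  data.frame(id = character(), atom1 = character(), atom2 = character(),
             atom3 = character(), atom4 = character(),
             target = numeric(), sigma = numeric(), period = integer(),
             stringsAsFactors = FALSE)
}

empty_chirals <- function() {
  data.frame(id = character(), centre = character(),
             atom1 = character(), atom2 = character(), atom3 = character(),
             sign = character(), stringsAsFactors = FALSE)
}

empty_planes <- function() {
  data.frame(plane_id = character(), atom_id = character(),
             dist_esd = numeric(), stringsAsFactors = FALSE)
}

BOND_ORDERS <- c("single", "double", "triple", "aromatic", "deloc")
CHIRAL_SIGNS <- c("positive", "negative", "both")

order_value <- function(order) {
  v <- c(single = 1, double = 2, triple = 3, aromatic = 1.5, deloc = 1.5)
  unname(v[order])
}

#' Construct a monomer description
#'
#' A monomer description holds the molecular graph of one compound (atoms
#' with element, formal charge and optional energy type; bonds with order)
#' together with its template restraints (angles, torsions, chiral centres
#' and planar groups).  A `minimal` description carries the graph, names and
#' chiralities only; a `complete` description additionally carries target
#' values and uncertainties for every bond and angle restraint plus planar
#' groups.
#'
#' @param code Compound id, conventionally up to three characters (e.g. "LYS").
#' @param name Free-text compound name.
#' @param group Monomer group; one of "peptide", "DNA", "RNA", "pyranose",
#'   "non-polymer" (others allowed).
#' @param level "minimal" or "complete".
#' @param atoms Data frame with columns name, element, energy_type, charge,
#'   parent_ref. `parent_ref` records the originating atom of a pre-edit
#'   monomer and is `NA` exactly for atoms introduced by an edit.
#' @param bonds,angles,torsions,chirals,planes Restraint data frames; see
#'   the `empty_*` shapes in the source for the expected columns.
#' @param journal List of graph edits already applied (provenance).
#' @return An object of class `monomer_description`.
#' @export
monomer_description <- function(code, name = "", group = "non-polymer",
                                level = "minimal",
                                atoms = empty_atoms(), bonds = empty_bonds(),
                                angles = empty_angles(),
                                torsions = empty_torsions(),
                                chirals = empty_chirals(),
                                planes = empty_planes(),
                                journal = list()) {
  stopifnot(is.character(code), length(code) == 1L, nzchar(code))
  level <- match.arg(level, c("minimal", "complete"))
  atoms <- as_atoms(atoms)
  desc <- structure(list(code = code, name = name, group = group,
                         level = level, atoms = atoms, bonds = bonds,
                         angles = angles, torsions = torsions,
                         chirals = chirals, planes = planes,
                         journal = journal),
                    class = "monomer_description")
  desc
}

as_atoms <- function(df) {
  need <- c("name", "element", "energy_type", "charge", "parent_ref")
  if (!"energy_type" %in% names(df)) df$energy_type <- NA_character_
  if (!"charge" %in% names(df)) df$charge <- 0L
  if (!"parent_ref" %in% names(df)) df$parent_ref <- df$name
  df$charge <- as.integer(df$charge)
  df[, need]
}

#' @export
print.monomer_description <- function(x, ...) {
  cat(sprintf("<monomer %s (%s, %s)> %d atoms, %d bonds, %d angles, %d torsions, %d chirals, %d plane rows\n",
              x$code, x$group, x$level, nrow(x$atoms), nrow(x$bonds),
              nrow(x$angles), nrow(x$torsions), nrow(x$chirals),
              nrow(x$planes)))
  invisible(x)
}

atom_names <- function(desc) desc$atoms$name

neighbours_of <- function(desc, atom) {
  b <- desc$bonds
  c(b$atom2[b$atom1 == atom], b$atom1[b$atom2 == atom])
}

bond_between <- function(desc, a1, a2) {
  which((desc$bonds$atom1 == a1 & desc$bonds$atom2 == a2) |
          (desc$bonds$atom1 == a2 & desc$bonds$atom2 == a1))
}

is_hydrogen <- function(desc, atom) {
  desc$atoms$element[match(atom, desc$atoms$name)] == "H"
}

# ---- canonicalization -------------------------------------------------------

canonical_bonds <- function(bonds) {
  if (nrow(bonds) == 0L) return(bonds)
  swap <- bonds$atom1 > bonds$atom2
  tmp <- bonds$atom1[swap]; bonds$atom1[swap] <- bonds$atom2[swap]
  bonds$atom2[swap] <- tmp
  bonds[order(bonds$atom1, bonds$atom2), , drop = FALSE]
}

canonical_angles <- function(angles) {
  if (nrow(angles) == 0L) return(angles)
  swap <- angles$atom1 > angles$atom3
  tmp <- angles$atom1[swap]; angles$atom1[swap] <- angles$atom3[swap]
  angles$atom3[swap] <- tmp
  angles[order(angles$atom2, angles$atom1, angles$atom3), , drop = FALSE]
}

canonical_torsions <- function(tors) {
  if (nrow(tors) == 0L) return(tors)
  rev_row <- paste(tors$atom3, tors$atom4) < paste(tors$atom2, tors$atom1)
  for (i in which(rev_row)) {
    tors[i, c("atom1", "atom2", "atom3", "atom4")] <-
      tors[i, c("atom4", "atom3", "atom2", "atom1")]
  }
  tors[order(tors$atom2, tors$atom3, tors$atom1, tors$atom4), , drop = FALSE]
}

# Chiral rows are stored with the three neighbours sorted; storing an odd
# permutation of the original neighbour list flips the declared sign.
canonical_chirals <- function(ch) {
  if (nrow(ch) == 0L) return(ch)
  for (i in seq_len(nrow(ch))) {
    trip <- c(ch$atom1[i], ch$atom2[i], ch$atom3[i])
    srt <- sort(trip)
    if (permutation_parity(match(srt, trip)) < 0 && ch$sign[i] != "both") {
      ch$sign[i] <- if (ch$sign[i] == "positive") "negative" else "positive"
    }
    ch[i, c("atom1", "atom2", "atom3")] <- srt
  }
  ch[order(ch$centre), , drop = FALSE]
}

permutation_parity <- function(p) {
  n <- length(p); visited <- logical(n); parity <- 1L
  for (i in seq_len(n)) {
    if (!visited[i]) {
      j <- i; len <- 0L
      while (!visited[j]) { visited[j] <- TRUE; j <- p[j]; len <- len + 1L }
      if (len %% 2L == 0L) parity <- -parity
    }
  }
  parity
}

canonical_planes <- function(pl) {
  if (nrow(pl) == 0L) return(pl)
  pl[order(pl$plane_id, pl$atom_id), , drop = FALSE]
}

canonicalize_description <- function(desc) {
  desc$atoms <- desc$atoms[order(desc$atoms$name), , drop = FALSE]
  desc$bonds <- canonical_bonds(desc$bonds)
  desc$angles <- canonical_angles(desc$angles)
  desc$torsions <- canonical_torsions(desc$torsions)
  desc$chirals <- canonical_chirals(desc$chirals)
  desc$planes <- canonical_planes(desc$planes)
  rownames(desc$atoms) <- rownames(desc$bonds) <- rownames(desc$angles) <- NULL
  rownames(desc$torsions) <- rownames(desc$chirals) <- rownames(desc$planes) <- NULL
  desc
}

# ---- graph edits ------------------------------------------------------------

#' Construct a graph edit
#'
#' Edits are the atomic operations of molecular-graph editing: adding or
#' deleting an atom, adding, deleting or retyping a bond, changing an atom's
#' name/element/energy type/charge, or (re)declaring a chiral centre.
#' Each applied edit is appended to the description's journal so that the
#' edited molecule can be diffed against its parent later.
#'
#' @param kind One of "add_atom", "delete_atom", "add_bond", "delete_bond",
#'   "change_bond", "change_atom", "set_chirality".
#' @param ... Payload fields required by `kind` (see [apply_edit()]).
#' @return An object of class `graph_edit`.
#' @export
graph_edit <- function(kind, ...) {
  kind <- match.arg(kind, c("add_atom", "delete_atom", "add_bond",
                            "delete_bond", "change_bond", "change_atom",
                            "set_chirality"))
  structure(c(list(kind = kind), list(...)), class = "graph_edit")
}

#' Apply a graph edit to a monomer description
#'
#' Deleting an atom removes the atom, every incident bond and every restraint
#' (angle, torsion, chiral centre, plane row) that references it.  Atoms
#' introduced by `add_atom` carry no parent reference, which is how the
#' diffing machinery later recognises them as additions.
#'
#' @param desc A [monomer_description()].
#' @param edit A [graph_edit()].  Payloads by kind:
#'   * `add_atom`: `name`, `element`, optionally `energy_type`, `charge`.
#'   * `delete_atom`: `name`.
#'   * `add_bond`: `atom1`, `atom2`, optionally `order` (default "single").
#'   * `delete_bond`: `atom1`, `atom2`.
#'   * `change_bond`: `atom1`, `atom2`, any of `order`, `target`, `sigma`.
#'   * `change_atom`: `name`, any of `new_name`, `element`, `energy_type`,
#'     `charge`.
#'   * `set_chirality`: `centre`, `sign`, optionally `atom1..atom3`.
#' @return The edited description (journal extended by `edit`).
#' @export
apply_edit <- function(desc, edit) {
  stopifnot(inherits(desc, "monomer_description"), inherits(edit, "graph_edit"))
  desc <- switch(edit$kind,
    add_atom = edit_add_atom(desc, edit),
    delete_atom = edit_delete_atom(desc, edit),
    add_bond = edit_add_bond(desc, edit),
    delete_bond = edit_delete_bond(desc, edit),
    change_bond = edit_change_bond(desc, edit),
    change_atom = edit_change_atom(desc, edit),
    set_chirality = edit_set_chirality(desc, edit))
  desc$journal <- c(desc$journal, list(edit))
  desc
}

edit_add_atom <- function(desc, e) {
  if (e$name %in% desc$atoms$name)
    stop("add_atom: duplicate atom name '", e$name, "' in ", desc$code)
  if (nchar(e$name) > 4L || !nzchar(e$name))
    stop("add_atom: atom name '", e$name, "' must be 1-4 characters")
  desc$atoms <- rbind(desc$atoms, data.frame(
    name = e$name, element = e$element,
    energy_type = e$energy_type %||% NA_character_,
    charge = as.integer(e$charge %||% 0L),
    parent_ref = NA_character_, stringsAsFactors = FALSE))
  desc
}

edit_delete_atom <- function(desc, e) {
  if (!e$name %in% desc$atoms$name)
    stop("delete_atom: no atom named '", e$name, "' in ", desc$code)
  nm <- e$name
  desc$atoms <- desc$atoms[desc$atoms$name != nm, , drop = FALSE]
  desc$bonds <- desc$bonds[desc$bonds$atom1 != nm & desc$bonds$atom2 != nm, , drop = FALSE]
  desc$angles <- desc$angles[desc$angles$atom1 != nm & desc$angles$atom2 != nm &
                               desc$angles$atom3 != nm, , drop = FALSE]
  keep_t <- !(desc$torsions$atom1 == nm | desc$torsions$atom2 == nm |
                desc$torsions$atom3 == nm | desc$torsions$atom4 == nm)
  desc$torsions <- desc$torsions[keep_t, , drop = FALSE]
  keep_c <- !(desc$chirals$centre == nm | desc$chirals$atom1 == nm |
                desc$chirals$atom2 == nm | desc$chirals$atom3 == nm)
  desc$chirals <- desc$chirals[keep_c, , drop = FALSE]
  desc$planes <- desc$planes[desc$planes$atom_id != nm, , drop = FALSE]
  # a planar group needs >= 3 atoms to mean anything
  tab <- table(desc$planes$plane_id)
  desc$planes <- desc$planes[desc$planes$plane_id %in% names(tab)[tab >= 3L], , drop = FALSE]
  desc
}

edit_add_bond <- function(desc, e) {
  ord <- e$order %||% "single"
  for (a in c(e$atom1, e$atom2))
    if (!a %in% desc$atoms$name)
      stop("add_bond: no atom named '", a, "' in ", desc$code)
  if (e$atom1 == e$atom2)
    stop("add_bond: cannot bond atom '", e$atom1, "' to itself")
  if (length(bond_between(desc, e$atom1, e$atom2)))
    stop("add_bond: bond ", e$atom1, "-", e$atom2, " already present")
  if (!ord %in% BOND_ORDERS) stop("add_bond: unknown bond order '", ord, "'")
  desc$bonds <- rbind(desc$bonds, data.frame(
    atom1 = e$atom1, atom2 = e$atom2, order = ord,
    target = e$target %||% NA_real_, sigma = e$sigma %||% NA_real_,
    stringsAsFactors = FALSE))
  desc
}

edit_delete_bond <- function(desc, e) {
  i <- bond_between(desc, e$atom1, e$atom2)
  if (!length(i))
    stop("delete_bond: no bond ", e$atom1, "-", e$atom2, " in ", desc$code)
  desc$bonds <- desc$bonds[-i, , drop = FALSE]
  desc
}

edit_change_bond <- function(desc, e) {
  i <- bond_between(desc, e$atom1, e$atom2)
  if (!length(i))
    stop("change_bond: no bond ", e$atom1, "-", e$atom2, " in ", desc$code)
  if (!is.null(e$order)) {
    if (!e$order %in% BOND_ORDERS) stop("change_bond: unknown order '", e$order, "'")
    desc$bonds$order[i] <- e$order
  }
  if (!is.null(e$target)) desc$bonds$target[i] <- e$target
  if (!is.null(e$sigma)) desc$bonds$sigma[i] <- e$sigma
  desc
}

edit_change_atom <- function(desc, e) {
  i <- match(e$name, desc$atoms$name)
  if (is.na(i)) stop("change_atom: no atom named '", e$name, "' in ", desc$code)
  if (!is.null(e$element)) desc$atoms$element[i] <- e$element
  if (!is.null(e$energy_type)) desc$atoms$energy_type[i] <- e$energy_type
  if (!is.null(e$charge)) desc$atoms$charge[i] <- as.integer(e$charge)
  if (!is.null(e$new_name) && e$new_name != e$name) {
    if (e$new_name %in% desc$atoms$name)
      stop("change_atom: new name '", e$new_name, "' already in use")
    desc <- rename_atom_everywhere(desc, e$name, e$new_name)
  }
  desc
}

rename_atom_everywhere <- function(desc, old, new) {
  sub1 <- function(x) { x[x == old] <- new; x }
  i <- match(old, desc$atoms$name)
  desc$atoms$name[i] <- new
  for (col in c("atom1", "atom2")) desc$bonds[[col]] <- sub1(desc$bonds[[col]])
  for (col in c("atom1", "atom2", "atom3")) desc$angles[[col]] <- sub1(desc$angles[[col]])
  for (col in c("atom1", "atom2", "atom3", "atom4"))
    desc$torsions[[col]] <- sub1(desc$torsions[[col]])
  for (col in c("centre", "atom1", "atom2", "atom3"))
    desc$chirals[[col]] <- sub1(desc$chirals[[col]])
  desc$planes$atom_id <- sub1(desc$planes$atom_id)
  desc
}

edit_set_chirality <- function(desc, e) {
  if (!e$centre %in% desc$atoms$name)
    stop("set_chirality: no atom named '", e$centre, "' in ", desc$code)
  sgn <- match.arg(e$sign, CHIRAL_SIGNS)
  i <- match(e$centre, desc$chirals$centre)
  if (!is.na(i) && is.null(e$atom1)) {
    desc$chirals$sign[i] <- sgn
    return(desc)
  }
  nb <- if (!is.null(e$atom1)) c(e$atom1, e$atom2, e$atom3) else {
    heavy <- setdiff(neighbours_of(desc, e$centre),
                     desc$atoms$name[desc$atoms$element == "H"])
    sort(heavy)[1:3]
  }
  if (anyNA(nb) || !all(nb %in% desc$atoms$name))
    stop("set_chirality: neighbours of '", e$centre, "' not resolvable")
  row <- data.frame(id = paste0("chir_", e$centre), centre = e$centre,
                    atom1 = nb[1], atom2 = nb[2], atom3 = nb[3], sign = sgn,
                    stringsAsFactors = FALSE)
  if (!is.na(i)) desc$chirals[i, ] <- row else desc$chirals <- rbind(desc$chirals, row)
  desc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- chiral volume ----------------------------------------------------------

#' Signed chiral volume of a centre and three neighbours
#'
#' Computes `det[v1 v2 v3]` with `vi = neighbour_i - centre` (no 1/6 factor).
#' The sign of the volume encodes the handedness of the centre; swapping any
#' two neighbours flips it.
#'
#' @param centre Numeric xyz of the central atom.
#' @param n1,n2,n3 Numeric xyz of the three neighbours, in declared order.
#' @return Signed volume in cubic angstroms.
#' @seealso [chirality_sign()]
#' @export
chiral_volume <- function(centre, n1, n2, n3) {
  m <- cbind(n1 - centre, n2 - centre, n3 - centre)
  det(m)
}

#' Classify a chiral volume
#'
#' Volumes within `margin` of zero (default 0.1 cubic angstroms) are reported
#' as "degenerate": the tolerance absorbs numerical noise and flags coincident
#' or coplanar neighbour geometries.
#'
#' @param volume Signed volume from [chiral_volume()].
#' @param margin Dead band around zero.
#' @return "positive", "negative" or "degenerate".
#' @export
chirality_sign <- function(volume, margin = 0.1) {
  if (volume > margin) "positive" else if (volume < -margin) "negative" else "degenerate"
}

# ---- validation -------------------------------------------------------------

#' Validate a monomer description
#'
#' Report-only consistency check: dangling restraint references, duplicate
#' atom names, disconnected fragments, over-valence heavy atoms, self-bonds
#' and duplicate bonds.  An empty report means the structural invariants hold.
#'
#' @param desc A [monomer_description()].
#' @return Data frame with columns `class`, `id`, `message`; zero rows when
#'   the description is valid.
#' @export
validate_monomer <- function(desc) {
  findings <- list()
  add <- function(class, id, message)
    findings[[length(findings) + 1L]] <<- data.frame(
      class = class, id = id, message = message, stringsAsFactors = FALSE)

  nm <- desc$atoms$name
  dup <- unique(nm[duplicated(nm)])
  for (d in dup) add("duplicate_atom", d, paste0("atom name '", d, "' used more than once"))

  refs <- list(bond = unlist(desc$bonds[c("atom1", "atom2")]),
               angle = unlist(desc$angles[c("atom1", "atom2", "atom3")]),
               torsion = unlist(desc$torsions[c("atom1", "atom2", "atom3", "atom4")]),
               chiral = unlist(desc$chirals[c("centre", "atom1", "atom2", "atom3")]),
               plane = desc$planes$atom_id)
  for (cls in names(refs)) {
    bad <- unique(setdiff(refs[[cls]], nm))
    for (b in bad) add("dangling_reference", b,
                       paste0(cls, " restraint references unknown atom '", b, "'"))
  }

  if (nrow(desc$bonds)) {
    if (any(desc$bonds$atom1 == desc$bonds$atom2))
      add("self_bond", desc$bonds$atom1[desc$bonds$atom1 == desc$bonds$atom2][1],
          "bond joins an atom to itself")
    key <- apply(desc$bonds[c("atom1", "atom2")], 1L,
                 function(r) paste(sort(r), collapse = "-"))
    for (k in unique(key[duplicated(key)]))
      add("duplicate_bond", k, paste0("more than one bond for pair ", k))
  }

  # connectivity over atoms actually present
  if (nrow(desc$atoms) > 1L) {
    comp <- connected_components(nm, desc$bonds)
    if (length(unique(comp)) > 1L)
      add("disconnected", desc$code,
          sprintf("graph has %d connected components", length(unique(comp))))
  }

  # valence (heavy atoms with known element only)
  for (i in seq_len(nrow(desc$atoms))) {
    el <- desc$atoms$element[i]
    if (el == "H" || !el %in% names(VALENCE)) next
    a <- desc$atoms$name[i]
    tot <- sum(order_value(desc$bonds$order[desc$bonds$atom1 == a | desc$bonds$atom2 == a]))
    cap <- effective_valence(el, desc$atoms$charge[i])
    if (floor(tot + 1e-9) > cap)
      add("over_valence", a, sprintf("atom '%s' (%s) has bond order sum %.1f > valence %d",
                                     a, el, tot, cap))
  }

  if (length(findings)) do.call(rbind, findings) else
    data.frame(class = character(), id = character(), message = character(),
               stringsAsFactors = FALSE)
}

connected_components <- function(names, bonds) {
  comp <- seq_along(names)
  names(comp) <- names
  find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
  for (k in seq_len(nrow(bonds))) {
    i0 <- match(bonds$atom1[k], names); j0 <- match(bonds$atom2[k], names)
    if (is.na(i0) || is.na(j0)) next   # dangling reference: reported elsewhere
    i <- find(i0); j <- find(j0)
    if (i != j) comp[i] <- j
  }
  vapply(seq_along(names), find, integer(1))
}
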