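# Per-atom structural environment used by typing, completion and the
# idealizer: heavy-bond order sum, hydrogen count, hybridization, ring
# membership.
atom_environment <- function(desc) {
  atoms <- desc$atoms
  n <- nrow(atoms)
  env <- data.frame(name = atoms$name, element = atoms$element,
                    charge = atoms$charge,
                    n_h = 0L, degree = 0L, max_order = 0,
                    n_double = 0L, aromatic = FALSE, in_ring = FALSE,
                    hyb = "sp3", stringsAsFactors = FALSE)
  idx <- function(a) match(a, atoms$name)
  for (k in seq_len(nrow(desc$bonds))) {
    a1 <- desc$bonds$atom1[k]; a2 <- desc$bonds$atom2[k]
    o <- desc$bonds$order[k]; ov <- order_value(o)
    for (pair in list(c(a1, a2), c(a2, a1))) {
      i <- idx(pair[1])
      env$degree[i] <- env$degree[i] + 1L
      env$max_order[i] <- max(env$max_order[i], ov)
      if (o == "double") env$n_double[i] <- env$n_double[i] + 1L
      if (o %in% c("aromatic", "deloc")) env$aromatic[i] <- TRUE
      if (atoms$element[idx(pair[2])] == "H")
        env$n_h[i] <- env$n_h[i] + 1L
    }
  }
  ring <- ring_atoms(desc)
  env$in_ring <- env$name %in% ring
  env$hyb <- ifelse(env$max_order >= 3 | env$n_double >= 2, "sp",
                    ifelse(env$aromatic | env$n_double >= 1, "sp2", "sp3"))
  # hypervalent third-row centres (phosphate P, sulfate-like S) stay
  # tetrahedral despite their formal double bonds
  env$hyb[env$element %in% c("P", "Se") |
            (env$element == "S" & env$degree >= 3L)] <- "sp3"
  # amide-style nitrogens: single-bonded N attached to a carbonyl carbon is
  # treated as sp2 (planar, conjugated)
  for (i in which(env$element == "N" & env$hyb == "sp3")) {
    nb <- neighbours_of(desc, env$name[i])
    for (b in nb) {
      j <- idx(b)
      if (atoms$element[j] == "C" && env$n_double[j] >= 1L) {
        dbl <- desc$bonds[desc$bonds$order == "double" &
                            (desc$bonds$atom1 == b | desc$bonds$atom2 == b), ]
        other <- ifelse(dbl$atom1 == b, dbl$atom2, dbl$atom1)
        if (any(atoms$element[idx(other)] == "O")) { env$hyb[i] <- "sp2"; break }
      }
    }
  }
  env
}

# Atoms that belong to at least one elementary cycle of the bond graph:
# an edge is a bridge iff removing it disconnects its endpoints; ring atoms
# are endpoints of non-bridge edges.
ring_atoms <- function(desc) {
  nm <- desc$atoms$name
  out <- character(0)
  for (k in seq_len(nrow(desc$bonds))) {
    rest <- desc$bonds[-k, , drop = FALSE]
    comp <- connected_components(nm, rest)
    i <- match(desc$bonds$atom1[k], nm); j <- match(desc$bonds$atom2[k], nm)
    if (comp[i] == comp[j]) out <- c(out, nm[i], nm[j])
  }
  unique(out)
}

#' Assign atom energy types
#'
#' Deterministically derives an energy type for every atom from its element,
#' hybridization (read off the bond orders), hydrogen count, formal charge
#' and ring membership.  The scheme follows the naming tradition of
#' refinement monomer libraries (CH1/CH2/CH3 for sp3 carbons by hydrogen
#' count, C for carbonyl carbons, CR/NR for aromatic ring atoms, NH1/NH2 for
#' planar N-H, NT/NT3 for sp3 amines, O/OH1/OS for oxygen environments).
#'
#' @param desc A [monomer_description()] with elements and bond orders set.
#' @param overwrite Recompute types even where already present.
#' @return The description with `energy_type` filled for every atom.
#' @export
assign_energy_types <- function(desc, overwrite = TRUE) {
  env <- atom_environment(desc)
  atoms <- desc$atoms
  for (i in seq_len(nrow(atoms))) {
    if (!overwrite && !is.na(atoms$energy_type[i])) next
    atoms$energy_type[i] <- energy_type_for(env[i, ], desc)
  }
  desc$atoms <- atoms
  desc
}

energy_type_for <- function(e, desc) {
  el <- toupper(e$element)
  if (!el %in% names(VALENCE))
    stop("cannot type atom '", e$name, "': element '", e$element,
         "' outside the valence table")
  switch(el,
    H = "H",
    C = {
      if (e$aromatic) "CR"
      else if (e$hyb == "sp") "CSP"
      else if (e$hyb == "sp2") {
        if (carbonyl_like(desc, e$name)) "C" else "C2"
      } else if (e$n_h >= 1L) paste0("CH", min(e$n_h, 3L)) else "CT"
    },
    N = {
      if (e$aromatic) "NR"
      else if (e$hyb == "sp") "NSP"
      else if (e$hyb == "sp2") {
        if (e$n_h >= 1L) paste0("NH", min(e$n_h, 2L)) else "N2"
      } else if (e$charge > 0L) "NT3" else "NT"
    },
    O = {
      if (e$max_order >= 2 || e$aromatic) "O"
      else if (e$n_h >= 1L) "OH1"
      else if (e$charge < 0L) "OC" else "OS"
    },
    S = if (e$n_h >= 1L) "SH1" else "S",
    P = "P",
    SE = "SE",
    el)
}

carbonyl_like <- function(desc, atom) {
  dbl <- desc$bonds[desc$bonds$order == "double" &
                      (desc$bonds$atom1 == atom | desc$bonds$atom2 == atom), ]
  if (!nrow(dbl)) return(FALSE)
  other <- ifelse(dbl$atom1 == atom, dbl$atom2, dbl$atom1)
  any(desc$atoms$element[match(other, desc$atoms$name)] == "O")
}
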