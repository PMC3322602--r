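# Standard valences of the elements the package models.  Formal charge
# shifts the effective valence by the charge (N+ -> 4, O- -> 1).
VALENCE <- c(H = 1L, C = 4L, N = 3L, O = 2L, P = 5L, S = 2L, SE = 2L,
             F = 1L, CL = 1L, BR = 1L, I = 1L)

effective_valence <- function(element, charge = 0L) {
  el <- toupper(element)
  if (!el %in% names(VALENCE))
    stop("no valence known for element '", element, "'")
  as.integer(VALENCE[[el]] + charge)
}

heavy_order_sum <- function(desc, atom) {
  b <- desc$bonds
  hit <- b$atom1 == atom | b$atom2 == atom
  other <- ifelse(b$atom1[hit] == atom, b$atom2[hit], b$atom1[hit])
  el <- desc$atoms$element[match(other, desc$atoms$name)]
  sum(order_value(b$order[hit][el != "H"]))
}

hydrogens_on <- function(desc, atom) {
  nb <- neighbours_of(desc, atom)
  nb[desc$atoms$element[match(nb, desc$atoms$name)] == "H"]
}

# Derive the suffix used to name hydrogens on a heavy atom: the heavy-atom
# name with its leading element symbol stripped (NZ -> "Z", C4A -> "4A",
# N -> "").
h_name_suffix <- function(name, element) {
  el <- toupper(element)
  if (toupper(substr(name, 1L, nchar(el))) == el)
    substring(name, nchar(el) + 1L)
  else name
}

hydrogen_names_for <- function(parent_name, element, n, taken) {
  suffix <- h_name_suffix(parent_name, element)
  out <- character(0)
  if (n == 1L) {
    cand <- paste0("H", suffix)
    if (nchar(cand) <= 4L && !cand %in% taken) return(cand)
  }
  k <- 1L
  while (length(out) < n) {
    cand <- paste0("H", suffix, k)
    while (nchar(cand) > 4L && nzchar(suffix)) {
      suffix <- substr(suffix, 1L, nchar(suffix) - 1L)
      cand <- paste0("H", suffix, k)
    }
    if (nchar(cand) > 4L) cand <- paste0("H", k)
    if (!cand %in% c(taken, out)) out <- c(out, cand)
    k <- k + 1L
  }
  out
}

#' Adjust explicit hydrogens to match heavy-atom valences
#'
#' For every heavy atom the expected hydrogen count is
#' `effective valence - floor(sum of bond orders to heavy neighbours)`,
#' with aromatic and delocalised bonds counted as 1.5 and the effective
#' valence shifted by the formal charge.  Surplus hydrogens are deleted
#' (highest name first) and missing ones added, named "H" plus the parent
#' heavy atom's suffix, numbered for uniqueness.  The returned edits are
#' exactly the automatic changes, suitable for journalling into a
#' modification entry.
#'
#' @param desc A [monomer_description()] whose heavy-atom graph is
#'   valence-consistent.
#' @return `list(desc = adjusted description, edits = list of graph_edit)`.
#'   Applying the function twice changes nothing further (idempotent).
#' @export
adjust_hydrogens <- function(desc) {
  edits <- list()
  # hydrogens orphaned by earlier heavy-atom deletions
  orphans <- Filter(function(a) !length(neighbours_of(desc, a)),
                    desc$atoms$name[desc$atoms$element == "H"])
  for (h in orphans) {
    e <- graph_edit("delete_atom", name = h)
    desc <- apply_edit(desc, e)
    edits <- c(edits, list(e))
  }
  heavy <- desc$atoms[desc$atoms$element != "H", , drop = FALSE]
  for (i in seq_len(nrow(heavy))) {
    a <- heavy$name[i]
    cap <- effective_valence(heavy$element[i], heavy$charge[i])
    want <- cap - floor(heavy_order_sum(desc, a) + 1e-9)
    if (want < 0)
      stop("over-valence at atom '", a, "': bond orders exceed valence ", cap)
    hs <- sort(hydrogens_on(desc, a))
    if (length(hs) > want) {
      for (h in rev(hs)[seq_len(length(hs) - want)]) {
        e <- graph_edit("delete_atom", name = h)
        desc <- apply_edit(desc, e)
        edits <- c(edits, list(e))
      }
    } else if (length(hs) < want) {
      new_names <- hydrogen_names_for(a, heavy$element[i],
                                      as.integer(want - length(hs)),
                                      desc$atoms$name)
      for (h in new_names) {
        e1 <- graph_edit("add_atom", name = h, element = "H", energy_type = "H")
        e2 <- graph_edit("add_bond", atom1 = a, atom2 = h, order = "single")
        desc <- apply_edit(desc, e1)
        desc <- apply_edit(desc, e2)
        edits <- c(edits, list(e1, e2))
      }
    }
  }
  list(desc = desc, edits = edits)
}
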