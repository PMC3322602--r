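# ---- built-in fragment library ---------------------------------------------

mk_atoms <- function(spec) {
  # spec: list of c(name, element) or c(name, element, charge)
  do.call(rbind, lapply(spec, function(s)
    data.frame(name = s[[1]], element = s[[2]],
               energy_type = NA_character_,
               charge = if (length(s) > 2L) as.integer(s[[3]]) else 0L,
               parent_ref = s[[1]], stringsAsFactors = FALSE)))
}

mk_bonds <- function(spec) {
  # spec: list of c(atom1, atom2) or c(atom1, atom2, order)
  do.call(rbind, lapply(spec, function(s)
    data.frame(atom1 = s[[1]], atom2 = s[[2]],
               order = if (length(s) > 2L) s[[3]] else "single",
               target = NA_real_, sigma = NA_real_, stringsAsFactors = FALSE)))
}

mk_chirals <- function(spec) {
  # spec: list of c(centre, a1, a2, a3, sign)
  if (!length(spec)) return(empty_chirals())
  do.call(rbind, lapply(spec, function(s)
    data.frame(id = paste0("chir_", s[[1]]), centre = s[[1]], atom1 = s[[2]],
               atom2 = s[[3]], atom3 = s[[4]], sign = s[[5]],
               stringsAsFactors = FALSE)))
}

backbone_atoms <- function() list(
  c("N", "N"), c("H", "H"), c("H2", "H"), c("CA", "C"), c("C", "C"),
  c("O", "O"), c("OXT", "O"), c("HXT", "H"))

backbone_bonds <- function() list(
  c("N", "H"), c("N", "H2"), c("N", "CA"), c("CA", "C"),
  c("C", "O", "double"), c("C", "OXT"), c("OXT", "HXT"))

fixture_gly <- function() monomer_description(
  "GLY", "glycine", group = "peptide",
  atoms = mk_atoms(c(backbone_atoms(), list(c("HA1", "H"), c("HA2", "H")))),
  bonds = mk_bonds(c(backbone_bonds(), list(c("CA", "HA1"), c("CA", "HA2")))))

fixture_ala <- function() monomer_description(
  "ALA", "alanine", group = "peptide",
  atoms = mk_atoms(c(backbone_atoms(), list(
    c("HA", "H"), c("CB", "C"), c("HB1", "H"), c("HB2", "H"), c("HB3", "H")))),
  bonds = mk_bonds(c(backbone_bonds(), list(
    c("CA", "HA"), c("CA", "CB"), c("CB", "HB1"), c("CB", "HB2"), c("CB", "HB3")))),
  chirals = mk_chirals(list(c("CA", "C", "CB", "N", "negative"))))

fixture_cys <- function() monomer_description(
  "CYS", "cysteine", group = "peptide",
  atoms = mk_atoms(c(backbone_atoms(), list(
    c("HA", "H"), c("CB", "C"), c("HB1", "H"), c("HB2", "H"),
    c("SG", "S"), c("HG", "H")))),
  bonds = mk_bonds(c(backbone_bonds(), list(
    c("CA", "HA"), c("CA", "CB"), c("CB", "HB1"), c("CB", "HB2"),
    c("CB", "SG"), c("SG", "HG")))),
  chirals = mk_chirals(list(c("CA", "C", "CB", "N", "negative"))))

fixture_lys <- function() monomer_description(
  "LYS", "lysine (protonated side-chain amine)", group = "peptide",
  atoms = mk_atoms(c(backbone_atoms(), list(
    c("HA", "H"), c("CB", "C"), c("HB1", "H"), c("HB2", "H"),
    c("CG", "C"), c("HG1", "H"), c("HG2", "H"),
    c("CD", "C"), c("HD1", "H"), c("HD2", "H"),
    c("CE", "C"), c("HE1", "H"), c("HE2", "H"),
    c("NZ", "N", 1L), c("HZ1", "H"), c("HZ2", "H"), c("HZ3", "H")))),
  bonds = mk_bonds(c(backbone_bonds(), list(
    c("CA", "HA"), c("CA", "CB"), c("CB", "HB1"), c("CB", "HB2"),
    c("CB", "CG"), c("CG", "HG1"), c("CG", "HG2"), c("CG", "CD"),
    c("CD", "HD1"), c("CD", "HD2"), c("CD", "CE"), c("CE", "HE1"),
    c("CE", "HE2"), c("CE", "NZ"), c("NZ", "HZ1"), c("NZ", "HZ2"),
    c("NZ", "HZ3")))),
  chirals = mk_chirals(list(c("CA", "C", "CB", "N", "negative"))))

# pyridoxal-5'-phosphate with the aldehyde oxygen O4A on C4A
fixture_plp <- function() monomer_description(
  "PLP", "pyridoxal-5'-phosphate", group = "non-polymer",
  atoms = mk_atoms(list(
    c("N1", "N"), c("C2", "C"), c("C2A", "C"),
    c("H2A1", "H"), c("H2A2", "H"), c("H2A3", "H"),
    c("C3", "C"), c("O3", "O"), c("HO3", "H"),
    c("C4", "C"), c("C4A", "C"), c("O4A", "O"), c("H4A", "H"),
    c("C5", "C"), c("C5A", "C"), c("H5A1", "H"), c("H5A2", "H"),
    c("C6", "C"), c("H6", "H"),
    c("O4P", "O"), c("P", "P"), c("O1P", "O"),
    c("O2P", "O"), c("HOP2", "H"), c("O3P", "O"), c("HOP3", "H"))),
  bonds = mk_bonds(list(
    c("N1", "C2", "aromatic"), c("C2", "C3", "aromatic"),
    c("C3", "C4", "aromatic"), c("C4", "C5", "aromatic"),
    c("C5", "C6", "aromatic"), c("C6", "N1", "aromatic"),
    c("C2", "C2A"), c("C2A", "H2A1"), c("C2A", "H2A2"), c("C2A", "H2A3"),
    c("C3", "O3"), c("O3", "HO3"),
    c("C4", "C4A"), c("C4A", "O4A", "double"), c("C4A", "H4A"),
    c("C5", "C5A"), c("C5A", "H5A1"), c("C5A", "H5A2"),
    c("C5A", "O4P"), c("O4P", "P"), c("P", "O1P", "double"),
    c("P", "O2P"), c("O2P", "HOP2"), c("P", "O3P"), c("O3P", "HOP3"),
    c("C6", "H6"))))

# alpha-D-glucopyranose-like sugar; chirality signs are the package's own
# internally consistent encoding of the alpha-D configuration
fixture_glc <- function() monomer_description(
  "GLC", "alpha-D-glucopyranose", group = "pyranose",
  atoms = mk_atoms(list(
    c("C1", "C"), c("H1", "H"), c("O1", "O"), c("HO1", "H"),
    c("C2", "C"), c("H2", "H"), c("O2", "O"), c("HO2", "H"),
    c("C3", "C"), c("H3", "H"), c("O3", "O"), c("HO3", "H"),
    c("C4", "C"), c("H4", "H"), c("O4", "O"), c("HO4", "H"),
    c("C5", "C"), c("H5", "H"), c("O5", "O"),
    c("C6", "C"), c("H61", "H"), c("H62", "H"), c("O6", "O"), c("HO6", "H"))),
  bonds = mk_bonds(list(
    c("C1", "C2"), c("C2", "C3"), c("C3", "C4"), c("C4", "C5"),
    c("C5", "O5"), c("O5", "C1"),
    c("C1", "H1"), c("C1", "O1"), c("O1", "HO1"),
    c("C2", "H2"), c("C2", "O2"), c("O2", "HO2"),
    c("C3", "H3"), c("C3", "O3"), c("O3", "HO3"),
    c("C4", "H4"), c("C4", "O4"), c("O4", "HO4"),
    c("C5", "H5"), c("C5", "C6"),
    c("C6", "H61"), c("C6", "H62"), c("C6", "O6"), c("O6", "HO6"))),
  chirals = mk_chirals(list(
    c("C1", "C2", "O1", "O5", "positive"),
    c("C2", "C1", "C3", "O2", "negative"),
    c("C3", "C2", "C4", "O3", "positive"),
    c("C4", "C3", "C5", "O4", "negative"),
    c("C5", "C4", "C6", "O5", "positive"))))

mod_del_atoms <- function(id, parent, group, atoms, name = "") {
  modification_entry(id, parent = parent, group = group, name = name,
                     atoms = do.call(rbind, lapply(atoms, function(a)
                       data.frame(fun = "delete", atom_id = a,
                                  new_atom_id = NA_character_,
                                  new_type_symbol = NA_character_,
                                  new_type_energy = NA_character_,
                                  new_charge = NA_integer_,
                                  stringsAsFactors = FALSE))))
}

fixture_links <- function() {
  trans <- link_entry(
    "TRANS", comp1 = "", mod1 = "DEL-OXT", group1 = "peptide",
    comp2 = "", mod2 = "NH1", group2 = "peptide",
    name = "trans peptide bond",
    bonds = data.frame(comp1 = 1L, atom1 = "C", comp2 = 2L, atom2 = "N",
                       order = "single", target = 1.329, sigma = 0.02,
                       stringsAsFactors = FALSE),
    angles = data.frame(
      comp1 = c(1L, 1L, 1L, 1L), atom1 = c("CA", "O", "C", "C"),
      comp2 = c(1L, 1L, 2L, 2L), atom2 = c("C", "C", "N", "N"),
      comp3 = c(2L, 2L, 2L, 2L), atom3 = c("N", "N", "CA", "H"),
      target = c(116.2, 123.0, 121.7, 119.15),
      sigma = c(2.0, 1.6, 1.8, 3.0), stringsAsFactors = FALSE),
    torsions = data.frame(
      id = "omega", comp1 = 1L, atom1 = "CA", comp2 = 1L, atom2 = "C",
      comp3 = 2L, atom3 = "N", comp4 = 2L, atom4 = "CA",
      target = 180, sigma = 5, period = 1L, stringsAsFactors = FALSE),
    planes = data.frame(
      plane_id = "plan-l1", comp = c(1L, 1L, 1L, 2L, 2L, 2L),
      atom_id = c("CA", "C", "O", "N", "H", "CA"), dist_esd = 0.02,
      stringsAsFactors = FALSE))
  ss <- link_entry(
    "SS", comp1 = "CYS", mod1 = "DEL-HG", group1 = "peptide",
    comp2 = "CYS", mod2 = "DEL-HG", group2 = "peptide",
    name = "disulfide bridge",
    bonds = data.frame(comp1 = 1L, atom1 = "SG", comp2 = 2L, atom2 = "SG",
                       order = "single", target = 2.031, sigma = 0.02,
                       stringsAsFactors = FALSE),
    angles = data.frame(
      comp1 = c(1L, 1L), atom1 = c("CB", "SG"),
      comp2 = c(1L, 2L), atom2 = c("SG", "SG"),
      comp3 = c(2L, 2L), atom3 = c("SG", "CB"),
      target = c(104.0, 104.0), sigma = 3.0, stringsAsFactors = FALSE),
    torsions = data.frame(
      id = "chi_ss", comp1 = 1L, atom1 = "CB", comp2 = 1L, atom2 = "SG",
      comp3 = 2L, atom3 = "SG", comp4 = 2L, atom4 = "CB",
      target = 90, sigma = 10, period = 2L, stringsAsFactors = FALSE))
  alpha14 <- link_entry(
    "ALPHA1-4", comp1 = "", mod1 = "DEL-O1", group1 = "pyranose",
    comp2 = "", mod2 = "DEL-HO4", group2 = "pyranose",
    name = "alpha 1->4 glycosidic bond",
    bonds = data.frame(comp1 = 1L, atom1 = "C1", comp2 = 2L, atom2 = "O4",
                       order = "single", target = 1.41, sigma = 0.02,
                       stringsAsFactors = FALSE),
    angles = data.frame(
      comp1 = c(1L, 1L, 1L), atom1 = c("O5", "C2", "C1"),
      comp2 = c(1L, 1L, 2L), atom2 = c("C1", "C1", "O4"),
      comp3 = c(2L, 2L, 2L), atom3 = c("O4", "O4", "C4"),
      target = c(112.0, 109.5, 117.0), sigma = 3.0, stringsAsFactors = FALSE),
    chirals = data.frame(
      id = "chir_C1", comp_centre = 1L, centre = "C1",
      comp1 = 1L, atom1 = "C2", comp2 = 2L, atom2 = "O4",
      comp3 = 1L, atom3 = "O5", sign = "positive", stringsAsFactors = FALSE))
  list(TRANS = trans, SS = ss, `ALPHA1-4` = alpha14)
}

#' Built-in fragment library
#'
#' A small, self-contained restraint library: complete descriptions of
#' GLY, ALA, CYS, LYS, PLP (with its aldehyde oxygen O4A) and a pyranose
#' sugar, plus generic modifications (DEL-OXT, NH1, DEL-O1, DEL-HO4,
#' DEL-HG) and links (a trans-peptide link, a disulfide link and an
#' alpha-1,4 glycosidic link).  The chemistry is hand-encoded from the
#' standard structures of these compounds so that the package is fully
#' testable without any external dictionary.
#'
#' @param complete Complete the monomer descriptions against `table`
#'   (default) or return them at minimal level.
#' @param table A [parameter_table()].
#' @return A [restraint_library()] with provenance "standard".
#' @export
builtin_fragments <- function(complete = TRUE,
                              table = builtin_parameter_table()) {
  mons <- list(fixture_gly(), fixture_ala(), fixture_cys(), fixture_lys(),
               fixture_plp(), fixture_glc())
  names(mons) <- vapply(mons, function(m) m$code, character(1))
  if (complete) mons <- lapply(mons, complete_description, table = table)
  mods <- list(
    `DEL-OXT` = mod_del_atoms("DEL-OXT", ".", "peptide", c("OXT", "HXT"),
                              "C-terminal carboxyl oxygen removal"),
    `NH1` = mod_del_atoms("NH1", ".", "peptide", "H2",
                          "amino-group hydrogen removal for peptide bond"),
    `DEL-O1` = mod_del_atoms("DEL-O1", ".", "pyranose", c("O1", "HO1"),
                             "anomeric hydroxyl removal"),
    `DEL-HO4` = mod_del_atoms("DEL-HO4", ".", "pyranose", "HO4",
                              "O4 hydroxyl hydrogen removal"),
    `DEL-HG` = mod_del_atoms("DEL-HG", "CYS", "peptide", "HG",
                             "thiol hydrogen removal"))
  restraint_library(monomers = mons, modifications = mods,
                    links = fixture_links(), provenance = "standard")
}

# ---- random molecule generator ---------------------------------------------

#' Generate a random valence-valid molecule
#'
#' Grows a random connected tree over C/N/O/S heavy atoms (each new atom
#' attaches to a previously placed atom with free valence), then fills the
#' open valences with hydrogens.  Deterministic per seed; every generated
#' molecule passes [validate_monomer()].  Intended as a property-test input
#' generator.
#'
#' @param seed Integer seed.
#' @param n_heavy Number of heavy atoms (2..30).
#' @param code Compound code for the result.
#' @return A minimal [monomer_description()].
#' @export
random_molecule <- function(seed, n_heavy, code = "RND") {
  stopifnot(n_heavy >= 2L, n_heavy <= 30L)
  rng <- local_rng(seed)
  elements <- c("C", "N", "O", "S")
  weights <- c(0.62, 0.16, 0.16, 0.06)
  pick_el <- function() elements[findInterval(rng(1), cumsum(weights)) + 1L]
  counts <- stats::setNames(integer(4), elements)
  nm_for <- function(el) {
    counts[el] <<- counts[el] + 1L
    paste0(el, counts[el])
  }
  el1 <- pick_el()
  atoms <- list(c(nm_for(el1), el1))
  bonds <- list()
  free <- stats::setNames(effective_valence(el1), atoms[[1]][1])
  for (i in seq_len(n_heavy - 1L)) {
    open <- names(free)[free >= 1L]
    if (!length(open)) break
    host <- open[1L + floor(rng(1) * length(open))]
    el <- pick_el()
    # never attach a new heavy atom to something that cannot take it
    if (effective_valence(el) < 1L) next
    nm <- nm_for(el)
    atoms[[length(atoms) + 1L]] <- c(nm, el)
    bonds[[length(bonds) + 1L]] <- c(host, nm)
    free[host] <- free[host] - 1L
    free[nm] <- effective_valence(el) - 1L
  }
  desc <- monomer_description(code, "random molecule",
                              atoms = mk_atoms(atoms), bonds = mk_bonds(bonds))
  desc <- adjust_hydrogens(desc)$desc
  desc$journal <- list()   # generator output is a fresh molecule, not an edit
  desc
}

# ---- library-design combinatorics -------------------------------------------

#' Construct a library design scheme
#'
#' Describes how a dictionary could represent polymers built from
#' `n_monomers` residue types occurring in `positions` chain contexts
#' (e.g. N-terminal / internal / C-terminal) and `conformations` backbone
#' conformations (e.g. cis / trans): either by enumerating one monomer
#' entry per combination ("monomer_only") or by storing each monomer once
#' plus a small set of generic modifications and links ("link_mod").
#'
#' @param scheme "monomer_only" or "link_mod".
#' @param n_monomers Number of distinct residue types.
#' @param positions Number of chain contexts.
#' @param conformations Number of conformations.
#' @param n_generic_mods,n_generic_links Entry counts for the link/mod
#'   scheme.
#' @return Object of class `design_scheme`.
#' @export
design_scheme <- function(scheme = c("monomer_only", "link_mod"),
                          n_monomers, positions = 1L, conformations = 1L,
                          n_generic_mods = 0L, n_generic_links = 0L) {
  scheme <- match.arg(scheme)
  stopifnot(n_monomers >= 0, positions >= 0, conformations >= 0,
            positions * conformations >= 1, n_generic_mods >= 0,
            n_generic_links >= 0)
  structure(list(scheme = scheme, n_monomers = n_monomers,
                 positions = positions, conformations = conformations,
                 n_generic_mods = n_generic_mods,
                 n_generic_links = n_generic_links),
            class = "design_scheme")
}

#' Count library entries required by a design scheme
#'
#' Under the monomer-only scheme every residue needs one entry per
#' (position, conformation) combination; under the link/modification scheme
#' each residue is stored once and the combinatorics are carried by a fixed
#' number of generic modification and link entries.
#'
#' @param ds A [design_scheme()].
#' @return Integer entry count.
#' @export
count_design_entries <- function(ds) {
  stopifnot(inherits(ds, "design_scheme"))
  if (ds$scheme == "monomer_only")
    as.integer(ds$n_monomers * ds$positions * ds$conformations)
  else
    as.integer(ds$n_monomers + ds$n_generic_mods + ds$n_generic_links)
}
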