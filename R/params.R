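# Covalent radii (angstrom), single-bond values.
COVALENT_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, P = 1.07,
                    S = 1.05, SE = 1.20, F = 0.57, CL = 1.02, BR = 1.20,
                    I = 1.39)

covalent_radius <- function(element) {
  el <- toupper(element)
  if (!el %in% names(COVALENT_RADII))
    stop("no covalent radius for element '", element, "'")
  unname(COVALENT_RADII[el])
}

#' Construct a restraint parameter table
#'
#' A parameter table keys target values and sigmas for bond and angle
#' restraints on atom energy types, with element-pair and geometric
#' fallbacks so that every lookup resolves.  Lookups are symmetric under
#' reversal of the type key.
#'
#' @param bonds Data frame (type1, type2, order, target, sigma) of
#'   energy-type keyed bond targets.
#' @param angles Data frame (type1, type2, type3, target, sigma); type2 is
#'   the vertex.
#' @param element_bonds Data frame (el1, el2, order, target, sigma) fallback.
#' @param defaults List with `bond_sigma`, `angle_sigma`, `torsion_sigma`,
#'   `plane_esd` and the per-hybridization default angles.
#' @return An object of class `parameter_table`.
#' @export
parameter_table <- function(bonds, angles, element_bonds,
                            defaults = list(bond_sigma = 0.02,
                                            angle_sigma = 3.0,
                                            torsion_sigma = 15.0,
                                            plane_esd = 0.02,
                                            angle_sp3 = 109.47,
                                            angle_sp2 = 120.0,
                                            angle_sp = 180.0)) {
  structure(list(bonds = bonds, angles = angles,
                 element_bonds = element_bonds, defaults = defaults),
            class = "parameter_table")
}

# Scale factors applied to the covalent-radius sum when deriving a bond
# target geometrically (last-resort fallback).
ORDER_SCALE <- c(single = 1.00, double = 0.87, triple = 0.78,
                 aromatic = 0.93, deloc = 0.93)

#' Look up a bond target
#'
#' Fallback chain: exact energy-type pair -> element pair -> covalent-radius
#' sum scaled by bond order.  The level actually used is returned so callers
#' can report fallback use.
#'
#' @param table A [parameter_table()].
#' @param type1,type2 Atom energy types.
#' @param el1,el2 Elements of the two atoms.
#' @param order Bond order string.
#' @return List with `target`, `sigma`, `level` ("typed", "element",
#'   "radii").
#' @export
lookup_bond <- function(table, type1, type2, el1, el2, order = "single") {
  b <- table$bonds
  hit <- which((b$type1 == type1 & b$type2 == type2 |
                  b$type1 == type2 & b$type2 == type1) & b$order == order)
  if (length(hit))
    return(list(target = b$target[hit[1]], sigma = b$sigma[hit[1]], level = "typed"))
  eb <- table$element_bonds
  E1 <- toupper(el1); E2 <- toupper(el2)
  hit <- which((eb$el1 == E1 & eb$el2 == E2 | eb$el1 == E2 & eb$el2 == E1) &
                 eb$order == order)
  if (length(hit))
    return(list(target = eb$target[hit[1]], sigma = eb$sigma[hit[1]], level = "element"))
  tgt <- (covalent_radius(el1) + covalent_radius(el2)) * ORDER_SCALE[[order]]
  list(target = tgt, sigma = table$defaults$bond_sigma, level = "radii")
}

#' Look up an angle target
#'
#' Fallback chain: exact energy-type triple (symmetric in the outer types)
#' -> default angle for the hybridization of the vertex atom.
#'
#' @param table A [parameter_table()].
#' @param type1,type2,type3 Energy types; `type2` is the vertex.
#' @param hyb2 Hybridization of the vertex ("sp3", "sp2", "sp").
#' @return List with `target`, `sigma`, `level` ("typed", "hybrid").
#' @export
lookup_angle <- function(table, type1, type2, type3, hyb2 = "sp3") {
  a <- table$angles
  hit <- which(a$type2 == type2 &
                 (a$type1 == type1 & a$type3 == type3 |
                    a$type1 == type3 & a$type3 == type1))
  if (length(hit))
    return(list(target = a$target[hit[1]], sigma = a$sigma[hit[1]], level = "typed"))
  tgt <- switch(hyb2, sp = table$defaults$angle_sp,
                sp2 = table$defaults$angle_sp2, table$defaults$angle_sp3)
  list(target = tgt, sigma = table$defaults$angle_sigma, level = "hybrid")
}

#' Built-in parameter table
#'
#' Ships energy-type keyed bond and angle targets in the Engh & Huber
#' tradition for the peptide and cofactor chemistry covered by the built-in
#' fragment library, plus element-pair fallbacks.  Values are data, not
#' code: the table can be replaced wholesale.
#'
#' @return A [parameter_table()].
#' @export
builtin_parameter_table <- function() {
  B <- function(t1, t2, order, target, sigma = 0.02)
    data.frame(type1 = t1, type2 = t2, order = order, target = target,
               sigma = sigma, stringsAsFactors = FALSE)
  bonds <- rbind(
    B("C", "O", "double", 1.231),       # carbonyl
    B("C", "OH1", "single", 1.304),     # carboxylic acid C-OH
    B("C", "NH1", "single", 1.329),     # amide C-N
    B("C", "NH2", "single", 1.328),
    B("C", "CH1", "single", 1.525),     # C(=O)-CA
    B("C", "CH2", "single", 1.516),
    B("CH1", "NH1", "single", 1.458),   # CA-N (amide)
    B("CH2", "NH1", "single", 1.455),
    B("CH1", "NT", "single", 1.475),
    B("CH2", "NT", "single", 1.475),
    B("CH1", "CH2", "single", 1.530),
    B("CH1", "CH3", "single", 1.521),
    B("CH2", "CH2", "single", 1.524),
    B("CH2", "CH3", "single", 1.513),
    B("CH2", "NT3", "single", 1.489),   # CE-NZ of lysine
    B("CH2", "SH1", "single", 1.808),   # CB-SG
    B("SH1", "SH1", "single", 2.031),
    B("S", "S", "single", 2.031),       # disulfide
    B("CH2", "S", "single", 1.808),
    B("CR", "CR", "aromatic", 1.390),
    B("CR", "NR", "aromatic", 1.337),
    B("CR", "CH3", "single", 1.498),
    B("CR", "CH2", "single", 1.502),
    B("CR", "C2", "single", 1.470),     # ring-conjugated sp2 substituent
    B("CR", "OH1", "single", 1.362),    # phenolic C-OH
    B("CR", "H", "single", 1.083),
    B("C2", "O", "double", 1.220),      # aldehyde C=O
    B("C2", "NT3", "double", 1.280),    # protonated Schiff base C=N
    B("C2", "N2", "double", 1.280),
    B("C2", "H", "single", 1.083),
    B("CH2", "OS", "single", 1.426),    # C-O ester/ether
    B("CH1", "OS", "single", 1.426),
    B("CH1", "OH1", "single", 1.432),
    B("CH2", "OH1", "single", 1.432),
    B("P", "OS", "single", 1.610),
    B("P", "OP", "double", 1.480),
    B("P", "OH1", "single", 1.570),
    B("CH1", "H", "single", 1.099),
    B("CH2", "H", "single", 1.092),
    B("CH3", "H", "single", 1.059),
    B("NH1", "H", "single", 1.010),
    B("NH2", "H", "single", 1.010),
    B("NT", "H", "single", 1.018),
    B("NT3", "H", "single", 1.040),
    B("OH1", "H", "single", 0.967),
    B("SH1", "H", "single", 1.338)
  )
  A <- function(t1, t2, t3, target, sigma = 3.0)
    data.frame(type1 = t1, type2 = t2, type3 = t3, target = target,
               sigma = sigma, stringsAsFactors = FALSE)
  angles <- rbind(
    A("CH1", "C", "O", 120.8, 1.7),
    A("CH2", "C", "O", 120.8, 1.7),
    A("CH1", "C", "OH1", 112.4, 1.7),
    A("CH2", "C", "OH1", 112.4, 1.7),
    A("O", "C", "OH1", 126.8, 1.7),     # closes the carboxyl to 360
    A("CH1", "C", "NH1", 116.2, 2.0),
    A("CH2", "C", "NH1", 116.2, 2.0),
    A("O", "C", "NH1", 123.0, 1.6),
    A("C", "NH1", "CH1", 121.7, 1.8),
    A("C", "NH1", "CH2", 121.7, 1.8),
    A("C", "NH1", "H", 119.15, 3.0),
    A("CH1", "NH1", "H", 119.15, 3.0),
    A("CH2", "NH1", "H", 119.15, 3.0),
    # pyridine-like aromatic ring: uniform 120 deg cannot close a hexagon
    # with unequal C-C and C-N bond lengths, so ring angles follow the
    # pyridine geometry and substituent angles bisect the remainder
    A("CR", "NR", "CR", 117.0, 2.0),
    A("NR", "CR", "CR", 123.8, 2.0),
    A("CR", "CR", "CR", 118.45, 2.0),
    A("NR", "CR", "CH3", 118.1, 3.0),
    A("NR", "CR", "H", 118.1, 3.0),
    A("CR", "CR", "H", 118.1, 3.0),
    A("CR", "CR", "CH3", 118.1, 3.0),
    A("CR", "CR", "OH1", 120.75, 3.0),
    A("CR", "CR", "CH2", 120.75, 3.0),
    A("CR", "CR", "C", 120.75, 3.0),
    A("CR", "CR", "C2", 120.75, 3.0)
  )
  EB <- function(e1, e2, order, target, sigma = 0.03)
    data.frame(el1 = e1, el2 = e2, order = order, target = target,
               sigma = sigma, stringsAsFactors = FALSE)
  element_bonds <- rbind(
    EB("C", "C", "single", 1.530), EB("C", "C", "double", 1.340),
    EB("C", "C", "triple", 1.200), EB("C", "C", "aromatic", 1.390),
    EB("C", "N", "single", 1.470), EB("C", "N", "double", 1.280),
    EB("C", "N", "aromatic", 1.337),
    EB("C", "O", "single", 1.430), EB("C", "O", "double", 1.230),
    EB("C", "S", "single", 1.810), EB("S", "S", "single", 2.031),
    EB("C", "H", "single", 1.090), EB("N", "H", "single", 1.010),
    EB("O", "H", "single", 0.970), EB("S", "H", "single", 1.338),
    EB("P", "O", "single", 1.610), EB("P", "O", "double", 1.480),
    EB("N", "N", "single", 1.450), EB("O", "O", "single", 1.480)
  )
  parameter_table(bonds = bonds, angles = angles, element_bonds = element_bonds)
}
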