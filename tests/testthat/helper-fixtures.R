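# Shared helpers: tiny molecules built in code, and a deterministic sampler
# of legal link-bond compositions over the built-in fragment library.

FIXTURE_LIB <- builtin_fragments()
PARAM_TABLE <- builtin_parameter_table()

# ethanol: the smallest molecule with sp3 carbons, a hydroxyl and hydrogens
make_ethanol <- function() {
  d <- monomer_description(
    "ETH", "ethanol",
    atoms = data.frame(
      name = c("C1", "C2", "O1", "H11", "H12", "H13", "H21", "H22", "HO1"),
      element = c("C", "C", "O", "H", "H", "H", "H", "H", "H"),
      stringsAsFactors = FALSE),
    bonds = data.frame(
      atom1 = c("C1", "C2", "C1", "C1", "C1", "C2", "C2", "O1"),
      atom2 = c("C2", "O1", "H11", "H12", "H13", "H21", "H22", "HO1"),
      order = "single", target = NA_real_, sigma = NA_real_,
      stringsAsFactors = FALSE))
  d
}

# linear heavy-atom chain A-B-C (no hydrogens), useful for enumeration tests
make_chain3 <- function() {
  monomer_description(
    "CH3X", "chain",
    atoms = data.frame(name = c("A", "B", "C"), element = "C",
                       stringsAsFactors = FALSE),
    bonds = data.frame(atom1 = c("A", "B"), atom2 = c("B", "C"),
                       order = "single", target = NA_real_, sigma = NA_real_,
                       stringsAsFactors = FALSE))
}

# heavy atoms of a monomer that carry at least one hydrogen (legal single
# link-bond endpoints: the new bond displaces one H)
link_candidates <- function(m) {
  heavy <- m$atoms$name[m$atoms$element != "H"]
  Filter(function(a) {
    nb <- c(m$bonds$atom2[m$bonds$atom1 == a], m$bonds$atom1[m$bonds$atom2 == a])
    any(m$atoms$element[match(nb, m$atoms$name)] == "H")
  }, heavy)
}

# deterministic random composition over the fixture library
sample_composition <- function(seed) {
  codes <- names(FIXTURE_LIB$monomers)
  set.seed(seed)
  cA <- sample(codes, 1); cB <- sample(codes, 1)
  mA <- FIXTURE_LIB$monomers[[cA]]; mB <- FIXTURE_LIB$monomers[[cB]]
  aA <- sample(link_candidates(mA), 1)
  aB <- sample(link_candidates(mB), 1)
  list(monA = mA, monB = mB, bond = list(aA, aB, "single"))
}

# run compose -> regularize -> split(lossless) -> apply_link and compare
run_roundtrip <- function(case, seed = 1) {
  ses <- compose_session(case$monA, case$monB, case$bond)
  ses <- regularize_session(ses, PARAM_TABLE, seed = seed)
  parts <- split_session(ses, PARAM_TABLE, sigma_multiplier = 0)
  out <- apply_link(complete_description(case$monA, PARAM_TABLE),
                    complete_description(case$monB, PARAM_TABLE),
                    parts$mod1, parts$mod2, parts$link)
  composites_equal(ses$composite, ses$map, out$desc, out$map)
}

# a small constructed PDB header with LINK/LINKR records
make_link_header <- function() {
  fmt <- function(a1, r1, c1, s1, a2, r2, c2, s2, dist) {
    sprintf("LINK        %-4s %3s %1s%4d                %-4s %3s %1s%4d   %6s %6s %5.2f",
            a1, r1, c1, s1, a2, r2, c2, s2, "1555", "1555", dist)
  }
  c("HEADER    OXIDOREDUCTASE                          01-JAN-10   1ABC",
    fmt("CB", "TYR", "A", 120, "ND1", "HIS", "A", 64, 1.53),
    fmt("C", "TYR", "A", 33, "N", "SER", "A", 34, 1.33),
    fmt("SG", "CYS", "A", 6, "SG", "CYS", "A", 127, 2.04),
    fmt("ND1", "HIS", "B", 64, "CB", "TYR", "B", 120, 1.52),
    fmt("C1", "NAG", "A", 201, "ND2", "ASN", "A", 52, 1.45),
    paste0("LINKR       C1   GLC A 301                ",
           "O4   GLC A 302                ALPHA1-4"),
    "ATOM      1  N   MET A   1      11.104   6.134  -6.504  1.00 10.00           N")
}
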