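Package: linksmith
Title: Template-Restraint Dictionaries for Covalently Linked Monomers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building and editing template-restraint dictionaries
    of the kind used in macromolecular refinement. Reads and writes the
    monomer-library CIF dialect (monomer, modification and link entries),
    edits molecular graphs with parent-atom provenance, completes minimal
    descriptions into full restraint sets (bonds, angles, torsions, chiral
    centres, planar groups) from an atom-energy-type parameter table,
    idealizes coordinates against those restraints, and turns two covalently
    joined monomers into two modification entries plus one link entry
    suitable for refinement. Also parses PDB-header LINK records and
    implements the exclusion/tally procedure used to survey covalent
    linkages between amino acids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
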