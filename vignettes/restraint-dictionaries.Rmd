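---
title: "Template-restraint dictionaries for linked monomers: models and methods"
author: "linksmith"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-restraint dictionaries for linked monomers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linksmith)
```

## The problem

Macromolecular refinement programs restrain model geometry against a
dictionary of template restraints.  Such a dictionary holds three kinds of
entries: **monomers** (the molecular graph of one compound plus target
values for bonds, angles, torsions, chiral centres and planar groups),
**modifications** (add/delete/change edits against a named monomer, e.g.
removal of the C-terminal carboxyl oxygen), and **links** (the
cross-monomer restraints that join two modified monomers, e.g. the trans
peptide bond or a glycosidic linkage).  The factorization matters: to
describe every position (N-terminal, internal, C-terminal) and backbone
conformation (cis, trans) of 20 amino acids with stand-alone monomer
entries would take 20 x 3 x 2 = 120 entries, while the link/modification
mechanism needs the 20 monomers plus two generic modifications and two
generic links - 24 entries.  `count_design_entries()` computes exactly this
bookkeeping.

When a structure contains a covalent linkage the standard dictionary does
not describe - a Schiff base between a lysine and its pyridoxal-5'-phosphate
cofactor, an engineered cross-link, an unusual glycan - the missing
restraints go into a user-side *additional library* whose entries shadow
same-named standard entries during refinement.  This package implements the
computational core of generating such entries: molecular-graph editing with
provenance, restraint completion from an atom-energy-type parameter table,
restrained idealization of coordinates, and the algorithm that turns a
composite of two covalently joined monomers into two modification entries
plus one link entry.

## Descriptions, completion and the parameter table

A *minimal* description carries the graph (atoms, elements, formal charges,
bond orders), atom names and declared chiralities.  A *complete*
description adds targets and sigmas for every bond and angle, one torsion
per rotatable non-ring bond, chiral-centre signs, and planar groups.
`complete_description()` performs the extension:

* every atom receives a deterministic **energy type** from its element,
  hybridization, hydrogen count, charge and ring membership (`CH2`, `C`,
  `CR`, `NH1`, `OH1`, ... in the naming tradition of refinement monomer
  libraries).  Hypervalent third-row centres (phosphate P, sulfate-like S)
  are treated as tetrahedral regardless of their formal double bonds.
* angles are enumerated as one restraint per bonded path of length two;
  torsions as one per rotatable central bond (end atoms chosen by highest
  atomic number, then name; period 2 with target 180 degrees between sp2
  atoms, period 3 otherwise; ring bonds carry no torsion - ring geometry is
  already fixed by bonds, angles and planes);
* chiral centres are detected at tetravalent atoms with at least three
  heavy substituents; declared signs are kept, new centres default to
  "both" (no handedness imposed);
* planar groups cover each sp2 atom with its bonded neighbours, merged when
  sharing two or more atoms (so an aromatic ring with a conjugated
  substituent becomes one plane);
* targets come from the built-in `parameter_table()` through a fallback
  chain: exact energy-type key, then element pair, then covalent-radius
  geometry.  Fallback uses are reported, never fatal.

The shipped table follows the Engh & Huber tradition for peptide values
(amide C-N 1.329/0.02 A, C=O 1.231/0.02 A, ...), with default sigmas of
0.02 A for bonds and 3.0 degrees for angles.  One deliberate refinement: a
six-membered aromatic ring with unequal C-C and C-N bond lengths cannot
close with all internal angles at 120 degrees, so pyridine-like typed rows
(117.0 at N, 123.8 adjacent, 118.45 elsewhere, substituents bisecting the
remainder) are included; without them every ring idealization carries a
systematic ~1.4-degree residual.

Descriptions can also be derived from coordinates. `perceive_graph()` bonds
two atoms when their distance is at most the covalent-radius sum plus 0.45 A
(a tolerance validated by round-tripping the idealized fixtures), raises
bond orders greedily shortest-bond-first while both endpoints have free
valence, infers a +1 charge on over-bonded nitrogen, and reads chirality
signs from signed volumes.  `targets_from_coordinates()` is the "as-is"
mode: the observed geometry becomes the targets, intended for
high-precision input coordinates; applied to imprecise models it produces
modifications with very many edits, which is why it is an explicit opt-in
rather than the default.

## Hydrogen bookkeeping and valence

`adjust_hydrogens()` sets the hydrogen count of every heavy atom to
*effective valence - floor(sum of bond orders to heavy neighbours)*, with
aromatic/delocalized bonds counted 1.5 and the effective valence shifted by
the formal charge (protonated lysine NZ keeps three hydrogens; after
forming the imine double bond it keeps one).  Added hydrogens are named
"H" plus the suffix of the parent heavy atom's name (NZ -> HZ1, HZ2, ...),
numbered for uniqueness and capped at four characters.  Orphaned hydrogens
left behind by heavy-atom deletions are removed.  The returned edit list is
exactly the set of automatic changes, so they can be journalled into
modification entries.  Over-valence is an error naming the atom - this is
the check that catches, for example, linking to an aldehyde carbon whose
doubly bonded oxygen was not deleted first.

## Idealization

`embed_coordinates()` builds starting coordinates by breadth-first
NeRF-style placement from bond and angle targets with seeded dihedral
choices, followed by a distance-geometry clean-up (bond targets, 1-3
distances implied by angle targets, and a soft repulsion between all other
pairs) that prevents rings from collapsing onto themselves and tetrahedral
centres from flattening.  The generator is deterministic per seed and never
touches the caller's RNG state.

`regularize()` minimizes the weighted restraint objective

$$\sum_b \frac{(d-d_0)^2}{\sigma_b^2} + \sum_a \frac{(\theta-\theta_0)^2}{\sigma_a^2}
  + \sum_t \frac{\Delta_p(\tau-\tau_0)^2}{\sigma_t^2}
  + \sum_{\text{planes}} \sum_i \frac{d_i^2}{\sigma_i^2}
  + \sum_{\text{chir}} w_c \,h(V)^2$$

with analytic gradients under BFGS.  $\Delta_p$ wraps a torsion deviation
into its periodic well; the plane term measures distances to the weighted
best-fit plane (smallest-eigenvector normal), whose gradient is exact by
the envelope theorem because the plane parameters are themselves the
weighted least-squares optimum; the chirality term is a one-sided hinge on
the signed volume, penalizing the wrong-sign region past a 0.1 cubic-angstrom
margin with weight 25 (volumes are classified with the same margin by
`chirality_sign()`).  Convergence is declared when the step or gradient
falls below 1e-4 A / 1e-6.

Two practical safeguards matter as much as the objective:

* **Wrong-handed centres** are repaired by reflecting the centre *and its
  non-reference substituents* (typically its hydrogen) through the plane of
  the three reference neighbours; reflecting the centre alone just gets
  pulled back by the minimizer.
* **Entangled conformers.**  The dictionary terms alone say nothing about
  non-bonded contacts, and a minimization can settle with one arm threaded
  through another at sub-covalent distances - at which point bond
  perception from the idealized coordinates would invent bonds.  The
  objective therefore includes a short-range *anti-collapse floor*: pairs
  at graph distance three or more are penalized only below the
  covalent-radius sum plus 0.55 A.  This is not a van der Waals model; at
  physically reasonable geometry the term is identically zero.  When a
  minimization settles outside the acceptance bar (bond 0.01 A, angle 1
  degree, no deep floor violations), the atoms implicated in the residuals
  are kicked and, if the basin survives kicking, the fold is restarted from
  a fresh deterministic embedding; after the restart budget the best
  settled conformer is returned with its residual report.

`restraint_residuals()` is the pure evaluator behind the reports; its
per-class maxima are exactly the maxima over the per-restraint rows.

## The link-generation algorithm

`compose_session()` takes two (possibly pre-edited) monomers and one
inter-monomer bond; the pristine parents are remembered for diffing.  After
composition the monomer interiors are fixed - the single editable property
is the link-bond order - which keeps the eventual modifications small.
`regularize_session()` then:

1. gives every composite atom a unique working name (side suffix on
   collisions, numeric bump within four characters) with a bijective map
   back to per-side original names;
2. merges the graphs, adds the link bond, and re-adjusts hydrogens across
   the junction (automatic edits extend the name map; hydrogens added
   later are named from the *original* name of their heavy atom);
3. wipes energy types and restraints and completes the composite from
   scratch, so hybridization changes propagate (the aldehyde carbon
   becomes an imine carbon, the amine nitrogen becomes planar);
4. embeds and idealizes the coordinates.

`split_session()` produces the dictionary entries: every restraint whose
atoms span both sides moves to the link entry (with a side discriminator
per atom); what remains on each side is diffed against the completed
pristine parent.  Parent references make deletions and additions direct
reads; surviving items are recorded as *changed* when their type changed or
their target moved by more than `sigma_multiplier` times the declared
sigma.  The default multiplier of 1 implements the standard change
criterion - sub-sigma drift is noise, not chemistry - and deliberately
discards it, so the default split is lossy by design.  Setting the
multiplier to 0 makes the split lossless, which is what the package's own
round-trip oracle uses: `apply_link()` over a lossless split must reproduce
the regularized composite exactly (atoms, bonds, restraint targets to
1e-6), compared in the side-qualified original-name space so the comparison
is independent of the renaming scheme.  Modification ids follow the
`<CODE>mod<n>` convention (`mod1`/`mod2` on the same code for disulfide-style
self-links) and the link id is `<CODE1>-<CODE2>`.

`save_additional_library()` writes the modification list, link list, two
modification blocks and the link block - five data blocks for the
lysine-PLP example.  Monomer blocks are added only for parents that the
base library cannot resolve; forcing one that *is* resolvable triggers a
shadowing warning, because a same-named monomer block would hide the
standard description from refinement (the classic pitfall when a structure
contains both the linked and the free cofactor).  Append mode merges with
precedence to the new entries and warns about every id it shadows.

## The dictionary CIF dialect

`read_library()`/`write_library()` speak the monomer-library CIF dialect:
index blocks `data_comp_list`, `data_mod_list`, `data_link_list` and
per-entry blocks `data_comp_<CODE>`, `data_mod_<ID>`, `data_link_<ID>`
with the `_chem_comp_*`, `_chem_mod_*` and `_chem_link_*` categories;
`desc_level` is "M" for minimal and "." for complete; chiral signs are
written `positiv`/`negativ`/`both`.  The writer is deterministic (index
blocks first, then entries in insertion order; 3 decimals for angstroms, 2
for degrees; values quoted when they contain whitespace or lead with an
underscore), the reader is tolerant (missing esd fields become documented
defaults - 0.02 A, 3.0 degrees - and are flagged; unknown blocks and
categories are preserved opaquely), and the pair satisfies two contracts
tested on every fixture: read-then-write is semantically the identity, and
write-read-write is byte-identical.  An index row naming a missing entry
block is a consistency error; an entry block without an index row is not.

## PDB LINK records

`parse_link_records()` reads LINK records by the PDB v3.3 fixed columns and
LINKR - the refinement dialect - with the link-entry id taken from columns
73-80 (a documented dialect assumption; the distance field is optional).
`filter_amino_amino()` implements the survey rule for special amino-amino
linkages: keep records where both residues are amino acids, then drop
main-chain C-N pairs and CYS SG-SG pairs, which describe ordinary polymer
chemistry and are treated as annotation mistakes when they appear as LINK
records.  The D-amino-acid handling in the survey set is not standardized,
so `standard_amino_acids()` makes the set explicit and configurable.
`tally_links()` canonicalizes each record to an unordered (residue, atom)
pair - invariant under side swaps - and reports occurrences and
distinct-file counts, the two columns of the usual survey tables.

## The built-in fragment set

`builtin_fragments()` ships complete descriptions of GLY, ALA, CYS, LYS
(side-chain amine protonated, +1), PLP (with the aldehyde oxygen O4A on
C4A, as required for the aldimine edit sequence) and a pyranose sugar,
plus generic modifications (DEL-OXT, NH1, DEL-O1, DEL-HO4, DEL-HG) and
links (trans-peptide, disulfide, alpha-1,4 glycosidic).  The chemistry is
hand-encoded from the standard structures of these compounds; chirality
signs are the package's own internally consistent encoding of the L/alpha-D
configurations rather than values copied from any external dictionary.
`random_molecule()` grows valence-valid connected trees over C/N/O/S and is
the property-test generator.

What the fixtures do and do not show: they exercise every code path
(aromatic rings, phosphate, thiols, sugars, charged amines, all three entry
types) at realistic chemistry, but they are idealized molecules - passing
tests demonstrates the correctness of the algorithms, not robustness to
the noisy geometry, partial occupancy or misassigned elements of real
deposited coordinates.  Graph perception in particular is documented to be
unreliable for imprecise coordinates, and no accuracy claim is attached to
it beyond the idealized round trip.

## Problem sizes and numerical choices

The test-suite and acceptance computations use the problem sizes a desk
check warrants: fixture monomers of 10-26 atoms, composites of up to ~50
atoms, 50 random compositions for the round-trip property, 100 random
molecules for the enumeration oracle, and five (tests) or three
(acceptance script) embedding seeds per idealization.  Tolerances:
idealization accepts max |bond deviation| 0.01 A and max |angle deviation|
1 degree; chiral classification uses the 0.1 cubic-angstrom margin;
composite equality is asserted to 1e-6 on targets.  All randomness flows
through explicit integer seeds; derived seeds stay well below 2^31.

## Known limitations

* Aromaticity is taken from declared bond orders; no perception from
  Kekule structures, tautomer handling or resonance models.
* Torsion targets are conventional (staggered / planar), not
  compound-specific; ring pucker is left to bonds and angles.
* The change-detection criterion is per-restraint; a coordination-sphere
  criterion (deciding inclusion by graph changes around an atom) would
  produce smaller modifications in some cases and is noted as future work.
* The energy-type scheme and parameter table cover the shipped chemistry
  with conservative fallbacks; they are data and can be replaced, but no
  claim is made that they match any external library's values row for row.
* Idealization is restraint satisfaction, not conformational search: the
  reported conformer is one clash-free minimum, not an ensemble.
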