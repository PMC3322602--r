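# linksmith

Template-restraint dictionaries for covalently linked monomers.

Macromolecular refinement restrains model geometry against a dictionary of
template restraints with three entry types: **monomers** (one compound's
molecular graph plus targets for bonds, angles, torsions, chiral centres
and planar groups), **modifications** (add/delete/change edits against a
parent monomer, such as `DEL-OXT`), and **links** (cross-monomer restraints
joining two modified monomers, such as the trans peptide bond or a
glycosidic linkage). The factorization is what keeps dictionaries small:
covering 20 amino acids in 3 chain positions and 2 conformations needs
20 × 3 × 2 = 120 stand-alone monomer entries, but only 20 + 2 + 2 = 24
entries under the link/modification scheme.

When a structure contains a covalent linkage the standard dictionary does
not describe — a lysine–pyridoxal-5′-phosphate Schiff base, a disulfide in
an unusual context, an engineered cross-link — the missing restraints go
into a user-side *additional library* whose entries shadow same-named
standard entries during refinement. `linksmith` implements the machinery
for building such libraries:

* **Dictionary I/O** — reader/writer for the monomer-library CIF dialect
  (`data_comp_*`, `data_mod_*`, `data_link_*` blocks), deterministic
  output, byte-stable re-serialization, additional-over-standard merge
  precedence.
* **Graph editing** — atom/bond edits with journalling and parent-atom
  provenance, automatic hydrogen bookkeeping from a valence model, signed
  chiral volumes.
* **Completion** — deterministic atom energy typing, restraint enumeration
  (angles, torsions, chiral centres, merged sp2 planes) and target lookup
  from an Engh & Huber-style parameter table with element and geometric
  fallbacks; graph perception from PDB coordinates; an "as-is" mode that
  adopts observed geometry as targets.
* **Idealization** — seeded coordinate embedding plus quasi-Newton
  minimization of the weighted restraint objective (1/σ² weights, periodic
  torsion wells, best-fit-plane penalties, chiral-volume hinges), with
  automatic repair of wrong-handed centres and entangled conformers.
* **Link generation** — compose two monomers with a covalent bond,
  regularize the composite, and split it into two modification entries plus
  one link entry; apply modifications and links back; save/append an
  additional library with name-shadowing warnings.
* **LINK-record survey** — fixed-column parsing of PDB LINK/LINKR header
  records, the amino–amino exclusion rule (main-chain C–N and CYS SG–SG
  pairs are annotation mistakes), and a canonicalized linkage-type tally.

A built-in fragment set (GLY, ALA, CYS, LYS, PLP, a pyranose; generic
modifications and links) makes the whole pipeline testable without any
external dictionary.

## Worked example: the lysine–PLP internal aldimine

Both LYS and PLP are in the (built-in) library; the task is an additional
library restraining the covalent linkage. Delete the aldehyde oxygen,
define the C4A=NZ double bond, regularize, split, save:

```r
library(linksmith)
lib <- builtin_fragments()

plp <- apply_edit(lib$monomers$PLP, graph_edit("delete_atom", name = "O4A"))
ses <- compose_session(lib$monomers$LYS, plp, list("NZ", "C4A", "double"),
                       parentA = lib$monomers$LYS, parentB = lib$monomers$PLP)
ses <- regularize_session(ses, seed = 1)
ses$report
#> <residual report> max |bond dev| 0.0006 A, max |angle dev| 0.442 deg, max |plane dev| 0.0000 A, chirals ok

parts <- split_session(ses)
parts$mod2
#> <modification PLPmod1 on PLP (group non-polymer)> 2 atom, 1 bond, 0 angle, 0 torsion, 0 chiral, 12 plane edits
parts$link
#> <link LYS-PLP> LYS + LYSmod1 -- PLP + PLPmod1: 1 bonds, 4 angles, 3 torsions, 0 chirals, 15 plane rows

save_additional_library(ses, "lys-plp.cif", base = lib)
count_cif_blocks("lys-plp.cif")
#> [1] 5
```

The report says the idealized composite satisfies every bond target to
0.0006 Å and every angle to 0.44°, with all declared chiralities met. The
two hydrogens displaced from NZ by the double bond were removed
automatically and journalled into `LYSmod1`; `PLPmod1` records the O4A
deletion (its second atom edit retypes the aldehyde carbon to an sp2 imine
carbon). The written file holds exactly five data blocks — modification
list, link list, `LYSmod1`, `PLPmod1` and the link `LYS-PLP` — and the link
block carries the NZ–C4A bond with every angle, torsion and plane that
spans the junction. Because both parents resolve in the base library, no
monomer block is written; forcing one would shadow the standard entry and
draws a warning.

The dictionary bookkeeping itself:

```r
count_design_entries(design_scheme("monomer_only", 20, 3, 2))
#> [1] 120
count_design_entries(design_scheme("link_mod", 20, n_generic_mods = 2,
                                   n_generic_links = 2))
#> [1] 24
```

## Command line

A thin CLI wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("exec","linksmith.R",package="linksmith"))') \
  make-link --lib base.cif --comp1 LYS --comp2 PLP \
  --delete 2:O4A --bond 1:NZ 2:C4A=double --out add.cif --seed 1
```

Other subcommands: `apply-mod`, `idealize` (writes an idealized PDB),
`complete`, `perceive` (`--as-is` adopts observed geometry as targets),
`links-tally`.

## Scope

The package generates and manipulates restraint dictionaries. It does not
refine against diffraction data, validate linkages against electron
density, or scan the PDB; graph perception from coordinates is documented
to be unreliable for imprecise models. See the methods vignette
(`vignettes/restraint-dictionaries.Rmd`) for the models, numerical choices
and known limitations.
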