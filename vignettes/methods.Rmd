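---
title: "Assigning polymerization heads and tails: models, rules and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assigning polymerization heads and tails}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A polymer repeat unit is a monomer with two open bonds. Writing repeat
units as p-SMILES requires knowing *which* two atoms form those bonds —
the head and the tail. For a database of plain monomer SMILES this is a
chemical inference problem: which functional group reacts, by which
mechanism, and at which atom.

`polytag` answers it in two layers. A rule layer maps functional-group
substructures to polymer classes and mechanisms. A quantum layer ranks
competing reactive sites by how much of the highest occupied molecular
orbital (HOMO) they carry — the orbital a nucleophilic attack donates
from — so that ambiguous monomers are resolved by electronic structure
rather than by pattern order.

# Class rules

Eleven SMARTS patterns (see `load_pattern_library()`) license five
classes:

* **polyvinyl** — an alkene `[CX3]=[CX3]` or alkyne `[CX2]#[CX2]`;
* **polyamide** — a primary amine together with a carboxylic acid or acyl
  halide, or a secondary amide whose N–C(=O) core lies in a ring (a
  lactam);
* **polyester** — an aliphatic alcohol with a carboxylic acid, a
  ring-member carboxylic acid, or a *strained* lactone (ester oxygen in a
  3- or 4-membered ring);
* **polyether** — an ether whose oxygen is a ring member;
* **polyurethane** — a hydroxyl on one `.`-component and an isocyanate on
  another.

The SMARTS strings are an operationalization choice: the groups themselves
are standard, but several edge decisions deserve a note.

*Primary amides map to no class alone.* Acrylamide's NH₂ matches the amine
pattern, but without an acid partner the polyamide rule cannot fire, so
the alkene is the only licensed route — which is the chemically correct
resolution for vinyl monomers carrying amide substituents.

*Lactones.* A cyclic ester contains an in-ring ether oxygen and no free
acid, so by the letter of the ether/acid rules every lactone looks like a
cyclic ether. The default library keeps that behavior for 5-membered and
larger lactones (γ-butyrolactone and caprolactone classify as polyethers —
a known, documented limitation of this rule family) while the strained
3/4-ring lactone route recovers polyester for β-lactones. The
`fix_lactones` option widens the polyester route to any lactone
(`[CX3](=O)[OX2;R]`); with it, all lactones classify as polyesters. In
both modes the *tagged structure* is identical, because ring opening keys
on the acyl neighbor of the ring heteroatom, not on the class label.

*Multiple candidates are kept.* A monomer matching several rules yields
several candidates; resolution is a separate, quantum-informed step.

# The nucleophilicity index

For a closed-shell molecule the per-atom index is

$$R_X = \frac{\sum_{\alpha \in X} p_\alpha^{\mathrm{HOMO}}}{1 - \varepsilon_{\mathrm{HOMO}}},$$

where the numerator is the Mulliken partition of the (normalized) HOMO
onto atom $X$, $p_X = \sum_{\alpha \in X} \sum_\beta C_{\alpha n} S_{\alpha\beta} C_{\beta n}$,
and $\varepsilon_{\mathrm{HOMO}}$ is the orbital energy in hartree. Two
observations shape the implementation:

* the denominator is atom-independent, so the $R_X$ *ranking* — the only
  thing downstream logic consumes — equals the $p_X$ ranking; the
  denominator is kept for scale familiarity. Units of
  $\varepsilon$ (hartree vs eV) therefore cannot change any assignment.
* the overlap-weighted Mulliken form is the default because it is what a
  per-MO atomic population analysis produces; a literal
  $\sum |C_\alpha|^2$ mode (`raw_coefficients = TRUE`) is available for
  comparison.

Populations of hydrogen atoms stay on the hydrogens; only heavy atoms are
eligible head/tail sites, matching every worked example in the field.

## The SCF engine

No quantum-chemistry backend is assumed: the package carries a restricted
Hartree–Fock implementation. Integrals over contracted Cartesian
Gaussians use the McMurchie–Davidson scheme (Hermite expansion
coefficients by recursion, Boys function by a series/downward recursion
below $T = 30$ and the asymptotic form with upward recursion above,
shell-pair data reuse, Schwarz screening at $10^{-11}$, packed
8-fold-symmetric ERI storage), compiled via Rcpp. The SCF driver uses
symmetric orthogonalization (eigenvalue cutoff $10^{-8}$), a core guess,
and DIIS over up to 8 Fock matrices; non-convergence triggers one damped
retry (mixing 0.5) before erroring. Default convergence: DIIS error
$< 10^{-7}$ and $|\Delta E| < 10^{-9}$ hartree.

STO-3G parameters are generated from the universal three-Gaussian 1s and
2sp fits scaled by the standard per-element Slater exponents — the
construction that defines the published tables — for H through Ne;
third-row elements are refused with a clear error. A 6-31G* set (H, C, N,
O; Cartesian d, polarization exponent 0.8) is included for
method-sensitivity checks but is not part of the validated default
protocol; B3LYP is not implemented and is refused explicitly.

The engine is verified three independent ways in the test suite: against
closed-form s-orbital integral formulas (a separate implementation in the
test helpers), against finite-difference p-integrals obtained by
differentiating those closed forms with respect to orbital centers, and
against a full independent closed-form H₂ energy. Two external anchors
were used during development: the RHF/STO-3G water energy at a standard
reference geometry (agreement to $3\times10^{-8}$ hartree) and the
RHF/6-31G* water energy at its optimized geometry (agreement to
$10^{-6}$ hartree).

## Geometries

Conformers come from seeded distance-geometry embedding (ETKDG) with
hydrogens added, followed by UFF refinement capped at 5000 steps — a
single conformer per monomer, deterministic for a fixed seed (default
42, exposed as `seed` everywhere). The embedding is delegated to RDKit
through the package's subprocess bridge. Open-shell or charged species
are refused before embedding: the SCF is spin-restricted.

A consequence worth stating: on these force-field geometries at
RHF/STO-3G, lone-pair-rich groups can out-rank π systems in HOMO
population. For acrylamide the HOMO is amide-centered, not vinyl-centered.
No assignment depends on this — the amide licenses no class alone, and
vinyl head/tail selection ranks $R_X$ *within* the alkene match — but a
group-level "vinyl has the higher index" reading does not hold at this
level of theory, and the package does not claim it.

## When the quantum step runs

`resolve_class()` never consults a profile when a single class is
licensed. The pipeline's `quantum = "auto"` mode computes a profile only
when (a) several distinct classes compete, or (b) the winning match does
not determine its nucleophilic atom structurally — in practice the
alkene/alkyne case, where either carbon may start the chain. Groups with
a designated key atom (amine → N, hydroxyl/alcohol → O, ring heteroatom)
select it directly; a test confirms on 4-aminobutanoic acid that the
$R_X$ arg-max and the structural convention choose the same atom.
`quantum = "always"` and `"never"` are available.

# Head/tail selection and graph edits

The head is the nucleophilic atom of the winning group; the tail depends
on the route:

* **vinyl** — the other carbon of the multiple bond; the bond order is
  reduced by one and both carbons are tagged.
* **condensation** — the acyl carbon of the acid/acyl halide; its
  hydroxyl (or halide) is deleted, and the head heteroatom loses a
  hydrogen implicitly when the tag bond is attached. Heavy-atom loss is
  exactly the leaving group.
* **ring opening** — one ring bond incident to the heteroatom is deleted:
  the heteroatom–acyl bond when an in-ring acyl neighbor exists
  (lactones, lactams), otherwise the bond on the less-substituted side
  (fewer heavy neighbors, ties by lower canonical index), so
  methyl-substituted epoxides open away from the substituent. Heavy atoms
  are conserved exactly. Fused or bridged ring heteroatoms are refused
  with an explicit status rather than guessed.
* **polyurethane** — each component is tagged as a polymerized entity:
  diols lose both hydroxyl hydrogens to tags; each isocyanate N=C bond is
  reduced and the carbon tagged, the nitrogen gaining a hydrogen
  (urethane-forming addition).
* **bifunctional condensation partners** (diamine + diacid, diol +
  diacid) are tagged per component: two nucleophilic heteroatoms, or two
  acyl carbons with both leaving groups removed.

All edits are molecular-graph operations executed on the canonical-order
parse and re-sanitized afterwards; a valence-violating result is reported
as a failure (`is_valid = FALSE`), never emitted. This is deliberate:
string-level SMILES surgery is known to produce pentavalent-carbon
artifacts on exactly these ring-opening cases, which motivated the
graph-based design.

Tag numbering is cosmetic under the validation protocol (tokens collapse
to `*`), and two conventions are used: head `[*:1]`/tail `[*:2]` for
vinyl and condensation routes; carbon end `[*:1]`, heteroatom end `[*:2]`
for ring-opened units, matching the printed ground-truth forms for those
examples. One documented account places a polyester head on the carbon
next to the hydroxyl rather than on the oxygen; the package keeps the
uniform O-nucleophile convention, and token collapse makes the two
readings compare equal.

# Validation protocol

Predictions and ground truth are aligned by polymer name, both tags are
rewritten to `*`, strings are canonicalized, and exact string equality is
scored. Unparseable entries count as incorrect. `score_dataset()` reports
class accuracy, head/tail accuracy, and a per-class breakdown. The
built-in fixture set covers all five classes, the four cyclic
ring-opening worked examples, and the two lactone misclassification
cases; scoring a larger external collection is the same code path on a
downloaded CSV.

# What the fixtures do and do not show

The fixtures are real literature monomers, not synthetic perturbations,
so they exercise genuine chemistry — but they are small (≤ 16 heavy
atoms), favor unambiguous class assignments, and contain no examples
where steric hindrance overrides electronic preference (bulky
2-substituted dienes are the known failure mode of a purely
nucleophilicity-ranked site choice; no steric descriptor is
implemented). Passing them demonstrates that the rules, the index and
the edits compose correctly; it does not bound accuracy on arbitrary
databases.

Problem sizes were chosen to keep the default test run interactive: the
quantum property checks run on molecules up to ~8 heavy atoms (a
40-basis-function SCF takes seconds; the largest fixture the pipeline
ever profiles, acrylamide/styrene scale, stays under half a minute), and
the full fixture pipeline completes in about two minutes because
single-candidate monomers skip the SCF entirely.

# Known limitations

* Accuracy of the site choice is bounded by RHF/STO-3G on UFF
  geometries; the orbital-ordering caveat above is the visible symptom.
* Third-row elements (S, P, Cl, …) are outside the quantum engine's
  basis tables; monomers containing them can still be classified and
  tagged whenever no profile is needed.
* Stereochemistry is not guaranteed across ring opening; fused-ring
  heteroatoms are refused; no steric-hindrance screening; no
  LUMO/electrophilicity refinement.
* The polyaddition subcategory relies on exact fingerprint identity with
  a configurable initiator table — a data table, not a model.
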