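# polytag

Automated head/tail atom assignment for polymer repeat units.

Machine-learning pipelines for polymer property prediction consume repeat
units written as p-SMILES, where wildcard atoms mark the two positions that
form bonds during polymerization (the *head* and *tail*). Curated monomer
collections rarely carry those marks. `polytag` derives them from plain
monomer or polymerization-reaction SMILES:

1. **Monomer identification** — for reaction SMILES
   (`reactants>>products`), every reactant is compared against the largest
   product by Tanimoto similarity of RDKit path fingerprints
   (`RDKFingerprint`); the most similar reactant is the monomer.
2. **Polymer class** — the monomer is matched against a SMARTS library of
   the functional groups that license five classes: polyvinyl (alkene /
   alkyne), polyamide (amine + acid/acyl halide, or a cyclic lactam),
   polyester (alcohol + acid, or a strained lactone), polyether (cyclic
   ether), polyurethane (diol + diisocyanate).
3. **Reactive-site ranking** — when several classes compete, candidate
   sites are ranked by a per-atom nucleophilicity index computed from a
   restricted Hartree-Fock wavefunction:

   R_X = Σ_{α∈X} p_α(HOMO) / (1 − ε_HOMO)

   where p is the Mulliken partition of the highest occupied molecular
   orbital over atoms and ε_HOMO its energy in hartree. Geometries come
   from seeded distance-geometry embedding refined with UFF (≤ 5000
   steps); the SCF runs in-process at RHF/STO-3G (6-31G* available) on
   McMurchie–Davidson integrals compiled via Rcpp.
4. **Mechanism** — a fixed table per class (polycondensation,
   polyaddition, ring-opening; polyaddition subcategory radical / anionic /
   cationic is assigned when a reaction lists a known initiator).
5. **Head/tail tagging** — graph edits (ring-bond deletion for cyclic
   monomers, leaving-group removal for condensations, bond-order reduction
   for vinyls) followed by RDKit valence sanitization produce a canonical
   repeat-unit SMILES carrying exactly one `[*:1]` and one `[*:2]` per
   polymerizing unit. Invalid structures are reported as failures, never
   emitted.

## Requirements

R (≥ 4.3) with Rcpp, jsonlite, yaml — and a Python 3 interpreter with
RDKit importable as `python` on the `PATH` (override with
`options(polytag.python = ...)` or `POLYTAG_PYTHON`). All cheminformatics
primitives are delegated to RDKit through a small batched subprocess; the
class rules, reactivity index, SCF engine and graph-edit logic live in the
package.

```sh
R CMD INSTALL .
Rscript -e 'testthat::test_dir("tests/testthat", package = "polytag", load_package = "installed")'
```

## Worked example

```r
library(polytag)

rows <- run_pipeline(data.frame(
  polymer_name = c("poly(propylene glycol)", "nylon-10", "polyacrylamide"),
  raw_smiles   = c("CC1CO1", "NCCCCCCCCCC(=O)O", "C=CC(N)=O")
))
rows[, c("polymer_name", "polymer_class", "mechanism", "tagged_smiles")]
```

```
            polymer_name polymer_class        mechanism             tagged_smiles
1 poly(propylene glycol)     polyether     ring_opening          CC(C[*:1])O[*:2]
2               nylon-10     polyamide polycondensation O=C(CCCCCCCCCN[*:1])[*:2]
3         polyacrylamide     polyvinyl     polyaddition      NC(=O)C(C[*:1])[*:2]
```

Propylene oxide is recognized as a cyclic ether: the ring is opened at the
oxygen on the unsubstituted side and the chain ends are tagged, giving the
poly(propylene glycol) repeat unit. The amino acid condenses: the amine
nitrogen is the nucleophilic head, the acid carbon the tail, and the
leaving hydroxyl is removed. Acrylamide polymerizes across the double
bond, whose order is reduced and whose carbons carry both tags.

Validation against a ground-truth set of tagged repeat units uses
head/tail *token equivalence*: both tags are collapsed to `*` and the
strings canonicalized before comparison.

```r
fx <- builtin_fixtures()
truth <- data.frame(polymer_name = fx$polymer_name,
                    tagged_smiles = fx$expected_tagged,
                    polymer_class = fx$expected_class)
score_dataset(run_pipeline(data.frame(polymer_name = fx$polymer_name,
                                      raw_smiles = fx$smiles)), truth)[
  c("class_accuracy", "headtail_accuracy")]
#> $class_accuracy    [1] 1
#> $headtail_accuracy [1] 1
```

A command-line front end mirrors the R interface:

```sh
inst/exec/polytag run --input input.csv --output out.csv --seed 42
inst/exec/polytag validate --pred out.csv --truth truth.csv --report report.csv
inst/exec/polytag fixtures --emit fixtures/
```

`--fix-lactones` opts into the corrected rule that lets any cyclic ester
found a polyester (by default only strained 3/4-membered lactones do,
which reproduces the documented behavior of classifying larger lactones
such as caprolactone as polyethers).

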