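# nanofp

Structural descriptors and toxicity QSAR for binary metal-oxide nanoparticles.

Binary metal oxides (TiO₂, ZnO, Al₂O₃, NiO, ...) are among the most widely
manufactured nanomaterials, and their reactivity and toxicity are governed
largely by the particle *shell* — the outermost few Ångström, where
undercoordinated surface sites live. `nanofp` turns an all-atom 3D structure
(a plain `.xyz` file) into a fixed-length count vector over local coordination
environments of the shell, the **NanoFingerprint**, and builds the
surrounding toolset a modeller needs:

* **Fingerprints** — bond inference from covalent radii, radial core/shell
  classification, and counting of the local structures `O(c)`, `M(c)`,
  `O(x,y)`, `M(x,y)` and bonded pairs `O(x,y)–M(x′,y′)` into a four-section
  vector; plus differencing, e.g. to track how crystalline optimisation heals
  undercoordinated oxygens.
* **Subcomponent search** — counting appearances of a small element-labelled
  query structure (XYZ or GRF) in the shell's bond graph, by backtracking
  subgraph matching.
* **Toxicity QSAR** — leave-one-out linear regression (LDH release) and
  stratified k-fold logistic classification with training-fold minority
  oversampling, with fingerprint sections concatenated onto physicochemical
  feature tables.
* **Generative model** — a per-position regression of `log(1 + count)` on
  `log(size)` that predicts a whole fingerprint from the metal and the
  particle size alone, so properties of particles too large to build in 3D
  can still be screened.
* **Synthetic data** — spherical particles cut from ideal lattices (rocksalt
  MO, fluorite MO₂, defective-rocksalt M₂O₃) and QSAR tables with planted
  effects, so everything above is testable offline.

## The descriptor

For a shell of thickness *t* below the outer radius, with per-atom
coordination capped at MAX, the fingerprint is

| section | content | length |
|---|---|---|
| 1 | *t* (Å), MAX, particle size (Å), metal atomic number, shell O count, shell metal count | 6 |
| 2 | `O(c)`, `M(c)` — atoms with total coordination *c* = 1..MAX | 2·MAX |
| 3 | `O(x,y)`, `M(x,y)` — atoms with *x* oxygen and *y* metal neighbours, 0..MAX each | 2·(MAX+1)² |
| 4 | bonded pairs of section-3 environments (O–O, M–M, O–M blocks) | 3·(MAX+1)⁴ |

Total length: `6 + 2·MAX + 2·(MAX+1)² + 3·(MAX+1)⁴` (44,191 at MAX = 10).
A second arithmetic convention that bins positive coordinations only
(`6 + 2·MAX + 2·MAX² + 3·MAX⁴` = 30,226 at MAX = 10) is exposed through
`fingerprint_length(convention = "positive-only")` for comparison with
published figures; the inclusive-zero layout is what the package stores.
Coordination is computed in the shell-restricted bond graph (both bond
endpoints in the shell), and atoms with more than MAX bonds are kept in the
section-1 populations but excluded from sections 2–4.

## Worked example

```r
library(nanofp)

# a synthetic rocksalt NiO particle, 16 A across
s <- make_particle(lattice_spec("rocksalt", 4.18, "Ni", 16))
s
#> <nano_structure: 251 atoms (Ni:135, O:116), source: synthetic>

fp <- build_fingerprint(s, thickness = 4, max_bonds = 6)
fp
#> <nano_fingerprint: Ni-O, MAX=6, length 7319>
#>   section 1: thickness=4 A, MAX=6, size=15.64 A, Z=28, O_shell=102, M_shell=122
#>   21 non-zero counting entries:  O(4)=24, O(5)=54, O(6)=24, M(3)=56, M(5)=54, M(6)=12, O(0,4)=24, O(0,5)=54, ...
```

The 4 Å shell of this cutout holds 102 oxygens and 122 nickels; the
fingerprint says, e.g., that 24 shell oxygens are 4-coordinate (`O(4) = 24`)
and none are dangling (`fp_count(fp, "O(1)")` is 0 — the ideal lattice has no
singly bonded oxygen). Searching for a bent O–Ni–O fragment in the same
shell:

```r
q <- pattern_graph(c("O", "Ni", "O"), rbind(c(1L, 2L), c(2L, 3L)))
find_subcomponents(s, q, thickness = 4)
#> <match_result: 888 appearance(s) of a 3-node query in the shell>
```

888 distinct atom triples in the shell realise that fragment. Predicting
shell populations of a larger particle from size alone:

```r
gen <- fit_generator(lapply(seq(10, 26, by = 2), function(d) {
  p <- make_particle(lattice_spec("rocksalt", 4.18, "Ni", d))
  list(metal = "Ni", size = compute_size(p),
       fingerprint = build_fingerprint(p, 4, 6))
}))
big <- predict_fingerprint(gen, "Ni", 30)
c(big$n_O_shell, big$n_M_shell)
#> [1] 460 569
```

An actual 30 Å cutout has 486 shell O and 446 shell Ni: the oxygen population
extrapolates within ~5%, while the metal population (driven by rougher facet
statistics) is ~28% off — see the methods vignette for why surface-site
counts of lattice cutouts are noisy in size.

## Command line

```sh
NANOFP_CLI=$(Rscript -e 'cat(system.file("cli", "nanofp.R", package = "nanofp"))')
Rscript $NANOFP_CLI fingerprint --in particle.xyz --thickness 5 --max 5
Rscript $NANOFP_CLI search --target big.xyz --query small.grf --thickness 4
Rscript $NANOFP_CLI predict --data train.csv --target ldh --input size=30,concentration=100
Rscript $NANOFP_CLI generate --metal Ni --size 300 --thickness 5 --max 6
Rscript $NANOFP_CLI synth particle --lattice fluorite --metal Ti --a 5.5 --diameter 20 --out p.xyz
```

All lengths are in Å (`--nm` converts); exit codes are 0 / 1 / 2 for
success / domain error / usage error.

### GRF query format

Line 1: `N M` (node and edge counts); then `N` lines `index element`
(0-based); then `M` lines `i j`, one unordered edge each. `#` lines are
comments.

```
3 2
0 O
1 Ti
2 O
0 1
1 2
```

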