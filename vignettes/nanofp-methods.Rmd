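---
title: "Shell fingerprints for metal oxide nanoparticles: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shell fingerprints for metal oxide nanoparticles: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanofp)
```

This vignette records the model behind `nanofp`, the choices we made where
the design was genuinely open, and what the synthetic test world does and
does not establish. It states no empirical result that the test suite does
not itself compute.

## 1. The model

A binary metal oxide nanoparticle is an ordered list of atoms (O plus one
metal species) with Cartesian coordinates in Å. Three steps turn it into the
descriptor:

**Bond inference.** XYZ files carry no connectivity, so bonds must be deduced
from geometry: atoms *i*, *j* are bonded iff
$d_{ij} \le \tau\,(r_i + r_j)$, with $r$ the tabulated single-bond covalent
radii and $\tau = 1.15$ a dimensionless tolerance. The radius table ships as
`inst/extdata/covalent_radii.csv`; $\tau$ is exposed everywhere
(`tolerance`). A tolerance near 1.15 is the conventional middle ground: small
enough that second-neighbour metal–metal contacts in rocksalt-type oxides
(at $a/\sqrt 2$) stay unbonded, large enough to absorb a few percent of bond
strain.

**Core/shell classification.** The particle centre is the centroid of all
atomic positions (the particle's intended construction is spherical, and the
centroid needs no parameters). With outer radius $R = \max_i \lVert x_i -
c\rVert$ and shell thickness $t$, atom *i* is a *shell* atom iff
$\lVert x_i - c \rVert \ge R - t$ — a closed boundary, so an atom exactly on
the inner surface of the band counts as shell. $t \ge \text{size}/2$ puts
every atom in the shell. Size is the maximum pairwise distance over the
whole particle (not only the shell): a user asking for a 3 nm particle's
fingerprint expects slot 3 to read 30 Å regardless of $t$.

**Counting.** Coordination is computed in the *shell-restricted* bond graph:
only edges with both endpoints in the shell count. Bonds crossing the
core/shell boundary are discarded; this keeps every conservation identity
exact within the shell subgraph (each pair slot in section 4 sums to a
number of shell–shell bonds, each environment slot in section 3 to a number
of shell atoms). The alternative — counting boundary-crossing bonds into the
coordination of shell atoms — would make section sums refer to a graph the
descriptor never sees. The choice is recorded here and in the shell
assignment's metadata.

The vector has four sections (lengths 6, $2M$, $2(M{+}1)^2$, $3(M{+}1)^4$
for $M = $ `max_bonds`):

1. thickness, MAX, size, metal atomic number, shell O count, shell metal count;
2. `O(c)` / `M(c)`: shell atoms of total coordination $c \in [1, M]$;
3. `O(x,y)` / `M(x,y)`: shell atoms with $x$ oxygen and $y$ metal
   neighbours, $x, y \in [0, M]$ (so isolated shell atoms land in `O(0,0)`);
4. bonded pairs of section-3 environments, in three blocks (O–O, M–M, O–M).

Atoms whose shell-subgraph degree exceeds MAX are dropped from sections 2–4
and from any pair involving them, but still count in section-1 slots 5/6 —
they exist in the shell even if the user's MAX cannot describe them. Picking
MAX at least the lattice's bulk coordination avoids any loss.

### Numerical and layout choices

* **Two length conventions.** The closed-form length
  $6 + 2M + 2(M{+}1)^2 + 3(M{+}1)^4$ follows from the inclusive-zero bins
  above and is what every stored vector satisfies. A widely quoted
  alternative arithmetic, $6 + 2M + 2M^2 + 3M^4 = 30{,}226$ at $M = 10$,
  corresponds to binning positive coordinations only; the two cannot both
  describe one vector. We treat the inclusive-zero formula as normative
  (section 3 explicitly starts at `O(0,0)`) and expose the positive-only
  arithmetic through `fingerprint_length(convention = "positive-only")` for
  reproducing the published figure.
* **Symmetric pair blocks.** The O–O and M–M blocks of section 4 nominally
  index an ordered $(M{+}1)^4$ grid, but an unordered bond realises
  `O(a)-O(b)` and `O(b)-O(a)` simultaneously. We canonicalise (smaller
  environment index first) and count each bond exactly once, which keeps the
  section-4 sum equal to the number of countable shell bonds. The mixed O–M
  block needs no canonicalisation (the oxygen end indexes the row).
* **1-based positions.** `index_of()`/`label_of()` speak 1-based vector
  positions, as R users expect; the layout's section bases are otherwise
  unchanged.
* **Differencing.** `diff_fingerprints()` subtracts sections 2–4 only.
  Section 1 mixes parameters and geometry with populations; subtracting a
  thickness from a thickness is meaningless, so the scalars are reported
  side by side. When comparing an optimised structure to its bulk-cut
  precursor, shell membership is decided once on the reference and
  transferred by atom index (`freeze_shell()`), so population differences
  reflect rebonding rather than membership churn.

## 2. Subcomponent search

Queries are element-labelled graphs, either given directly (GRF) or inferred
from a query XYZ by the same bond criterion. Matching is **subgraph
monomorphism** on the shell-restricted bond graph: every query edge must map
to a target edge, extra target edges among the matched atoms are permitted.
This is the permissive reading of "appearances" — a fragment does not stop
appearing because the crystal adds one more contact between its atoms. The
strict alternative (induced matching) is available via `induced = TRUE`.
Embeddings covering the same atom set (query automorphisms, e.g. swapping
the two oxygens of an O–M–O path) collapse to one counted appearance: counts
answer "how many places", not "how many mappings". All matched atoms must be
shell atoms; geometry beyond bond inference (angles, distances) is
deliberately not enforced. The matcher is plain backtracking with
rarest-label-first ordering; an independent brute-force enumerator in the
test suite checks it exhaustively on small cases.

## 3. QSAR protocols

Two evaluation protocols mirror common practice in nanotoxicity QSAR:

* `evaluate_loo_linear()`: leave-one-out OLS; reports the mean and standard
  deviation of squared prediction errors. Suitable for small regression sets
  (tens of samples, e.g. LDH release panels).
* `evaluate_cv_logistic()`: stratified k-fold (default 10) maximum-likelihood
  logistic regression. Class imbalance is handled by duplicating minority
  rows **in the training folds only**, with replacement, until classes
  balance; evaluation folds are untouched, so the correction cannot leak
  labels. Balanced accuracy is $(TPR + TNR)/2$; false positives/negatives
  are reported as mean counts per fold (their natural unit under k-fold).

No regularisation is applied by default — with the published protocols
unspecified, plain maximum likelihood is the least surprising choice — but a
small-λ ridge path (`ridge = TRUE`, via glmnet) exists for wide fingerprint
blocks, and zero-variance columns (ubiquitous in high-MAX sections) are
dropped before fitting. `assemble_features()` implements the three designs
used to test whether structure helps: base physicochemical features only,
fingerprint sections only, and their concatenation.

## 4. The generative model

`fit_generator()` regresses, independently per vector position,
$\log(1 + \text{count})$ on $[1, \log(\text{size}), \text{metal
indicators}]$, and `predict_fingerprint()` inverts the transform, clamps at
zero and rounds. Rationale: shell populations scale like powers of the
diameter (area-like for surface sites), so log–log linearity is the natural
two-parameter family; with a handful of training structures per metal,
anything richer (the obvious neural alternatives) overfits. Positions zero
across all training data are hard-zeroed — the model should not invent local
structures it has never seen. Two training sizes per metal determine the
two parameters exactly; more sizes average out facet noise (below).

## 5. The synthetic world

The generators exist so every pipeline stage is testable offline; they are
idealisations, and their defaults are stated once here:

* **Lattices.** Rocksalt MO is exact (6/6 coordination). MO₂ uses the
  fluorite geometry (metal fcc, oxygen in all tetrahedral holes, 8/4) — not
  rutile, whose two-parameter cell adds nothing for testing counting code.
  M₂O₃ is a defective rocksalt: one third of the metal sites are vacated by
  a fixed congruence on the site indices. All three reach their formula
  stoichiometry within 10% for diameters ≳ 6 lattice constants.
* **Default constants in tests.** NiO-like rocksalt ($a = 4.18$ Å), TiO₂-like
  fluorite ($a = 5.5$ Å), Al₂O₃-like defective rocksalt ($a = 4.2$ Å): with
  the packaged radii and $\tau = 1.15$ these bond first neighbours only.
* **Jitter.** Optional uniform positional noise emulates thermal/relaxation
  disorder. It must stay below the bond-criterion margin (≈ 0.1 Å for the
  NiO defaults) or coordination statistics decouple from the lattice family;
  tests use 0.02–0.08 Å depending on whether they need stable coordination
  or merely varied geometry.
* **Facet noise.** Surface-site counts of spherical cutouts are *not* smooth
  in diameter: whole facets appear and disappear as the sphere boundary
  crosses lattice planes, so e.g. the 3-coordinate oxygen count can jump
  between neighbouring sizes. This is why generative-model tests train on a
  dense ladder of sizes (8 points) and why the metal-sublattice populations
  extrapolate worse than the oxygen ones.
* **Surrogate optimisation.** `perturb_optimise()` moves a seeded fraction
  of dangling shell oxygens (degree ≤ 1) to the midpoint of their two
  nearest metals, guaranteeing higher coordination after re-inference. It
  reproduces the *signature* of crystalline relaxation (fewer `O(1)`, more
  high-coordination oxygen) without any energetics.
* **QSAR tables.** Standard-normal features with planted linear or logistic
  effects; a logit intercept plants class imbalance.

A green test on this world establishes that the *code* implements the
*stated counting rules and protocols*; it does not establish that the
fingerprint predicts real toxicity, and the idealised cutouts' counts must
never be confused with those of DFT-relaxed anatase structures. Published
benchmark numbers that depend on external inputs (the appendix feature
tables of the cited toxicity studies; externally generated anatase
particles) are wired as tests that run only when those files are supplied
under `inst/extdata/`.

## 6. Known limitations

* Binary oxides only: one metal species plus oxygen; no ternary or doped
  systems.
* Bond perception is a hard distance cutoff — no bond orders, no
  periodic-boundary images, and strained bonds near the tolerance boundary
  can flip under sub-0.1 Å coordinate noise.
* The shell is a radial band about the centroid; strongly aspherical
  particles will classify poorly.
* Subcomponent search is exponential in query size in the worst case; it is
  intended for fragments of a few atoms.
* The generative model extrapolates power laws; far outside the training
  size range its metal-sublattice predictions degrade first (facet noise).
* The packaged 30-atom Al₂O₃ cluster is a synthetic idealised-lattice
  stand-in with correct stoichiometry (18 O / 12 Al), not a relaxed
  structure.
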