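---
title: "Aligning protein surface patches: model, optimizer and scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning protein surface patches: model, optimizer and scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfalign)
```

## The problem

Two protein binding sites are similar when their atoms can be brought
into spatial register by a rigid-body motion. `surfalign` represents a
binding site as a *surface patch*: a finite set of atom centers in
Angstrom, each carrying one of five physico-chemical classes —
hydrogen-bond acceptor (`ACC`), donor (`DO`), acceptor/donor (`AD`),
aliphatic (`ALI`), aromatic (`PI`) — or `NONE` when the atom falls
outside the classification. Given a query patch $P$ ($n$ atoms) and a
target patch $Q$ ($m$ atoms, $n \le m$), the package searches for the
isometry $T_a$, parameterized by a unit quaternion $a_r$ and a
translation $a_t$, that minimizes a dissimilarity $g(a)$ between
$T_a(P)$ and $Q$.

Two dissimilarities are implemented. The **closest-point objective**
maps every transformed query atom to its nearest target atom and takes
the mean squared residual; it is the inner problem of the classical ICP
registration loop, and it is degenerate in a specific way: many query
atoms may collapse onto one target atom, producing a deceptively small
value. The **matching distance** repairs this by requiring the map to
be *injective*: it is the mean residual of the minimum-cost assignment
of query atoms to target atoms,

$$ g(a) \;=\; \frac{1}{n}\min_{\varphi\ \text{injective}}
   \sum_{p \in P} \lVert \varphi(p) - T_a(p)\rVert^2, $$

computed by solving an asymmetric (rectangular) assignment problem on
the bipartite graph whose edge costs are squared distances. In
`same-property` mode an edge exists only between atoms of equal class;
the label filter both sharpens the energy landscape and enforces
chemical plausibility of the match. Because injectivity restricts the
class of maps, the matching distance can never be smaller than the
closest-point objective at the same transform — a property the test
suite checks on randomized instances.

## Degenerate inputs and conventions

* Quaternions are stored with $a_0 \ge 0$ (first nonzero component
  positive when $a_0 = 0$), resolving the two-to-one cover so that
  population members and reported transforms are comparable.
* Nearest-neighbour ties and assignment alternate optima are broken
  toward the lowest target index, making every objective evaluation
  deterministic.
* If the mapped target points are all coincident the closed-form
  transform degenerates; the rotation is left at identity and only the
  centroids are aligned.
* `NONE`-labelled query atoms have no admissible partner in
  `same-property` mode; they are excluded from the assignment graph and
  from the objective mean (the denominator is the number of matchable
  query atoms) and are reported as unmatched. A labelled query atom
  whose class is absent from the target makes the graph infeasible: the
  package raises a structured error naming the atom, or, in `relax`
  mode, admits cross-class edges at a penalty of ten times the squared
  joint diameter so that batch runs complete.
* If $n > m$ the patches are swapped internally; the reported transform
  is inverted back and the assignment transposed, so reports are always
  in the user's query frame.

## The optimizer

The objective is piecewise smooth but non-differentiable across
reassignment boundaries, so the global search is a **controlled random
search** (CRS): a population-based, derivative-free method. A
population of $M$ random transforms (quaternions uniform on the unit
3-sphere; translations uniform in a box centered on the centroid offset
with half-width the sum of the patch half-diameters) is evaluated, then
repeatedly updated: draw $N{+}1 = 7$ distinct members, form their
weighted centroid $a_c$, reflect it over the worst drawn point
$a^\dagger$ as $\check a = (1+\alpha)a_c - \alpha a^\dagger$,
renormalize the quaternion block, and accept the candidate iff it
improves on the population maximum. The search stops when
$g_{\max} - g_{\min} < \varepsilon$ or the evaluation budget is spent.
Population extremes are non-increasing by construction, and runs are
bitwise reproducible under a fixed seed.

Tunable parameters, defaults, and the reasoning behind them:

| parameter | default | meaning |
|---|---|---|
| `M` | 150 (= 25·N) | population size; the conventional multiple of the dimension count that balances global coverage against convergence speed |
| `epsilon` | 1e-4 Å² | absolute stopping tolerance on the population spread |
| `alpha0` | 0.95 | reflection strength ceiling |
| `max_evals` | 20000 | total objective-evaluation budget |
| `aligned_cutoff` | 2.0 Å | post-superposition distance within which an assigned pair counts as *aligned* |
| site `cutoff` | 4.0 Å | ligand distance shell defining a binding site |

The reflection parameter follows
$\alpha_k = \alpha_0 \cdot \frac{s}{s + 10\varepsilon} \cdot
\frac{1}{1 + k/(50M)}$ with $s = g_{\max}-g_{\min}$: non-increasing in
both the iteration count and the spread, and tending to zero as the
spread approaches the stopping tolerance. This shape was chosen
empirically. Schedules that scale $\alpha$ with the *relative* spread
$s/s_0$ looked natural but collapsed the population onto local minima
long before the global basin was found (zero out of twenty synthetic
recoveries); near-full-strength reflections for as long as the
population is dispersed — the regime in which CRS has its global reach
— recovered planted transforms reliably, and the endgame decay then
merely accelerates the final contraction. For the same reason the
centroid weights are mild: drawn members are weighted by
$1/(g_i - g_{\min} + \eta)$ with $\eta$ at half the population spread,
keeping the weights within about a factor of three. Sharper weighting
(small $\eta$) degenerates the centroid to the best drawn point and
reintroduces the collapse. `weighted_centroid = FALSE` restores the
plain average of classic CRS.

The **ICP baseline** (`run_icp`, or `method = "icp"`) alternates the
closest-point mapping with the closed-form optimal transform for that
mapping (the quaternion eigenvalue solution of the absolute-orientation
problem). Its objective is non-increasing and it converges quickly —
to the local minimum nearest its starting pose. The test suite contains
a deliberate trap: a clone pair related by a 180° rotation, from which
ICP started at the identity settles at a large residual while the CRS
search reaches the true pose. This contrast is the reason a global
method is worth its extra evaluations.

## From PDB file to patch

`read_structure()` parses fixed-column ATOM/HETATM records (via
`bio3d`, with a pre-scan that reports malformed coordinate records by
line number), resolves alternate locations by highest occupancy, uses
the first MODEL, and flags waters and hydrogens, which are excluded by
default. `extract_binding_site()` takes every remaining polymer atom
within 4.0 Å (inclusive, atom-center to atom-center, no van der Waals
radii) of any atom of the selected ligand copy. Extraction is monotone
in the cutoff. Whether shells of this kind should include waters,
hydrogens, or non-polymer cofactor atoms is a modelling choice; the
defaults exclude all three and each is switchable.

Atom classes come from a shipped per-(residue, atom) rule table
(`inst/extdata/atom_property_rules.tsv`) implementing standard
pseudocenter chemistry — e.g. backbone O is `ACC`, backbone N is `DO`
(except proline), lysine NZ is `DO`, aspartate OD1/OD2 are `ACC`,
serine OG is `AD`, phenylalanine ring carbons are `PI` — with
element-based fallbacks for standard residues and `NONE` (with a
warning) otherwise. The table is data, editable without code changes;
exact parity with any published typing scheme is not claimed.

## Scores

With the fitted transform in hand, the *aligned pairs* are the assigned
pairs within `aligned_cutoff` of each other after superposition. How a
published "number of aligned atoms" smaller than $n$ arises from a
total assignment is generally not recoverable from method descriptions;
a post-hoc distance cutoff is the standard convention and is the main
caveat when comparing aligned-atom counts across tools. Over exactly
these pairs the package reports RMSD, the match-quality score
$\mathrm{SAS} = \mathrm{RMSD} \times 100 / n_\text{aligned}$ (lower is
better), and the normalized similarity
$2\,n_\text{aligned}/(n+m) \in [0,1]$. `all_vs_all()` fills a symmetric
similarity matrix (each unordered pair computed once, smaller patch as
query), and `retrieval_by_group()` evaluates ligand-group retrieval by
per-query ROC curves, their trapezoidal AUCs, and vertically averaged
per-group curves.

## The synthetic generator

`make_instance()` plants ground truth: a query sampled uniformly in a
20 Å box, a known random rigid motion, optional isotropic Gaussian
coordinate noise of standard deviation $\sigma$ per axis (so the
expected squared displacement at the truth is $3\sigma^2$), and decoy
atoms kept at least $2\sigma + 1$ Å away from every true correspondent
— a margin that makes the planted assignment the unique optimum at
$\sigma = 0$. `write_mock_pdb()` renders an instance as a valid PDB
whose residue/atom names encode the labels (an `ACC` atom is written as
an aspartate OD1, and so on) plus a fake ligand placed so the default
4.0 Å shell recovers exactly the patch, exercising the whole
extraction-typing-alignment pipeline end to end.

What the generator emulates is registration difficulty: noise, decoys,
label constraints, unknown pose. What it does **not** emulate is
protein geometry — covalent connectivity, secondary structure, realistic
atom densities, correlated (rotameric) displacements, or conformational
change of a ligand between complexes. Passing the synthetic recovery
tests therefore demonstrates that the optimizer and objectives do what
they claim on well-posed instances; it does not by itself certify
retrieval performance on real, flexibly bound ligands.

## Problem sizes used by the tests

The test suite favors instance sizes at which independent oracles are
exact: assignment solutions are checked against exhaustive enumeration
for $n \le 6$, $m \le 7$ (100 seeded graphs), and the closed-form
transform against multi-start Nelder–Mead on 5-point instances.
Optimizer recovery experiments use 20-atom patches (with up to 10
decoys) over 100 seeds, the scale at which a single CRS run takes well
under a second; batch and CLI round-trips use 8–15-atom patches with
reduced evaluation budgets. These sizes are the package's validation
conditions, not limits — real binding sites of 50–100 atoms are the
intended operating range, and the compiled assignment kernel keeps a
single evaluation at that scale in the tens of microseconds.

## Known limitations

* Rigid-body superposition only: no flexibility, scaling or reflection.
* The aligned-atom cutoff convention makes cross-tool comparisons of
  aligned-atom counts approximate by construction.
* CRS is stochastic; although 100-seed recovery rates are high, any
  single run can miss the global basin. Reports carry the seed and full
  configuration so runs are exactly repeatable.
* The typing table covers the twenty standard amino acids; modified
  residues fall back to element rules or `NONE`.
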