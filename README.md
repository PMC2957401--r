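# surfalign

Local structural alignment of protein surface patches — binding sites
represented as labelled atom point clouds — by derivative-free global
optimization over rigid-body transforms.

## Who this is for

Structural bioinformaticians comparing ligand binding sites: given two
PDB structures with bound ligands, `surfalign` extracts each site as
the protein atoms within 4.0 Å of the ligand, types every atom as
hydrogen-bond acceptor (ACC), donor (DO), acceptor/donor (AD),
aliphatic (ALI) or aromatic (PI), and finds the rotation + translation
that best superposes the two atom sets, reporting the matched atom
pairs, RMSD, SAS and a normalized similarity usable for all-vs-all
classification and ROC retrieval.

## The method

A rigid transform is a unit quaternion $a_r$ plus translation $a_t$.
For a fixed transform the dissimilarity between the transformed query
$T_a(P)$ ($n$ atoms) and the target $Q$ ($m$ atoms, $n \le m$) is the
**matching distance**

$$ g(a) = \frac{1}{n}\,\min_{\varphi:\,P \hookrightarrow Q}
   \sum_{p\in P}\lVert\varphi(p)-T_a(p)\rVert^2 , $$

the mean residual of the minimum-cost *injective* assignment of query
atoms to target atoms — an asymmetric (rectangular) assignment problem
on a bipartite graph whose edges can be restricted to atoms of equal
physico-chemical class. Unlike the closest-point distance used inside
ICP, the matching distance cannot be shrunk by collapsing many query
atoms onto one target atom. The outer minimization over transforms is a
**controlled random search** (CRS): a population of 150 random
transforms is iteratively improved by weighted centroid-over-worst
reflections (quaternion renormalized after each reflection) until the
population values collapse within a tolerance. An **ICP** baseline
(closest-point mapping alternated with the closed-form optimal
transform) is included; it converges to the local minimum nearest its
starting pose, which is exactly the failure mode the global search
avoids.

Post-alignment scores over the assigned pairs within a 2 Å cutoff:
`RMSD`, `SAS = RMSD × 100 / n_aligned` (lower is better), and
`similarity = 2 n_aligned / (n + m)` in [0, 1].

## Worked example

Synthetic instances carry a known ground truth, so recovery can be
verified end to end:

```r
library(surfalign)
inst <- make_instance(n = 20, decoys = 10, sigma = 0.1, seed = 42)
fit <- align_patches(inst$P, inst$Q, objective = "matching",
                     mode = "same-property", seed = 7)
fit
#> Surface patch alignment (crs, matching objective, same-property)
#>   query 20 atoms -> target 30 atoms
#>   aligned atoms: 20 | RMSD: 0.143 A | SAS: 0.71 | similarity: 0.8
#>   objective: 0.0203 A^2 ( converged )
round(coef(fit), 4)
#>      a0      a1      a2      a3      tx      ty      tz
#>  0.3083  0.4803  0.7090 -0.4143  3.9076 -5.2041 -9.1338
mean(fit$assignment == inst$correspondence)
#> [1] 1
```

All 20 true atoms are matched to their planted correspondents despite
10 decoys and 0.1 Å coordinate noise; the RMSD of 0.143 Å is the noise
floor, and SAS 0.71 reflects a high-quality match (many aligned atoms,
small RMSD). `coef()` returns the fitted 7-vector; `fitted()`,
`residuals()`, `predict()` and `plot()` behave as for any fitted model.

With PDB input the pipeline is:

```r
s1 <- read_structure("1abc.pdb")
p1 <- extract_binding_site(s1, ligand = "ATP", cutoff = 4.0)
p2 <- extract_binding_site(read_structure("2xyz.pdb"), "ATP")
fit <- align_patches(p1, p2, seed = 1)
write_alignment_report(fit, "pair_report.json")
```

A thin command-line wrapper (`exec/surfalign`) exposes the same
pipeline as subcommands `extract`, `align`, `icp`, `batch` (all-vs-all
matrix + ROC retrieval from a manifest) and `simulate`.

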