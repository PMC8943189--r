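---
title: "Methods: hemispheric structural-connectome asymmetry analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hemispheric structural-connectome asymmetry analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemiconn)
```

# The analysis

`hemiconn` analyzes hemispheric asymmetry of weighted structural
connectomes in cohorts with unilateral brain lesions (the motivating
setting is glioma patients mapped with diffusion tractography). Each
subject contributes a whole-brain 79-node connectome — a DKT cortical
parcellation plus subcortical gray matter, cerebella and brainstem, with
streamline counts as edge weights — which is split into an ipsilesional
and a contralesional 40-node hemisphere (39 lateralized nodes plus the
shared brainstem), homolog regions aligned row by row, interhemispheric
edges excluded. The pipeline then asks three questions:

1. **Which connections differ between hemispheres?** Threshold-free
   network-based statistics (TFNBS) with permutation family-wise error
   control.
2. **How does network topology differ?** Weighted graph measures
   (efficiencies, clustering, small-worldness, assortativity, hierarchy,
   rich club, betweenness) compared with paired tests.
3. **Do the differences track clinical status?** Spearman correlations of
   edge strengths and metrics against motor/deficit scales, TMS
   excitability, tumor volume and grade, with Benjamini–Hochberg FDR.

Because patient-level connectomes of this kind are generally not
shareable, the package ships a seeded synthetic-cohort generator that
reproduces the statistical structure the analysis assumes, including a
ground-truth lesion ledger for recovery testing.

# The edge-wise model and TFNBS

For subject $s$ and edge $(i,j)$, the paired difference
$d_s = w^{contra}_{ij} - w^{ipsi}_{ij}$ (sign flipped when testing the
opposite direction) is modeled as

$$ d_s = \beta_0 + \beta_1\,\mathrm{side}_s + \varepsilon_s, $$

where $\mathrm{side}_s \in \{-1,+1\}$ is the mean-centered lesion
hemisphere — a nuisance covariate absorbing natural left/right asymmetry
of human brains. The tested statistic is the one-sided intercept $t$ with
$n-2$ degrees of freedom, truncated at zero. If the cohort is all
one-sided the covariate is dropped (plain one-sample $t$, $n-1$ df) with a
warning.

TFNBS replaces each statistic $t_{ij}$ by

$$ \mathrm{score}_{ij} = \sum_{h_k \le t_{ij}} e(h_k)^{E}\, h_k^{H}\, dh,
   \qquad h_k = k\,dh,\quad dh = \max(t)/n_{\text{steps}}, $$

with defaults $E = 0.4$, $H = 3$, $n_{\text{steps}} = 100$. The extent
$e(h)$ has two selectable definitions:

* `"component"` (default): the number of edges in the connected component
  of the suprathreshold graph containing $(i,j)$ — the definition used by
  the TFNBS tool family;
* `"incident"`: the number of suprathreshold edges incident to $i$ or $j$,
  the edge itself included — a literal node-centred reading of the same
  enhancement idea.

Both are exposed because the two readings genuinely coexist in the
literature; all shipped analyses use `"component"`. The integration grid
is adaptive ($dh$ scales with the statistic maximum) so scores are defined
for any statistic scale; published implementations often fix $dh$, which
changes absolute score values but not their ordering, and permutation
p-values are invariant to monotone rescalings of the score.

**Inference.** The null distribution of the maximal enhanced score is
built by Freedman–Lane permutation: residuals from the covariate-only
reduced model are sign-flipped per subject (differences are exchangeable
in sign under the no-asymmetry null), the fitted covariate part is added
back, and the full statistic and score maps are recomputed. With a
constant covariate this reduces exactly to pure sign-flipping, which the
test suite asserts. FWE-corrected p-values use the positively biased
estimator $p = (1 + \#\{\max^{null} \ge \mathrm{score}\})/(n_{perm}+1)$,
so the attainable minimum is $1/(n_{perm}+1)$ and no p-value is ever zero.
Each direction (contra &gt; ipsi, ipsi &gt; contra) is tested one-sided in
its own run. When $n_{perm} > 2^n$ distinct sign patterns exist the
sampler keeps drawing with replacement and warns. The inner score loop is
compiled (Rcpp) with a union-find over suprathreshold edges; a guard of
$10^{-12}\max(t)$ on the threshold comparison keeps the top integration
bin from being lost to floating-point rounding.

# Topology metrics

Edge lengths are reciprocal weights $1/w$ on **raw streamline counts** —
no weight normalization. This convention makes efficiencies carry the
scale of the weights themselves (thousands, for realistic streamline
counts), which is what makes cohort efficiency means in the few-thousand
range interpretable; it is deliberate and documented rather than an
oversight.

* **Global/nodal efficiency**: mean inverse shortest-path length,
  disconnected pairs contributing zero; global efficiency is the mean of
  the nodal values.
* **Local efficiency**: global efficiency of each node's
  neighbor-induced subgraph with original weights, the node removed;
  fewer than two neighbors scores zero. This is one of several
  literature variants; it matches common graph-toolbox behavior.
* **Clustering**: Onnela weighted form, weights normalized by the graph
  maximum (scale-invariant by construction).
* **Hierarchy** $\beta$: negative slope of $\log C_i$ on $\log k_i$ over
  nodes with $k \ge 2$ and $C > 0$; degenerate constant-degree graphs
  return 0, fewer than 3 eligible nodes return `NA`.
* **Rich club**: raw weighted coefficient $\phi^w(k)$ (club weight over
  the equally many strongest edges anywhere); no random-null
  normalization, since only raw values enter downstream comparisons.
* **Small-worldness**: $\gamma = C/\bar C_{null}$,
  $\lambda = L/\bar L_{null}$, $\sigma = \gamma/\lambda$, with
  Maslov–Sneppen degree-preserving rewiring ($10E$ swap attempts) and the
  weight multiset randomly reassigned to rewired positions. $L$ averages
  over *connected* pairs only, because rewired nulls may disconnect; the
  efficiency measures keep the zero-for-disconnected convention instead.
* **Betweenness**: weighted Brandes accumulation over reciprocal-weight
  lengths, endpoints excluded.

Shortest paths, betweenness and rewiring are delegated to igraph; the
test suite verifies efficiencies, betweenness and rich club against
independent brute-force oracles (Floyd–Warshall, exhaustive path
enumeration, direct enumeration) to $10^{-10}$, and checks the
homogeneity property $E(cW) = cE(W)$.

# Cohort statistics

Hemisphere contrasts of scalar metrics use both the paired two-sided $t$
and the Wilcoxon signed-rank test (zero differences dropped; exact null
for $n \le 25$ without ties, else normal approximation with continuity
correction) — the two are reported side by side rather than choosing one.
Zero-variance differences are flagged explicitly ($t = 0, p = 1$ for
all-zero; $p \to 0$ for an exact constant shift).

Clinical correlations are Spearman with mid-rank ties and t-approximation
p-values ($n-2$ df, adequate for $n \ge 8$). FDR families are **declared
explicitly** per analysis block (one family per algorithm × hemispheric
view: all selected edge features and scalar metrics crossed with the
clinical variables); constant features are dropped with a warning and the
family shrinks accordingly. Cross-algorithm agreement is plain Pearson
per metric, per hemisphere or pooled.

# The synthetic cohort

The generator's defaults are the study conditions and are not tuned per
analysis:

| parameter | default | rationale |
|---|---|---|
| `n_subjects` | 37 | cohort size of the motivating study |
| `lesion_side_p_right` | 21/37 | observed side split |
| `subgroup_weights` | 16:15:8:3 | precentral:postcentral:insular:frontal counts; tags sum past 37, so multi-membership is allowed with `overlap_p = 5/37` |
| `grade_weights` | 13:10:14 | WHO II:III:IV counts |
| `volume_mean`, `volume_sd` | 24.97, 23.84 cm³ | lognormal matched by moments |
| `rmt_ratio_mean`, `rmt_ratio_sd` | 1.02, 0.166 | pathological/healthy RMT ratio |
| `mrc_marginal` | {2:1, 3:1, 4:12, 5:23} | assigned by damage quantiles at cohort level |
| `nihss_missing` | 3 | missingness of the deficit scale |
| `lesion_effect_delta` | 0.3 | no published edge-level effect size exists; 0.3 is a test-design choice giving a clearly detectable but not saturating signal |
| `weight_log_mean` | log 4600 | places hemispheric global efficiency near the 5×10³ scale of real streamline-count connectomes (set once from the efficiency–weight linearity, a qualitative anchor only) |

Construction: a **mirror-symmetric template** (modular intra-hemispheric
topology, mirrored module assignments and weights; brainstem edges
mirrored per side; homotopic interhemispheric edges) ensures that with no
lesion effect the split hemispheres are exchangeable — the calibration
configuration (`lesion_effect_delta = 0`, `nihss_coupling = 0`) is a true
global null. Each subject applies per-edge lognormal noise
(`subject_noise_sd`) plus a global scale factor (`subject_scale_sd`);
the global factor exists because i.i.d. per-edge noise averages out in
network-level metrics, and without a shared factor between-subject
efficiency variance would be unrealistically small (real cohorts differ
in total streamline count). The lesion multiplies all ipsilesional edges
incident to a localized node set (the subgroup's seed region plus its
strongest same-module neighbors, 4 nodes by default) by $1-\delta_s$,
with $\delta_s$ Beta-distributed around a mean that increases with WHO
grade and tumor volume. NIHSS couples linearly to the realized fractional
weight loss; MRC follows the configured marginal ordered by damage.
The second "tractography algorithm" is a correlated replicate: a global
scale factor (0.8) and per-edge lognormal noise (sd 0.2) on the same
subject matrix, zero pattern preserved.

**What the generator does not emulate**: tract geometry, edema and mass
effects, distance-dependent weight profiles, hub topology of real
cortex, or lateralized baseline asymmetries (the template is exactly
mirror-symmetric, so the side covariate is exactly null in synthetic
data — it is exercised, not stressed). Binary topology is mirror-fixed
within subject, so purely degree-based measures (degree, assortativity)
are identical between hemispheres by construction; tests on those
measures exercise the degenerate-input paths. Passing recovery tests
therefore shows the statistics behave correctly under the stated model,
not that the model captures everything about real lesioned brains.

# Problem sizes, numerical choices, determinism

* The shipped analyses use 2000 permutations (1000 in the one-call
  driver) and 25–50 small-world nulls; the calibration suite uses 100
  null cohorts × 500 permutations and the FDR suite 200 replicate
  cohorts. These sizes give Monte-Carlo error comfortably inside the
  asserted bands while keeping each run in minutes on a single core.
* All randomness flows from explicit integer seeds; the pipeline derives
  stage seeds as `root * 1000 + offset`, so stages are independently
  reproducible and two runs with one config are byte-identical (the
  report manifest records an md5 config hash that the determinism test
  compares).
* Matrices are validated on construction: symmetric to $10^{-9}$ (then
  symmetrized as $(W+W^\top)/2$), nonnegative, finite, zero diagonal.
  Serialization is dense labeled TSV, round-tripping to $10^{-12}$.
* Degenerate inputs return explicit markers rather than errors where a
  cohort-level analysis must continue: undefined assortativity/hierarchy
  (`NA`), Wilcoxon on all-zero differences (`NA`), subgroup blocks with
  $n < 3$ skipped with a warning.

# Known limitations

* Spearman p-values use the t-approximation; for $n < 8$ an exact
  permutation p would be preferable (not currently implemented).
* The TFNBS adaptive grid means absolute scores are not comparable
  across datasets with different statistic maxima; only within-result
  ordering and permutation p-values are.
* Rich-club coefficients are raw, not null-normalized.
* The lesion model is multiplicative and edge-local; it produces the
  subnetwork and efficiency signatures the statistics target, but it is
  a modeling device, not a biological claim.

# A worked example

```{r example, eval = FALSE}
cohort <- simulate_cohort(generator_config(seed = 7))
pairs <- lapply(seq_len(37), function(i) {
  split_hemispheres(cohort$subjects[[i]]$connectome_a,
                    cohort$clinical$lesion_side[i])
})
res <- permutation_fwe(pairs, cohort$clinical$lesion_side,
                       tfnbs_params(n_perm = 2000, seed = 11))
head(significant_edges(res))
metric_set(pairs[[1]]$ipsi, n_rand = 50, seed = 1)
```
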