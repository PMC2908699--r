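---
title: "Divide-and-conquer decomposition of a transcription factor's binding motif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Divide-and-conquer decomposition of a transcription factor's binding motif}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(submotifr)
```

## The problem

A bacterial transcription factor such as PhoP binds dozens of sites
whose sequences only loosely resemble one consensus. A single position
weight matrix (PWM) averaged over all sites blurs the sub-patterns that
distinguish groups of co-regulated promoters: thresholds strict enough
for specificity discard weak but functional sites, and permissive
thresholds flood genome scans with false hits. `submotifr` implements a
divide-and-conquer alternative:

1. **Divide** — cluster the aligned binding sites into *submotifs*,
   organized into general-to-specific families;
2. **Combine** — encode each submotif as a PWM and let all submotif PWMs
   vote (one positive vote suffices);
3. **Optimize** — tune which submotifs are used and their score
   thresholds with a genetic algorithm under a joint
   accuracy/complexity fitness;
4. **Fuse** — optionally join submotif membership with the distance
   between the binding site and the RNA-polymerase site (promoter
   architecture) through fuzzy IF-THEN rules.

Downstream, the package scans annotated genomes with the resulting
multi-classifier, calls ChIP-chip peaks, assembles the
expression/occupancy/site gene-category table with an empirical false
discovery estimate, and profiles per-position rates of binding-site
evolution under the Halpern–Bruno (HB) model against an HKY85
background.

## Clustering: what is computed and why

Sites of common length $L$ are one-hot encoded into $4L$ binary
features, so squared Euclidean distance equals twice the Hamming
distance. The headline clustering route reports **possibilistic
memberships**

$$u_{ij} = \frac{1}{1 + \left(d_{ij}^2 / \eta_i\right)^{1/(m-1)}},$$

with fuzzifier $m = 2$: a site at a centroid has membership 1,
memberships need not sum to 1 across clusters, and an outlier far from
every centroid weakly belongs to everything. Cluster extraction uses the
hard cut $u \ge 0.5$.

Two numerical facts shaped the implementation, and both are verified by
tests rather than assumed:

* **Iterating centroids on the possibilistic memberships collapses
  them.** With $u^m$-weighted means, every centroid migrates to the
  global mean on one-hot sequence data — the well-documented
  coincident-cluster pathology of possibilistic c-means; the equal-weight
  possibilistic/probabilistic hybrid collapses too on this geometry.
  `pfcm()` therefore drives the centroids with the *constrained*
  fuzzy-c-means fixed point (memberships $w_{ij} \propto d_{ij}^{-2}$
  normalized per site, centroids $w^m$-weighted means) and computes the
  possibilistic layer from the converged centroids. The Xie–Beni index,
  which is defined as a score of fuzzy-c-means partitions, consumes the
  constrained $w$.
* **The bandwidth $\eta$ must be estimated, not fixed at 1.** On one-hot
  features, within-cluster squared distances are of order 10–20; with
  $\eta = 1$ no site ever reaches membership 0.5 and no cluster is
  extracted. The default `eta = "auto"` uses the classic estimate
  $\eta_i = \sum_j w_{ij}^m d_{ij}^2 / \sum_j w_{ij}^m$, which places a
  typical member near membership one half. A numeric `eta` reproduces
  the literal fixed-bandwidth variant.

Initial centroids are seeded from randomly chosen distinct site rows,
each subsequent seed drawn with probability proportional to its squared
distance from the seeds already picked (k-means++-style spreading);
uniform seeding routinely plants two centroids in one tight group, which
then merge.

The number of clusters is chosen by minimizing the Xie–Beni index
(compactness over separation) across candidate $c$, keeping **every**
$c$ within 5% of the minimum — nested data legitimately admits more than
one optimum, and all optimal partitions are clustered and pooled. The
pooled clusters are organized into a tree by the hypergeometric overlap
probability (PI): cluster B is attached beneath the smallest
larger-or-equal cluster A with PI below `alpha_hier` (default 0.01),
otherwise beneath the root single motif.

Two baseline routes are provided for comparison. Single-linkage
agglomerative clustering cuts dendrogram links whose Matlab-style
inconsistency coefficient exceeds a cutoff; note that with the stock
depth 2 the standardization set holds at most three links, capping the
coefficient at $2/\sqrt{3} \approx 1.155$, so the stock cutoff 1.15 is
intentionally marginal — recovery tests use depth 3, cutoff 1.5.
Subtractive clustering iteratively builds a PWM on the remaining
positives, learns the threshold maximizing CC or SCC against the
negatives, peels the recovered sites off as one cluster, and stops when
the measure drops to 0.5; it separates structure only when the negative
set punishes over-inclusive thresholds (see the synthetic worlds below).

## Classification and optimization

Each submotif PWM scores a sequence by its log-odds sum against the
background, min–max normalized by the best and worst achievable scores,
so the consensus scores exactly 1 (ties at score = threshold count
positive). The multi-classifier declares a site when **any** active
voter reaches its threshold. Performance uses the Matthews correlation
(CC) and its standardized form (SCC), which rescales the negative-class
counts to the positive-class magnitude (`FP' = FP·P/N`, `TN' = TN·P/N`)
before the CC formula; with balanced data SCC = CC. For the classical
confusion counts TP = 57, FN = 12, FP = 2, TN = 770, this implementation
returns SCC 0.836 and CC 0.885.

The genetic algorithm works on chromosomes of (presence, threshold)
pairs, one per candidate submotif: tournament selection (size 2),
max–min arithmetical crossover (the four offspring
$a x + (1-a) y$, $a y + (1-a) x$, $\min(x,y)$, $\max(x,y)$ with
$a \sim U(0,1)$ per event; the fittest is kept), asymmetric presence
mutation (on→off 0.05, off→on 0.005), threshold jitter of up to ±10% of
the current value, and one elite. Fitness is
$w_1 \cdot \text{measure} - w_2 \cdot \text{complexity}$, complexity
being the fraction of submotifs used. Defaults (population 50,
generations 100, crossover 0.8) are config-overridable; the test suite
runs smaller GAs (population 20–30, generations 25–40) to stay inside
its runtime budget — on these data the fitness plateaus well before
that.

A boundary worth knowing: with $w_1 = w_2 = 1$ and $k$ equal-size
submotif families, the complexity price of covering one more family
(about $2/k$ for two submotifs) can exceed its SCC contribution, and the
fitness-optimal classifier is legitimately sparse. The family-survival
analysis therefore sweeps the selection pressure ($w_2 \in \{0.1, 0.25,
0.5\}$) and checks that every family keeps an active submotif in each
pressure's optimum; at $w_2 = 1$ on six equal submotifs it would not,
and that is a property of the stated world, not a defect.

## Fuzzy promoter-architecture rules

Normalized PWM scores are read as memberships to a submotif fuzzy set;
signed TF-to-TSS distances are covered by triangular fuzzy sets
(close/medium/far, apexes near −34/−44/−68 bp) fitted by least squares
between the triangular membership and the peak-normalized distance
histogram (bin 2 bp). Candidate rules are the Cartesian product of
submotif and distance sets; a pair becomes a rule when the hypergeometric
PI of its member-set overlap is below $10^{-4}$. The crisp member sets
use the submotif's own score threshold (default 0.8) for the sequence
antecedent — a flat 0.5 cut on min–max-normalized scores admits most of
the training set and erases the enrichment signal — and 0.5 for the
distance antecedent. Inference is product-AND, threshold gate, then
maximum over fired rules; the same GA engine optimizes rule presence and
thresholds.

## Rates of binding-site evolution

The HKY85 background generator $Q$ (transition/transversion ratio
$\kappa$, equilibrium frequencies $\pi$) is normalized to one expected
substitution per unit distance and scaled by the fitted pairwise
distance; `estimate_hky85()` fits $\kappa$ and the distance by
maximizing the pooled pairwise likelihood over non-overlapping sequence
pairs. The Halpern–Bruno rate from base $a$ to $b$ at a position with
PWM column $f$ is

$$R_{ab} = Q_{ab}\,\frac{\ln \lambda}{1 - 1/\lambda},\qquad
\lambda = \frac{f_b\,Q_{ba}}{f_a\,Q_{ab}},$$

which reduces to $Q_{ab}$ when $\lambda = 1$ and vanishes as
$f_b \to 0$. Since divergence time is assumed shared within a species,
profiles report expected *distances* $K$ (rate × time):
$K^{\text{model}}_p = \sum_a f_a(p) \sum_{b \ne a} R_{ab}(p)$ against
the constant $K^{\text{background}} = \sum_a \pi_a \sum_{b \ne a}
Q_{ab}$. High-information positions evolve slowly (Spearman correlation
of IC with $K$ below −0.9 on random columns), and consequently a
strongly conserved submotif's profile deviates *more* from the
background (larger mean square difference) than a weakly conserved
one — the ordering the per-submotif MSD comparisons report. PWM columns
are pseudocounted before the rate computation; zero frequencies are a
domain error.

## The synthetic world

All tests run on seeded generators; every fixture is a pure function of
its configuration and seed. The stated world:

* **Box geometry** — 19-bp sites: two direct-repeat hexamers (positions
  3–8 and 12–17) around a 3-bp spacer, matching the classical
  tandem-repeat box.
* **Families** — 3 families × 2 submotifs × 10 sites. Family consensus
  is random; hexamers are conserved at 0.92 (parents), the child's
  sharpened hexamer at 0.98, spacer/flanks at 0.75. Siblings diverge at
  4 consensus positions inside their sharpened hexamer. These levels
  were chosen from the separation analysis: fuzzy c-means with $m = 2$
  prefers coincident centroids unless the between-centroid squared
  distance exceeds twice the within-cluster scatter, and the stated
  world satisfies that criterion at both the family and the submotif
  scale. A world below that boundary is not clusterable by this method,
  by construction.
* **Negatives** — half are *chimeric decoys*: the first hexamer of one
  family's consensus fused to the second hexamer of another's, at
  family-level conservation. Per-position independent models cannot
  tell a chimera from a true site (each half matches one family), while
  a family-specific submotif sees only a half-match — this is the
  mechanism by which submotif voting beats the single motif, emulating
  negatives drawn from other TFs sharing the direct-repeat grammar.
  The other half are background windows.
* **Distances** — per-family triangular classes with apexes −34, −44,
  −68 bp and half-width 6 bp (signed offset of the box's TSS-proximal
  edge, upstream negative).
* **Genome** — one 50-kb chromosome, ~40 equally spaced operon-head
  genes with 180-bp intergenic gaps; planted promoter sites are
  *functional binders*: sampled from their submotif but resampled until
  they score ≥ 0.88 under it (genomic sites are under selection to
  bind; the sampling tail of a PWM is not a site). A second synthetic
  species lacks the last family (planted submotif turnover).
* **Tiling signal** — 50-bp tiles, N(0, 0.25) baseline, 5-tile boxcars
  at N(3, 0.2) over ChIP-positive promoters (about a third of planted
  genes). Peak tiles are kept below ~5% of the array because the
  calling cutoff is tied to mean + 6 SD of *all* tiles, which dense
  peaks would inflate past their own amplitude.
* **Expression calls** — planted genes are expressed except two
  designated ChIP-positive ones (the binding-without-expression,
  peak-only class); background genes are expressed with probability
  0.05. Unexpressed, unpeaked ("neither") genes therefore carry no
  planted sites, which makes the neither-category site fraction a
  genuine false-discovery estimate.

What a green test does **not** establish: the generators are
statistical stand-ins. Real binding-site collections have unequal
family sizes, correlated positions, composition bias, and negatives
that are not adversarially constructed; real tiling data has spatial
autocorrelation and probe effects. The tests establish that each
algorithm does what its contract says on data with the structure the
method assumes — not that the method will recover biology from any
collection.

## Numerical choices

* Coordinates are 0-based half-open internally; GFF3 converts at the
  boundary. Ambiguity codes are rejected by default (`ambiguity =
  "skip"` drops offending sites).
* PWM pseudocount 0.5, distributed by the background; background
  defaults to uniform and accepts genome composition.
* Score normalization is by best/worst *achievable* scores (not the
  observed range), the reproducible convention; a constant shift of
  every log-odds column cancels.
* Genome-scan thresholds come from `calibrate_thresholds()`: the
  maximum score of each voter over null background regions plus a 0.03
  margin. Training thresholds answer a different question (decoy
  discrimination over 19-mers) and admit too many hits over kilobases.
* Convergence: clustering stops at 100 iterations or centroid movement
  below 1e-6; ties in the Xie–Beni optimum are kept within a 5%
  relative band; minimum cluster size 2 (a one-sequence PWM is
  degenerate).
* Peak FDR randomization shuffles tile values within chromosome,
  20 times, seeded; a peak's score is the fraction of shuffles
  producing an equal-or-denser peak.
* Fuzzy rule thresholds are initialized at 0.4 (the product of the two
  antecedent cuts) and refined by the GA.

## Worked example

```{r example, eval = FALSE}
library(submotifr)

ts <- make_training_set(synth_config(seed = 1))
X <- one_hot_encode(ts$positives)
sel <- select_cluster_numbers(X, 2:8, runs_per_c = 3, seed = 2)
clusters <- unlist(lapply(sel$partitions, partition_to_clusters,
                          collection = ts$positives), recursive = FALSE)
tree <- build_hierarchy(clusters, ts$positives)
subs <- lapply(setdiff(names(tree$nodes), "root"), function(nid)
  build_pwm(ts$positives[tree$nodes[[nid]]$member_ids], name = nid))
res <- ga_optimize(subs, ts$positives, ts$negatives,
                   ga_config(w2 = 0, population = 20, generations = 25,
                             seed = 3))
scc(evaluate_classifier(res$classifier, ts$positives, ts$negatives))
```

## Known limitations

* Sites must be pre-aligned and equal-length; there is no ragged-site
  alignment, no higher-order sequence model, and no de novo motif
  discovery.
* The possibilistic memberships are a read-out layer; they do not feed
  back into centroid estimation (doing so collapses the centroids — see
  above).
* The HKY85 estimator pools non-overlapping pairs rather than fitting a
  tree; it matches the intended use (a background distance scale), not
  full phylogenetic inference. No indel model.
* `categorize_genes` attributes a peak to a gene only when the peak
  overlaps the gene's own intergenic (or coding) region; distance-window
  attribution is not implemented.
* The CLI consumes JSON configuration (not YAML), one file per run,
  with flag overrides.
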