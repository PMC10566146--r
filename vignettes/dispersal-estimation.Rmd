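---
title: "Estimating per-generation dispersal from georeferenced SNPs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating per-generation dispersal from georeferenced SNPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

The effective dispersal rate $\sigma$ — the root-mean-square single-axis
displacement between a child and one of its parents chosen at random, per
generation — controls how genetic variation is structured across a
landscape. Under restricted dispersal, nearby individuals are more related
than distant ones (isolation by distance), so georeferenced SNP genotypes
carry information about $\sigma$. `dispersr` estimates $\sigma$ from a
genotype matrix and a table of per-sample coordinates in two ways:

* a **pairwise convolutional network** trained on simulations from the
  package's own continuous-space model, in the simulation-based-inference
  style: feature extraction is performed independently on every pair of
  individuals with shared weights, each pair's features are concatenated
  with the pair's geographic distance, and a final linear unit maps the
  stacked features of all $\binom{n}{2}$ pairs to $\hat\sigma$;
* **Rousset's regression**, the classical estimator: the slope $b$ of the
  least-squares fit of a pairwise genetic statistic against log geographic
  distance estimates the reciprocal of Wright's neighbourhood size
  $4\pi D \sigma^2$, so $\hat\sigma = \sqrt{1/(4\pi D b)}$ given an
  external density $D$. A non-positive slope leaves $\hat\sigma$ undefined;
  such outcomes are counted, not silently dropped.

## The simulation model

`run_simulation()` implements an individual-based model on a
`habitat_width` × `habitat_width` square with non-overlapping generations.
One interaction scale $\sigma_f$ (map units) is shared by three kernels:

* **dispersal** — each offspring is displaced from its mother by
  independent per-axis Gaussian draws of scale $\sigma_f$;
* **mating** — for each offspring the mother picks a father with
  probability proportional to a Gaussian kernel of scale $\sigma_f$,
  truncated at $3\sigma_f$; a mother with no candidate in range skips that
  attempt;
* **competition** — each individual's expected offspring number is
  $\lambda_i = 2 / (1 + d_i / K)$, where $d_i$ is the local density
  measured with a Gaussian kernel of scale $\sigma_f$ and $K$ is the
  carrying capacity (individuals per square map unit). This keeps the
  census near $K \cdot W^2$ (within ±25% in practice).

Because a child's displacement from its mother has scale $\sigma_f$ and
from its father has scale $\sqrt{2}\sigma_f$ (mother-father distance adds
another kernel draw), the displacement to a randomly chosen parent has
RMS per-axis scale $\sigma = \sigma_f\sqrt{3/2}$. `effective_sigma()`
applies this map; it is the regression target everywhere.

Kernel choices the underlying literature leaves open, and how this package
resolves them:

* **Boundaries**: out-of-bounds displacements are redrawn by default
  (`boundary = "reflect"` mirrors instead). Redrawing truncates the kernel
  for mothers near an edge, which is why kernel-fidelity checks condition
  on mothers at least $3\sigma_f$ from every edge.
* **Degenerate scale** $\sigma_f = 0$: offspring sit exactly on their
  mother, mate choice becomes uniform, and regulation global. This keeps
  the degenerate case well-defined instead of instantly extinct.
* **Burn-in**: the default run length is $\lceil 10 W / \sigma_f \rceil$
  generations, capped by `generation_cap`. Short runs weaken the
  isolation-by-distance signal; the package's own benchmark configuration
  uses 100 generations (below).

## Neutral variation on the realized genealogy

The spatial pass records the full pedigree. SNPs are then overlaid on the
realized genealogy of the individuals one actually samples, exactly as
tree-sequence workflows overlay neutral mutations after simplification:
for each locus, the lineage of every sampled haplotype is traced backward
through the pedigree with an independent Mendelian coin per meiosis, and
one mutation is placed on a pedigree branch chosen uniformly among
branches that still carry ancestry of the sample (generations weighted by
surviving-lineage counts estimated from auxiliary traces, an approximation
to exact branch-length weighting). Every kept locus is therefore
biallelic and segregating *within the sample* — the ascertainment a real
SNP matrix restricted to a sample has. Linkage is approximated piecewise:
genomically adjacent sites are grouped into blocks that share one
realized genealogy, while blocks recombine freely. The default block
count, $\lceil G \cdot r \cdot L \rceil$ (the expected number of
recombination breakpoints a lineage accumulates over the pedigree depth),
matches the number of independent genealogical segments the recorded
pedigree can express — 100 blocks of 5 sites at the reduced scale. The
approximation overstates linkage within a block at deep times and
ignores it between neighbouring blocks; it reproduces the short-range
allele-sharing structure real genomes have without building full
ancestral-recombination machinery. Site positions are drawn uniformly
along the genome and sorted; genotypes are folded to minor-allele counts
(ties at frequency 0.5 keep the current allele).

`run_simulation()` also produces a population-wide site set for
population-level analyses; `sample_dataset()` is the training path
(sample individuals, overlay mutations on their genealogy, subsample to
`m` SNPs). Tree sequences from external spatial simulators are ingested
by exporting their genotypes to VCF and their individual coordinates to a
text table, then using `read_vcf()` and `read_locations()` — the package
does not parse the succinct tree-sequence format itself.

## The network

For each pair the two individuals' genotype rows form a 2-channel input
(4 channels phased). Blocks of convolution (kernel spanning 2 SNPs),
rectified-linear activation and average pooling (10 SNPs) repeat until the
SNP axis falls below the pool width; for `m = 500` that gives two blocks
(500 → 49 → 4) with 32 and 64 filters, for `m = 5000` three (499 → 49 → 4)
with 32/64/128. The flattened output is concatenated with the pair's
Euclidean distance — divided by the habitat width recorded in the training
store, so the distance input is O(1) — and passed through a 128-unit
rectified-linear dense layer. All of this is the "extractor", shared
across pairs; its parameter count does not grow with $n$. The features of
all pairs, stacked in a frozen lexicographic order, feed one linear unit
that predicts the z-scored target.

Design points the architecture description leaves open, resolved as:

* **Block depth/filters**: derived from `m` as above, all configurable in
  `network_spec()` and recorded in the trained weights.
* **Within-pair ordering**: individuals appear in sample-index order; the
  architecture is not symmetric under swapping the two rows. Instead of a
  dedicated swap augmentation, training randomly permutes the sample
  order of each presentation (`augment_permute`, on by default): the
  estimand is invariant under relabelling samples, so the augmentation is
  label-preserving, it covers within-pair swaps as a special case, and it
  pushes the position-specific head towards symmetric aggregation over
  pairs — a strong regulariser when training sets are small. Prediction
  always uses the canonical order, so estimates stay deterministic.
* **Target scaling**: training z-scores $\sigma$ over the training set
  (`normalize_targets()`); the constants ride along with the weights and
  are inverted at prediction. No output clipping: a negative
  $\hat\sigma$ is returned with a warning, as a symptom of an
  under-trained model rather than something to hide.
* **k_extract**: with many samples the $\binom{n}{2}$ pairs make the
  extractor's gradient expensive; `k_extract` pairs, redrawn every batch,
  are allowed to propagate gradients into the extractor while the forward
  pass and the head's gradients always use every pair. Estimates are
  therefore exactly independent of `k_extract`; only the optimisation
  path changes.

Training uses mean squared error on the normalised target and Adam with
learning rate $10^{-4}$ by default (the reference recipe at full scale);
decoupled weight decay is available (`weight_decay`) for small training
sets. Draws from one simulation sample individuals independently, so the
same individual may appear in several draws — they are distinct datasets
with a shared label, which is why validation splits by simulation.
Validation datasets are split off by *simulation* — draws from one
simulation never straddle the split, since they share a label — and the
best-validation checkpoint is restored, with early stopping on patience.
Runs are bit-reproducible for a fixed seed on a fixed device/thread
configuration.

## Reduced-scale benchmark configuration

Full-scale training (50 × 50 habitat, 1000 simulations × 50 draws of
n = 100, m = 5000) is available as the `paper_scale` preset but takes GPU
days. The package standardises a reduced configuration (`desk` preset)
for its own tests and the acceptance script: 10 × 10 habitat, carrying
capacity 5, $\sigma_f \sim U(0.2, 3)$, 100 generations, 250 simulations ×
4 draws of n = 10 individuals and m = 500 SNPs, with 25 × 3 held-out
simulations. The 100-generation run length was chosen at design time by
measuring the information ceiling of the generator with a
criterion-independent probe (random-forest regression of $\sigma$ on rich
pairwise summaries); longer burn-ins and minor-allele-count ascertainment
were probed the same way and bought too little to justify their cost. The
training recipe for this scale — a slimmed extractor (16/32 filters,
64-unit pair dense layer), learning rate $3 \times 10^{-3}$, batch 8,
60 epochs, decoupled weight decay $10^{-3}$, permutation augmentation,
and targets z-scored on the log scale (relative error is the quantity of
interest, so the loss should weight small and large $\sigma$ evenly) —
was tuned on training/validation data only; at a few hundred training
datasets the full-scale 32/64/128 extractor memorises its training
simulations without generalising, and the augmentation/decay pair is what
closes that gap.

A structural limit of the reduced geometry is worth stating plainly.
Effective $\sigma$ spans 0.24–3.67 map units while the habitat is only 10
wide: Wright's neighbourhood size $4\pi K \sigma^2$ exceeds the entire
population once $\sigma \gtrsim 1.5$, so the upper part of the prior is
effectively panmictic and carries almost no spatial information. If that
segment is treated as unidentifiable, the attainable $r^2$ over the whole
prior is capped near 0.6 regardless of estimator; the trained network
sits at that cap (and above a random-forest-on-summaries reference),
while at full scale — where the prior stays identifiable across its whole
range — the same architecture family is far more accurate. Results on the
reduced configuration should therefore be read as a pipeline exercise
with known geometric limits, not as the method's accuracy.

What the reduced-scale tests do *not* show: robustness to demographic
history, heterogeneous habitat, misspecified density, genotyping error or
missingness — the generator varies none of these (a single nuisance-free
model, as in the benchmark it mirrors). Empirical use requires simulating
training data that reflect the study system and sampling design
(`sample_individuals(scheme = "nearest")` matches simulated individuals
to empirical localities after `project_coordinates()`).

## Rousset baseline details

The pairwise statistic is an individual-level analogue of
$F/(1-F)$ built from probabilities of allelic identity: per locus,
identity between the pair $Q_b = (g_i g_j + (2-g_i)(2-g_j))/4$ from
minor-allele counts $g$, identity within an individual $Q_w \in \{0, 1\}$
(heterozygous/homozygous); averaging over loci (and individuals for
$Q_w$), $\hat a = (\bar Q_w - \bar Q_b)/(1 - \bar Q_w)$. The regression
uses log distance (two-dimensional theory); pairs at exactly zero
distance are excluded with a logged count. Benchmarks hand the method the
true density $K$, mirroring how the baseline is treated in comparative
evaluations. Its known failure mode — a non-positive slope on weakly
structured data — is reported as an undefined estimate and summarised as
`undefined_fraction`.

## Numerical and degenerate-input policy

* Pooling truncates a partial window at the end of the SNP axis; the last
  block's pool shrinks to the axis length if needed so the axis never
  vanishes.
* Rectified units use the derivative-zero convention exactly at the kink.
* Monomorphic datasets, zero-variance targets, empty stores, sample-count
  mismatches, population extinction and non-finite losses are explicit
  classed errors, not silent results.
* The binary dataset store is versioned, little-endian, and validates its
  header and record lengths; truncation reports the byte offset.

## Known limitations

* The simulator is a benchmarking model: no demographic perturbations, no
  environmental heterogeneity, no selection, free recombination between
  sites. It is not a substitute for simulations tailored to a study
  system at empirical scales.
* The mutation overlay's generation weighting is approximate (see above);
  site-frequency spectra are realistic in shape but not exact.
* Rousset inversion requires an externally supplied density; errors in
  that density propagate as $1/\sqrt{D}$.
* Training at full scale in this implementation is CPU-bound; the
  `paper_scale` preset is provided for completeness, not routine use.
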