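---
title: "Detection power and subclade structure in clone-library surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detection power and subclade structure in clone-library surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonesurvey)
```

## The problem

Sanger clone-library surveys of microbial symbionts — here, chlamydomonad
green algae ("Oophila") living in the egg capsules of North American
amphibians — sample a handful of cloned PCR amplicons per capsule. Two
questions recur in such surveys:

1. **Detection power.** If every sequenced clone belongs to the dominant
   symbiont, how abundant could an undetected second taxon still be?
2. **Structure.** How do the sampled sequences partition into subclades, and
   how does subclade membership relate to host and site?

`clonesurvey` implements both analyses as a tested pipeline, together with a
synthetic survey generator so that every stage can be validated without any
sequence downloads.

## The detection model

With clones drawn independently and a non-target taxon at per-capsule
incidence $q$, the cumulative probability of seeing it at least once in $n$
clones is

$$P = 1 - (1 - q)^n.$$

The model's two inversions are the workhorses:

* $q_{\max} = 1 - (1-P)^{1/n}$ (`max_incidence()`): the largest incidence
  compatible with zero detections at confidence $P$;
* $n_{\min} = \lceil \log(1-P)/\log(1-q) \rceil$ (`required_clones()`): the
  smallest library achieving detection probability $P$; and the geometric
  expectation $1/q$ (`expected_clones_to_detection()`) — at $q = 0.01$, one
  hundred clones on average before the first hit.

Two assumptions are inherited from the sampling design and are restated in
every report the pipeline writes: *equal incidence of the non-target taxon
among all samples*, and *no amplification bias during PCR*. Under them,
clones pool across capsules and hosts as i.i.d. draws, which is what
justifies the pooled row of `incidence_table()` using $n_{\mathrm{total}} =
\sum_h n_h$. Violations (patchy contamination, primer bias) make the pooled
bound optimistic; the per-host rows are then the safer summary.

```{r}
m <- read_manifest(example_manifest_path())
per_host <- c(
  "A. maculatum" = count_accessions(m, host == "A. maculatum",
                                    location != "Culture collection"),
  "A. gracile"   = count_accessions(m, host == "A. gracile"),
  "L. sylvatica" = count_accessions(m, host == "L. sylvatica"),
  "L. aurora"    = count_accessions(m, host == "L. aurora")
)
incidence_table(per_host, P = 0.99)
```

The bundled manifest transcribes a published four-host survey: 126
amphibian-derived accessions plus three culture-collection strains. Note the
well-known wrinkle of such printed tables: the closed form at $n = 27$ gives
0.1568, which rounds to 0.157 while the original table prints 0.156, and the
$L.\ sylvatica$ row back-solves to a different $n$ than its accession list.
The package does not reverse-engineer the original rounding; it reports full
precision alongside a fixed, documented convention (round half away from
zero, 3 decimals).

## Distances, masking, classification

Distance analysis uses uncorrected ("p") distances: the proportion of
differing residues among *comparable* sites, where a site is comparable iff
both residues are plain `A/C/G/T`. Gaps and IUPAC ambiguity codes are
excluded per pair (pairwise deletion) and ambiguity codes never count as
match or mismatch, even when compatible (`R` vs `A`): any partial-match
weighting would be an arbitrary convention. A pair with no comparable sites
is an explicit error, never a silent zero. Alignment masks (removal of
ambiguously aligned regions) are inputs — one 1-based inclusive range per
line — not inferred; all column indices in the R API are 1-based.

`subclade_range_table()` condenses a distance matrix to min–max percentage
distances per group pair, the familiar upper-triangle layout; singleton
groups report `NA` within-group cells, not 0.

Subclade assignment uses nearest-reference classification
(`assign_to_subclades()`): each clone goes to the reference at minimal
p-distance, with ties broken by lexicographic label (and flagged by
`margin = 0`), and `UNASSIGNED` beyond a distance threshold. The default
threshold of 0.02 sits in the gap between the published within-pair subclade
scale (≤ ~1.9%) and the cross-pair scale (≥ ~3%). This is a deliberately
desk-scale stand-in for reading subclades off a phylogeny: it is exact on
the package's synthetic data, but on real data a clone falling between two
references (recombinant, chimeric, or simply a lineage absent from the
panel) is silently nearest to something; the margin column and the
`UNASSIGNED` class are the guard rails.

## The tree stage

`nj_tree()` is standard neighbor joining on the p-distance matrix (via
`ape::nj`), unrooted, with negative branch-length estimates clamped to zero
and the deficit moved to the longest adjacent edge. NJ is exact on additive
matrices — the test suite verifies topology and branch lengths are recovered
on 50 random 6–10 leaf trees. `bootstrap_supports()` resamples alignment
columns with replacement (the post-mask columns, matching what is actually
analysed), rebuilds the tree per replicate, and scores each internal split
of the point tree by its replicate percentage. Replicates where a pair loses
all comparable sites are discarded with a warning; more than 10% discarded
is an error. `is_monophyletic()` treats monophyly as bipartition membership,
the correct notion on unrooted trees.

Likelihood and parsimony analyses are out of scope by design: those are the
domain of published tools (RAxML, PAUP\*), and the package instead exports
PHYLIP matrices and FASTA for them. NJ bootstrap values are not expected to
match ML/MP supports numerically.

## What the synthetic generator emulates

`simulate_references()` builds a panel of subclade reference sequences at
requested pairwise divergences by fitting the divergence matrix to an
unrooted tree and assigning each edge its own disjoint set of substituted
columns — so realized divergences equal fitted path lengths up to
site-count rounding (the feasibility check allows the larger of 20%
relative error and 1.5/L, the quantisation of a three-edge path). The
default divergence matrix uses the midpoints of the published
between-subclade ranges (I–II 1.2%, III–IV 1.6%, cross pairs 3.3–3.7%) at
the published alignment length L = 1685.

`simulate_capsule_library()` draws each clone independently: non-target with
probability $q$, otherwise a subclade by the capsule's mixture, copied from
the reference with per-site substitutions at `error_rate` (default 0.005,
uniform over the three alternative bases — Jukes–Cantor-like, so
clone-to-reference distance is binomial with mean exactly `error_rate`).
Non-target clones substitute 20% of sites of reference I, which guarantees
≥10% divergence from every reference; the original study reports no
divergence for non-target taxa, so this floor is a package convention.
`simulate_survey()` assembles capsules into a survey with a generated
manifest and a truth table; per-capsule random substreams are derived by
hashing the capsule id with the master seed, so output is independent of
iteration order.

The default design (`survey_design_default()`) mirrors the published
survey's accounting — 85/27/9/5 clones across the four hosts, 4–14 clones
per sampling event — with host mixtures following the reported subclade
structure (A. maculatum mostly I with some III, A. gracile II, L. aurora
III, L. sylvatica IV) and $q = 0$, the observed outcome of zero non-target
detections.

What the generator does **not** emulate: indels (synthetic alignments are
gap-free, so gap handling is tested on hand-built fixtures), rate
heterogeneity along a phylogeny, chimeras, within-capsule clustering of
contaminants (an assumption-faithful i.i.d. model; a beta-distributed
per-capsule $q$ would be the natural extension), or PCR bias. Passing tests
therefore demonstrate correctness of the algorithms under the detection
model's own assumptions, not robustness to their violation on real
libraries.

## Numerical choices

* Detection probabilities use `-expm1(n * log1p(-q))`; the naive power form
  underflows for small $q$ and large $n$ and is forbidden internally.
* The inversion round trip $q \to P \to q$ is exact to 1e-12 only while $P$
  is bounded away from 1; once $1-P$ saturates below double precision
  (e.g. $q = 0.2$, $n \gtrsim 150$) the inversion has no information left.
  Tests assert the tight round trip in the informative regime only.
* `required_clones()` settles knife-edge cases (where the stable and naive
  forms disagree in the last ulp at exact equality) against the plain power
  form, so it agrees with a brute-force scan everywhere.
* Displayed values round half away from zero (3 decimals for incidences, 2
  for percentage distances); machine-readable outputs always carry full
  precision.
* NJ tie-breaking is delegated to `ape::nj`'s deterministic implementation;
  classification ties break lexicographically.

## Reproducibility and problem sizes

Every stochastic function takes an integer seed and restores the caller's
RNG state; `run_survey_pipeline()` drives all randomness from one seed and
re-running a config reproduces every artifact byte for byte (the run
manifest echoes the config without machine-local paths).

The test suite exercises the stochastic claims at sizes chosen to keep the
full run in a couple of minutes while leaving the binomial bounds sharp:
Monte Carlo detection checks at $10^5$ libraries per trial over 200 seeded
trials (restricted to grid cells where the closed form lies in [0.02,
0.98] — at saturated cells the estimated standard error degenerates and a
3-SE criterion is vacuous); coverage of the pooled incidence estimator over
500 replicates of 126 clones at $q \in \{0.01, 0.036, 0.1\}$; and structure
recovery over 20 seeded surveys of four planted subclades (cross divergence
≥3%, 1000 masked columns, 100 bootstrap replicates), requiring monophyly,
≥95% support, and ≥99% truth-label recovery.

## Limitations

The classifier and the range table inherit the reference panel's
completeness; taxa without a reference are only ever `UNASSIGNED`. The
detection bounds are as good as the i.i.d. assumptions. The NJ stage is a
fast distance method: for publication-grade phylogenies export the matrices
to ML/parsimony tools. Real alignments bring gaps and ambiguity codes whose
pairwise-deletion handling can leave few comparable sites between short,
non-overlapping sequences — the package errors loudly in that case rather
than report a distance.
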