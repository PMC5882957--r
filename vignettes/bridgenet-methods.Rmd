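---
title: "Methods: multi-tissue co-expression networks and bridging genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-tissue co-expression networks and bridging genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Female reproductive physiology is coordinated across tissues: over a
~21-day oestrous cycle the ovary, endometrium and oviduct remodel in a
synchronized way, and the genes mediating that synchronization are of
direct interest for fertility research. `bridgenet` implements an
integrated analysis for multi-tissue time-course transcriptomes that asks
two questions:

1. Within each tissue, which genes share a temporal expression program
   (tissue-specific co-expression modules)?
2. Which genes *connect* tissues — i.e. co-express, across the full
   tissue-by-time condition space, with genes of at least two different
   tissues (**bridging genes**), and what core network do they form?

The reference design the package targets is three tissues sampled at days
0, 3, 6, 9, 12, 15 and 18 of the cycle with three biological replicates
per tissue-day, expression quantified as FPKM, and differential expression
(log2 fold change vs day 0, with FDR q-values) supplied by upstream
software. Everything downstream of that differential-expression table is
in scope here.

# Pipeline overview

```
simulate (or load FPKM + DEG table)
  -> stringent 3-rule gene filter
  -> per-gene log2FC profiles over all (tissue, day) conditions
  -> Pearson correlation between gene profiles
  -> PCIT edge significance
  -> |r| > 0.90 co-expression network
  -> max-|FC| tissue assignment
  -> tissue sub-networks, bridging genes, core network
  -> profile clustering (k-means / PAM), condition correlations,
     enrichment and qPCR concordance arithmetic
```

Every stage is an exported function; `run_pipeline()` chains them from a
YAML or list config, persists each stage's output (TSV/GraphML/SIF) and
records a machine-readable summary. All randomness flows from a single
seed.

# The model and its stages

## Input filtering

Genes enter the network stage only if they pass three rules, applied in
order for reporting purposes (the kept set does not depend on the order):

- **R1** — a significant FDR (q < 0.05) in at least one tissue × day;
- **R2** — not an rRNA transcript, and not a de-novo transcript mapping to
  more than two gene symbols;
- **R3** — |log2FC| ≥ 3.0 in at least one tissue × day.

The cut-offs are `gcn_filter_config()` fields. R3 is deliberately
stringent: the network is meant to capture strong, unambiguous temporal
programs. Genes missing from the annotation table are treated as an
unexcluded "unknown" biotype — the filter removes only what is positively
identified as removable.

## Profiles and correlations

Each gene's profile is the vector of log2 fold changes against the
baseline day, over all conditions in the declared order (tissue order
crossed with ascending non-baseline days; 18 columns in the default
design). When recomputed from FPKM, fold changes use replicate-mean FPKM
with a pseudocount of 1, `log2((mean_d + 1) / (mean_0 + 1))`; baseline-day
columns are identically zero and are excluded, since constant columns
would only distort correlations. Profiles are correlated with the plain
Pearson coefficient across the *full* concatenated condition vector —
this is the only reading under which an edge between genes peaking in
different tissues can exist at all, which is precisely what bridging
analysis needs.

## PCIT edge significance

PCIT (partial correlation and information theory) decides which pairwise
correlations are direct rather than explained by a third gene. For every
unordered trio {x, y, z} the three first-order partial correlations are
computed, e.g.

$$r_{xy\cdot z} = \frac{r_{xy} - r_{xz} r_{yz}}
{\sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}},$$

and the trio's tolerance is the mean of the three |partial/direct|
ratios,

$$\varepsilon = \frac{1}{3}\left(
  \left|\frac{r_{xy\cdot z}}{r_{xy}}\right| +
  \left|\frac{r_{xz\cdot y}}{r_{xz}}\right| +
  \left|\frac{r_{yz\cdot x}}{r_{yz}}\right|\right).$$

The edge (x, y) is flagged non-significant if some z satisfies
$|r_{xy}| < \varepsilon\,|r_{xz}|$ **and**
$|r_{xy}| < \varepsilon\,|r_{yz}|$ — its correlation is dominated, up to
the locally estimated tolerance, by both legs of an indirect path. Ties
are retained (strict inequalities). The network then keeps edges that are
both PCIT-significant and above the correlation threshold.

Numerical guards, chosen because the published description assumes
generic real-data correlations and leaves degeneracies open:

- square-root arguments are clamped at 0;
- a partial correlation whose denominator is below 1e-12 (the
  conditioning gene is collinear with the pair) is defined as 0;
- tolerance ratio terms with |direct| < 1e-12 are skipped and the
  remaining terms averaged; a trio with no usable term eliminates
  nothing;
- edges with |r| < 1e-8 are non-significant outright;
- with two genes (no trio exists) the single edge is significant.

The optimized kernel is C++; `pcit_mask_ref()` is an independently
written literal triple-loop R implementation kept as a cross-check
oracle, and the test suite asserts exact mask equality on hundreds of
random sample-correlation matrices.

A caution worth stating explicitly: PCIT's tolerance is a *ratio*
statistic. If many genes are near-exact copies of each other
(correlations within ~1e-4 of 1), every partial correlation in such a
trio approaches ±1, the tolerance approaches 1, and the algorithm
eliminates nearly all edges among the copies. This is mathematically
correct behaviour — an edge between near-duplicates *is* fully explained
by any third near-duplicate — but it means PCIT should not be fed
artificial data in which distinct genes have literally identical
profiles. The synthetic generator therefore gives every gene its own
kinetic heterogeneity (below).

## Threshold semantics

The default edge rule is |r| > 0.90. The squared reading (r² > 0.90,
i.e. |r| > 0.949) is also implemented (`mode = "r2"` in
`build_network()`) because figure captions and methods sections in this
literature vary between the two conventions; the absolute-value reading
is the default and both are explicit flags, so neither is silently
guessed.

## Tissue assignment and topology

Genes are assigned to the tissue (and day) of their maximum |log2FC| —
a deterministic, reproducible proxy for the visual cluster-based
assignment used in the source literature; exact ties are broken by the
declared tissue order, then the earliest day, and flagged. Per tissue,
the sub-network is the induced subgraph on that tissue's genes with
intra-tissue-isolated nodes removed and reported. A **bridging gene** is
any network gene whose direct neighbours span at least two distinct
tissues — the rule depends only on the edge set and neighbour labels, not
on the gene's own label. The **core network** is the subgraph induced on
the bridging genes; its bridge connectivity is the number of full-network
edges with at least one bridging endpoint. Core sub-clusters are reported
descriptively as connected components — the package deliberately does not
guess a community-detection method where none is specified by the
underlying analysis tradition.

## Clustering, PCA and condition correlations

Expression-profile clustering uses k-means (Lloyd iterations, Euclidean
distance) on median-centred profiles with k = 5 by default, seeded
initial centres sampled from the data rows, and 10 restarts keeping the
lowest within-cluster sum of squares — a single random-start Lloyd run
lands in poor local optima often enough to matter (in our validation a
single start merged planted clusters and silhouette then preferred the
wrong k). `choose_k()` scans a k range and selects the highest mean
silhouette width, ties to the smaller k; silhouette was chosen because it
is a standard, implementation-independent internal criterion. Sample
structure is examined with column-centred PCA (via SVD, unscaled — the
log2(FPKM+1) transform is already variance-stabilizing in the relevant
range) and with PAM (k = 3, one cluster per tissue), which is
deterministic.

Condition-versus-condition correlation matrices (`condition_corr_matrix`)
correlate condition *columns* across a declared gene set — the reading in
which the matrix axes enumerate phases × tissues. Zero-variance columns
are flagged and their entries set to 0 rather than propagating NaN.
A point that matters when interpreting these matrices: for genes whose
response is confined to a single tissue, a condition of tissue A and a
condition of tissue B have *disjoint support* across genes, and the
across-gene correlation between such columns is dominated by the product
of the column means — an ovary-down/endometrium-up design then yields
*positive* A-vs-B correlation. Genuinely negative cross-tissue
correlation requires genes responding in both tissues with opposite
signs, i.e. the core-network genes. This is why the sign-structure
analysis is computed over the bridging genes.

## Enrichment, qPCR and concordance

Gene-set enrichment is the exact hypergeometric upper tail
P[X ≥ k] with fold enrichment (k/n)/(K/N), computed against an explicit
universe (GMT members outside the universe are dropped and counted), with
Benjamini–Hochberg q-values across all tested sets and the conventional
display cut-offs (−log10 p > 1, hit count > 3, both strict) as flags. The
modified one-tailed EASE variant used by some web services is *not*
replicated — its background tables are service-internal, so exactness
against those outputs is out of reach and not claimed.

qPCR relative quantification follows 2^−ΔΔCT with the target CT
normalised against the *geometric mean* of the reference-gene CTs per
sample and a declared calibrator sample (whose RQ is exactly 1).
Cross-platform concordance is Pearson r/r² plus an ordinary
least-squares fit of one platform's log2FC on the other's over matched
gene × condition pairs.

# The synthetic-data generator

The generator (`synthetic_design()`, `simulate_dataset()`) is a
first-class module: it defines the study conditions under which the
pipeline is validated, with planted ground truth for every stage.

## What it emulates

- **Design**: 3 tissues × 7 days (0–18) × 3 replicates.
- **Modules**: five temporal archetypes mimicking the expression clusters
  of cycling reproductive tissues — endometrial up- and down-regulation
  peaking days 6–12, ovarian up- and down-regulation spanning days 3–12,
  broad oviductal down-regulation. Default module sizes
  198/176/198/176/132 plus 24 bridging genes give 904 network-input
  genes, the scale at which the pipeline is exercised.
- **Per-gene realization**: gene FPKM in (tissue t, day d, replicate) is
  `baseline · offset_t · 2^(signal(t, d) + N(0, noise_sd))` with
  `signal = amplitude · effect_size · multiplier(t, d)`. Amplitude is
  per-gene U(0.85, 1); effect size 4.0 (peak |log2FC| comfortably above
  the 3.0 filter); replicate noise sd 0.5 on the log2 scale.
- **Kinetic heterogeneity**: each gene's archetype multipliers are
  perturbed by N(0, 0.10) and renormalised to peak 1. Co-expressed genes
  in real data track a shared program imperfectly; as noted above, exact
  copies are also a degenerate input for PCIT, so the jitter is both the
  realistic and the numerically sound choice.
- **Baselines**: log-normal(log 500, 0.7) truncated below at 200 FPKM,
  with per-tissue offsets 2^U(−2, 2). Truncation keeps the +1-pseudocount
  distortion of observed log2FC (which for down-regulation is
  ≈ log2(1 + 2^|FC|/baseline), much larger than for up-regulation)
  strictly below the margin between the planted peak (≥ 3.4) and the 3.0
  cut-off, so the stringent filter recovers exactly the planted genes in
  the noise-free limit. The wide tissue offsets make tissue identity
  dominate sample-space distances, as it does in real multi-tissue data
  (PCA and PAM separate tissues cleanly, including day-0 samples).
  Offsets cancel exactly in within-tissue fold changes.
- **q-values**: Uniform(0, 0.01) where the planted |log2FC| reaches 3.0,
  Uniform(0.2, 1) otherwise — a calibrated surrogate for an upstream
  differential-expression test, sufficient to exercise the q-filter and
  consistent with the planted truth by construction.

## Bridging-gene geometry

Planting *recoverable* bridging genes is the delicate part, and the
design is dictated by a bound worth recording. If module genes respond
only in their own tissue, a bridge mixing archetypes of tissues A and B
splits its variance between the two tissues' condition blocks; over the
full condition vector its correlation with a pure module gene is capped
at √3/2 ≈ 0.866 (variance-split bound, attained by constant anti-signed
profiles), i.e. *below* the 0.90 edge threshold. Bridge–module edges
above 0.90 are therefore impossible in this generative family, and
bridging must be carried by bridge–bridge edges. The generator plants,
per tissue pair, a group of 8 bridges split into two sign-mirrored
subgroups: forward genes carry `primary + 0.85 · secondary`, mirrored
genes the negated signal with dominance reversed. Within a group all
pairs are correlated at |r| ≈ 0.99 before attenuation, while the
max-|FC| rule deterministically assigns the two subgroups to the two
tissues (the dominance gap of 0.6·amplitude dwarfs both the pseudocount
distortion and, with high probability, the replicate noise). Bridges use
their own early/late-phase archetypes, phase-shifted from the module
programs, keeping bridge–module correlations near 0.83 so that module
genes are not spuriously flagged as bridging under noise.

Consequences to keep in mind when reading results on synthetic data:
cross-tissue edges are bridge–bridge edges (all of them are incident to
planted bridges — the "triangular" topology); and each tissue sub-network
contains its planted module genes plus the bridges assigned to that
tissue, exactly as bridging genes appear inside tissue clusters in real
integrated networks.

## What it does not emulate

Read-level artefacts (no FASTQ, alignment or assembly noise), library
size and count overdispersion, batch effects, correlated replicate
structure, missing data, annotation noise (the generator emits no rRNA or
multi-symbol decoys; the biotype filter rule is exercised by dedicated
unit fixtures), and any real regulatory biology: passing the recovery tests shows
the *pipeline* is correct under its stated assumptions, not that those
assumptions hold for any particular real dataset.

# Validation and problem sizes

The test suite validates each operation against independent oracles
(hand computations, textbook two-pass formulas, brute-force triple loops,
Monte-Carlo resampling) and the whole pipeline against planted truth:

- noise-free default design (904 network genes): filter, sub-network,
  bridging and assignment recovery are all exact;
- noisy design (sd 0.5, 10 seeds): mean bridging precision ≈ 0.95,
  recall ≈ 0.97, tissue-assignment accuracy 1.0;
- k-means at k = 5 recovers planted archetypes (adjusted Rand index 1.0);
  silhouette selects k = 5 from 2..8;
- PCIT mask equality with the reference implementation on 200 random
  correlation matrices (n ≤ 30), and the 904-gene problem completes in a
  few seconds on one CPU;
- all interchange formats (GraphML, SIF + attribute TSVs, expression /
  DEG / truth / profile TSVs) round-trip losslessly.

`scripts/acceptance.R` re-runs these studies from scratch at the same
problem sizes and writes the headline numbers as JSON.

# Known limitations

- The max-|FC| tissue assignment is a deterministic proxy; genes with
  genuinely multi-tissue responses sit near its decision boundary and
  their assignment under noise is stochastic (bridging detection is
  robust to this by construction, via subgroup redundancy).
- PCIT is O(n³) in trios; the C++ kernel handles ~10³ genes in seconds
  but the algorithm is not intended for 10⁴–10⁵-node problems.
- The enrichment module implements the exact hypergeometric test only;
  results will differ from web services that use modified statistics or
  proprietary backgrounds.
- Condition-correlation analysis assumes the gene set has variance in
  every condition; degenerate columns are reported and zeroed rather
  than imputed.
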