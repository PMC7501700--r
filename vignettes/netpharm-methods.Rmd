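---
title: "Methods: network pharmacology of multi-herb formulas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network pharmacology of multi-herb formulas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

`netpharm` analyzes a multi-herb formula as a bipartite pharmacology
problem: hundreds of ingredients, each a small molecule, interact with a
shared universe of protein targets, and the therapeutic hypothesis is that
a subset of ingredients collectively engages a disease-relevant
neighborhood of that universe. This vignette documents the models, the
tunable parameters, the numerical conventions, and the design decisions
behind each stage, along with what the synthetic benchmarks do and do not
establish.

## Resource diffusion on the tripartite graph

### The graph

`build_tripartite()` assembles three node layers: drugs (compounds),
substructure bits, and protein targets. A drug is connected to every
fingerprint bit set to 1 in its row and to every target it is known to
interact with. There are no within-layer or substructure–target edges.
Compounds with an all-zero fingerprint row carry no chemical information
and are excluded with a warning; an empty DTI list is legal
(new-chemical-entity mode), in which case predictions are driven purely by
substructure sharing.

### The diffusion contract

The update rule is fixed as the package's contract and is chosen so each
of the four parameters plays exactly its advertised role. Variants of
substructure-based network inference differ in bookkeeping details across
implementations, so the precise rule used here is spelled out:

* **Initial resource** (`initial_resource()`): a unit mass for drug $d$ is
  split — fraction $\alpha$ evenly over $d$'s substructure neighbors and
  $1-\alpha$ evenly over its known targets. A drug with no known targets
  sends everything to its substructure side.
* **One round** (`propagate()`): (i) every substructure/target node
  returns its mass evenly to its neighboring drugs; (ii) every drug sends
  fraction $\beta$ of its mass to its substructure neighbors and $1-\beta$
  to its target neighbors (all of it to the side that exists when the
  other is empty), and *within* a side allocates to neighbor $v$
  proportionally to $\deg(v)^{\gamma}$, where $\deg$ is the static total
  degree in the tripartite graph, computed once before diffusion.
* **Score**: after $k$ rounds the mass on each target node is the
  prediction score. Scores are reported raw (no normalization); only
  ranks are contractually meaningful.

Defaults are $\alpha = \beta = 0.1$, $\gamma = -0.5$, $k = 2$, and the
top 20 ranked targets are kept per compound. $\alpha$ and $\beta$ small
mean most information flows through the known-DTI side with the chemistry
acting as a correction; $\gamma < 0$ damps promiscuous hub targets; $k=2$
reaches targets two collaborative hops away.

Because each drug's outflow is normalized within each side, total mass is
conserved for *every* $\gamma$, not only $\gamma = 0$; the test suite
asserts conservation to $10^{-9}$ per round and checks the full update
against an independent dense, loop-based oracle on hundreds of random
small graphs.

Two further conventions guarantee reproducibility:

* **"Putative" means "not already known"**: a drug's known targets are
  removed from its ranked list (`exclude_known = FALSE` is available for
  evaluation harnesses).
* **Ties** are broken by lexicographic gene symbol.

### Hold-out evaluation

`evaluate_auc()` hides a seeded uniform fraction of the known DTIs,
refits on the rest, and scores every non-retained (drug, target) pair.
Held-out edges are positives; never-known pairs are negatives; the AUC is
the rank (Mann–Whitney) statistic. Targets that lose all training edges
score zero — they attract no mass — rather than being dropped, so the
evaluation cannot silently shrink its negative set.

## Drug–target network statistics

`assemble_network()` unions known and predicted edges, keeping
provenance; when the same edge appears in both lists the known record
wins. `degree_summary()` reports the two global means
$D = \text{edges}/\text{compounds}$ and
$K = \text{edges}/\text{targets}$. Reported means are rounded **half-up**
to one decimal (the convention used in published tables; R's own
`round()` rounds half to even), with full precision retained in the
returned object. For the key-ingredient subnetwork the ambiguous phrase
"average degree" is interpreted as the mean *target-side* degree
(edges/targets); both sides are always reported so the reader can take
either. Degree counts known + predicted edges together by default, with a
provenance filter available.

Herb-level operations treat a herb's target set as the union of its
compounds' network neighbors. Overlap matrices are symmetric with item-set
sizes on the diagonal.

## Compound–disease prioritization

For compound $i$ with target set $T_i$ inside a universe $U$ of which
$D \subset U$ are disease genes, the 2×2 table is
$a = |T_i \cap D|$, $b = |T_i \setminus D|$, $c = |D \setminus T_i|$,
$d = |U| - a - b - c$, and the p-value is the right (enrichment) tail of
the hypergeometric law, computed exactly. Decisions that the data do not
force, made once and documented:

* **Universe** = the target genes present in the assembled network
  (`universe = "network"`), the natural analogue of testing against the
  formula's own target space; `"union"` (network targets plus disease
  genes) is available. Published q-values for this kind of screen cannot
  be pinned without knowing the original background, so cross-study
  comparisons should be qualitative (orderings), not numeric.
* **One-sided (greater)**: enrichment, not depletion, is the hypothesis.
* **BH family** = all compounds tested in the run. Compounds with zero
  in-universe targets are excluded from the family rather than assigned
  $p = 1$: they cannot be enriched, and padding the family with them
  would deflate everyone else's q.

`ora_hypergeometric()` applies the same tail test per annotation set for
GMT collections, BH-adjusted across sets; it is deliberately
DAG-unaware (no GO propagation, no pathway topology).

## The four-step screen

`four_step_screen()` is a pure conjunction of four gates — main-component
membership, Rule of Five (strict `<` at every boundary, exactly as the
rule is stated), HIA/BBB probabilities at an inclusive 0.5 cutoff, and
enrichment $q < q^*$. Because it is a conjunction, gate order is
immaterial and tightening any threshold can only shrink the retained set;
both properties are tested. Missing physicochemical or ADMET data makes a
compound *ineligible* (NA) rather than failed, and ineligible compounds
are never retained — a conservative choice that keeps curation gaps
visible in the audit table instead of silently passing them.

The HIA/BBB positive-call cutoff is not standardized by the upstream
classifiers that produce these probabilities; 0.5 on the positive-class
probability is the package default and is configurable. ADMET
probabilities are inputs: the package gates on them and does not
reimplement any trained ADMET model.

The nine benchmark ingredients shipped in
`inst/extdata/dss_key_ingredients.csv` are the nine key anti-AD
ingredients reported for the Danggui-Shaoyao-san (DSS) formula, with
their reported physicochemical values, ADMET probabilities and q-values.
Two cells were typographically merged in the available transcription of
the table; they were completed with the compounds' standard H-bond
donor/acceptor counts
(ferulic acid: 2 donors, 4 acceptors; gallic acid: 4 and 4). Every
plausible reading passes the Rule-of-Five gate, so the screen's outcome
does not depend on the resolution.

## The synthetic benchmark generator

`generate_synthetic()` produces a complete dataset with the statistical
structure the analysis assumes; `null_dataset()` produces its
structureless twin. The default configuration — 6 herbs over a shared
pool of 400 compounds, 200 targets, 300 fingerprint bits, 30 disease
genes, 20 planted actives, planting strength $s = 0.6$ against a
background disease fraction of $30/200 = 0.15$ — is the regime used by
the whole test suite, sized so the full suite and the acceptance script
run in well under a minute each while keeping every estimate stable
across seeds.

Design of the coupling, which is the scientifically load-bearing part:

* **Latent scaffold modules.** Each compound belongs to one of 40 latent
  modules; each module owns a profile of 15 targets. A compound draws
  ~85% of its targets (Poisson mean 8, truncated at 1) from its module
  and 15% uniformly. Compounds sharing a module therefore share targets —
  the collaborative structure that makes hold-out recovery possible at
  all. A generator whose compounds draw targets independently has *no*
  recoverable signal, however fingerprints are wired: the diffusion
  model's known-DTI channel would be pure noise.
* **Driver bits.** Each target owns 3 driver bits among the 300; a
  compound carries each driver bit of each of its targets with
  probability 0.9 (the fingerprint–target coupling), plus background
  noise bits at density 0.02. Chemistry thus mirrors pharmacology, the
  assumption behind substructure-based inference.
* **Disease neighborhood and planting.** Disease genes are excluded from
  the background module profiles: they form a pathway neighborhood that
  background compounds reach only through the uniform-noise channel,
  while each planted active draws at least $\lceil s \cdot n \rceil$ of
  its $n$ targets from the disease set (realized fraction ≥ $s$ by
  construction, which the suite asserts). Planted actives consequently
  share disease targets and disease-driver bits with each other, so both
  their known profiles and their diffusion predictions concentrate on the
  disease neighborhood — the situation the prioritization statistic is
  designed to detect.
* **Herb structure.** Each of 6 herbs samples 100 compounds from the
  shared pool (compounds left uncovered are assigned to a random herb),
  reproducing the heavy inter-herb ingredient sharing characteristic of
  real formulas.
* **Reproducibility.** One seed; each component (disease draw, planting,
  drivers, targets, fingerprints, herbs, physicochemistry) uses a
  deterministically derived sub-stream, so adding a component never
  perturbs the others, and a config + seed pair regenerates byte-identical
  files via `write_dataset()`.

The null twin removes planting and all coupling (uniform targets, noise
fingerprints at the matched marginal density). The suite uses it for
type-I-error control of the enrichment screen (significant fraction at
$q<0.05$ near zero over 20 seeds) and for the diffusion AUC, which must
sit near 0.5 when there is nothing to learn.

What passing these benchmarks shows: the statistics are implemented
correctly, calibrated under the null, and able to recover a planted
signal of realistic strength end-to-end. What it does not show: real
fingerprints are not conditionally independent bits, real DTI networks
have curation biases and hub structure far heavier-tailed than Poisson,
real disease gene sets overlap pathway modules rather than excluding
them, and the synthetic SMILES/physicochemical columns are placeholders.
Performance numbers on synthetic defaults therefore validate the
machinery, not any particular biological claim.

## Numerical and degenerate-input conventions

* Exact hypergeometric tails via `stats::phyper`; the test oracle is an
  independent `choose()`-based pmf summation, compared exhaustively on
  every 2×2 table with total ≤ 30.
* BH adjustment via `stats::p.adjust(method = "BH")` after validating
  inputs to $[0,1]$.
* Empty layers are legal where the science allows (no known DTIs); empty
  networks, empty universes, and negative tables are errors.
* Gene identity is the uppercased symbol string; no alias mapping.
  Compound identity is the supplied id string; no structure-based
  deduplication.
* Delimiters are inferred from file extension (`.tsv` tab, `.csv`
  comma); headers are mandatory; duplicate ids and non-binary
  fingerprint cells are errors naming the offender.

## The pipeline

`run_pipeline()` composes the stages — diffusion, network assembly,
degree/overlap analysis, enrichment, screening — from one config
(R object or YAML), writes each stage's TSV, and emits a manifest with
input digests, per-stage counts, the seed, and the package version. Stage
outputs are pure functions of (inputs, config, seed): the suite asserts
byte-identical TSVs across re-runs. The exported functions plus
`scripts/acceptance.R` are the intended entry points; there is no
separate shell binary.

## Known limitations

* The diffusion rule is this package's fixed contract; other
  implementations of substructure-based network inference may normalize
  or iterate differently, so absolute scores are not comparable across
  tools (ranks within a compound generally are).
* Whether resource renormalization under $\gamma \ne 0$ matches any
  particular external tool is unresolved by design; within-drug ranks,
  which are all the pipeline consumes, are unaffected by any per-drug
  monotone rescaling.
* Enrichment q-values depend on the BH family and universe; compare
  orderings, not magnitudes, across studies.
* No visualization/layout, no web-service annotation, no SDF/structure
  parsing, and no trained ADMET models — probabilities, fingerprints and
  curated gene lists are consumed as inputs.
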