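---
title: "Context-specific metabolic models and in silico drug screening with gemscreen"
author: "gemscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-specific metabolic models and in silico drug screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gemscreen)
```

# The problem

Glioma subtypes (glioblastoma, astrocytoma, oligodendroglioma) rewire their
metabolism in subtype-specific ways, and those rewirings are therapeutic
opportunities: a metabolite exchange that is pinned at optimal growth, a gene
whose deletion halves growth, or a pair of redundant biosynthesis routes that
two drugs can close together. `gemscreen` implements the full inference chain
that turns a generic genome-scale metabolic reconstruction, an RNA-seq
expression matrix and a defined extracellular medium (in practice,
cerebrospinal-fluid-like) into such predictions, and then ranks the candidate
drugs against curated evidence tables.

The chain is: **discretize** expression into expressed/unknown/inactive gene
calls, **map** calls to reactions through gene-protein-reaction (GPR) rules,
**extract** a compact flux-consistent context-specific model per subtype
(FASTCORE-family two-LP scheme), then on each model run **flux variability
analysis** of the exchanges, a **single-gene deletion** screen, **drug and
drug-combination** knockouts with Bliss-independence scoring and a
healthy-control safety check, and finally an evidence-tiered **ranking**.

# The model

All simulation rests on flux balance analysis (FBA): given stoichiometry $S$
and bounds $l \le v \le u$ (mmol·gDW$^{-1}$·h$^{-1}$), maximize biomass flux
$v_{bio}$ subject to the steady state $S v = 0$. Flux variability analysis
(FVA) then constrains $v_{bio} \ge f \cdot z^\*$ and minimizes/maximizes each
reaction separately. Exchange reactions use the export-positive convention:
uptake is negative flux, and a medium is a table of maximal uptake rates that
become lower bounds of the exchanges (`applyMedium()`); no concentration-to-
rate conversion is attempted, so media must be supplied in rate units.

No linear-programming package is available as an R dependency here, so the
package carries its own LP engine: a bounded-variable primal simplex
(two phases, explicit basis inverse, Dantzig pricing with a Bland's-rule
fallback against cycling) written in C++. The test suite cross-checks it
against `boot::simplex`, an entirely independent implementation, on hundreds
of randomized networks; agreement is required to $10^{-6}$.

Key quantities downstream:

* **grRatio** $= z^\*_{KO} / z^\*_{WT}$, the knockout-to-wild-type growth
  ratio; the drug effect is $E = 1 - \mathrm{grRatio}$.
* **Bliss independence**: for a pair with effects $E_A, E_B$, the expected
  joint effect is $E_{exp} = E_A + E_B - E_A E_B$. The pair is synergistic
  when $E_{AB} > E_{exp} + \delta$, antagonistic below $E_{exp} - \delta$,
  additive otherwise. The excess form is the default; a combination-index
  (ratio) form is available via `classifyBliss(..., method = "ratio")`.
* **Narrow-bounded exchange**: relative FVA range
  $r = (\max - \min) / R_{max} \le 0.10$ at $f = 1$, where $R_{max}$ is the
  *attainable* range of the same reaction with the objective constraint
  removed. "Maximal range" could also mean the raw bound span; both are
  implemented (`rmax = "attainable"` is the default because it makes $r$
  medium-aware and never flags a reaction narrow merely because its
  nominal caps are huge). A reaction with $R_{max} = 0$ is fully fixed and
  reported narrow.

# Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `fraction` (f) | 1.0 | FVA optimality fraction; presets 0.9, 0.95. At f = 1 the constraint is relaxed to $(1-10^{-6})z^\*$ to avoid numerical infeasibility. |
| `epsilon` | 1e-4 | flux-consistency threshold of the FASTCORE family |
| `tau` (solver) | 1e-9 | LP feasibility/optimality tolerance |
| `p_hi`, `p_lo` | 0.9, 0.1 | posterior thresholds of the expression discretization |
| `q` | 0.9 | consensus threshold: fraction of samples in which a reaction must be core |
| `cutoff` | 0.5 | minimal growth reduction for essentiality and drug hits, inclusive ("at least 50%") |
| `delta` | 0.05 | Bliss synergy tolerance |
| `eta` | 0.05 | tolerated loss of control-model biomass/ATP in the safety check |
| `ratio_cutoff` | 0.10 | narrow-bounded relative-range rule, inclusive |

Boundary conventions were chosen inclusive throughout (a knockout reducing
growth by exactly 50% is essential; a relative range of exactly 10% is
narrow; a xenograft growth reduction of exactly 25% is effective), matching
the "at least"/"a maximum of" phrasing such thresholds carry in the
literature.

# Discretization and model extraction

`discretizeExpression()` fits, per sample, a two-component Gaussian mixture
(via `mclust`) to $\log_2(x+1)$ of the genes with nonzero expression. A gene
is called expressed at posterior $\ge$ `p_hi` for the high-mean component,
inactive at $\le$ `p_lo`, unknown in between; zero-expression genes are
inactive directly. The fit is deterministic (model-based hierarchical
initialisation), so identical samples give identical calls. Degenerate
samples (all values equal) yield all-unknown calls with a warning rather
than a spurious fit.

`mapCallsToReactions()` scores each GPR with AND→min, OR→max over the
ternary calls; +1 reactions are core, −1 inactive, 0 or empty-GPR unknown.
`buildConsensusModel()` pools per-sample assignments ("agreement" mode):
reactions core in at least `q` of a subtype's samples form the consensus
core, reactions inactive in at least `q` are closed. How the original study
pooled sample evidence into consensus models is not recoverable from its
text; both this mode and a pooled-calls mode (`poolGeneCalls()`, majority
vote on the gene level before mapping) are provided, with agreement as the
default because it keeps per-sample model membership interpretable.
"Unknown" reactions are neutral during extraction — they carry no penalty
relief and no core privilege; the extractor adds them only when needed to
keep the core consistent.

`fastcoreExtract()` implements the FASTCORE-family two-LP scheme on a
reversible-split network: LP7 maximizes the number of core reactions
carrying at least `epsilon` flux; an L1-penalty LP then minimizes total
non-core flux subject to the covered cores staying at `epsilon`, and the
support of that sparse mode is accepted. Because the split network is purely
irreversible, the L1 objective is a plain linear objective — no auxiliary
variables. The loop repeats on uncovered cores; ties are broken by the fixed
input reaction order, so extraction is deterministic. The biomass reaction,
the ATP-demand reaction and the medium-opened exchanges are always
force-included, otherwise no growth objective would survive extraction. A
final consistency pass guarantees the advertised contract (output ⊇ core,
induced subnetwork consistent at `epsilon`); a blocked core reaction is an
error that names the reaction.

# The screens

`singleGeneDeletion()` closes, per gene, every reaction whose GPR evaluates
false under the deletion and re-solves; ratios are clipped to $[0,1]$.
`screenSingleDrugs()` deletes each drug's whole mapped target set jointly —
a drug hitting both of two redundant branches can be lethal although each
single-gene knockout is harmless. `screenCombinations()` pairs FDA-approved
drugs with approved anti-brain-tumour chemotherapies (AntiBC) and
investigational anti-glioma drugs (IAG); FDA drugs that already shut down
biomass on their own are excluded from pairing (they need no partner, and
the study design excludes them globally rather than per model so that one
candidate pair list exists across subtypes). `safetyCheck()` applies a
joint deletion to the healthy control model and requires both maximal
biomass and maximal ATP-demand flux to retain $1-\eta$ of their wild-type
optima.

`rankCandidates()` orders retained candidates lexicographically: effective
evidence tiers (in vitro, xenograft, clinical) descending, then drug–drug
interaction severity ascending, then potency (median IC50 after averaging
duplicate cell-line records) ascending, then LogBB (CSF-to-plasma log
ratio) descending, drug id last. DDI severities order
none < minor < unknown < major: the unknown level has no stated place in
the source ordering, and placing it between minor and major is the
conservative reading (an unknown interaction should not outrank a known
minor one). CSF LogBB is preferred over the binary BBB flag whenever both
exist. The evidence-tier criteria live in a config list
(`.TIER_RULES_DEFAULT`) so the scheme is auditable and replaceable.

# The synthetic-data generator

`generateScenario()` emits every input the pipeline consumes, with planted,
LP-verifiable truth. The toy network (~34 reactions with the default three
decoy chains) has a biomass reaction draining six precursors:

* **prec1** — two fully redundant routes (genes `gB1`, `gB2`) active in all
  subtypes: the planted *pan* synergy pair (drug `dB1` + AntiBC `bB2`);
  a third route `gB3` exists only in the healthy control, which is why the
  pair is tumour-selective.
* **prec2** — redundant pair `gC1`/`gC2` everywhere plus bypass `gC3` in
  subtypes 2, 3 and the control: the planted *subtype-1-specific* pair
  (`dC1` + IAG `iC2`), passing the control safety check.
* **prec3** — a sole route gated by `gE`: the planted pan essential gene and
  the planted lethal single drug `dE` (excluded from pairing).
* **prec4** — routes `gF1`/`gF2` with subtype-restricted expression: planted
  subtype-specific essential genes.
* **nut1** — growth-limiting nutrient (uptake cap 2 sets $z^\* = 2$), its
  exchange is pinned at the optimum in every subtype (pan narrow-bounded).
* **aa** — importable everywhere, synthesizable from glucose only outside
  subtype 1: its exchange (and the glucose exchange) is narrow-bounded only
  in subtype 1, the planted subtype-specific narrow exchange. The ATP route
  capacity is deliberately small (0.5) so the ATP drain cannot blur these
  forced-uptake plants.

Expression is drawn per sample from silent ~ LogNormal(log 1, 0.5) and
expressed ~ LogNormal(log 64, 0.5) — about five standard deviations apart in
log space, which gives clean bimodality at toy scale; defaults are 8 samples
per subtype and 4 controls, the small-cohort regime the pipeline must
tolerate. Decoy chains with seeded random subtype activity, off-network
genes and a planted dead-end reaction (blocked, caught by the consistency
filter) provide realistic clutter. What the generator does **not** emulate:
dropout/noise structure of real RNA-seq, overlapping expression modes,
many-to-many GPRs at genome scale, or real CSF composition values — so
passing tests demonstrate the machinery recovers planted truth under clean
separation, not that real-data discretization is this easy.

`verifyScenario()` re-derives every planted claim by brute force —
per-gene and per-pair knockout LPs, exchange FVA with an explicit optimality
row, text-substitution GPR evaluation — in a code path deliberately separate
from the screening functions, and reports mismatches as rows rather than
exceptions. It is the oracle the acceptance checks build on.

# A worked run

```{r pipeline, eval = FALSE}
sc <- generateScenario(seed = 1)
dir <- tempfile("scenario")
writeScenario(sc, dir)

res <- runPipeline(list(
  network = file.path(dir, "model.json"),
  medium = file.path(dir, "medium.csv"),
  expression = file.path(dir, "expression.tsv"),
  labels = file.path(dir, "labels.csv"),
  catalog = file.path(dir, "catalog.tsv"),
  evidence_dir = file.path(dir, "evidence"),
  out_dir = file.path(dir, "out"),
  seed = 1))

res$comboSpecificity
#>   drugA drugB                 hit_models          specificity
#> 1   dB1   bB2 subtype1,subtype2,subtype3                  pan
#> 2   dC1   iC2                   subtype1 specific to subtype1
```

The run writes one TSV per stage plus a `manifest.json` (input MD5 hashes,
thresholds, seed, package version — no timestamps, so re-running an
identical config reproduces identical bytes).

# Numerical choices and degenerate inputs

* Solver tolerance $10^{-9}$; consistency support threshold
  $\max(10^{-7},\ \epsilon\cdot10^{-4})$ on the split network.
* FVA results are capped at the reaction's own bounds; with Recon-style
  ±1000 caps present, unbounded directions cannot occur and are never
  reported as ±∞.
* Lethality uses a $10^{-6}$ ratio tolerance rather than the raw solver
  tolerance: growth ratios inherit noise from two LP solves.
* Infeasible LPs report status `infeasible`; `fba()` never silently returns
  zero. Non-growing models abort the exchange/essentiality/drug stages with
  an instruction to check medium and extraction.
* Degenerate discretization inputs (all-equal samples, < 4 nonzero genes)
  yield unknown calls rather than a forced fit.
* A medium metabolite without a matching exchange warns and is skipped; an
  empty consensus core, a blocked biomass, or a control model without an
  ATP-demand reaction are errors.

# Problem sizes used in the checks

The bundled tests run the oracles at sizes where exhaustive verification is
exact and fast: 200 randomized networks of up to 15 reactions for the
dual-solver FBA/FVA and consistency checks, 50 planted two-route toys of at
most 12 reactions for extraction-minimality (exhaustive subset search), 20
generator seeds for essentiality recovery, and the default 3-subtype
scenario for the end-to-end and byte-reproducibility checks. These sizes
were chosen so that each oracle is a complete enumeration rather than a
sample, while the whole suite stays interactive.

# Known limitations

* The LP engine is dense; it is sized for context-specific toy and
  mid-scale models, not for a genome-scale reconstruction with tens of
  thousands of reactions. Swapping in an external solver behind `solveLP()`
  is the intended path there.
* No thermodynamic or loop-law constraints; FVA ranges can include
  thermodynamically infeasible cycles. Random flux sampling would tighten
  wide ranges and is deliberately out of scope.
* Knockouts are binary (a drug removes its targets completely); no
  dose-response modelling, and no drug-drug interaction prediction — DDI
  severity is consumed as an input column.
* Essentiality is essentiality *for the biomass objective*: regulatory or
  non-metabolic gene functions are invisible to the screen.
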