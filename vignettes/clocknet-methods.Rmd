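---
title: "Differential miRNA co-expression networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential miRNA co-expression networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clocknet)
```

## The problem and the model

Circadian clock genes (ARNTL/BMAL1, CLOCK, the PER and CRY families, NR1D1/2,
RORA, TIMELESS, TIPIN, CSNK1E, SIRT1) are post-transcriptionally regulated by
miRNAs, and their deregulation is a recurrent feature of colorectal and other
cancers. With matched tumor and adjacent-normal profiles from the same
patients, two complementary signals are available: the *paired* expression
shift of each miRNA, and the change in *co-expression structure* — pairs of
miRNAs that are tightly correlated in normal mucosa but decouple (or flip
sign) in tumor. `clocknet` treats both signals as first-class and combines
them with a validated miRNA→clock-gene target map to nominate candidate
regulatory axes.

The analysis assumes log2-scale, approximately normal expression values that
are already normalized across arrays (level-3-style inputs). A quantile
normalization utility is provided as a stand-in for upstream processing, not
as a replacement for it: it forces every sample to a common empirical
distribution (ties receive the mean reference value at their rank positions),
is idempotent, and preserves within-sample ranks. It should be applied to
raw-ish inputs only — on data that are already on a common scale it is
unnecessary, and because it pulls extreme values toward the pooled
distribution it will shrink very large planted or real fold changes. The
synthetic cohorts this package generates are on a common scale by
construction, so the bundled analyses run with `normalize = FALSE`.

### Paired differential expression

For feature $g$ with complete pairs $d_i = \text{tumor}_i -
\text{control}_i$ (log2), the paired t statistic is $t =
\bar d / (s_d/\sqrt n)$ on $n-1$ degrees of freedom, two-sided. Fold changes
are reported in the signed convention used throughout the field's microarray
literature: $\mathrm{FC} = 2^{\bar d}$ when $\bar d \ge 0$ and
$-2^{-\bar d}$ otherwise, so down-regulation appears as a negative reciprocal
and $|\mathrm{FC}| \ge 1$ always. Multiplicity is handled by the
Benjamini–Hochberg step-up rule (the standard choice for microarray DE when
only "FDR" is specified); a feature is called differential when
$|\mathrm{FC}| \ge 1.5$ and $\mathrm{FDR} \le 0.05$. Zero-variance
differences with a nonzero mean are reported with $p = 0$ and an explicit
`degenerate` flag rather than silently; features with fewer than 3 complete
pairs are skipped with a warning.

### Correlation networks

Co-expression is measured by the Pearson product–moment correlation with the
exact small-sample significance transform $t = r\sqrt{n-2}/\sqrt{1-r^2}$,
$df = n-2$ (not the Fisher z approximation — at $n = 14$ the difference
matters). An edge is retained iff $|r| \ge$ `r_cut` and $p \le$ `alpha`.
Defaults are `r_cut = 0.8`, `alpha = 0.05` raw — the filter is a screening
rule, not an inference, which is why no multiplicity correction is applied to
edge p-values by default (a BH mode exists for users who want it). The 0.6
preset supports the looser screen sometimes used for Venn-style pair
counting. Missing values are deleted pairwise and the complete-pair count is
recorded per edge (`n_used`, minimum 5); constant vectors are untestable and
are skipped with the reason recorded. The full unfiltered pair table
(`correlation_table()`) is always available, because interesting biology
sometimes sits below the hard threshold.

### Edge-set coherence partition

Two condition networks built at identical thresholds are compared as sets of
unordered pairs (canonical lexicographic keys). A pair present in both with
equal sign is *coherently correlated* (common); present in both with opposite
signs it is a *sign flip* — kept as a distinct fourth category because
folding such pairs into "common" would hide exactly the rewiring the method
looks for, and dropping them would miscount the Venn; otherwise the pair is
exclusive to the network containing it. The four sets are disjoint and cover
the union — this is enforced by property tests against a brute-force set
algebra reference on randomized instances, along with the mirror symmetry of
swapping the two networks.

### Symbol resolution and clock-controller tagging

miRNA symbols are resolved against a miRBase-`aliases.txt`-dialect table:
matching is case-insensitive after `hsa-` prefix normalization, and a symbol
found in exactly one accession row maps to that row's most recent (last)
alias. Legacy names that match several rows — typically names shared by the
-5p and -3p mature products — and names matching no row are kept unchanged
and reported, never guessed. Resolution is idempotent. A correlated pair is
tagged *clock-controller* iff at least one member has a validated clock-gene
target; the gene universe is configurable and defaults to the core
oscillator set.

### Topology

Seven per-node indices are computed from scratch on the unweighted,
undirected, simple graph (correlation magnitude is an edge attribute, never a
path weight): degree; degree centrality $k/(n-1)$ with $n$ the graph order;
betweenness by Brandes' accumulation, normalized by $2/((n_c-1)(n_c-2))$
with $n_c$ the node's connected-component order (0 when $n_c < 3$);
closeness $(n_c-1)/\sum d$; average shortest path length $\sum d/(n_c-1)$;
clustering coefficient $2e_N/(k(k-1))$ (0 when $k < 2$); and radiality
$(\Delta_c + 1 - \mathrm{aspl})/\Delta_c$ with $\Delta_c$ the component
diameter. Path metrics are normalized per component (the NetworkAnalyzer
convention) because thresholded small-cohort networks fragment into many
small clusters, and whole-graph normalization would zero them out. Degenerate
conventions: a two-node component has radiality 1 directly from the formula;
an isolated node reports closeness 0, `NA` path length, and radiality 1 by
convention with a `radiality_convention` flag (a strictly positive closeness
cannot be defined there — this is the one place the container's nominal
"closeness in (0,1]" range is relaxed). The implementation is validated to
1e-9 against two independent oracles: exhaustive simple-path enumeration on
every labeled graph of order ≤ 5 plus random connected graphs of order 6–7,
and a pair-dependency count over an independently computed distance matrix on
500 random Erdős–Rényi graphs of order ≤ 40; igraph provides a third
cross-check in the unit tests. These sizes keep the oracle runs inside a few
minutes while covering every structural case the enumeration can reach
(exhausting order ≤ 7 up to labeling — nearly a million graphs — would add
no structural coverage at three orders of magnitude more cost).

### Candidate ranking

The qualitative selection "by expression level and topological
considerations" is made explicit: a miRNA is *eligible* iff it targets at
least one clock gene and is DE-significant, and eligible miRNAs are scored by

$$ w_1\,|\log_2 \mathrm{FC}| \; + \; w_2\,\text{lost-edge fraction} \; + \;
w_3\,|\Delta\,\text{degree centrality}| $$

where the lost-edge fraction is the share of the node's control-network edges
absent from tumor (0 when the control degree is 0). The default weights
(1, 1, 1) are deliberately neutral and documented as arbitrary — the formula
is a transparent, tunable stand-in for expert judgment, not a fitted model.
Scaling all weights preserves the ranking; ties break by fold-change
magnitude, then symbol.

### Validation statistics

* `gene_mirna_correlation()` — Pearson r with the same small-sample p, for
  testing inverse miRNA–target coupling.
* `ddct()` — $2^{-\Delta\Delta C_t}$ with both sign conventions exposed:
  `"paper"` uses $\Delta\Delta C_t = \Delta C_t(\text{calibrator}) - \Delta
  C_t(\text{target})$, the exact reciprocal of the `"livak"` convention; the
  default follows the subtraction order stated in the source protocol, and
  `ct_ratio()` covers the reference/target Ct-ratio summary some reports plot
  instead. Neither is asserted to be the "true" per-patient computation.
* `median_split_association()` — subjects split at the median (ties to "low":
  deterministic and conservative for the high-expression group), Pearson's
  chi-squared without continuity correction (the named test; Yates available
  behind a flag), with a low-expected-count warning flag.
* `msi_classify()` — Bethesda 5-marker calls: ≥ 4 unstable → MSI-H, 0 → MSS.
  Counts of 1 or 3 are not anchored by the stated rule; they map to MSI-L by
  monotone interpolation and carry an `interpolated` flag.

## The synthetic cohort generator

`generate_cohort()` emulates a matched microarray cohort: log2 intensities
centered at 8.0, `n_patients = 14` pairs and `n_mirnas = 300` by default.
Planted correlation modules use a shared latent factor: member $i$ is
$\ell_i F + \sqrt{1-|\rho|}\,\varepsilon_i$ with $\ell_i = \pm\sqrt{|\rho|}$,
giving *exact* population pairwise correlation $\ell_i\ell_j$ — closed-form
control of the planted structure. For negative $\rho$ the loadings alternate
in sign (mutual anti-correlation of a whole module at one negative value is
not representable; the ground truth records the per-pair targets). Tumor
modules may differ from control modules (rewiring, sign flips), planted log2
shifts are added to tumor columns, and a clock-gene mRNA can be coupled to
its targeting miRNA at an exact negative correlation through the miRNA's
latent value. Each logical block (background noise per condition, modules per
condition, coupling) draws from its own seed derived from the master seed, so
adding a module never perturbs unrelated features — a property the tests
check directly.

Defaults and the one free parameter: the noise level `noise_sd` is the
per-feature standard deviation in log2 units. The source cohorts do not state
a noise magnitude; 0.3 is used as a realistic microarray-scale default (0.2
in the planted demonstration scenario, where the fold-change recovery band
was derived). At `noise_sd = 0.2` and $n = 14$ the standard error of a
planted mean log2 shift is $0.2\sqrt{2}/\sqrt{14} \approx 0.076$, so a
planted shift of $-2.766$ (signed FC $\approx -6.8$) is recovered within
$[-7.8, -5.8]$ in well over 95% of cohorts — the band the acceptance checks
use.

What the generator does **not** emulate: probe-level effects, batch and
array-position artifacts, count-based (RNA-seq) noise, heavy-tailed
intensity distributions, and correlated noise between the tumor and control
sample of one patient. Passing tests therefore demonstrate that the
pipeline's statistics behave as designed under their own assumptions — not
that any particular biological dataset will reproduce a given network.

## Problem sizes and numerical choices

The bundled tests and the acceptance script run at the cohort scale the
method targets: 14 matched pairs, 200–301 features, 20-seed calibration
batches, 100-repeat recovery checks, 1000 randomized partition instances, and
the topology oracle sizes above — a few minutes end to end on one core.
Determinism: every stochastic step is governed by one integer seed; the
pipeline's analysis stages are deterministic by construction, and artifacts
are written with full (17 significant digit) precision so fixtures round-trip
exactly and repeated runs are byte-identical. Floating-point tolerances in
the tests are 1e-9 for topology (exact graph algorithms), 1e-12 for
normalization idempotence, and one ulp (1e-15) for the BH comparison against
an independently coded step-up rule, whose multiplication order differs
harmlessly.

## Known limitations

* Pearson correlation only — no partial correlation, mutual information or
  soft thresholding; at $n = 14$, an 0.8 screen is a blunt instrument and the
  unfiltered table should accompany any interpretation.
* The candidate score is a ranking heuristic; its weights have no
  probabilistic interpretation.
* Cross-dataset node flags are based on symbol co-occurrence in a second
  dataset analyzed with the same settings, not on any cross-cohort statistic.
* Survival analysis, target-site prediction and network visualization beyond
  attribute export are out of scope.
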