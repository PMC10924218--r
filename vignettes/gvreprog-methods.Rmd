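---
title: "Methods: models, parameters and design choices in gvreprog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in gvreprog}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gvreprog)
```

`gvreprog` analyses two complementary readouts of somatic nuclear
reprogramming by oocyte germinal vesicles: nascent transcriptomes of
transplanted nuclei sequenced against a two-species hybrid reference, and
confocal images of their chromatin. This vignette explains the models, the
parameters that matter, the synthetic-data generators, and the choices made
where the design was genuinely open. It states no empirical result beyond
what the package's tests and `scripts/acceptance.R` themselves compute.

## 1. Expression model

### Quantification

Counts are length-normalised to transcripts per million; each sample's TPM
column sums to $10^6$ by construction. All thresholds act on
replicate-aggregated TPM (arithmetic mean by default; medians via
`classification_config(aggregate = "median")`) with a single pseudocount
(default 1, the same "+1" used for log display scales) applied in every
ratio. Keeping one pseudocount everywhere avoids the subtle inconsistencies
that arise when each computation picks its own offset.

### Response classes

The classification rules are threshold-based, not a dispersion-modelling
differential expression test — deliberately, because the analysis this
package implements applies fixed cutoffs to nascent transcription:

* *activated*: donor TPM $<$ `tpm_expressed` (1) and NT TPM $\ge$
  `tpm_inducible` (1) — a silent gene turned on;
* *enhanced*: donor expressed and pseudocounted NT/donor fold change $\ge$
  `fc_enhance` (2);
* *repressed*: pseudocounted donor/NT fold change $\ge$ `fc_repress` (2);
* *unchanged*: otherwise.

Precedence is activated, else enhanced, else repressed; the three conditions
are mutually exclusive by arithmetic except at degenerate boundary values,
which precedence resolves deterministically. The activation/enhancement
boundary (a silent donor versus an expressed one) and the fold-change cuts
are exposed in `classification_config()` because the underlying study design
fixes only the inducibility threshold (TPM $\ge$ 1) and the resistance fold
change ($\ge$ 4); 2-fold is the field's conventional minimum for calling a
change, and both cuts are configurable rather than hard-coded.

### Resistance

A gene is resistant in a focal cell type when (a) it is inducible in at
least one other cell type, (b) its focal NT TPM sits $\ge$ `fc_resist` (4)
below the comparator, and (c) it is not itself repressed in the focal cell
type. The exclusion implements the rule that genes the oocyte actively
downregulates must not masquerade as resistant; we read the exclusion as
applying to the focal cell type, the minimal interpretation. The comparator
is the mean over the other cell types' NT replicate means
(`mode = "mean"`); `mode = "pairwise"` requires the fold change against
every other cell type in which the gene is inducible. The two modes are not
nested: a comparator cell type in which the gene is silent relaxes the
pairwise test while dragging the mean down, so both are provided and tested
against a brute-force oracle.

## 2. The expression generator

`simulate_expression()` encodes the study conditions: three donor cell
types (ESC, MEF, MYO), three replicates ("recipient females") per
condition, donor samples plus NT samples at 24 h and 48 h, and per-gene
response classes drawn at the configured proportions (defaults 16%
activated, 10% enhanced, 14% repressed, 60% unchanged — the induced
fraction is then about a quarter of genes, and roughly 40% change overall).
Key modelling decisions:

* **Nascent-only sampling.** NT counts reflect only post-transfer
  transcription, never carried-over donor RNA, because the assay sequences
  BrUTP-labelled nascent transcripts.
* **Shared induced target.** Each gene has one induced target TPM shared
  across cell types; activated and enhanced genes converge to it. This is
  the "deterministic reprogramming" property: different donors, one induced
  state.
* **Class correlation.** With probability `class_correlation` (0.7) a cell
  type adopts the gene's shared response program instead of an independent
  draw. The mixture leaves marginal class proportions untouched while
  coupling *which* genes are induced across cell types, so NT–NT
  transcriptome correlations exceed donor–NT correlations, as reprogramming
  convergence requires. 0.7 was chosen so the coupling is strong but
  imperfect — the overlap of inducible sets is large yet incomplete.
* **Donor structure.** Donor log2 levels are a per-gene baseline
  (`donor_mean_log2`, sd 2) plus a cell-type deviation
  (`celltype_sd_log2` = 0.6), making donor profiles cell-type-specific but
  largely shared, as for related cell lines of one organism. The deviation
  was fixed at 0.6 so that spurious $\ge$ 4-fold cross-cell-type differences
  among non-induced genes are the exception (sub-percent of genes) rather
  than the rule: resistance should be a curated gene-set phenomenon, not
  bulk donor noise.
* **Self-calibration.** TPM is compositional — a valid expected profile
  must total $10^6$. Levels are drawn in relative log2 units and rescaled by
  a short fixed-point loop (six iterations, reusing the same random draws)
  so every donor and NT profile totals $10^6$ to within a few percent while
  all class constraints hold in final TPM units with margin (activated
  donors $< 0.5$, induced targets $\ge 1.5$, enhanced fold changes $\ge
  2^{1.4}$, repressed $\ge 2^{1.2}$). The margins exist so that profile-sum
  wobble can never flip a constructed class; the `mean` entries of the level
  parameters therefore set *relative* locations only.
* **Forced resistance.** Forced-resistant genes are drawn per cell type
  (defaults ESC 4%, MEF 3%, MYO 10% of induced-elsewhere genes — the
  myoblast asymmetry) from genes already *unchanged* in the focal cell type
  and induced elsewhere. Their focal donor level is lowered below 0.5 TPM,
  their NT level set equal to it (no induction), and the shared target
  raised to at least 16 TPM so the 4-fold criterion holds with margin.
  Because no class labels change, forcing cannot distort realized class
  frequencies.
* **Truth labels.** The recorded per-gene class and resistant flags are
  obtained by applying the definitional rules to the noise-free expected
  TPM. By construction the sampled class always realizes the definitional
  class (asserted in tests), and genes that satisfy the resistance rule
  without being forced are truthfully flagged too — recovery metrics
  therefore measure counting noise only, not construction artifacts.
* **Counts.** Negative binomial around the TPM-implied expected count given
  gene length and library size (`nb_dispersion` = 0.1, a typical bulk
  replicate dispersion; 0 gives the Poisson limit). 48 h samples are fresh
  draws from the same means as 24 h, encoding the observation that nothing
  further changes between the two days beyond replicate noise. Per-female
  effects default to zero for the same reason: the outcome does not depend
  on the oocyte source.

What the generator does *not* emulate: transcript-level structure, 3'
coverage bias, ambient RNA, batch effects, or donor-versus-NT correlations
as low as bulk data can show (60% of genes are exactly unchanged by
construction, which bounds how dissimilar donor and NT profiles can be).
Passing recovery tests therefore demonstrates correctness of the estimators
under the stated noise model, not robustness to every artifact of real
libraries.

## 3. Hybrid reference and read assignment

The hybrid reference concatenates species A chromosomes, then species B
renamed with the `xla_` prefix; a name collision after prefixing is an
error, not a warning. Annotation intervals follow the 1-based closed
GRanges/IRanges convention end to end — one convention, no boundary
conversions, and the GTF round trip is tested to be lossless.

Read assignment replaces a spliced aligner with a unique k-mer test
(default k = 25, both strands), because species attribution — not
alignment — is the analytic content at desk scale: a random 25-mer has
essentially zero probability of occurring in an unrelated genome by chance,
so k-mer sharing identifies genuinely shared sequence. Reads whose k-mers
occur in both species are `ambiguous`; a species-labelled read receives a
gene only when all k-mers of one strand are exonic and gene-unique (union
semantics — shared exonic k-mers disqualify, mirroring how reads
overlapping two genes are dropped). Strandedness is not assumed; the
library protocol does not state it. The counting identity
$A + B + \mathrm{ambiguous} + \mathrm{unassigned} = \mathrm{total}$ is
asserted on every run. For real data the pluggable loader
(`read_counts_tsv()`) accepts externally produced count tables.

## 4. Imaging model

### Thresholds

`huang_threshold()` minimizes Huang's fuzziness (histogram-weighted Shannon
entropy of fuzzy memberships built from the two class means, with the
gray-level range as fuzzifier). `iterative_otsu()` chains Otsu thresholds:
each stage maximizes between-class variance on the histogram restricted to
values *at or above* the previous threshold (inclusive, per the chaining
rule), yielding `t_bg < t_mid < t_dense` and the four-way background /
loose / middle / dense partition. The background cut is iteration 1 of the
chain — the restriction rule makes the chain start naturally from the full
histogram. Numerical conventions: thresholds are returned as the midpoint
between the optimal split level and the next occupied level, so `>= t` is
an exact binarization; ties resolve to the lowest split; a constant image
(Huang) or a collapsed restricted histogram (Otsu) is an error. Both
optimizers are verified against exhaustive brute-force search in the test
suite, on 100+ random 8-bit histograms.

### Segmentation

`recursive_watershed()` emits connected components already inside the area
gate untouched; oversized components are split by EBImage's tolerance-based
watershed on the Euclidean distance transform, which is exactly h-maxima
suppression for marker selection. The schedule — start at half the
component's distance-map maximum, decay by 0.7 per level, floor at 1 px —
makes the first pass conservative (a high tolerance refuses to split) and
recursion progressively more permissive, so over-segmentation is traded
against under-segmentation gradually. Oversized remnants at the floor or
depth limit are reported as *unresolved*, never silently dropped, and
sub-`min_area` fragments are tallied; the conservation identity (emitted +
unresolved + discarded = foreground) is tested. The procedure is fully
deterministic. Analysis is 2D per slice: the quantity of interest is
projected chromatin *area*, and the default size gate (300–1080 px²)
brackets the simulator's nucleus sizes; for real data derive the gate from
pixel size and a 5–20 µm diameter prior.

### Occupancy and areas

HP1α occupancy per density class is positive-pixel fraction above an Otsu
cutoff computed within chromatin pixels (the automatic default, since a
fixed microscope-dependent cutoff would not transfer across settings; a
fixed mode exists). Empty classes are flagged undefined rather than divided
by zero. Chromatin areas are compared with an equal-variance two-sample
Student's t-test, matching the study's figure convention; two identical
zero-variance groups are reported as "no difference" (t = 0, p = 1) rather
than NaN.

## 5. The image generator

`img_sim_config()` defaults encode: 512×512 px fields, 20 nuclei of which
three touching pairs, semi-axes 14–18 px, concentric density regimes at
50/30/20% of nucleus area with DNA intensities 80/150/220 over a ~0
background (noise sd 6, 8-bit), HP1α occupancies 0.2/0.5/0.8 increasing
with density, and a paired "24 h" set with areas ×2 and occupancies halved
(dispersal with heterochromatin loss).

Nucleus masks are built as the *n nearest available pixels* under the
nucleus's elliptical metric with `n = round(πab)` — exact-area,
deterministic, disjoint-but-touching within clusters. The paired set reuses
the same geometry with `n` scaled by the dispersal factor, which is why the
noise-free fold change is exactly 2.0 rather than approximately so: plain
rasterized ellipses cannot double their pixel count exactly. The semi-axis
range 14–18 px was chosen together with the size gate so the largest single
nucleus (~1018 px) stays below `max_area` while the smallest touching pair
(~1150 px) stays above it; with a much wider radius range, a small pair
becomes area-indistinguishable from a large single nucleus and no area gate
can separate them. Not emulated: 3D point-spread functions, optical
clearing artifacts, autofluorescence, intensity gradients across the field,
or non-elliptical nuclear shapes.

## 6. Pipeline and reproducibility

`run_pipeline()` executes the enabled stages in dependency order from one
flat configuration (list or YAML) — full-run reproducibility is the point,
so there are no per-stage flag sets to drift apart. Every output file's md5
lands in `manifest.json` along with seeds and package version; reruns under
a fixed seed are byte-identical (asserted in the acceptance tests). A
top-level seed derives stage seeds as seed, seed+1, seed+2.

## 7. Problem sizes and runtime choices

The test suite and acceptance script use 5000 genes × 3 cell types for
classification and resistance recovery (seeds 1–10 and 1–3 respectively),
400 genes at Poisson/10⁸-read settings for the noise-free limit, 500
fixture reads over two 2×20 kb toy genomes for assignment, single 512×512
fields per seed for segmentation/occupancy (seeds 1–10), and three images
per group for the noisy area comparison. These sizes give binomial/NB
sampling errors comfortably inside the recovery bars while keeping a full
run in tens of seconds on one CPU.

## 8. Known limitations

* The k-mer assigner requires exact sequence identity; it is a surrogate
  for alignment on curated or simulated inputs, not a read mapper with
  mismatch tolerance.
* Classification is threshold-based by design; no shrinkage or multiple
  testing is applied, so single-replicate noise propagates directly into
  class calls at the boundaries.
* The resistance comparator treats "the other cell types" symmetrically;
  with many cell types a mixed-effects formulation would be preferable.
* Segmentation assumes roughly convex nuclei whose distance-map maxima mark
  centers; heavily concave or chain-like clusters can remain unresolved (by
  report, not silently).
* 2D areas understate 3D volume changes; the dispersal factor acts on area.
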