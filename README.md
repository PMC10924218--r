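# gvreprog

Quantifying somatic nuclear reprogramming by oocyte germinal vesicles.

When permeabilized somatic nuclei (embryonic stem cells, fibroblasts,
myoblasts, or human lines) are transplanted into the germinal vesicle (GV) of
an amphibian oocyte, the oocyte reprograms them toward a totipotency-like
transcriptional state within a day or two, without DNA replication or cell
division. Two kinds of measurements capture this process:

* **a sequencing arm** — nascent (BrUTP-labelled) transcripts of the
  transplanted nuclei, sequenced against a *hybrid* two-species reference so
  that reads from the transplanted genome can be separated from host
  (oocyte) transcription;
* **an imaging arm** — confocal stacks of transplanted nuclei stained with a
  DNA dye (chromatin density) and immunolabelled for HP1&alpha;
  (heterochromatin), which quantify chromatin dispersal and heterochromatin
  loss.

`gvreprog` implements both arms as one tested, scriptable R package, together
with synthetic-data generators that stand in for the raw reads and image
stacks, so every stage of the analysis is verifiable against known ground
truth.

## What the package computes

**Expression.** Counts are normalised to transcripts per million,
TPM<sub>g</sub> = 10<sup>6</sup> (c<sub>g</sub>/L<sub>g</sub>) / &Sigma;<sub>j</sub>(c<sub>j</sub>/L<sub>j</sub>),
with L the summed exon length. A gene is *oocyte-inducible* in a cell type
when its replicate-mean nascent TPM after nuclear transfer (NT) reaches 1.
Each gene is assigned one response class per cell type, on pseudocounted
replicate means:

| class | rule (defaults) |
|---|---|
| activated | donor TPM &lt; 1 and NT TPM &ge; 1 |
| enhanced  | donor TPM &ge; 1 and (NT+1)/(donor+1) &ge; 2 |
| repressed | (donor+1)/(NT+1) &ge; 2 |
| unchanged | none of the above |

A gene is *reprogramming-resistant* in a focal cell type when it is inducible
in at least one other cell type, its NT expression sits &ge; 4-fold below the
other cell types' NT mean (pseudocounted), and it is not itself repressed in
the focal cell type (genes the oocyte downregulates are excluded).

**Hybrid reference.** Two genomes are concatenated, the second species'
chromosomes renamed with an `xla_` prefix (`chr1` &rarr; `xla_chr1`), and
annotations merged with a species tag. Reads are assigned to species by
unique k-mer content (default k = 25, both strands): hits in one species
label the read, hits in both make it `ambiguous`, none `unassigned`.
Uniquely exonic reads are counted per gene with union semantics, and
species A + species B + ambiguous + unassigned always equals the read total.

**Imaging.** Nuclei are binarized with a Huang fuzzy threshold, and touching
nuclei are separated by a recursive watershed on the Euclidean distance
transform with a decaying h-maxima tolerance, size-gating objects at each
recursion level. Chromatin is classified into background / loose / middle /
dense by chained Otsu thresholds, each stage recomputed on the histogram
restricted to values at or above the previous threshold. Per density class,
HP1&alpha; occupancy is the fraction of class area above an (Otsu or fixed)
intensity cutoff; chromatin areas are compared between timepoints with an
equal-variance Student's t-test.

## Worked example

```r
library(gvreprog)

## sequencing arm: simulate counts with known classes, then recover them
sim  <- simulate_expression(expr_sim_config(n_genes = 2000, seed = 1))
expr <- compute_tpm(sim$counts)          # every column sums to 1e6
rt   <- classify_response(expr, cell_type = "MEF")
attr(rt, "summary")
#>       class    n percent
#> 1 activated  256   12.80
#> 2  enhanced  233   11.65
#> 3 repressed  282   14.10
#> 4 unchanged 1229   61.45

find_resistant(expr)$sizes
#> ESC MEF MYO
#> 103  90 143
```

About a quarter of genes are induced (activated + enhanced) and roughly 40%
change overall, and the myoblast-like cell type carries the largest
resistant set — the generator's defaults encode exactly these study
conditions, and the classifier recovers them from noisy counts.

```r
## imaging arm: segment touching nuclei and quantify the HP1 gradient
b   <- simulate_images(img_sim_config(seed = 7))$baseline[[1]]
seg <- recursive_watershed(b$dna >= huang_threshold(b$dna))
seg
#> gv_segmentation: 20 nuclei (0 unresolved, 0 discarded small)
#> areas 637-966 px; extraction depth 0-4

part <- iterative_otsu(b$dna)
hp1a_occupancy(part, b$hp1)
#>    class area_px positive_px occupancy defined
#> 1  loose    8003        1621 0.2025490    TRUE
#> 2 middle    4830        2398 0.4964803    TRUE
#> 3  dense    3222        2610 0.8100559    TRUE
```

All 20 simulated nuclei — including the touching pairs, split at recursion
depths up to 4 — are recovered, and the estimated HP1&alpha; occupancy
reproduces the configured 0.2 / 0.5 / 0.8 gradient: the denser the
chromatin, the more of it is HP1&alpha;-occupied.

A full run (simulation &rarr; reference/assignment/counting &rarr;
classification &rarr; image quantification) is driven by one config:

```r
run_pipeline("config.yaml")   # or a named list; see ?run_pipeline
```

which writes TSV/JSON/TIFF outputs plus a `manifest.json` of seeds and file
checksums; reruns under the same seed are byte-identical. A thin CLI wrapper
is installed at `inst/scripts/run-pipeline.R`.

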