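# bgcdiel

Biosynthetic gene cluster (BGC) inventory bookkeeping and diel expression
analysis for soil-biocrust metagenomes and wet-up metatranscriptomes.

Biological soil crusts are cyanobacteria-dominated surface communities that
spend most of their life desiccated and spring to life after rain. Long-read
metagenome assemblies of biocrust recover thousands of secondary-metabolite
gene clusters, and metatranscriptomes sampled across a laboratory wetting
experiment (13 samples over 10 timepoints spanning three diurnal cycles,
with night samples at 11.5 h and 18 h after wetting) reveal when those
clusters are transcribed. `bgcdiel` implements the downstream analysis of
such data for microbial ecologists: it consumes gene annotations (GFF3), BGC
tables, BLAST tabular alignment hits, and transcript count matrices — it
does not assemble reads or detect clusters (that is antiSMASH's job).

## What it computes

**Inventory bookkeeping.** Contigs are eligible for cluster analysis when
longer than 5 kb (strict). A cluster is *full-length* when it is not
truncated on either contig edge: `start > m` and `L − end > m` with margin
`m = 0` by default. A cluster counts as *previously sequenced* ("known")
only when reference alignments reach ≥ 75% identity over ≥ 80% of the query
length, where coverage is the union of query intervals of hits to the single
best subject and identity is the alignment-length-weighted mean; anything
less — including no hits at all — is *novel*. Taxonomy is the best hit
surviving E < 1e−10 and bitscore > 60 (both strict).

**Diel expression pipeline.** For gene *g* in sample *s* with raw count
x<sub>gs</sub> and sample total T<sub>s</sub>:

1. remove genes with max<sub>s</sub> x<sub>gs</sub> < 20;
2. normalize: x′<sub>gs</sub> = x<sub>gs</sub> / T<sub>s</sub> ·
   mean<sub>s</sub>(T<sub>s</sub>);
3. average replicates (duplicate 15-min, triplicate 1-h) to 10 timepoints;
4. z-score each gene over the 10 timepoints (sample sd; constant genes are
   excluded and reported);
5. BGC profiles are per-timepoint means of member-gene z-scores; the peak is
   the earliest-tie argmax and is a *night peak* at 11.5 h or 18 h.

*Constitutive transcription* is defined on raw counts only: a gene is
constitutive when its pooled mapped-transcript count reaches 5 at every one
of the 10 timepoints (*transcription breadth* = 10).

**Co-occurrence networks.** Undirected edges join BGCs whose z-profiles have
Pearson r strictly above 0.8 (p-values from the t transform on 8 df are
reported, with one-step Bonferroni or Benjamini-Hochberg correction, but
play no role in edge inclusion). Phylum-level correlations average member
BGC profiles per phylum before correlating.

**Synthetic experiments.** `simulate_bgc_experiment()` generates contigs,
BGCs, genes, alignment hits, and negative-binomial diel count matrices with
known ground truth (constitutive flags, diel phase, full-length and novelty
status), so every stage has a recovery test without any data download.

## Worked example

```r
library(bgcdiel)

dir <- file.path(tempdir(), "demo")
cfg <- pipeline_config(input_dir = dir, output_dir = dir, seed = 7)
run_simulate(cfg)     # synthetic 13-sample wet-up experiment
run_annotate(cfg)     # full-length / novelty / taxonomy calls
run_expression(cfg)   # filter -> normalize -> collapse -> z-score; breadth
run_network(cfg)      # co-occurrence network + phylum correlations
cat(run_report(cfg), sep = "\n")
```

```
BGC inventory and diel transcription report
===========================================

Inventory: 200 BGCs (160 full-length, 12 previously sequenced, 94.0% novel, 2.03 Mb cumulative span)

Constitutive transcription by gene set:
  background     1000 genes,    45 constitutive (4.5%)
  core             46 genes,     8 constitutive (17.4%)
  secondary      1351 genes,    81 constitutive (6.0%)
  all            2397 genes,   134 constitutive (5.6%)

Night-peaking BGC fraction by phylum:
  Actinobacteria       24 BGCs, 20.8% peaking at night
  Bacteroidetes        18 BGCs, 72.2% peaking at night
  Chloroflexi          14 BGCs, 21.4% peaking at night
  Cyanobacteria       115 BGCs, 80.0% peaking at night
  Proteobacteria       26 BGCs, 19.2% peaking at night

Co-occurrence network: 197 nodes, 7005 edges (r > 0.8)

Top phylum correlation: Bacteroidetes ~ Cyanobacteria, r = 0.988 (adjusted p = 8.51e-07, bonferroni)
```

Reading the output: 94.0% of the simulated clusters have no adequate
reference match (novel); constitutive transcription is rare overall (~5%)
but three times more common among core housekeeping genes (17.4%) than
among biosynthetic genes (6.0%); the cyanobacteria concentrate their BGC
transcription at night (80% night peaks) while the heterotrophic phyla peak
during the day; and the network splits into night and day co-expression
blocks, with Bacteroidetes tracking the cyanobacteria most closely.

The individual stages are ordinary tibble-in/tibble-out functions that can
be piped directly:

```r
sim <- simulate_bgc_experiment(sim_config(seed = 7))
profiles <- sim$counts |>
  filter_low_counts() |>
  normalize_totals() |>
  collapse_replicates(sim$metadata) |>
  zscore_profiles() |>
  bgc_profiles(sim$genes)
net <- build_bgc_network(profiles, r_threshold = 0.8)
glance(net)   # nodes, edges, density, components
tidy(net)     # edge list with r, p, p_adj
autoplot(net) # ggplot of the network
```

## Layout

- `R/` — simulation, I/O, inventory bookkeeping, expression pipeline,
  network analysis, pipeline orchestration, plotting.
- `inst/scripts/bgc-pipeline.R` — thin subcommand CLI
  (`simulate | annotate | expression | network | report`) over the same
  functions.
- `vignettes/bgc-diel-methods.Rmd` — the model, parameter, and design notes.
- `tests/testthat/` — unit, property, and acceptance suites with
  independent brute-force oracles.
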