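# probecap

Probe-capture (hybridization-capture) targeted metagenomics of functional
marker genes, simulated and evaluated end to end in R.

## The problem

Microbial guilds that drive inorganic nitrogen and methane cycling --
nitrifiers, denitrifiers, anammox bacteria, methanogens, methanotrophs --
are typically rare members of soil and sediment communities. Their marker
genes (*nifH*, *amoA*, *nxrB*, *hzoA*, *nrfA*, *napA*, *narG*, *nirK*,
*nirS*, *norB*, *nosZ*, *pmoA*, *mmoX*, *mcrA*) are poorly sampled by
shotgun metagenomes at realistic depths, and PCR amplicon assays carry
primer bias. Probe capture enriches a sequencing library for all variants
of such genes using large panels of 50-mer hybridization probes designed
from clustered gene databases.

probecap implements the computational method behind such a study as a
self-contained toolkit for method developers and benchmarkers:

* **target registry & profiles** -- the 14-family marker-gene registry with
  homolog groups; position-specific scoring models with Gumbel-calibrated
  E-values (the `E < 0.001` filtering contract); 100%-identity
  dereplication with cd-hit substring semantics;
* **probe design** -- greedy 80%-identity clustering and up to six unique
  50-mer probes per cluster (coverage-scored, Tm-47 preference,
  homopolymer/ambiguity guards), assembled into a deduplicated panel;
* **mock communities** -- mass fractions solved for target weighted GC
  mol% (47-63), dosage-based expected abundances (the ground truth), and a
  synthetic genome generator that plants marker genes with recorded truth
  coordinates;
* **capture simulation** -- 630 bp fragmentation, a logistic
  probe-identity capture model with optional GC-dependent efficiency, and
  paired PE300 reads with truth labels;
* **read classification** -- six-frame translation, BLOSUM62 local
  matching with a 60% identity floor, up to 4 matches per direction with
  <= 15 aa overlaps, best-E collapse and homolog disambiguation
  (amoA/pmoA, nxrB/narH, napA+narG/nrfA, with narH/fdhA decoys);
* **evaluation** -- expected-vs-observed Pearson correlation,
  homolog-aware precision/recall, 90%-identity binning, rarefaction with
  the exact hypergeometric expectation.

The statistic at the core of the benchmark: with mass fractions `f_i`,
copy numbers `c_gi` and genome lengths `L_i`, the expected relative
abundance of gene g is `100 * d_g / sum_h d_h` with dosage
`d_g = sum_i f_i c_gi / L_i`; the observed profile is
`rel_target_g = 100 * n_g / sum_h n_h` over classified reads, and fidelity
is Pearson's r between the two.

## Worked example

```r
library(probecap)

cfg <- run_config(master_seed = 1, n_fragments = 10000)
res <- run_end_to_end(cfg)

res$manifest$counts
res$manifest$on_target_fraction
head(res$classification$abundance)
res$evaluation$pearson_r
```

Output from this exact run:

```
$target_db
[1] 112

$probes
[1] 84

$strains
[1] 19

$fragments
[1] 10000

$captured
[1] 724

$reads
[1] 1448

$annotated_reads
[1] 778

on_target_fraction: 0.7044199
  family count rel_target rel_total
1   nifH    30   3.846154  2.071823
2   amoA    47   6.025641  3.245856
3   nxrB    22   2.820513  1.519337
4   hzoA    37   4.743590  2.555249
5   nrfA    16   2.051282  1.104972
6   napA    77   9.871795  5.317680
pearson_r: 0.8925514
```

Reading it: the 14-family synthetic panel (84 unique 50-mer probes over
112 dereplicated target variants) captured 724 of 10,000 fragments from the
19-entry mock pool, 70% of them on-target; 778 of the 1,448 captured reads
receive a family annotation (the unannotated mates sit on the off-gene end
of partially overlapping fragments), and the classified profile correlates
with the designed mock truth at r = 0.89. Capture GC bias is on by default
(`capture_model()`); with `gc_bias = FALSE` and `p_max = 1` the acceptance
suite measures r = 0.998 at 50,000 fragments on a six-family mock.

A command-line interface wrapping design/classify/bench lives at
`inst/cli/probecap.R`.

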