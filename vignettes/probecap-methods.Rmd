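---
title: "probecap: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{probecap: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## What this package models

Hybridization-capture ("probe capture") targeted metagenomics enriches a
shotgun library for genes of interest before sequencing: biotinylated 50-mer
oligonucleotide probes, designed from a clustered database of all known gene
variants, hybridize to matching DNA fragments, which are pulled down on
streptavidin beads and sequenced. The approach is attractive for functional
guilds -- nitrifiers, denitrifiers, methanogens, methanotrophs -- whose
marker genes (amoA, nxrB, hzoA, nrfA, napA, narG, nirK, nirS, norB, nosZ,
nifH, pmoA, mmoX, mcrA) are individually rare in soil and sediment
communities, so that neither deep shotgun sequencing nor primer-biased PCR
amplicons recover their diversity well.

probecap implements the full computational side of such a study as one
reproducible toolkit: target-database curation, probe panel design, mock
community design with a controlled weighted GC mol%, an in-silico capture
simulator with an optional GC-dependent efficiency term, the read
classification pipeline (six-frame translation, identity-thresholded protein
matching, homolog disambiguation, dual normalization), and the benchmark
statistics (expected-versus-observed correlation, precision/recall, identity
binning, rarefaction). Everything runs on synthetic fixtures generated in
code, so a green test establishes the internal consistency of the method --
not the performance of any wet-lab protocol.

## Profile models and E-values

Field pipelines delegate variant discovery and read annotation to
profile-HMM searches with an `E < 0.001` report threshold. probecap
reproduces that filtering contract at desk scale with a simpler, fully
self-contained object: a position-specific scoring matrix (PSSM) with
affine-gap local (Smith-Waterman) scoring. `build_profile()` turns an
alignment into per-column log-odds scores
`log((count + pseudocount) / (rows + pseudocount * |alphabet|)) - log(background)`
(pseudocount 1, uniform background by default, both configurable). A column
is a match column iff its gap fraction is strictly below 0.5; at exactly 0.5
the column is dropped -- a deterministic tie rule.

E-values are calibrated per profile (`calibrate_profile()`): best local
scores of i.i.d. background decoys are fitted with a Gumbel distribution by
the method of moments, and at search time `E = n_db * P(S >= s)` under that
null. The same machinery, fitted on decoy peptides pooled over the database,
supplies E-values for the protein-mapping stage (BLOSUM62, gap open 11 /
extend 1). The method-of-moments fit is deliberate: it is deterministic,
has no convergence failures, and the contract it must honour is loose (the
test suite checks that among 10,000 fresh decoys the fraction with
`E < 0.001` stays below 0.005, and that true members of a family score
`E < 1e-6`).

## One identity convention

Greedy clustering, identity binning and probe matching all share one pinned
alignment convention: optimal pairwise alignment under match +1, mismatch
-1, gap -1 (linear), with the deterministic tie-break diagonal > up > left.
Identity is identities / shorter-sequence length for global comparisons (the
cd-hit convention used for the 80% probe-design clustering and the 90%
binning cutoff) and identities / alignment columns for local comparisons.
Pinning the scoring scheme *and* the tie-break makes the match count of the
optimal alignment a well-defined quantity, which is what lets the test suite
hold the implementation to exact equality against independently coded
brute-force oracles on hundreds of random instances.

## Probe design

`cluster_sequences()` performs greedy incremental clustering (descending
length, ties by id; a sequence joins the first representative it matches at
>= 80% identity, else founds a cluster). `design_probes()` enumerates every
50-mer of the representative, discards candidates with ambiguity codes or
homopolymer runs >= 8, scores candidates by member coverage (a member is
covered when some 50-mer window matches with <= 5 mismatches, i.e. 90%
probe identity -- hybridization tolerates mismatches), breaks ties by
|Tm - 47| then by smaller offset, and selects greedily up to six probes with
pairwise offset spacing >= 25. The melting temperature uses the standard
length-adjusted GC formula `Tm = 64.9 + 41 (nGC - 16.4) / k`; note a 50-mer
with 25 G/C melts at 71.95 degC under this formula -- the 47 degC target is
the capture *hybridization* temperature, used only as a scoring preference,
never as a hard filter. The exact candidate scoring of the original design
software is not public; this scoring is a faithful-contract reconstruction
and is flagged as such.

## Mock communities and ground truth

A mock design is a set of strains (name, genome or fragment, length, GC
mol%) plus a copy-number matrix. `solve_fractions()` inverts the
weighted-GC map: it returns the mass fractions minimizing KL divergence to a
prior subject to `sum(f) = 1`, `f >= 0` and `sum(f * gc) = target`; the
solution is an exponential tilt `f_i = prior_i exp(lambda gc_i) / Z` with
lambda found by monotone root finding and polished by Newton steps to a
1e-9 residual. The six shipped design targets are weighted GC 47, 50, 53,
57, 60 and 63 mol%.

Ground truth is gene dosage: `d_g = sum_i f_i c_{gi} / L_i` (copies per
unit DNA mass), normalized to percent. Dosage is invariant under uniform
scaling of all genome lengths, which is why the example strain pool can ship
with genome lengths scaled down 100x from the real organisms without
changing any expected abundance. DNA concentrations only matter when
converting pipetted volumes to mass fractions (`volumes_to_fractions()`).

The synthetic world is generated by `synth_family_sequences()` and
`synth_strain()`:

* one 200-codon consensus coding sequence per family (600 nt; a desk-scale
  stand-in for the 0.7-2.5 kb real genes). Equal lengths across families are
  deliberate: read counts are proportional to dosage times gene length, so
  equal lengths keep the count-based observed profile directly comparable to
  the dosage-based truth;
* homologous families share ancestry: amoA and pmoA derive from one ancestor
  (about 60-70% amino-acid identity in the realized fixture), and the
  nitrate-reductase-like cluster (napA, narG, nrfA, plus the decoy labels
  narH and fdhA, plus nxrB via narH) from another -- so homolog confusion
  and its competitive resolution are exercised honestly. Unrelated families
  are independent random genes;
* per-family variants (8 per family, divergence 0.02-0.15) form the
  synthetic target database for clustering, probe design and profiles;
* strain genomes are i.i.d. background at the requested GC mol% with gene
  copies planted codon-aware (substitutions only, stops never introduced,
  default divergence 0.10 from the consensus) at non-overlapping positions
  on random strands, truth recorded as 0-based half-open intervals;
* `example_mock_pool()` is a synthetic stand-in for the published 18-organism
  (+ one anammox hzoA PCR fragment) mock community: organism names and
  approximate genome GC values are real, gene content is a plausible
  reconstruction, lengths are scaled. The hzoA fragment uses the same dosage
  arithmetic as genomes (an assumption; the source protocol does not state
  how the fragment was normalized).

What the generator does *not* emulate: real gene length variation,
plasmids, rRNA operons, GC skew, PCR duplicates, indel sequencing errors,
chimeras. A green benchmark therefore establishes that the pipeline
recovers what the model plants -- not that any wet-lab capture behaves this
way.

## The capture model

Fragmentation follows the library protocol anchors: insert sizes
Normal(630, 60) truncated to [50, genome length], uniform starts and
strands, paired 300 nt reads (PE300) from fragment ends with uniform
substitution errors (default 0.005) and constant Q30 qualities (the
classifier never reads qualities, so a richer error model would be dead
weight).

Capture probability of a fragment is

    p = p_max * s(x) * gamma(gc)
    s(x) = 1 / (1 + exp(-kappa (x - x0)))          kappa = 30, x0 = 0.8
    gamma(gc) = clamp(gamma0 + gamma1 * gc, 0, 1)  gamma0 = 0.2, gamma1 = 1

where `x` is the fragment's best probe-match identity and `gc` its GC
fraction. The logistic-times-linear form and every default are simulator
inventions: the source observation is only directional (high-GC targets are
captured more efficiently), and no wet-lab quantity constrains `p_max` or
the GC slope. All parameters live in `capture_model()`.

Numerical choices in `hybridize()`:

* `x` is computed by exact local alignment against the (probe, strand)
  pairs that share an 11-mer seed with the fragment, capped at the 8
  pairs with the most shared seeds (homologous families share probes; the
  best-matching probe is always among the top seed-sharers);
* seed-free fragments get a background-identity estimate from a fixed panel
  subset (2 probes, fragment truncated to 400 nt). Under the defaults
  s(background identity) is about 1e-3, so this approximation only perturbs
  an already negligible off-target trickle;
* short local matches are penalized as `matches / max(columns, 30)`
  (`probe_match_min_len`), so a spurious 12-base block cannot masquerade as
  a high-identity probe match.

With defaults, the shipped 19-entry pool yields about 65-70% on-target
captured fragments -- qualitatively in line with enrichment levels reported
for real capture libraries, though that number depends entirely on the
invented efficiency parameters.

## Read classification

All six reading frames of each read are translated (stops rendered `*`,
trailing partial codons dropped) and locally aligned against the
family-labelled protein database. A hit is retained when its identity
(identities / alignment columns) is >= 60% and its `E <= 0.001`. No minimum
coverage is applied -- reads that barely overlap a protein still count.
Within each *direction* (the three forward frames pooled; likewise the
three reverse frames) hits are admitted in descending score order, each new
hit may overlap every already admitted hit of that direction by at most 15
amino acids on read coordinates, and at most 4 hits are admitted per
direction. "Direction = strand" is an interpretation: the source method
says "each direction" while translating six frames, and pooling frames per
strand is what makes the "single read spans neighboring proteins" rationale
coherent. The E-value ceiling is likewise an interpretive addition (the
reference mapper applies E <= 0.001 by default; without it, "no minimum
coverage" would admit arbitrarily short random 60%-identity blocks).

Per direction, same-family hits collapse to the best-E hit. Across the
read, when retained families fall in the same homolog group -- amoA/pmoA,
or the nitrate-reductase cluster {napA, narG, nrfA, narH, fdhA}, or
{nxrB, narH} -- only the best-E family is kept and the displaced families
are recorded in a reassignment audit trail. The decoy labels narH and fdhA
sit in the protein database precisely to absorb reads that a
reference-database cross-check would have reannotated; they are counted in
no target family. narH belongs to two groups; where a single merged label
is needed (homolog-merged precision), labels project onto the first
declared group containing them, so narH reports with the nitrate-reductase
group.

Abundance tables carry both published normalizations: `rel_target`
(percent of reads among the 14 target families -- the mock-community
convention) and `rel_total` (percent of all sequenced reads -- the shotgun
convention).

## Evaluation

`compare_abundance()` computes Pearson r between expected and observed
rel_target percentages over shared families (>= 3 required; a constant
observed vector yields NA with a warning rather than a fabricated
statistic). `precision_recall()` scores read-level family assignment
against planted truth, with optional projection of both sides onto homolog
groups first -- the treatment needed for amoA/pmoA, where a single KEGG
model covers both genes and per-family precision is not identifiable.
`bin_at_identity()` reuses the greedy clustering rule at a 90% cutoff as
the de-novo analogue of taxonomic binning; note de-novo bins are a coarser
object than reference-database bins, so published bin counts are not
comparable targets. `rarefy_bins()` subsamples without replacement and also
reports the exact hypergeometric expectation
`sum_b (1 - C(N - n_b, d) / C(N, d))`, which the Monte-Carlo mean must
match within Monte-Carlo error. Published per-gene significance tests are
reported descriptively (signed deviations) rather than re-implemented; the
original testing scheme's paired structure is under-specified, and the
tests themselves are off-the-shelf.

## Reproducibility

Every stochastic stage takes an explicit seed; `run_end_to_end()` derives
per-stage seeds by hashing (master seed, stage name), so any stage can be
re-run in isolation from the manifest, and identical config plus master
seed gives bit-identical outputs (asserted in the acceptance suite). The
acceptance criteria the test suite enforces: printed method constants as
working defaults; expected-abundance recovery with r >= 0.95 under unbiased
capture at 50,000 fragments; strictly lower per-design r for a 47-GC than a
63-GC design with the GC bias enabled (the directional effect, isolated on
capture-truth tabulation); exact equality of clustering and binning with
brute-force oracles on 200 random instances; rarefaction against the closed
form; perfect precision/recall on clean non-homolog reads plus
merged >= unmerged precision on an amoA/pmoA confusion set; and end-to-end
determinism.

## Known limitations

* The capture efficiency model is phenomenological; nothing calibrates it
  to chemistry, so absolute on-target rates and capture probabilities are
  not predictions.
* Background (off-target) capture is essentially absent under the default
  model, unlike real libraries (28-39% off-target is common); enrichment
  *specificity* claims should not be read off this simulator.
* No frameshift-aware alignment: indel sequencing errors would break the
  translated mapping (real pipelines share this limitation; the simulator
  emits substitution errors only, by design).
* Profile search is PSSM-based, not a full profile HMM; it honours the
  E-filter contract but is weaker than HMMER on remote homology.
* The example strain pool's gene content is a plausible reconstruction,
  not the published supplementary table.
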