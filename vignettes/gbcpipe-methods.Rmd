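---
title: "Methods and design notes for gbcpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for gbcpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

gbcpipe packages the downstream statistical machinery of an integrative
cancer-genomics analysis — consequence annotation, mutational signatures,
recurrence statistics, neoantigen prediction, immune-editing simulation,
expression-program scoring and repertoire diversity — as seed-reproducible
components. This vignette records the models, the parameters that matter,
and the design decisions taken where the underlying procedures left genuine
freedom.

## The coordinate model

Mutations live in 1-based CDS coordinates on the coding strand; codon *i*
covers positions 3i−2..3i. Insertions are anchored *after* `cds_pos`
(VCF-style left anchoring); deletions are inclusive ranges. Working in CDS
space removes any dependence on a reference genome or transcript database:
a gene is fully specified by its coding sequence plus optional 5'/3'
flanking bases, which are only needed to resolve trinucleotide contexts at
the CDS edges and to translate through a lost stop codon. The price is that
events outside the CDS (essential splice sites, promoters) cannot be
represented structurally; the mutation table therefore accepts a
`consequence_override` column so that, e.g., splice events can still enter
truncating-fraction statistics. Multi-nucleotide substitutions are rejected
outright rather than silently decomposed.

## Consequence annotation and mutant proteins

SNVs are classified by comparing the affected codon before and after the
edit; indels by length modulo 3. Any edit that destroys codon 1's ATG is
`start_lost` and yields an empty mutant protein (flagged, not an error).
Frameshift proteins are re-translated in the shifted frame to the first new
stop codon; if none occurs before the CDS end the protein is flagged
`no_stop_reached` and translation halts there — we do not invent 3' UTR
sequence. A lost stop codon is translated onwards only through whatever
`flank3` the gene model actually provides. The novel span of a frameshift
or stop-lost protein runs from the first altered residue to the new
C-terminus; for substitutions it is the minimal differing window (empty for
synonymous and for pure truncations, which contain no novel sequence).

## Spectra and signatures

SNV contexts use the standard pyrimidine-strand collapse: six substitution
types (C>A, C>G, C>T, T>A, T>C, T>G) crossed with 16 flanking-base
combinations gives the canonical 96 classes. Context sources occasionally
print other counts for the number of substitution types; six is the only
reading consistent with the printed list and with the 96-class scheme, and
is what we implement. SNVs at a CDS edge with no declared flank are counted
as context-unresolvable and excluded from the spectrum (and reported).

Signatures are extracted by multiplicative-update NMF on the 96 × n count
matrix under the generalized Kullback–Leibler divergence — the objective
under which mutation counts are Poisson draws from signature mixtures, and
the de-facto standard in this field. Numerical choices: entries are floored
at 1e−12 to keep updates defined; iteration stops at 2000 updates or a
relative objective change below 1e−8; 10 random restarts are run and the
best final objective kept, ties broken by lowest restart index; `W` columns
are normalized to probability vectors with the scale absorbed into the
exposures `H`. The objective trace is retained and asserted non-increasing
in the tests. The rank k is a user parameter: automatic rank selection is
deliberately out of scope because no principled default exists at the
cohort sizes this package targets.

## Recurrence statistics

* `fisher_exact_2x2` uses the two-sided point-probability rule (sum of
  hypergeometric probabilities ≤ observed × (1 + 1e−7)); the test suite
  verifies equality against a direct `choose()`-based enumeration for every
  table with margins ≤ 15. Odds ratios use the cross-product with a
  Haldane–Anscombe 0.5 correction only when a cell is zero, flagged.
* Gene significance deliberately substitutes a simple Poisson background
  for the convolution test of dedicated driver-detection tools: the
  cohort-wide protein-altering rate per CDS base (MSI outlier samples
  excluded, given burdens that can exceed 1000 events) scales each gene's
  expectation by its length; the upper-tail Poisson p-value is
  BH-adjusted, and `q_score = −log10(q)` with SMG at `q_score ≥ 1`. These
  q-scores are comparable in spirit, not numerically, to covariate-aware
  tools; the package's aim is a calibrated, transparent background, which
  the test suite checks (uniform null p-values, planted 10× gene
  recovered).
* A hotspot is a codon with protein-altering mutations in ≥ 2 *distinct*
  samples — the smallest recurrence worth reporting; the threshold is
  configurable.
* The truncating-excess randomization test re-places a gene's mutations at
  uniform positions (indels keep type and length; SNV substitution types
  are drawn from the cohort's six-type frequencies conditioned on the
  reference base at the landing site, falling back to uniform when the
  cohort has no observations for that base) and recomputes the truncating
  fraction; the empirical p uses the standard +1 correction, so it is never
  exactly zero. The choice of truncating *fraction* as the statistic is a
  design decision: the procedure this emulates is cited but not specified
  in the sources this package draws on.

## Neoantigens and immune editing

Candidate peptides are all 8–11mers overlapping at least one novel residue,
deduplicated, and filtered against the same gene's wild-type protein
(peptides present in the wild type are by definition not neoantigens).
Proteome-wide self-filtering is *not* performed — a declared limitation.
Binders are called at IC50 ≤ 500 nM; the inclusive reading is adopted
because the operational definition in the procedures we follow is
inclusive, and the boundary case is tested explicitly. Per-patient counts
consider only mutations with RNA support (≥ 1 read by default).

The affinity predictor is a contract: any deterministic
`(peptide, allele) → IC50` function works, and a TSV adapter ingests
external NetMHC-class scores. The bundled surrogate draws a k × 20
position-weight matrix per (allele, length) from a seeded deterministic
stream; the peptide score `z` is the normalized weight sum (standard normal
for random peptides) and `IC50 = clip(50000·10^(−a·z), 0.1, 50000)` nM with
sharpness `a = 1`, under which a random 9-mer binds at 500 nM with
probability ≈ P(z ≥ 2) ≈ 0.023 — a realistic per-peptide binder rate. The
surrogate is a synthetic stand-in for an external predictor: it preserves
the *structure* of the problem (determinism, allele specificity,
length-specific scoring), not any biochemical truth.

The immune-editing Monte Carlo draws, per iteration and per population,
one mutation and one allele copy uniformly (allele pools preserve observed
multiplicities), represents the pair by its best-affinity peptide, and
records a binder; after `n_sim = 5000` draws per pool the binder counts are
compared by a two-sided Fisher test, alongside the odds ratio of the two
binder proportions. Implementation note: because draws only ever touch the
finite (mutation × allele) grid, best affinities are precomputed once,
making the simulation O(grid) + O(n_sim).

## Expression programs, splicing, MSI, repertoires

The NRF2 activation score is the sum of per-gene z-scores over a 27-gene
signature, with NRF2+ at score > 15 (strict). The exact scoring formula
behind the published threshold is not printed in the sources; the z-score
sum is adopted because it is scale-free (invariant to per-gene affine
rescaling) and because under it the null score for 27 genes has standard
deviation √27 ≈ 5.2, putting the threshold near 3 SD — consistent with how
the threshold is used. Both the gene list and the threshold are
configurable; the bundled default list contains 27 canonical NFE2L2 target
genes. Zero-variance genes contribute 0 and are flagged; missing signature
genes are reported, not imputed.

Splice-variant filtering applies, in order: PSI nullification when the
supporting denominator is below 10; then the keep rule — some tumour sample
with FPKM > 2 *and* non-missing PSI > 0.1, a normal-panel zero fraction
above 99.8%, and no alternative-start/end or retained-intron flag. MSI is a
strict score > 0.35 rule. TCR diversity is the Shannon index in nats
(computed by vegan, the standard tool for the job), compared between groups
by a two-sided Mann–Whitney test — exact for combined n ≤ 20 without ties,
normal approximation with tie correction otherwise.

## The synthetic cohort generator

The generator's defaults are the study conditions the pipeline is designed
around: two populations of 60 and 91 samples; negative-binomial mutation
burden (mean 65, size 1) over a 46-gene panel, with 3 MSI-like outliers at
mean 1500 events (matching the heavy-tailed burden distributions such
cohorts show); an ELF3-like driver receiving 1-nt frameshift indels at
per-population rates 4/60 vs 28/91, concentrated (70%) at three hotspot
codons; a planted 10×-rate gene for significance calibration; pathway genes
whose planted mutations shift a 27-gene expression program by +1.5 SD; HLA
alleles drawn from population-specific frequency vectors (6 copies per
sample); and Dirichlet-multinomial clonotype repertoires with concentration
0.15 for frameshift carriers vs 1.0 otherwise. Driver genes carry a heavily
damped passenger load (2% of length-proportional weight) so their mutation
status reflects the planted events — the defensible reading of a small
modelled panel standing in for an exome.

SNV placement is two-stage: a 96-class is drawn from the sample's planted
signature mixture (renormalized over the trinucleotide contexts actually
present in the gene), then a position is drawn uniformly among sites with
that context, and the alternate base follows from the class through the
strand collapse. Drawing the class first — rather than a position first
with a class conditional on its context — is what makes the empirical
96-class spectrum converge to the planted mixture (total variation < 0.05
at ≥ 10,000 SNVs, asserted in the tests) even for skewed signatures whose
context usage differs from the CDS composition; a position-first scheme
converges to the product of the CDS context distribution and the
conditional, which is not the planted mixture.

What the generator does *not* emulate: real codon usage and genome-wide
context composition, subclonality and copy number, linkage between HLA
alleles, germline variation, sequencing error, or biochemically meaningful
peptide–MHC affinity. Recovery tests passing on this generator demonstrate
that the statistical machinery is correct and calibrated under its stated
assumptions — not that the defaults reproduce any particular real cohort's
numbers.

## Calibration and problem sizes in the test suite

The statistical acceptance checks run at sizes chosen to balance power and
determinism-friendliness: signature recovery uses 100 Poisson samples at
rank 2; the immune-editing null calibration uses 200 independent seeds at
500 draws per pool against one shared allele pool (the exact Fisher test is
intrinsically slightly conservative, so its p-value distribution under the
null is discrete and stochastically above uniform; at these sizes the
Kolmogorov–Smirnov check against uniformity has ≈ 90% pass probability by
construction, which we accept rather than replacing the exact test with a
mid-p variant); significance calibration uses 150 null genes of 450 codons
with a 150-codon planted gene at 10× rate, keeping the planted excess below
2% of the total so null p-values stay uniform; and the population-rate
power check runs 200 reduced cohorts with the default 4/60 vs 28/91 rates,
where the regional Fisher test rejects in well over 80% of runs.

## Known limitations

CDS-only representation (no genuine splice or non-coding events); a single
transcript per gene; the Poisson background ignores per-gene covariates
(replication timing, expression) that dedicated driver callers model; the
surrogate predictor is structural, not biochemical; no proteome-wide
self-peptide filter; and hierarchical clustering / survival layers of the
original analyses are out of scope by design.
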