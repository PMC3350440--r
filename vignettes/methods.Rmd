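---
title: "Methods: three-way transcriptome orthology, polymorphism and molecular evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: three-way transcriptome orthology, polymorphism and molecular evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthotrio)
```

# The problem

Comparative transcriptomics of closely related non-model species —
here, a trio of *Stegodyphus* spiders in which one lineage
(*S. mimosarum*) has evolved permanent sociality and regular inbreeding
while two congeners (*S. lineatus*, *S. tentoriicola*) remain
outcrossing — asks three linked questions. Which transcripts are
orthologous across the species? Along which branches, and how strongly,
has purifying selection acted on protein-coding change (dN/dS)? And
within each species, how much heterozygosity segregates, and with what
ratio of nonsynonymous to synonymous polymorphisms (piA/piS)? A strong
reduction of effective population size under inbreeding predicts
depleted heterozygosity and relaxed selection in the social lineage.

The original sequencing data for this design (454 assemblies and their
per-base pileups) are not required by this package. Instead, a
first-class simulator generates three transcriptomes descended from a
common ancestor with *known* orthology, *known* per-branch divergence
and *known* planted heterozygosity, so that every stage of the pipeline
is validated against ground truth. External data in standard formats
(FASTA transcripts, BLAST-style tabular hits, aligned FASTA, and a
documented pileup TSV) flow through the same functions.

# Pipeline stages and their models

## Orthology: reciprocal best hits, closed in a triangle

For each ordered species pair, the best hit of each query is the
maximum-bitscore subject among hits with E-value at or below 1e-5; ties
break by lower E-value, then lexicographically smaller subject id (the
underlying search tools do not guarantee an order, and determinism is
required for reproducible runs). A pair is a putative ortholog when the
best hits are reciprocal. A transcript triplet is accepted only when
all three pairwise reciprocal-best-hit edges exist and close a triangle
on the same three transcripts; transcripts reciprocal in only two
comparisons (an open path — the classic signature of paralogy or
assembly artifacts) are classified `two_pair_only` and excluded, and
components whose edges disagree on membership are
`inconsistent_triangle`.

The package ships a deliberately simple internal similarity scorer
(`toy_similarity_scores()`): the score of a pair is its number of
shared k-mers (default k = 12), with `10^-score` as a monotone E-value
stand-in. It exists so simulated data can exercise the orthology stage
without an external aligner; real analyses should feed BLAST tabular
output through `read_hits()`.

## ORF extraction and the minimum-length rule

The longest open reading frame is the longest maximal run of non-stop
codons over the six frames (both strands by default, since cDNA
orientation is unknown; a start codon is *not* required). The length
threshold below which such a run is uninformative comes from treating
stop-codon occurrence as Bernoulli with p = 3/64 per codon: the
probability that n random codons contain no stop is (61/64)^n, and the
smallest n with (61/64)^n < 0.05 is

```{r}
min_orf_codons(0.05)          # ceil of log(0.05)/log(61/64) = 62.3991
```

so alignments shorter than 189 bp are discarded. The boundary is
"shorter than": an alignment of exactly 189 columns is kept.

## Alignment curation

Externally aligned coding sequences (e.g. PRANK output) are curated
for frame integrity: the alignment is cut immediately before the first
gap run whose length is not divisible by three (a putative frame shift
from a sequencing or assembly error) — in *all* rows, because cutting a
single row would destroy the columnar alignment; this repeats until no
frame-shift run remains. Every surviving gap run (length divisible by
three) is then moved to the nearest codon boundary (ties left), and
trailing partial codons are trimmed. Residues are never created or
destroyed other than by truncation.

Surviving genes are dealt, in seeded shuffled order, into 20
concatenation units whose gene counts differ by at most one (the first
`N %% 20` units take the extra gene). The units are the replication
grain: every genome-wide confidence limit here is a t-interval or
bootstrap across units, which is why there are 20 of them rather than
one concatenate.

## SNP mining and piA/piS

Polymorphisms are mined from per-base pileups under four filters, all
recorded in every output header: depth within 10–150, minor allele
frequency strictly above 0.3 (computed among the two top alleles),
contigs strictly longer than 100 nt, and positions more than 10 nt from
either contig edge. A site whose third allele exceeds a 1% error
allowance is skipped — one diploid individual carries at most two true
alleles. A gap allele among the top two is counted as an indel event,
not a SNP. Calls are polarized by the base the two other species carry
at the orthologous position (both must agree and match one of the two
alleles; anything else leaves the call unpolarized and therefore
`undetermined`). The derived allele is substituted into the ancestral
codon of the reading frame: an amino-acid change is nonsynonymous.

Site denominators use Nei–Gojobori (1986) fractional counting with
stop-excluded possible-change sets, so each coding position contributes
exactly one site split between synonymous and nonsynonymous fractions,
and — importantly — the denominators are restricted to the positions
that actually passed the coverage and edge filters
(`coding_site_counts(positions = ...)`), keeping the per-site rates
unbiased. With one diploid individual per species, heterozygous calls
per site are the polymorphism measure; the constant factor relating
that to expected heterozygosity cancels in piA/piS.

## Divergence: counting, not maximum likelihood

Maximum-likelihood codon models (codeml's free-ratio model in the
original protocol) are deliberately out of scope; the package uses pure
counting:

* `ng86_pairwise()` — Nei–Gojobori sites averaged over the two
  sequences; per differing codon, synonymous/nonsynonymous steps
  averaged over minimal mutational pathways with equal weights,
  skipping pathways through stop codons (all pathways are used in the
  degenerate all-stop case); Jukes–Cantor correction
  d = −(3/4)·log(1 − 4p/3), undefined (flagged `NA`) at p ≥ 3/4.
* `branch_distances_star()` — on the three-taxon star topology every
  pairwise distance is the sum of two terminal branches, so per-branch
  dN and dS solve as b1 = (d12 + d13 − d23)/2 and cyclically. This is
  the package's default branch estimator.
* `branch_counts_3taxon()` — the per-column parsimony alternative: at
  codon columns where exactly one species deviates, the shared state is
  the internal-node codon and the difference is assigned to the
  deviating branch; three-state columns are skipped and their fraction
  reported.

The choice of the decomposition estimator as the default was made after
validating both on simulation: the parsimony column rule discards
exactly the multi-hit codons that carry most multiple substitutions,
which biases dS down by roughly 14% at the divergences this design
targets (branch dS 0.139/0.073), whereas the decomposition of pairwise
NG86+JC distances uses every codon and recovers simulated branch dS and
dN to within about 1–2% (and omega to within ~0.003) at 2×10^5 codons.
The parsimony counter remains exported and tested — its per-branch
difference *counts* are useful diagnostics and its sums agree with
pairwise counting whenever multi-hit columns are rare — but all
headline estimates, the pipeline and the confidence intervals use the
decomposition. Omega per branch is dN/dS, flagged undefined when dS is
zero; confidence limits are mean ± t(n−1, 0.975)·SE across the 20
units.

## Codon usage

GC3 is computed on degenerate third positions only (ATG and TGG are
the only sense codons excluded under the standard code). The effective
number of codons uses the background-composition-corrected form: per
synonymous family, expected codon frequencies are the products of
background base frequencies over the three positions renormalized
within the family; the chi-square statistic of observed versus expected
converts to the homozygosity analogue F = (X² + n − k)/(k(n − 1)); and
class-averaged F values aggregate as Nc' = 2 + 9/F2 + 1/F3 + 5/F4 +
3/F6, with the six-fold families (Leu, Ser, Arg) kept whole rather than
split 4+2, and the result clamped to [20, 61]. Families with fewer than
two observations are skipped; an entire empty degeneracy class is an
error rather than a silent extrapolation. Confidence intervals are
percentile bootstraps over the concatenation units; unit tables are
tabulated once and combined per resample (`combine_usage_tables()`).

## Clock dating

A synonymous molecular clock is calibrated either externally (total
path dS of 2.64 — 1.32 per branch — against a tarantula outgroup whose
split is dated at ~245 My, giving (2.64/2)/245e6 = 5.39e-9 per site per
year) or taken directly from a mutation-accumulation estimate
(8.4e-9). With per-branch synonymous divergences (d1; d2, d3) and the
inner pair (2,3), the inner split is mean(d2, d3)/rate and the outer
split is midpoint-rooted: ((d1 + mean(d2, d3))/2)/rate. The species are
annual, so generations equal years.

# The simulator: what it emulates, and what not

`simulate_triplet_transcriptomes()` draws each gene's ancestral codon
sequence from a codon frequency vector (uniform over the 61 sense
codons by default) and evolves it independently down the three star
branches under a continuous-time codon model: each single-nucleotide
codon change fires at relative rate 1 if synonymous and omega if
nonsynonymous; stop-generating changes are rejected. The branch
"length" is calibrated numerically on the ancestral sequence so that
the expected synonymous flux per NG86 synonymous site equals the
requested branch dS (exact as t → 0; multiple hits at realistic t are
what the JC correction at estimation time absorbs). There is no
transition/transversion bias (kappa = 1): the downstream estimators are
counting-based, and recovery validation does not need it.

Defaults are the study conditions: branch dS {0.139, 0.073, 0.073},
omega 0.1 on every branch; the paper-scale preset uses 1,345 genes with
codon lengths log-normal around a median of 171 (truncated to
63–1,092). Decoys exercise the rejection paths: species-specific orphan
genes, and paralogs made by duplicating a gene and evolving the copy an
extra two-fold branch length.

`simulate_pileups()` treats each transcript as a fully coding contig of
one diploid individual (the design sequenced one individual per
species, so there is no within-species sample structure to model).
Heterozygous sites are planted at chosen per-site rates separately for
synonymous and nonsynonymous changes — `round(pi * sites)` positions
drawn among eligible positions admitting a change of that class, which
controls planting variance relative to Bernoulli-per-site without
changing the target rate. Planting respects the caller's own edge and
contig-length exclusions, so error-free recovery is exact by
construction rather than approximate. Default per-species targets give
piA/piS of 0.10, 0.32 and 0.18 with total heterozygosity ~8-fold
depressed in sp2, the social species, mirroring the contrast the
original design reported. Depth is negative-binomial with mean 50 and
size 20 — centred comfortably inside the caller's 10–150 window, a
deliberate choice since the original assembler pileups (median contig
coverage ~4.2–4.7) are not reproducible here. Sequencing error
defaults to 0.2% per base, safely below the MAF 0.3 filter; an
`allele_balance = "exact"` mode replaces the Binomial(depth, 1/2) read
split with a deterministic half split for error-free fixtures.

What the simulator does **not** emulate — and what passing recovery
tests therefore do not certify about real data: real codon usage and
composition bias (sequences are uniform unless codon frequencies are
supplied, so simulated Nc' sits near 61, not at the ~50 of real
transcriptomes); insertions and deletions inside transcripts (indels
exist only as pileup gap alleles, so alignment curation is exercised by
constructed cases, not by the generator); assembly chimerism and
splice-variant redundancy; rate variation among genes and branches
beyond gene length variation; and linkage or departures from
equilibrium within species.

# Numerical choices and degenerate inputs

* Codons containing `N` (or alignment gaps) are excluded from all
  counting statistics — the conservative choice; they also break ORF
  runs, since a run containing `N` cannot be certified stop-free.
* MAF exactly 0.3, alignments exactly 189 bp, contigs exactly 100 nt:
  the filters are strict (`>`), strict (`>=` keep at 189), strict
  (`> 100`) respectively, matching the protocol's wording.
* Outgroup disagreement at a SNP position leaves the call unpolarized
  and excluded from effect classification. On simulated data this
  exclusion is slightly asymmetric — synonymous SNPs co-occur with
  synonymous outgroup divergence more often than nonsynonymous ones do
  — which inflates small-sample piA/piS estimates by a few percent at
  dS ~ 0.07; the recovery tolerance accounts for it.
* JC correction is undefined at p >= 3/4 and returns `NA` rather than
  a clamped value.
* Bitscore ties, unit dealing, bootstraps and every simulation draw are
  governed by explicit integer seeds, and the RNG state of the calling
  session is always restored.
* `jc_correct`, `ng86_*` and the simulator share one precomputed codon
  table (neighbour structure, per-position site fractions, 64×64
  pathway-averaged difference counts), built once per session.

# Problem sizes used in validation

Recovery tests run at the scale where their tolerances are meaningful:
branch-rate recovery on 2×10^5 codons (400 genes × 500 codons),
piA/piS recovery on ~10^5 coding sites, heterozygosity-depression
recovery on 2×~1.8×10^5 sites, and the end-to-end smoke test on a
dozen-gene fixture that completes in seconds. The analysis scripts
under `analysis/` run the full paper-scale configuration (1,345 genes,
~0.84 Mb aligned per species); each step completes in well under a
minute.

# Known limitations

* The branch estimator assumes the star topology is correct; it does
  not infer topology.
* piA/piS from one diploid individual is a coarse estimate of
  population-level constraint; the package reports counts alongside the
  ratio so users can judge the sampling noise.
* The counting estimator has no among-site rate variation and the JC
  correction assumes equal base frequencies; at divergences well beyond
  dS ~ 0.3 a likelihood method should replace it.
* The toy k-mer scorer is not a substitute for BLAST on real data; its
  E-value is a monotone transform of the score, not a statistical
  expectation.
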