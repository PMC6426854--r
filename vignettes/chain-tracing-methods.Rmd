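---
title: "Methods: tracing taxa and strains across a dairy production chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracing taxa and strains across a dairy production chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Raw-milk cheeses are made without thermal treatment, so bacteria present
in the cow's gut can in principle travel the whole production chain —
feces (CF) contaminate the litter (LIT), litter contact seeds the teat
and the raw milk (MIL), and milk microbes end up in the fresh cheese
(PC) — and from the cheese reach the consumer's gut. `dairytrace`
implements the computational side of testing that hypothesis at three
levels of resolution:

1. **Taxon level** — which genera/OTUs are consistently present in
   several matrices of the same production site (prevalence-based
   core-microbiota analysis)?
2. **Strain level, targeted** — can a specific strain, identified by a
   marker contig assembled from shotgun metagenomics, be traced across
   matrices by strain-specific primers and by exact read mapping?
3. **Strain level, confirmatory** — do two samples carry the *same*
   strain, judged by SNP allele-frequency profiles and by average
   nucleotide identity (ANI) between isolate genomes?

Every stage is exercised end to end on synthetic data with planted
transmission events, so recovery can be checked against known truth.

# Prevalence-based sharing logic

A taxon is *present* in a (site, matrix) group of samples when its
prevalence — the fraction of the group's samples in which it is detected
(abundance strictly > 0) — strictly exceeds the threshold
(`prevalence_threshold`, default 0.70). With the study design of 10
samples per group, "strictly greater than 70%" means at least 8 of 10
samples. The strictness matters at the boundary and is asserted in the
tests (7/10 fails, 8/10 passes).

Sharing is then pure set algebra on the presence map:

* `shared_across_matrices()` intersects per-matrix presence at one site;
* `pairwise_sharing_counts()` tabulates the size of that intersection
  for every combination of two or more matrices, per site and averaged
  across sites (published shared-OTU figures are cross-site averages, so
  both are reported);
* `site_sharing()` applies the core rule: a taxon *qualifies* at a site
  when present in at least `min_matrices_for_core` (default 3) of the
  four matrices. PC is deliberately not mandatory per site: that is the
  only reading under which the packaged published core table reproduces
  its own printed summary counts (13 qualifying taxa, 2 shared at ≥4
  sites, 3 at exactly 3 sites), because one family lacks a reported PC
  cell at one site yet is counted among the four-site taxa.

The published core table ships as a plain-text fixture
(`table1_fixture()`), with a dash transcribed as "not reported/absent".
Because the published numbers mix prevalence-based and detection-based
statements, `prevalence_filter()` exposes both modes
(`mode = "prevalence"` and `mode = "detection"`) rather than guessing
which produced a given printed count.

Genus tables, 16S OTU tables and bifidobacterial ITS phylotype tables
all share one code path: an OTU "at 100% identity" is simply a finer
taxon label supplied by the caller. OTU picking and taxonomic
classification are upstream of this package.

# Alpha diversity

`chao1()` implements the classic estimator
\(S_{obs} + F_1^2/(2F_2)\) with the bias-corrected fallback
\(S_{obs} + F_1(F_1-1)/(2(F_2+1))\) when no doubletons exist, so the
estimate is always finite. `shannon()` uses the natural logarithm (the
index's conventional definition; the base is an argument). Rarefaction
subsamples without replacement (multivariate hypergeometric, via
`vegan::rrarefy`) at 10 evenly spaced depths by default, averaging a
configurable number of repeats per depth; at full depth it returns the
observed richness exactly. The original box plots were drawn at a single
fixed subsampling depth; since the exact procedure behind them is not
stated, `alpha_diversity()` exposes `depth` as a parameter instead of
hard-wiring one.

# Synthetic communities and the transmission plan

`community_spec()` + `generate_chain_profiles()` draw each sample's
composition from a Dirichlet distribution centred on the matrix's mean
profile with a single concentration parameter (`overdispersion`,
default 200). This is the simplest compositional noise model with a
tunable amount of prevalence leakage. Any unassigned mass goes to an
unreported remainder component. Zeros are *structural*: values below
`detection_floor` (default 1e-4) are set to 0, which gives the sharing
logic controllable absences. Per-sample dispersion of real matrix
compositions is not reported anywhere we could anchor to, so the
overdispersion default is a free parameter chosen to give visibly noisy
but stable group means; it is not a literature value.

Planted taxa from the `transmission_plan()` are injected at their exact
carry-over abundance and the background is rescaled by (1 − planted
total), so compositions stay ≤ 1 and a planted taxon has prevalence
exactly 1.0 in its planted groups and exactly 0 elsewhere. The
generator's defaults mirror the emulated study design: 10 samples per
(site, matrix) group, four matrices, and a cheese profile dominated by
the two lactic families at mean relative abundances 0.903 and 0.087.

Strain truth is planted with `mutate_genome()` (exactly *n* substitutions
at distinct uniform positions, truth set recorded) and
`simulate_reads()` (uniform start positions, both strands, per-base
substitution errors at `error_rate`, no indels, truth per read). Reads
are substitution-only because the whole downstream stack — strict
mapper, tolerant mapper, pileup — is ungapped; this keeps the planted
guarantees exact: an error-free read always passes the 100%/100% rule,
a read with at least one injected error never does.

What the generator does *not* emulate: amplicon chemistry and chimeras,
indel and quality-dependent error models, 16S copy-number effects, GC
bias, genome rearrangements, and real taxonomic correlation structure
between matrices. Passing recovery tests therefore demonstrates the
correctness of the *logic* under its stated assumptions, not performance
on real sequencing data.

# Strain markers, primers and in-silico PCR

Contigs shorter than or equal to `min_len` (default 3000 bp, strict) are
discarded, mirroring the accuracy filter applied before taxonomic
assignment of assembled sequences; the largest remaining contig of a
species — taken to represent a chromosomal region of one specific
strain — is the marker (ties broken by smallest id for determinism).

`design_primers()` performs a deterministic left-to-right scan: forward
windows ordered by (start, length), then amplicon lengths ascending,
then reverse-primer lengths ascending; the first pair wins. Constraints:
primer length 18–25 nt, product 100–600 bp, GC 40–60%, and a
melting-temperature window (50–65 °C) under the Wallace rule
2(A+T) + 4(G+C) — a deliberate, documented approximation rather than
nearest-neighbour thermodynamics, adequate for synthetic validation.
Specificity is *exact-substring absence*: a primer (or its reverse
complement) occurring anywhere in the user-supplied background set
disqualifies it, and each primer must occur exactly once in the marker.
This replaces a BLAST search against the public nucleotide database with
a deterministic, desk-scale, conservative criterion; the background set
is the caller's responsibility. If no pair survives, the marker is not
strain-discriminative and an explicit error says so.

`in_silico_pcr()` reports an amplicon wherever the forward primer
matches exactly and the reverse primer's reverse complement matches
exactly downstream within `max_product`; both orientations are searched
and a single mismatch in either site suppresses the product. The
presence call is ≥ 1 amplicon — the in-silico analogue of a band on a
gel.

# Strict and tolerant read mapping

`strict_map()` encodes the published presence rule: a read counts only
if it (or its reverse complement) is an exact, full-length substring of
a reference contig. All occurrences are reported. Internally constant-
width read sets are matched with a preprocessed dictionary
(`Biostrings::PDict`/`matchPDict`), which is equivalent to naive
substring search — an equivalence the test suite re-verifies against a
plain-R brute-force oracle on hundreds of randomized instances. Reads
containing ambiguous bases never match, preserving the exactness of the
100% rule.

`tolerant_map()` is the mismatch-tolerant engine used for SNP profiling:
ungapped, full-length, at most ⌊`max_mismatch_frac` × length⌋
substitutions (default 0.05), candidate locations from exact seed
matches (pigeonhole: with ≤ k mismatches at least one of k+1
non-overlapping seeds is exact), every candidate verified by direct
mismatch counting. Each read gets its single best location; ties are
treated as ambiguous and the read is discarded rather than placed
randomly — determinism is worth more here than a marginal gain in
coverage. Setting `identity_cutoff` < 1 in `mapping_config()` routes the
strict mapper through this engine; `coverage_cutoff` < 1 additionally
allows alignments truncated by contig ends (the aligned fraction of the
read must still reach the cutoff). Alignments are never gapped; this is
a stated limitation relative to production aligners.

Presence from mapping uses two conservative knobs: at least `min_reads`
hits (default 1 for the PCR analogy; the packaged pipeline uses 10) and
breadth of coverage at least `min_breadth` (default 0.5). The original
heat-map does not state its minimum evidence for a "detected" call, so
both are explicit parameters.

# SNP profiles and same-strain decisions

`pileup()` tallies aligned bases per reference position (conservation:
total tallied bases equal total aligned bases, asserted in tests).
`snp_profile()` keeps positions with coverage ≥ `min_cov` (default 5)
and records the variant allele frequency (1 − reference-base frequency)
and the major-allele frequency.

`profile_distance()` is the mean absolute variant-frequency difference
over jointly covered positions *that show variation* (≥ 0.1 in either
sample). Restricting the mean to variant positions keeps the distance on
the allele-frequency scale regardless of reference length — with the
average taken over all positions, 50 strain-distinguishing SNPs on a
100 kb reference would dilute to 5×10⁻⁴ and no fixed threshold could
separate strains across reference sizes. Joint coverage (not variation)
governs sufficiency: fewer than `min_joint` (default 50) jointly covered
positions yields an `insufficient-overlap` verdict, so two variant-free
samples of the same strain compare as identical rather than as
non-overlapping. On profiles sharing a reference and support the
distance is a pseudometric (non-negative, symmetric, zero on identical
profiles, triangle inequality), which the tests check on random
profiles.

`same_strain()` declares identity when the distance is ≤ `delta`
(default 0.01) *and* both samples are homogeneous — at least `h`
(default 0.95) of profile positions have a major-allele frequency
≥ 0.9, i.e. each sample is dominated by a single strain. These
thresholds are calibration parameters validated on synthetic planted
truth (within-strain distances land at ~0, between-strain comparisons at
~1 on the variant positions); they are not literature values, because
the source analyses report SNP similarity only qualitatively.

# Fragment ANI

`ani()` follows the fragment convention of BLAST-based ANI: the query is
cut into 1020 bp fragments, each fragment is placed at its best ungapped
location in the subject (exact 16-mer seeds propose candidate diagonals,
full mismatch counting verifies them, both strands), and fragments are
retained when they align with ≥ 30% identity over ≥ 70% of their length.
One direction's ANI is the mean identity of retained fragments; the
reported value averages both directions. The original analysis names
only the program it used, so these are declared defaults of the
convention that program implements, all configurable. Identical genomes
score exactly 100%; a genome against its reverse complement also scores
100% (strand awareness); ANI decreases monotonically with planted
substitution load, and 1% uniform substitutions give ≈ 99% — all
asserted in the tests. Ungapped fragment placement means ANI between
genomes with substantial indel divergence will be underestimated; within
the package's scope (isogenic-vs-diverged strain discrimination) this
does not bite.

# Expression screen

`rpkm()` is the exact published formula
`numReads/(geneLength/1000 × totalNumReads/1,000,000)`.
`fold_screen()` flags genes whose condition/control RPKM ratio strictly
exceeds `fold` (default 3). A control RPKM of 0 with a positive
condition value is included and flagged infinite (the source is silent
here; exclusion would hide exactly the strongest inductions); zero in
both conditions is excluded. Whether the original 3-fold rule compared
replicate means or required every replicate to pass is not stated, so
both modes exist (`mode = "mean"`, the default, and
`mode = "per_replicate"`). The published counts of upregulated genes
depend on the real RNA-seq data and annotations and are out of reach
desk-side; the mechanism is validated on planted counts instead.

# Pipeline, demo and determinism

`make_demo()` writes a miniature two-site chain (CF/LIT/MIL/PC, 10
samples per matrix) with two planted taxa and two planted strains — one
transmitted chain-wide across all four matrices of one site, one partial
(LIT and PC of the other) — plus per-group reads and assemblies, marker
contigs, isolate genomes with a 50-SNP diverged "other site" variant for
the ANI stage, an expression table with a known number of >3-fold genes,
truth files and a ready `config.yaml`. `run_pipeline()` executes the
stages in workflow order and writes one TSV per report plus a JSON
manifest with md5 checksums of every output; a rerun under the same
config is byte-identical, which the tests assert. Orchestration is a
plain R API (`run_pipeline()`, `make_demo()`,
`read_pipeline_config()`); there is no shell executable, as the
package's users drive it from R.

# Problem sizes and numerical choices

The test suite and the demo run at deliberately modest sizes chosen so
the whole battery completes in minutes while keeping every statistical
check well-powered: strain genomes of 10–20 kb, read sets of 2,000–10,000
reads at 100–150 bp, 30–50× coverage for SNP recovery, 50 random
transmission plans for exact recovery, hundreds of randomized instances
for the oracle-equivalence checks, and a ~1 Mb genome for the ANI
identity benchmark. Allele-frequency recovery is judged against 3σ
binomial bounds at the observed per-position coverage; Monte Carlo
comparisons against exact expectations (rarefaction) use a 0.5-taxon
tolerance at 40 repeats.

Tie-breaking and degenerate-input rules, collected: marker selection
ties → smallest id; ambiguous multi-locus reads → unmapped; reads with
ambiguous bases → never match in strict mode, count as mismatches in
tolerant mode; empty read sets, empty references, empty strain lists,
all-zero count vectors and empty sample groups → explicit errors; an
empty SNP profile is allowed (it simply yields insufficient overlap
downstream); fragment ANI with no retained fragments in either direction
→ explicit "no ANI support" error rather than a fabricated 0.

# Known limitations

* All alignment is ungapped; indels, rearrangements and gapped homology
  are invisible to the mapper, the pileup and the fragment ANI.
* Primer specificity is exact-substring screening against a
  user-supplied background, not a thermodynamic or database-wide search.
* The Wallace Tm rule is a rough approximation outside 18–25 nt primers.
* The synthetic generator's noise model is Dirichlet-compositional with
  structural zeros; real amplicon data have additional sources of
  variance, so thresholds tuned here should be re-examined on real data.
* Published figures that depend on the full sequencing data (average
  shared-OTU counts, relative-abundance percentages of specific species,
  counts of upregulated genes) cannot be recomputed from this package
  alone and are not claimed by it.
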