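---
title: "Models and methods behind the mmsdk pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the mmsdk pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmsdk)
```

## The assay model

MMSDK couples a methylation-sensitive restriction digest with tag
sequencing. *MluI* recognizes ACGCGT and is blocked by CpG methylation, so
only **unmethylated** sites are cut; fragmentation with *NlaIII* (CATG) and
*MmeI* release produces 17–18 nt tags anchored at each *MluI* site. Tag
abundance at a site therefore rises when the site is less methylated — all
direction logic downstream inverts the tag ratio sign
(`classify_direction()`): a tumor/normal tag ratio of log2 ≤ −1 is called
hypermethylated, ≥ +1 hypomethylated. DGE expression profiling is the
SAGE-style counterpart: 17 nt tags adjacent to *NlaIII* sites in cDNA, one
locus per gene after mapping.

The in-silico digest (`build_mmsdk_library()`) mirrors the chemistry under
the all-unmethylated hypothesis. Coordinates are 0-based half-open
throughout; *MluI* cuts at motif offset +1 (A^CGCGT) and *NlaIII* at +4
(CATG^), the enzymes' published cut positions. Each *MluI* cut spawns an
upstream and a downstream fragment reaching to the nearest *NlaIII* cut or,
if one intervenes first, to an obstacle (chromosome end or adjacent *MluI*
cut). Obstacle-bounded fragments carry no internal *NlaIII* site and yield
no tag; that bookkeeping — not an error path — is what makes the fragment
census of a reference genome meaningful. Tags are read from the *NlaIII*
boundary into the fragment (for downstream fragments that is the reverse
complement), exclude the CATG itself, and require at least 18 interior
bases; the 17-mer form is the prefix of the 18-mer. Whether the ~17 nt tag
should include its CATG anchor is a convention choice; we exclude it, the
classic SAGE reading, and the mapper is built around that choice
consistently, so either convention would round-trip.

ACGCGT is its own reverse complement, so a forward scan is the complete
site set. CATG likewise (C↔G, A↔T reversed); for DGE we scan forward and
emit both orientations per site: the 17 bases after the CATG, and the
reverse complement of the 17 bases before it.

## Counting and pooling

Reads are cleaned (`filter_reads()`): N-containing reads always go;
`min_len = 18` reproduces the small-RNA length floor; `drop_singletons`
implements the erroneous-tag filter used for mRNA tags (single-copy
sequences are more likely sequencing artifacts than real transcripts);
mean-quality < Q20 reads are dropped only when qualities exist. Adapter
removal (`clip_adapter()`) is a semi-global alignment of the adapter
against every read suffix (+1/−1/−2 scoring, clip at score ≥ 7), which
handles partial adapters at the read end and tolerates substitutions.

Mapping (`map_tags()`) assigns a tag to a locus only when it has a unique
best hit at Hamming distance ≤ 1; ties are discarded as ambiguous and never
rescued, so results are independent of input order. Aligner-specific
mapping-quality thresholds used with general-purpose mappers are exactly a
uniqueness guarantee in this setting, so the contract here is stated
directly as uniqueness rather than through a proxy score. 18-mer reads are
matched at full length first and fall back to their 17-mer prefix — a read
from a 17 nt tag can carry one downstream template base — and both forms
resolve to the same library entry.

Replicates are pooled per condition by the arithmetic mean of counts,
rounded **half-up** to an integer, and library sizes are pooled the same
way (`pool_by_mean()`). Whether rounding happens before or after averaging,
and whether pooled library sizes are means or sums, changes nothing
qualitatively but must be fixed for reproducibility; mean-then-round-half-up
for both is this package's convention. R's default banker's rounding is
deliberately not used.

## The differential test

For pooled counts x (tumor, library n1) and y (normal, library n2), with
r = n2/n1, the conditional probability of observing k tags in the second
library given x in the first is

p(k|x) = r^k (x+k)! / ( x! k! (1+r)^(x+k+1) ),

a negative-binomial mass that integrates the Poisson rate out under a flat
prior. Both tails at the observed y are summed directly in log space — the
upper tail by explicit summation from k = y upward until terms fall below
machine noise, never by complementation, so p-values in the 1e-12 range
remain accurate to absolute 1e-12 against brute-force summation. The
two-sided p doubles the smaller inclusive tail and caps at 1. Tail-doubling
with inclusive tails is one of several defensible two-sided conventions;
the "sum of all outcomes no more likely than observed" alternative is
available via `alternative = "less_likely"`. A caveat worth knowing: with
inclusive tails the p-value is not exactly invariant under swapping the
two libraries (the identity that does hold exactly is lower tail ↔ strict
upper tail of the swapped orientation); the discrepancy is one probability
mass term and immaterial at realistic counts.

P-values use raw integer counts, never normalized values. The log2 ratio is
computed on the TPM scale with a pseudocount of 0.5 TPM on both sides —
zero-count loci otherwise have undefined ratios; 0.5 is small against the
|log2| ≥ 1 calling threshold and symmetric between conditions. Significance
requires FDR ≤ 0.05 **and** |log2Ratio| ≥ 1, both inclusive, with BH
adjustment (`bh_adjust()`, the textbook step-up) computed within each omics
layer separately, since each layer is its own family of hypotheses.

`compare_region_distributions()` contrasts tumor-vs-normal log2
distributions per genic region class (CpG-rich promoters, CpG-poor
promoters, exons, introns) with the two-sided Wilcoxon rank-sum test: exact
enumeration when both groups are ≤ 12 and untied, otherwise the normal
approximation with tie and continuity correction.

## CpG islands and annotation

`detect_cgi()` applies the three classic criteria — GC ≥ 50%,
observed/expected CpG > 0.6 with obs/exp = nCpG·L/(nC·nG), length strictly
greater than 200 bp — as a seed-and-merge scan: 200-bp windows stepped by
1 bp that pass all criteria are merged; each merged span is re-tested as a
whole and, if the union dips below a threshold, trimmed one base at a time
from alternating ends until it passes or falls to the length floor.
Trimming from alternating ends is an arbitrary but deterministic tie-break;
since every constituent window already passes, trimming is rarely invoked.

`annotate_loci()` assigns each locus one region class with precedence
promoter > exon > intron > intergenic. "Promoter" is TSS ± 1,000 bp
(strand-aware) by default — there is no universal definition, 1 kb is a
common compromise, and the window is a parameter recorded with the output.
A promoter locus overlapping any CpG island is a CGI-promoter. When a
curated island track exists it can be supplied in place of `detect_cgi()`
output; `digest_reference_summary()` accepts one as BED.

## miRNA target consensus and integration

`consensus_targets()` keeps (miRNA, gene) pairs supported by at least 2 of
the 3 prediction tools and present in the union of the experimentally
supported databases. "Agreement of two of three tools" is read as ≥ 2-of-3
rather than one fixed tool pair — the reproducible, stricter-than-union
reading — and consensus is computed at pair granularity, not gene-only,
which again is the stricter of the two possible readings. miRNA ids are
compared case-insensitively with any "hsa-" prefix stripped; -3p/-5p arms
are never collapsed, because guessing arm equivalences silently merges
distinct molecules. `pair_with_de()` restricts to differentially expressed
miRNAs; the anticorrelation filter (repressed miRNA with induced target or
vice versa) is off by default since the consensus definition itself carries
no direction constraint.

`join_meth_expr()` works at gene level: a gene with several MluI loci takes
its most significant locus (smallest p, ties by larger |log2|, then by
locus id — multi-locus genes are common and the collapse rule must be
explicit). Joint categories pair the inverted methylation direction with
the expression direction: hyper-repressed, hyper-induced, hypo-repressed,
hypo-induced, or ns unless both layers pass their thresholds.
`hypergeom_enrich()` is the standard right-tail hypergeometric test over a
user-supplied GMT collection, BH-adjusted; the universe defaults to the
genes with data in the layer under test (testing against the whole genome
inflates enrichment when detection itself is biased), and is configurable.

## The synthetic-data generator

`simulate_genome()` plants what the pipeline consumes: `n_mlu_sites`
cassettes (CATG — 30–500 bp gap — ACGCGT — gap — CATG) so every planted
site has *NlaIII* boundaries and yields both tags; CpG-island segments
generated CpG-dense and re-drawn until every 200-bp window inside passes
all three criteria; and simple 2–4-exon gene models, half of them with
their TSS inside a planted island so CGI-promoter joints exist. The
background is i.i.d. at the configured GC (human-like 0.41 by default).
Accidental ACGCGT occurrences are rewritten to a fixed point so the
planted-site truth is exact; accidental CATG is left alone — realistic, and
truth tracks only the *MluI* anchors. One integer seed drives everything
through per-stage derived sub-streams, so stages regenerate independently
and byte-identically.

`simulate_counts()` draws independent Poisson counts at a constant baseline
rate (default 100 tags/locus across 9 tumor/normal pairs), with `n_spiked`
loci's tumor rates multiplied by 2^(±`spike_log2fc`), signs recorded in the
truth. Poisson is chosen to match the differential test's own model, which
makes the spike-recovery and calibration checks a test of the pipeline
rather than of a model mismatch; a negative-binomial option
(`dispersion > 0`, variance μ + dispersion·μ²) exists for robustness
studies only and is off by default. `simulate_reads()` emits tag+adapter
reads with optional per-base substitution errors and optional
reverse-complemented fractions for orientation stress.

What the generator does **not** emulate — and hence what green tests do not
establish about real data: base-quality profiles and quality-dependent
errors, indels, PCR duplicates, per-locus rate heterogeneity and
biological replicate dispersion, incomplete digestion, and CpG depletion of
the background (i.i.d. sequence has obs/exp ≈ 1, so GC-rich background
windows can satisfy the island criteria far more often than in a real
genome — island calls on synthetic background are correct by the criteria
but denser than biological reality).

## Numerical and scale choices

Problem sizes in the test-suite and acceptance script are chosen to
exercise each property at convincing scale while staying desk-sized: the
digestion oracle runs on 100 random 50-kb genomes; the p-value oracle over
the full (x, y) ∈ [0,30]² grid at three library ratios; null calibration on
10,000 loci (fraction of p < 0.05 expected slightly below nominal because
the statistic is discrete); spike recovery on 5,000 loci × 9 pairs × 3
seeds; the read-level round trip on a 200-kb genome with 100 cassettes.
The four reference-genome digestion counts (21,038 / 42,126 / 694 / 2,942
on human hg18 with the UCSC island track) need a local copy of that
multi-gigabyte assembly, pointed to by `options(mmsdk.hg18_fasta=,
mmsdk.hg18_cgi_bed=)`; without it that check reports failure rather than
silently passing.

Known limitations: the mapper is an exact/1-mismatch hash, not a gapped
aligner, and is meant for tag-length sequences only; pooling by averaging
discards replicate variance by design (the two-library test models pooled
libraries, not per-patient variability); fragment bookkeeping counts two
fragments per site minus chromosome-end losses, which is the natural model
for the digest but need not match every published census convention; and
enrichment results are only as good as the supplied GMT — no ontology
download or term-graph propagation is attempted.
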