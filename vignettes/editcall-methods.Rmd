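---
title: "Detecting A-to-I RNA editing without a reference genome: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting A-to-I RNA editing without a reference genome: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(editcall)
```

## The detection model

A-to-I editing is read by sequencers as an A-to-G substitution relative to
the genome. Without a reference genome, the genomic state of each position
must itself be inferred from data: `editcall` compares RNA-seq reads and
DNA-seq reads from the same animal, both aligned to a de novo transcriptome
reduced to protein-coding ORFs. The transcriptome consensus is built from
RNA, which creates the central subtlety: a site's consensus base depends on
how strongly it is edited. Two regimes follow, each with its own test.

**Weak sites** (editing level below ~50%): the consensus keeps the genomic
A, and edited reads appear as a minority of G's. For a position covered by
`n` uniquely-aligned RNA bases of quality Q ≥ 30, of which `k` carry a given
alternative base, the null hypothesis is that all `k` arose from sequencing
error, with upper-tail p-value `P(X ≥ k)` for `X ~ Binomial(n, ε)`. Since
only Q ≥ 30 bases are counted, ε = 0.001 is a (slightly conservative) upper
bound on the post-filter error rate. Every (covered coding position ×
3 alternative bases) pair is a hypothesis — zero-mismatch alternatives enter
the family with p = 1 — and the family is corrected by Benjamini–Hochberg at
FDR 10%. Finally, any site at which one or more DNA reads disagree with the
consensus is discarded: a heterozygous SNP puts ~50% non-consensus bases in
*both* RNA and DNA, so even modest DNA coverage vetoes it. The veto is exact
(tolerance 0) by default; `dna_discordance_tolerance = 0.001` reproduces the
variant used when DNA coverage is so high that sporadic DNA errors would
otherwise veto every site. No DNA-coverage floor is imposed
(`min_dna_cov = 0`): a site with zero DNA coverage passes the veto
vacuously, which is why DNA depth drives weak-site *precision* (see the
saturation analysis).

**Strong sites** (editing level above ~50%): the RNA-derived consensus
carries the edited G, so every genomic DNA read disagrees with it. For `d`
DNA reads all carrying the same non-consensus base, the alternative
explanation is a SNP; assuming no allele-specific expression, a heterozygous
site would put each DNA read on either allele with probability 1/2, giving
`p = π_SNP (1/2)^d` with SNP prior `π_SNP = 0.001`. These candidate p-values
form their own BH family at FDR 10% — the two procedures are corrected
separately, mirroring their independent logic. Strong candidates with no
supporting RNA read are dropped; because "supporting" is ambiguous, both
readings are implemented (`strong_support_mode = "any"`, the default: any
quality-filtered RNA base at the site; `"alt"`: an RNA base carrying the
edited allele).

**Site representation.** Tables are genome-centric: `ref_base` is the
inferred genomic base, `alt_base` the edited base, so a strong site whose
consensus is G and whose DNA reads are all A is reported as `A>G` — the
direction in which editing counts are tabulated — with the transcriptome
base kept in `consensus_base`. `editing_level` is always the fraction of
RNA reads carrying the edited base. Internally positions are 0-based
half-open; every emitted table is 1-based inclusive and says so in its
header.

**Noise floor.** Editing only produces A-to-G; the other 11 mismatch types
(assembly errors, SNPs that slipped through, somatic mutations, systematic
misalignment) estimate the false-positive rate of each procedure as
`non-A-to-G / A-to-G` calls, assuming noise is type-symmetric — an
assumption the null-simulation test checks with a chi-square homogeneity
test across types.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `q_min` | 30 | Phred cutoff; bases below are discarded everywhere |
| `error_prob` | 0.001 | binomial error rate among Q≥30 bases |
| `fdr` | 0.10 | BH level, per procedure |
| `snp_prior` | 0.001 | prior probability that a position is a SNP |
| `dna_discordance_tolerance` | 0 | DNA-veto tolerance for weak sites |
| `min_dna_cov` | 0 | DNA coverage floor for weak sites |
| `min-mapq` | max observed | "uniquely aligned" operationalization |

"Uniquely aligned" is aligner-specific; by default a record is unique when
its mapping quality equals the maximum observed in its file, and an explicit
cutoff can be given instead. Mate pairs are treated as independent reads.
Read ends are *not* trimmed: aligning to a transcriptome removes the
splice-junction artifacts that usually motivate end-trimming, and the
mismatch-by-read-position histogram is computed as QC instead
(`--trim-ends` exists for sensitivity analysis).

## Downstream analyses

**Clusters.** Bona fide editing clusters along transcripts and within
single reads. A site cluster is a maximal run of ≥ 3 same-type sites in one
ORF with no intervening site of another type; the literal reading — any
number of unmodified bases may intervene, with no distance cap — is the
default, with `max_gap` as a sensitivity variant. Read-level clusters count
reads whose mismatches of one type run uninterrupted by other-type
mismatches.

**Sequence context.** A-to-I sites show depleted G immediately 5' and
enriched G immediately 3'. `neighbor_preference()` compares site flanks
against all A's in the coding regions and produces the `context_model`:
per (5',3') combination, the fraction of A's with that context that are
edited. Sites at ORF boundaries are excluded from the affected flank.

**Tissue comparison.** Editing levels of already-called sites are
re-quantified per tissue (no re-calling), and each site/tissue-pair is
tested with a two-sided binomial analysis of each tissue's edited-read
count at the pooled proportion, taking the smaller of the two tissue
p-values; two-sidedness is by doubling the smaller tail. This is one
defensible reading of a "binomial analysis" between two samples; Fisher's
exact test is available as an alternative and both are conservative under
the Bonferroni correction applied over all (site × pair) tests at
α = 0.05. Variable sites are clustered hierarchically (average linkage,
Euclidean distance on level vectors — unstated in the original analysis,
so chosen as the most common convention and made configurable), with
uncovered cells imputed by the site's mean level.

**Recoding.** Codon consequences use the standard genetic code (an
alternative code can be passed for mitochondrial ORFs); stop-affecting
changes count as recoding. The null for "how much recoding would chance
produce" is the context-preserving randomization: A positions are screened
in random order and accepted with their context's modelled probability,
without replacement, repeating passes until the observed site count is
matched. On an all-AAA ORF this converges to a 2/3 nonsynonymous fraction
(positions 1 and 2 of AAA recode, position 3 is synonymous), the analytic
anchor used in the tests. Per-level-bin comparisons draw one matched-size
randomization per run and partition it randomly into the observed bin
sizes, which is distributionally equivalent to per-bin draws but much
cheaper. The cumulative recoding level of an ORF is the sum of editing
levels over its recoding sites; "heavily edited" means that sum exceeds 1.
Substitution-score analyses take an externally computed per-position score
table; their null shuffles editing levels within recoding type, preserving
both the type spectrum and each type's level distribution.

**Junctions.** DNA reads from intron-containing loci are soft-clipped at
exon boundaries when locally aligned to the transcriptome. Clipped flanks
are grouped by (ORF, position, side) on their first 20 clipped bases
(shorter flanks join a longer group sharing their prefix — the comparison
length is not dictated by anything in the data, so it is exposed);
a flank whose leading 20-mer occurs exactly anywhere in the ORF set is
discarded as realignable. The exact k-mer scan is a deliberate
approximation of a full local alignment check: it is deterministic, fast,
and errs on the permissive side only for flanks with ≥ 1 mismatch to the
transcriptome in their first 20 bases. Groups with ≥ 3 reads are reported.

## The simulator

`simulate_dataset()` emulates the structure of a matched editing study:
random ORFs with start/stop discipline; editing sites placed on A's by
context-weighted sampling (default weights emulate the observed 5'/3'
preference); per-site levels from Beta(1,3) by default (right-skewed, most
sites weakly edited, a realistic shape for editing-level spectra);
heterozygous SNPs at 0.001/bp carried at 50% in *both* DNA and RNA reads;
per-base errors at 0.1% independent of the two-component quality model
(~90% of bases near Q38, ~10% near Q20, so the Q30 filter does real work);
reads emitted as already-aligned records, making outputs deterministic
given the seed. Default coverages (100× RNA, 30× DNA) and density (5/kb)
are the package's standard test conditions; they are an order of magnitude
below the original study's sequencing depth, scaled so the full pipeline
runs in seconds while keeping every statistical mechanism operative.
Intron simulation draws DNA reads from exon–intron–exon loci and reproduces
the soft-clipping geometry a local aligner would emit, dropping reads
anchored by < 20 aligned bases.

What the simulator does **not** emulate — and what passing tests therefore
do not certify about real data: transcriptome mis-assembly, position- and
cycle-dependent Illumina error profiles, alignment artifacts (reads are
placed, not aligned), PCR duplicates, linked SNP haplotypes, and
expression-dependent coverage variation. The false-positive structure of
real data (the 15%/4% noise floor) comes from exactly these unmodelled
processes; the simulator's role is to validate the statistical machinery,
not to reproduce the noise biology.

## Numerical and degenerate-input choices

* Binomial tails via `pbinom`; BH via `p.adjust` (the step-up rejection set
  equals q ≤ FDR).
* Consensus building: majority vote over all RNA bases (no quality filter —
  assembly sees every read); ties and zero coverage keep the reference.
* `n = 0` positions are untestable (weak), `d = 0` (strong); `ref_base = N`
  positions are never testable.
* Empirical p-values use the (1+hits)/(1+runs) estimator, two-sided by
  doubling, with a 1e-9 relative tolerance on comparisons so that
  permutation nulls that merely reorder identical values are not pushed off
  p = 1 by floating-point summation order.
* Deletion-spanning positions contribute nothing; inserted bases are
  ignored; soft-clipped bases are excluded from pileups but kept for
  junction inference.
* Problem sizes in the test suite and acceptance script (10–60 ORFs of
  100 codons, 20 null replicates, 10,000 randomization draws) were chosen
  once to keep every binomial/chi-square check well-powered at desk scale.

## Known limitations

* SAM/BAM input is read per file into memory (via Rsamtools), not streamed;
  datasets at the scale of hundreds of millions of reads should be
  pre-split by reference or processed per ORF batch.
* The strong-site test assumes no allele-specific expression, as stated;
  strong ASE would inflate the SNP probability beyond `(1/2)^d`.
* The two-sample "binomial analysis" for tissues is a composite test; its
  Bonferroni-corrected use is conservative, and the Fisher alternative is
  preferable when per-tissue coverage is very low.
* Junction inference reports ORF-side positions only; it does not assemble
  full intron sequences.
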