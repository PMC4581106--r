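---
title: "Marker discovery from multi-accession transcriptome panels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker discovery from multi-accession transcriptome panels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transmark)
```

# The setting

`transmark` operates downstream of variant calling. The assumed study
design is a small panel of related accessions (typically three) whose
RNA-seq reads were mapped against the representative transcripts
("unigenes", one per locus) of one of them, with a standard caller
producing a multi-sample VCF annotated with site quality (QUAL),
strand-bias FS, quality-by-depth QD, depth, and per-sample GT/DP/AD. The
package turns that call set into three marker resources: a hard-filtered
SNP panel with its summary statistics, CAPS assays (PCR plus restriction
digestion), and SSR assays (microsatellite length polymorphism).

Coordinates are 1-based and inclusive everywhere in the data model and
reports, matching VCF conventions; any half-open arithmetic is internal.

# The two-round filter

Transcriptome variant calls carry characteristic artifacts that the
filter is designed around:

* **Clusters.** Misassembly and paralog co-mapping produce runs of calls.
  Any `cluster_size` (3) sites on one transcript whose inclusive span
  (max − min + 1) is at most `cluster_window_bp` (100) all fail. The span
  tie at exactly 100 bp counts as "within". The rule is evaluated by
  sliding over consecutive k-tuples, which is provably equivalent to
  checking every k-subset: any qualifying subset contains a qualifying
  consecutive run. The cluster rule is applied to the survivors of the
  other round-1 filters, so a site already discarded for, say, strand
  bias cannot pull two clean neighbours down with it.
* **Mapping artifacts.** Sites where more than 10 % of reads have zero
  mapping quality fail (`MQ0`); the fraction is read from INFO `MQ0F`,
  reconstructed as `MQ0/DP` when only those are present, and treated as
  absent otherwise. Absent annotations always pass: a threshold on a
  value the caller never produced is a no-op, not a rejection.
* **Support thresholds.** FS > 60, QD < 2, QUAL < 11, total depth < 11.
* **Allele frequency.** With only three genotypes a genotype-based minor
  allele frequency is nearly meaningless (its granularity is 1/6), so
  the `min_maf` = 0.01 rule is applied to the pooled minor-allele *read
  count* frequency: per-allele AD counts summed over samples, minor =
  least common observed allele. The same statistic is reported per site
  (`marcf`) as a confidence measure — values near 0.5 indicate balanced
  support, values near 0 suggest sequencing error or misalignment.
* **Transcript geometry (round 2).** The first and last 30 bp of each
  transcript are excluded, as are sites within 30 bp of a predicted
  exon–exon junction (junctions are where spliced-alignment artifacts
  concentrate). At least `min_deep_genotypes` = 2 samples must have
  depth **strictly greater than** 10 — the rule is deliberately strict
  rather than ≥ 10. Finally, sites where the reference accession itself
  is heterozygous are removed: if the accession the assembly came from
  is not homozygous at a position, the position is unreliable as a
  reference coordinate.

Reasons from both rounds are accumulated rather than short-circuited, so
the verdict table is complete for reporting; the pipeline is idempotent
(re-running on the passing set removes nothing).

# Classification and statistics

Region classification partitions each annotated transcript by the
predicted ORF: positions before `orf_start` are 5′UTR, positions inside
the inclusive ORF interval are CDS, the rest 3′UTR; transcripts without
an ORF annotation yield region `UNKNOWN` rather than a guess.
Substitution classes are unordered allele pairs, with A/G and C/T the
two transitions; Ts/Tv tables are computed over biallelic sites,
stratified by region, with percentages formatted at one decimal using
half-up rounding.

Pairwise polymorphism between two accessions is only asserted when both
genotypes are called and both depths exceed 10 (strictly). "Polymorphic"
covers both the homozygous–homozygous case (`POLY_HOM`, the diagnostic
markers) and any comparison involving a heterozygote (`POLY_OTHER`);
three-way Venn partitions are produced under both definitions because
the two answer different questions (how many loci differ at all vs how
many are fixed differences). For triallelic sites the minor-allele
read-count frequency uses the single least common observed allele, a
literal reading of "least common", not the sum of non-major alleles.

SNP frequency is total reference length divided by SNP count, reported
as bp-per-SNP at integer precision; the mean SNPs-per-transcript uses
*all* transcripts as denominator, not only SNP-containing ones. N50
follows the descending-cumulative rule with the result constrained to an
observed length.

# CAPS prediction

An enzyme is diagnostic for a biallelic SNP when a recognition match
*covering the SNP position* exists in exactly one of the two allele
windows (± 10 bp, truncated at transcript ends; 10 bp exceeds the
longest bundled recognition site minus one). Requiring the match to
cover the SNP is the standard CAPS definition; a mere difference in
site *counts* elsewhere in the amplicon would admit assays that do not
actually distinguish the alleles at the SNP. Scanning handles the full
IUPAC degeneracy of recognition sequences; an N in the transcript never
matches a pattern letter other than N, so masked regions cannot produce
phantom sites. All 20 bundled enzymes have palindromic recognition
sequences, making forward-strand scanning exhaustive (a tested
property).

The amplicon is a single 200–400 bp window covering the SNP, chosen to
centre the SNP as nearly as primer feasibility allows; ties go to the
smaller amplicon (maximising the smaller cut fragment), then leftmost.
One primer pair is designed on the amplicon flanks under the same
constraint machinery as SSR primers. For each diagnostic enzyme the
package digests both allele versions of the amplicon *in silico*
(cut position = match start − 1 + cut offset; boundary cuts produce no
fragment) and reports the two fragment ladders, which always sum to the
amplicon length. An optional scorability screen rejects markers whose
ladders differ by less than a user-set number of base pairs, measured as
the symmetric Hausdorff distance between the two fragment-length sets;
the default of 0 disables the screen, reproducing the behaviour of
recognition-difference-only pipelines, because scorability thresholds
depend on the gel system. Loci may legitimately yield several markers —
output is one row per (locus, enzyme) with a per-locus rollup, since
with nested sites (every SacI site contains an AluI site) a single locus
is often cut by multiple enzymes.

Genome projection maps transcript positions through user-supplied
alignment blocks affinely; on the minus strand positions count down from
the block's genomic end. Positions in unaligned gaps raise `UNMAPPED`
rather than extrapolating.

# SSR detection and primers

Detection finds maximal perfect tandem repeats of primitive 2–6 bp units
meeting the thresholds 6/5/5/5/5 (di- through hexanucleotide);
mononucleotide runs are excluded by those criteria. Internally the
sequence is compared against itself at lag *k*: a period-*k* region
appears as a run of matches, only whole repeat units are counted, and
the first unit of the run names the motif. A repeat region is reported
exactly once, at its smallest primitive unit: non-primitive motifs
(`ATAT`) are skipped and longer-unit loci wholly contained in a reported
shorter-unit locus are suppressed, mirroring MISA's non-redundant
reporting. The test-suite pins this behaviour to an independent
regex-based oracle on repeat-rich random sequences.

The canonical motif class is the lexicographic minimum over all
rotations of the motif and of its reverse complement, so GA, AG, TC and
CT all belong to one class. The class label pairs that representative
with the minimal *distinct* rotation of its reverse complement, which
names classes the way the field writes them — "AG/CT", "AAG/CTT", and
"AT/TA" for the palindromic AT unit (whose reverse complement equals
itself, so the display partner falls back to the remaining rotation).
There are exactly 4 dinucleotide and 10 trinucleotide classes, a tested
invariant.

Compound SSRs are consecutive loci separated by at most 100 interrupting
bases — MISA's default interruption distance, used here because the
threshold itself is rarely reported alongside the tool's name.

Primer design enumerates products deterministically: smallest product
first, then most-centred target, then leftmost; each primer takes its
smallest feasible length. Constraints are the published SSR parameters
(amplicon 100–280 bp, Tm 55–65 °C, length 18–28 nt, GC 45–55 %), also
applied (with the 200–400 bp amplicon range) to CAPS amplicons. The
melting temperature uses the GC-fraction formula
Tm = 64.9 + 41 (nG + nC − 16.4) / length — chosen because only the
acceptable Tm *window* is part of the assay specification, not a
thermodynamic model, and the GC-fraction formula makes feasibility a
function of window GC count alone, which in turn lets the search
precompute minimal feasible primer lengths per position and resolve each
target arithmetically. GC content is counted over the whole primer,
inclusive. Since the formula is monotone in GC, the Tm and GC windows
jointly imply primers of roughly 21–28 nt at 45–55 % GC.

# The synthetic-data generator

Every pipeline stage is validated against data with planted ground
truth. The generator emulates a three-accession panel: 200 unigenes of
1.5–3.5 kb (uniform), an ORF covering 13 % 5′UTR / 60 % CDS of most
transcripts (3 % left unannotated to exercise `UNKNOWN`), ~5000 SNPs
placed outside the filtered zones with at least 51 bp spacing (so no
accidental clusters), substitution classes drawn at a target Ts/Tv of
1.7, per-accession zygosity mixes (the reference accession never
heterozygous, 5 % divergent-homozygous; one partner mostly homozygous;
one highly heterozygous, emulating a self-incompatible outcrosser),
Poisson read depths around 100× with a 2 % error-read fraction in
homozygous allele counts, 50 planted SSR loci, 20 planted
CAPS-diagnostic contexts, and exactly one planted violation event per
filter reason on two reserved transcripts. These defaults are the
package's standard study conditions; the acceptance checks run at
exactly this scale.

Design points worth recording:

* One pseudo-random stream per feature family, each seeded from the
  master seed, so adding a family never perturbs the others' draws; a
  fixed spec reproduces byte-identical files (a tested property).
* Sequences are scrubbed of accidental above-threshold repeats before
  planting, `plant_ssr` verifies its locus round-trips through the
  detector at exactly the planted coordinates (re-randomising flanks
  when they would extend or merge the repeat), and generation ends with
  an exactness check that the detector sees precisely the planted SSR
  set.
* A planted cluster violation necessarily comprises three sites — the
  rule cannot fail fewer — so the truth table records three `CLUSTER`
  sites for the one planted event and one site for every other reason.
* The planted low-depth site carries a site-level INFO depth below
  threshold while per-sample depths stay high, the one geometry in which
  the site-depth rule can fire alone (callers emit site DP after their
  own read filtering, so the two can legitimately disagree).
* Sites where every accession would be homozygous for the alternate
  allele are avoided (the reference accession keeps its assembly
  allele): at such a site the reference allele is supported only by
  error reads and the site could not survive the allele-frequency
  filter, which would contaminate the clean planted set.

What the generator does *not* emulate — and therefore what passing tests
do not show about real data: sequencing-error and misalignment structure
beyond a flat error-read fraction, paralog collapse (the main source of
real cluster and MQ0 failures), splice-aware coverage dips at real exon
junctions, allele-specific expression, indels (excluded from the SNP
contract), and linkage between nearby sites. Recovery rates on synthetic
data are upper bounds, not field estimates of validation rates.

# Problem sizes and runtime

The default test run generates one mid-sized study (40 transcripts,
~600 SNPs) shared across test files plus the full-scale study above for
the acceptance checks; the oracle suites use 100 repeat-rich 10 kb
sequences (SSR), 60 instances of 1 kb (CAPS) and panels up to 200 sites
(cluster brute force). The complete suite and the acceptance script each
run in a few minutes on one CPU.

# Known limitations

* CAPS design is single-amplicon, single-primer-pair; no dCAPS
  (mismatch-primer) rescue of SNPs without a differential site, no
  methylation-sensitivity modelling, no multi-pair ranking.
* SSR detection is perfect-repeat only; imperfect or interrupted repeats
  are reported as separate (possibly compound) loci or missed.
* Primer design screens length/GC/Tm/product size, not secondary
  structure, dimers or cross-hybridisation; the Tm model is the
  GC-fraction formula, not nearest-neighbour thermodynamics.
* The VCF reader trusts the caller's annotations; no recalibration or
  genotype refinement is attempted.
* No codon-level synonymous/non-synonymous annotation of CDS SNPs.
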