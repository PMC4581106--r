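# transmark

Post-assembly molecular marker discovery for non-model plant
transcriptomes in R.

When several related accessions or species are resequenced by RNA-seq and
mapped against one reference transcriptome, the resulting multi-sample
variant calls are a rich source of breeder-friendly markers — provided
they survive aggressive hard filtering (transcriptome variant calls are
noisy near transcript edges, splice junctions and low-coverage regions)
and can be turned into assays scorable on an agarose gel. `transmark`
implements that whole post-calling workflow:

* **Two-round SNP hard filtering.** Round 1 removes clustered calls (any
  3 SNPs spanning ≤ 100 bp on one transcript), sites with > 10 % of reads
  at zero mapping quality, strand bias (Phred-scaled Fisher FS > 60),
  pooled minor-allele read-count frequency < 0.01, quality-by-depth
  QD < 2, site quality < 11 and total depth < 11. Round 2 applies the
  transcript-aware rules: the first/last 30 bp of each transcript, 30 bp
  around every predicted exon–exon junction, a requirement of at least 2
  genotypes with depth > 10, and exclusion of sites where the reference
  accession itself is called heterozygous.
* **Classification and summary statistics.** 5′UTR/CDS/3′UTR region by
  the predicted ORF; substitution class and transition/transversion (Ts/Tv)
  tables by region; per-sample zygosity; pairwise polymorphism status at
  10× depth and the three-way Venn partition; minor-allele read-count
  frequency; per-unigene SNP distributions; SNP frequency (bp per SNP);
  assembly N50 and size bins; IUPAC masking of variant positions.
* **CAPS marker prediction.** A SNP becomes a cleaved amplified
  polymorphic sequence (CAPS) marker when one of 20 common restriction
  enzymes has a recognition site overlapping the SNP in exactly one
  allele. `transmark` scans both allele windows with full IUPAC
  degeneracy, places a single 200–400 bp amplicon with one primer pair,
  and — going beyond recognition-difference pipelines — predicts the
  digestion fragment ladder of each allele so unscorable markers can be
  screened out. Transcript coordinates can be projected onto genome
  scaffolds through alignment blocks.
* **SSR (microsatellite) detection.** Maximal perfect tandem repeats of
  2–6 bp primitive units at the MISA thresholds 6/5/5/5/5 (di- through
  hexanucleotide), motif canonicalization under rotation and reverse
  complement (GA, AG, TC, CT → "AG/CT"), compound-SSR grouping, and
  constrained primer design (amplicon 100–280 bp, Tm 55–65 °C, length
  18–28 nt, GC 45–55 %).
* **A synthetic-data generator** that plants SNPs (with controlled
  region placement, Ts/Tv and zygosity structure), filter violations,
  CAPS-diagnostic contexts and SSR loci at known coordinates, so the
  entire pipeline is testable end-to-end without any sequencing data.

## Worked example

```r
library(transmark)

# a small synthetic study: 30 unigenes, ~400 SNPs across 3 accessions
# (A = the reference accession), 10 planted SSRs, 5 planted CAPS contexts,
# and one planted violation per filter reason
sim <- generate(sim_spec(seed = 1, n_transcripts = 30, n_snps = 400,
                         n_ssr = 10, n_caps = 5))
sim$tx
#> transcriptome: 30 transcripts, 72,426 bp total
sim$panel
#> snp_panel: 419 sites, 3 samples (A, B, C)

flt <- run_filter_pipeline(sim$panel, sim$tx,
                           filter_config(reference_sample = "A"))
flt$report
#>       CLUSTER          MQ0  STRAND_BIAS      LOW_MAF       LOW_QD
#>             3            1            1            1            1
#>      LOW_QUAL    LOW_DEPTH         EDGE     BOUNDARY
#>             1            1            1            1
#> INSUFFICIENT_DEEP_GENOTYPES  REF_HET  n_input  n_pass
#>                           1        1      419     406
```

Each planted violation is caught for exactly its reason (the cluster rule
necessarily removes all three sites of the planted cluster). The passing
sites classify and summarise:

```r
cls <- classify_panel(flt$passing, sim$tx)
tstv_summary(cls)$tstv
#>       ALL       CDS  FIVE_UTR THREE_UTR
#>       1.7       1.6       1.4       2.1
snp_frequency(sum(sim$tx$length), n_sites(flt$passing))
#> [1] 178        # one SNP every 178 bp
```

The generator drew substitutions at a target Ts/Tv of 1.7 and the
summary recovers it. SSR detection finds exactly the planted loci, and
CAPS prediction reports one row per (locus, diagnostic enzyme) with the
two allele fragment ladders:

```r
head(detect_ssrs_transcriptome(sim$tx)[, c(1:2, 4:5, 7)], 3)
#>   transcript_id start  motif n_repeats canonical_class
#> 1        TX0003   749  TTCTT         6     AAAAG/CTTTT
#> 2        TX0006   817 CATGAT         7   ATCATG/ATGATC
#> 3        TX0008  1100    GGC         8         CCG/CGG

caps <- caps_markers(flt$passing, sim$tx)
head(caps$markers[, c("transcript_id", "pos", "enzyme", "allele_cut",
                      "ladder_ref", "ladder_alt")], 3)
#>   transcript_id  pos enzyme allele_cut   ladder_ref      ladder_alt
#> 1        TX0003  148  HinfI        ALT          201          97,104
#> 2        TX0003 1074   TaqI        ALT   29,102,234   29,78,102,156
#> 3        TX0003 1245   TaqI        ALT 13,66,70,114 13,17,53,66,114
```

At TX0003:148 the alternate allele is cut by HinfI: the undigested 201 bp
amplicon against the 97 + 104 bp ladder is easily scored on a gel.

A thin command-line wrapper over the same functions is installed at
`inst/cli/transmark.R` (`Rscript transmark.R all --config run.yaml`).

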