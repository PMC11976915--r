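# synapa

Analysis toolkit for 3′-end sequencing (3′-seq) of polyadenylated mRNA, aimed
at two questions neuroscience labs ask of such data: **which transcripts does
an RNA-binding protein bind in vivo** (cross-linking RIP followed by 3′-seq),
and **which 3′ UTR isoforms of a gene localize differentially** between
subcellular fractions such as synaptosomes and total input.

3′-seq reads one position per transcript — the cleavage/poly(A) site — so a
gene with alternative polyadenylation (APA) appears as several discrete
read-end clusters of different 3′ UTR length. Two artifacts dominate raw
data: internal priming of the oligo-dT primer on genomic A-rich stretches,
and spurious ends far from any real gene. `synapa` implements the full
cluster-level workflow:

1. **Internal-priming blacklist.** A candidate end base *b* is masked if, on
   the transcribed strand, the base run immediately downstream is
   `A^k, k >= run_len`, or at least *h* of the *w* downstream bases are A
   (presets: 6 / 7-of-10 for RIP libraries, 4 / 6-of-8 for synaptosome
   libraries). Bases within 25 nt of an annotated 3′ end are exempt; only
   signal within a gene body or ≤ 500 nt (RIP) / ≤ 2000 nt (synaptosome)
   downstream is kept.
2. **Cluster calling.** Positions with single-sample depth ≥ 6 seed
   intervals `[s−15, s+16)`; overlapping or abutting intervals merge; reads
   are re-counted across all samples; clusters are kept only if they
   intersect 50-nt windows around high-confidence validated 3′ ends, and are
   assigned to the nearest same-strand gene.
3. **Differential expression.** A self-contained negative-binomial Wald test
   (median-of-ratios size factors s_j; per-feature method-of-moments
   dispersion α̂ shrunk 50/50 toward a fitted trend a₀ + a₁/μ; statistic
   log2FC/SE with the delta-method SE). RIP targets are genes with
   log₂(IP/input) > 1, p < 0.05, baseMean > 10 and log₂(IP/control-IP) > 1.
4. **Weighted 3′ UTR length.** Per APA gene and condition,
   `W = Σ_i f_i · e_i`, where e_i is isoform i's share of the gene's
   normalized expression and f_i its length fraction — either real
   (length / longest length) or ranked (i/k). Four difference statistics
   (subtracted and log₂, each metric) are z-scored across genes; a gene
   exceeding the one-tailed 5% point (|z| ≥ 1.645) in any distribution is
   called longer- or shorter-in-synaptosome by the sign of the difference.
5. **Isoform binding preference.** Clusters split at the gene-specific
   proximal poly(A) site; long-isoform proportion = distal/(proximal+distal);
   paired two-sided t-test of RIP vs input proportions across genes.
6. **Enrichment.** Exact two-sided Fisher tests for gene-set overlap and for
   IUPAC motif occurrence (e.g. the Pumilio response element consensus
   `UGUANAUA`) in target vs background 3′ UTR sequences.

A first-class synthetic-data generator (`sim_config()`,
`generate_reference()`, `simulate_end_reads()`) emits a genome with planted
A-tract decoys, gene models, a validated-end set, and per-sample read ends
with known ground truth (isoform usage shifts, RIP enrichment factors,
internal-priming reads), so every stage is testable against planted truth.

All coordinates are 0-based, half-open (BED-native).

## Worked example

```r
library(synapa)

cfg <- sim_config(n_genes = 60, n_localized_genes = c(6, 3),
                  n_rip_targets = 12, seed = 42)
ref    <- generate_reference(cfg)
design <- sample_design()                       # input/synaptosome/rip/control_rip x3
reads  <- simulate_end_reads(ref$truth, design, cfg)

sites <- call_sites(reads, ref$genome, ref$annotation, ref$validated,
                    bl_params = blacklist_params("xrip"))
#> call_sites: 247401 reads -> 247401 in windows -> 235031 after blacklist;
#>   146 clusters -> 146 validated -> 146 assigned

conditions <- setNames(design$condition, design$sample_id)
cm <- count_matrix(gene_level_counts(sites$clusters),
                   conditions[colnames(gene_level_counts(sites$clusters))])
targets <- call_pum_targets(nb_wald_test(cm, "input", "rip"),
                            nb_wald_test(cm, "control_rip", "rip"))
sum(targets$is_target)
#> [1] 12        # exactly the 12 planted RIP target genes

iso <- build_isoform_table(sites$clusters, ref$annotation, conditions)
loc <- call_localized_genes(gene_length_stats(iso))
table(loc$class)
#>  longer_in_syn            ns shorter_in_syn
#>              2            38              6

sp  <- split_proximal_distal(sites$clusters,
                             proximal_sites_from_isoforms(iso), ref$annotation)
bt  <- binding_preference_test(
         long_isoform_proportion(sp, conditions, "input"),
         long_isoform_proportion(sp, conditions, "rip"),
         genes = targets$gene_id[targets$is_target])
#> t = 6.41, df = 11, p = 5.04e-05 (mean long_prop 0.75 rip vs 0.58 input)
```

The 235031/247401 reads surviving the blacklist reflect removal of the 5%
planted internal-priming reads (all of them) and essentially no true-site
reads. All 12 planted RIP targets are recovered with no false calls; 6 of
the 6 planted shorter-in-synaptosome genes are called in the shorter class;
and the positive t-test confirms the planted 2× distal binding weight (RIP
long-isoform proportion 0.75 vs 0.58 in input).

## Command line

```sh
inst/cli/synapa run-all --seed 1 --out out/            # full synthetic pipeline
inst/cli/synapa call-sites --mode xrip --genome g.fa \
    --annotation ann.gff3 --reads ends.bed --validated val.bed --out clusters.tsv
inst/cli/synapa motif --targets utrs.fa --background bg.fa --motif UGUANAUA
```

Subcommands: `simulate`, `call-sites`, `de`, `call-targets`, `utr-length`,
`binding`, `nutr-signal`, `enrich`, `motif`, `run-all`.

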