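test_that("generator is deterministic under a fixed seed", {
  cfg <- sim_config(n_genes = 20, n_localized_genes = 2, n_rip_targets = 4,
                    seed = 1)
  r1 <- generate_reference(cfg)
  r2 <- generate_reference(cfg)
  expect_identical(as.character(r1$genome), as.character(r2$genome))
  expect_identical(r1$truth$isoforms, r2$truth$isoforms)
  expect_identical(r1$truth$genes, r2$truth$genes)
  design <- sample_design(replicates = 2)
  expect_identical(simulate_end_reads(r1$truth, design, cfg),
                   simulate_end_reads(r2$truth, design, cfg))
})

test_that("forced two-isoform genes yield exactly 2 records per gene", {
  cfg <- sim_config(n_genes = 10, isoforms_per_gene = c(0, 1, 0, 0),
                    n_localized_genes = 0, n_rip_targets = 0, seed = 2)
  ref <- generate_reference(cfg)
  expect_equal(nrow(ref$truth$isoforms), 20L)
  expect_true(all(table(ref$truth$isoforms$gene_id) == 2L))
})

test_that("planted decoys are A-runs >= 8 on the transcribed strand, away from true sites", {
  cfg <- sim_config(n_genes = 12, n_decoy_sites = 5, n_localized_genes = 0,
                    n_rip_targets = 0, seed = 3)
  ref <- generate_reference(cfg)
  dec <- ref$truth$decoys
  expect_equal(nrow(dec), 5L)
  for (i in seq_len(nrow(dec))) {
    s <- as.character(ref$genome[[dec$chrom[i]]])
    p <- dec$pos[i]
    run <- if (dec$strand[i] == "+") substr(s, p + 2, p + 9)
           else substr(s, p - 7, p)
    expect_identical(run, strrep(if (dec$strand[i] == "+") "A" else "T", 8))
    ends <- ref$truth$isoforms$end_pos[
      ref$annotation$ends$chrom == dec$chrom[i]]
    expect_true(all(abs(ends - p) >= 50))
  }
})

test_that("usage shares are valid and condition totals conserve reads", {
  cfg <- sim_config(n_genes = 30, n_localized_genes = 4, n_rip_targets = 5,
                    seed = 4)
  ref <- generate_reference(cfg)
  iso <- ref$truth$isoforms
  for (col in c("base_share", "input_share", "syn_share")) {
    sums <- tapply(iso[[col]], iso$gene_id, sum)
    expect_true(all(abs(sums - 1) < 1e-9))
    expect_true(all(iso[[col]] >= 0 & iso[[col]] <= 1))
  }
  design <- sample_design(replicates = 2)
  reads <- simulate_end_reads(ref$truth, design, cfg)
  for (s in design$sample_id) {
    r <- reads[reads$sample_id == s, ]
    expect_equal(nrow(r), sum(r$origin == "true") + sum(r$origin == "decoy"))
    # emitted decoy fraction matches the configured rate
    expect_equal(mean(r$origin == "decoy"), cfg$internal_priming_rate,
                 tolerance = 0.01)
  }
})

test_that("internal_priming_rate = 0 emits no reads at decoy positions", {
  cfg <- sim_config(n_genes = 10, internal_priming_rate = 0,
                    n_localized_genes = 0, n_rip_targets = 0, seed = 5)
  ref <- generate_reference(cfg)
  reads <- simulate_end_reads(ref$truth, sample_design(replicates = 2), cfg)
  expect_true(all(reads$origin == "true"))
  decoy_key <- paste(ref$truth$decoys$chrom, ref$truth$decoys$pos,
                     ref$truth$decoys$strand)
  expect_false(any(paste(reads$chrom, reads$pos, reads$strand) %in%
                     decoy_key))
})

test_that("simulated counts follow the NB mean-variance relation", {
  # 500 replicate samples of a fixed-usage world; variance must match
  # mu + alpha * mu^2 within 10%
  cfg <- sim_config(n_genes = 4, isoforms_per_gene = c(1, 0, 0, 0),
                    n_localized_genes = 0, n_rip_targets = 0,
                    internal_priming_rate = 0, end_scatter_sd = 0,
                    seed = 6)
  ref <- generate_reference(cfg)
  design <- sample_design(conditions = "input", replicates = 500)
  reads <- simulate_end_reads(ref$truth, design, cfg)
  g1 <- ref$truth$genes[1, ]
  r1 <- reads[reads$chrom == g1$chrom & reads$strand == g1$strand &
                reads$pos == ref$truth$isoforms$end_pos[1], ]
  counts <- as.vector(table(factor(r1$sample_id,
                                   levels = design$sample_id)))
  mu <- cfg$mean_depth
  expect_equal(mean(counts), mu, tolerance = 0.1)
  expect_equal(var(counts), mu + cfg$nb_dispersion * mu^2, tolerance = 0.1)
})

test_that("RIP enrichment gives 8x proximal and 16x distal count ratios", {
  cfg <- sim_config(n_genes = 20, isoforms_per_gene = c(0, 1, 0, 0),
                    n_rip_targets = 10, n_localized_genes = 0,
                    mean_depth = 1e4, nb_dispersion = 0,
                    end_scatter_sd = 0, internal_priming_rate = 0,
                    seed = 7)
  ref <- generate_reference(cfg)
  design <- sample_design(conditions = c("input", "rip"), replicates = 1)
  reads <- simulate_end_reads(ref$truth, design, cfg)
  iso <- ref$truth$isoforms
  tgt <- ref$truth$genes$gene_id[ref$truth$genes$is_rip_target]
  count_at <- function(sample, positions) {
    sum(reads$sample_id == sample & reads$pos %in% positions)
  }
  prox <- iso$end_pos[iso$gene_id %in% tgt & iso$isoform == 1]
  dist <- iso$end_pos[iso$gene_id %in% tgt & iso$isoform == 2]
  for (case in list(list(pos = prox, ratio = 8), list(pos = dist, ratio = 16))) {
    n_in <- count_at("input_1", case$pos)
    n_rip <- count_at("rip_1", case$pos)
    # Poisson counts: ratio estimate with 3 SD tolerance of the expectation
    se <- case$ratio * sqrt(1 / n_in + 1 / n_rip)
    expect_lt(abs(n_rip / n_in - case$ratio), 3 * se)
  }
})

test_that("generator errors are informative", {
  expect_error(generate_reference(
    sim_config(n_genes = 50, genome_length = 1000, n_localized_genes = 0,
               n_rip_targets = 0, seed = 1)),
    "too small")
  cfg <- sim_config(n_genes = 5, n_localized_genes = 0, n_rip_targets = 0,
                    seed = 1)
  ref <- generate_reference(cfg)
  expect_error(simulate_end_reads(ref$truth, NULL, cfg), "empty design")
  expect_error(sim_config(n_genes = 4, n_localized_genes = 3,
                          n_rip_targets = 0, seed = 1) |>
                 generate_reference(), "exceed")
})

test_that("localized carriers receive the full stated distal-share shift", {
  cfg <- sim_config(n_genes = 300, n_localized_genes = c(20, 20),
                    n_rip_targets = 0, seed = 8)
  ref <- generate_reference(cfg)
  iso <- data.table::as.data.table(ref$truth$isoforms)
  distal <- iso[, .SD[.N], by = gene_id]
  g <- ref$truth$genes
  shift <- distal$syn_share - distal$input_share
  cls <- g$loc_class[match(distal$gene_id, g$gene_id)]
  expect_true(all(abs(shift[cls == "shorter_in_synaptosome"] + 0.4) < 1e-9))
  expect_true(all(abs(shift[cls == "longer_in_synaptosome"] - 0.4) < 1e-9))
  expect_true(all(abs(shift[cls == "null"]) < 1e-9))
})
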