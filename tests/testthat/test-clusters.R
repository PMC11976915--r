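reads_from_depths <- function(depths, sample_id = "s1", chrom = "c1",
                              strand = "+") {
  data.frame(chrom = chrom,
             pos = rep(as.integer(names(depths)), depths),
             strand = strand, sample_id = sample_id,
             stringsAsFactors = FALSE)
}

test_that("worked example: seeds merge, summit at pooled maximum", {
  r <- reads_from_depths(c(`100` = 7L, `103` = 2L, `130` = 6L, `160` = 3L))
  cs <- call_clusters(r, params = cluster_params())
  expect_equal(nrow(cs$clusters), 1L)
  expect_equal(cs$clusters$start, 85L)   # [85,116) and [115,146) merge
  expect_equal(cs$clusters$end, 146L)
  expect_equal(cs$clusters$summit, 100L)
  # 160 stays unclustered (depth 3 < 6)
})

test_that("boundary and per-sample seeding rules", {
  r <- reads_from_depths(c(`50` = 6L))
  cs <- call_clusters(r, params = cluster_params())
  expect_equal(cs$clusters$end - cs$clusters$start, 31L)
  # depth 7 split 4+3 across samples is no seed
  r2 <- rbind(reads_from_depths(c(`50` = 4L), "s1"),
              reads_from_depths(c(`50` = 3L), "s2"))
  expect_equal(nrow(call_clusters(r2)$clusters), 0L)
  # abutting intervals merge: seeds 31 apart abut ([85,116) + [116,147)),
  # seeds 32 apart leave a gap
  r3 <- rbind(reads_from_depths(c(`100` = 6L)),
              reads_from_depths(c(`132` = 6L)))
  expect_equal(nrow(call_clusters(r3)$clusters), 2L)
  r4 <- rbind(reads_from_depths(c(`100` = 6L)),
              reads_from_depths(c(`131` = 6L)))
  expect_equal(nrow(call_clusters(r4)$clusters), 1L)
})

test_that("summit ties break leftmost and strands stay separate", {
  r <- rbind(reads_from_depths(c(`100` = 6L, `110` = 6L)),
             reads_from_depths(c(`100` = 8L), strand = "-"))
  cs <- call_clusters(r)
  plus <- cs$clusters[cs$clusters$strand == "+", ]
  expect_equal(plus$summit, 100L)
  expect_equal(nrow(cs$clusters), 2L)
})

test_that("call_clusters and count_clusters match the brute-force oracle", {
  for (seed in 1:30) {
    inst <- random_instance(seed)
    got <- call_clusters(inst)
    want <- bf_clusters(inst)
    expect_equal(nrow(got$clusters), nrow(want), info = paste("seed", seed))
    if (nrow(want)) {
      expect_equal(got$clusters[, c("chrom", "strand", "start", "end",
                                    "summit")],
                   want[, c("chrom", "strand", "start", "end", "summit")],
                   ignore_attr = TRUE, info = paste("seed", seed))
      samples <- sort(unique(inst$sample_id))
      counted <- count_clusters(inst, got, samples = samples)
      expect_equal(unname(counted$counts),
                   unname(bf_counts(inst, got$clusters, samples)),
                   info = paste("seed", seed))
    }
  }
})

test_that("seed depth and extension behave monotonically", {
  for (seed in 1:8) {
    inst <- random_instance(seed)
    n_lo <- nrow(call_clusters(inst, params = cluster_params(seed_depth = 4))$clusters)
    n_hi <- nrow(call_clusters(inst, params = cluster_params(seed_depth = 8))$clusters)
    expect_gte(n_lo, n_hi)
    n_narrow <- nrow(call_clusters(inst, params = cluster_params(extension = 5))$clusters)
    n_wide <- nrow(call_clusters(inst, params = cluster_params(extension = 30))$clusters)
    expect_gte(n_narrow, n_wide)
  }
})

test_that("counting respects the half-open convention and preconditions", {
  r <- reads_from_depths(c(`100` = 10L))
  cs <- call_clusters(r)
  extra <- data.frame(chrom = "c1", pos = c(cs$clusters$end, cs$clusters$end - 1L),
                      strand = "+", sample_id = "s1")
  counted <- count_clusters(rbind(r, extra), cs)
  expect_equal(unname(counted$counts[1, "s1"]), 11L)  # pos = end excluded
  bad <- cs
  bad$clusters <- rbind(bad$clusters, bad$clusters)
  expect_error(count_clusters(r, bad), "overlapping")
})

test_that("validation keeps only clusters near validated ends, idempotently", {
  r <- reads_from_depths(c(`100` = 7L, `130` = 6L))
  cs <- count_clusters(r, call_clusters(r))
  expect_equal(cs$clusters$start, 85L)
  # validated end at 200: window [175,226) disjoint from [85,146)
  expect_equal(nrow(validate_clusters(cs,
    data.frame(chrom = "c1", pos = 200L, strand = "+"))$clusters), 0L)
  # validated end at 150: window [125,176) overlaps
  v <- validate_clusters(cs,
    data.frame(chrom = "c1", pos = 150L, strand = "+"))
  expect_equal(nrow(v$clusters), 1L)
  expect_true(v$clusters$validated)
  # exact touch: cluster end 146 == window start for v = 171 -> removed
  expect_equal(nrow(validate_clusters(cs,
    data.frame(chrom = "c1", pos = 171L, strand = "+"))$clusters), 0L)
  expect_equal(nrow(validate_clusters(cs,
    data.frame(chrom = "c1", pos = 170L, strand = "+"))$clusters), 1L)
  # wrong strand does not validate
  expect_equal(nrow(validate_clusters(cs,
    data.frame(chrom = "c1", pos = 150L, strand = "-"))$clusters), 0L)
  # idempotence
  v2 <- validate_clusters(v, data.frame(chrom = "c1", pos = 150L,
                                        strand = "+"))
  expect_identical(v$clusters, v2$clusters)
  expect_identical(v$counts, v2$counts)
  expect_warning(validate_clusters(cs, data.frame(chrom = character(0),
    pos = integer(0), strand = character(0))), "empty validated")
})

test_that("gene assignment picks the nearest 3' boundary", {
  genes <- data.frame(
    gene_id = c("near", "far"), chrom = "c1",
    start = c(100L, 300L), end = c(1060L, 1500L), strand = "+",
    utr_start = c(150L, 350L))
  ends <- data.frame(gene_id = c("near", "far"), chrom = "c1",
                     pos = c(1059L, 1499L), strand = "+")
  ann <- gene_annotation(genes, ends)
  r <- reads_from_depths(c(`1099` = 7L))   # summit 1099: 40 nt past 'near'
  cs <- count_clusters(r, call_clusters(r))
  got <- assign_clusters_to_genes(cs, ann, blacklist_params("xrip"))
  expect_equal(got$clusters$gene_id, "near")  # dist 40 vs 400
  # summit upstream of all genes -> dropped
  r2 <- reads_from_depths(c(`20` = 7L))
  cs2 <- count_clusters(r2, call_clusters(r2))
  expect_equal(nrow(suppressMessages(
    assign_clusters_to_genes(cs2, ann, blacklist_params("xrip")))$clusters),
    0L)
})
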