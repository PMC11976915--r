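# annotation with one plus-strand gene (utr_start 1000) and one
# minus-strand gene (utr_start 5900)
utr_fixture_annotation <- function() {
  gene_annotation(
    genes = data.frame(
      gene_id = c("gp", "gm"), chrom = "c1", start = c(800L, 5000L),
      end = c(2000L, 6100L), strand = c("+", "-"),
      utr_start = c(1000L, 5900L)),
    ends = data.frame(gene_id = c("gp", "gp", "gm"), chrom = "c1",
                      pos = c(1100L, 1300L, 5600L),
                      strand = c("+", "+", "-")))
}

test_that("isoform table computes lengths, fractions and shares", {
  ann <- utr_fixture_annotation()
  counts <- rbind(c(60, 60, 20, 20),    # gp iso 1, len 100
                  c(60, 60, 60, 60),    # gp iso 2, len 200
                  c(30, 30, 90, 90),    # gp iso 3, len 300
                  c(50, 50, 50, 50))    # gm, single isoform -> excluded
  cs <- make_cluster_set("c1", c("+", "+", "+", "-"),
                         c(1100L, 1200L, 1300L, 5600L), counts,
                         gene_id = c("gp", "gp", "gp", "gm"))
  colnames(cs$counts) <- c("in1", "in2", "sy1", "sy2")
  cond <- c(in1 = "input", in2 = "input", sy1 = "synaptosome",
            sy2 = "synaptosome")
  iso <- build_isoform_table(cs, ann, cond)
  expect_setequal(unique(iso$gene_id), "gp")      # gm is not APA
  expect_equal(iso$utr_len, c(100L, 200L, 300L))
  expect_equal(iso$rank_fraction, c(1, 2, 3) / 3)
  expect_equal(iso$pct_of_longest, c(100, 200, 300) / 300)
  expect_equal(iso$share_a, c(0.4, 0.4, 0.2))     # all size factors 1 here
  expect_equal(iso$share_b, c(20, 60, 90) / 170)
  expect_true(all(abs(tapply(iso$share_a, iso$gene_id, sum) - 1) < 1e-9))
})

test_that("two-isoform genes give 0.5/1.0 length fractions; low expression filtered", {
  ann <- utr_fixture_annotation()
  counts <- rbind(c(50, 50, 50, 50),
                  c(50, 50, 50, 50),
                  c(2, 2, 2, 2))         # below min_expr everywhere
  cs <- make_cluster_set("c1", "+", c(1100L, 1200L, 1300L), counts,
                         gene_id = "gp")
  colnames(cs$counts) <- c("in1", "in2", "sy1", "sy2")
  cond <- c(in1 = "input", in2 = "input", sy1 = "synaptosome",
            sy2 = "synaptosome")
  iso <- build_isoform_table(cs, ann, cond, min_expr = 5)
  expect_equal(nrow(iso), 2L)
  expect_equal(iso$pct_of_longest, c(0.5, 1.0))
  expect_equal(iso$rank_fraction, c(0.5, 1.0))
})

test_that("isoforms upstream of the UTR start are dropped with a warning", {
  ann <- utr_fixture_annotation()
  counts <- rbind(c(50, 50, 50, 50), c(50, 50, 50, 50), c(50, 50, 50, 50))
  cs <- make_cluster_set("c1", "+", c(900L, 1100L, 1300L), counts,
                         gene_id = "gp")
  colnames(cs$counts) <- c("in1", "in2", "sy1", "sy2")
  cond <- c(in1 = "input", in2 = "input", sy1 = "synaptosome",
            sy2 = "synaptosome")
  expect_warning(iso <- build_isoform_table(cs, ann, cond), "upstream")
  expect_equal(iso$utr_len, c(100L, 300L))
})

test_that("weighted length reproduces the worked examples", {
  rec2 <- data.frame(pct_of_longest = c(0.5, 1), rank_fraction = c(0.5, 1))
  w <- weighted_length(rec2, c(0.5, 0.5))
  expect_identical(unname(w["rank"]), 0.75)
  expect_identical(unname(w["real"]), 0.75)
  # all expression on the distal isoform
  expect_equal(unname(weighted_length(rec2, c(0, 1))["rank"]), 1.0)
  # three isoforms, equal shares, ranked metric
  rec3 <- data.frame(pct_of_longest = c(0.2, 0.7, 1),
                     rank_fraction = c(1, 2, 3) / 3)
  expect_equal(unname(weighted_length(rec3, rep(1 / 3, 3))["rank"]), 2 / 3)
  expect_error(weighted_length(rec2, c(0.5, 0.4)), "sum to 1")
})

test_that("weighted length is bounded and label-permutation invariant", {
  set.seed(31)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    lens <- sort(sample.int(500, k))
    rec <- data.frame(pct_of_longest = lens / max(lens),
                      rank_fraction = seq_len(k) / k)
    sh <- rgamma(k, 1); sh <- sh / sum(sh)
    w <- weighted_length(rec, sh)
    expect_gte(w["real"], min(rec$pct_of_longest) - 1e-12)
    expect_lte(w["real"], 1)
    perm <- sample(k)
    expect_equal(weighted_length(rec[perm, ], sh[perm]), w)
  }
})

test_that("gene_length_stats produces the four difference statistics", {
  iso <- data.frame(gene_id = "g", cluster_id = c("a", "b"),
                    end_pos = c(1L, 2L), utr_len = c(100L, 200L),
                    mean_a = c(50, 50), mean_b = c(20, 80),
                    rank_fraction = c(0.5, 1), pct_of_longest = c(0.5, 1),
                    share_a = c(0.5, 0.5), share_b = c(0.2, 0.8))
  st <- gene_length_stats(iso)
  expect_equal(st$weighted_rank_a, 0.75)
  expect_equal(st$weighted_rank_b, 0.5 * 0.2 + 1 * 0.8)
  expect_equal(st$diff_sub_rank, 0.15)
  expect_equal(st$diff_log2_rank, log2(0.9 / 0.75))
  expect_equal(st$diff_sub_real, st$diff_sub_rank)  # same fractions here
})

test_that("localization calls follow the one-tailed z rule", {
  set.seed(32)
  n <- 200
  base <- rnorm(n, 0, 0.01)
  st <- data.frame(gene_id = paste0("g", 1:n),
                   weighted_real_a = 0.5, weighted_real_b = 0.5,
                   weighted_rank_a = 0.5, weighted_rank_b = 0.5,
                   diff_sub_real = base, diff_log2_real = rnorm(n, 0, 0.01),
                   diff_sub_rank = rnorm(n, 0, 0.01),
                   diff_log2_rank = rnorm(n, 0, 0.01))
  # keep the probe genes at the mean of the other three distributions so
  # only diff_sub_real can trigger
  for (col in c("diff_log2_real", "diff_sub_rank", "diff_log2_rank"))
    st[[col]][1:3] <- mean(st[[col]])
  st$diff_sub_real[1] <- mean(base)                      # at the mean -> ns
  st$diff_sub_real[2] <- mean(base) + 2 * sd(base)       # upper tail
  st$diff_sub_real[3] <- mean(base) - 3 * sd(base)       # lower tail
  got <- call_localized_genes(st)
  expect_equal(got$class[1], "ns")
  expect_equal(got$class[2], "longer_in_syn")
  expect_equal(got$class[3], "shorter_in_syn")
  expect_false(any(got$conflict[1:3]))
  # z-scores agree with direct standardization
  x <- st$diff_sub_real
  expect_equal(got$z_diff_sub_real, (x - mean(x)) / sd(x))
})

test_that("conflicting directions yield ns with a flag; degenerate sd skipped", {
  n <- 100
  set.seed(33)
  st <- data.frame(gene_id = paste0("g", 1:n),
                   weighted_real_a = 0.5, weighted_real_b = 0.5,
                   weighted_rank_a = 0.5, weighted_rank_b = 0.5,
                   diff_sub_real = rnorm(n, 0, 0.01),
                   diff_log2_real = rnorm(n, 0, 0.01),
                   diff_sub_rank = rnorm(n, 0, 0.01),
                   diff_log2_rank = 0)
  st$diff_sub_real[5] <- 0.2    # strongly positive here
  st$diff_log2_real[5] <- -0.2  # strongly negative there
  expect_warning(got <- call_localized_genes(st), "zero variance")
  expect_equal(got$class[5], "ns")
  expect_true(got$conflict[5])
  expect_true(all(is.na(got$z_diff_log2_rank)))
  w <- capture_warnings(call_localized_genes(st[1:10, ]))
  expect_true(any(grepl("fewer than 30", w)))
})
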