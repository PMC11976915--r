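#' Build the per-isoform 3' UTR table for APA genes
#'
#' Treats each validated, gene-assigned cluster as one 3'-end isoform
#' (its summit is the isoform 3' end).  3' UTR lengths are the strand-aware
#' distance from the gene's most proximal 3' UTR start to the isoform end.
#' Isoforms with mean size-factor-normalized count `>= min_expr` in at
#' least one of the two conditions are retained; genes with at least two
#' retained isoforms (APA genes) are kept.  For each isoform the fraction
#' of the longest 3' UTR (`pct_of_longest`), the ranked length fraction
#' `i/k` (`rank_fraction`, proximal to distal), and the per-condition
#' expression shares are computed.
#'
#' @param cluster_set a counted, validated, gene-assigned `cluster_set`.
#' @param annotation a [gene_annotation()].
#' @param conditions named character vector mapping sample ids to
#'   conditions.
#' @param cond_a,cond_b the two conditions compared (reference first).
#' @param min_expr expression threshold on the mean normalized count
#'   (default 5).
#' @param require_both if `TRUE` (default), a gene must have nonzero total
#'   expression in both conditions to enter the table.
#' @return data.frame with one row per retained isoform: `gene_id`,
#'   `cluster_id`, `end_pos`, `utr_len`, `pct_of_longest`, `rank_fraction`,
#'   `mean_a`, `mean_b`, `share_a`, `share_b`.
#' @export
build_isoform_table <- function(cluster_set, annotation, conditions,
                                cond_a = "input", cond_b = "synaptosome",
                                min_expr = 5, require_both = TRUE) {
  cl <- cluster_set$clusters
  stopifnot(!is.null(cluster_set$counts))
  use <- !is.na(cl$gene_id) & cl$validated
  cl <- cl[use, , drop = FALSE]
  cnt <- cluster_set$counts[use, , drop = FALSE]
  cond <- conditions[colnames(cnt)]
  sa <- which(cond == cond_a); sb <- which(cond == cond_b)
  if (!length(sa) || !length(sb))
    stop("conditions '", cond_a, "' and '", cond_b,
         "' must both be present in the sample map")
  sf <- size_factors(cnt[, c(sa, sb), drop = FALSE])
  nrm <- sweep(cnt[, c(sa, sb), drop = FALSE], 2, sf, "/")
  mean_a <- rowMeans(nrm[, seq_along(sa), drop = FALSE])
  mean_b <- rowMeans(nrm[, length(sa) + seq_along(sb), drop = FALSE])

  g <- annotation$genes
  gm <- match(cl$gene_id, g$gene_id)
  utr_len <- ifelse(g$strand[gm] == "+", cl$summit - g$utr_start[gm],
                    g$utr_start[gm] - cl$summit)
  neg <- utr_len <= 0
  if (any(neg)) {
    warning(sum(neg), " isoform(s) with 3' end at or upstream of the UTR ",
            "start dropped")
  }
  tab <- data.table::data.table(
    gene_id = cl$gene_id, cluster_id = rownames(cnt),
    end_pos = cl$summit, utr_len = utr_len,
    mean_a = mean_a, mean_b = mean_b)[utr_len > 0]
  tab <- tab[mean_a >= min_expr | mean_b >= min_expr]
  tab <- tab[, if (.N >= 2L) .SD, by = gene_id]
  if (nrow(tab) == 0L) return(as.data.frame(tab))
  if (require_both) {
    tot <- tab[, .(ta = sum(mean_a), tb = sum(mean_b)), by = gene_id]
    drop_g <- tot$gene_id[tot$ta == 0 | tot$tb == 0]
    if (length(drop_g))
      message(length(drop_g),
              " gene(s) not expressed in both conditions excluded")
    tab <- tab[!gene_id %in% drop_g]
  }
  data.table::setorder(tab, gene_id, utr_len)
  tab[, `:=`(rank_fraction = seq_len(.N) / .N,
             pct_of_longest = utr_len / max(utr_len),
             share_a = if (sum(mean_a) > 0) mean_a / sum(mean_a) else NA_real_,
             share_b = if (sum(mean_b) > 0) mean_b / sum(mean_b) else NA_real_),
      by = gene_id]
  as.data.frame(tab)
}

#' Expression-weighted 3' UTR length for one gene
#'
#' `sum(length_fraction_i * share_i)` over the gene's isoforms, with the
#' length fraction taken as the fraction of the longest 3' UTR (real
#' metric) or the ranked fraction `i/k` (ranked metric).
#'
#' @param records the rows of a [build_isoform_table()] for one gene.
#' @param shares numeric vector of expression shares summing to 1 (for
#'   example `records$share_a`).
#' @return named numeric vector `c(real = ..., rank = ...)`.
#' @export
#' @examples
#' rec <- data.frame(pct_of_longest = c(0.5, 1), rank_fraction = c(0.5, 1))
#' weighted_length(rec, c(0.5, 0.5))  # rank = 0.75
weighted_length <- function(records, shares) {
  if (anyNA(shares) || abs(sum(shares) - 1) > 1e-6)
    stop("expression shares must be defined and sum to 1 ",
         "(gene unexpressed in this condition?)")
  c(real = sum(records$pct_of_longest * shares),
    rank = sum(records$rank_fraction * shares))
}

#' Per-gene weighted 3' UTR length statistics
#'
#' Computes the expression-weighted 3' UTR length (real and ranked
#' metrics) per condition and the four difference statistics: subtracted
#' and log2-fold differences (condition b minus / over condition a) for
#' both metrics.
#'
#' @param iso_table a [build_isoform_table()] result.
#' @return data.frame with one row per gene: `weighted_real_a/b`,
#'   `weighted_rank_a/b`, `diff_sub_real`, `diff_log2_real`,
#'   `diff_sub_rank`, `diff_log2_rank`.
#' @export
gene_length_stats <- function(iso_table) {
  dt <- data.table::as.data.table(iso_table)
  out <- dt[, {
    wa <- weighted_length(.SD, share_a)
    wb <- weighted_length(.SD, share_b)
    .(weighted_real_a = wa[["real"]], weighted_real_b = wb[["real"]],
      weighted_rank_a = wa[["rank"]], weighted_rank_b = wb[["rank"]])
  }, by = gene_id]
  out[, `:=`(diff_sub_real = weighted_real_b - weighted_real_a,
             diff_log2_real = log2(weighted_real_b / weighted_real_a),
             diff_sub_rank = weighted_rank_b - weighted_rank_a,
             diff_log2_rank = log2(weighted_rank_b / weighted_rank_a))]
  as.data.frame(out)
}

#' Call genes with significant 3' UTR length change
#'
#' Each of the four difference distributions (subtracted / log2, real /
#' ranked metric) is z-standardized across genes.  A gene is significant
#' if it exceeds the one-tailed 5% point in either tail
#' (`|z| >= qnorm(1 - alpha)`) in ANY of the four distributions; the class
#' follows the sign of the triggering difference (positive = longer in the
#' second condition).  Genes triggering in both directions across
#' distributions are classified `ns` with a conflict flag.
#'
#' @param stats a [gene_length_stats()] result.
#' @param alpha per-tail significance level (default 0.05).
#' @return data.frame with per-distribution z-scores, the `class` column
#'   (`"longer_in_syn"`, `"shorter_in_syn"`, `"ns"`) and a `conflict`
#'   flag.
#' @export
call_localized_genes <- function(stats, alpha = 0.05) {
  dists <- c("diff_sub_real", "diff_log2_real", "diff_sub_rank",
             "diff_log2_rank")
  n <- nrow(stats)
  if (n < 30)
    warning("fewer than 30 APA genes: normal approximation of the ",
            "difference distributions is unreliable")
  zc <- qnorm(1 - alpha)
  z <- matrix(NA_real_, nrow = n, ncol = length(dists),
              dimnames = list(NULL, paste0("z_", dists)))
  for (j in seq_along(dists)) {
    x <- stats[[dists[j]]]
    s <- sd(x)
    if (is.na(s) || s == 0) {
      warning("distribution ", dists[j], " has zero variance: skipped")
      next
    }
    z[, j] <- (x - mean(x)) / s
  }
  pos <- rowSums(z >= zc, na.rm = TRUE) > 0
  neg <- rowSums(z <= -zc, na.rm = TRUE) > 0
  class <- rep("ns", n)
  class[pos & !neg] <- "longer_in_syn"
  class[neg & !pos] <- "shorter_in_syn"
  conflict <- pos & neg
  data.frame(gene_id = stats$gene_id, z, class = class,
             conflict = conflict, stringsAsFactors = FALSE)
}
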