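#' Gene-specific proximal poly(A) sites from an isoform table
#'
#' The proximal site of each APA gene is the most proximal expressed
#' isoform 3' end (the retained isoform with the shortest 3' UTR).
#'
#' @param iso_table a [build_isoform_table()] result.
#' @return named integer vector, gene id -> genomic summit position.
#' @export
proximal_sites_from_isoforms <- function(iso_table) {
  dt <- data.table::as.data.table(iso_table)
  ps <- dt[, .(pos = end_pos[which.min(utr_len)]), by = gene_id]
  setNames(ps$pos, ps$gene_id)
}

#' Split a gene's clusters into proximal and distal counts
#'
#' A cluster is proximal iff its summit is at or before the gene-specific
#' proximal poly(A) site in transcription coordinates (on the minus strand:
#' summit at or above the site genomically), else distal.  Counts are
#' merged per side per sample.
#'
#' @param cluster_set a counted, gene-assigned `cluster_set`.
#' @param proximal_sites named vector gene id -> proximal site position
#'   (e.g. from [proximal_sites_from_isoforms()]).
#' @param annotation a [gene_annotation()] (for strands).
#' @return An object of class `isoform_split`: matrices `proximal` and
#'   `distal` (genes x samples) and the `proximal_site` vector.
#' @export
split_proximal_distal <- function(cluster_set, proximal_sites, annotation) {
  cl <- cluster_set$clusters
  stopifnot(!is.null(cluster_set$counts))
  genes <- intersect(unique(cl$gene_id), names(proximal_sites))
  use <- cl$gene_id %in% genes
  cl <- cl[use, , drop = FALSE]
  cnt <- cluster_set$counts[use, , drop = FALSE]
  strand <- annotation$genes$strand[match(cl$gene_id,
                                          annotation$genes$gene_id)]
  ps <- proximal_sites[cl$gene_id]
  is_prox <- ifelse(strand == "+", cl$summit <= ps, cl$summit >= ps)
  glev <- sort(genes)
  agg <- function(rows) {
    m <- matrix(0, nrow = length(glev), ncol = ncol(cnt),
                dimnames = list(glev, colnames(cnt)))
    if (any(rows)) {
      r <- rowsum(cnt[rows, , drop = FALSE], cl$gene_id[rows])
      m[rownames(r), ] <- r
    }
    m
  }
  structure(list(proximal = agg(is_prox), distal = agg(!is_prox),
                 proximal_site = proximal_sites[glev]),
            class = "isoform_split")
}

#' Long 3' UTR isoform proportion per gene
#'
#' `long_prop = distal / (proximal + distal)` on condition-averaged,
#' size-factor-normalized counts.  Genes with zero total in the condition
#' are excluded with a message.
#'
#' @param split an [split_proximal_distal()] result.
#' @param conditions named character vector sample id -> condition.
#' @param condition the condition to average over.
#' @return data.frame `gene_id`, `condition`, `long_prop`.
#' @export
long_isoform_proportion <- function(split, conditions, condition) {
  total <- split$proximal + split$distal
  sf <- size_factors(total[rowSums(total == 0) == 0, , drop = FALSE])
  sel <- which(conditions[colnames(total)] == condition)
  if (!length(sel)) stop("no samples with condition '", condition, "'")
  pn <- sweep(split$proximal, 2, sf, "/")[, sel, drop = FALSE]
  dn <- sweep(split$distal, 2, sf, "/")[, sel, drop = FALSE]
  pm <- rowMeans(pn); dm <- rowMeans(dn)
  tot <- pm + dm
  if (any(tot == 0))
    message(sum(tot == 0), " gene(s) with zero total signal in '",
            condition, "' excluded")
  keep <- tot > 0
  data.frame(gene_id = rownames(total)[keep], condition = condition,
             long_prop = dm[keep] / tot[keep], stringsAsFactors = FALSE)
}

#' Binding-preference test on long-isoform proportions
#'
#' Paired two-sided Student's t-test on per-gene long-isoform proportion
#' differences (`b - a`, e.g. RIP minus input), across the supplied genes.
#' If all differences are exactly zero, `t = 0` and `p = 1`; a nonzero
#' constant difference is flagged degenerate.  An unpaired two-sample
#' variant (equal variances) is available.
#'
#' @param props_a,props_b [long_isoform_proportion()] results (or data
#'   frames with `gene_id` and `long_prop`).
#' @param genes optional gene subset; default: genes present in both.
#' @param paired paired test (default) or unpaired.
#' @return list with `t`, `df`, `p`, `mean_a`, `mean_b`, `mean_diff`, `n`,
#'   `degenerate`.
#' @export
binding_preference_test <- function(props_a, props_b, genes = NULL,
                                    paired = TRUE) {
  common <- intersect(props_a$gene_id, props_b$gene_id)
  if (!is.null(genes)) common <- intersect(common, genes)
  a <- props_a$long_prop[match(common, props_a$gene_id)]
  b <- props_b$long_prop[match(common, props_b$gene_id)]
  n <- length(common)
  if (n < 3) stop("need >= 3 genes with proportions in both samples")
  if (paired) {
    d <- b - a
    if (all(d == 0))
      return(list(t = 0, df = n - 1L, p = 1, mean_a = mean(a),
                  mean_b = mean(b), mean_diff = 0, n = n,
                  degenerate = FALSE))
    s <- sd(d)
    if (s == 0)
      return(list(t = sign(mean(d)) * Inf, df = n - 1L, p = 0,
                  mean_a = mean(a), mean_b = mean(b), mean_diff = mean(d),
                  n = n, degenerate = TRUE))
    tstat <- mean(d) / (s / sqrt(n))
    list(t = tstat, df = n - 1L, p = 2 * pt(-abs(tstat), n - 1),
         mean_a = mean(a), mean_b = mean(b), mean_diff = mean(d), n = n,
         degenerate = FALSE)
  } else {
    sp <- sqrt(((n - 1) * var(a) + (n - 1) * var(b)) / (2 * n - 2))
    if (sp == 0)
      return(list(t = 0, df = 2L * n - 2L, p = if (mean(b) == mean(a)) 1 else 0,
                  mean_a = mean(a), mean_b = mean(b),
                  mean_diff = mean(b) - mean(a), n = n,
                  degenerate = mean(b) != mean(a)))
    tstat <- (mean(b) - mean(a)) / (sp * sqrt(2 / n))
    list(t = tstat, df = 2L * n - 2L, p = 2 * pt(-abs(tstat), 2 * n - 2),
         mean_a = mean(a), mean_b = mean(b), mean_diff = mean(b) - mean(a),
         n = n, degenerate = FALSE)
  }
}

#' Whitelisted signal in proximal and distal (nUTR) 3' UTR regions
#'
#' For each gene with annotated proximal and distal 3' ends, reads within
#' the 100 bases upstream of (through) each end are counted
#' unconditionally for that region; other reads falling in the proximal
#' region (UTR start to proximal end) or the distal region (proximal end
#' to distal end) are counted only if they lie within
#' `validation_radius` of a validated 3' end.  Region totals per sample
#' feed a proximal-vs-distal differential test.
#'
#' @param nutr_genes data.frame with columns `gene_id`, `chrom`, `strand`,
#'   `utr_start`, `proximal_end`, `distal_end` (0-based positions;
#'   `distal_end` strictly downstream of `proximal_end`).
#' @param reads data.frame of read 3' ends.
#' @param validated data.frame of validated 3' ends.
#' @param window whitelist window upstream of each end (default 100).
#' @param validation_radius radius around validated ends (default 25).
#' @return data.frame `gene_id`, `region`, `sample_id`, `count`.
#' @export
nutr_region_counts <- function(nutr_genes, reads, validated, window = 100L,
                               validation_radius = 25L) {
  need <- c("gene_id", "chrom", "strand", "utr_start", "proximal_end",
            "distal_end")
  if (!all(need %in% names(nutr_genes)))
    stop("nutr_genes must have columns: ", paste(need, collapse = ", "))
  miss <- is.na(nutr_genes$distal_end) | is.na(nutr_genes$proximal_end)
  if (any(miss)) {
    message(sum(miss), " gene(s) without both annotated ends skipped")
    nutr_genes <- nutr_genes[!miss, , drop = FALSE]
  }
  samples <- sort(unique(reads$sample_id))
  rd <- data.table::as.data.table(reads)
  vd <- data.table::as.data.table(validated)
  out <- vector("list", nrow(nutr_genes))
  for (i in seq_len(nrow(nutr_genes))) {
    g <- nutr_genes[i, ]
    fwd <- g$strand == "+"
    if ((fwd && g$distal_end <= g$proximal_end) ||
        (!fwd && g$distal_end >= g$proximal_end))
      stop("gene ", g$gene_id,
           ": distal_end must be strictly downstream of proximal_end")
    r <- rd[chrom == g$chrom & strand == g$strand]
    v <- vd[chrom == g$chrom & strand == g$strand]
    near_valid <- if (nrow(v) == 0) rep(FALSE, nrow(r)) else
      vapply(r$pos, function(p) any(abs(p - v$pos) <= validation_radius),
             logical(1))
    in_win <- function(p, end_pos) if (fwd)
      p >= end_pos - window & p <= end_pos
    else p >= end_pos & p <= end_pos + window
    between <- function(p, from, to) if (fwd) p >= from & p <= to
               else p <= from & p >= to
    prox_ok <- in_win(r$pos, g$proximal_end) |
      (between(r$pos, g$utr_start, g$proximal_end) & near_valid)
    dist_ok <- in_win(r$pos, g$distal_end) |
      (between(r$pos, g$proximal_end, g$distal_end) &
         !between(r$pos, g$utr_start, g$proximal_end) & near_valid)
    cnt_p <- table(factor(r$sample_id[prox_ok], levels = samples))
    cnt_d <- table(factor(r$sample_id[dist_ok], levels = samples))
    out[[i]] <- data.frame(
      gene_id = g$gene_id,
      region = rep(c("proximal", "distal"), each = length(samples)),
      sample_id = rep(samples, 2),
      count = as.integer(c(cnt_p, cnt_d)), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
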