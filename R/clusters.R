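new_cluster_set <- function(clusters, counts = NULL) {
  rownames(clusters) <- NULL
  if (!is.null(counts)) {
    stopifnot(nrow(counts) == nrow(clusters))
    if (is.null(rownames(counts)))
      rownames(counts) <- sprintf("cl%05d", seq_len(nrow(counts)))
  }
  structure(list(clusters = clusters, counts = counts),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d clusters (%d validated, %d gene-assigned)%s\n",
              nrow(x$clusters), sum(x$clusters$validated),
              sum(!is.na(x$clusters$gene_id)),
              if (is.null(x$counts)) ", no counts"
              else sprintf(", counts for %d samples", ncol(x$counts))))
  invisible(x)
}

# map 0-based positions to rows of a non-overlapping, per-(chrom,strand)
# sorted cluster table; NA where no cluster contains the position
map_pos_to_clusters <- function(chrom, strand, pos, clusters) {
  out <- rep(NA_integer_, length(pos))
  key <- paste(clusters$chrom, clusters$strand)
  qkey <- paste(chrom, strand)
  for (k in unique(qkey)) {
    ci <- which(key == k)
    if (!length(ci)) next
    ci <- ci[order(clusters$start[ci])]
    qi <- which(qkey == k)
    idx <- findInterval(pos[qi], clusters$start[ci])
    hit <- idx >= 1L & pos[qi] < clusters$end[ci][pmax(idx, 1L)]
    out[qi[hit]] <- ci[idx[hit]]
  }
  out
}

#' Call 3'-end clusters from read-end depth
#'
#' Seeds are positions where any single sample's read depth reaches
#' `seed_depth`; each seed spawns the interval
#' `[seed - extension, seed + extension + 1)`; overlapping or abutting
#' intervals on the same strand are merged; the summit is the position of
#' maximal pooled (all-sample) depth within the merged interval, leftmost
#' on ties.  Blacklisted positions contribute no depth.
#'
#' @param reads data.frame with `chrom`, `pos`, `strand`, `sample_id`
#'   (already restricted to gene windows).
#' @param mask optional [compute_blacklist()] mask; masked reads are
#'   discarded before seeding.
#' @param params a [cluster_params()].
#' @return A `cluster_set` (no counts yet), sorted by `(chrom, start)`.
#' @export
call_clusters <- function(reads, mask = NULL, params = cluster_params()) {
  stopifnot(inherits(params, "cluster_params"))
  dt <- data.table::as.data.table(reads)[, .(chrom, pos, strand, sample_id)]
  if (!is.null(mask))
    dt <- dt[!is_blacklisted(mask, chrom, pos, strand)]
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      summit = integer(0), gene_id = character(0),
                      validated = logical(0), stringsAsFactors = FALSE)
  if (nrow(dt) == 0L) return(new_cluster_set(empty))

  depth_ps <- dt[, .(n = .N), by = .(chrom, strand, pos)]
  seed_tab <- dt[, .(n = .N), by = .(chrom, strand, pos, sample_id)][
    , .(maxd = max(n)), by = .(chrom, strand, pos)][maxd >= params$seed_depth]
  if (nrow(seed_tab) == 0L) return(new_cluster_set(empty))

  ivl <- seed_tab[, .(chrom, strand,
                      start = pmax(pos - params$extension, 0L),
                      end = pos + params$extension + 1L)]
  data.table::setorder(ivl, chrom, strand, start, end)
  ivl[, newc := start > data.table::shift(cummax(end), fill = -1L),
      by = .(chrom, strand)]
  ivl[, cid := cumsum(newc), by = .(chrom, strand)]
  merged <- ivl[, .(start = min(start), end = max(end)),
                by = .(chrom, strand, cid)]

  # summit: leftmost position of maximal pooled depth inside the interval
  ci <- map_pos_to_clusters(depth_ps$chrom, depth_ps$strand, depth_ps$pos,
                            as.data.frame(merged))
  pool <- depth_ps[!is.na(ci)][, cl := ci[!is.na(ci)]]
  data.table::setorder(pool, cl, -n, pos)
  summit_tab <- pool[, .SD[1L], by = cl]
  merged[, summit := NA_integer_]
  merged$summit[summit_tab$cl] <- summit_tab$pos

  clusters <- data.frame(
    chrom = merged$chrom, start = merged$start, end = merged$end,
    strand = merged$strand, summit = merged$summit,
    gene_id = NA_character_, validated = FALSE, stringsAsFactors = FALSE)
  clusters <- clusters[order(clusters$chrom, clusters$start,
                             clusters$strand), ]
  new_cluster_set(clusters)
}

#' Count reads per cluster and sample
#'
#' Each read is assigned to at most one cluster (same strand, position in
#' `[start, end)`).  The counts matrix is complete, with zero columns for
#' samples without reads in any cluster.
#'
#' @param reads data.frame of (filtered) reads.
#' @param cluster_set a `cluster_set` with non-overlapping clusters per
#'   strand.
#' @param samples optional character vector fixing the sample columns.
#' @return the `cluster_set` with a filled counts matrix.
#' @export
count_clusters <- function(reads, cluster_set, samples = NULL) {
  cl <- cluster_set$clusters
  # precondition: clusters must not overlap within a strand
  key <- paste(cl$chrom, cl$strand)
  for (k in unique(key)) {
    ci <- which(key == k)
    o <- order(cl$start[ci])
    if (any(cl$start[ci][o][-1] < head(cl$end[ci][o], -1)))
      stop("overlapping clusters on ", k,
           ": count_clusters requires non-overlapping clusters per strand")
  }
  if (is.null(samples)) samples <- sort(unique(reads$sample_id))
  counts <- matrix(0L, nrow = nrow(cl), ncol = length(samples),
                   dimnames = list(sprintf("cl%05d", seq_len(nrow(cl))),
                                   samples))
  if (nrow(cl) && nrow(reads)) {
    ci <- map_pos_to_clusters(reads$chrom, reads$strand, reads$pos, cl)
    ok <- !is.na(ci) & reads$sample_id %in% samples
    if (any(ok)) {
      tab <- table(factor(ci[ok], levels = seq_len(nrow(cl))),
                   factor(reads$sample_id[ok], levels = samples))
      counts <- counts + unclass(tab)
      dimnames(counts) <- list(sprintf("cl%05d", seq_len(nrow(cl))), samples)
    }
  }
  new_cluster_set(cl, counts)
}

#' Validate clusters against a high-confidence 3'-end set
#'
#' A cluster is kept iff its interval intersects the half-open window
#' `[v - validation_radius, v + validation_radius + 1)` around some
#' same-strand validated end `v`.  Kept clusters get `validated = TRUE`;
#' all others are removed.  Re-running on the output is a no-op.
#'
#' @param cluster_set a `cluster_set`.
#' @param validated data.frame with `chrom`, `pos`, `strand`.
#' @param params a [cluster_params()].
#' @return the filtered `cluster_set`.
#' @export
validate_clusters <- function(cluster_set, validated,
                              params = cluster_params()) {
  cl <- cluster_set$clusters
  if (is.null(validated) || nrow(validated) == 0L) {
    warning("empty validated-end set: all clusters removed")
    keep <- logical(nrow(cl))
  } else {
    vr <- GenomicRanges::GRanges(validated$chrom,
      IRanges::IRanges(validated$pos - params$validation_radius + 1L,
                       validated$pos + params$validation_radius + 1L),
      strand = validated$strand)
    cr <- GenomicRanges::GRanges(cl$chrom,
      IRanges::IRanges(cl$start + 1L, cl$end), strand = cl$strand)
    keep <- IRanges::overlapsAny(cr, vr)
  }
  out <- cl[keep, , drop = FALSE]
  out$validated <- rep(TRUE, nrow(out))
  cnt <- if (is.null(cluster_set$counts)) NULL
         else cluster_set$counts[keep, , drop = FALSE]
  new_cluster_set(out, cnt)
}

#' Assign clusters to genes
#'
#' A cluster is assigned to the same-strand gene whose body-or-downstream
#' window contains its summit; if several genes qualify, the one with the
#' nearest 3' boundary wins.  Unassignable clusters are dropped with a
#' message.
#'
#' @param cluster_set a `cluster_set`.
#' @param annotation a [gene_annotation()].
#' @param params a [blacklist_params()] (for `downstream_limit`).
#' @return the `cluster_set` with `gene_id` filled in.
#' @export
assign_clusters_to_genes <- function(cluster_set, annotation, params) {
  cl <- cluster_set$clusters
  g <- annotation$genes
  w <- gene_windows(g, params$downstream_limit)
  three_prime <- ifelse(g$strand == "+", g$end - 1L, g$start)
  gr_w <- GenomicRanges::GRanges(w$chrom,
    IRanges::IRanges(w$win_start + 1L, w$win_end), strand = w$strand)
  gr_s <- GenomicRanges::GRanges(cl$chrom,
    IRanges::IRanges(cl$summit + 1L, width = 1L), strand = cl$strand)
  hits <- GenomicRanges::findOverlaps(gr_s, gr_w)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  dist <- abs(cl$summit[qh] - three_prime[sh])
  ord <- order(qh, dist, g$gene_id[sh])
  first <- !duplicated(qh[ord])
  assign <- rep(NA_character_, nrow(cl))
  assign[qh[ord][first]] <- g$gene_id[sh[ord][first]]
  if (any(is.na(assign)))
    message(sum(is.na(assign)), " unassignable cluster(s) dropped")
  keep <- !is.na(assign)
  out <- cl[keep, , drop = FALSE]
  out$gene_id <- assign[keep]
  cnt <- if (is.null(cluster_set$counts)) NULL
         else cluster_set$counts[keep, , drop = FALSE]
  new_cluster_set(out, cnt)
}

#' Full site-calling stage
#'
#' Runs blacklist computation, gene-window restriction, cluster calling,
#' re-counting across all samples, validation and gene assignment in the
#' order of the analysis workflow (filter, cluster, quantify, validate).
#'
#' @param reads data.frame of read 3' ends.
#' @param genome `DNAStringSet`.
#' @param annotation a [gene_annotation()].
#' @param validated data.frame of validated 3' ends.
#' @param bl_params a [blacklist_params()].
#' @param cl_params a [cluster_params()].
#' @return a list: `clusters` (the final `cluster_set`), `stats` (per-stage
#'   read/cluster counts).
#' @export
call_sites <- function(reads, genome, annotation, validated,
                       bl_params = blacklist_params("xrip"),
                       cl_params = cluster_params()) {
  check_chrom_consistency(genome, reads, annotation$genes, validated)
  mask <- compute_blacklist(genome, annotation, bl_params)
  n0 <- nrow(reads)
  kept <- restrict_to_gene_windows(reads, annotation, bl_params)
  n1 <- nrow(kept)
  masked <- is_blacklisted(mask, kept$chrom, kept$pos, kept$strand)
  kept <- kept[!masked, , drop = FALSE]
  n2 <- nrow(kept)
  cs <- call_clusters(kept, mask = NULL, params = cl_params)
  n_called <- nrow(cs$clusters)
  cs <- count_clusters(kept, cs, samples = sort(unique(reads$sample_id)))
  cs <- validate_clusters(cs, validated, cl_params)
  n_valid <- nrow(cs$clusters)
  cs <- assign_clusters_to_genes(cs, annotation, bl_params)
  stats <- list(reads_in = n0, reads_in_windows = n1,
                reads_after_blacklist = n2, clusters_called = n_called,
                clusters_validated = n_valid,
                clusters_assigned = nrow(cs$clusters))
  message(sprintf(
    "call_sites: %d reads -> %d in windows -> %d after blacklist; %d clusters -> %d validated -> %d assigned",
    n0, n1, n2, n_called, n_valid, nrow(cs$clusters)))
  list(clusters = cs, stats = stats)
}
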