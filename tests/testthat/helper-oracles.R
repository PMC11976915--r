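# Independent reference implementations used as oracles.  These are kept
# deliberately naive (per-position loops, direct enumeration) and share no
# code with the package internals they check.

# brute-force cluster calling: scan every position, seed where any single
# sample reaches seed_depth, expand, merge overlap-or-adjacent, summit =
# leftmost max pooled depth
bf_clusters <- function(reads, seed_depth = 6L, extension = 15L) {
  out <- list()
  for (key in unique(paste(reads$chrom, reads$strand))) {
    parts <- strsplit(key, " ")[[1]]
    r <- reads[reads$chrom == parts[1] & reads$strand == parts[2], ]
    if (!nrow(r)) next
    positions <- sort(unique(r$pos))
    seeds <- integer(0)
    for (p in positions) {
      per_sample <- table(r$sample_id[r$pos == p])
      if (max(per_sample) >= seed_depth) seeds <- c(seeds, p)
    }
    if (!length(seeds)) next
    ivl <- cbind(start = pmax(seeds - extension, 0L),
                 end = seeds + extension + 1L)
    ivl <- ivl[order(ivl[, 1]), , drop = FALSE]
    merged <- list(ivl[1, ])
    if (nrow(ivl) > 1) for (i in 2:nrow(ivl)) {
      last <- merged[[length(merged)]]
      if (ivl[i, "start"] <= last["end"]) {
        last["end"] <- max(last["end"], ivl[i, "end"])
        merged[[length(merged)]] <- last
      } else merged <- c(merged, list(ivl[i, ]))
    }
    for (m in merged) {
      inside <- r$pos[r$pos >= m["start"] & r$pos < m["end"]]
      depth <- table(inside)
      summit <- as.integer(names(depth)[which.max(depth)])
      out[[length(out) + 1]] <- data.frame(
        chrom = parts[1], strand = parts[2],
        start = unname(m["start"]), end = unname(m["end"]),
        summit = summit, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame(chrom = character(0),
    strand = character(0), start = integer(0), end = integer(0),
    summit = integer(0)))
  df <- do.call(rbind, out)
  df[order(df$chrom, df$start, df$strand), ]
}

# per-read membership counting oracle
bf_counts <- function(reads, clusters, samples) {
  m <- matrix(0L, nrow(clusters), length(samples),
              dimnames = list(NULL, samples))
  for (i in seq_len(nrow(clusters))) {
    sel <- reads$chrom == clusters$chrom[i] &
      reads$strand == clusters$strand[i] &
      reads$pos >= clusters$start[i] & reads$pos < clusters$end[i]
    if (any(sel))
      for (s in samples) m[i, s] <- sum(reads$sample_id[sel] == s)
  }
  m
}

# exact two-sided Fisher p by direct enumeration via log-binomials
bf_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  logp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  probs <- exp(logp)
  p_obs <- probs[support == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

# Benjamini-Hochberg step-up, written out directly
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# random read-end instances for the cluster oracle
random_instance <- function(seed, max_pos = 500L) {
  set.seed(seed)
  n_samples <- sample(1:3, 1)
  samples <- paste0("s", seq_len(n_samples))
  n_pos <- sample(5:40, 1)
  pos <- sample.int(max_pos, n_pos, replace = TRUE)
  counts <- sample.int(9L, n_pos, replace = TRUE)
  data.frame(chrom = sample(c("cA", "cB"), n_pos, replace = TRUE)[
               rep(seq_len(n_pos), counts)],
             pos = rep(pos, counts),
             strand = sample(c("+", "-"), n_pos, replace = TRUE)[
               rep(seq_len(n_pos), counts)],
             sample_id = unlist(lapply(counts, function(k)
               sample(samples, k, replace = TRUE))),
             stringsAsFactors = FALSE)
}

# minimal one-gene annotation for blacklist / window fixtures
tiny_annotation <- function(chrom = "c1", strand = "+", start = 0L,
                            end = 100L, utr_start = NULL, ends = NULL) {
  if (is.null(utr_start)) utr_start <- if (strand == "+") start else end - 1L
  if (is.null(ends)) ends <- if (strand == "+") end - 1L else start
  gene_annotation(
    genes = data.frame(gene_id = "g1", chrom = chrom, start = start,
                       end = end, strand = strand, utr_start = utr_start),
    ends = data.frame(gene_id = "g1", chrom = chrom, pos = ends,
                      strand = strand))
}

# cluster_set builder for downstream-module fixtures
make_cluster_set <- function(chrom, strand, summits, counts,
                             gene_id = "g1", width = 31L) {
  clusters <- data.frame(
    chrom = chrom, start = summits - (width - 1L) %/% 2L,
    end = summits + (width + 1L) %/% 2L, strand = strand,
    summit = summits, gene_id = gene_id, validated = TRUE,
    stringsAsFactors = FALSE)
  counts <- as.matrix(counts)
  rownames(counts) <- sprintf("cl%05d", seq_len(nrow(counts)))
  synapa:::new_cluster_set(clusters, counts)
}
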