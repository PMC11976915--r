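#' Compute the internal-priming blacklist mask
#'
#' A base `b` on strand `s` is masked iff, on the transcribed strand, the
#' run of A starting at the base immediately downstream of `b` has length
#' `>= run_len`, OR at least `window_hits` of the `window_len` bases
#' immediately downstream are A.  On the minus strand "downstream" runs
#' toward lower coordinates and A on the transcribed strand corresponds to
#' T on the reference.  Bases within `exempt_radius` of an annotated 3' end
#' on the same strand are never masked.  At contig ends the run rule needs
#' `run_len` available bases to fire; the density rule uses the available
#' bases against the same hit threshold.
#'
#' @param genome a `DNAStringSet` of reference contigs.
#' @param annotation a [gene_annotation()] (its `ends` provide the
#'   exemption anchors), or `NULL` for no exemption.
#' @param params a [blacklist_params()].
#' @return An object of class `blacklist_mask`: per contig, logical vectors
#'   `plus` and `minus` over all positions (`TRUE` = masked).
#' @export
compute_blacklist <- function(genome, annotation, params) {
  stopifnot(inherits(params, "blacklist_params"))
  ends <- if (is.null(annotation)) NULL else annotation$ends
  masks <- lapply(names(genome), function(cn) {
    s <- as.character(genome[[cn]])
    raw <- charToRaw(s)
    n <- length(raw)
    isA <- raw == as.raw(65L)
    isT <- raw == as.raw(84L)

    # plus strand: downstream = increasing coordinates, A on reference
    r <- rle(isA)
    countdown <- rep(r$lengths, r$lengths) - sequence(r$lengths) + 1L
    countdown[!rep(r$values, r$lengths)] <- 0L
    run_plus <- c(countdown[-1L], 0L) >= params$run_len
    csA <- c(0L, cumsum(isA))
    i <- seq_len(n)
    dens_plus <- (csA[pmin(n, i + params$window_len) + 1L] - csA[i + 1L]) >=
      params$window_hits
    mask_plus <- run_plus | dens_plus

    # minus strand: downstream = decreasing coordinates, T on reference
    rt <- rle(isT)
    countup <- sequence(rt$lengths)
    countup[!rep(rt$values, rt$lengths)] <- 0L
    run_minus <- c(0L, countup[-n]) >= params$run_len
    csT <- c(0L, cumsum(isT))
    dens_minus <- (csT[i] - csT[pmax(1L, i - params$window_len)]) >=
      params$window_hits
    mask_minus <- run_minus | dens_minus

    if (!is.null(ends)) {
      ee <- ends[ends$chrom == cn, ]
      for (strand_ch in c("+", "-")) {
        ep <- ee$pos[ee$strand == strand_ch]
        if (!length(ep)) next
        ex <- rep(FALSE, n)
        for (p in ep) {
          lo <- max(1L, p + 1L - params$exempt_radius)
          hi <- min(n, p + 1L + params$exempt_radius)
          ex[lo:hi] <- TRUE
        }
        if (strand_ch == "+") mask_plus <- mask_plus & !ex
        else mask_minus <- mask_minus & !ex
      }
    }
    list(plus = mask_plus, minus = mask_minus)
  })
  names(masks) <- names(genome)
  structure(masks, class = "blacklist_mask")
}

#' Query a blacklist mask
#'
#' @param mask a [compute_blacklist()] result.
#' @param chrom,pos,strand vectors describing positions (0-based).
#' @return logical vector, `TRUE` where the position is masked.
#' @export
is_blacklisted <- function(mask, chrom, pos, strand) {
  out <- logical(length(pos))
  for (cn in unique(chrom)) {
    sel <- chrom == cn
    m <- mask[[cn]]
    if (is.null(m)) stop("contig '", cn, "' not in blacklist mask")
    p <- pos[sel] + 1L
    v <- ifelse(strand[sel] == "+", m$plus[p], m$minus[p])
    v[is.na(v)] <- FALSE
    out[sel] <- v
  }
  out
}

#' Restrict reads to gene bodies and their downstream windows
#'
#' Keeps reads whose position lies within a same-strand gene body or at
#' most `downstream_limit` bases downstream (in transcription direction) of
#' its 3' boundary; everything else is dropped with a message.
#'
#' @param reads data.frame with `chrom`, `pos`, `strand`, `sample_id`.
#' @param annotation a [gene_annotation()].
#' @param params a [blacklist_params()] (its `downstream_limit` is used).
#' @return the filtered reads data.frame.
#' @export
restrict_to_gene_windows <- function(reads, annotation, params) {
  g <- annotation$genes
  win_start <- ifelse(g$strand == "+", g$start,
                      pmax(0L, g$start - params$downstream_limit))
  win_end <- ifelse(g$strand == "+", g$end + params$downstream_limit, g$end)
  windows <- GenomicRanges::GRanges(g$chrom,
    IRanges::IRanges(win_start + 1L, win_end), strand = g$strand)
  rr <- GenomicRanges::GRanges(reads$chrom,
    IRanges::IRanges(reads$pos + 1L, width = 1L), strand = reads$strand)
  keep <- IRanges::overlapsAny(rr, windows)
  message(sum(!keep), " of ", length(keep),
          " reads outside gene windows dropped")
  reads[keep, , drop = FALSE]
}

# gene search windows shared by restrict_to_gene_windows and
# assign_clusters_to_genes: body plus downstream_limit past the 3' boundary
gene_windows <- function(genes, downstream_limit) {
  data.frame(
    gene_id = genes$gene_id, chrom = genes$chrom, strand = genes$strand,
    win_start = ifelse(genes$strand == "+", genes$start,
                       pmax(0L, genes$start - downstream_limit)),
    win_end = ifelse(genes$strand == "+", genes$end + downstream_limit,
                     genes$end),
    stringsAsFactors = FALSE)
}
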