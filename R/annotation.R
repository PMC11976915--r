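#' Gene annotation container
#'
#' Bundles the gene models the pipeline needs: gene spans with the position
#' of the most proximal 3' UTR start, plus the set of annotated 3' ends
#' (poly(A) sites) per gene.  All coordinates are 0-based; gene spans are
#' half-open `[start, end)`; `utr_start` and 3'-end positions are 0-based
#' single bases.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (`"+"`/`"-"`), `utr_start`.
#' @param ends data.frame with columns `gene_id`, `chrom`, `pos`, `strand`:
#'   the annotated 3' ends.  Used for the blacklist exemption and as the
#'   default annotated-end set.
#' @return An object of class `gene_annotation`.
#' @export
gene_annotation <- function(genes, ends) {
  genes <- as.data.frame(genes)
  ends <- as.data.frame(ends)
  need_g <- c("gene_id", "chrom", "start", "end", "strand", "utr_start")
  need_e <- c("gene_id", "chrom", "pos", "strand")
  if (!all(need_g %in% names(genes)))
    stop("genes must have columns: ", paste(need_g, collapse = ", "))
  if (!all(need_e %in% names(ends)))
    stop("ends must have columns: ", paste(need_e, collapse = ", "))
  if (any(genes$start >= genes$end))
    stop("gene with start >= end: ",
         genes$gene_id[which(genes$start >= genes$end)[1]])
  if (!all(genes$strand %in% c("+", "-")) || !all(ends$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  orphan <- setdiff(genes$gene_id, ends$gene_id)
  if (length(orphan))
    stop("gene without annotated 3' ends: ", orphan[1])
  structure(list(genes = genes, ends = ends), class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("gene_annotation: %d genes, %d annotated 3' ends on %d contig(s)\n",
              nrow(x$genes), nrow(x$ends), length(unique(x$genes$chrom))))
  invisible(x)
}

#' Write / read gene annotation as GFF3
#'
#' Genes are written as `gene` features carrying a `utr_start` attribute
#' (converted to 1-based in the file, like all GFF coordinates), with one
#' `polyA_site` child per annotated 3' end.
#'
#' @param annotation a [gene_annotation()] object.
#' @param path output (input) file path.
#' @return `write_gff3` returns `path` invisibly; `read_gff3` returns a
#'   [gene_annotation()].
#' @export
write_gff3 <- function(annotation, path) {
  stopifnot(inherits(annotation, "gene_annotation"))
  g <- annotation$genes
  e <- annotation$ends
  gr_g <- GenomicRanges::GRanges(g$chrom,
           IRanges::IRanges(g$start + 1L, g$end), strand = g$strand,
           type = "gene", ID = g$gene_id, utr_start = g$utr_start + 1L)
  gr_e <- GenomicRanges::GRanges(e$chrom,
           IRanges::IRanges(e$pos + 1L, e$pos + 1L), strand = e$strand,
           type = "polyA_site",
           ID = paste0(e$gene_id, ":pA", seq_len(nrow(e))),
           utr_start = NA_integer_)
  gr_e$Parent <- IRanges::CharacterList(as.list(e$gene_id))
  gr_g$Parent <- IRanges::CharacterList(rep(list(character(0)), length(gr_g)))
  gr <- c(gr_g, gr_e)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gff3
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gi <- gr[gr$type == "gene"]
  if (!length(gi)) stop("no gene features in ", path)
  genes <- data.frame(
    gene_id = gi$ID,
    chrom = as.character(GenomicRanges::seqnames(gi)),
    start = GenomicRanges::start(gi) - 1L,
    end = GenomicRanges::end(gi),
    strand = as.character(GenomicRanges::strand(gi)),
    utr_start = as.integer(gi$utr_start) - 1L,
    stringsAsFactors = FALSE)
  pe <- gr[gr$type == "polyA_site"]
  parent <- vapply(pe$Parent, function(x) x[1], character(1))
  ends <- data.frame(
    gene_id = parent,
    chrom = as.character(GenomicRanges::seqnames(pe)),
    pos = GenomicRanges::start(pe) - 1L,
    strand = as.character(GenomicRanges::strand(pe)),
    stringsAsFactors = FALSE)
  missing_children <- setdiff(genes$gene_id, ends$gene_id)
  if (length(missing_children))
    stop("GFF3 gene missing 3'-end (polyA_site) children: ",
         missing_children[1])
  gene_annotation(genes, ends)
}

#' Flattened BED12 export of gene models
#'
#' One BED12 record per gene; `thickStart` carries the 3' UTR start and the
#' blocks mark the annotated 3' ends (1-bp blocks).
#'
#' @inheritParams write_gff3
#' @export
write_bed12 <- function(annotation, path) {
  g <- annotation$genes
  e <- annotation$ends
  sp <- split(e$pos, e$gene_id)
  rows <- vapply(seq_len(nrow(g)), function(i) {
    p <- sort(sp[[g$gene_id[i]]])
    paste(g$chrom[i], g$start[i], g$end[i], g$gene_id[i], 0L, g$strand[i],
          g$utr_start[i], g$utr_start[i] + 1L, "0", length(p),
          paste0(paste(rep(1L, length(p)), collapse = ","), ","),
          paste0(paste(p - g$start[i], collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}
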