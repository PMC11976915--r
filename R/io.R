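#' Read and write read-end BED files
#'
#' Read 3' ends are exchanged as 6-column BED, one record per read:
#' `chrom, pos, pos+1, sample, 1, strand`.  Positions are 0-based.
#'
#' @param path file path.
#' @param reads data.frame with columns `chrom`, `pos`, `strand`,
#'   `sample_id` (extra columns are dropped on write).
#' @return `read_end_bed` returns a data.frame of reads; `write_end_bed`
#'   returns `path` invisibly.
#' @export
read_end_bed <- function(path) {
  b <- read_bed6(path)
  data.frame(chrom = b$chrom, pos = b$start, strand = b$strand,
             sample_id = b$name, stringsAsFactors = FALSE)
}

#' @rdname read_end_bed
#' @export
write_end_bed <- function(reads, path) {
  dt <- data.table::data.table(
    chrom = reads$chrom, start = reads$pos, end = reads$pos + 1L,
    name = reads$sample_id, score = 1L, strand = reads$strand)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read and write validated 3'-end sets (BED6)
#'
#' @param path file path.
#' @param ends data.frame with columns `chrom`, `pos`, `strand`.
#' @return data.frame of unique `(chrom, pos, strand)` records.
#' @export
read_validated_bed <- function(path) {
  b <- read_bed6(path)
  out <- unique(data.frame(chrom = b$chrom, pos = b$start, strand = b$strand,
                           stringsAsFactors = FALSE))
  out
}

#' @rdname read_validated_bed
#' @export
write_validated_bed <- function(ends, path) {
  dt <- unique(data.table::data.table(
    chrom = ends$chrom, start = ends$pos, end = ends$pos + 1L,
    name = "validated_end", score = 0L, strand = ends$strand))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

# strict BED6 reader: validates column count, coordinates, strand,
# reporting 1-based line numbers of offenders
read_bed6 <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          colClasses = list(character = 1),
                          showProgress = FALSE)
  if (ncol(dt) < 6L)
    stop("expected >= 6 BED columns in ", path, ", found ", ncol(dt))
  data.table::setnames(dt, 1:6,
    c("chrom", "start", "end", "name", "score", "strand"))
  bad <- which(!is.finite(dt$start) | !is.finite(dt$end) |
                 dt$start < 0 | dt$start >= dt$end)
  if (length(bad))
    stop("malformed BED record (start >= end or negative) at line ", bad[1],
         " of ", path)
  bad_strand <- which(!dt$strand %in% c("+", "-"))
  if (length(bad_strand))
    stop("invalid strand at line ", bad_strand[1], " of ", path)
  as.data.frame(dt)
}

#' Check chromosome-name consistency across datasets
#'
#' @param genome a `DNAStringSet` (or any named object whose names are
#'   contig names).
#' @param ... data.frames with a `chrom` column.
#' @return invisibly `TRUE`; errors naming the offending contig otherwise.
#' @export
check_chrom_consistency <- function(genome, ...) {
  contigs <- names(genome)
  for (df in list(...)) {
    if (is.null(df)) next
    miss <- setdiff(unique(df$chrom), contigs)
    if (length(miss)) {
      hint <- if (any(paste0("chr", miss) %in% contigs) ||
                  any(sub("^chr", "", miss) %in% contigs))
        " (naming style mismatch: try adding/removing the 'chr' prefix)"
      else ""
      stop("chromosome '", miss[1], "' not present in the genome", hint)
    }
  }
  invisible(TRUE)
}

#' Write / read a cluster set
#'
#' Clusters are written as BED6+ (`thickStart` column carries the summit,
#' then the `gene`, `validated` flag and one count column per sample) and
#' can be round-tripped losslessly.
#'
#' @param x a `cluster_set` (see [call_clusters()]).
#' @param path file path.
#' @return `read_cluster_bed` returns a `cluster_set`.
#' @export
write_cluster_bed <- function(x, path) {
  stopifnot(inherits(x, "cluster_set"))
  cl <- x$clusters
  dt <- data.table::data.table(
    chrom = cl$chrom, start = cl$start, end = cl$end,
    name = rownames(x$counts), score = 0L, strand = cl$strand,
    summit = cl$summit,
    gene = ifelse(is.na(cl$gene_id), ".", cl$gene_id),
    validated = as.integer(cl$validated))
  cnt <- data.table::as.data.table(x$counts)
  data.table::setnames(cnt, paste0("count.", colnames(x$counts)))
  out <- cbind(dt, cnt)
  data.table::fwrite(out, path, sep = "\t", col.names = TRUE)
  invisible(path)
}

#' @rdname write_cluster_bed
#' @export
read_cluster_bed <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1),
                          showProgress = FALSE)
  cc <- grep("^count\\.", names(dt), value = TRUE)
  counts <- as.matrix(dt[, cc, with = FALSE])
  colnames(counts) <- sub("^count\\.", "", cc)
  rownames(counts) <- dt$name
  clusters <- data.frame(
    chrom = dt$chrom, start = dt$start, end = dt$end, strand = dt$strand,
    summit = dt$summit,
    gene_id = ifelse(dt$gene == ".", NA_character_, dt$gene),
    validated = as.logical(dt$validated), stringsAsFactors = FALSE)
  new_cluster_set(clusters, counts)
}

#' Write / read a counts table (feature x sample TSV)
#'
#' @param counts integer or numeric matrix with feature rownames and sample
#'   colnames.
#' @param path file path.
#' @return `read_counts_tsv` returns a matrix.
#' @export
write_counts_tsv <- function(counts, path) {
  dt <- data.table::data.table(feature = rownames(counts))
  dt <- cbind(dt, data.table::as.data.table(counts))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          showProgress = FALSE)
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- dt[[1]]
  m
}

#' Write / read a sample sheet
#'
#' @param design data.frame with columns `sample_id`, `condition`,
#'   `replicate`.
#' @param path file path.
#' @export
write_sample_sheet <- function(design, path) {
  data.table::fwrite(design[, c("sample_id", "condition", "replicate")],
                     path, sep = "\t")
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                        showProgress = FALSE))
  need <- c("sample_id", "condition", "replicate")
  if (!all(need %in% names(df)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  df
}

#' Read a one-column gene list (TSV, optional header)
#'
#' @param path file path.
#' @return character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- x[nzchar(x)]
  x <- vapply(strsplit(x, "\t", fixed = TRUE), `[`, character(1), 1L)
  if (length(x) && x[1] %in% c("gene", "gene_id")) x <- x[-1]
  unique(x)
}

# fixed-precision number formatting for byte-stable text outputs
format_num <- function(x) signif(x, 6)
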