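#' Two-sided Fisher's exact test on a 2x2 table
#'
#' The exact two-sided p-value is the sum of hypergeometric probabilities
#' (margins fixed) of all tables whose probability does not exceed that of
#' the observed table (within a relative tolerance factor of 1e-12).
#'
#' @param a,b,c,d the cells: in-set & in-category, in-set & out,
#'   out & in-category, out & out.  Alternatively `a` may be a 2x2 matrix.
#' @return list with `odds_ratio` (`a*d / b*c`, with `Inf` when `b*c = 0`
#'   and `a*d > 0`, `NaN` when both products are zero) and `p`.
#' @export
#' @examples
#' fisher_exact_two_sided(5, 5, 5, 5)  # p = 1
fisher_exact_two_sided <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2))
    b <- a[1, 2]; c <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("table cells must be non-negative integers")
  m <- a + b; n <- c + d; k <- a + c
  or <- if (b * c > 0) (a * d) / (b * c)
        else if (a * d > 0) Inf
        else NaN
  if (m + n == 0) return(list(odds_ratio = or, p = 1))
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
  list(odds_ratio = or, p = p)
}

#' Category-overlap enrichment
#'
#' Enrichment of a query gene set in a category, against a background:
#' `ratio = (|query & category| / |category|) / (|query| / |background|)`,
#' with the two-sided Fisher p-value on the corresponding 2x2 table built
#' over the background.
#'
#' @param query,category,background character vectors of gene ids;
#'   `query` and `category` must be subsets of `background`.
#' @return list with `ratio`, `overlap` (`|query & category|`), `table`
#'   (2x2 matrix), `odds_ratio`, `p`.
#' @export
overlap_enrichment <- function(query, category, background) {
  query <- unique(query); category <- unique(category)
  background <- unique(background)
  if (length(setdiff(query, background)) ||
      length(setdiff(category, background)))
    stop("query and category must be subsets of the background")
  if (length(category) == 0)
    stop("empty category: enrichment ratio undefined")
  a <- length(intersect(query, category))
  b <- length(query) - a
  cc <- length(category) - a
  d <- length(background) - a - b - cc
  ratio <- (a / length(category)) / (length(query) / length(background))
  ft <- fisher_exact_two_sided(a, b, cc, d)
  tab <- matrix(c(a, cc, b, d), 2, 2,
                dimnames = list(c("query", "not_query"),
                                c("category", "not_category")))
  list(ratio = ratio, overlap = a, table = tab,
       odds_ratio = ft$odds_ratio, p = ft$p)
}

#' Scan sequences for an IUPAC motif
#'
#' Counts matches of a degenerate IUPAC pattern (N matches any base,
#' U is equivalent to T) at every start position, in the given (transcript)
#' orientation.  Offsets are 0-based.
#'
#' @param sequences named character vector or `DNAStringSet`/`RNAStringSet`
#'   in transcript orientation.
#' @param motif IUPAC pattern string (e.g. the Pumilio response element
#'   consensus `"UGUANAUA"`).
#' @return list with `counts` (named integer vector of hits per sequence)
#'   and `offsets` (named list of 0-based match starts).
#' @export
#' @examples
#' scan_motif(c(x = "UGUAAAUA"), "UGUANAUA")$counts
scan_motif <- function(sequences, motif) {
  pat <- toupper(gsub("U", "T", motif))
  if (!nzchar(pat)) stop("empty motif pattern")
  bad <- setdiff(strsplit(pat, "")[[1]], names(Biostrings::IUPAC_CODE_MAP))
  if (length(bad))
    stop("invalid IUPAC letter(s) in motif: ", paste(bad, collapse = ", "))
  if (is.character(sequences)) {
    seqs <- Biostrings::DNAStringSet(toupper(gsub("U", "T", sequences)))
  } else {
    seqs <- Biostrings::DNAStringSet(sequences)
  }
  if (is.null(names(seqs)))
    names(seqs) <- paste0("seq", seq_along(seqs))
  hits <- Biostrings::vmatchPattern(pat, seqs, fixed = FALSE)
  offsets <- lapply(hits, function(h) Biostrings::start(h) - 1L)
  list(counts = setNames(lengths(offsets), names(seqs)), offsets = offsets)
}

#' Motif enrichment in target vs background sequences
#'
#' A sequence is motif-positive iff it has at least one match; enrichment
#' is the two-sided Fisher test on positive/negative x target/background.
#'
#' @param target_seqs,background_seqs sequence sets (see [scan_motif()]).
#' @param motif IUPAC pattern.
#' @return list with `table` (2x2), `odds_ratio`, `p`, `prop_target`,
#'   `prop_background`.
#' @export
motif_enrichment <- function(target_seqs, background_seqs, motif) {
  if (!length(target_seqs) || !length(background_seqs))
    stop("both sequence sets must be non-empty")
  th <- scan_motif(target_seqs, motif)$counts > 0
  bh <- scan_motif(background_seqs, motif)$counts > 0
  a <- sum(th); b <- sum(!th); cc <- sum(bh); d <- sum(!bh)
  ft <- fisher_exact_two_sided(a, b, cc, d)
  tab <- matrix(c(a, cc, b, d), 2, 2,
                dimnames = list(c("target", "background"),
                                c("positive", "negative")))
  list(table = tab, odds_ratio = ft$odds_ratio, p = ft$p,
       prop_target = mean(th), prop_background = mean(bh))
}
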