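#' Count matrix with sample metadata
#'
#' @param counts non-negative integer matrix, features x samples.
#' @param conditions character vector (or named vector over colnames)
#'   giving each sample's condition.
#' @param feature_gene optional named character vector mapping feature ids
#'   to gene ids.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, conditions, feature_gene = NULL) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)))
    stop("counts must have sample column names")
  if (!is.null(names(conditions)))
    conditions <- conditions[colnames(counts)]
  if (length(conditions) != ncol(counts) || anyNA(conditions))
    stop("every sample needs a condition")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  structure(list(counts = counts,
                 conditions = setNames(as.character(conditions),
                                       colnames(counts)),
                 feature_gene = feature_gene),
            class = "count_matrix")
}

#' Median-of-ratios size factors
#'
#' Per-feature geometric means over samples (features with any zero
#' excluded); each sample's factor is the median over features of
#' count / geometric mean.
#'
#' @param counts a matrix or [count_matrix()].
#' @return named numeric vector of positive scale factors.
#' @export
#' @examples
#' m <- cbind(s1 = c(10, 30), s2 = c(20, 60))
#' size_factors(m)  # 1/sqrt(2), sqrt(2)
size_factors <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  lg <- rowMeans(log(m))
  use <- is.finite(lg)
  if (!any(use))
    stop("no feature with nonzero counts in all samples; ",
         "median-of-ratios needs at least one (consider a pseudo-reference ",
         "on filtered features)")
  sf <- apply(m, 2, function(col) median(col[use] / exp(lg[use])))
  if (any(sf <= 0)) stop("non-positive size factor")
  sf
}

#' Negative-binomial Wald differential test
#'
#' Self-contained stand-in for a DESeq2-style analysis: counts are
#' normalized by median-of-ratios size factors; per-feature NB dispersion
#' is estimated by the method of moments (df-weighted across the two
#' conditions), floored at 1e-8 and shrunk 50/50 toward a fitted
#' mean-dispersion trend `a0 + a1/mu`; the log2 fold change is computed
#' from normalized condition means with pseudocount 0.5; the Wald statistic
#' is `log2fc / se` with the standard error from the NB delta method; the
#' two-sided p-value uses the normal reference and BH adjustment is applied
#' over tested features.
#'
#' @param x a [count_matrix()].
#' @param condition_a reference (denominator) condition.
#' @param condition_b numerator condition; `log2fc > 0` means higher in
#'   `condition_b`.
#' @return data.frame with columns `feature`, `baseMean`, `log2fc`, `se`,
#'   `stat`, `p`, `padj`, `status` (`"tested"` / `"untested"` for all-zero
#'   features).
#' @export
nb_wald_test <- function(x, condition_a, condition_b) {
  stopifnot(inherits(x, "count_matrix"))
  cond <- x$conditions
  ia <- which(cond == condition_a)
  ib <- which(cond == condition_b)
  if (length(ia) < 2L || length(ib) < 2L)
    stop("need >= 2 replicates per condition (", condition_a, ": ",
         length(ia), ", ", condition_b, ": ", length(ib), ")")
  m <- x$counts[, c(ia, ib), drop = FALSE]
  sf <- size_factors(m)
  nrm <- sweep(m, 2, sf, "/")
  na <- length(ia); nb <- length(ib)
  A <- nrm[, seq_len(na), drop = FALSE]
  B <- nrm[, na + seq_len(nb), drop = FALSE]

  all_zero <- rowSums(m) == 0
  baseMean <- rowMeans(nrm)
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- apply(A, 1, var); vB <- apply(B, 1, var)

  mom_one <- function(mu, v) ifelse(mu > 0, (v - mu) / mu^2, NA_real_)
  wA <- na - 1L; wB <- nb - 1L
  aA <- mom_one(mA, vA); aB <- mom_one(mB, vB)
  num <- ifelse(is.na(aA), 0, wA * aA) + ifelse(is.na(aB), 0, wB * aB)
  den <- ifelse(is.na(aA), 0, wA) + ifelse(is.na(aB), 0, wB)
  a_mom <- pmax(ifelse(den > 0, num / den, NA_real_), 1e-8)

  # mean-dispersion trend alpha(mu) = a0 + a1/mu, least squares on tested
  # features; coefficients clamped at zero, median fallback if degenerate
  ok <- !all_zero & !is.na(a_mom) & baseMean > 0
  a_trend <- rep(NA_real_, nrow(m))
  if (sum(ok) >= 10) {
    fit <- tryCatch(lm(a_mom[ok] ~ I(1 / baseMean[ok])), error = function(e) NULL)
    if (!is.null(fit)) {
      a0 <- max(coef(fit)[1], 0); a1 <- max(coef(fit)[2], 0)
      a_trend <- pmax(a0 + a1 / baseMean, 1e-8)
    }
  }
  if (anyNA(a_trend))
    a_trend[is.na(a_trend)] <- max(median(a_mom[ok], na.rm = TRUE), 1e-8)
  alpha <- pmax(0.5 * a_mom + 0.5 * a_trend, 1e-8)
  na_i <- is.na(alpha)
  alpha[na_i] <- a_trend[na_i]

  log2fc <- log2((mB + 0.5) / (mA + 0.5))
  varA <- (mA + alpha * mA^2) / na
  varB <- (mB + alpha * mB^2) / nb
  se <- sqrt(varA / (mA + 0.5)^2 + varB / (mB + 0.5)^2) / log(2)
  stat <- ifelse(se > 0, log2fc / se, 0)
  p <- 2 * pnorm(-abs(stat))

  tested <- !all_zero
  p[!tested] <- NA_real_
  stat[!tested] <- NA_real_
  padj <- rep(NA_real_, length(p))
  padj[tested] <- p.adjust(p[tested], method = "BH")
  data.frame(feature = rownames(m) %||% as.character(seq_len(nrow(m))),
             baseMean = baseMean, log2fc = log2fc, se = se, stat = stat,
             p = p, padj = padj,
             status = ifelse(tested, "tested", "untested"),
             stringsAsFactors = FALSE)
}

#' Aggregate cluster counts to gene level
#'
#' Gene-level counts are the sums of each gene's validated cluster counts.
#'
#' @param cluster_set a counted, gene-assigned `cluster_set`.
#' @param validated_only sum only validated clusters (default `TRUE`).
#' @return integer matrix genes x samples.
#' @export
gene_level_counts <- function(cluster_set, validated_only = TRUE) {
  cl <- cluster_set$clusters
  stopifnot(!is.null(cluster_set$counts))
  keep <- !is.na(cl$gene_id) & (!validated_only | cl$validated)
  cnt <- cluster_set$counts[keep, , drop = FALSE]
  gid <- cl$gene_id[keep]
  out <- rowsum(cnt, gid)
  storage.mode(out) <- "integer"
  out
}

#' Call RIP target genes
#'
#' A gene is a target iff `log2fc(rip/input) > lfc_min` with
#' `p < p_max` and `baseMean > base_mean_min`, and
#' `log2fc(rip/ctrl) > ctrl_lfc_min`.  The fold-change rules are
#' directional by default (RIP targets are enrichments); set
#' `absolute_lfc = TRUE` in the params for the literal two-sided rule.
#' The control comparison is fold-change only.  Genes absent from the
#' control comparison are not callable and reported as such.
#'
#' @param rip_vs_input,rip_vs_ctrl [nb_wald_test()] results keyed by gene.
#' @param params a [target_call_params()].
#' @return data.frame with per-gene evidence and the logical `is_target`
#'   column.
#' @export
call_pum_targets <- function(rip_vs_input, rip_vs_ctrl,
                             params = target_call_params()) {
  m <- match(rip_vs_input$feature, rip_vs_ctrl$feature)
  not_callable <- is.na(m)
  if (any(not_callable))
    message(sum(not_callable),
            " gene(s) absent from the control comparison: not callable")
  ctrl_lfc <- rip_vs_ctrl$log2fc[m]
  pass_lfc <- if (params$absolute_lfc)
    abs(rip_vs_input$log2fc) > params$lfc_min
  else rip_vs_input$log2fc > params$lfc_min
  pass_ctrl <- if (params$absolute_lfc)
    abs(ctrl_lfc) > params$ctrl_lfc_min
  else ctrl_lfc > params$ctrl_lfc_min
  is_target <- pass_lfc &
    !is.na(rip_vs_input$p) & rip_vs_input$p < params$p_max &
    rip_vs_input$baseMean > params$base_mean_min &
    !not_callable & !is.na(pass_ctrl) & pass_ctrl
  data.frame(gene_id = rip_vs_input$feature,
             log2fc_rip_input = rip_vs_input$log2fc,
             p_rip_input = rip_vs_input$p,
             baseMean = rip_vs_input$baseMean,
             log2fc_rip_ctrl = ctrl_lfc,
             callable = !not_callable,
             is_target = is_target & !is.na(is_target),
             stringsAsFactors = FALSE)
}

#' Call synaptosome-enriched and -depleted genes
#'
#' Enriched iff `padj < alpha` and `log2fc > 0`; depleted iff
#' `padj < alpha` and `log2fc < 0`.
#'
#' @param syn_vs_input a gene-level [nb_wald_test()] result (synaptosome as
#'   `condition_b`).
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @return list with character vectors `enriched` and `depleted`.
#' @export
call_synaptosome_de <- function(syn_vs_input, alpha = 0.05) {
  sig <- !is.na(syn_vs_input$padj) & syn_vs_input$padj < alpha
  list(enriched = syn_vs_input$feature[sig & syn_vs_input$log2fc > 0],
       depleted = syn_vs_input$feature[sig & syn_vs_input$log2fc < 0])
}
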