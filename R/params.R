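#' Internal-priming blacklist parameters
#'
#' Parameter bundle controlling which candidate 3'-end bases are masked as
#' likely internal-priming artifacts, and how far downstream of an annotated
#' gene 3'-seq signal is still accepted.
#'
#' Two presets are provided, matching the two library types this filter was
#' designed for:
#' \describe{
#'   \item{`"xrip"`}{run of >= 6 downstream A, or >= 7 A among the 10
#'     downstream bases; signal kept up to 500 bases downstream of a gene.}
#'   \item{`"synaptosome"`}{run of >= 4 downstream A, or >= 6 A among the 8
#'     downstream bases; signal kept up to 2000 bases downstream of a gene.}
#' }
#' Bases within `exempt_radius` (25) of an annotated 3' end on the same
#' strand are never masked.
#'
#' @param mode `"xrip"` or `"synaptosome"` preset.
#' @param run_len minimum length of a downstream A-run that triggers masking.
#' @param window_hits,window_len mask if at least `window_hits` of the
#'   `window_len` bases immediately downstream are A.
#' @param exempt_radius bases around an annotated 3' end exempt from masking.
#' @param downstream_limit how far downstream of a gene 3' boundary reads are
#'   still considered (bases).
#' @return An object of class `blacklist_params`.
#' @export
#' @examples
#' blacklist_params("xrip")
#' blacklist_params("synaptosome", downstream_limit = 1000)
blacklist_params <- function(mode = c("xrip", "synaptosome"),
                             run_len = NULL, window_hits = NULL,
                             window_len = NULL, exempt_radius = 25L,
                             downstream_limit = NULL) {
  mode <- match.arg(mode)
  preset <- switch(mode,
    xrip        = list(run_len = 6L, window_hits = 7L, window_len = 10L,
                       downstream_limit = 500L),
    synaptosome = list(run_len = 4L, window_hits = 6L, window_len = 8L,
                       downstream_limit = 2000L))
  p <- list(
    mode             = mode,
    run_len          = as.integer(run_len %||% preset$run_len),
    window_hits      = as.integer(window_hits %||% preset$window_hits),
    window_len       = as.integer(window_len %||% preset$window_len),
    exempt_radius    = as.integer(exempt_radius),
    downstream_limit = as.integer(downstream_limit %||% preset$downstream_limit))
  stopifnot(p$window_hits <= p$window_len,
            p$run_len > 0, p$window_hits > 0, p$window_len > 0,
            p$exempt_radius > 0, p$downstream_limit > 0)
  structure(p, class = "blacklist_params")
}

#' Cluster-calling parameters
#'
#' @param seed_depth minimum read depth at one position in a single sample
#'   for that position to seed a cluster (default 6).
#' @param extension bases a seed is extended on each side before merging
#'   (default 15).
#' @param validation_radius half-width of the window around a validated
#'   3' end that a cluster must intersect to survive validation (default 25,
#'   i.e. 50-nt windows).
#' @return An object of class `cluster_params`.
#' @export
cluster_params <- function(seed_depth = 6L, extension = 15L,
                           validation_radius = 25L) {
  p <- list(seed_depth = as.integer(seed_depth),
            extension = as.integer(extension),
            validation_radius = as.integer(validation_radius))
  stopifnot(p$seed_depth > 0, p$extension > 0, p$validation_radius > 0)
  structure(p, class = "cluster_params")
}

#' RIP target-calling thresholds
#'
#' A gene is called a RIP target when its enrichment in the IP over input
#' exceeds `lfc_min` (log2) at `p_max`, its baseMean exceeds
#' `base_mean_min`, and its enrichment over the control IP exceeds
#' `ctrl_lfc_min`.
#'
#' @param lfc_min minimum log2 fold change IP/input (default 1).
#' @param p_max maximum unadjusted p-value for the IP/input test
#'   (default 0.05).
#' @param base_mean_min minimum baseMean in the IP/input comparison
#'   (default 10).
#' @param ctrl_lfc_min minimum log2 fold change IP/control-IP (default 1).
#' @param absolute_lfc if `TRUE`, the fold-change thresholds are applied to
#'   `|log2fc|` (the literal two-sided rule) instead of the enrichment
#'   direction only.
#' @return An object of class `target_call_params`.
#' @export
target_call_params <- function(lfc_min = 1, p_max = 0.05, base_mean_min = 10,
                               ctrl_lfc_min = 1, absolute_lfc = FALSE) {
  stopifnot(lfc_min > 0, p_max > 0, base_mean_min > 0, ctrl_lfc_min > 0)
  structure(list(lfc_min = lfc_min, p_max = p_max,
                 base_mean_min = base_mean_min, ctrl_lfc_min = ctrl_lfc_min,
                 absolute_lfc = isTRUE(absolute_lfc)),
            class = "target_call_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() that never falls into the 1:n trap for length-1 vectors
resample <- function(x, size) x[sample.int(length(x), size)]

#' @export
print.blacklist_params <- function(x, ...) {
  cat(sprintf(
    "blacklist_params [%s]: A-run >= %d | %d/%d downstream A; exempt +-%d of annotated ends; downstream limit %d\n",
    x$mode, x$run_len, x$window_hits, x$window_len, x$exempt_radius,
    x$downstream_limit))
  invisible(x)
}
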