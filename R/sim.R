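#' Simulation configuration
#'
#' Describes the synthetic world the generator emits: multi-isoform genes
#' with Dirichlet baseline isoform usage, planted localization shifts
#' (distal usage share moved by `localization_effect` in the synaptosome
#' condition), planted RIP target genes (counts multiplied by
#' `rip_enrichment` in RIP samples, with an extra `distal_binding_weight`
#' on non-proximal isoforms), negative-binomial replicate counts, Gaussian
#' positional scatter of read ends, and internal-priming decoy reads emitted
#' exactly at planted A-tract positions.
#'
#' @param n_genes number of genes.
#' @param n_chroms number of contigs (genes distributed round-robin).
#' @param genome_length total genome size in bases, or `NULL` to size the
#'   genome automatically from the gene layout.  An explicit value smaller
#'   than the layout requires is an error.
#' @param isoforms_per_gene probability weights over 1..4 isoforms.
#' @param utr_start_offset bases from gene 5' start to the 3' UTR start.
#' @param isoform_spacing minimum distance between poly(A) sites (bases).
#' @param usage_concentration Dirichlet concentration for baseline isoform
#'   usage shares.
#' @param localization_effect magnitude of the shift in distal usage share
#'   for planted localized genes (applied negatively for
#'   `shorter_in_synaptosome`, positively for `longer_in_synaptosome`).
#' @param n_localized_genes planted localized genes: a single count applied
#'   to both directions, or a length-2 vector
#'   `c(shorter_in_synaptosome, longer_in_synaptosome)`.
#' @param n_rip_targets planted RIP target genes.
#' @param rip_among_shorter fraction of RIP targets drawn from the planted
#'   shorter-in-synaptosome genes (0 = targets independent of localization).
#' @param rip_enrichment multiplicative RIP enrichment factor for targets.
#' @param distal_binding_weight extra multiplicative factor on distal (all
#'   non-proximal) isoforms of targets in RIP samples.
#' @param nb_dispersion negative-binomial dispersion alpha
#'   (variance = mu + alpha * mu^2).
#' @param mean_depth expected reads per expressed isoform per sample.
#' @param end_scatter_sd positional jitter SD of read ends (bases).
#' @param internal_priming_rate fraction of each sample's reads emitted at
#'   decoy positions.
#' @param n_decoy_sites number of planted A-tract decoys (`NULL` = one per
#'   gene).
#' @param replicates replicates per condition.
#' @param intergenic_gap bases between consecutive genes.
#' @param seed integer seed; all generator randomness derives from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200L, n_chroms = 2L, genome_length = NULL,
                       isoforms_per_gene = c(0.25, 0.40, 0.25, 0.10),
                       utr_start_offset = 200L, isoform_spacing = 300L,
                       usage_concentration = 5,
                       localization_effect = 0.4, n_localized_genes = 10L,
                       n_rip_targets = 40L, rip_among_shorter = 0,
                       rip_enrichment = 8, distal_binding_weight = 2,
                       nb_dispersion = 0.1, mean_depth = 200,
                       end_scatter_sd = 3, internal_priming_rate = 0.05,
                       n_decoy_sites = NULL, replicates = 3L,
                       intergenic_gap = 1000L, seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_chroms = as.integer(n_chroms),
    genome_length = if (is.null(genome_length)) NULL else as.numeric(genome_length),
    isoforms_per_gene = isoforms_per_gene / sum(isoforms_per_gene),
    utr_start_offset = as.integer(utr_start_offset),
    isoform_spacing = as.integer(isoform_spacing),
    usage_concentration = usage_concentration,
    localization_effect = localization_effect,
    n_localized_genes = if (length(n_localized_genes) == 2L)
      as.integer(n_localized_genes)
    else rep(as.integer(n_localized_genes), 2L),
    n_rip_targets = as.integer(n_rip_targets),
    rip_among_shorter = rip_among_shorter,
    rip_enrichment = rip_enrichment,
    distal_binding_weight = distal_binding_weight,
    nb_dispersion = nb_dispersion, mean_depth = mean_depth,
    end_scatter_sd = end_scatter_sd,
    internal_priming_rate = internal_priming_rate,
    n_decoy_sites = if (is.null(n_decoy_sites)) as.integer(n_genes)
                    else as.integer(n_decoy_sites),
    replicates = as.integer(replicates),
    intergenic_gap = as.integer(intergenic_gap),
    seed = as.integer(seed))
  stopifnot(cfg$n_genes > 0, cfg$n_chroms > 0,
            length(cfg$isoforms_per_gene) == 4,
            all(cfg$isoforms_per_gene >= 0),
            cfg$utr_start_offset >= 0, cfg$isoform_spacing > 0,
            cfg$usage_concentration > 0,
            cfg$localization_effect >= 0, cfg$localization_effect <= 1,
            all(cfg$n_localized_genes >= 0), cfg$n_rip_targets >= 0,
            cfg$rip_among_shorter >= 0, cfg$rip_among_shorter <= 1,
            cfg$rip_enrichment > 0, cfg$distal_binding_weight > 0,
            cfg$nb_dispersion >= 0, cfg$mean_depth > 0,
            cfg$end_scatter_sd >= 0,
            cfg$internal_priming_rate >= 0, cfg$internal_priming_rate < 1,
            cfg$n_decoy_sites >= 0, cfg$replicates >= 1)
  structure(cfg, class = "sim_config")
}

#' Experimental design for the simulator
#'
#' @param conditions conditions to simulate, any subset of
#'   `c("input", "synaptosome", "rip", "control_rip")`.
#' @param replicates replicates per condition.
#' @return data.frame with columns `sample_id`, `condition`, `replicate`.
#' @export
sample_design <- function(conditions = c("input", "synaptosome", "rip",
                                         "control_rip"),
                          replicates = 3L) {
  conditions <- match.arg(conditions, several.ok = TRUE)
  data.frame(
    sample_id = paste0(rep(conditions, each = replicates), "_",
                       rep(seq_len(replicates), length(conditions))),
    condition = rep(conditions, each = replicates),
    replicate = rep(seq_len(replicates), length(conditions)),
    stringsAsFactors = FALSE)
}

DECOY_RUN_LEN <- 8L  # planted A-runs: >= 8 nt on the transcribed strand
DECOY_CLEARANCE <- 50L  # minimum distance between a decoy and any true site

#' Generate the synthetic reference world
#'
#' Lays out non-overlapping, strand-alternating genes, draws isoform counts
#' and baseline/condition usage shares, plants A-tract internal-priming
#' decoys (runs of `>= 8` A on the transcribed strand, at least 50 bases
#' from any true poly(A) site and outside the 25-nt annotation-exemption
#' radius), and emits the genome, gene models, validated-end set (every
#' true poly(A) site) and the ground-truth table.  Deterministic given
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return A list with elements `genome` (`DNAStringSet`), `annotation`
#'   ([gene_annotation()]), `validated` (data.frame `chrom,pos,strand`) and
#'   `truth` (class `sim_truth`: `$genes`, `$isoforms`, `$decoys`,
#'   `$config`).
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config

  k <- sample.int(4L, cfg$n_genes, replace = TRUE,
                  prob = cfg$isoforms_per_gene)
  # localized and RIP-target genes need >= 2 isoforms to carry their effect
  n_special <- sum(cfg$n_localized_genes) + cfg$n_rip_targets
  if (n_special > cfg$n_genes)
    stop("n_localized_genes and n_rip_targets exceed n_genes")
  if (sum(k >= 2) < n_special) {
    promote <- resample(which(k == 1L), n_special - sum(k >= 2))
    k[promote] <- 2L
  }

  # per-gene layout in transcription coordinates
  jitter <- matrix(sample.int(100L, cfg$n_genes * 4L, replace = TRUE),
                   ncol = 4L)
  end_off <- lapply(seq_len(cfg$n_genes), function(i)
    cfg$utr_start_offset + cfg$isoform_spacing * seq_len(k[i]) +
      cumsum(jitter[i, seq_len(k[i])]))
  glen <- vapply(end_off, function(e) max(e) + 1L, numeric(1))

  chrom_of <- rep(seq_len(cfg$n_chroms), length.out = cfg$n_genes)
  gap <- cfg$intergenic_gap
  gene_start <- integer(cfg$n_genes)
  chrom_len <- numeric(cfg$n_chroms)
  for (i in seq_len(cfg$n_genes)) {
    cc <- chrom_of[i]
    gene_start[i] <- chrom_len[cc] + gap
    chrom_len[cc] <- gene_start[i] + glen[i]
  }
  chrom_len <- chrom_len + gap
  if (!is.null(cfg$genome_length)) {
    need <- sum(chrom_len)
    if (cfg$genome_length < need)
      stop("genome_length = ", cfg$genome_length, " is too small: ",
           "placing ", cfg$n_genes, " non-overlapping genes with spacing ",
           cfg$isoform_spacing, " and gap ", gap, " requires >= ", need,
           " bases")
    extra <- floor((cfg$genome_length - need) / cfg$n_chroms)
    chrom_len <- chrom_len + extra
  }
  chrom_names <- paste0("chrS", seq_len(cfg$n_chroms))

  strand <- ifelse(seq_len(cfg$n_genes) %% 2L == 1L, "+", "-")
  gene_id <- sprintf("g%04d", seq_len(cfg$n_genes))

  # genomic coordinates: for '-' genes the transcription layout is mirrored
  gene_end <- gene_start + glen
  utr_start <- ifelse(strand == "+",
                      gene_start + cfg$utr_start_offset,
                      gene_end - 1L - cfg$utr_start_offset)
  iso <- data.table::rbindlist(lapply(seq_len(cfg$n_genes), function(i) {
    off <- end_off[[i]]
    pos <- if (strand[i] == "+") gene_start[i] + off
           else gene_end[i] - 1L - off
    data.table::data.table(gene_id = gene_id[i], isoform = seq_len(k[i]),
                           end_pos = as.integer(pos))
  }))

  # planted effects
  # baseline usage shares ~ Dirichlet(concentration), drawn before effect
  # assignment so that localized carriers can be chosen among genes whose
  # distal share can absorb the full stated shift (clamping is a fallback)
  shares <- lapply(k, function(ki) {
    x <- rgamma(ki, shape = cfg$usage_concentration)
    x / sum(x)
  })
  distal_share <- vapply(shares, function(s) s[length(s)], numeric(1))

  apa <- which(k >= 2)
  eff <- cfg$localization_effect
  pick_carriers <- function(eligible, fallback, n) {
    n1 <- min(n, length(eligible))
    c(resample(eligible, n1), resample(fallback, n - n1))
  }
  elig_short <- apa[distal_share[apa] >= eff + 0.01]
  shorter <- pick_carriers(elig_short, setdiff(apa, elig_short),
                           cfg$n_localized_genes[1])
  rest <- setdiff(apa, shorter)
  elig_long <- rest[distal_share[rest] <= 1 - eff - 0.01]
  longer <- pick_carriers(elig_long, setdiff(rest, elig_long),
                          cfg$n_localized_genes[2])
  loc_class <- rep("null", cfg$n_genes)
  loc_class[shorter] <- "shorter_in_synaptosome"
  loc_class[longer] <- "longer_in_synaptosome"
  n_from_short <- min(round(cfg$rip_among_shorter * cfg$n_rip_targets),
                      length(shorter))
  pool <- setdiff(apa, shorter)
  targets <- c(resample(shorter, n_from_short),
               resample(pool, cfg$n_rip_targets - n_from_short))
  is_target <- seq_len(cfg$n_genes) %in% targets

  syn_shares <- lapply(seq_len(cfg$n_genes), function(i) {
    s <- shares[[i]]
    if (loc_class[i] == "null" || k[i] < 2) return(s)
    delta <- if (loc_class[i] == "longer_in_synaptosome")
      cfg$localization_effect else -cfg$localization_effect
    d_new <- min(max(s[k[i]] + delta, 0.01), 0.99)
    rest <- s[-k[i]]
    rest <- rest / sum(rest) * (1 - d_new)
    out <- c(rest, d_new)
    out / sum(out)
  })
  iso[, base_share := unlist(shares)]
  iso[, input_share := unlist(shares)]
  iso[, syn_share := unlist(syn_shares)]

  genes <- data.frame(
    gene_id = gene_id, chrom = chrom_names[chrom_of],
    strand = strand, start = as.integer(gene_start),
    end = as.integer(gene_end), utr_start = as.integer(utr_start),
    n_isoforms = k, loc_class = loc_class, is_rip_target = is_target,
    distal_binding_weight = ifelse(is_target, cfg$distal_binding_weight, 1),
    stringsAsFactors = FALSE)
  gmap <- match(iso$gene_id, genes$gene_id)
  iso_chrom <- genes$chrom[gmap]
  iso_strand <- genes$strand[gmap]

  # genome: uniform random bases, then plant decoy A-tracts
  seqs <- vapply(chrom_len, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  split_seqs <- lapply(seqs, function(s) strsplit(s, "", fixed = TRUE)[[1]])

  decoys <- place_decoys(cfg, genes, iso, iso_chrom, iso_strand)
  for (i in seq_len(nrow(decoys))) {
    cc <- match(decoys$chrom[i], chrom_names)
    p <- decoys$pos[i]
    if (decoys$strand[i] == "+") {
      split_seqs[[cc]][(p + 2L):(p + 1L + DECOY_RUN_LEN)] <- "A"
    } else {
      split_seqs[[cc]][(p - DECOY_RUN_LEN + 1L):p] <- "T"
    }
  }
  genome <- Biostrings::DNAStringSet(vapply(split_seqs, paste,
                                            character(1), collapse = ""))
  names(genome) <- chrom_names

  ends <- data.frame(gene_id = iso$gene_id, chrom = iso_chrom,
                     pos = iso$end_pos, strand = iso_strand,
                     stringsAsFactors = FALSE)
  annotation <- gene_annotation(genes[, c("gene_id", "chrom", "start", "end",
                                          "strand", "utr_start")], ends)
  validated <- unique(ends[, c("chrom", "pos", "strand")])

  truth <- structure(list(genes = genes, isoforms = as.data.frame(iso),
                          decoys = decoys, config = cfg),
                     class = "sim_truth")
  list(genome = genome, annotation = annotation, validated = validated,
       truth = truth)
}

# choose decoy positions inside gene bodies, >= DECOY_CLEARANCE from every
# true poly(A) site (also keeps them outside the 25-nt exemption radius)
place_decoys <- function(cfg, genes, iso, iso_chrom, iso_strand) {
  if (cfg$n_decoy_sites == 0L)
    return(data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  host <- rep(seq_len(nrow(genes)), length.out = cfg$n_decoy_sites)
  out <- vector("list", cfg$n_decoy_sites)
  for (d in seq_len(cfg$n_decoy_sites)) {
    g <- host[d]
    sites <- iso$end_pos[iso$gene_id == genes$gene_id[g]]
    lo <- genes$start[g] + DECOY_RUN_LEN + 1L
    hi <- genes$end[g] - DECOY_RUN_LEN - 2L
    cand <- setdiff(lo:hi, unlist(lapply(sites, function(s)
      (s - DECOY_CLEARANCE):(s + DECOY_CLEARANCE))))
    if (!length(cand))
      stop("cannot place decoy in gene ", genes$gene_id[g],
           ": no position >= ", DECOY_CLEARANCE, " bases from a true site")
    out[[d]] <- data.frame(chrom = genes$chrom[g],
                           pos = resample(cand, 1L),
                           strand = genes$strand[g],
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate per-sample read 3'-end observations
#'
#' Per sample, isoform read counts are drawn
#' `NB(mean = mean_depth * usage_share * condition factors, dispersion
#' alpha)`; synaptosome samples use the localization-shifted shares, RIP
#' samples multiply target-gene means by `rip_enrichment` (times
#' `distal_binding_weight` for non-proximal isoforms), control RIP has no
#' enrichment.  Each read's position is its isoform 3' end plus rounded
#' `Normal(0, end_scatter_sd)` jitter; internal-priming reads are placed
#' exactly at decoy positions so that they constitute
#' `internal_priming_rate` of each sample's reads.  Deterministic given
#' `config$seed`.
#'
#' @param truth the `sim_truth` from [generate_reference()].
#' @param design a [sample_design()] data.frame.
#' @param config the same [sim_config()].
#' @return data.frame of reads with columns `chrom`, `pos`, `strand`,
#'   `sample_id` and `origin` (`"true"` or `"decoy"`).
#' @export
simulate_end_reads <- function(truth, design, config) {
  stopifnot(inherits(truth, "sim_truth"))
  if (is.null(design) || nrow(design) == 0L)
    stop("empty design: at least one sample is required")
  set.seed(config$seed + 10007L)

  iso <- data.table::as.data.table(truth$isoforms)
  g <- truth$genes
  iso[, `:=`(chrom = g$chrom[match(gene_id, g$gene_id)],
             strand = g$strand[match(gene_id, g$gene_id)],
             n_isoforms = g$n_isoforms[match(gene_id, g$gene_id)],
             is_rip_target = g$is_rip_target[match(gene_id, g$gene_id)])]

  per_sample <- vector("list", nrow(design))
  for (s in seq_len(nrow(design))) {
    cond <- design$condition[s]
    share <- if (cond == "synaptosome") iso$syn_share else iso$input_share
    mu <- config$mean_depth * share
    if (cond == "rip") {
      fac <- ifelse(iso$is_rip_target, config$rip_enrichment, 1) *
        ifelse(iso$is_rip_target & iso$isoform > 1L,
               config$distal_binding_weight, 1)
      mu <- mu * fac
    }
    cnt <- if (config$nb_dispersion > 0)
      rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
    else
      stats::rpois(length(mu), mu)
    pos <- rep(iso$end_pos, cnt) +
      as.integer(round(rnorm(sum(cnt), 0, config$end_scatter_sd)))
    true_reads <- data.table::data.table(
      chrom = rep(iso$chrom, cnt), pos = pos,
      strand = rep(iso$strand, cnt),
      sample_id = design$sample_id[s], origin = "true")
    n_decoy <- 0L
    if (config$internal_priming_rate > 0 && nrow(truth$decoys) > 0)
      n_decoy <- as.integer(round(nrow(true_reads) *
        config$internal_priming_rate / (1 - config$internal_priming_rate)))
    if (n_decoy > 0L) {
      di <- sample.int(nrow(truth$decoys), n_decoy, replace = TRUE)
      decoy_reads <- data.table::data.table(
        chrom = truth$decoys$chrom[di], pos = truth$decoys$pos[di],
        strand = truth$decoys$strand[di],
        sample_id = design$sample_id[s], origin = "decoy")
      per_sample[[s]] <- rbind(true_reads, decoy_reads)
    } else {
      per_sample[[s]] <- true_reads
    }
  }
  reads <- as.data.frame(data.table::rbindlist(per_sample))
  reads$pos <- pmax(reads$pos, 0L)
  reads
}

#' Write the ground-truth table as TSV
#'
#' Two files are produced: `<prefix>_isoforms.tsv` (one row per isoform,
#' gene-level columns joined in) and `<prefix>_decoys.tsv`.
#'
#' @param truth a `sim_truth`.
#' @param prefix output path prefix.
#' @export
write_truth_tsv <- function(truth, prefix) {
  g <- truth$genes
  iso <- truth$isoforms
  m <- match(iso$gene_id, g$gene_id)
  out <- cbind(iso, g[m, c("chrom", "strand", "utr_start", "n_isoforms",
                           "loc_class", "is_rip_target",
                           "distal_binding_weight")])
  data.table::fwrite(out, paste0(prefix, "_isoforms.tsv"), sep = "\t")
  data.table::fwrite(truth$decoys, paste0(prefix, "_decoys.tsv"), sep = "\t")
  invisible(prefix)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(
    "sim_truth: %d genes (%d localized shorter, %d longer, %d RIP targets), %d isoforms, %d decoys\n",
    nrow(x$genes), sum(x$genes$loc_class == "shorter_in_synaptosome"),
    sum(x$genes$loc_class == "longer_in_synaptosome"),
    sum(x$genes$is_rip_target), nrow(x$isoforms), nrow(x$decoys)))
  invisible(x)
}
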