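#' Pipeline configuration
#'
#' Bundles the inputs, mode preset, thresholds and output directory for
#' [run_pipeline()].  Either `simulate` is a [sim_config()] (the synthetic
#' world is generated as stage 1), or the four input paths must point to
#' existing files.
#'
#' @param outdir output directory (created if needed).
#' @param mode blacklist mode preset: `"xrip"` or `"synaptosome"`.
#' @param simulate a [sim_config()] or `NULL`.
#' @param genome,annotation,reads,validated,sample_sheet input file paths
#'   (FASTA, GFF3, end-read BED with `name` = sample, validated-end BED,
#'   sample sheet TSV); ignored when `simulate` is given.
#' @param seed integer seed for any stage randomness.
#' @param min_expr,alpha,target_params tunables forwarded to the stages.
#' @param cl_params a [cluster_params()].
#' @param resume skip stages whose outputs already exist.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, mode = c("xrip", "synaptosome"),
                            simulate = NULL, genome = NULL,
                            annotation = NULL, reads = NULL,
                            validated = NULL, sample_sheet = NULL,
                            seed = 1L, min_expr = 5, alpha = 0.05,
                            target_params = target_call_params(),
                            cl_params = cluster_params(),
                            resume = FALSE) {
  mode <- match.arg(mode)
  if (is.null(simulate)) {
    paths <- c(genome = genome, annotation = annotation, reads = reads,
               validated = validated, sample_sheet = sample_sheet)
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("input file(s) not found: ", paste(missing, collapse = ", "))
  }
  structure(list(outdir = outdir, mode = mode, simulate = simulate,
                 genome = genome, annotation = annotation, reads = reads,
                 validated = validated, sample_sheet = sample_sheet,
                 seed = as.integer(seed), min_expr = min_expr,
                 alpha = alpha, target_params = target_params,
                 cl_params = cl_params, resume = isTRUE(resume)),
            class = "pipeline_config")
}

#' Load and validate pipeline inputs
#'
#' @param config a [pipeline_config()] with file inputs.
#' @return list with `genome`, `annotation`, `reads`, `validated`,
#'   `design`.
#' @export
load_inputs <- function(config) {
  genome <- Biostrings::readDNAStringSet(config$genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  annotation <- read_gff3(config$annotation)
  reads <- read_end_bed(config$reads)
  validated <- read_validated_bed(config$validated)
  design <- read_sample_sheet(config$sample_sheet)
  check_chrom_consistency(genome, annotation$genes, reads, validated)
  miss <- setdiff(reads$sample_id, design$sample_id)
  if (length(miss))
    stop("sample '", miss[1], "' in reads has no sample-sheet entry")
  list(genome = genome, annotation = annotation, reads = reads,
       validated = validated, design = design)
}

stage_log <- function(manifest, stage, files, counts = list()) {
  manifest$stages[[stage]] <- list(
    files = lapply(files, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))),
    counts = counts)
  manifest
}

#' Run the full analysis pipeline
#'
#' Executes (optionally) simulate, then call-sites, differential
#' expression, target calling, 3' UTR length / localization, isoform
#' binding preference and enrichment, in dependency order.  Every stage
#' writes plain-text outputs under `config$outdir`; a JSON run manifest
#' records the config hash, per-stage file checksums and record counts.
#' With `resume = TRUE`, a stage whose outputs all exist is skipped
#' (downstream stages still re-run if an upstream stage ran).
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(out, paste0(...))
  cfg_json <- jsonlite::toJSON(config[setdiff(names(config), "outdir")],
                               auto_unbox = TRUE, digits = NA, force = TRUE)
  tf <- tempfile(); writeLines(cfg_json, tf)
  manifest <- list(tool = "synapa",
                   version = as.character(utils::packageVersion("synapa")),
                   config_hash = unname(tools::md5sum(tf)), stages = list())
  unlink(tf)
  done <- function(files) config$resume && all(file.exists(files))
  ran_any <- FALSE

  # stage 1: obtain inputs (simulate or load)
  sim_files <- pth(c("genome.fa", "annotation.gff3", "annotation.bed12",
                     "validated.bed", "reads.bed", "sample_sheet.tsv",
                     "truth_isoforms.tsv", "truth_decoys.tsv"))
  if (!is.null(config$simulate)) {
    if (!done(sim_files) || ran_any) {
      ref <- generate_reference(config$simulate)
      design <- sample_design(replicates = config$simulate$replicates)
      reads <- simulate_end_reads(ref$truth, design, config$simulate)
      Biostrings::writeXStringSet(ref$genome, pth("genome.fa"))
      write_gff3(ref$annotation, pth("annotation.gff3"))
      write_bed12(ref$annotation, pth("annotation.bed12"))
      write_validated_bed(ref$validated, pth("validated.bed"))
      write_end_bed(reads, pth("reads.bed"))
      write_sample_sheet(design, pth("sample_sheet.tsv"))
      write_truth_tsv(ref$truth, pth("truth"))
      ran_any <- TRUE
    } else {
      ref <- list(genome = Biostrings::readDNAStringSet(pth("genome.fa")),
                  annotation = read_gff3(pth("annotation.gff3")),
                  validated = read_validated_bed(pth("validated.bed")))
      reads <- read_end_bed(pth("reads.bed"))
      design <- read_sample_sheet(pth("sample_sheet.tsv"))
    }
    genome <- ref$genome; annotation <- ref$annotation
    validated <- ref$validated
    manifest <- stage_log(manifest, "simulate", sim_files,
                          list(reads = nrow(reads)))
  } else {
    inp <- load_inputs(config)
    genome <- inp$genome; annotation <- inp$annotation
    reads <- inp$reads; validated <- inp$validated; design <- inp$design
    manifest <- stage_log(manifest, "load_inputs",
                          unlist(config[c("genome", "annotation", "reads",
                                          "validated", "sample_sheet")]),
                          list(reads = nrow(reads)))
  }
  conditions <- setNames(design$condition, design$sample_id)

  # stage 2: site calling
  site_files <- pth(c("clusters.tsv", "cluster_counts.tsv"))
  bl <- blacklist_params(config$mode)
  if (!done(site_files) || ran_any) {
    sc <- call_sites(reads, genome, annotation, validated,
                     bl_params = bl, cl_params = config$cl_params)
    cs <- sc$clusters
    write_cluster_bed(cs, pth("clusters.tsv"))
    write_counts_tsv(cs$counts, pth("cluster_counts.tsv"))
    site_counts <- sc$stats
    ran_any <- TRUE
  } else {
    cs <- read_cluster_bed(pth("clusters.tsv"))
    site_counts <- list(clusters_assigned = nrow(cs$clusters))
  }
  manifest <- stage_log(manifest, "call_sites", site_files, site_counts)

  # stage 3: differential expression at gene level
  gcounts <- gene_level_counts(cs)
  cm <- count_matrix(gcounts, conditions[colnames(gcounts)])
  have <- function(x) sum(conditions == x) >= 2
  de <- list()
  if (have("input") && have("rip"))
    de$rip_vs_input <- nb_wald_test(cm, "input", "rip")
  if (have("control_rip") && have("rip"))
    de$rip_vs_ctrl <- nb_wald_test(cm, "control_rip", "rip")
  if (have("input") && have("synaptosome"))
    de$syn_vs_input <- nb_wald_test(cm, "input", "synaptosome")
  de_files <- character(0)
  for (nm in names(de)) {
    f <- pth("de_", nm, ".tsv")
    df <- de[[nm]]
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], format_num)
    data.table::fwrite(df, f, sep = "\t")
    de_files <- c(de_files, f)
  }
  manifest <- stage_log(manifest, "de", de_files,
                        list(genes_tested = nrow(gcounts),
                             comparisons = length(de)))

  # stage 4: target calling
  targets <- NULL
  if (!is.null(de$rip_vs_input) && !is.null(de$rip_vs_ctrl)) {
    targets <- call_pum_targets(de$rip_vs_input, de$rip_vs_ctrl,
                                config$target_params)
    data.table::fwrite(targets, pth("targets.tsv"), sep = "\t")
    manifest <- stage_log(manifest, "call_targets", pth("targets.tsv"),
                          list(targets = sum(targets$is_target)))
  }

  # stage 5: 3' UTR length / localization
  loc <- NULL
  if (have("input") && have("synaptosome")) {
    iso <- build_isoform_table(cs, annotation, conditions,
                               min_expr = config$min_expr)
    if (nrow(iso)) {
      stats <- gene_length_stats(iso)
      loc <- call_localized_genes(stats, alpha = config$alpha)
      data.table::fwrite(iso, pth("isoforms.tsv"), sep = "\t")
      data.table::fwrite(merge(stats, loc, by = "gene_id"),
                         pth("utr_length.tsv"), sep = "\t")
      manifest <- stage_log(manifest, "utr_length",
                            pth(c("isoforms.tsv", "utr_length.tsv")),
                            list(apa_genes = nrow(stats),
                                 localized = sum(loc$class != "ns")))
    }
  }

  # stage 6: binding preference (needs RIP)
  if (have("input") && have("rip")) {
    iso_rip <- build_isoform_table(cs, annotation, conditions,
                                   cond_a = "input", cond_b = "rip",
                                   min_expr = config$min_expr)
    if (nrow(iso_rip)) {
      ps <- proximal_sites_from_isoforms(iso_rip)
      sp <- split_proximal_distal(cs, ps, annotation)
      pr_in <- long_isoform_proportion(sp, conditions, "input")
      pr_rip <- long_isoform_proportion(sp, conditions, "rip")
      test_genes <- if (!is.null(targets))
        targets$gene_id[targets$is_target] else NULL
      bt <- tryCatch(
        binding_preference_test(pr_in, pr_rip, genes = test_genes),
        error = function(e) NULL)
      props <- rbind(pr_in, pr_rip)
      data.table::fwrite(props, pth("long_isoform_props.tsv"), sep = "\t")
      if (!is.null(bt))
        writeLines(jsonlite::toJSON(bt, auto_unbox = TRUE, digits = NA),
                   pth("binding_test.json"))
      manifest <- stage_log(manifest, "binding",
                            pth(c("long_isoform_props.tsv",
                                  if (!is.null(bt)) "binding_test.json")),
                            list(genes = length(unique(props$gene_id))))
    }
  }

  # stage 7: enrichment of targets among localized classes
  if (!is.null(targets) && !is.null(loc)) {
    bg <- loc$gene_id
    tg <- intersect(targets$gene_id[targets$is_target], bg)
    rows <- lapply(c("shorter_in_syn", "longer_in_syn"), function(cls) {
      cat_genes <- loc$gene_id[loc$class == cls]
      if (!length(cat_genes) || !length(tg)) return(NULL)
      en <- overlap_enrichment(tg, cat_genes, bg)
      data.frame(category = cls, overlap = en$overlap,
                 category_size = length(cat_genes), ratio = en$ratio,
                 odds_ratio = en$odds_ratio, p = en$p)
    })
    rows <- do.call(rbind, rows)
    if (!is.null(rows)) {
      data.table::fwrite(rows, pth("enrichment.tsv"), sep = "\t")
      manifest <- stage_log(manifest, "enrich", pth("enrichment.tsv"),
                            list(categories = nrow(rows)))
    }
  }

  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, force = TRUE),
             pth("manifest.json"))
  invisible(manifest)
}
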