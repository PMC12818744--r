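# End-to-end orchestration: a flat configuration, a discovery stage that
# writes the motif-statistics artifacts, and a design stage that writes
# the trio matrix and ranked peptide designs.  Every output is
# reproducible byte-for-byte from (inputs, config, seed); a JSON manifest
# records how each run was produced.

#' Pipeline configuration
#'
#' A flat key-value configuration; every field has a default and any
#' field can be supplied through `...` or read from a YAML file with
#' [read_pipeline_config()].  When `simulate` is TRUE the input paths are
#' ignored and a synthetic database is generated from `generator`.
#'
#' @param positive_fasta,region_tsv,negative_fasta Input paths
#'   (ignored under `simulate`).
#' @param motif_list Optional TSV of motifs for the design stage (else
#'   the discovery output is used).
#' @param output_dir Directory for artifacts.
#' @param simulate Generate inputs with [generate_database()].
#' @param k_min,k_max,cf_threshold Discovery settings.
#' @param top_k_trios,filter_ranges,kappa_na Design settings.
#' @param generator A [generator_config()] (used under `simulate`).
#' @param seed Integer master seed; stage seeds are derived at fixed
#'   offsets (simulation uses `seed`, any future stochastic stage would
#'   use `seed + 1000 * stage_index`).
#' @return `pipeline_config` list.
#' @export
pipeline_config <- function(positive_fasta = NULL, region_tsv = NULL,
                            negative_fasta = NULL, motif_list = NULL,
                            output_dir = "phasemotif_out", simulate = FALSE,
                            k_min = 3L, k_max = 6L, cf_threshold = 0.2,
                            top_k_trios = 10L,
                            filter_ranges = default_filter_ranges(),
                            kappa_na = "pass",
                            generator = NULL, seed = 1L) {
  if (is.null(generator)) generator <- generator_config(seed = seed)
  structure(list(positive_fasta = positive_fasta, region_tsv = region_tsv,
                 negative_fasta = negative_fasta, motif_list = motif_list,
                 output_dir = output_dir, simulate = simulate,
                 k_min = as.integer(k_min), k_max = as.integer(k_max),
                 cf_threshold = cf_threshold,
                 top_k_trios = as.integer(top_k_trios),
                 filter_ranges = filter_ranges, kappa_na = kappa_na,
                 generator = generator, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML key-value file
#'
#' @param path YAML file of scalar keys matching [pipeline_config()]
#'   arguments.
#' @param ... Overrides applied after the file.
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  vals <- utils::modifyList(vals, list(...))
  do.call(pipeline_config, vals)
}

pipeline_inputs <- function(config) {
  if (config$simulate) {
    gen <- config$generator
    gen$seed <- config$seed
    db <- generate_database(generator_config(
      n_positive = gen$n_positive, n_negative = gen$n_negative,
      protein_length_range = gen$protein_length_range,
      dpr_length_mean = gen$dpr_length_mean,
      nodpr_length_mean = gen$nodpr_length_mean,
      dprs_per_protein_range = gen$dprs_per_protein_range,
      composition_dpr = gen$composition_dpr,
      composition_nodpr = gen$composition_nodpr,
      composition_negative = gen$composition_negative,
      planted_motifs = gen$planted_motifs, seed = gen$seed))
    return(db)
  }
  for (p in c(config$positive_fasta, config$region_tsv, config$negative_fasta))
    if (is.null(p) || !file.exists(p))
      stop("input path missing or not found: ",
           if (is.null(p)) "(unset)" else p, call. = FALSE)
  pos <- read_fasta(config$positive_fasta)
  neg <- read_fasta(config$negative_fasta)
  regions <- read_regions(config$region_tsv)
  regions <- extract_region_sequences(pos, regions)
  neg$source_set <- "negative"
  pos$source_set <- "positive"
  list(records = rbind(pos, neg), regions = regions)
}

write_manifest <- function(config, dir, stage, files) {
  manifest <- list(
    stage = stage,
    seed = config$seed,
    config = config[setdiff(names(config), c("generator", "filter_ranges"))],
    filter_ranges = config$filter_ranges,
    files = files,
    package_version = as.character(utils::packageVersion("phasemotif")),
    r_version = R.version.string)
  jsonlite::write_json(manifest, file.path(dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null", force = TRUE)
}

#' Run the motif-discovery stage
#'
#' Loads or simulates the database, runs [discover_motifs()] (globally
#' and per family), and writes: `motif_stats.tsv` (all candidates with
#' folds and CF), `selected_motifs.tsv`, `per_region_counts.tsv`,
#' `per_family/<family>.tsv`, `motif_summary.tsv` (length distribution
#' and residue membership of the selected set), and a manifest.
#'
#' @param config A [pipeline_config()].
#' @return Invisible list with the in-memory results.
#' @export
run_discover <- function(config) {
  t0 <- Sys.time()
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- pipeline_inputs(config)
  records <- inputs$records
  regions <- inputs$regions
  dpr <- regions[regions$kind == "DPR", , drop = FALSE]
  nodpr <- regions[regions$kind == "NODPR", , drop = FALSE]
  neg_seqs <- records$sequence[records$source_set == "negative"]
  message("discover: ", nrow(dpr), " DPRs, ", nrow(nodpr), " NODPRs, ",
          length(neg_seqs), " negative proteins")

  res <- discover_motifs(dpr$subsequence, neg_seqs, config$k_min,
                         config$k_max, config$cf_threshold,
                         nodpr_sequences = nodpr$subsequence)
  pos_records <- records[records$source_set == "positive", , drop = FALSE]
  fam <- discover_per_family(pos_records, regions, neg_seqs, config$k_min,
                             config$k_max, config$cf_threshold)

  files <- c(motif_stats = file.path(config$output_dir, "motif_stats.tsv"),
             selected = file.path(config$output_dir, "selected_motifs.tsv"),
             per_region = file.path(config$output_dir, "per_region_counts.tsv"),
             summary = file.path(config$output_dir, "motif_summary.tsv"))
  write_motif_table(res$stats, files["motif_stats"])
  write_motif_table(res$selected, files["selected"])
  prc <- per_region_counts(res$selected$motif, dpr)
  utils::write.table(prc, files["per_region"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (nrow(res$selected))
    write_summary_tsv(motif_set_summary(res$selected$motif), files["summary"])
  famdir <- file.path(config$output_dir, "per_family")
  dir.create(famdir, showWarnings = FALSE)
  for (f in names(fam))
    write_motif_table(fam[[f]]$selected,
                      file.path(famdir, paste0(gsub("[^A-Za-z0-9-]", "_", f),
                                               ".tsv")))
  write_manifest(config, config$output_dir, "discover", as.list(files))
  message(sprintf("discover: done in %.1f s (%d candidates, %d selected)",
                  as.numeric(difftime(Sys.time(), t0, units = "secs")),
                  nrow(res$stats), nrow(res$selected)))
  invisible(list(records = records, regions = regions, discovery = res,
                 per_family = fam))
}

write_summary_tsv <- function(summ, path) {
  ld <- data.frame(table = "length_distribution",
                   key = summ$length_distribution$length,
                   count = summ$length_distribution$count,
                   percent = summ$length_distribution$percent)
  aa <- data.frame(table = "aa_membership",
                   key = summ$aa_membership$residue,
                   count = summ$aa_membership$count,
                   percent = summ$aa_membership$percent)
  utils::write.table(rbind(ld, aa), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the trio-scoring and peptide-design stage
#'
#' Takes a motif list (explicit `motif_list` TSV, or the selected motifs
#' of a prior/discovery run), scores all trios over the DPR sequences,
#' designs peptides from the top trios, and writes `trio_scores.tsv`,
#' `designs.tsv` and a manifest.
#'
#' @param config A [pipeline_config()].
#' @param discovery Optional result of [run_discover()] to reuse its
#'   database and selected motifs.
#' @return Invisible list with `trios` and `designs`.
#' @export
run_design <- function(config, discovery = NULL) {
  t0 <- Sys.time()
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(discovery)) discovery <- run_discover(config)
  motifs <- if (!is.null(config$motif_list))
    read_motif_table(config$motif_list)$motif
  else discovery$discovery$selected$motif
  if (length(motifs) < 3L)
    stop("design stage needs at least 3 motifs", call. = FALSE)
  dpr <- discovery$regions[discovery$regions$kind == "DPR", , drop = FALSE]
  trios <- score_all_trios(motifs, dpr$subsequence)
  designs <- design_peptides(trios, config$top_k_trios,
                             config$filter_ranges, config$kappa_na)
  files <- c(trios = file.path(config$output_dir, "trio_scores.tsv"),
             designs = file.path(config$output_dir, "designs.tsv"))
  utils::write.table(trios, files["trios"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(designs, files["designs"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_manifest(config, config$output_dir, "design", as.list(files))
  message(sprintf("design: %d trios, %d designs in %.1f s",
                  nrow(trios), nrow(designs),
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(list(trios = trios, designs = designs))
}
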