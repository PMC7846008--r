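# End-to-end orchestration: annotate -> cluster -> aggregate -> stats.

#' Pipeline configuration
#'
#' Collects every tunable parameter of the analysis with its default:
#' Calpha contact cutoff 5.0 A, connected-region cutoff 6.0 A, SASA probe
#' 1.4 A, soft-disorder thresholds {0.5, 1, 2, 3} with 1.0 as the primary,
#' clustering thresholds 0.9/0.9, NDI dissimilarity fraction 0.05, minimum
#' chain length 20.
#'
#' @param contact_cutoff Calpha contact cutoff in Angstrom.
#' @param region_cutoff connected-region linkage cutoff in Angstrom.
#' @param probe SASA probe radius in Angstrom.
#' @param thetas soft-disorder thresholds (sigma units), ascending.
#' @param theta_primary threshold used for USDR-based metrics.
#' @param static_b optional absolute B-factor threshold (static variant).
#' @param id_min,len_ratio_min clustering thresholds.
#' @param diff_frac NDI dissimilarity fraction (0.01 variant supported).
#' @param max_resolution optional resolution filter in Angstrom.
#' @param representative `"best"` or `"random"`.
#' @param seed integer seed for stochastic choices.
#' @param min_len minimum protein chain length.
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(contact_cutoff = 5.0, region_cutoff = 6.0,
                            probe = 1.4, thetas = c(0.5, 1, 2, 3),
                            theta_primary = 1, static_b = NULL,
                            id_min = 0.9, len_ratio_min = 0.9,
                            diff_frac = 0.05, max_resolution = NULL,
                            representative = "best", seed = 1L,
                            min_len = 20L) {
  stopifnot(contact_cutoff > 0, region_cutoff > 0, probe > 0,
            all(diff(thetas) > 0), theta_primary %in% thetas,
            diff_frac > 0, diff_frac < 1)
  structure(
    list(contact_cutoff = contact_cutoff, region_cutoff = region_cutoff,
         probe = probe, thetas = thetas, theta_primary = theta_primary,
         static_b = static_b, id_min = id_min,
         len_ratio_min = len_ratio_min, diff_frac = diff_frac,
         max_resolution = max_resolution, representative = representative,
         seed = as.integer(seed), min_len = as.integer(min_len)),
    class = "PipelineConfig"
  )
}

#' Run the full analysis pipeline
#'
#' Parses every PDB file in `input` (or accepts a list of already-parsed
#' `EntryStructure`s), annotates all usable protein chains, clusters
#' near-identical chains, summarizes every cluster, scores USDR(theta
#' primary) against UIR per cluster, and bins the per-cluster metrics over
#' NDI. Unreadable files are logged and skipped, never fatal. Deterministic
#' for a fixed config and seed.
#'
#' @param input directory containing `.pdb` files, or a list of
#'   `EntryStructure` objects.
#' @param config a `PipelineConfig`.
#' @param out_dir optional output directory for TSV/JSON/DOT reports.
#' @return invisibly, a list with `annotations`, `clusters`, `summaries`,
#'   `metrics` (per-cluster data.frame), `binned` (per-NDI-bin medians) and
#'   `log` (skipped files).
#' @export
run_pipeline <- function(input, config = pipeline_config(), out_dir = NULL) {
  log <- character(0)
  if (is.character(input)) {
    files <- sort(list.files(input, pattern = "\\.pdb$", full.names = TRUE))
    if (!length(files)) stop("no PDB files found in ", input)
    entries <- list()
    for (f in files) {
      e <- tryCatch(parse_pdb_entry(f), error = function(err) {
        log <<- c(log, sprintf("skipped %s: %s", basename(f),
                               conditionMessage(err)))
        NULL
      })
      if (!is.null(e)) entries[[e$entry_id]] <- e
    }
  } else {
    entries <- input
  }
  if (!length(entries)) stop("no parseable entries")

  annotations <- list()
  structures <- list()
  for (e in entries) {
    if (!isTRUE(e$is_xray)) {
      log <- c(log, sprintf("skipped %s: not X-ray", e$entry_id))
      next
    }
    for (ch in usable_protein_chains(e, min_len = config$min_len)) {
      ann <- tryCatch(
        annotate_chain(e, ch, thetas = config$thetas,
                       cutoff = config$contact_cutoff, probe = config$probe,
                       static_b = config$static_b),
        error = function(err) {
          log <<- c(log, sprintf("skipped %s_%s: %s", e$entry_id,
                                 ch$chain_id, conditionMessage(err)))
          NULL
        })
      if (is.null(ann)) next
      annotations[[ann$label]] <- ann
      structures[[ann$label]] <- ch
    }
  }
  if (!length(annotations)) stop("no usable protein chains")

  groups <- build_clusters(annotations, id_min = config$id_min,
                           len_ratio_min = config$len_ratio_min)
  clusters <- list()
  for (g in groups) {
    cl <- make_cluster(g, structures, mode = config$representative,
                       seed = config$seed,
                       max_resolution = config$max_resolution)
    if (!is.null(cl)) clusters[[cl$cluster_id]] <- cl
  }

  summaries <- lapply(clusters, summarize_cluster,
                      diff_frac = config$diff_frac,
                      region_cutoff = config$region_cutoff,
                      theta_primary = config$theta_primary)

  th <- as.character(config$theta_primary)
  metrics <- do.call(rbind, lapply(summaries, function(s)
    metrics_record(s$USDR[[th]], s$UIR, s$L_ref, cluster_id = s$cluster_id)))
  metrics$NDI <- vapply(summaries, `[[`, integer(1), "NDI")[metrics$cluster_id]
  rownames(metrics) <- NULL

  binned <- NULL
  scored <- metrics[metrics$NDI >= 1L & !is.na(metrics$PPV), , drop = FALSE]
  if (nrow(scored))
    binned <- binned_median(scored$PPV, scored$NDI, binning = "log2")

  result <- list(annotations = annotations, clusters = clusters,
                 summaries = summaries, metrics = metrics, binned = binned,
                 log = log, config = config)

  if (!is.null(out_dir)) .write_pipeline_outputs(result, out_dir)
  invisible(result)
}

.write_pipeline_outputs <- function(result, out_dir) {
  dir.create(file.path(out_dir, "annotations"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "summaries"), recursive = TRUE,
             showWarnings = FALSE)
  for (ann in result$annotations)
    write_annotation_tsv(ann, file.path(out_dir, "annotations",
                                        paste0(ann$label, ".tsv")))
  write_clusters_json(result$clusters, file.path(out_dir, "clusters.json"))
  for (s in result$summaries)
    write_summary(s, file.path(out_dir, "summaries"))
  m <- result$metrics
  num <- vapply(m, is.numeric, logical(1))
  m[num] <- lapply(m[num], function(v) sprintf("%.6g", v))
  write.table(m, file.path(out_dir, "metrics.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(result$binned)) {
    b <- result$binned
    num <- vapply(b, is.numeric, logical(1))
    b[num] <- lapply(b[num], function(v) sprintf("%.6g", v))
    write.table(b, file.path(out_dir, "binned.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  writeLines(c("# pipeline log", result$log),
             file.path(out_dir, "pipeline.log"))
  invisible(out_dir)
}
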