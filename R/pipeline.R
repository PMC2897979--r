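#' Run the chase analysis pipeline end to end
#'
#' Stages, in order: read and filter expression, optional scaling, decay
#' fitting (both estimators), genome-wide summary, operon validation and
#' typing (when an annotation is given), probe-level fits plus polymerase
#' velocity (when a probe table is given), and profile clustering with
#' functional enrichment (when categories are available). A missing
#' annotation or probe table skips the dependent stages with a logged
#' warning instead of failing the run. All outputs are TSV/JSON files under
#' `out_dir`; a manifest records the effective configuration, input
#' digests, per-stage row counts and output digests, so identical inputs,
#' seed and configuration reproduce identical files.
#'
#' @param expression path to the expression table (TSV or GEO series
#'   matrix).
#' @param out_dir output directory.
#' @param annotation,probes,qpcr optional paths to the annotation, probe
#'   and qPCR tables.
#' @param config a [pipeline_config()].
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(expression, out_dir, annotation = NULL,
                         probes = NULL, qpcr = NULL,
                         config = pipeline_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings <- character(0)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) stop("stage '", name, "': ",
                                            conditionMessage(e), call. = FALSE))
  }
  inputs <- c(expression = expression, annotation = annotation,
              probes = probes, qpcr = qpcr)

  expr <- stage("preprocess", {
    e <- read_expression(expression)
    e <- scale_matrix(e, config$scaling_scheme)
    e
  })
  flt <- filter_low_expression(expr, config$expression_threshold)
  est <- stage("fit", estimate_all(flt$kept, config))
  smry <- stage("summarize", summarize_decay(est, config))

  out <- list()
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
    out[[name]] <<- p
  }
  wr(est, "decay.tsv")

  ann <- NULL
  if (!is.null(annotation)) {
    ann <- read_annotation(annotation)
    ops <- stage("operons", {
      if (any(!is.na(ann$operon_id))) operon_calls(ann, flt$kept, config) else NULL
    })
    if (!is.null(ops)) wr(ops, "operons.tsv")
    dist <- ann %>% dplyr::filter(!is.na(.data$operon_id)) %>%
      dplyr::select("gene_id", distance_nt = "dist_to_operon_start_nt")
    if (nrow(dist) >= 3) {
      corr <- tryCatch(
        correlate_position_stability(est, dist, "half_life"),
        error = function(e) NULL)
      if (!is.null(corr)) smry$position_stability <- corr[c("r", "p", "n")]
    }
  } else {
    warnings <- c(warnings, "no annotation: operon stage skipped")
  }

  if (!is.null(probes)) {
    vel <- stage("probes", {
      pr <- read_probes(probes)
      fits <- probe_decay_fits(pr, config)
      polymerase_velocity(fits)
    })
    wr(vel$pairs, "velocity.tsv")
    smry$velocity <- vel[c("mean", "se", "median", "n_pairs", "n_excluded")]
  } else {
    warnings <- c(warnings, "no probe table: velocity stage skipped")
  }

  if (!is.null(ann) && "category" %in% names(ann)) {
    clus <- stage("cluster", {
      std <- standardize_profiles(flt$kept)
      if (nrow(std$profiles) <= 13) return(NULL)
      fit <- fuzzy_cmeans(std$profiles, c = min(12, nrow(std$profiles) - 1),
                          m = config$fuzzifier, seed = config$seed)
      cats <- ann %>% dplyr::filter(!is.na(.data$category)) %>%
        dplyr::select("gene_id", "category")
      enr <- enrichment_test(fit$cluster, cats)
      list(fit = fit, enr = enr)
    })
    if (!is.null(clus)) {
      wr(tibble::tibble(gene_id = names(clus$fit$cluster),
                        cluster = unname(clus$fit$cluster),
                        max_membership = apply(clus$fit$membership, 1, max),
                        well_supported = unname(clus$fit$well_supported)),
         "clusters.tsv")
      wr(clus$enr, "enrichment.tsv")
    }
  } else {
    warnings <- c(warnings, "no categories: cluster stage skipped")
  }

  smry_flat <- smry
  jsonlite::write_json(smry_flat, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out[["summary.json"]] <- file.path(out_dir, "summary.json")

  manifest <- list(
    package_version = as.character(utils::packageVersion("riftkin")),
    config = unclass(config),
    inputs = as.list(tools::md5sum(inputs[!vapply(inputs, is.null, logical(1))])),
    n_genes_kept = length(flt$kept_ids),
    n_genes_excluded = length(flt$excluded_ids),
    outputs = as.list(tools::md5sum(unlist(out))),
    warnings = warnings)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  for (w in warnings) message(w)
  invisible(manifest)
}

#' Human-readable run report
#'
#' Re-reads the emitted tables and renders a text summary (decay medians
#' with the ">cap" convention, stability fraction, operon and velocity
#' summaries). When ggplot2 is available and `plot_file` is given, decay
#' profile panels normalized to t = 0 are drawn for the requested genes.
#'
#' @param out_dir a [run_pipeline()] output directory.
#' @param expr optional long expression tibble for profile panels.
#' @param plot_genes gene ids to plot.
#' @param plot_file output file for the panels (pdf/png by extension).
#' @param config a [pipeline_config()].
#' @return character vector of report lines (also printed).
#' @export
make_report <- function(out_dir, expr = NULL, plot_genes = NULL,
                        plot_file = NULL, config = pipeline_config()) {
  est <- utils::read.delim(file.path(out_dir, "decay.tsv"))
  smry <- summarize_decay(tibble::as_tibble(est), config)
  lines <- c(
    sprintf("genes fitted: %d", smry$n_genes),
    sprintf("median half-life: %.2f min (80%% of genes in %.2f-%.2f min)",
            smry$median_half_life, smry$half_life_p10, smry$half_life_p90),
    sprintf("median decay rate: %.2f min", smry$median_decay_rate),
    sprintf("stable transcripts (> %g min or never declining): %.1f%%",
            config$stability_cutoff_min, 100 * smry$frac_stable))
  ops_path <- file.path(out_dir, "operons.tsv")
  if (file.exists(ops_path)) {
    ops <- utils::read.delim(ops_path)
    lines <- c(lines, sprintf(
      "operons: %d retained (%d type I, %d type II), %d weak expression, %d inconsistent",
      sum(ops$retained), sum(ops$type == "I", na.rm = TRUE),
      sum(ops$type == "II", na.rm = TRUE),
      sum(ops$reason == "weak_expression"),
      sum(ops$reason == "inconsistent_profiles")))
  }
  vel_path <- file.path(out_dir, "velocity.tsv")
  if (file.exists(vel_path)) {
    vel <- utils::read.delim(vel_path)
    lines <- c(lines, sprintf(
      "polymerase velocity: median %.2f nt/s over %d probe pairs",
      stats::median(vel$v_nt_per_s), nrow(vel)))
  }
  if (!is.null(plot_file) && !is.null(expr) && length(plot_genes) &&
      requireNamespace("ggplot2", quietly = TRUE)) {
    m <- collapse_replicates(expr %>% dplyr::filter(.data$id %in% plot_genes),
                             na_all = "na") %>%
      dplyr::group_by(.data$id) %>%
      dplyr::mutate(norm = .data$signal / .data$signal[.data$time == 0]) %>%
      dplyr::ungroup()
    p <- ggplot2::ggplot(m, ggplot2::aes(x = .data$time, y = .data$norm)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::facet_wrap(~id, scales = "free_y") +
      ggplot2::labs(x = "minutes after rifampicin", y = "signal / signal(t=0)")
    ggplot2::ggsave(plot_file, p, width = 8, height = 6)
    lines <- c(lines, sprintf("profile panels written to %s", plot_file))
  }
  writeLines(lines)
  invisible(lines)
}
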