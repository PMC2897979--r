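#' Genes eligible for sub-gene probe analysis
#'
#' The elongation-rate analysis uses genes at least 2 kb long that are
#' monocistronic or sit first in their operon, so every probe's delay is
#' measured from the transcript's own start.
#'
#' @param annotation annotation tibble.
#' @param min_length_nt minimum gene length.
#' @return character vector of gene ids.
#' @export
select_probe_genes <- function(annotation, min_length_nt = 2000) {
  ok <- annotation$length_nt >= min_length_nt &
    (is.na(annotation$operon_id) | annotation$operon_position == 1)
  annotation$gene_id[ok]
}

#' Decay fits for single probes
#'
#' Applies the twofold and two-phase estimators to each probe's series,
#' after the probe-level baseline filter (mean t = 0 signal at least
#' `config$probe_t0_threshold`). Genes left with fewer than 2 usable probes
#' are dropped from the velocity analysis.
#'
#' @param probes list with `positions` and `expr`, as from [read_probes()]
#'   or [simulate_probe_level()].
#' @param config a [pipeline_config()].
#' @return tibble `probe_id, gene_id, position_nt` plus the per-probe
#'   estimate columns of [estimate_all()].
#' @export
probe_decay_fits <- function(probes, config = pipeline_config()) {
  flt <- filter_low_expression(probes$expr, config$probe_t0_threshold)
  est <- estimate_all(flt$kept, config)
  names(est)[names(est) == "gene_id"] <- "probe_id"
  out <- dplyr::inner_join(probes$positions, est, by = "probe_id") %>%
    dplyr::arrange(.data$gene_id, .data$position_nt)
  usable <- out %>% dplyr::group_by(.data$gene_id) %>%
    dplyr::filter(dplyr::n() >= 2) %>% dplyr::ungroup()
  dropped <- setdiff(out$gene_id, usable$gene_id)
  if (length(dropped))
    message("dropped from velocity analysis (<2 usable probes): ",
            paste(dropped, collapse = ", "))
  usable
}

#' RNA polymerase elongation rate from probe pairs
#'
#' For each gene, every probe is paired with the gene's first (5'-most)
#' usable probe: s is their nucleotide distance, t the difference of their
#' decay estimates in minutes, and v = s / (60 t) nucleotides per second.
#' Pairs with t <= 0 (a downstream probe apparently no more stable) are
#' excluded and counted - a non-positive elongation rate is physically
#' meaningless. The global summary pools all retained pairs: mean,
#' standard error and median, computed for the chosen metric.
#'
#' @param probe_estimates output of [probe_decay_fits()].
#' @param metric `"half_life"` or `"decay_rate"`.
#' @return list with `pairs` (tibble `gene_id, probe_id, pair_s_nt,
#'   pair_t_min, v_nt_per_s`), `per_gene` mean velocities, `mean`, `se`,
#'   `median`, `n_pairs`, `n_excluded`.
#' @export
polymerase_velocity <- function(probe_estimates,
                                metric = c("half_life", "decay_rate")) {
  metric <- match.arg(metric)
  pairs <- lapply(split(probe_estimates, probe_estimates$gene_id), function(pr) {
    pr <- pr[order(pr$position_nt), ]
    v <- pr[[metric]]
    keep <- is.finite(v)
    pr <- pr[keep, ]; v <- v[keep]
    if (nrow(pr) < 2) return(NULL)
    tibble::tibble(gene_id = pr$gene_id[-1], probe_id = pr$probe_id[-1],
                   pair_s_nt = pr$position_nt[-1] - pr$position_nt[1],
                   pair_t_min = v[-1] - v[1])
  })
  pairs <- dplyr::bind_rows(pairs)
  if (!nrow(pairs)) stop("no probe pairs available")
  n_excluded <- sum(pairs$pair_t_min <= 0)
  retained <- pairs %>% dplyr::filter(.data$pair_t_min > 0) %>%
    dplyr::mutate(v_nt_per_s = .data$pair_s_nt / (60 * .data$pair_t_min))
  if (!nrow(retained)) stop("no retained probe pairs (all half-life differences <= 0)")
  per_gene <- retained %>% dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(mean_v = mean(.data$v_nt_per_s), n_pairs = dplyr::n(),
                     .groups = "drop")
  list(pairs = retained, per_gene = per_gene,
       mean = mean(retained$v_nt_per_s),
       se = stats::sd(retained$v_nt_per_s) / sqrt(nrow(retained)),
       median = stats::median(retained$v_nt_per_s),
       n_pairs = nrow(retained), n_excluded = n_excluded, metric = metric)
}
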