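#' Distance from the operon's first start codon
#'
#' Strand-aware nucleotide distance from the start codon of the operon's
#' first gene (position 1) to the focal gene's start codon: plus-strand
#' start codons sit at `start`, minus-strand ones at `end`. The first gene
#' is at distance 0; monocistrons return 0 with a flag.
#'
#' @param annotation annotation tibble (see [read_annotation()]).
#' @param gene_id focal gene.
#' @return list with `distance_nt` and `monocistron`.
#' @export
distance_to_operon_start <- function(annotation, gene_id) {
  g <- annotation[annotation$gene_id == gene_id, ]
  if (!nrow(g)) stop("gene '", gene_id, "' absent from the annotation")
  if (is.na(g$operon_id))
    return(list(distance_nt = 0, monocistron = TRUE))
  members <- annotation[!is.na(annotation$operon_id) &
                          annotation$operon_id == g$operon_id, ]
  first <- members[members$operon_position == 1, ]
  if (!nrow(first)) stop("operon '", g$operon_id, "' lacks a position-1 gene")
  d <- if (g$strand == "+") g$start - first$start else first$end - g$end
  if (d < 0) stop("negative distance for '", gene_id,
                  "': inconsistent operon coordinates")
  list(distance_nt = d, monocistron = FALSE)
}

#' Correlate operon position with RNA stability
#'
#' Spearman rank correlation (average ranks for ties) between distance from
#' the operon start and a decay estimate, with the two-sided p-value from
#' the large-sample t approximation. p-values below 1e-16 are reported at
#' that floor, matching the convention for extreme significance.
#'
#' @param estimates output of [estimate_all()].
#' @param distances tibble `gene_id, distance_nt`.
#' @param metric `"half_life"` or `"decay_rate"`.
#' @return list with `r`, `p` (floored), `p_label`, `n`.
#' @export
correlate_position_stability <- function(estimates, distances,
                                         metric = c("half_life", "decay_rate")) {
  metric <- match.arg(metric)
  merged <- dplyr::inner_join(estimates, distances, by = "gene_id")
  v <- merged[[metric]]
  keep <- is.finite(v) & v > 0
  x <- merged$distance_nt[keep]; y <- v[keep]
  if (length(x) < 3) stop("need at least 3 genes with both values")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    return(list(r = NA_real_, p = NA_real_, p_label = NA_character_,
                n = length(x), flag = "all_tied"))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  p <- max(ct$p.value, 1e-16)
  list(r = unname(ct$estimate), p = p,
       p_label = if (ct$p.value <= 1e-16) "<= 1e-16" else format(p, digits = 3),
       n = length(x))
}

#' Validate predicted operons against expression profiles
#'
#' An operon is excluded as `weak_expression` when the median t = 0 signal
#' across its members falls below the expression threshold (or fewer than
#' two members are expressed), and as `inconsistent_profiles` when any
#' adjacent pair of members has a Spearman correlation of their
#' t0-normalized mean profiles below `rho_min` - profiles that differ
#' between individual genes are inconsistent with one polycistronic
#' message. Retained operons carry reason `none`.
#'
#' @param annotation annotation tibble with operon columns.
#' @param expr long expression tibble.
#' @param config a [pipeline_config()] (uses `expression_threshold` and
#'   `operon_rho_min`).
#' @return tibble `operon_id, n_genes, retained, reason, median_t0,
#'   min_adjacent_rho`.
#' @export
validate_operons <- function(annotation, expr, config = pipeline_config()) {
  ops <- annotation %>% dplyr::filter(!is.na(.data$operon_id))
  mean_series <- collapse_replicates(expr %>%
                                       dplyr::filter(.data$id %in% ops$gene_id),
                                     na_all = "na")
  rows <- lapply(split(ops, ops$operon_id), function(mem) {
    mem <- mem[order(mem$operon_position), ]
    prof <- lapply(mem$gene_id, function(g) {
      s <- mean_series[mean_series$id == g, ]
      s$signal / s$signal[s$time == min(s$time)]
    })
    t0 <- vapply(mem$gene_id, function(g) {
      s <- mean_series[mean_series$id == g, ]
      s$signal[s$time == min(s$time)]
    }, numeric(1))
    med_t0 <- stats::median(t0, na.rm = TRUE)
    n_expressed <- sum(!is.na(t0) & t0 >= config$expression_threshold)
    if (n_expressed < 2 || med_t0 < config$expression_threshold) {
      return(tibble::tibble(operon_id = mem$operon_id[1], n_genes = nrow(mem),
                            retained = FALSE, reason = "weak_expression",
                            median_t0 = med_t0, min_adjacent_rho = NA_real_))
    }
    rho <- vapply(seq_len(nrow(mem) - 1), function(i) {
      suppressWarnings(stats::cor(prof[[i]], prof[[i + 1]], method = "spearman",
                                  use = "complete.obs"))
    }, numeric(1))
    ok <- min(rho, na.rm = TRUE) >= config$operon_rho_min
    tibble::tibble(operon_id = mem$operon_id[1], n_genes = nrow(mem),
                   retained = ok,
                   reason = if (ok) "none" else "inconsistent_profiles",
                   median_t0 = med_t0, min_adjacent_rho = min(rho, na.rm = TRUE))
  })
  dplyr::bind_rows(rows) %>% dplyr::arrange(.data$operon_id)
}

#' Classify an operon's decay profile
#'
#' Works on t0-normalized replicate-mean profiles. Each member's peak ratio
#' is its maximum normalized signal over t > 0. The operon is called type
#' II when any member at position >= 2 transiently rises: peak ratio at
#' least `1 + rise_threshold`, attained before the final timepoint and
#' followed by decline. Otherwise it is type I (plateau before decay).
#'
#' @param annotation annotation tibble with operon columns.
#' @param expr long expression tibble.
#' @param operon_id operon to classify.
#' @param config a [pipeline_config()] (uses `rise_threshold`).
#' @return list with `operon_id`, `type`, `max_peak_ratio`, `rise_threshold`
#'   and `members` tibble (`gene_id, position, peak_ratio, peak_time,
#'   onset_time`).
#' @export
classify_operon_profile <- function(annotation, expr, operon_id,
                                    config = pipeline_config()) {
  mem <- annotation[!is.na(annotation$operon_id) &
                      annotation$operon_id == operon_id, ]
  if (nrow(mem) < 2) stop("operon '", operon_id, "' has fewer than 2 annotated members")
  mem <- mem[order(mem$operon_position), ]
  mean_series <- collapse_replicates(expr %>%
                                       dplyr::filter(.data$id %in% mem$gene_id),
                                     na_all = "na")
  members <- lapply(seq_len(nrow(mem)), function(i) {
    s <- mean_series[mean_series$id == mem$gene_id[i], ]
    s <- s[order(s$time), ]
    norm <- s$signal / s$signal[1]
    late <- which(s$time > 0)
    pk <- late[which.max(norm[late])]
    rises <- norm[pk] >= 1 + config$rise_threshold &&
      pk < length(norm) && any(norm[(pk + 1):length(norm)] < norm[pk])
    tibble::tibble(gene_id = mem$gene_id[i], position = mem$operon_position[i],
                   peak_ratio = norm[pk], peak_time = s$time[pk],
                   onset_time = s$time[max(which(norm == max(norm)))],
                   transient_rise = rises)
  })
  members <- dplyr::bind_rows(members)
  type <- if (any(members$transient_rise & members$position >= 2)) "II" else "I"
  list(operon_id = operon_id, type = type,
       max_peak_ratio = max(members$peak_ratio),
       rise_threshold = config$rise_threshold, members = members)
}

#' Run the operon analysis end to end
#'
#' Validates each annotated operon and classifies the retained ones,
#' producing the per-operon call table.
#'
#' @param annotation annotation tibble.
#' @param expr long expression tibble.
#' @param config a [pipeline_config()].
#' @return tibble `operon_id, n_genes, retained, reason, type,
#'   min_adjacent_rho, max_peak_ratio`.
#' @export
operon_calls <- function(annotation, expr, config = pipeline_config()) {
  val <- validate_operons(annotation, expr, config)
  calls <- lapply(seq_len(nrow(val)), function(i) {
    if (!val$retained[i]) return(tibble::tibble(type = NA_character_,
                                                max_peak_ratio = NA_real_))
    cl <- classify_operon_profile(annotation, expr, val$operon_id[i], config)
    tibble::tibble(type = cl$type, max_peak_ratio = cl$max_peak_ratio)
  })
  dplyr::bind_cols(val, dplyr::bind_rows(calls))
}
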