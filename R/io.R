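#' Read a chase expression table
#'
#' Accepts the wide TSV dialect (`gene_id`/`probe_id`, `replicate`, then one
#' column per timepoint named `t0, t2.5, ...`) or a GEO series-matrix file,
#' auto-detected by its `!series_matrix_table_begin` sentinel. In the GEO
#' dialect, sample titles must encode the design as `..t<minutes>_rep<k>`.
#'
#' @param path input file.
#' @param timepoints if given, the minutes the file is required to contain;
#'   a missing time column is an error naming that column.
#' @return long tibble `id, replicate, time, signal`.
#' @export
read_expression <- function(path, timepoints = NULL) {
  head_lines <- readLines(path, n = 200L, warn = FALSE)
  if (any(grepl("^!series_matrix_table_begin", head_lines)) ||
      any(grepl("^!Sample_title", head_lines))) {
    return(.read_series_matrix(path, timepoints))
  }
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  id_col <- intersect(c("gene_id", "probe_id", "id"), names(df))[1]
  if (is.na(id_col)) stop("expression table needs a gene_id or probe_id column")
  if (!"replicate" %in% names(df)) stop("expression table needs a replicate column")
  tcols <- grep("^t[0-9]", names(df), value = TRUE)
  if (length(tcols) < 2) stop("no time columns (t0, t2.5, ...) found")
  if (!is.null(timepoints)) {
    want <- .time_label(timepoints)
    missing <- setdiff(want, tcols)
    if (length(missing))
      stop("missing required time column(s): ", paste(missing, collapse = ", "))
    tcols <- want
  }
  bad <- tcols[!vapply(df[tcols], is.numeric, logical(1))]
  if (length(bad)) stop("non-numeric signal in column(s): ", paste(bad, collapse = ", "))
  long <- df %>%
    tidyr::pivot_longer(dplyr::all_of(tcols), names_to = "tcol",
                        values_to = "signal") %>%
    dplyr::mutate(time = as.numeric(sub("^t", "", .data$tcol))) %>%
    dplyr::select(id = dplyr::all_of(id_col), "replicate", "time", "signal") %>%
    dplyr::arrange(.data$id, .data$replicate, .data$time)
  tibble::as_tibble(long)
}

.read_series_matrix <- function(path, timepoints = NULL) {
  lines <- readLines(path, warn = FALSE)
  title_line <- grep("^!Sample_title", lines, value = TRUE)
  if (!length(title_line)) stop("series matrix lacks !Sample_title")
  titles <- gsub('^"|"$', "", strsplit(title_line[1], "\t")[[1]][-1])
  m <- regmatches(titles, regexec("t([0-9.]+)_rep([0-9]+)", titles))
  if (any(vapply(m, length, integer(1)) != 3))
    stop("sample titles must encode ...t<minutes>_rep<k>")
  stime <- vapply(m, function(x) as.numeric(x[2]), numeric(1))
  srep <- vapply(m, function(x) as.integer(x[3]), integer(1))
  beg <- grep("^!series_matrix_table_begin", lines)
  fin <- grep("^!series_matrix_table_end", lines)
  if (!length(beg) || !length(fin)) stop("series matrix table sentinels not found")
  tab <- utils::read.delim(text = lines[(beg + 1):(fin - 1)],
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) != length(titles) + 1)
    stop("series matrix table does not match the sample metadata")
  if (!is.null(timepoints)) {
    missing <- setdiff(timepoints, unique(stime))
    if (length(missing))
      stop("missing required time column(s): ",
           paste(.time_label(missing), collapse = ", "))
  }
  long <- lapply(seq_along(titles), function(j) {
    tibble::tibble(id = as.character(tab[[1]]), replicate = srep[j],
                   time = stime[j], signal = as.numeric(tab[[j + 1]]))
  })
  dplyr::bind_rows(long) %>%
    dplyr::arrange(.data$id, .data$replicate, .data$time)
}

#' Write a minimal GEO-style series matrix
#'
#' Convenience inverse of the series-matrix reader, used to exercise the
#' accession-benchmark input path on locally generated data.
#'
#' @param expr long expression tibble.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_series_matrix <- function(expr, path) {
  keys <- expr %>% dplyr::distinct(.data$time, .data$replicate) %>%
    dplyr::arrange(.data$time, .data$replicate)
  titles <- sprintf("chase_%s_rep%d", .time_label(keys$time), keys$replicate)
  wide <- expr %>%
    dplyr::mutate(col = sprintf("chase_%s_rep%d", .time_label(.data$time),
                                .data$replicate)) %>%
    dplyr::select("id", "col", "signal") %>%
    tidyr::pivot_wider(names_from = "col", values_from = "signal")
  wide <- wide[, c("id", titles)]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste(c("!Sample_title", sprintf('"%s"', titles)), collapse = "\t"),
    "!series_matrix_table_begin",
    paste(c("ID_REF", titles), collapse = "\t")), con)
  utils::write.table(wide, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines("!series_matrix_table_end", con)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Columns: `gene_id, start, end, strand, length_nt, category, operon_id,
#' operon_position, dist_to_operon_start_nt`; coordinates 1-based inclusive;
#' `operon_id` empty for monocistrons.
#'
#' @param path input TSV.
#' @return tibble, one row per gene.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("gene_id", "start", "end", "strand", "length_nt")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("annotation lacks column(s): ", paste(missing, collapse = ", "))
  tibble::as_tibble(df)
}

#' Read a tiled probe table
#'
#' Probe metadata (`probe_id, gene_id, position_nt`) plus the replicate/time
#' signal columns, as written by [write_fixture()].
#'
#' @param path input TSV.
#' @return list with `positions` (metadata tibble) and `expr` (long series
#'   keyed by probe id).
#' @export
read_probes <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("probe_id", "gene_id", "position_nt", "replicate")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("probe table lacks column(s): ", paste(missing, collapse = ", "))
  tcols <- grep("^t[0-9]", names(df), value = TRUE)
  long <- df %>%
    tidyr::pivot_longer(dplyr::all_of(tcols), names_to = "tcol", values_to = "signal") %>%
    dplyr::mutate(time = as.numeric(sub("^t", "", .data$tcol))) %>%
    dplyr::select(id = "probe_id", "replicate", "time", "signal") %>%
    dplyr::arrange(.data$id, .data$replicate, .data$time)
  list(positions = df %>% dplyr::distinct(.data$probe_id, .data$gene_id,
                                          .data$position_nt) %>% tibble::as_tibble(),
       expr = tibble::as_tibble(long))
}

#' Partition genes by baseline expression
#'
#' A gene is kept iff its mean signal across replicates at t = 0 is at least
#' `threshold` (boundary values are kept). Genome-wide summaries are
#' restricted to the kept set.
#'
#' @param expr long expression tibble.
#' @param threshold linear-intensity threshold (>= 0).
#' @return list with `kept` and `excluded` long tibbles and the
#'   corresponding id vectors.
#' @export
filter_low_expression <- function(expr, threshold) {
  stopifnot(threshold >= 0)
  t0 <- expr %>%
    dplyr::filter(.data$time == min(.data$time)) %>%
    dplyr::group_by(.data$id) %>%
    dplyr::summarise(m = mean(.data$signal, na.rm = TRUE), .groups = "drop")
  kept_ids <- t0$id[t0$m >= threshold]
  excluded_ids <- setdiff(unique(expr$id), kept_ids)
  list(kept = expr %>% dplyr::filter(.data$id %in% kept_ids),
       excluded = expr %>% dplyr::filter(.data$id %in% excluded_ids),
       kept_ids = kept_ids, excluded_ids = excluded_ids)
}

#' Scale arrays to a common reference median
#'
#' Each array (one replicate at one timepoint) is multiplied by a single
#' constant so that the median of the reference set on that array equals the
#' grand median of those per-array medians. The reference set is all genes
#' (`all_genes_median`), the supplied spike-control ids (`spike_median`) or
#' designated stable RNA gene ids (`rna_gene_median`); `none` is the
#' identity. Within-array signal ratios are preserved exactly.
#'
#' @param expr long expression tibble.
#' @param scheme scaling scheme.
#' @param reference_ids ids of the reference set, required for the spike and
#'   RNA-gene schemes.
#' @return scaled long tibble.
#' @export
scale_matrix <- function(expr,
                         scheme = c("none", "all_genes_median",
                                    "spike_median", "rna_gene_median"),
                         reference_ids = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "none") return(expr)
  ref_ids <- if (scheme == "all_genes_median") unique(expr$id) else reference_ids
  if (!length(ref_ids)) stop("scheme '", scheme, "' needs a non-empty reference set")
  if (!all(ref_ids %in% expr$id))
    stop("reference ids absent from the expression table: ",
         paste(setdiff(ref_ids, expr$id), collapse = ", "))
  med <- expr %>%
    dplyr::filter(.data$id %in% ref_ids) %>%
    dplyr::group_by(.data$replicate, .data$time) %>%
    dplyr::summarise(array_median = stats::median(.data$signal, na.rm = TRUE),
                     .groups = "drop")
  grand <- stats::median(med$array_median)
  expr %>%
    dplyr::left_join(med, by = c("replicate", "time")) %>%
    dplyr::mutate(signal = .data$signal * grand / .data$array_median) %>%
    dplyr::select(-"array_median")
}

#' Collapse replicates to a mean series
#'
#' Per gene and timepoint: the mean over replicates, ignoring masked (NA)
#' values, with the standard error reported alongside.
#'
#' @param expr long expression tibble.
#' @param na_all what to do when every replicate is masked at some
#'   timepoint: `"error"` (default) or `"na"` (emit a masked mean).
#' @return tibble `id, time, signal, se, n_rep`.
#' @export
collapse_replicates <- function(expr, na_all = c("error", "na")) {
  na_all <- match.arg(na_all)
  out <- expr %>%
    dplyr::group_by(.data$id, .data$time) %>%
    dplyr::summarise(
      n_rep = sum(!is.na(.data$signal)),
      se = if (sum(!is.na(.data$signal)) > 1)
        stats::sd(.data$signal, na.rm = TRUE) / sqrt(sum(!is.na(.data$signal)))
      else NA_real_,
      signal = if (any(!is.na(.data$signal)))
        mean(.data$signal, na.rm = TRUE) else NA_real_,
      .groups = "drop") %>%
    dplyr::select("id", "time", "signal", "se", "n_rep") %>%
    dplyr::arrange(.data$id, .data$time)
  if (na_all == "error" && any(out$n_rep == 0))
    stop("all replicates masked at some timepoint for: ",
         paste(unique(out$id[out$n_rep == 0]), collapse = ", "))
  out
}
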