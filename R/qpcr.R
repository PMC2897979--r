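#' Read a qPCR Ct table
#'
#' Columns `gene_id, time, dCt`, where `dCt` is the mean threshold cycle of
#' the triplicate PCR reactions for that gene and timepoint.
#'
#' @param path input TSV.
#' @param reference_gene id of the endogenous reference transcript (default
#'   the RNase P RNA gene `rnpB`); must be measured at every timepoint.
#' @return tibble of class `qpcr_table` with attribute `reference_gene`.
#' @export
read_qpcr <- function(path, reference_gene = "rnpB") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("gene_id", "time", "dCt"), names(df))
  if (length(missing)) stop("qPCR table lacks column(s): ", paste(missing, collapse = ", "))
  qpcr_table(tibble::as_tibble(df), reference_gene)
}

#' Assemble a qPCR Ct table
#'
#' @param df tibble with `gene_id, time, dCt`.
#' @param reference_gene reference transcript id; must be present at every
#'   timepoint occurring in the table.
#' @return `df` with class `qpcr_table` and attribute `reference_gene`.
#' @export
qpcr_table <- function(df, reference_gene = "rnpB") {
  tp <- unique(df$time)
  ref_tp <- df$time[df$gene_id == reference_gene]
  if (!all(tp %in% ref_tp))
    stop("reference gene '", reference_gene, "' not measured at every timepoint")
  structure(df, class = c("qpcr_table", class(df)),
            reference_gene = reference_gene)
}

#' Relative expression from qPCR cycle thresholds
#'
#' The 2^-ddCt quantity: `2^-(dCt(gene) - dCt(reference))` per timepoint.
#' One PCR cycle difference is one twofold change, so the resulting series
#' is directly eligible for the same decay fitting as array series.
#'
#' @param q a [qpcr_table()].
#' @param gene gene id to quantify.
#' @return tibble `id, replicate, time, signal` (replicate 1), compatible
#'   with the decay fitters.
#' @export
qpcr_relative_expression <- function(q, gene) {
  ref <- attr(q, "reference_gene")
  g <- q[q$gene_id == gene, , drop = FALSE]
  if (!nrow(g)) stop("gene '", gene, "' absent from the qPCR table")
  r <- q[q$gene_id == ref, c("time", "dCt")]
  names(r)[2] <- "dCt_ref"
  merged <- dplyr::inner_join(tibble::as_tibble(g), tibble::as_tibble(r), by = "time")
  if (nrow(merged) < nrow(g))
    stop("reference measurement missing at some timepoint for gene '", gene, "'")
  tibble::tibble(id = gene, replicate = 1L, time = merged$time,
                 signal = 2^-(merged$dCt - merged$dCt_ref)) %>%
    dplyr::arrange(.data$time)
}

#' Array-versus-qPCR concordance
#'
#' Per gene, the Spearman rank correlation between the array expression
#' profile (replicate mean) and the qPCR relative-expression profile over
#' their shared timepoints, averaged over the gene set. Used to rank
#' scaling schemes (higher is better).
#'
#' @param array_expr long array expression tibble.
#' @param qpcr_expr long qPCR-derived expression tibble (e.g. rows of
#'   [qpcr_relative_expression()] bound together).
#' @param gene_set genes to score; must be present in both inputs.
#' @return list with `mean_spearman`, and `per_gene` tibble.
#' @export
concordance_score <- function(array_expr, qpcr_expr, gene_set) {
  if (!length(gene_set)) stop("empty gene set")
  absent <- setdiff(gene_set, intersect(array_expr$id, qpcr_expr$id))
  if (length(absent)) stop("genes absent from an input: ", paste(absent, collapse = ", "))
  a <- collapse_replicates(array_expr %>% dplyr::filter(.data$id %in% gene_set))
  b <- collapse_replicates(qpcr_expr %>% dplyr::filter(.data$id %in% gene_set))
  per_gene <- vapply(gene_set, function(g) {
    ga <- a[a$id == g, ]
    gb <- b[b$id == g, ]
    shared <- intersect(ga$time, gb$time)
    if (length(shared) < 3) stop("fewer than 3 shared timepoints for gene '", g, "'")
    stats::cor(ga$signal[match(shared, ga$time)],
               gb$signal[match(shared, gb$time)], method = "spearman")
  }, numeric(1))
  list(mean_spearman = mean(per_gene),
       per_gene = tibble::tibble(gene_id = gene_set, spearman = unname(per_gene)))
}
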