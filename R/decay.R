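#' Fit one exponential decay segment
#'
#' Ordinary least squares of log2 signal on time. The decay constant k is
#' minus the slope (positive k = decline); its reciprocal is the segment's
#' characteristic time per twofold change in minutes. With exactly two
#' points the fit passes through both and the MSE is zero.
#'
#' @param t minutes at the segment's points.
#' @param signal positive linear intensities (mask non-positive values
#'   upstream).
#' @return list with `k` (per min), `twofold_time` (min; `Inf` for a flat
#'   segment, negative for a rising one), `mse` (mean squared log2
#'   residual), `n` and `window`.
#' @export
fit_exponential_segment <- function(t, signal) {
  keep <- !is.na(t) & !is.na(signal)
  t <- t[keep]; signal <- signal[keep]
  if (length(t) < 2) stop("need at least 2 points to fit a segment")
  if (any(signal <= 0)) stop("non-positive signal; mask before log fitting")
  l <- log2(signal)
  tm <- mean(t); lm_ <- mean(l)
  slope <- sum((t - tm) * (l - lm_)) / sum((t - tm)^2)
  k <- -slope
  resid <- l - (lm_ + slope * (t - tm))
  list(k = k,
       twofold_time = if (k == 0) Inf else 1 / k,
       mse = mean(resid^2), n = length(t), window = range(t))
}

#' Half-life by the twofold decay-step method
#'
#' Finds the earliest sampled timepoint at which the signal has dropped to
#' half (or less) of its t = 0 level, fits an exponential through t = 0 and
#' that point, and reports the fitted time per twofold change. When no
#' twofold decrease occurs within the horizon, an all-timepoint fit is used
#' instead (its twofold time can exceed the horizon, or be negative for a
#' rising signal) and the transcript is flagged stable.
#'
#' @param t sampled minutes (replicate-mean series).
#' @param signal positive signals at `t`; NAs are masked.
#' @param horizon last minute considered for the twofold search.
#' @return list with `half_life` (min), `stable`, `method`
#'   (`"twofold"`/`"fallback"`) and `t_half` (the detection timepoint, NA
#'   for fallback).
#' @export
twofold_half_life <- function(t, signal, horizon = 60) {
  keep <- !is.na(signal) & !is.na(t)
  t <- t[keep]; signal <- signal[keep]
  if (length(t) < 2) stop("unfittable series: fewer than 2 usable points")
  o <- order(t); t <- t[o]; signal <- signal[o]
  if (any(signal <= 0)) stop("non-positive signal; mask before fitting")
  e0 <- signal[1]
  j <- which(t > t[1] & t <= horizon & signal <= e0 / 2)
  if (length(j)) {
    j <- j[1]
    fit <- fit_exponential_segment(t[c(1, j)], signal[c(1, j)])
    list(half_life = fit$twofold_time, stable = FALSE,
         method = "twofold", t_half = t[j])
  } else {
    fit <- fit_exponential_segment(t, signal)
    list(half_life = fit$twofold_time, stable = TRUE,
         method = "fallback", t_half = NA_real_)
  }
}

#' Relative two-phase decay fit
#'
#' Decay is fit as two successive exponentials on the log2 scale. The onset
#' `t_on` is the last sampled timepoint attaining the series maximum (t = 0
#' when expression is maximal there), so rates are measured relative to the
#' point of maximal expression. Every sampled timepoint strictly between
#' `t_on` and the last timepoint is tried as the breakpoint `x`; `x` belongs
#' to both segments, and the fit minimizing the pooled MSE of the logged
#' data (squared log2 residuals of both segments over their total point
#' count, the breakpoint counted twice) is kept, ties going to the earliest
#' `x`. The reported decay rate is the first segment's time per twofold
#' change.
#'
#' @param t sampled minutes (replicate-mean series).
#' @param signal positive signals at `t`; NAs are masked.
#' @return list with `ok`, `t_on`, `breakpoint`, `fit1`, `fit2`, `mse` and
#'   `decay_rate` (min); `ok = FALSE` (with reason) when fewer than 4
#'   usable points remain at or after the onset.
#' @export
two_phase_fit <- function(t, signal) {
  keep <- !is.na(signal) & !is.na(t)
  t <- t[keep]; signal <- signal[keep]
  o <- order(t); t <- t[o]; signal <- signal[o]
  if (any(signal <= 0)) stop("non-positive signal; mask before fitting")
  i_on <- max(which(signal == max(signal)))
  tt <- t[i_on:length(t)]; yy <- signal[i_on:length(signal)]
  n <- length(tt)
  if (n < 4)
    return(list(ok = FALSE, reason = "fewer than 4 points after onset",
                t_on = tt[1], breakpoint = NA_real_, decay_rate = NA_real_,
                mse = NA_real_))
  cand <- 2:(n - 1)
  fits <- lapply(cand, function(ci) {
    f1 <- fit_exponential_segment(tt[1:ci], yy[1:ci])
    f2 <- fit_exponential_segment(tt[ci:n], yy[ci:n])
    list(ci = ci, f1 = f1, f2 = f2,
         mse = (f1$mse * f1$n + f2$mse * f2$n) / (f1$n + f2$n))
  })
  mses <- vapply(fits, `[[`, numeric(1), "mse")
  # earliest breakpoint among numerical ties (floating-point jitter must not
  # override the tie rule for exact fits)
  best <- fits[[which(mses <= min(mses) + max(1e-12, 1e-9 * min(mses)))[1]]]
  list(ok = TRUE, t_on = tt[1], breakpoint = tt[best$ci],
       fit1 = best$f1, fit2 = best$f2, mse = best$mse,
       decay_rate = best$f1$twofold_time)
}

#' Estimate decay kinetics for every gene
#'
#' Applies both estimators to the replicate-mean series of each gene:
#' half-life by the twofold decay-step method and decay rate by the
#' relative two-phase model. Standard errors come from per-replicate
#' refits. Non-positive or missing intensities are masked per point; genes
#' with fewer than 4 usable timepoints are flagged unfittable rather than
#' aborting the run.
#'
#' @param expr long expression tibble (`id, replicate, time, signal`).
#' @param config a [pipeline_config()].
#' @return tibble `gene_id, half_life, half_life_se, decay_rate,
#'   decay_rate_se, t_on, breakpoint, stable, n_points, flags`.
#' @export
estimate_all <- function(expr, config = pipeline_config()) {
  expr <- expr %>% dplyr::mutate(signal = ifelse(!is.na(.data$signal) &
                                                   .data$signal <= 0,
                                                 NA_real_, .data$signal))
  mean_series <- collapse_replicates(expr, na_all = "na")
  horizon <- max(expr$time)
  reps <- sort(unique(expr$replicate))
  by_gene <- split(mean_series, mean_series$id)
  rep_split <- split(expr, list(expr$id, expr$replicate), drop = TRUE)

  rows <- lapply(names(by_gene), function(g) {
    s <- by_gene[[g]]
    usable <- !is.na(s$signal)
    if (sum(usable) < 4) {
      return(tibble::tibble(gene_id = g, half_life = NA_real_,
                            half_life_se = NA_real_, decay_rate = NA_real_,
                            decay_rate_se = NA_real_, t_on = NA_real_,
                            breakpoint = NA_real_, stable = NA,
                            n_points = sum(usable), flags = "unfittable"))
    }
    tf <- twofold_half_life(s$time, s$signal, horizon = horizon)
    tp <- two_phase_fit(s$time, s$signal)
    rep_vals <- vapply(reps, function(r) {
      rs <- rep_split[[paste(g, r, sep = ".")]]
      if (is.null(rs) || sum(!is.na(rs$signal)) < 4) return(c(NA_real_, NA_real_))
      htf <- tryCatch(twofold_half_life(rs$time, rs$signal, horizon = horizon)$half_life,
                      error = function(e) NA_real_)
      htp <- tryCatch({
        f <- two_phase_fit(rs$time, rs$signal)
        if (f$ok) f$decay_rate else NA_real_
      }, error = function(e) NA_real_)
      c(htf, htp)
    }, numeric(2))
    se_of <- function(v) {
      v <- v[is.finite(v)]
      if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
    }
    stable <- tf$stable || tf$half_life < 0 ||
      tf$half_life > config$stability_cutoff_min
    tibble::tibble(
      gene_id = g, half_life = tf$half_life, half_life_se = se_of(rep_vals[1, ]),
      decay_rate = if (tp$ok) tp$decay_rate else NA_real_,
      decay_rate_se = se_of(rep_vals[2, ]),
      t_on = if (tp$ok) tp$t_on else NA_real_,
      breakpoint = if (tp$ok) tp$breakpoint else NA_real_,
      stable = stable, n_points = sum(usable),
      flags = paste(c(if (tf$method == "fallback") "no_twofold",
                      if (!tp$ok) "two_phase_unfittable"), collapse = ";"))
  })
  dplyr::bind_rows(rows)
}

#' Genome-wide decay summaries
#'
#' Medians of the half-life and decay rate, the central-80% half-life
#' interval (10th/90th percentiles), and the stable fraction. Medians and
#' percentiles are taken over genes with positive finite estimates (stable
#' transcripts with fallback fits, whose values can be arbitrarily large or
#' negative, are counted in `frac_stable` instead); a subset median can
#' additionally censor values above the report cap, the convention used
#' when summarizing compendia printed with ">cap" entries.
#'
#' @param estimates output of [estimate_all()].
#' @param config a [pipeline_config()].
#' @param subset_ids optional gene ids restricting a secondary summary
#'   (e.g. an ncRNA/asRNA set).
#' @return list of summary scalars (and `subset`, when requested).
#' @export
summarize_decay <- function(estimates, config = pipeline_config(),
                            subset_ids = NULL) {
  if (!nrow(estimates)) stop("empty estimate table")
  hl <- estimates$half_life
  dr <- estimates$decay_rate
  pos_hl <- hl[is.finite(hl) & hl > 0 & !estimates$stable]
  pos_dr <- dr[is.finite(dr) & dr > 0 & !estimates$stable]
  out <- list(
    n_genes = nrow(estimates),
    median_half_life = stats::median(pos_hl),
    median_decay_rate = stats::median(pos_dr),
    half_life_p10 = unname(stats::quantile(pos_hl, 0.1, type = 7)),
    half_life_p90 = unname(stats::quantile(pos_hl, 0.9, type = 7)),
    frac_stable = mean(estimates$stable, na.rm = TRUE))
  if (!is.null(subset_ids)) {
    sub <- estimates[estimates$gene_id %in% subset_ids, ]
    if (!nrow(sub)) stop("empty subset")
    out$subset <- list(
      n = nrow(sub),
      median_decay_rate = censored_median(sub$decay_rate,
                                          cap = config$decay_rate_report_cap))
  }
  out
}

#' Median of a capped decay-rate compendium
#'
#' Values above the report cap (rendered ">cap" in formatted tables) and
#' negative fallback values are censored; the median is taken over the
#' remaining finite values.
#'
#' @param values decay rates in minutes.
#' @param cap report cap in minutes.
#' @return median of the uncensored values.
#' @export
censored_median <- function(values, cap = 20) {
  v <- values[is.finite(values) & values > 0 & values <= cap]
  if (!length(v)) stop("no uncensored values")
  stats::median(v)
}

#' Render decay rates with the report-cap convention
#'
#' @param x decay rates in minutes.
#' @param cap values above the cap (or negative, i.e. non-declining) are
#'   printed `">cap"`.
#' @param digits rounding for uncensored values.
#' @return character vector.
#' @export
format_decay_rate <- function(x, cap = 20, digits = 1) {
  ifelse(!is.finite(x) | x > cap | x < 0, paste0(">", cap),
         formatC(round(x, digits), format = "f", digits = digits))
}

#' Measured decay rates of ncRNAs and asRNAs in Prochlorococcus MED4
#'
#' The published compendium of decay rates for the expressed non-coding and
#' antisense RNAs of the MED4 rifampicin chase (tRNAs and rRNAs excluded).
#' Stable housekeeping RNAs are censored at the 20-minute report cap.
#'
#' @return tibble `name, decay_rate_label, decay_rate_min, censored`.
#' @export
med4_ncrna_decay_rates <- function() {
  path <- system.file("extdata", "med4_ncrna_decay_rates.tsv",
                      package = "riftkin", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  tibble::tibble(
    name = df$name,
    decay_rate_label = df$decay_rate,
    decay_rate_min = suppressWarnings(as.numeric(df$decay_rate)),
    censored = is.na(suppressWarnings(as.numeric(df$decay_rate))))
}
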