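#' Chase experiment design
#'
#' Describes the sampling layout of a rifampicin chase: which minutes after
#' transcription arrest are sampled, how many biological replicates, the
#' multiplicative noise level and the saturation ceiling of the scanner.
#'
#' @param timepoints minutes after rifampicin addition; strictly increasing,
#'   first must be 0 (the pre-arrest sample).
#' @param replicates number of biological replicates (cultures).
#' @param noise_sigma standard deviation of multiplicative noise on the
#'   natural-log scale (0.1 corresponds to ~10% intensity scatter).
#' @param saturation_cap maximum reportable linear intensity; signals are
#'   hard-clipped here, emulating array saturation of highly expressed genes.
#' @param seed integer seed of the fixture's RNG stream.
#' @return list of class `chase_design`.
#' @export
chase_design <- function(timepoints = CHASE_TIMEPOINTS, replicates = 3,
                         noise_sigma = 0.1, saturation_cap = Inf, seed = 1L) {
  stopifnot(length(timepoints) >= 2, timepoints[1] == 0,
            all(diff(timepoints) > 0), replicates >= 1,
            noise_sigma >= 0, saturation_cap > 0)
  structure(list(timepoints = as.numeric(timepoints),
                 replicates = as.integer(replicates),
                 noise_sigma = noise_sigma,
                 saturation_cap = saturation_cap,
                 seed = as.integer(seed)),
            class = "chase_design")
}

#' True kinetic parameters of one transcript
#'
#' The generative counterpart of the two-phase decay model: an optional
#' pre-decay ramp (constant plateau when `rise_amplitude = 0`) until the
#' onset delay `d`, a first exponential phase with half-life `h1` until the
#' phase break `b`, then a continuous switch to half-life `h2`.
#'
#' @param gene_id transcript identifier.
#' @param E0 baseline linear intensity at t = 0; must be positive.
#' @param d onset delay in minutes (time before decline starts).
#' @param h1,h2 fast and slow half-lives in minutes, `0 < h1 <= h2`.
#' @param b phase break in minutes, must exceed `d`.
#' @param a rise amplitude: the plateau ramps linearly from `E0` at t = 0 to
#'   `(1 + a) * E0` at t = d. `a = 0` gives a flat plateau; `a > 0` requires
#'   `d > 0`.
#' @param operon_id,operon_position,dist_nt,length_nt optional annotation
#'   carried into ground-truth tables.
#' @return list of class `true_kinetics`.
#' @export
true_kinetics <- function(gene_id, E0, d = 0, h1, h2 = h1, b = d + 10, a = 0,
                          operon_id = NA_character_, operon_position = NA_integer_,
                          dist_nt = 0, length_nt = 800) {
  stopifnot(E0 > 0, d >= 0, h1 > 0, h2 >= h1, b > d, a >= 0)
  if (a > 0 && d <= 0) stop("a rise (a > 0) requires a positive onset delay d")
  structure(list(gene_id = gene_id, E0 = E0, d = d, h1 = h1, h2 = h2,
                 b = b, a = a, operon_id = operon_id,
                 operon_position = operon_position, dist_nt = dist_nt,
                 length_nt = length_nt),
            class = "true_kinetics")
}

#' Noise-free signal of a transcript at time t
#'
#' Piecewise continuous model: linear ramp (or plateau) on `[0, d)`, decay at
#' half-life `h1` on `[d, b)`, decay at half-life `h2` from `b` on, with the
#' level matched at each boundary.
#'
#' @param k a [true_kinetics()] object.
#' @param t minutes (vectorized), `t >= 0`.
#' @return linear-intensity signal, same length as `t`.
#' @export
noiseless_signal <- function(k, t) {
  stopifnot(inherits(k, "true_kinetics"), all(t >= 0))
  out <- numeric(length(t))
  ramp <- t < k$d
  out[ramp] <- k$E0 * (1 + k$a * t[ramp] / k$d)
  phase1 <- !ramp & t < k$b
  out[phase1] <- k$E0 * (1 + k$a) * 2^(-(t[phase1] - k$d) / k$h1)
  phase2 <- t >= k$b
  level_b <- k$E0 * (1 + k$a) * 2^(-(k$b - k$d) / k$h1)
  out[phase2] <- level_b * 2^(-(t[phase2] - k$b) / k$h2)
  out
}

#' Simulate one transcript's chase series
#'
#' Applies independent multiplicative log-normal noise per replicate and
#' timepoint, then clips at the design's saturation cap. The RNG stream is
#' derived from the design seed and the gene id, so draws are reproducible
#' and independent of which other genes are simulated.
#'
#' @param k a [true_kinetics()] object.
#' @param design a [chase_design()].
#' @return long tibble `id, replicate, time, signal`.
#' @export
simulate_gene <- function(k, design) {
  stopifnot(inherits(design, "chase_design"))
  tp <- design$timepoints
  base <- noiseless_signal(k, tp)
  eps <- withr::with_seed(.gene_seed(design$seed, k$gene_id), {
    matrix(rnorm(design$replicates * length(tp), sd = design$noise_sigma),
           nrow = design$replicates, byrow = TRUE)
  })
  sig <- pmin(design$saturation_cap,
              rep(base, each = design$replicates) * exp(as.vector(eps)))
  tibble::tibble(
    id = k$gene_id,
    replicate = rep(seq_len(design$replicates), times = length(tp)),
    time = rep(tp, each = design$replicates),
    signal = sig
  )
}

.kinetics_row <- function(k) {
  tibble::tibble(gene_id = k$gene_id, E0 = k$E0, onset_delay = k$d,
                 fast_half_life = k$h1, slow_half_life = k$h2,
                 phase_break = k$b, rise_amplitude = k$a,
                 operon_id = k$operon_id, operon_position = k$operon_position,
                 dist_to_operon_start_nt = k$dist_nt,
                 gene_length_nt = k$length_nt)
}

.simulate_kinetics_set <- function(kin_list, design) {
  list(truth = dplyr::bind_rows(lapply(kin_list, .kinetics_row)),
       expr = dplyr::bind_rows(lapply(kin_list, simulate_gene, design = design)),
       design = design)
}

#' Simulate a polycistronic operon
#'
#' Gene g sits `(g - 1) * spacing_nt` nucleotides from the operon's first
#' start codon; its decay onset is delayed by the polymerase travel time
#' `s / (60 * velocity)` minutes and its half-life grows with distance
#' (`stability_slope_min_per_kb`). Type I operons plateau before declining;
#' in type II operons downstream members transiently rise before decay, with
#' the rise amplitude growing toward `rise_max` at the distal end.
#'
#' @param n_genes number of members (>= 2).
#' @param spacing_nt start-codon to start-codon distance between neighbours.
#' @param velocity_nt_per_s polymerase elongation rate driving the onset
#'   delays.
#' @param profile_type `"I"` (plateau) or `"II"` (transient rise).
#' @param design a [chase_design()].
#' @param h1_first first member's fast half-life (min).
#' @param stability_slope_min_per_kb half-life increase per kb of distance.
#' @param E0_first first member's baseline intensity; downstream members are
#'   attenuated by `E0_atten` per position (distal operon regions are more
#'   weakly expressed).
#' @param E0_atten per-position attenuation factor.
#' @param rise_max distal rise amplitude for type II operons (1 = twofold
#'   peak).
#' @param operon_id,gene_prefix identifiers for the emitted rows.
#' @return list with `truth` (ground-truth tibble), `expr` (long series) and
#'   `design`.
#' @export
simulate_operon <- function(n_genes, spacing_nt = 1000, velocity_nt_per_s = 5,
                            profile_type = c("I", "II"), design = chase_design(),
                            h1_first = 2.5, stability_slope_min_per_kb = 0.8,
                            E0_first = 1000, E0_atten = 0.9, rise_max = 1,
                            operon_id = "op1", gene_prefix = operon_id) {
  profile_type <- match.arg(profile_type)
  if (n_genes < 2) stop("an operon needs at least 2 genes")
  s <- (seq_len(n_genes) - 1) * spacing_nt
  d <- s / (60 * velocity_nt_per_s)
  h1 <- h1_first + stability_slope_min_per_kb * s / 1000
  a <- if (profile_type == "II") rise_max * s / max(s) else rep(0, n_genes)
  kin <- lapply(seq_len(n_genes), function(g) {
    true_kinetics(gene_id = sprintf("%s_g%d", gene_prefix, g),
                  E0 = E0_first * E0_atten^(g - 1),
                  d = d[g], h1 = h1[g], h2 = h1[g], b = d[g] + 10, a = a[g],
                  operon_id = operon_id, operon_position = g,
                  dist_nt = s[g], length_nt = spacing_nt)
  })
  out <- .simulate_kinetics_set(kin, design)
  out$profile_type <- profile_type
  out
}

#' Simulate tiled probe-level series along one long gene
#'
#' Probes sit every `probe_spacing_nt` nucleotides from the start codon
#' (positions 0, 80, 160, ... < gene length). The probe at position p
#' inherits the gene's kinetics with its onset delay increased by the
#' polymerase travel time `p / (60 * velocity)` and its half-life increased
#' by `slow_slope_min_per_kb * p / 1000` (decay also slows along the
#' transcript).
#'
#' @param gene_length_nt gene length; must be >= 2000 when
#'   `for_velocity = TRUE` (elongation-rate analysis uses genes of at least
#'   2 kb).
#' @param probe_spacing_nt tiling step (the array has a probe pair every
#'   80 nt).
#' @param velocity_nt_per_s true polymerase elongation rate.
#' @param design a [chase_design()].
#' @param E0,h1 baseline intensity and fast half-life at the 5' end.
#' @param slow_slope_min_per_kb half-life increase per kb along the gene.
#' @param gene_id identifier; probe ids are `<gene_id>_p<position>`.
#' @param for_velocity tag the fixture for elongation-rate analysis
#'   (enforces the 2 kb minimum).
#' @return list with `truth`, `expr` (ids are probe ids), `positions`
#'   (tibble `probe_id, gene_id, position_nt`) and `design`.
#' @export
simulate_probe_level <- function(gene_length_nt, probe_spacing_nt = 80,
                                 velocity_nt_per_s = 5, design = chase_design(),
                                 E0 = 1000, h1 = 2.5, slow_slope_min_per_kb = 0.5,
                                 gene_id = "gene1", for_velocity = TRUE) {
  if (for_velocity && gene_length_nt < 2000)
    stop("elongation-rate fixtures need genes of at least 2000 nt")
  pos <- seq(0, gene_length_nt - 1, by = probe_spacing_nt)
  kin <- lapply(pos, function(p) {
    true_kinetics(gene_id = sprintf("%s_p%05d", gene_id, p),
                  E0 = E0, d = p / (60 * velocity_nt_per_s),
                  h1 = h1 + slow_slope_min_per_kb * p / 1000,
                  b = p / (60 * velocity_nt_per_s) + 10,
                  length_nt = gene_length_nt)
  })
  out <- .simulate_kinetics_set(kin, design)
  out$positions <- tibble::tibble(
    probe_id = vapply(kin, function(k) k$gene_id, character(1)),
    gene_id = gene_id, position_nt = pos)
  out
}

#' Simulate a genome-scale chase fixture
#'
#' Monocistrons plus operons, with kinetics drawn to emulate the measured
#' transcriptome-wide conditions: a log-normal half-life distribution with
#' median ~2.4 min and an 80% range of roughly 1.1-8.9 min, ~3% stable
#' transcripts (flat profiles, mostly structural RNA genes), a fraction of
#' genes with two decay phases, and operons split ~82/18 between plateau
#' (type I) and transient-rise (type II) profiles.
#'
#' @param n_genes total number of transcripts, including operon members.
#' @param n_operons number of operons (3-6 members each).
#' @param design a [chase_design()]; its seed drives all draws.
#' @param frac_stable,frac_two_phase,frac_delayed mixture fractions for
#'   monocistrons.
#' @param frac_type_II fraction of operons with transient-rise profiles.
#' @param median_h1,sdlog_h1 log-normal half-life distribution parameters.
#' @return list with `truth`, `expr`, `annotation` (coordinates, strand,
#'   category, operon structure) and `design`.
#' @export
simulate_genome <- function(n_genes = 1000, n_operons = 50,
                            design = chase_design(),
                            frac_stable = 0.03, frac_two_phase = 0.3,
                            frac_delayed = 0.1, frac_type_II = 9 / 50,
                            median_h1 = 2.4, sdlog_h1 = 0.82) {
  op_sizes <- if (n_operons > 0) {
    withr::with_seed(.gene_seed(design$seed, "operon-sizes"),
                     sample(3:6, n_operons, replace = TRUE))
  } else integer(0)
  n_in_operons <- sum(op_sizes)
  n_mono <- n_genes - n_in_operons
  if (n_mono < 0) stop("n_genes too small for the requested operons")

  draws <- withr::with_seed(.gene_seed(design$seed, "genome-kinetics"), {
    list(E0 = exp(rnorm(n_mono, log(500), 1.2)),
         h1 = median_h1 * exp(rnorm(n_mono, 0, sdlog_h1)),
         class_u = runif(n_mono),
         b = sample(c(5, 10, 20), n_mono, replace = TRUE),
         slow = runif(n_mono, 2, 6),
         delay = sample(c(2.5, 5), n_mono, replace = TRUE),
         len = round(runif(n_mono, 400, 2000)),
         strand = sample(c("+", "-"), n_mono + n_operons, replace = TRUE),
         op_h1 = median_h1 * exp(rnorm(max(n_operons, 1), 0, sdlog_h1 / 2)),
         op_type = runif(max(n_operons, 1)))
  })
  kin <- vector("list", n_mono)
  category <- character(n_mono)
  cats <- c("amino acid biosynthesis", "photosynthesis", "translation",
            "transport", "cell envelope", "hypothetical")
  for (i in seq_len(n_mono)) {
    u <- draws$class_u[i]
    gid <- sprintf("PMS%04d", i)
    if (u < frac_stable) {
      kin[[i]] <- true_kinetics(gid, E0 = draws$E0[i] * 4, h1 = 5000,
                                length_nt = draws$len[i])
      category[i] <- "RNA gene"
    } else if (u < frac_stable + frac_two_phase) {
      h1 <- min(draws$h1[i], draws$b[i] * 0.9)
      kin[[i]] <- true_kinetics(gid, E0 = draws$E0[i], h1 = h1,
                                h2 = h1 * draws$slow[i], b = draws$b[i],
                                length_nt = draws$len[i])
      category[i] <- cats[1 + (i %% length(cats))]
    } else if (u < frac_stable + frac_two_phase + frac_delayed) {
      kin[[i]] <- true_kinetics(gid, E0 = draws$E0[i], d = draws$delay[i],
                                h1 = draws$h1[i], b = draws$delay[i] + 20,
                                length_nt = draws$len[i])
      category[i] <- cats[1 + (i %% length(cats))]
    } else {
      kin[[i]] <- true_kinetics(gid, E0 = draws$E0[i], h1 = draws$h1[i],
                                length_nt = draws$len[i])
      category[i] <- cats[1 + (i %% length(cats))]
    }
  }
  mono <- .simulate_kinetics_set(kin, design)

  ops <- lapply(seq_len(n_operons), function(j) {
    simulate_operon(op_sizes[j], spacing_nt = 1000,
                    profile_type = if (draws$op_type[j] < frac_type_II) "II" else "I",
                    design = design, h1_first = draws$op_h1[j],
                    operon_id = sprintf("op%03d", j))
  })

  truth <- dplyr::bind_rows(c(list(mono$truth), lapply(ops, `[[`, "truth")))
  expr <- dplyr::bind_rows(c(list(mono$expr), lapply(ops, `[[`, "expr")))

  # sequential chromosome layout; minus-strand operons run right-to-left so
  # the first member (position 1) owns the rightmost start codon
  ann <- vector("list", n_mono + n_operons)
  cursor <- 1
  for (i in seq_len(n_mono)) {
    len <- kin[[i]]$length_nt
    ann[[i]] <- tibble::tibble(
      gene_id = kin[[i]]$gene_id, start = cursor, end = cursor + len - 1,
      strand = draws$strand[i], length_nt = len, category = category[i],
      operon_id = NA_character_, operon_position = NA_integer_,
      dist_to_operon_start_nt = 0)
    cursor <- cursor + len + 100
  }
  for (j in seq_len(n_operons)) {
    tr <- ops[[j]]$truth
    n <- nrow(tr)
    strand <- draws$strand[n_mono + j]
    len <- 800
    slot <- if (strand == "+") seq_len(n) - 1 else n - seq_len(n)
    starts <- cursor + slot * 1000
    ann[[n_mono + j]] <- tibble::tibble(
      gene_id = tr$gene_id, start = starts, end = starts + len - 1,
      strand = strand, length_nt = len,
      category = if (ops[[j]]$profile_type == "II") "ATP synthesis" else "translation",
      operon_id = tr$operon_id, operon_position = tr$operon_position,
      dist_to_operon_start_nt = tr$dist_to_operon_start_nt)
    cursor <- cursor + n * 1000 + 200
  }
  list(truth = truth, expr = expr,
       annotation = dplyr::bind_rows(ann), design = design,
       operon_types = tibble::tibble(
         operon_id = vapply(ops, function(o) o$truth$operon_id[1], character(1)),
         type = vapply(ops, `[[`, character(1), "profile_type")))
}

# per-value formatting: format() on a vector pads decimals ("0.0"), which
# would corrupt the t0/t2.5/... column dialect
.time_label <- function(t) {
  vapply(t, function(x) paste0("t", format(x, trim = TRUE, scientific = FALSE)),
         character(1))
}

.expr_to_wide <- function(expr, id_col = "gene_id") {
  wide <- expr %>%
    dplyr::mutate(tcol = .time_label(.data$time)) %>%
    dplyr::select("id", "replicate", "tcol", "signal") %>%
    tidyr::pivot_wider(names_from = "tcol", values_from = "signal") %>%
    dplyr::arrange(.data$id, .data$replicate)
  names(wide)[names(wide) == "id"] <- id_col
  wide
}

#' Write a simulated fixture to TSV files
#'
#' Emits the standard file dialects consumed by the readers: a wide
#' expression table (`gene_id, replicate, t0, t2.5, ...`), the annotation
#' table, an optional probe table (probe metadata joined with the probe
#' series) and the ground-truth kinetics table.
#'
#' @param sim output of [simulate_genome()], [simulate_operon()] or
#'   [simulate_probe_level()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_fixture <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(truth = file.path(dir, "truth.tsv"))
  wr <- function(df, path) utils::write.table(
    df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  if (!is.null(sim$positions)) {
    wide <- .expr_to_wide(sim$expr, id_col = "probe_id")
    probes <- dplyr::left_join(sim$positions, wide, by = "probe_id")
    paths["probes"] <- file.path(dir, "probes.tsv")
    wr(probes, paths["probes"])
  } else {
    paths["expression"] <- file.path(dir, "expression.tsv")
    wr(.expr_to_wide(sim$expr), paths["expression"])
  }
  if (!is.null(sim$annotation)) {
    paths["annotation"] <- file.path(dir, "annotation.tsv")
    wr(sim$annotation, paths["annotation"])
  }
  wr(sim$truth, paths["truth"])
  invisible(paths)
}
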