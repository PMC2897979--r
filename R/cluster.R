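#' Standardize decay profiles for clustering
#'
#' Per gene, the replicate-mean log2 series is centered and scaled to unit
#' standard deviation over timepoints, so clustering groups profile shapes
#' rather than expression levels. Constant profiles (zero variance) are
#' excluded and reported.
#'
#' @param expr long expression tibble with positive signals.
#' @return list with `profiles` (matrix genes x timepoints), `times` and
#'   `excluded` (constant-profile gene ids).
#' @export
standardize_profiles <- function(expr) {
  m <- collapse_replicates(expr, na_all = "na")
  times <- sort(unique(m$time))
  if (length(times) < 3) stop("need at least 3 timepoints")
  wide <- m %>% dplyr::select("id", "time", "signal") %>%
    tidyr::pivot_wider(names_from = "time", values_from = "signal") %>%
    dplyr::arrange(.data$id)
  mat <- log2(as.matrix(wide[, -1, drop = FALSE]))
  rownames(mat) <- wide$id
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  sds <- apply(mat, 1, stats::sd)
  excluded <- rownames(mat)[sds == 0]
  mat <- mat[sds > 0, , drop = FALSE]
  mat <- (mat - rowMeans(mat)) / apply(mat, 1, stats::sd)
  list(profiles = mat, times = times, excluded = excluded)
}

#' Fuzzy c-means clustering of profiles
#'
#' Standard alternating-update fuzzy c-means with fuzzifier m on Euclidean
#' distances: cluster centers are membership^m-weighted means, memberships
#' are proportional to inverse distance^(2/(m-1)). Starts from seeded
#' random memberships; the best of `nstart` restarts by final objective is
#' kept. The objective is non-increasing across iterations and the run is
#' reproducible for a fixed seed.
#'
#' @param profiles matrix (genes x timepoints), e.g. from
#'   [standardize_profiles()].
#' @param c number of clusters, less than the number of profiles.
#' @param m fuzzifier (> 1); 2 by convention for expression profiles.
#' @param max_iter,tol iteration cap and convergence tolerance on the
#'   maximum membership change.
#' @param seed integer seed.
#' @param nstart random restarts.
#' @param support_threshold a gene is "well supported" in its cluster when
#'   its maximum membership reaches this value.
#' @return list with `membership` (genes x c, rows sum to 1), `centers`,
#'   `cluster` (hard labels), `well_supported`, `objective` (final value)
#'   and `objective_trace` of the winning restart.
#' @export
fuzzy_cmeans <- function(profiles, c, m = 2, max_iter = 200, tol = 1e-6,
                         seed = 1L, nstart = 5, support_threshold = 0.5) {
  n <- nrow(profiles)
  stopifnot(c >= 2, c < n, m > 1, tol > 0)
  runs <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(nstart), function(r) {
      u <- matrix(stats::runif(n * c), n, c)
      u <- u / rowSums(u)
      .fcm_run(profiles, u, m, max_iter, tol)
    })
  })
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "objective"))]]
  hard <- max.col(best$membership, ties.method = "first")
  maxmem <- best$membership[cbind(seq_len(n), hard)]
  list(membership = best$membership, centers = best$centers,
       cluster = stats::setNames(hard, rownames(profiles)),
       well_supported = stats::setNames(maxmem >= support_threshold,
                                        rownames(profiles)),
       objective = best$objective, objective_trace = best$trace,
       iterations = best$iterations)
}

.fcm_run <- function(x, u, m, max_iter, tol) {
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    um <- u^m
    centers <- (t(um) %*% x) / colSums(um)
    # squared Euclidean distances gene x cluster
    d2 <- outer(rowSums(x^2), rep(1, nrow(centers))) -
      2 * x %*% t(centers) + outer(rep(1, nrow(x)), rowSums(centers^2))
    d2[d2 < 0] <- 0
    trace <- c(trace, sum(um * d2))
    zero <- d2 < .Machine$double.eps
    inv <- d2^(-1 / (m - 1))
    u_new <- inv / rowSums(inv)
    hit <- rowSums(zero) > 0
    if (any(hit)) {
      u_new[hit, ] <- 0
      u_new[hit, ] <- zero[hit, , drop = FALSE] /
        rowSums(zero[hit, , drop = FALSE])
    }
    delta <- max(abs(u_new - u))
    u <- u_new
    if (delta < tol) break
  }
  um <- u^m
  centers <- (t(um) %*% x) / colSums(um)
  d2 <- outer(rowSums(x^2), rep(1, nrow(centers))) -
    2 * x %*% t(centers) + outer(rep(1, nrow(x)), rowSums(centers^2))
  d2[d2 < 0] <- 0
  list(membership = u, centers = centers, objective = sum(um * d2),
       trace = c(trace, sum(um * d2)), iterations = it)
}

#' Hypergeometric functional enrichment of clusters
#'
#' For every cluster x category pair: the upper-tail hypergeometric
#' probability of observing at least k category members in a cluster of
#' size n drawn from a universe of N genes containing K category members
#' (k = 0 gives p = 1, the tail including the observation). p-values are
#' Bonferroni-adjusted over all tested pairs and floored at 1e-16 for
#' reporting.
#'
#' @param cluster named vector of hard cluster labels (names = gene ids),
#'   e.g. `fuzzy_cmeans()$cluster`.
#' @param categories tibble `gene_id, category`; must only name genes, the
#'   universe is the clustered gene set.
#' @return tibble `cluster, category, k, n, K, N, p, p_adj, p_label`.
#' @export
enrichment_test <- function(cluster, categories) {
  universe <- names(cluster)
  categories <- categories[categories$gene_id %in% universe, ]
  if (!nrow(categories)) stop("no category annotations overlap the clustered genes")
  N <- length(universe)
  cats <- split(categories$gene_id, categories$category)
  rows <- list()
  for (cl in sort(unique(cluster))) {
    members <- universe[cluster == cl]
    for (cat in names(cats)) {
      K <- length(cats[[cat]])
      k <- length(intersect(members, cats[[cat]]))
      p <- stats::phyper(k - 1, K, N - K, length(members), lower.tail = FALSE)
      rows[[length(rows) + 1]] <- tibble::tibble(
        cluster = cl, category = cat, k = k, n = length(members), K = K, N = N,
        p = p)
    }
  }
  out <- dplyr::bind_rows(rows)
  out$p_adj <- pmin(1, out$p * nrow(out))
  out$p_label <- ifelse(out$p_adj <= 1e-16, "<= 1e-16",
                        format(pmax(out$p_adj, 1e-16), digits = 3))
  out
}

#' Choose the cluster number by functional enrichment
#'
#' For each candidate cluster count, the profiles are clustered and scored
#' by the number of (cluster, category) pairs whose Bonferroni-adjusted
#' enrichment p-value falls below alpha; the candidate maximizing the score
#' wins, ties going to the smallest count.
#'
#' @param profiles standardized profile matrix.
#' @param categories tibble `gene_id, category`.
#' @param config a [pipeline_config()] (uses `cluster_range`, `fuzzifier`,
#'   `enrichment_alpha`, `seed`).
#' @param nstart random restarts per candidate.
#' @return list with `c` (chosen count), `scores` tibble and the winning
#'   `fit`.
#' @export
select_cluster_number <- function(profiles, categories,
                                  config = pipeline_config(), nstart = 3) {
  cand <- config$cluster_range
  cand <- cand[cand >= 2 & cand < nrow(profiles)]
  if (!length(cand)) stop("empty candidate cluster range")
  fits <- lapply(cand, function(cc) {
    fit <- fuzzy_cmeans(profiles, cc, m = config$fuzzifier,
                        seed = config$seed + cc, nstart = nstart)
    enr <- enrichment_test(fit$cluster, categories)
    list(fit = fit, score = sum(enr$p_adj < config$enrichment_alpha))
  })
  scores <- vapply(fits, `[[`, numeric(1), "score")
  best <- which.max(scores)  # first maximum = smallest c on ties
  list(c = cand[best],
       scores = tibble::tibble(c = cand, score = scores),
       fit = fits[[best]]$fit)
}
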