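# two planted profile SHAPES on the chase grid: immediate exponential decay
# versus a long plateau followed by decay. (Two pure exponentials with
# different half-lives standardize to the same straight line in t, so the
# planted groups must differ in shape, not just in rate.)
make_two_groups <- function(n_per = 15, sigma = 0.1, seed = 12) {
  tp <- c(0, 2.5, 5, 10, 20, 40, 60)
  withr::with_seed(seed, dplyr::bind_rows(lapply(seq_len(2 * n_per), function(i) {
    fast <- i <= n_per
    base <- if (fast) 1000 * 2^(-tp / 2)
            else 1000 * pmin(1, 2^(-(tp - 20) / 5))
    tibble::tibble(id = sprintf("%s%02d", if (fast) "f" else "s", i),
                   replicate = 1L, time = tp,
                   signal = base * exp(rnorm(7, 0, sigma)))
  })))
}

test_that("profile standardization centers, scales and drops constants", {
  expr <- make_two_groups()
  flat <- tibble::tibble(id = "flat", replicate = 1L,
                         time = c(0, 2.5, 5, 10, 20, 40, 60), signal = 500)
  std <- standardize_profiles(dplyr::bind_rows(expr, flat))
  expect_equal(unname(rowMeans(std$profiles)), rep(0, nrow(std$profiles)),
               tolerance = 1e-12)
  expect_equal(unname(apply(std$profiles, 1, sd)), rep(1, nrow(std$profiles)),
               tolerance = 1e-12)
  expect_equal(std$excluded, "flat")
  # proportional profiles standardize identically (scale invariance)
  a <- expr[expr$id == "f01", ]
  b <- a; b$id <- "f01x"; b$signal <- a$signal * 42
  std2 <- standardize_profiles(dplyr::bind_rows(a, b))
  expect_equal(std2$profiles["f01", ], std2$profiles["f01x", ], tolerance = 1e-12)
  # oracle: direct center/scale of the log2 profile
  l <- log2(a$signal[order(a$time)])
  expect_equal(unname(std2$profiles["f01", ]), unname((l - mean(l)) / sd(l)),
               tolerance = 1e-12)
})

test_that("fuzzy c-means separates planted groups with valid memberships", {
  std <- standardize_profiles(make_two_groups())
  fit <- fuzzy_cmeans(std$profiles, c = 2, seed = 3)
  expect_equal(unname(rowSums(fit$membership)), rep(1, 30), tolerance = 1e-9)
  own <- fit$membership[cbind(1:30, fit$cluster)]
  expect_true(all(own > 0.9))
  # the two planted groups land in different clusters
  expect_equal(length(unique(fit$cluster[1:15])), 1)
  expect_equal(length(unique(fit$cluster[16:30])), 1)
  expect_false(fit$cluster[1] == fit$cluster[30])
  # objective non-increasing per iteration; seeded runs bit-identical
  expect_true(all(diff(fit$objective_trace) <= 1e-9))
  fit2 <- fuzzy_cmeans(std$profiles, c = 2, seed = 3)
  expect_identical(fit$membership, fit2$membership)
  expect_identical(fit$objective, fit2$objective)
  # permuting gene order changes no assignment
  perm <- withr::with_seed(9, sample(nrow(std$profiles)))
  fitp <- fuzzy_cmeans(std$profiles[perm, ], c = 2, seed = 3)
  agree <- table(fit$cluster[perm], fitp$cluster)
  expect_equal(sum(apply(agree, 1, max)), 30)
})

test_that("cross-check: agrees with e1071's fuzzy c-means on separated groups", {
  skip_if_not_installed("e1071")
  std <- standardize_profiles(make_two_groups())
  fit <- fuzzy_cmeans(std$profiles, c = 2, seed = 3)
  ref <- withr::with_seed(4, e1071::cmeans(std$profiles, centers = 2, m = 2))
  agree <- table(fit$cluster, ref$cluster)
  expect_equal(sum(apply(agree, 1, max)), 30)
  # centers coincide up to label order
  d <- as.matrix(dist(rbind(fit$centers, ref$centers)))[1:2, 3:4]
  expect_lt(min(d[1, ]) + min(d[2, ]), 0.1)
})

test_that("hypergeometric enrichment equals the exact combinatorial oracle", {
  # exhaustive small-universe sweep
  for (N in c(10, 20, 30)) {
    genes <- sprintf("g%02d", 1:N)
    for (K in c(3, N %/% 2)) {
      cats <- tibble::tibble(gene_id = genes[1:K], category = "cat")
      for (n in c(2, N %/% 3)) {
        cl <- stats::setNames(rep(2L, N), genes)
        cl[1:n] <- 1L
        res <- enrichment_test(cl, cats)
        r1 <- res[res$cluster == 1, ]
        expect_equal(r1$p, oracle_hyper_upper(r1$k, K, N, n), tolerance = 1e-12)
      }
    }
  }
  # fully loaded cluster: p = C(20,10)/C(100,10)
  genes <- sprintf("g%03d", 1:100)
  cl <- stats::setNames(rep(2L, 100), genes); cl[1:10] <- 1L
  cats <- tibble::tibble(gene_id = genes[1:20], category = "cat")
  res <- enrichment_test(cl, cats)
  expect_equal(res$p[res$cluster == 1], choose(20, 10) / choose(100, 10),
               tolerance = 1e-12)
  # cluster = universe and k = 0 both give p = 1
  all_one <- stats::setNames(rep(1L, 30), sprintf("g%02d", 1:30))
  expect_equal(enrichment_test(all_one,
                               tibble::tibble(gene_id = "g01", category = "c"))$p, 1)
  cl0 <- stats::setNames(c(1L, rep(2L, 29)), sprintf("g%02d", 1:30))
  res0 <- enrichment_test(cl0, tibble::tibble(gene_id = "g05", category = "c"))
  expect_equal(res0$p[res0$cluster == 1], 1)
})

test_that("planted enrichment weakens as cluster purity drops", {
  std <- standardize_profiles(make_two_groups(n_per = 20, sigma = 0.05))
  genes <- rownames(std$profiles)
  fast <- grep("^f", genes, value = TRUE)
  p_at_purity <- vapply(c(1, 0.7, 0.55), function(purity) {
    n_keep <- round(length(fast) * purity)
    members <- c(fast[seq_len(n_keep)],
                 grep("^s", genes, value = TRUE)[seq_len(length(fast) - n_keep)])
    cl <- stats::setNames(ifelse(genes %in% members, 1L, 2L), genes)
    cats <- tibble::tibble(gene_id = fast, category = "fast_decay")
    res <- enrichment_test(cl, cats)
    res$p_adj[res$cluster == 1]
  }, numeric(1))
  expect_true(all(diff(p_at_purity) > 0))
})

test_that("enrichment-guided selection finds the planted cluster number", {
  tp <- c(0, 2.5, 5, 10, 20, 40, 60)
  # three planted decay shapes: immediate decline, plateau-then-decline,
  # transient rise before decline; 8 genes per shape keep the categories
  # tight, so splitting a planted group beyond the true count costs
  # significance under Bonferroni instead of duplicating it
  shapes <- list(function(t) 2^(-t / 3),
                 function(t) pmin(1, 2^(-(t - 20) / 5)),
                 function(t) ifelse(t < 10, 1 + t / 10, 2 * 2^(-(t - 10) / 5)))
  expr <- withr::with_seed(22, dplyr::bind_rows(lapply(1:24, function(i) {
    cls <- 1 + (i - 1) %% 3
    tibble::tibble(id = sprintf("g%02d_c%d", i, cls), replicate = 1L, time = tp,
                   signal = 1000 * shapes[[cls]](tp) * exp(rnorm(7, 0, 0.05)))
  })))
  std <- standardize_profiles(expr)
  cats <- tibble::tibble(gene_id = rownames(std$profiles),
                         category = sub("^.*_", "", rownames(std$profiles)))
  cfg <- pipeline_config(cluster_range = 2:5, seed = 7)
  sel <- select_cluster_number(std$profiles, cats, cfg, nstart = 2)
  expect_equal(sel$c, 3)
  # reproducible for a fixed seed
  sel2 <- select_cluster_number(std$profiles, cats, cfg, nstart = 2)
  expect_identical(sel$scores, sel2$scores)
})
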