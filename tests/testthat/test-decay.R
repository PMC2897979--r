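grid7 <- c(0, 2.5, 5, 10, 20, 40, 60)

test_that("exponential segment fits match closed-form expectations", {
  # two points: exact fit through both, MSE 0
  f <- fit_exponential_segment(c(0, 5), c(100, 50))
  expect_equal(f$k, 0.2)
  expect_equal(f$twofold_time, 5)
  expect_equal(f$mse, 0)
  # flat series: zero decay constant, infinite twofold time
  f2 <- fit_exponential_segment(c(0, 5, 10), c(100, 100, 100))
  expect_equal(f2$k, 0)
  expect_identical(f2$twofold_time, Inf)
  # noisy series: equals an independently coded OLS slope, near the truth
  y <- withr::with_seed(21, 100 * 2^(-grid7 / 3) * exp(rnorm(7, 0, 0.05)))
  f3 <- fit_exponential_segment(grid7, y)
  l <- log2(y)
  slope <- sum((grid7 - mean(grid7)) * (l - mean(l))) /
    sum((grid7 - mean(grid7))^2)
  expect_equal(f3$k, -slope, tolerance = 1e-12)
  expect_lt(abs(f3$k - 1 / 3) / (1 / 3), 0.05)
  expect_error(fit_exponential_segment(0, 100), "2 points")
  expect_error(fit_exponential_segment(c(0, 5), c(100, -1)), "positive")
})

test_that("twofold decay-step half-life follows the detection rule", {
  # exact sampling of a 5-minute half-life detects at t = 5
  tf <- twofold_half_life(grid7, 100 * 2^(-grid7 / 5))
  expect_equal(tf$half_life, 5, tolerance = 1e-12)
  expect_equal(tf$t_half, 5)
  # 3-minute half-life: at 2.5 min the drop is below twofold, detection at 5
  # and the two-point fit gives (t_j - t_0) / log2(E0 / Ej) = 3 exactly
  tf2 <- twofold_half_life(grid7, 100 * 2^(-grid7 / 3))
  expect_equal(tf2$t_half, 5)
  expect_equal(tf2$half_life, 5 / log2(100 / (100 * 2^(-5 / 3))), tolerance = 1e-12)
  expect_equal(tf2$half_life, 3, tolerance = 1e-12)
  # a rising series falls back to the all-point fit: negative and stable
  tf3 <- twofold_half_life(grid7, 100 * 2^(grid7 / 50))
  expect_true(tf3$stable)
  expect_equal(tf3$method, "fallback")
  expect_lt(tf3$half_life, 0)
})

test_that("two-phase fits recover breakpoints and rates; brute force agrees", {
  # pure exponential: every breakpoint fits exactly, ties go earliest
  y <- 100 * 2^(-grid7 / 5)
  tp <- two_phase_fit(grid7, y)
  expect_equal(tp$breakpoint, 2.5)
  expect_equal(tp$mse, 0, tolerance = 1e-20)
  expect_equal(tp$fit1$twofold_time, 5, tolerance = 1e-9)
  expect_equal(tp$fit2$twofold_time, 5, tolerance = 1e-9)
  # piecewise truth with the break on the grid, brute-force confirmed
  k <- true_kinetics("g", E0 = 100, h1 = 2.5, h2 = 20, b = 10)
  y2 <- noiseless_signal(k, grid7)
  tp2 <- two_phase_fit(grid7, y2)
  expect_equal(tp2$breakpoint, 10)
  expect_equal(tp2$fit1$twofold_time, 2.5, tolerance = 1e-9)
  expect_equal(tp2$fit2$twofold_time, 20, tolerance = 1e-9)
  bf <- oracle_two_phase(grid7, y2)
  expect_equal(tp2$breakpoint, bf$x)
  expect_equal(tp2$decay_rate, unname(bf$rate1), tolerance = 1e-9)
  # onset rule: the last maximal timepoint starts the first phase
  y3 <- c(100, 100, 120, 120, 60, 30, 15)
  tp3 <- two_phase_fit(grid7, y3)
  expect_equal(tp3$t_on, 10)
  expect_equal(tp3$decay_rate, 10, tolerance = 1e-9)
})

test_that("fits are scale invariant and onset shifts leave decay rates alone", {
  k <- true_kinetics("g", E0 = 300, h1 = 3, h2 = 12, b = 10)
  y <- noiseless_signal(k, grid7)
  for (const in c(0.01, 7, 1e4)) {
    expect_equal(twofold_half_life(grid7, const * y)$half_life,
                 twofold_half_life(grid7, y)$half_life, tolerance = 1e-12)
    a <- two_phase_fit(grid7, const * y)
    b <- two_phase_fit(grid7, y)
    expect_equal(a$breakpoint, b$breakpoint)
    expect_equal(a$decay_rate, b$decay_rate, tolerance = 1e-12)
  }
  # delayed onset: twofold half-life grows, two-phase decay rate does not
  for (d in c(2.5, 5, 10)) {
    kd <- true_kinetics("g", E0 = 100, d = d, h1 = 3, h2 = 3, b = d + 10)
    yd <- noiseless_signal(kd, grid7)
    expect_gt(twofold_half_life(grid7, yd)$half_life, 3)
    expect_equal(two_phase_fit(grid7, yd)$decay_rate, 3, tolerance = 1e-9)
  }
})

test_that("estimate_all recovers noiseless kinetics and flags the hard cases", {
  kin <- withr::with_seed(31, lapply(1:100, function(i) {
    true_kinetics(sprintf("g%03d", i), E0 = exp(runif(1, 4, 8)),
                  h1 = runif(1, 1.5, 8))
  }))
  d0 <- chase_design(noise_sigma = 0)
  expr <- dplyr::bind_rows(lapply(kin, simulate_gene, design = d0))
  est <- estimate_all(expr)
  truth <- vapply(kin, `[[`, numeric(1), "h1")[match(est$gene_id,
                                                     vapply(kin, `[[`, character(1), "gene_id"))]
  expect_lt(max(abs(est$half_life - truth) / truth), 1e-9)
  expect_lt(max(abs(est$decay_rate - truth) / truth), 1e-9)
  # delayed-onset genes: half-life exceeds decay rate, decay rate exact
  kd <- lapply(1:10, function(i)
    true_kinetics(sprintf("d%02d", i), E0 = 1000, d = c(2.5, 5, 10)[1 + i %% 3],
                  h1 = 2 + i / 5, b = 30))
  estd <- estimate_all(dplyr::bind_rows(lapply(kd, simulate_gene, design = d0)))
  truthd <- vapply(kd, `[[`, numeric(1), "h1")[match(estd$gene_id,
                                                     vapply(kd, `[[`, character(1), "gene_id"))]
  expect_equal(estd$decay_rate, truthd, tolerance = 1e-9)
  expect_true(all(estd$half_life > estd$decay_rate))
  # unfittable genes are reported, not fatal
  bad <- tibble::tibble(id = "dead", replicate = 1L, time = grid7,
                        signal = c(100, NA, NA, NA, NA, 50, 25))
  estb <- estimate_all(bad)
  expect_match(estb$flags, "unfittable")
})

test_that("decay summaries match sort-based percentile oracles", {
  est <- withr::with_seed(17, tibble::tibble(
    gene_id = sprintf("g%04d", 1:1000),
    half_life = exp(rnorm(1000, log(2.4), 0.8)),
    decay_rate = exp(rnorm(1000, log(2.6), 0.8)),
    stable = FALSE))
  s <- summarize_decay(est)
  expect_equal(s$median_half_life, median(est$half_life))
  srt <- sort(est$half_life)
  # type-7 interpolated percentiles, computed by hand from the sorted values
  idx <- function(p) {
    h <- (1000 - 1) * p + 1
    srt[floor(h)] + (h - floor(h)) * (srt[floor(h) + 1] - srt[floor(h)])
  }
  expect_equal(s$half_life_p10, idx(0.1), tolerance = 1e-12)
  expect_equal(s$half_life_p90, idx(0.9), tolerance = 1e-12)
  one <- summarize_decay(est[1, ])
  expect_equal(one$median_half_life, est$half_life[1])
  expect_equal(one$half_life_p10, one$half_life_p90)
  expect_error(summarize_decay(est[0, ]), "empty")
})

test_that("the capped-median convention censors >cap and negative entries", {
  expect_equal(censored_median(c(1, 3, 5, 25, -10, Inf), cap = 20), 3)
  expect_error(censored_median(c(25, 30), cap = 20), "no uncensored")
  expect_equal(format_decay_rate(c(3.14, 25, -5)), c("3.1", ">20", ">20"))
})

test_that("the bundled ncRNA/asRNA compendium has the published structure", {
  tab <- med4_ncrna_decay_rates()
  expect_equal(nrow(tab), 31)
  expect_equal(sum(tab$censored), 9)
  expect_equal(sum(!tab$censored), 22)
})
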