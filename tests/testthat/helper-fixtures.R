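# shared fixture builders and independent oracles

# independent scalar piecewise evaluator of the generative model, coded
# straightforwardly (no shared vectorized code path with noiseless_signal)
oracle_signal <- function(E0, d, h1, h2, b, a, t) {
  if (t < d) return(E0 * (1 + a * t / d))
  peak <- E0 * (1 + a)
  if (t < b) return(peak * 2^(-(t - d) / h1))
  peak * 2^(-(b - d) / h1) * 2^(-(t - b) / h2)
}

# brute-force two-phase fit: lm() per segment over every admissible
# breakpoint, pooled MSE with the breakpoint in both segments; NULL when
# fewer than 4 points remain at or after the onset (unfittable by contract)
oracle_two_phase <- function(t, y) {
  i_on <- max(which(y == max(y)))
  tt <- t[i_on:length(t)]; yy <- log2(y[i_on:length(y)])
  n <- length(tt)
  if (n < 4) return(NULL)
  fits <- lapply(2:(n - 1), function(ci) {
    f1 <- lm(yy[1:ci] ~ tt[1:ci])
    f2 <- lm(yy[ci:n] ~ tt[ci:n])
    list(x = tt[ci],
         mse = (sum(resid(f1)^2) + sum(resid(f2)^2)) / (ci + (n - ci + 1)),
         rate1 = -1 / coef(f1)[2], rate2 = -1 / coef(f2)[2])
  })
  mses <- vapply(fits, `[[`, numeric(1), "mse")
  fits[[which(mses <= min(mses) + max(1e-12, 1e-9 * min(mses)))[1]]]
}

# rank transform + product-moment formula, independent of stats::cor's
# spearman path
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# exact combinatorial upper-tail hypergeometric, small universes only
oracle_hyper_upper <- function(k, K, N, n) {
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# standard multi-operon fixture: position-dependent half-life truth
make_operon_set <- function(n_operons, noise_sigma, seed,
                            profile_types = rep("I", n_operons), ...) {
  sims <- lapply(seq_len(n_operons), function(j) {
    simulate_operon(3 + (j %% 4), profile_type = profile_types[j],
                    design = chase_design(noise_sigma = noise_sigma,
                                          seed = seed + j),
                    operon_id = sprintf("op%03d", j), ...)
  })
  list(sims = sims,
       truth = dplyr::bind_rows(lapply(sims, `[[`, "truth")),
       expr = dplyr::bind_rows(lapply(sims, `[[`, "expr")),
       annotation = dplyr::bind_rows(lapply(sims, function(s) {
         tr <- s$truth
         n <- nrow(tr)
         tibble::tibble(gene_id = tr$gene_id,
                        start = 1 + tr$dist_to_operon_start_nt,
                        end = 800 + tr$dist_to_operon_start_nt, strand = "+",
                        length_nt = 800, category = NA_character_,
                        operon_id = tr$operon_id,
                        operon_position = tr$operon_position,
                        dist_to_operon_start_nt = tr$dist_to_operon_start_nt)
       })))
}

# 20-gene tiled-probe fixture at a given true polymerase velocity
make_probe_set <- function(velocity, noise_sigma, seed, n_genes = 20) {
  lens <- round(seq(2000, 4600, length.out = n_genes))
  sims <- lapply(seq_len(n_genes), function(i) {
    simulate_probe_level(lens[i], velocity_nt_per_s = velocity,
                         design = chase_design(noise_sigma = noise_sigma,
                                               seed = seed + i),
                         gene_id = sprintf("g%02d", i))
  })
  list(positions = dplyr::bind_rows(lapply(sims, `[[`, "positions")),
       expr = dplyr::bind_rows(lapply(sims, `[[`, "expr")),
       truth = dplyr::bind_rows(lapply(sims, `[[`, "truth")))
}
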