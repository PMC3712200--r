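# Shared fixtures built in code: a planted two-family scenario emulating the
# study design (down-regulated "metabolic-like" pathways, up-regulated
# "signaling-like" pathways, plus null pathways), and small oracles.

make_planted_scenario <- function(seed, n_genes = 2000, effect = 3, noise = 0.5,
                                  sets_per_family = 8, n_null_sets = 24,
                                  set_size = 40) {
  truth <- planted_truth(n_genes = n_genes, frac_up = 0.15, frac_down = 0.15,
                         effect_size = effect, noise_sd = noise)
  expr <- simulate_dose_expression(dose_design(), truth, seed = seed)
  set.seed(seed + 1)
  draw_sets <- function(pool, n, prefix) {
    purrr::map_dfr(seq_len(n), function(i) {
      tibble::tibble(set = sprintf("%s%02d", prefix, i),
                     gene = sample(pool, set_size), sign = 1)
    })
  }
  collection <- dplyr::bind_rows(
    draw_sets(truth$down_genes, sets_per_family, "metab"),
    draw_sets(truth$up_genes, sets_per_family, "signal"),
    draw_sets(truth$null_genes, n_null_sets, "null")
  )
  family <- function(set) sub("[0-9]+$", "", set)
  list(truth = truth, expr = expr, collection = collection, family = family)
}

# Independent hypergeometric tail by exhaustive draw enumeration (tiny N only).
brute_hyper_tail <- function(k, K, n, N) {
  universe <- seq_len(N)
  inset <- universe <= K
  draws <- utils::combn(N, n)
  mean(colSums(matrix(inset[draws], nrow = n)) >= k)
}

# Independent two-sided Fisher p: enumerate all same-margin tables with
# probabilities computed from binomial coefficients directly.
brute_fisher_two_sided <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; cc <- m[2, 1]; d <- m[2, 2]
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc; n <- sum(m)
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  tab_prob <- function(x) {
    exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1))
  }
  probs <- vapply(lo:hi, tab_prob, numeric(1))
  p_obs <- tab_prob(a)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Perturbation-factor power series sum_{k>=0} B^k dE, valid for spectral
# radius < 1.
power_series_pf <- function(B, de, n_terms = 200) {
  pf <- de
  term <- de
  for (i in seq_len(n_terms)) {
    term <- B %*% term
    pf <- pf + term
  }
  drop(pf)
}

expect_uniform_ks <- function(x, alpha = 0.01) {
  p <- suppressWarnings(stats::ks.test(x, "punif"))$p.value
  expect_gt(p, alpha)
}
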