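test_that("profile enumeration matches the closed-form count", {
  expect_equal(nrow(enumerate_profiles(4, 1)), 27)
  expect_equal(nrow(enumerate_profiles(4, 2)), 125)
  p2 <- enumerate_profiles(2, 1)
  expect_equal(nrow(p2), 3)
  expect_setequal(apply(p2, 1, paste, collapse = ","), c("0,-1", "0,0", "0,1"))
  # all profiles start at 0 with bounded steps
  p <- enumerate_profiles(5, 2)
  expect_true(all(p[, 1] == 0))
  expect_true(all(abs(p[, -1] - p[, -ncol(p)]) <= 2))
  expect_equal(nrow(p), 5^4)
})

test_that("greedy max-min selection picks the monotone extremes first", {
  cand <- enumerate_profiles(2, 1)
  sel <- select_distinct_profiles(cand, 2)
  expect_setequal(apply(sel, 1, paste, collapse = ","), c("0,-1", "0,1"))
  # m = all returns everything
  expect_equal(nrow(select_distinct_profiles(cand, 3)), 3)
  # invariant to candidate input order
  cand4 <- enumerate_profiles(4, 2)
  set.seed(1)
  shuffled <- cand4[sample(nrow(cand4)), ]
  s1 <- select_distinct_profiles(cand4, 10)
  s2 <- select_distinct_profiles(shuffled, 10)
  expect_equal(s1[dosepath:::lex_key(s1), ], s2[dosepath:::lex_key(s2), ])
  expect_error(select_distinct_profiles(cand, 0), "positive")
  expect_error(select_distinct_profiles(cand, 9), "exceeds")
})

test_that("genes are assigned to their best-correlated profile", {
  profiles <- rbind(c(0, 1, 2, 3), c(0, 0, 0, 0), c(0, -1, -2, -3))
  expr <- tibble::tibble(gene = c("up", "down", "flat"),
                         s1 = c(1, -1, 0), s2 = c(2, -2, 0), s3 = c(3, -3, 0))
  a <- assign_genes(expr, profiles)
  expect_equal(a$profile_id[a$gene == "up"], 1L)
  expect_equal(a$correlation[a$gene == "up"], 1)
  expect_equal(a$profile_id[a$gene == "down"], 3L)
  expect_equal(a$correlation[a$gene == "down"], 1)
  # a gene that is the exact negative of a profile correlates -1 with it and
  # is assigned elsewhere
  cors <- dosepath:::std_rows(cbind(0, matrix(c(-1, -2, -3), 1))) %*%
    t(dosepath:::std_rows(profiles))
  expect_equal(cors[1, 1], -1)
  # zero-variance gene lands on the flat profile with correlation 0
  expect_equal(a$profile_id[a$gene == "flat"], 2L)
  expect_equal(a$correlation[a$gene == "flat"], 0)
})

test_that("assignment is invariant to positive scaling of a gene", {
  profiles <- select_distinct_profiles(enumerate_profiles(4, 2), 10)
  set.seed(3)
  base <- matrix(rnorm(60), 20, 3)
  e1 <- tibble::tibble(gene = sprintf("g%02d", 1:20)) |>
    dplyr::bind_cols(as.data.frame(base) |> stats::setNames(c("a", "b", "c")))
  e2 <- e1
  e2[, -1] <- e1[, -1] * 7.3
  expect_equal(assign_genes(e1, profiles)$profile_id,
               assign_genes(e2, profiles)$profile_id)
})

test_that("planted monotone structure reaches minimal permutation significance", {
  tr <- planted_truth(n_genes = 400, frac_up = 0.15, frac_down = 0.15,
                      effect_size = 6, noise_sd = 0.2)
  expr <- simulate_dose_expression(dose_design(), tr, seed = 11)
  fit <- mine_patterns(expr, n_permutations = 1000, seed = 4)
  sig <- fit$profile_stats
  expect_true(any(sig$perm_p < 0.001 & sig$class == "up"))
  expect_true(any(sig$perm_p < 0.001 & sig$class == "down"))
  # recovery of planted genes into correct monotone profiles
  cls <- sig$class[fit$assignment$profile_id]
  expect_gte(mean(cls[fit$assignment$gene %in% tr$up_genes] == "up"), 0.95)
  expect_gte(mean(cls[fit$assignment$gene %in% tr$down_genes] == "down"), 0.95)
})

test_that("noise-free planted data yields exactly the planted pattern sets", {
  tr <- planted_truth(n_genes = 300, frac_up = 0.1, frac_down = 0.1,
                      effect_size = 4, noise_sd = 0)
  expr <- simulate_dose_expression(dose_design(), tr, seed = 5)
  fit <- mine_patterns(expr, n_permutations = 1000, seed = 6)
  expect_setequal(fit$up_genes, tr$up_genes)
  expect_setequal(fit$down_genes, tr$down_genes)
  expect_length(intersect(fit$up_genes, fit$down_genes), 0)
})

test_that("permutation significance strengthens with planted effect size", {
  p_at_effect <- vapply(c(0.5, 1.5, 3), function(eff) {
    tr <- planted_truth(n_genes = 300, frac_up = 0.2, frac_down = 0,
                        effect_size = eff, noise_sd = 1)
    expr <- simulate_dose_expression(dose_design(), tr, seed = 21)
    fit <- mine_patterns(expr, n_permutations = 200, seed = 22)
    min(fit$profile_stats$perm_p[fit$profile_stats$class == "up"])
  }, numeric(1))
  expect_true(all(diff(p_at_effect) <= 0))
})

test_that("doubling permutations leaves estimates within Monte-Carlo error", {
  tr <- planted_truth(n_genes = 300, frac_up = 0.1, frac_down = 0.1,
                      effect_size = 1, noise_sd = 1)
  expr <- simulate_dose_expression(dose_design(), tr, seed = 8)
  profiles <- select_distinct_profiles(enumerate_profiles(4, 2), 20)
  s1 <- profile_fdr(expr, profiles, n_permutations = 400, seed = 9)
  s2 <- profile_fdr(expr, profiles, n_permutations = 800, seed = 9)
  se <- sqrt(s1$perm_p * (1 - s1$perm_p) / 400)
  expect_true(all(abs(s1$perm_p - s2$perm_p) <= 2 * se + 1e-9))
})

test_that("no significant profiles means empty pattern sets", {
  profiles <- rbind(c(0, 1, 2, 3), c(0, -1, -2, -3))
  assignment <- tibble::tibble(gene = c("a", "b"), profile_id = c(1L, 2L),
                               correlation = c(1, 1))
  stats_tbl <- tibble::tibble(profile_id = 1:2, n_genes = c(1L, 1L),
                              expected = c(1, 1), eo_fdr = c(1, 1),
                              perm_p = c(0.5, 0.5))
  out <- build_patterns(assignment, stats_tbl, profiles, 0.001)
  expect_length(out$down_genes, 0)
  expect_length(out$up_genes, 0)
})
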