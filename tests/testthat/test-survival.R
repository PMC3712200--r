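test_that("univariate Cox fit agrees with the survival package", {
  skip_if_not_installed("survival")
  sv <- simulate_survival(n_subjects = 300, risk_genes = c(gA = 0.5),
                          baseline_hazard = 0.1, censor_rate = 0.25, seed = 1)
  ours <- cox_univariate(sv$gA, sv$time, sv$event, standardize = FALSE)
  ref <- survival::coxph(survival::Surv(sv$time, sv$event) ~ sv$gA,
                         ties = "breslow")
  expect_equal(ours$beta, unname(stats::coef(ref)), tolerance = 1e-6)
  expect_equal(ours$se, sqrt(unname(stats::vcov(ref)[1, 1])), tolerance = 1e-4)
  expect_true(ours$converged)
})

test_that("Cox fit handles degenerate and symmetric inputs", {
  sv <- simulate_survival(n_subjects = 100, baseline_hazard = 0.1,
                          censor_rate = 0.2, seed = 2, genes = "gA")
  # constant covariate: HR 1 with a warning
  expect_warning(fit0 <- cox_univariate(rep(3, 100), sv$time, sv$event),
                 "zero-variance")
  expect_equal(fit0$hazard_ratio, 1)
  expect_equal(fit0$p_value, 1)
  # negating the covariate negates beta exactly
  f1 <- cox_univariate(sv$gA, sv$time, sv$event, standardize = FALSE)
  f2 <- cox_univariate(-sv$gA, sv$time, sv$event, standardize = FALSE)
  expect_equal(f1$beta, -f2$beta, tolerance = 1e-10)
  expect_error(cox_univariate(sv$gA, sv$time, rep(FALSE, 100)), "2 events")
})

test_that("Cox fit recovers planted coefficients within 3 standard errors", {
  hits <- vapply(1:40, function(s) {
    sv <- simulate_survival(n_subjects = 500, risk_genes = c(gA = log(2)),
                            baseline_hazard = 0.1, censor_rate = 0.2, seed = 100 + s)
    fit <- cox_univariate(sv$gA, sv$time, sv$event, standardize = FALSE)
    abs(fit$beta - log(2)) <= 3 * fit$se
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("permutation p flags a strongly coupled covariate and is floored", {
  sv <- simulate_survival(n_subjects = 200, risk_genes = c(gA = 2),
                          baseline_hazard = 0.1, censor_rate = 0.2, seed = 3)
  p <- permutation_p(sv$gA, sv$time, sv$event, n_permutations = 1000, seed = 4)
  expect_lte(p, 0.001)
  expect_gt(p, 0)  # floored at 1/n_permutations, never exactly 0
})

test_that("screening and selection operate on the packaged survival table", {
  tab <- survival_gene_table()
  expect_equal(nrow(tab), 98)
  expect_length(select_survival_genes(tab, alpha = 0), 0)
  expect_length(select_survival_genes(tab, alpha = 1), 98)
  expect_length(select_survival_genes(tab, alpha = 0.05), 98)
  expect_equal(sum(tab$pattern == "down"), 48)
  expect_equal(sum(tab$pattern == "up"), 50)
})

test_that("cross-tabulation counts pattern by hazard direction", {
  tab <- survival_gene_table()
  ct <- cross_tabulate(tab)
  expect_equal(unname(ct$counts), matrix(c(32, 24, 16, 26), 2))
  expect_equal(ct$odds_ratio, (32 * 26) / (16 * 24))
  # swapping down/up labels transposes the rows
  swapped <- dplyr::mutate(tab, pattern = ifelse(pattern == "down", "up", "down"))
  ct2 <- cross_tabulate(swapped)
  expect_equal(unname(ct2$counts), unname(ct$counts[2:1, ]))
  # all genes HR > 1: degenerate column reported as Inf with a flag
  onecol <- dplyr::mutate(tab, hazard_ratio = hazard_ratio + 1)
  expect_warning(ct3 <- cross_tabulate(onecol), "Inf")
  expect_equal(ct3$odds_ratio, Inf)
  expect_true(ct3$degenerate)
  # HR exactly 1 excluded with a warning
  tab1 <- tab
  tab1$hazard_ratio[1] <- 1
  expect_warning(ct4 <- cross_tabulate(tab1), "exactly 1")
  expect_equal(sum(ct4$counts), 97)
  expect_error(cross_tabulate(tab[0, ]), "empty")
  # tidy/glance surface the cells and the test
  expect_equal(sum(tidy(ct)$count), 98)
  expect_equal(glance(ct)$p_value, ct$p_value)
})

test_that("two-sided Fisher matches fisher.test across table shapes", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  expect_equal(fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2))$p_value,
               2 / choose(20, 10), tolerance = 1e-12)
  # exhaustive comparison with the independent enumeration oracle and with
  # stats::fisher.test over all tables with total <= 16
  for (n in c(5, 9, 12, 16)) {
    for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
      d <- n - a - b - cc
      m <- matrix(c(a, cc, b, d), 2)
      p <- fisher_exact_2x2(m)$p_value
      expect_equal(p, brute_fisher_two_sided(m), tolerance = 1e-10)
    }
  }
  set.seed(8)
  for (i in 1:200) {
    m <- matrix(rmultinom(1, sample(17:30, 1), runif(4, 0.05, 1)), 2)
    expect_equal(fisher_exact_2x2(m)$p_value, stats::fisher.test(m)$p.value,
                 tolerance = 1e-9)
    expect_equal(fisher_exact_2x2(m)$p_value, brute_fisher_two_sided(m),
                 tolerance = 1e-10)
  }
  expect_error(fisher_exact_2x2(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
  expect_error(fisher_exact_2x2(matrix(0, 2, 2)), "positive")
})

test_that("null permutation p-values are approximately uniform", {
  ps <- vapply(1:60, function(s) {
    sv <- simulate_survival(n_subjects = 60, baseline_hazard = 0.1,
                            censor_rate = 0.2, seed = 500 + s, genes = "gA")
    permutation_p(sv$gA, sv$time, sv$event, n_permutations = 200, seed = 600 + s)
  }, numeric(1))
  expect_uniform_ks(ps)
})
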