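two_gene_chain <- function(sign) {
  pathway_topology(tibble::tibble(source = "g1", target = "g2", sign = sign),
                   genes = c("g1", "g2"))
}

test_that("p_nde is the hypergeometric upper tail shared with enrichment", {
  expect_equal(p_nde(0, 5, 5, 20), 1)
  expect_equal(p_nde(5, 5, 5, 20), 1 / choose(20, 5))
  # identical counts give the enrichment p
  universe <- sprintf("g%02d", 1:20)
  res <- fisher_enrichment(universe[1:5],
                           tibble::tibble(set = "s", gene = universe[1:5], sign = 1),
                           universe)
  expect_equal(p_nde(5, 5, 5, 20), res$p_value)
  expect_error(p_nde(6, 5, 5, 20), "inconsistent")
})

test_that("perturbation factors solve PF = dE + B PF", {
  # B = 0: PF = dE, tA = 0
  t0 <- pathway_topology(tibble::tibble(source = character(), target = character(),
                                        sign = numeric()), genes = c("a", "b"))
  pf0 <- perturbation_factors(t0, c(a = 2, b = -1))
  expect_equal(unname(pf0$pf), c(2, -1))
  expect_equal(pf0$ta, 0)
  # single activation edge: dE on the source propagates once
  pf1 <- perturbation_factors(two_gene_chain(1), c(g1 = 1))
  expect_equal(unname(pf1$pf), c(1, 1))
  expect_equal(unname(pf1$acc), c(0, 1))
  expect_equal(pf1$ta, 1)
  # inhibition flips the accumulated sign
  pf2 <- perturbation_factors(two_gene_chain(-1), c(g1 = 1))
  expect_equal(pf2$ta, -1)
})

test_that("perturbation factors match the power-series oracle", {
  for (s in 1:5) {
    topo <- simulate_topology(sprintf("g%02d", 1:25), edge_density = 0.08, seed = s)
    if (topo$spectral_radius >= 1) next
    de <- stats::setNames(rnorm(5), topo$genes[1:5])
    pf <- perturbation_factors(topo, de)
    de_full <- stats::setNames(rep(0, 25), topo$genes)
    de_full[names(de)] <- de
    expect_equal(unname(pf$pf), unname(power_series_pf(topo$B, de_full)),
                 tolerance = 1e-6)
  }
})

test_that("singular topologies are excluded with a warning", {
  # a <-> b with +1 both ways and no other edges: B has columns summing to 1
  # and (I - B) is singular
  topo <- pathway_topology(tibble::tibble(source = c("a", "b"), target = c("b", "a"),
                                          sign = c(1, 1)))
  expect_warning(out <- perturbation_factors(topo, c(a = 1)), "singular")
  expect_null(out)
})

test_that("perturbation bootstrap flags a strongly activated chain", {
  # linear activation chain with every gene differential at +2
  n <- 10
  genes <- sprintf("g%02d", 1:n)
  topo <- pathway_topology(tibble::tibble(source = genes[-n], target = genes[-1],
                                          sign = 1), genes = genes)
  de <- stats::setNames(rep(2, n), genes)
  pool <- c(rnorm(200), rep(2, 20))  # mostly weak differential pool
  out <- p_pert(topo, de, de_pool = pool, n_boot = 3000, seed = 1)
  expect_lte(out$p_pert, 0.01)
  # all-zero dE: observed tA is 0 and the evidence is null
  out0 <- p_pert(topo, stats::setNames(numeric(0), character(0)),
                 de_pool = pool, n_boot = 300, seed = 1)
  expect_equal(out0$p_pert, 1)
  expect_equal(out0$ta_obs, 0)
  # Monte-Carlo consistency when doubling the bootstrap size
  p1 <- p_pert(topo, de, de_pool = pool, n_boot = 1000, seed = 2)$p_pert
  p2 <- p_pert(topo, de, de_pool = pool, n_boot = 2000, seed = 2)$p_pert
  expect_lte(abs(p1 - p2), 2 * sqrt(p1 * (1 - p1) / 1000) + 2e-3)
})

test_that("the global p combines both evidences by Fisher's product", {
  expect_equal(combine_global(1, 1), 1)
  cc <- 0.01
  expect_equal(combine_global(0.1, 0.1), cc - cc * log(cc), tolerance = 1e-12)
  expect_equal(combine_global(0.1, 0.1),
               stats::pchisq(-2 * log(0.01), df = 4, lower.tail = FALSE),
               tolerance = 1e-10)
  # symmetric and monotone in each argument
  expect_equal(combine_global(0.02, 0.3), combine_global(0.3, 0.02))
  grid <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(vapply(grid, combine_global, numeric(1), p_pert = 0.2)) > 0))
  # never below the product itself
  expect_gte(combine_global(0.05, 0.2), 0.01)
  expect_error(combine_global(0, 0.5), "\\(0, 1\\]")
})

test_that("classification thresholds match Bonferroni and BH", {
  one <- tibble::tibble(pathway = "p1", p_g = 0.01)
  expect_equal(classify_pathways(one, alpha = 0.01)$class, "bonferroni")
  flat <- tibble::tibble(pathway = sprintf("p%d", 1:5), p_g = rep(1, 5))
  expect_true(all(classify_pathways(flat)$class == "ns"))
  set.seed(7)
  mixed <- tibble::tibble(pathway = sprintf("p%d", 1:40),
                          p_g = c(runif(5, 0, 1e-5), runif(35)))
  out <- classify_pathways(mixed, alpha = 0.01)
  M <- nrow(mixed)
  expect_equal(out$class == "bonferroni", mixed$p_g <= 0.01 / M)
  expect_equal(out$class %in% c("bonferroni", "fdr"), bh_adjust(mixed$p_g) <= 0.01)
})

test_that("run_spia analyzes planted pathways and reports exclusions", {
  set.seed(10)
  genes <- sprintf("g%03d", 1:200)
  n <- 12
  chain_genes <- genes[1:n]
  topo_hit <- pathway_topology(tibble::tibble(source = chain_genes[-n],
                                              target = chain_genes[-1], sign = 1),
                               genes = chain_genes, name = "hit")
  topo_cold <- simulate_topology(genes[101:120], edge_density = 0.1, seed = 2,
                                 name = "cold")
  de_table <- tibble::tibble(gene = c(chain_genes, genes[50:69]),
                             log2_ratio = c(rep(2.5, n), rnorm(20, 0, 0.3)))
  fit <- run_spia(list(topo_hit, topo_cold), de_table, genes,
                  n_boot = 500, seed = 3)
  res <- tidy(fit)
  expect_equal(nrow(res), 1)  # cold pathway has no DE genes -> excluded
  expect_equal(fit$excluded$pathway, "cold")
  expect_equal(res$pathway, "hit")
  expect_lt(res$p_g, 0.01)
  expect_true(res$class %in% c("bonferroni", "fdr"))
  g <- glance(fit)
  expect_equal(g$n_pathways + g$n_excluded, 2)
})
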