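#' Over-representation evidence for one pathway
#'
#' Hypergeometric upper-tail probability of observing at least
#' `n_de_on_pathway` differential genes among `pathway_size` pathway genes,
#' given `n_de_total` differential genes in a universe of `universe_size`.
#'
#' @param n_de_on_pathway Differential genes on the pathway.
#' @param pathway_size Pathway genes present in the universe.
#' @param n_de_total Differential genes in the universe.
#' @param universe_size Universe size.
#' @return The probability `P(X >= n_de_on_pathway)`.
#' @export
p_nde <- function(n_de_on_pathway, pathway_size, n_de_total, universe_size) {
  if (n_de_on_pathway > min(pathway_size, n_de_total) ||
      pathway_size > universe_size || n_de_total > universe_size)
    abort("inconsistent counts")
  hypergeom_tail(n_de_on_pathway, pathway_size, n_de_total, universe_size)
}

#' Propagate differential expression through a pathway topology
#'
#' Solves the perturbation-factor system `PF = dE + B %*% PF`, i.e.
#' `PF = (I - B)^{-1} dE`, over the source-normalized signed influence
#' matrix `B`. The net accumulation per gene is `Acc = PF - dE` and the total
#' net accumulation is `tA = sum(Acc)`.
#'
#' @param topology A `pathway_topology`.
#' @param delta_e Named numeric vector of log2 fold-changes for the
#'   pathway's differential genes (genes absent from the vector count as 0).
#' @return A list with `pf` (named vector), `acc`, `ta`, and the solve
#'   residual `resid` (`max |(I - B) PF - dE|`, checked < 1e-8).
#' @export
perturbation_factors <- function(topology, delta_e) {
  stopifnot(inherits(topology, "pathway_topology"))
  genes <- topology$genes
  de <- stats::setNames(rep(0, length(genes)), genes)
  common <- intersect(names(delta_e), genes)
  de[common] <- delta_e[common]
  A <- diag(length(genes)) - topology$B
  pf <- tryCatch(solve(A, de), error = function(e) NULL)
  if (is.null(pf)) {
    warn(sprintf("pathway '%s' has singular (I - B); excluded from analysis",
                 topology$name))
    return(NULL)
  }
  resid <- max(abs(A %*% pf - de))
  if (resid >= 1e-8) {
    warn(sprintf("pathway '%s': perturbation solve residual %.3g >= 1e-8; excluded",
                 topology$name, resid))
    return(NULL)
  }
  acc <- pf - de
  list(pf = stats::setNames(drop(pf), genes), acc = stats::setNames(drop(acc), genes),
       ta = sum(acc), resid = resid)
}

#' Perturbation evidence by topology bootstrap
#'
#' Null total-accumulation values are generated by placing the observed
#' number of differential genes at random pathway positions, with
#' fold-changes resampled with replacement from the pool of all differential
#' log2 ratios, and recomputing `tA` each round. The two-sided probability is
#' the fraction of null values at least as far from the null median as the
#' observed `tA`, floored at `1 / n_boot`.
#'
#' @inheritParams perturbation_factors
#' @param de_pool Numeric vector of all differential-gene log2 ratios (the
#'   resampling pool).
#' @param n_boot Bootstrap rounds (>= 100; the reference analysis used
#'   3,000).
#' @param seed Integer seed.
#' @return A list with `p_pert`, `ta_obs`, and the null vector `ta_null`.
#' @export
p_pert <- function(topology, delta_e, de_pool, n_boot = 3000L, seed) {
  if (n_boot < 100) abort("`n_boot` must be >= 100")
  genes <- topology$genes
  n_de <- sum(names(delta_e) %in% genes & delta_e != 0)
  obs <- perturbation_factors(topology, delta_e)
  if (is.null(obs)) return(NULL)
  if (n_de == 0) return(list(p_pert = 1, ta_obs = 0, ta_null = numeric()))
  inv <- solve(diag(length(genes)) - topology$B)
  withr_seed(seed)
  ta_null <- vapply(seq_len(n_boot), function(b) {
    pos <- sample.int(length(genes), n_de)
    de_b <- numeric(length(genes))
    de_b[pos] <- sample(de_pool, n_de, replace = TRUE)
    pf <- inv %*% de_b
    sum(pf - de_b)
  }, numeric(1))
  med <- stats::median(ta_null)
  p <- mean(abs(ta_null - med) >= abs(obs$ta - med))
  list(p_pert = max(p, 1 / n_boot), ta_obs = obs$ta, ta_null = ta_null)
}

#' Combine over-representation and perturbation evidence
#'
#' Fisher product combination of two independent probabilities:
#' `c = p_nde * p_pert` and `P_G = c - c * log(c)`, the upper tail of a
#' chi-squared distribution with 4 degrees of freedom at `-2 log(c)`.
#'
#' @param p_nde,p_pert Probabilities in `(0, 1]`.
#' @return The global probability `P_G`.
#' @export
combine_global <- function(p_nde, p_pert) {
  if (any(c(p_nde, p_pert) <= 0) || any(c(p_nde, p_pert) > 1))
    abort("both probabilities must lie in (0, 1]")
  cc <- p_nde * p_pert
  ifelse(cc == 1, 1, cc - cc * log(cc))
}

#' Classify pathways by global significance
#'
#' @param results Tibble with a `p_g` column (one row per analyzable
#'   pathway).
#' @param alpha Significance level (default 0.01).
#' @return The input with a `class` column: `"bonferroni"` when
#'   `p_g <= alpha / M`, else `"fdr"` when the BH-adjusted `p_g <= alpha`,
#'   else `"ns"`.
#' @export
classify_pathways <- function(results, alpha = 0.01) {
  stopifnot("p_g" %in% names(results))
  M <- nrow(results)
  adj <- bh_adjust(results$p_g)
  results$p_g_fdr <- adj
  results$class <- dplyr::case_when(
    results$p_g <= alpha / M ~ "bonferroni",
    adj <= alpha ~ "fdr",
    .default = "ns"
  )
  results
}

#' Topology-based pathway impact analysis
#'
#' For each pathway: over-representation evidence `P_NDE` (hypergeometric
#' upper tail), perturbation evidence `P_PERT` (topology bootstrap of the
#' total net accumulation `tA`), the combined global `P_G` (Fisher product),
#' and a significance class at level `alpha` (Bonferroni / FDR / ns).
#' Pathways with a singular `(I - B)` or no differential genes are excluded
#' from classification and reported separately.
#'
#' @param topologies A list of `pathway_topology` objects.
#' @param de_table Tibble with columns `gene`, `log2_ratio` for the
#'   differential genes.
#' @param universe Character vector, the gene background.
#' @param n_boot Bootstrap rounds per pathway (default 3000).
#' @param alpha Significance level (default 0.01).
#' @param seed Integer seed.
#' @return An object of class `spia_fit`: list with `results` (classified
#'   tibble: pathway, pathway_size, n_de, ta, p_nde, p_pert, p_g, p_g_fdr,
#'   class) and `excluded` (tibble: pathway, reason).
#' @export
run_spia <- function(topologies, de_table, universe, n_boot = 3000L,
                     alpha = 0.01, seed) {
  stopifnot(all(c("gene", "log2_ratio") %in% names(de_table)))
  universe <- unique(as.character(universe))
  de_table <- dplyr::filter(de_table, .data$gene %in% universe)
  de <- stats::setNames(de_table$log2_ratio, de_table$gene)
  rows <- list(); excl <- list()
  for (i in seq_along(topologies)) {
    topo <- topologies[[i]]
    genes_u <- intersect(topo$genes, universe)
    n_on <- sum(names(de) %in% topo$genes)
    if (n_on == 0) {
      excl[[length(excl) + 1]] <- tibble(pathway = topo$name, reason = "no differential genes")
      next
    }
    pert <- p_pert(topo, de, de_pool = de_table$log2_ratio, n_boot = n_boot,
                   seed = child_seed(seed, i))
    if (is.null(pert)) {
      excl[[length(excl) + 1]] <- tibble(pathway = topo$name, reason = "singular (I - B)")
      next
    }
    pn <- p_nde(sum(names(de) %in% genes_u), length(genes_u), length(de), length(universe))
    rows[[length(rows) + 1]] <- tibble(
      pathway = topo$name, pathway_size = length(genes_u), n_de = n_on,
      ta = pert$ta_obs, p_nde = pn, p_pert = pert$p_pert,
      p_g = combine_global(pn, pert$p_pert)
    )
  }
  results <- if (length(rows)) classify_pathways(dplyr::bind_rows(rows), alpha)
             else tibble()
  structure(
    list(results = results,
         excluded = if (length(excl)) dplyr::bind_rows(excl)
                    else tibble(pathway = character(), reason = character()),
         alpha = alpha),
    class = "spia_fit"
  )
}

#' @export
print.spia_fit <- function(x, ...) {
  cat("<spia_fit>", nrow(x$results), "pathways analyzed,", nrow(x$excluded),
      "excluded | classes:", paste(names(table(x$results$class)),
                                   table(x$results$class), collapse = ", "), "\n")
  invisible(x)
}
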