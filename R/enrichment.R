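#' Benjamini-Hochberg step-up adjustment
#'
#' Thin, validated wrapper around the standard step-up procedure
#' (`stats::p.adjust(method = "BH")`): sort ascending, take
#' `q_i = min_{j >= i} p_j * M / j`, clip at 1, return in input order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric())
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    abort("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Gene-set over-representation by Fisher's exact test
#'
#' One-sided (over-representation) hypergeometric tail probability
#' `P(X >= k)` for the overlap `k` between a query gene list and each set in
#' a collection, against a gene universe; Benjamini-Hochberg FDR across sets.
#' Sets are intersected with the universe before testing, as is the query.
#'
#' @param query Character vector of query gene ids (a subset of `universe`).
#' @param collection Gene-set tibble with columns `set`, `gene` (signs, if
#'   present, are ignored).
#' @param universe Character vector: the gene background (e.g. all genes
#'   surviving preprocessing).
#' @param ease When `TRUE`, applies the EASE-score variant that deducts one
#'   from the overlap count before taking the tail (default `FALSE`, plain
#'   Fisher).
#' @return A tibble sorted by ascending p with columns `set`, `overlap` (k),
#'   `set_size` (K), `query_size` (n), `universe_size` (N), `p_value`, `fdr`.
#' @export
fisher_enrichment <- function(query, collection, universe, ease = FALSE) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) abort("empty universe")
  query <- intersect(unique(as.character(query)), universe)
  sets <- collection |>
    dplyr::distinct(.data$set, .data$gene) |>
    dplyr::filter(.data$gene %in% universe)
  n <- length(query)
  N <- length(universe)
  res <- sets |>
    dplyr::group_by(.data$set) |>
    dplyr::summarise(
      overlap = sum(.data$gene %in% query),
      set_size = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      query_size = n,
      universe_size = N,
      p_value = hypergeom_tail(.data$overlap - as.integer(ease),
                               .data$set_size, n, N)
    ) |>
    dplyr::arrange(.data$p_value, .data$set)
  res$fdr <- bh_adjust(res$p_value)
  res
}

# Upper-tail hypergeometric probability P(X >= k) of drawing k or more
# members of a K-sized set in n draws from a universe of size N.
hypergeom_tail <- function(k, K, n, N) {
  k <- pmax(k, 0)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}
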