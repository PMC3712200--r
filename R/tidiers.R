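#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a pattern-mining fit
#'
#' @param x A `pattern_fit`.
#' @param ... Unused.
#' @return One row per profile: `profile_id`, `class`, `n_genes`, `expected`,
#'   `fdr`, `perm_p`.
#' @method tidy pattern_fit
#' @export
tidy.pattern_fit <- function(x, ...) {
  x$profile_stats |>
    dplyr::select("profile_id", "class", "n_genes", "expected", "eo_fdr",
                  "perm_p", "significant")
}

#' @rdname tidy.pattern_fit
#' @return `glance` returns a one-row summary: gene and profile counts,
#'   Down-/Up-pattern sizes and the FDR threshold.
#' @method glance pattern_fit
#' @export
glance.pattern_fit <- function(x, ...) {
  tibble(
    n_genes = nrow(x$assignment),
    n_profiles = nrow(x$profiles),
    n_down = length(x$down_genes),
    n_up = length(x$up_genes),
    n_significant = sum(x$profile_stats$significant),
    fdr_threshold = x$config$fdr_threshold
  )
}

#' Tidy a pathway impact analysis fit
#'
#' @param x A `spia_fit`.
#' @param ... Unused.
#' @return One row per analyzable pathway with evidence and class columns.
#' @method tidy spia_fit
#' @export
tidy.spia_fit <- function(x, ...) x$results

#' @rdname tidy.spia_fit
#' @method glance spia_fit
#' @export
glance.spia_fit <- function(x, ...) {
  tibble(
    n_pathways = nrow(x$results),
    n_excluded = nrow(x$excluded),
    n_bonferroni = sum(x$results$class == "bonferroni"),
    n_fdr = sum(x$results$class == "fdr"),
    alpha = x$alpha
  )
}

#' Tidy a univariate Cox fit
#'
#' @param x A `coxu_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `beta`, `hazard_ratio`, `se`, `p_value`.
#' @method tidy coxu_fit
#' @export
tidy.coxu_fit <- function(x, ...) {
  tibble(beta = x$beta, hazard_ratio = x$hazard_ratio, se = x$se,
         p_value = x$p_value)
}

#' @rdname tidy.coxu_fit
#' @method glance coxu_fit
#' @export
glance.coxu_fit <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events, iterations = x$iterations,
         converged = x$converged)
}

#' Tidy a pattern-vs-hazard contingency result
#'
#' @param x A `contingency_result`.
#' @param ... Unused.
#' @return One row per cell: `pattern`, `hazard`, `count`.
#' @method tidy contingency_result
#' @export
tidy.contingency_result <- function(x, ...) {
  as_tibble(as.data.frame(as.table(x$counts))) |>
    dplyr::rename(count = "Freq") |>
    dplyr::mutate(pattern = as.character(.data$pattern),
                  hazard = as.character(.data$hazard))
}

#' @rdname tidy.contingency_result
#' @method glance contingency_result
#' @export
glance.contingency_result <- function(x, ...) {
  tibble(odds_ratio = x$odds_ratio, p_value = x$p_value,
         n = sum(x$counts), degenerate = x$degenerate)
}
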