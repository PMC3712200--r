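#' Filter probes by local-background signal
#'
#' Removes array elements whose foreground signal does not exceed
#' `factor` times the local background. The default keeps a probe only when
#' the criterion holds in every sample (`mode = "every"`); `mode = "any"`
#' keeps probes passing in at least one sample.
#'
#' @param raw A long tibble with columns `probe`, `sample`, `signal`,
#'   `background` (and optionally `gene`).
#' @param factor Positive multiple of the background required of the signal
#'   (default 1.4).
#' @param mode `"every"` (default) or `"any"`: whether the criterion must
#'   hold in all samples or at least one.
#' @return The retained rows, with attribute `n_eliminated` giving the number
#'   of probes removed.
#' @export
filter_low_signal <- function(raw, factor = 1.4, mode = c("every", "any")) {
  mode <- match.arg(mode)
  stopifnot(all(c("probe", "sample", "signal", "background") %in% names(raw)))
  if (nrow(raw) == 0) abort("empty intensity matrix")
  if (factor < 0) abort("`factor` must be non-negative")
  ok <- raw |>
    dplyr::group_by(.data$probe) |>
    dplyr::summarise(keep = if (mode == "every") all(.data$signal >= factor * .data$background)
                     else any(.data$signal >= factor * .data$background),
                     .groups = "drop")
  kept <- ok$probe[ok$keep]
  out <- dplyr::filter(raw, .data$probe %in% kept)
  attr(out, "n_eliminated") <- sum(!ok$keep)
  out
}

#' Quantile-normalize intensity columns
#'
#' Forces every sample column onto the same empirical distribution (the
#' row-wise mean of the per-sample sorted values), preserving within-sample
#' rank order. Ties share the average of the sorted-mean values across the
#' tied ranks.
#'
#' @param x A tibble whose first column is an id (probe or gene) followed by
#'   numeric sample columns of equal length, or a plain numeric matrix.
#' @return Same shape as the input, with normalized values.
#' @export
#' @examples
#' quantile_normalize(tibble::tibble(probe = c("p1", "p2"),
#'                                   a = c(1, 5), b = c(3, 7)))
quantile_normalize <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) < 2) abort("need at least 2 sample columns")
    return(limma::normalizeQuantiles(x, ties = TRUE))
  }
  m <- as_expr_matrix(x)
  if (ncol(m) < 2) abort("need at least 2 sample columns")
  norm <- limma::normalizeQuantiles(m, ties = TRUE)
  out <- x
  out[, -1] <- as.data.frame(norm)
  out
}

#' Average duplicate probes per gene
#'
#' Collapses a probe-level table to gene level by the arithmetic mean of each
#' gene's probes per sample. Probes without a gene mapping are dropped.
#'
#' @param x A tibble with a `probe` id column, numeric sample columns, and
#'   either a `gene` column or a separate `probe_to_gene` map.
#' @param probe_to_gene Optional data frame with columns `probe`, `gene`.
#' @return A tibble with column `gene` followed by the per-sample means.
#' @export
collapse_probes <- function(x, probe_to_gene = NULL) {
  if (!is.null(probe_to_gene)) {
    stopifnot(all(c("probe", "gene") %in% names(probe_to_gene)))
    x <- x |>
      dplyr::select(-dplyr::any_of("gene")) |>
      dplyr::inner_join(as_tibble(probe_to_gene), by = "probe")
  }
  if (!"gene" %in% names(x)) abort("no `gene` column and no `probe_to_gene` map")
  x |>
    dplyr::filter(!is.na(.data$gene), .data$gene != "") |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric), mean), .groups = "drop")
}

#' Log2 treated/control expression ratios
#'
#' @param x A tibble with an id column first, then strictly positive
#'   normalized intensity columns, one of which is the vehicle control.
#' @param control Name of the control column.
#' @return A tibble with the id column and one `log2(treated/control)` column
#'   per treated sample (control column dropped), in the input order.
#' @export
compute_log_ratios <- function(x, control) {
  stopifnot(control %in% names(x))
  id <- names(x)[1]
  treated <- setdiff(names(x)[-1], control)
  vals <- as.matrix(x[, c(treated, control)])
  bad <- which(vals <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("non-positive intensity for id '%s' in sample '%s'",
                  x[[id]][bad[1, 1]], c(treated, control)[bad[1, 2]]))
  }
  out <- x[, id, drop = FALSE]
  for (s in treated) out[[s]] <- log2(x[[s]] / x[[control]])
  as_tibble(out)
}

#' Select differentially expressed genes by fold change
#'
#' A gene is retained when its absolute log2 ratio reaches
#' `log2(fold_threshold)` in at least one sample (fold ratio greater than the
#' threshold or less than its reciprocal).
#'
#' @param expr Expression tibble (`gene` + log2-ratio sample columns).
#' @param fold_threshold Fold-change cutoff on the natural scale (> 1),
#'   default 2.
#' @return Character vector of retained gene ids.
#' @export
select_differential <- function(expr, fold_threshold = 2) {
  if (fold_threshold <= 1) abort("`fold_threshold` must be > 1")
  m <- as_expr_matrix(expr)
  cut <- log2(fold_threshold)
  rownames(m)[apply(abs(m) >= cut, 1, any)]
}

#' Run the full preprocessing chain
#'
#' Background filter, quantile normalization, log ratios against the vehicle
#' control, then duplicate-probe averaging on the ratios, in that order.
#'
#' @inheritParams filter_low_signal
#' @param control Name of the control sample.
#' @param probe_to_gene Optional probe-to-gene map (else `raw$gene` is used).
#' @param factor Background filter multiple (default 1.4).
#' @return Gene-level log2-ratio tibble (`gene` + treated sample columns).
#' @export
preprocess_raw <- function(raw, control, probe_to_gene = NULL, factor = 1.4,
                           mode = c("every", "any")) {
  kept <- filter_low_signal(raw, factor = factor, mode = match.arg(mode))
  wide <- kept |>
    dplyr::select(dplyr::all_of(c("probe", "sample", "signal"))) |>
    tidyr::pivot_wider(names_from = "sample", values_from = "signal")
  norm <- quantile_normalize(wide)
  ratios <- compute_log_ratios(norm, control = control)
  map <- probe_to_gene %||% dplyr::distinct(kept, .data$probe, .data$gene)
  collapse_probes(ratios, probe_to_gene = map)
}
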