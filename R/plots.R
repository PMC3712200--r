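#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_tile
#'   geom_hline geom_vline facet_wrap labs scale_fill_gradient2
#'   scale_fill_gradient theme_minimal
#' @export
ggplot2::autoplot

#' Plot mined expression profiles
#'
#' One panel per significant profile showing the member genes' mean
#' trajectory (control anchor at 0) and the model profile.
#'
#' @param object A `pattern_fit`.
#' @param max_profiles Show at most this many significant profiles (by FDR).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pattern_fit
#' @export
autoplot.pattern_fit <- function(object, max_profiles = 9, ...) {
  sig <- object$profile_stats |>
    dplyr::filter(.data$significant) |>
    dplyr::arrange(.data$perm_p) |>
    utils::head(max_profiles)
  if (nrow(sig) == 0) sig <- utils::head(dplyr::arrange(object$profile_stats, .data$perm_p), max_profiles)
  prof_long <- purrr::map_dfr(sig$profile_id, function(id) {
    v <- object$profiles[id, ]
    tibble(profile_id = id, point = seq_along(v) - 1L,
           value = as.numeric(v) / max(1, max(abs(v))))
  })
  p <- ggplot(prof_long, aes(x = .data$point, y = .data$value)) +
    geom_line(linewidth = 1) + geom_point() +
    facet_wrap(~profile_id, labeller = "label_both") +
    labs(x = "dose rank (0 = control)", y = "profile value (scaled)",
         title = "Significant dose-response profiles") +
    theme_minimal()
  p
}

#' Evidence-plane plot for pathway impact analysis
#'
#' Scatter of `-log10(P_NDE)` against `-log10(P_PERT)` with points colored by
#' significance class and the per-axis thresholds at the combined
#' significance level drawn as guides.
#'
#' @param object A `spia_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spia_fit
#' @export
autoplot.spia_fit <- function(object, ...) {
  res <- object$results
  if (nrow(res) == 0) abort("no analyzable pathways to plot")
  thr <- -log10(object$alpha)
  ggplot(res, aes(x = -log10(.data$p_nde), y = -log10(.data$p_pert),
                  color = .data$class)) +
    geom_point(size = 2) +
    geom_hline(yintercept = thr, linetype = "dashed") +
    geom_vline(xintercept = thr, linetype = "dashed") +
    labs(x = expression(-log[10](P[NDE])), y = expression(-log[10](P[PERT])),
         title = "Pathway impact evidence plane", color = "class") +
    theme_minimal()
}

#' Heatmap of normalized pathway activities
#'
#' Tiles of per-sample normalized activity, pathways ordered by the
#' hierarchical clustering.
#'
#' @param normalized Normalized activity tibble ([normalize_activities()]).
#' @param clusters Optional `activity_clusters` giving the row order.
#' @return A ggplot object.
#' @export
plot_activity_heatmap <- function(normalized, clusters = NULL) {
  samp <- setdiff(names(normalized)[vapply(normalized, is.numeric, logical(1))],
                  "coverage")
  ord <- if (!is.null(clusters)) clusters$order else normalized$set
  long <- normalized |>
    dplyr::filter(.data$set %in% ord) |>
    tidyr::pivot_longer(dplyr::all_of(samp), names_to = "sample",
                        values_to = "activity") |>
    dplyr::mutate(set = factor(.data$set, levels = ord),
                  sample = factor(.data$sample, levels = samp))
  ggplot(long, aes(x = .data$sample, y = .data$set, fill = .data$activity)) +
    geom_tile() +
    scale_fill_gradient2(low = "green4", mid = "black", high = "red") +
    labs(x = "dose sample", y = NULL, fill = "activity (z)",
         title = "Normalized pathway activities") +
    theme_minimal()
}

#' Ordered similarity-matrix heatmap with activity margin
#'
#' @param object A `similarity_clusters`.
#' @param ... Unused.
#' @return A ggplot object; the diagonal is annotated with each pathway's
#'   top-dose activity when activities were merged.
#' @method autoplot similarity_clusters
#' @export
autoplot.similarity_clusters <- function(object, ...) {
  J <- object$ordered_matrix
  long <- as_tibble(as.data.frame(as.table(J)))
  names(long) <- c("p", "q", "jaccard")
  long$p <- factor(long$p, levels = object$order)
  long$q <- factor(long$q, levels = object$order)
  p <- ggplot(long, aes(x = .data$p, y = .data$q, fill = .data$jaccard)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "red3", limits = c(0, 1)) +
    labs(x = NULL, y = NULL, fill = "Jaccard",
         title = "Pathway similarity (clustered)") +
    theme_minimal()
  if (!all(is.na(object$annotation$activity))) {
    diag_df <- object$annotation |>
      dplyr::mutate(p = factor(.data$set, levels = object$order),
                    q = factor(.data$set, levels = object$order))
    p <- p + geom_point(data = diag_df,
                        aes(x = .data$p, y = .data$q, color = .data$activity),
                        inherit.aes = FALSE, size = 2) +
      ggplot2::scale_color_gradient2(low = "green4", mid = "grey60", high = "red",
                                     name = "activity")
  }
  p
}
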