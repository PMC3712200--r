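#' Signed pathway activity per sample
#'
#' The activity of a pathway in a sample is the linear combination of the
#' log2 expression ratios of its genes, each with weight +1, multiplied by
#' -1 for genes acting as repressors:
#' `A_p(s) = sum_g w_g * x_gs`, `w_g` in {+1, -1}. Genes of the set absent
#' from the expression matrix are skipped and counted against coverage.
#'
#' @param expr Expression tibble (`gene` + log2-ratio sample columns).
#' @param gene_set Tibble with columns `gene`, `sign` for one pathway.
#' @param set_name Pathway name used in error messages.
#' @return A list with `activity` (named per-sample vector) and `coverage`
#'   (fraction of set genes present in `expr`).
#' @export
pathway_activity <- function(expr, gene_set, set_name = "gene set") {
  m <- as_expr_matrix(expr)
  gene_set <- dplyr::distinct(as_tibble(gene_set), .data$gene, .keep_all = TRUE)
  present <- gene_set$gene %in% rownames(m)
  if (!any(present)) abort(sprintf("no genes of '%s' are in the expression matrix", set_name))
  g <- gene_set[present, ]
  act <- drop(g$sign %*% m[g$gene, , drop = FALSE])
  list(activity = act, coverage = mean(present))
}

#' Activity matrix for a gene-set collection
#'
#' @inheritParams pathway_activity
#' @param collection Signed gene-set tibble with columns `set`, `gene`,
#'   `sign`.
#' @return A tibble: `set`, `coverage`, then one raw-activity column per
#'   sample.
#' @export
activity_matrix <- function(expr, collection) {
  sets <- split(collection, collection$set)
  rows <- purrr::imap(sets, function(gs, nm) {
    a <- pathway_activity(expr, gs, set_name = nm)
    dplyr::bind_cols(tibble(set = nm, coverage = a$coverage),
                     as_tibble(as.list(a$activity)))
  })
  dplyr::bind_rows(rows)
}

#' Normalize pathway activities across samples
#'
#' Per-pathway z-score across samples using the population standard
#' deviation. Zero-variance pathways are set to all-zero and flagged.
#'
#' @param raw Activity tibble from [activity_matrix()] (`set`, optional
#'   `coverage`, sample columns).
#' @return The same shape plus a logical `constant` column flagging
#'   zero-variance pathways.
#' @export
normalize_activities <- function(raw) {
  samp <- setdiff(names(raw)[vapply(raw, is.numeric, logical(1))], "coverage")
  if (length(samp) < 2) abort("need at least 2 samples to normalize")
  m <- as.matrix(raw[, samp])
  mu <- rowMeans(m)
  sd_pop <- sqrt(rowMeans((m - mu)^2))
  z <- (m - mu) / ifelse(sd_pop > 0, sd_pop, 1)
  z[sd_pop == 0, ] <- 0
  out <- raw
  out[, samp] <- as.data.frame(z)
  out$constant <- sd_pop == 0
  out
}

#' Permutation FDR for pathway activities
#'
#' Per pathway, the test statistic is the maximum absolute raw activity over
#' samples (`statistic = "max_abs"`; `"top_dose"` uses the absolute activity
#' in the last sample instead). The null distribution is built from random
#' gene sets of the same size and sign multiset drawn from the expression
#' matrix's gene universe. The per-pathway empirical p is the fraction of
#' null statistics at least as large as the observed one; Benjamini-Hochberg
#' adjustment across pathways gives the FDR used for screening.
#'
#' @inheritParams activity_matrix
#' @param n_permutations Null draws per pathway (>= 100; the reference
#'   analysis used 1,000).
#' @param seed Integer seed.
#' @param fdr_threshold Screening cutoff on the BH-adjusted FDR (default
#'   0.05).
#' @param statistic `"max_abs"` (default) or `"top_dose"`.
#' @return A tibble: `set`, `statistic`, `perm_p` (pre-adjustment empirical
#'   p), `fdr` (BH-adjusted), `significant`.
#' @export
activity_fdr <- function(expr, collection, n_permutations = 1000L, seed,
                         fdr_threshold = 0.05, statistic = c("max_abs", "top_dose")) {
  statistic <- match.arg(statistic)
  if (n_permutations < 100) abort("`n_permutations` must be >= 100")
  m <- as_expr_matrix(expr)
  stat_fun <- function(act) if (statistic == "max_abs") max(abs(act)) else abs(act[length(act)])
  sets <- split(collection, collection$set)
  rows <- purrr::imap(sets, function(gs, nm) {
    gs <- dplyr::distinct(gs, .data$gene, .keep_all = TRUE)
    gs <- gs[gs$gene %in% rownames(m), ]
    if (nrow(gs) == 0) abort(sprintf("no genes of '%s' are in the expression matrix", nm))
    if (nrow(gs) > nrow(m)) abort(sprintf("'%s' is larger than the gene universe", nm))
    # null stream keyed by set content, not set name: identical pathways get
    # identical FDRs under the same seed
    content_key <- sum(utf8ToInt(paste(sort(paste0(gs$gene, gs$sign)), collapse = ""))) %% 65521L
    withr_seed(child_seed(seed, content_key))
    obs <- stat_fun(drop(gs$sign %*% m[gs$gene, , drop = FALSE]))
    null <- vapply(seq_len(n_permutations), function(b) {
      idx <- sample.int(nrow(m), nrow(gs))
      stat_fun(drop(gs$sign %*% m[idx, , drop = FALSE]))
    }, numeric(1))
    tibble(set = nm, statistic = obs, perm_p = mean(null >= obs))
  })
  out <- dplyr::bind_rows(rows)
  out$fdr <- bh_adjust(out$perm_p)
  out$significant <- out$fdr < fdr_threshold
  out
}

#' Hierarchically cluster pathway activities
#'
#' Agglomerative clustering of pathways over their normalized per-sample
#' activities (default: average linkage on correlation distance `1 - r`).
#' The two principal subclusters are reported together with each subcluster's
#' mean dose trend (the sign of the correlation between dose rank and mean
#' activity), reproducing the decreasing-vs-increasing split of the study
#' design.
#'
#' @param normalized Normalized activity tibble from [normalize_activities()]
#'   (constant pathways are dropped with a warning).
#' @param linkage Linkage method for `stats::hclust` (default "average").
#' @param metric `"correlation"` (default) or `"euclidean"`.
#' @return An object of class `activity_clusters`: list with `order` (pathway
#'   ids in dendrogram order), `hclust`, `subclusters` (tibble: set, cluster),
#'   `trends` (tibble: cluster, mean dose trend sign).
#' @export
cluster_activities <- function(normalized, linkage = "average",
                               metric = c("correlation", "euclidean")) {
  metric <- match.arg(metric)
  keep <- if ("constant" %in% names(normalized)) !normalized$constant
          else rep(TRUE, nrow(normalized))
  if (any(!keep)) warn(sprintf("dropping %d constant pathway(s) from clustering", sum(!keep)))
  norm <- normalized[keep, ]
  samp <- setdiff(names(norm)[vapply(norm, is.numeric, logical(1))], "coverage")
  if (nrow(norm) < 2) abort("need at least 2 pathways to cluster")
  m <- as.matrix(norm[, samp]); rownames(m) <- norm$set
  d <- if (metric == "correlation") stats::as.dist(1 - stats::cor(t(m)))
       else stats::dist(m)
  hc <- stats::hclust(d, method = linkage)
  cl <- stats::cutree(hc, k = 2)
  trends <- tibble(cluster = sort(unique(cl))) |>
    dplyr::mutate(trend = vapply(.data$cluster, function(k) {
      prof <- colMeans(m[cl == k, , drop = FALSE])
      sign(stats::cor(seq_along(prof), prof))
    }, numeric(1)))
  structure(
    list(order = rownames(m)[hc$order], hclust = hc,
         subclusters = tibble(set = rownames(m), cluster = unname(cl)),
         trends = trends),
    class = "activity_clusters"
  )
}

#' @export
print.activity_clusters <- function(x, ...) {
  n <- table(x$subclusters$cluster)
  cat("<activity_clusters>", length(x$order), "pathways | subcluster sizes:",
      paste(n, collapse = "/"), "| trends:",
      paste(ifelse(x$trends$trend > 0, "increasing", "decreasing"), collapse = ", "), "\n")
  invisible(x)
}
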