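#' Jaccard similarity matrix of gene sets
#'
#' `J(p, q) = |genes(p) & genes(q)| / |genes(p) | genes(q)|` over set
#' memberships (signs ignored). Joint absences never contribute; a pair with
#' an empty union is defined as 0. The diagonal is 1.
#'
#' @param collection Gene-set tibble with columns `set`, `gene`.
#' @return A symmetric numeric matrix with set names as dimnames, values in
#'   `[0, 1]`.
#' @export
jaccard_matrix <- function(collection) {
  members <- lapply(split(as.character(collection$gene), collection$set), unique)
  if (length(members) < 2) abort("need at least 2 gene sets")
  ids <- names(members)
  genes <- unique(unlist(members))
  inc <- vapply(members, function(g) genes %in% g, logical(length(genes)))
  inter <- crossprod(inc * 1)            # |A & B|
  sizes <- diag(inter)
  uni <- outer(sizes, sizes, "+") - inter
  J <- ifelse(uni > 0, inter / uni, 0)
  diag(J) <- 1
  dimnames(J) <- list(ids, ids)
  J
}

#' Cluster the similarity matrix and merge pathway activities
#'
#' Agglomerative clustering (default average linkage) on the dissimilarity
#' `1 - J`. The clustering uses the similarity matrix only; each pathway's
#' normalized activity at the top dose is then attached as the diagonal /
#' margin annotation.
#'
#' @param J Similarity matrix from [jaccard_matrix()].
#' @param activities Normalized activity tibble ([normalize_activities()]);
#'   its pathway ids must all appear in `J`. May be `NULL` to skip the merge.
#' @param linkage Linkage method (default "average").
#' @return An object of class `similarity_clusters`: list with `order`
#'   (pathway ids in dendrogram order), `hclust`, `ordered_matrix`, and
#'   `annotation` (tibble: set, activity at top dose; `NA` when no
#'   activities were supplied).
#' @export
cluster_similarity <- function(J, activities = NULL, linkage = "average") {
  if (nrow(J) < 2) abort("need at least 2 pathways")
  hc <- stats::hclust(stats::as.dist(1 - J), method = linkage)
  ord <- rownames(J)[hc$order]
  ann <- tibble(set = ord, activity = NA_real_)
  if (!is.null(activities)) {
    if (!all(activities$set %in% rownames(J)))
      abort("activity pathway ids must be a subset of the similarity matrix ids")
    samp <- setdiff(names(activities)[vapply(activities, is.numeric, logical(1))],
                    "coverage")
    top <- samp[length(samp)]
    ann <- dplyr::left_join(ann,
                            dplyr::select(activities, "set", activity_top = dplyr::all_of(top)),
                            by = "set") |>
      dplyr::mutate(activity = .data$activity_top, activity_top = NULL)
  }
  structure(
    list(order = ord, hclust = hc, ordered_matrix = J[ord, ord],
         annotation = ann),
    class = "similarity_clusters"
  )
}

#' @export
print.similarity_clusters <- function(x, ...) {
  cat("<similarity_clusters>", length(x$order), "pathways | mean off-diagonal J =",
      signif(mean(x$ordered_matrix[upper.tri(x$ordered_matrix)]), 3), "\n")
  invisible(x)
}
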