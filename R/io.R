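#' Read and write expression matrices as TSV
#'
#' Tab-separated, one row per gene; first column `gene`, remaining columns
#' are ordered sample labels (doses) of log2 treated/control ratios.
#'
#' @param path File path.
#' @param expr Expression tibble.
#' @return `read_expression_tsv` returns the expression tibble;
#'   `write_expression_tsv` returns `path` invisibly.
#' @export
read_expression_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  names(out)[1] <- "gene"
  out$gene <- as.character(out$gene)
  out
}

#' @rdname read_expression_tsv
#' @export
write_expression_tsv <- function(expr, path) {
  readr::write_tsv(expr, path)
  invisible(path)
}

#' Read and write signed gene sets in GMT form
#'
#' One set per line: name, description, then members annotated with their
#' sign as `GENE|+1` (activator) or `GENE|-1` (repressor). Members without an
#' annotation are read as activators.
#'
#' @param path File path.
#' @param collection Gene-set tibble (`set`, `gene`, `sign`).
#' @param descriptions Optional named character vector of set descriptions.
#' @return `read_gmt` returns the gene-set tibble; `write_gmt` returns `path`
#'   invisibly.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  rows <- purrr::map_dfr(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) abort("malformed GMT line: fewer than 3 fields")
    members <- f[-(1:2)]
    has_sign <- grepl("\\|[+-]?1$", members)
    gene <- ifelse(has_sign, sub("\\|[+-]?1$", "", members), members)
    sign <- ifelse(has_sign & grepl("\\|-1$", members), -1, 1)
    tibble(set = f[1], gene = gene, sign = sign)
  })
  rows
}

#' @rdname read_gmt
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  sets <- split(collection, collection$set)
  lines <- purrr::imap_chr(sets, function(gs, nm) {
    desc <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else "na"
    members <- sprintf("%s|%+d", gs$gene, as.integer(gs$sign))
    paste(c(nm, desc, members), collapse = "\t")
  })
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read and write signed topologies as 3-column TSV
#'
#' Columns `source`, `target`, `sign` (+1 activation, -1 inhibition), one
#' edge per row.
#'
#' @param path File path.
#' @param topology A `pathway_topology`.
#' @param genes Optional pathway gene universe for isolated genes.
#' @param name Pathway name for the object read back.
#' @return `read_topology_tsv` returns a `pathway_topology`;
#'   `write_topology_tsv` returns `path` invisibly.
#' @export
read_topology_tsv <- function(path, genes = NULL, name = NULL) {
  edges <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             source = readr::col_character(),
                             target = readr::col_character(),
                             sign = readr::col_double()
                           ))
  pathway_topology(edges, genes = genes,
                   name = name %||% sub("\\.tsv$", "", basename(path)))
}

#' @rdname read_topology_tsv
#' @export
write_topology_tsv <- function(topology, path) {
  readr::write_tsv(topology$edges, path)
  invisible(path)
}

#' Read and write subject-level survival tables as TSV
#'
#' Columns `subject`, `time`, `event` (0/1 or logical), then one numeric
#' column per gene.
#'
#' @param path File path.
#' @param survival_data Survival tibble.
#' @return `read_survival_tsv` returns the survival tibble;
#'   `write_survival_tsv` returns `path` invisibly.
#' @export
read_survival_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("subject", "time", "event") %in% names(out)))
  out$event <- as.logical(out$event)
  out
}

#' @rdname read_survival_tsv
#' @export
write_survival_tsv <- function(survival_data, path) {
  out <- survival_data
  out$event <- as.integer(out$event)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Packaged survival-gene table
#'
#' The per-gene survival screening table shipped with the package
#' (`table3.tsv`): Down-/Up-pattern genes of the dose series with their log2
#' fold induction at the top dose, log-rank screening p-value and Cox hazard
#' ratio from a public lung-cancer cohort.
#'
#' @return A tibble with columns `gene`, `pattern`, `fold_induction`,
#'   `p_value`, `hazard_ratio`.
#' @export
survival_gene_table <- function() {
  path <- system.file("extdata", "table3.tsv", package = "dosepath",
                      mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE)
}
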