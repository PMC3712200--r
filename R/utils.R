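#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Convert a genes-x-samples tibble (first column = gene id) to a numeric
# matrix with gene rownames; sample order is the column order.
as_expr_matrix <- function(expr) {
  stopifnot(is.data.frame(expr), ncol(expr) >= 2)
  m <- as.matrix(expr[, -1, drop = FALSE])
  if (!is.numeric(m)) abort("expression values must be numeric")
  rownames(m) <- as.character(expr[[1]])
  m
}

expr_tibble <- function(m, id_name = "gene") {
  out <- as_tibble(m, .name_repair = "minimal")
  out <- tibble(!!id_name := rownames(m)) |> dplyr::bind_cols(out)
  out
}

# Rand index between two label vectors: fraction of pairs on which the
# two partitions agree (both together or both apart).
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}

# Seed helper: deterministic child seeds below 2^31 derived from one seed.
# Arithmetic in doubles (exact below 2^53) to avoid integer overflow.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(k)) %% 2147483647)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    abort(sprintf("`%s` must be a single value in [0, 1]", name))
  x
}
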