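#' Dose-series design
#'
#' Describes the ordered treatment series: dose levels in increasing order,
#' with the first level the vehicle control (dose 0), and the number of
#' arrays per level. The default matches a 4-point series of 0, 1.25, 5 and
#' 20 ug/mL with a single array per dose.
#'
#' @param dose_levels Numeric vector of non-negative concentrations (ug/mL),
#'   strictly increasing, first entry 0 (vehicle control). At least 3 levels.
#' @param replicate_count Positive integer, arrays per dose level.
#' @return An object of class `dose_design`.
#' @export
#' @examples
#' dose_design()
dose_design <- function(dose_levels = c(0, 1.25, 5, 20), replicate_count = 1L) {
  if (length(dose_levels) < 3) abort("`dose_levels` needs at least 3 levels")
  if (any(dose_levels < 0)) abort("`dose_levels` must be non-negative")
  if (any(diff(dose_levels) <= 0)) abort("`dose_levels` must be strictly increasing")
  if (dose_levels[1] != 0) abort("the first dose level must be the vehicle control (0)")
  replicate_count <- as.integer(replicate_count)
  if (is.na(replicate_count) || replicate_count < 1) abort("`replicate_count` must be >= 1")
  structure(
    list(dose_levels = as.numeric(dose_levels), replicate_count = replicate_count),
    class = "dose_design"
  )
}

#' @export
print.dose_design <- function(x, ...) {
  cat("<dose_design> levels (ug/mL):", paste(x$dose_levels, collapse = ", "),
      "| replicates per level:", x$replicate_count, "\n")
  invisible(x)
}

# Sample labels for the treated (non-control) columns, in dose order.
treated_labels <- function(design) {
  doses <- design$dose_levels[-1]
  if (design$replicate_count == 1L) return(as.character(doses))
  as.vector(t(outer(doses, seq_len(design$replicate_count),
                    function(d, r) paste0(d, "_r", r))))
}

#' Planted ground truth for the expression simulator
#'
#' Partitions a gene universe into monotonically up-regulated, monotonically
#' down-regulated and null genes, and fixes the signal scale.
#'
#' @param n_genes Size of the gene universe.
#' @param frac_up,frac_down Fractions of the universe planted as monotone
#'   up / down genes (the rest are null).
#' @param effect_size Maximum absolute log2 ratio, reached at the top dose.
#' @param noise_sd Standard deviation of the i.i.d. Gaussian noise added to
#'   every log2 ratio.
#' @param up_genes,down_genes,null_genes Alternatively, explicit disjoint
#'   gene-id sets whose union is the universe (overrides `n_genes`/fractions).
#' @return An object of class `planted_truth` with fields `up_genes`,
#'   `down_genes`, `null_genes`, `effect_size`, `noise_sd`.
#' @export
#' @examples
#' planted_truth(n_genes = 100, frac_up = 0.1, frac_down = 0.1,
#'               effect_size = 3, noise_sd = 0.5)
planted_truth <- function(n_genes = 3000, frac_up = 0.1, frac_down = 0.1,
                          effect_size = 3, noise_sd = 0.5,
                          up_genes = NULL, down_genes = NULL, null_genes = NULL) {
  if (effect_size <= 0) abort("`effect_size` must be positive")
  if (noise_sd < 0) abort("`noise_sd` must be non-negative")
  if (is.null(up_genes) && is.null(down_genes) && is.null(null_genes)) {
    if (n_genes < 1) abort("empty gene universe")
    if (frac_up + frac_down > 1) abort("`frac_up + frac_down` must be <= 1")
    ids <- sprintf("g%05d", seq_len(n_genes))
    n_up <- round(frac_up * n_genes)
    n_down <- round(frac_down * n_genes)
    up_genes <- ids[seq_len(n_up)]
    down_genes <- ids[n_up + seq_len(n_down)]
    null_genes <- setdiff(ids, c(up_genes, down_genes))
  } else {
    up_genes <- as.character(up_genes %||% character())
    down_genes <- as.character(down_genes %||% character())
    null_genes <- as.character(null_genes %||% character())
    all_ids <- c(up_genes, down_genes, null_genes)
    if (length(all_ids) == 0) abort("empty gene universe")
    if (anyDuplicated(all_ids)) abort("gene sets of a planted truth must be disjoint")
  }
  structure(
    list(up_genes = up_genes, down_genes = down_genes, null_genes = null_genes,
         effect_size = effect_size, noise_sd = noise_sd),
    class = "planted_truth"
  )
}

#' @export
print.planted_truth <- function(x, ...) {
  cat("<planted_truth>", length(x$up_genes), "up,", length(x$down_genes), "down,",
      length(x$null_genes), "null | effect", x$effect_size, "| noise sd", x$noise_sd, "\n")
  invisible(x)
}

#' Simulate a dose-response log-ratio expression matrix
#'
#' Generates log2 treated/control ratios for each gene at each treated dose.
#' Planted up genes follow a profile linear in dose rank, scaled so the
#' expectation at the top dose equals `effect_size`; down genes are the
#' mirror image; null genes have expectation zero. I.i.d. Gaussian noise with
#' sd `noise_sd` is added everywhere.
#'
#' @param design A [dose_design()].
#' @param truth A [planted_truth()].
#' @param seed Integer seed; the output is deterministic given the seed.
#' @return A tibble with column `gene` followed by one numeric column per
#'   treated sample (named by dose), in dose order.
#' @export
#' @examples
#' expr <- simulate_dose_expression(dose_design(),
#'   planted_truth(n_genes = 50, effect_size = 3, noise_sd = 0.5), seed = 1)
simulate_dose_expression <- function(design, truth, seed) {
  stopifnot(inherits(design, "dose_design"), inherits(truth, "planted_truth"))
  genes <- c(truth$up_genes, truth$down_genes, truth$null_genes)
  if (length(genes) == 0) abort("empty gene universe")
  n_treated <- length(design$dose_levels) - 1L
  ranks <- seq_len(n_treated) / n_treated          # 1/(k-1) .. 1 over treated doses
  base <- c(rep(1, length(truth$up_genes)), rep(-1, length(truth$down_genes)),
            rep(0, length(truth$null_genes)))
  mu <- outer(base * truth$effect_size, ranks)     # genes x treated doses
  mu <- mu[, rep(seq_len(n_treated), each = design$replicate_count), drop = FALSE]
  withr_seed(seed)
  noise <- matrix(stats::rnorm(length(genes) * ncol(mu), sd = truth$noise_sd),
                  nrow = length(genes))
  m <- mu + noise
  rownames(m) <- genes
  colnames(m) <- treated_labels(design)
  out <- expr_tibble(m)
  out[order(out$gene), , drop = FALSE]
}

# set.seed wrapper kept in one place so every generator uses the same RNG kind
withr_seed <- function(seed) {
  if (is.null(seed) || is.na(seed)) abort("a `seed` is required")
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
}

#' Simulate overlapping signed gene sets
#'
#' Draws `n_sets` gene sets from a universe such that the expected pairwise
#' Jaccard similarity approximates `overlap_fraction`. For positive overlap
#' the sets are sampled from a common pool whose size is chosen from the
#' closed-form expectation `|pool| = s * (1 + f) / (2 f)` (s = mean set size,
#' f = target overlap); for `overlap_fraction = 0` sets are drawn disjointly
#' while the universe has capacity. Each member carries an activator (+1) or
#' repressor (-1) sign.
#'
#' @param universe Character vector of gene ids.
#' @param n_sets Number of sets.
#' @param size_range Integer pair (min, max) of set sizes.
#' @param overlap_fraction Target expected pairwise Jaccard, in [0, 1].
#' @param repressor_fraction Probability that a member is a repressor (-1).
#' @param seed Integer seed.
#' @param set_names Optional character vector of set names.
#' @return A tibble with columns `set`, `gene`, `sign` (+1/-1); one row per
#'   set membership.
#' @export
simulate_gene_sets <- function(universe, n_sets, size_range = c(20L, 80L),
                               overlap_fraction = 0.2, repressor_fraction = 0,
                               seed, set_names = NULL) {
  universe <- unique(as.character(universe))
  if (n_sets <= 0) abort("`n_sets` must be positive")
  size_range <- as.integer(size_range)
  if (length(size_range) != 2 || size_range[1] > size_range[2])
    abort("`size_range` must be an ordered (min, max) pair")
  if (size_range[2] > length(universe)) abort("`size_range` exceeds the universe size")
  check_prob(overlap_fraction, "overlap_fraction")
  check_prob(repressor_fraction, "repressor_fraction")
  set_names <- set_names %||% sprintf("set%03d", seq_len(n_sets))
  stopifnot(length(set_names) == n_sets)

  withr_seed(seed)
  sizes <- if (size_range[1] == size_range[2]) rep(size_range[1], n_sets) else
    sample(seq(size_range[1], size_range[2]), n_sets, replace = TRUE)

  if (overlap_fraction == 0) {
    pool <- sample(universe)  # permuted once; consumed greedily for disjointness
    members <- vector("list", n_sets)
    used <- 0L
    for (i in seq_len(n_sets)) {
      if (used + sizes[i] <= length(pool)) {
        members[[i]] <- pool[used + seq_len(sizes[i])]
        used <- used + sizes[i]
      } else {
        members[[i]] <- sample(universe, sizes[i])
      }
    }
  } else {
    s_bar <- mean(size_range)
    pool_size <- max(size_range[2], round(s_bar * (1 + overlap_fraction) / (2 * overlap_fraction)))
    pool_size <- min(pool_size, length(universe))
    pool <- sample(universe, pool_size)
    members <- lapply(seq_len(n_sets), function(i) sample(pool, sizes[i]))
  }

  out <- tibble(
    set = rep(set_names, lengths(members)),
    gene = unlist(members, use.names = FALSE)
  )
  out$sign <- ifelse(stats::runif(nrow(out)) < repressor_fraction, -1, 1)
  out
}

#' Simulate a signed directed pathway topology
#'
#' Each ordered gene pair carries a directed edge with probability
#' `edge_density`; the edge is activating (+1) with probability
#' `activation_prob`, else inhibitory (-1). The signed adjacency `beta`
#' (rows = targets, columns = sources) is normalized per source: each column
#' is divided by that gene's outgoing-edge count (zero columns stay zero),
#' giving the influence matrix `B` used by the perturbation analysis.
#'
#' @param gene_set Character vector of gene ids (non-empty).
#' @param edge_density Probability of each ordered-pair edge, in [0, 1].
#' @param activation_prob Probability that an edge activates, in [0, 1].
#' @param seed Integer seed.
#' @param name Optional pathway name.
#' @return An object of class `pathway_topology`: list with `name`, `genes`,
#'   `edges` (tibble source/target/sign), `beta`, `B`, and `spectral_radius`
#'   of `B`.
#' @export
simulate_topology <- function(gene_set, edge_density, activation_prob = 0.8,
                              seed, name = "pathway") {
  gene_set <- unique(as.character(gene_set))
  if (length(gene_set) == 0) abort("`gene_set` must be non-empty")
  check_prob(edge_density, "edge_density")
  check_prob(activation_prob, "activation_prob")
  n <- length(gene_set)
  withr_seed(seed)
  adj <- matrix(stats::runif(n * n) < edge_density, n, n)
  diag(adj) <- FALSE
  sgn <- matrix(ifelse(stats::runif(n * n) < activation_prob, 1, -1), n, n)
  beta <- t(adj * sgn)  # beta[target, source]
  dimnames(beta) <- list(gene_set, gene_set)
  edges_idx <- which(t(adj), arr.ind = TRUE)  # rows of beta
  edges <- tibble(
    source = gene_set[edges_idx[, 2]],
    target = gene_set[edges_idx[, 1]],
    sign = beta[edges_idx]
  )
  pathway_topology(edges, genes = gene_set, name = name)
}

#' Build a pathway topology from a signed edge list
#'
#' @param edges A data frame with columns `source`, `target`, `sign`
#'   (sign in -1/+1).
#' @param genes Optional gene universe of the pathway (defaults to all genes
#'   appearing in `edges`).
#' @param name Pathway name.
#' @return A `pathway_topology` object (see [simulate_topology()]).
#' @export
pathway_topology <- function(edges, genes = NULL, name = "pathway") {
  edges <- as_tibble(edges)
  stopifnot(all(c("source", "target", "sign") %in% names(edges)))
  if (nrow(edges) > 0 && !all(edges$sign %in% c(-1, 1)))
    abort("edge signs must be -1 or +1")
  genes <- unique(as.character(genes %||% c(edges$source, edges$target)))
  if (length(genes) == 0) abort("`genes` must be non-empty")
  n <- length(genes)
  beta <- matrix(0, n, n, dimnames = list(genes, genes))
  if (nrow(edges) > 0)
    beta[cbind(match(edges$target, genes), match(edges$source, genes))] <- edges$sign
  outdeg <- colSums(beta != 0)
  B <- sweep(beta, 2, pmax(outdeg, 1), "/")
  rho <- if (n > 0) max(Mod(eigen(B, only.values = TRUE)$values)) else 0
  structure(
    list(name = name, genes = genes, edges = edges, beta = beta, B = B,
         spectral_radius = rho),
    class = "pathway_topology"
  )
}

#' @export
print.pathway_topology <- function(x, ...) {
  cat("<pathway_topology>", x$name, "|", length(x$genes), "genes,",
      nrow(x$edges), "edges | spectral radius", signif(x$spectral_radius, 3), "\n")
  invisible(x)
}

#' Simulate subject-level survival data under proportional hazards
#'
#' Event times are exponential with hazard
#' `baseline_hazard * exp(sum(coefficient * expression))`. Censoring is
#' independent exponential with rate chosen so the expected censored fraction
#' under the null equals `censor_rate` (`censor_rate = 0` means no
#' censoring). Per-gene expression covariates are standard normal unless an
#' expression table is supplied.
#'
#' @param n_subjects Number of subjects (>= 20).
#' @param risk_genes Named numeric vector of log-hazard coefficients per
#'   risk gene (may be empty).
#' @param baseline_hazard Positive baseline hazard rate (per unit time).
#' @param censor_rate Expected censored fraction in [0, 1).
#' @param seed Integer seed.
#' @param genes Gene ids to simulate expression for (defaults to the risk
#'   genes; ignored when `expression` is given).
#' @param expression Optional subjects x genes data frame of covariates
#'   (first column `subject` or plain numeric columns).
#' @return A tibble with columns `subject`, `time`, `event` (logical) and one
#'   numeric column per gene.
#' @export
simulate_survival <- function(n_subjects = 130, risk_genes = numeric(),
                              baseline_hazard = 0.1, censor_rate = 0.2,
                              seed, genes = NULL, expression = NULL) {
  if (n_subjects < 20) abort("`n_subjects` must be at least 20")
  if (baseline_hazard <= 0) abort("`baseline_hazard` must be positive")
  if (censor_rate < 0 || censor_rate >= 1) abort("`censor_rate` must be in [0, 1)")
  withr_seed(seed)
  genes <- genes %||% names(risk_genes) %||% character()
  if (is.null(expression)) {
    expr_m <- matrix(stats::rnorm(n_subjects * length(genes)), nrow = n_subjects,
                     dimnames = list(NULL, genes))
  } else {
    expression <- as.data.frame(expression)
    if ("subject" %in% names(expression)) expression$subject <- NULL
    expr_m <- as.matrix(expression)
    if (nrow(expr_m) != n_subjects) abort("`expression` must have one row per subject")
    genes <- colnames(expr_m)
  }
  lp <- if (length(risk_genes)) {
    missing <- setdiff(names(risk_genes), colnames(expr_m))
    if (length(missing)) abort("risk genes absent from expression: ", paste(missing, collapse = ", "))
    drop(expr_m[, names(risk_genes), drop = FALSE] %*% risk_genes)
  } else rep(0, n_subjects)
  t_event <- stats::rexp(n_subjects, rate = baseline_hazard * exp(lp))
  if (censor_rate > 0) {
    c_rate <- baseline_hazard * censor_rate / (1 - censor_rate)
    t_cens <- stats::rexp(n_subjects, rate = c_rate)
    event <- t_event <= t_cens
    time <- pmin(t_event, t_cens)
  } else {
    event <- rep(TRUE, n_subjects)
    time <- t_event
  }
  dplyr::bind_cols(
    tibble(subject = sprintf("s%04d", seq_len(n_subjects)), time = time, event = event),
    as_tibble(expr_m, .name_repair = "minimal")
  )
}
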