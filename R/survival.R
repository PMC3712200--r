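#' Univariate Cox proportional-hazards fit
#'
#' Newton-Raphson maximization of the Cox partial likelihood for a single
#' covariate, with Breslow handling of tied event times. Convergence when the
#' change in the score-scaled step falls below 1e-8, or after 50 iterations.
#' The default screening p-value is the Wald test; [permutation_p()] provides
#' the permutation alternative used for gene screening.
#'
#' @param expression Numeric covariate, one value per subject.
#' @param time Positive follow-up times.
#' @param event Logical (or 0/1) event indicators; at least 2 events.
#' @param standardize Center and scale the covariate before fitting (default
#'   `TRUE`), so the hazard ratio is per standard deviation.
#' @return An object of class `coxu_fit`: list with `beta`, `hazard_ratio`,
#'   `se`, `p_value` (Wald), `n`, `n_events`, `iterations`, `converged`.
#'   A zero-variance covariate gives `beta = 0`, `p_value = 1` with a
#'   warning.
#' @export
cox_univariate <- function(expression, time, event, standardize = TRUE) {
  x <- as.numeric(expression)
  time <- as.numeric(time)
  event <- as.logical(event)
  n <- length(x)
  stopifnot(length(time) == n, length(event) == n)
  if (any(!is.finite(x))) abort("covariate must be finite")
  if (sum(event) < 2) abort("need at least 2 events")
  if (stats::sd(x) == 0) {
    warn("zero-variance covariate; returning a null fit")
    return(structure(list(beta = 0, hazard_ratio = 1, se = NA_real_, p_value = 1,
                          n = n, n_events = sum(event), iterations = 0L,
                          converged = TRUE), class = "coxu_fit"))
  }
  if (standardize) x <- (x - mean(x)) / stats::sd(x)
  fit <- cox_nr(x, time, event)
  structure(c(fit, list(n = n, n_events = sum(event))), class = "coxu_fit")
}

# Newton-Raphson on the univariate Breslow partial likelihood.
# Sort by decreasing time so risk sets are cumulative prefixes.
cox_nr <- function(x, time, event, max_iter = 50L, tol = 1e-8) {
  ord <- order(time, decreasing = TRUE)
  x <- x[ord]; time <- time[ord]; event <- event[ord]
  # Breslow: all subjects with time >= t_i are at risk, ties included; with
  # decreasing sort, the risk set of an event is the prefix up to the last
  # index sharing its time.
  risk_end <- cumsum(tabulate(match(time, unique(time))))[match(time, unique(time))]
  ev_idx <- which(event)
  beta <- 0; it <- 0L; converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- exp(beta * x)
    s0 <- cumsum(w)[risk_end][ev_idx]
    s1 <- cumsum(w * x)[risk_end][ev_idx]
    s2 <- cumsum(w * x^2)[risk_end][ev_idx]
    U <- sum(x[ev_idx] - s1 / s0)
    I <- sum(s2 / s0 - (s1 / s0)^2)
    if (I <= 0) break
    step <- U / I
    beta <- beta + step
    if (abs(step) < tol) { converged <- TRUE; break }
  }
  w <- exp(beta * x)
  s0 <- cumsum(w)[risk_end][ev_idx]
  s1 <- cumsum(w * x)[risk_end][ev_idx]
  s2 <- cumsum(w * x^2)[risk_end][ev_idx]
  I <- sum(s2 / s0 - (s1 / s0)^2)
  se <- if (I > 0) 1 / sqrt(I) else NA_real_
  p <- if (is.na(se)) 1 else 2 * stats::pnorm(-abs(beta) / se)
  list(beta = beta, hazard_ratio = exp(beta), se = se, p_value = p,
       iterations = it, converged = converged)
}

#' @export
print.coxu_fit <- function(x, ...) {
  cat(sprintf("<coxu_fit> HR = %.3f (beta = %.3f, se = %.3f), p = %.3g, %d/%d events\n",
              x$hazard_ratio, x$beta, x$se, x$p_value, x$n_events, x$n))
  invisible(x)
}

#' Permutation p-value for a univariate Cox coefficient
#'
#' Refits the model with the subject-to-expression assignment permuted and
#' returns the two-sided tail: the fraction of null `|beta|` at least as
#' large as the observed `|beta|`, floored at `1 / n_permutations`.
#'
#' @inheritParams cox_univariate
#' @param n_permutations Permutation rounds (the reference analysis used
#'   10,000).
#' @param seed Integer seed.
#' @return The permutation p-value.
#' @export
permutation_p <- function(expression, time, event, n_permutations = 10000L, seed) {
  obs <- cox_univariate(expression, time, event)
  if (is.na(obs$beta)) return(1)
  x <- as.numeric(expression)
  if (stats::sd(x) > 0) x <- (x - mean(x)) / stats::sd(x)
  withr_seed(seed)
  null_beta <- vapply(seq_len(n_permutations), function(b) {
    cox_nr(sample(x), time, as.logical(event))$beta
  }, numeric(1))
  max(mean(abs(null_beta) >= abs(obs$beta)), 1 / n_permutations)
}

#' Screen genes for survival association
#'
#' Univariate Cox fit per gene on standardized expression, with either the
#' Wald p (fast, default) or the permutation p as the screening p-value.
#'
#' @param survival_data Tibble from [simulate_survival()] or
#'   [read_survival_tsv()]: columns `subject`, `time`, `event`, then one
#'   column per gene.
#' @param genes Genes to screen (default: all gene columns).
#' @param p_method `"wald"` (default) or `"permutation"`.
#' @param n_permutations Rounds for the permutation p.
#' @param seed Integer seed (required for `p_method = "permutation"`).
#' @return A tibble: `gene`, `beta`, `hazard_ratio`, `p_value`.
#' @export
screen_survival_genes <- function(survival_data, genes = NULL,
                                  p_method = c("wald", "permutation"),
                                  n_permutations = 10000L, seed = NULL) {
  p_method <- match.arg(p_method)
  genes <- genes %||% setdiff(names(survival_data), c("subject", "time", "event"))
  purrr::imap_dfr(stats::setNames(genes, genes), function(g, nm) {
    fit <- cox_univariate(survival_data[[g]], survival_data$time, survival_data$event)
    p <- if (p_method == "permutation") {
      permutation_p(survival_data[[g]], survival_data$time, survival_data$event,
                    n_permutations = n_permutations,
                    seed = child_seed(seed, match(g, genes)))
    } else fit$p_value
    tibble(gene = nm, beta = fit$beta, hazard_ratio = fit$hazard_ratio, p_value = p)
  })
}

#' Select survival-related genes
#'
#' @param table Tibble with columns `gene`, `p_value` (e.g. a screening
#'   result or the packaged survival-gene table).
#' @param alpha Screening level (default 0.05); genes with `p_value < alpha`
#'   are selected.
#' @return Character vector of gene ids.
#' @export
select_survival_genes <- function(table, alpha = 0.05) {
  stopifnot(all(c("gene", "p_value") %in% names(table)))
  table$gene[table$p_value < alpha]
}

#' Cross-tabulate expression pattern against hazard direction
#'
#' Counts survival-screened pattern genes in the 2x2 table (rows: Down-/
#' Up-pattern; columns: hazard ratio > 1 / < 1) and computes the odds ratio
#' `(a d) / (b c)` with `a` = down & HR > 1, `b` = down & HR < 1, `c` = up &
#' HR > 1, `d` = up & HR < 1, plus the two-sided Fisher exact p. Genes with
#' hazard ratio exactly 1 are excluded with a warning; genes without a
#' down/up pattern label or with `p_value >= alpha` are excluded.
#'
#' @param table Tibble with columns `gene`, `pattern` (values `down` / `up` /
#'   other), `p_value`, `hazard_ratio`.
#' @param alpha Screening level applied to `p_value` (default 0.05).
#' @return An object of class `contingency_result`: list with `counts` (2x2
#'   matrix), `odds_ratio` (Inf with a flag when a margin cell is 0) and
#'   `p_value`.
#' @export
cross_tabulate <- function(table, alpha = 0.05) {
  stopifnot(all(c("pattern", "p_value", "hazard_ratio") %in% names(table)))
  if (nrow(table) == 0) abort("empty table")
  t2 <- dplyr::filter(table, .data$pattern %in% c("down", "up"), .data$p_value < alpha)
  if (any(t2$hazard_ratio == 1)) {
    warn(sprintf("excluding %d gene(s) with hazard ratio exactly 1", sum(t2$hazard_ratio == 1)))
    t2 <- dplyr::filter(t2, .data$hazard_ratio != 1)
  }
  a <- sum(t2$pattern == "down" & t2$hazard_ratio > 1)
  b <- sum(t2$pattern == "down" & t2$hazard_ratio < 1)
  cc <- sum(t2$pattern == "up" & t2$hazard_ratio > 1)
  d <- sum(t2$pattern == "up" & t2$hazard_ratio < 1)
  counts <- matrix(c(a, cc, b, d), 2, 2,
                   dimnames = list(pattern = c("down", "up"),
                                   hazard = c("HR>1", "HR<1")))
  degenerate <- b * cc == 0
  or <- if (!degenerate) (a * d) / (b * cc) else Inf
  if (degenerate) warn("a contingency cell is 0; odds ratio undefined, reported as Inf")
  ft <- fisher_exact_2x2(counts)
  structure(list(counts = counts, odds_ratio = or, p_value = ft$p_value,
                 degenerate = degenerate),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  print(x$counts)
  cat(sprintf("odds ratio = %.3f, two-sided Fisher p = %.4g\n", x$odds_ratio, x$p_value))
  invisible(x)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact minimum-likelihood two-sided p: with the margins fixed, all tables
#' whose hypergeometric probability is at most that of the observed table
#' (within relative tolerance 1e-7 for floating-point ties) contribute to the
#' p-value. The odds ratio reported is the sample odds ratio `(a d) / (b c)`.
#'
#' @param counts 2x2 matrix (or length-4 vector, column-major) of
#'   non-negative integers with a positive total.
#' @return A list with `odds_ratio` and `p_value`.
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(32, 24, 16, 26), 2))$p_value # ~0.0697
fisher_exact_2x2 <- function(counts) {
  m <- matrix(as.numeric(counts), 2, 2)
  if (any(m < 0) || any(m != round(m))) abort("counts must be non-negative integers")
  if (sum(m) == 0) abort("table total must be positive")
  a <- m[1, 1]; b <- m[1, 2]; cc <- m[2, 1]; d <- m[2, 2]
  r1 <- a + b; c1 <- a + cc; n <- sum(m)
  lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
  support <- lo:hi
  probs <- stats::dhyper(support, r1, n - r1, c1)
  p_obs <- stats::dhyper(a, r1, n - r1, c1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  or <- if (b * cc > 0) (a * d) / (b * cc) else if (a * d > 0) Inf else NaN
  list(odds_ratio = or, p_value = min(p, 1))
}
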