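#' Build the contingency table for one miRNA-pathway pair
#'
#' The four counts of the over-representation test. With `T` the miRNA's
#' target set, `U` the target universe (union of all miRNAs' targets) and
#' `P` the pathway's extended gene set restricted to `U` (genes never
#' annotated as a target of any considered miRNA carry no information and
#' are excluded from the pathway side):
#' `np_plus = |T intersect P|`, `np_minus = |P| - np_plus`,
#' `nm_plus = |T|`, `nm_minus = |U| - |T|`.
#'
#' A pair with `|P| = 0` is flagged `degenerate`: no testable genes remain,
#' so the pair carries no evidence either way and is dropped (with its
#' weight) from the per-miRNA combination rather than contributing p = 1.
#'
#' @param targets Character vector: the miRNA's target genes (must be
#'   non-empty and a subset of `universe`).
#' @param pathway_genes Character vector: the pathway's extended gene set.
#' @param universe Character vector: the target universe.
#' @return One-row tibble with integer columns `np_plus`, `np_minus`,
#'   `nm_plus`, `nm_minus` and logical `degenerate`.
#' @examples
#' build_contingency(c("G1", "G2"), c("G1", "G3", "G99"), paste0("G", 1:10))
#' @export
build_contingency <- function(targets, pathway_genes, universe) {
  stopifnot(length(targets) >= 1L)
  targets <- unique(targets)
  if (!all(targets %in% universe)) {
    stop("targets must be a subset of the universe", call. = FALSE)
  }
  p_set <- intersect(unique(pathway_genes), universe)
  np_plus <- sum(targets %in% p_set)
  tibble::tibble(
    np_plus = as.integer(np_plus),
    np_minus = as.integer(length(p_set) - np_plus),
    nm_plus = as.integer(length(targets)),
    nm_minus = as.integer(length(universe) - length(targets)),
    degenerate = length(p_set) == 0L
  )
}

validate_contingency <- function(np_plus, np_minus, nm_plus, nm_minus) {
  counts <- cbind(np_plus, np_minus, nm_plus, nm_minus)
  if (anyNA(counts) || any(counts < 0)) {
    stop("contingency counts must be non-negative and non-missing", call. = FALSE)
  }
  if (any(np_plus > nm_plus) || any(np_minus > nm_minus)) {
    stop("invalid contingency table: requires np_plus <= nm_plus and np_minus <= nm_minus",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' One-tailed Fisher exact test for over-representation
#'
#' The upper-tail hypergeometric probability `P(X >= np_plus)` with
#' population `N = nm_plus + nm_minus`, `K = np_plus + np_minus` successes
#' (pathway genes in the background) and `n = nm_plus` draws (the miRNA's
#' targets). This is the one-sided enrichment direction: small values mean
#' the miRNA's targets over-represent the pathway. Vectorized over tables.
#'
#' @param np_plus,np_minus,nm_plus,nm_minus Contingency counts as in
#'   [build_contingency()]; vectors are recycled to a common length.
#' @return Numeric vector of p-values in (0, 1]; `np_plus = 0` gives
#'   exactly 1.
#' @examples
#' fisher_one_tailed(2, 2, 5, 15)
#' @export
fisher_one_tailed <- function(np_plus, np_minus, nm_plus, nm_minus) {
  validate_contingency(np_plus, np_minus, nm_plus, nm_minus)
  p <- stats::phyper(np_plus - 1, np_plus + np_minus,
                     nm_plus + nm_minus - (np_plus + np_minus),
                     nm_plus, lower.tail = FALSE)
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, clipped at 1 and monotone-enforced; output
#' order matches input order. The pipeline applies this within each miRNA
#' across its pathway p-values by default (`fdr_scope = "per_mirna"`), or
#' across all pairs at once (`"global"`).
#'
#' @param p Numeric vector of p-values in (0, 1]; may be empty.
#' @return Numeric vector of adjusted p-values, same length and order.
#' @export
fdr_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Lancaster chi-square quantile transform
#'
#' Maps a p-value to the `(1 - p)` quantile of a chi-square distribution
#' with `w` degrees of freedom, realized as Gamma(shape `w/2`, scale 2) so
#' fractional weights are exact. At `w = 2` this is Fisher's
#' `-2 log(p)`. Zero p-values (floating underflow) are clamped to the
#' smallest positive double before transforming.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param w Positive degrees-of-freedom weights, recycled against `p`.
#' @return Non-negative transformed values; `p = 1` maps to 0.
#' @examples
#' lancaster_transform(0.05, 2)  # equals -2 * log(0.05)
#' @export
lancaster_transform <- function(p, w) {
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (anyNA(w) || any(w <= 0)) {
    stop("weights must be positive", call. = FALSE)
  }
  n0 <- sum(p == 0)
  if (n0 > 0L) {
    message("lancaster_transform: clamped ", n0,
            " zero p-value(s) to the smallest positive double")
    p[p == 0] <- .Machine$double.xmin
  }
  stats::qgamma(p, shape = w / 2, scale = 2, lower.tail = FALSE)
}

#' Null models for the combined Lancaster statistic
#'
#' Constructs the object consumed by [combine_lancaster()]. Under
#' `independent`, the statistic `T = sum_i q_{w_i}(1 - p_i)` is referred to
#' its exact null: a sum of independent Gamma(`w_i/2`, 2) variables, i.e.
#' Gamma(`sum(w_i)/2`, 2) (chi-square with `sum(w_i)` df). The
#' `moment_matched` and `permutation` kinds are produced by
#' [estimate_null()] and account for correlation between the per-pathway
#' tests induced by shared genes.
#'
#' @param kind One of `"independent"`, `"moment_matched"`, `"permutation"`.
#' @param scale Scale of the matched chi-square (1 under independence).
#' @param df_effective Effective degrees of freedom (`sum(w_i)` under
#'   independence).
#' @param t_perm Stored permutation statistics (permutation kind).
#' @param n_permutations Number of permutations behind `t_perm`.
#' @param seed Seed used to generate the permutations.
#' @return An object of class `mir_null`.
#' @export
null_model <- function(kind = c("independent", "moment_matched", "permutation"),
                       scale = 1, df_effective = NULL, t_perm = NULL,
                       n_permutations = length(t_perm), seed = NA_integer_) {
  kind <- match.arg(kind)
  if (kind == "independent" && !isTRUE(all.equal(scale, 1))) {
    stop("independent null has scale 1", call. = FALSE)
  }
  if (kind == "permutation" && length(t_perm) == 0L) {
    stop("permutation null requires stored permutation statistics", call. = FALSE)
  }
  structure(
    list(kind = kind, scale = scale, df_effective = df_effective,
         t_perm = t_perm, n_permutations = n_permutations, seed = seed),
    class = "mir_null"
  )
}

#' @export
print.mir_null <- function(x, ...) {
  cat("<mir_null> kind =", x$kind)
  if (!is.null(x$df_effective)) {
    cat(sprintf(", scale = %.4g, df_effective = %.4g", x$scale, x$df_effective))
  }
  if (!is.null(x$t_perm)) cat(",", x$n_permutations, "stored permutations")
  cat("\n")
  invisible(x)
}

#' Combine per-pathway p-values with the weighted Lancaster method
#'
#' Computes `T = sum_i lancaster_transform(p_i, w_i)` and refers it to the
#' chosen null. With all weights equal to 2 and the independent null this
#' is exactly Fisher's combined probability test on `2k` degrees of
#' freedom. The `moment_matched` null refers `T` to a scaled chi-square
#' with moments fitted by [estimate_null()]; the `permutation` null uses
#' the empirical tail `(1 + #\{T_perm >= T\}) / (1 + n_permutations)`.
#'
#' @param p Numeric vector: one (FDR-adjusted, by default) p-value per
#'   pathway for this miRNA.
#' @param w Positive weights, one per pathway (relevance-class weights).
#' @param null A `mir_null` object; defaults to the independent null.
#' @return One-row tibble with `lancaster_T`, `df_nominal` (`sum(w)`),
#'   `p_combined`, `neg_log10_p`.
#' @examples
#' combine_lancaster(c(0.01, 0.5, 0.9), c(2, 1, 0.5))
#' @export
combine_lancaster <- function(p, w, null = null_model("independent")) {
  if (length(p) != length(w)) {
    stop("mismatch between pathway p-values and weights: lengths ",
         length(p), " vs ", length(w), call. = FALSE)
  }
  if (length(p) == 0L) {
    stop("cannot combine an empty set of p-values", call. = FALSE)
  }
  stopifnot(inherits(null, "mir_null"))
  t_stat <- sum(lancaster_transform(p, w))
  df_nom <- sum(w)
  p_comb <- switch(null$kind,
    independent = stats::pgamma(t_stat, shape = df_nom / 2, scale = 2,
                                lower.tail = FALSE),
    moment_matched = stats::pgamma(t_stat, shape = null$df_effective / 2,
                                   scale = 2 * null$scale, lower.tail = FALSE),
    permutation = (1 + sum(null$t_perm >= t_stat)) / (1 + null$n_permutations)
  )
  p_comb <- min(max(p_comb, .Machine$double.xmin), 1)
  tibble::tibble(
    lancaster_T = t_stat,
    df_nominal = df_nom,
    p_combined = p_comb,
    neg_log10_p = -log10(p_comb)
  )
}

# Internal: per-pathway p-values for one target set against precomputed
# universe-restricted pathway gene sets. p_sets is a list of character
# vectors; returns the vector of raw upper-tail p-values.
pair_p_raw <- function(targets, p_sets, n_universe) {
  np_plus <- vapply(p_sets, function(p) sum(p %in% targets), integer(1))
  sizes <- lengths(p_sets)
  nm_plus <- length(targets)
  fisher_one_tailed(np_plus, sizes - np_plus, nm_plus, n_universe - nm_plus)
}

# Internal: the statistic T for one target set, following the configured
# pipeline (raw Fisher p's -> optional per-set BH -> weighted transform).
pipeline_t_stat <- function(targets, p_sets, n_universe, weights,
                            combine_on = "adjusted") {
  p <- pair_p_raw(targets, p_sets, n_universe)
  if (combine_on == "adjusted") p <- fdr_adjust(p)
  sum(suppressMessages(lancaster_transform(p, weights)))
}

#' Estimate a correlation-aware null for the combined statistic
#'
#' Pathways share genes, so the per-pathway tests are positively
#' correlated and the independent chi-square reference for `T` can be
#' miscalibrated. This estimator draws `n_permutations` pseudo-miRNAs --
#' uniform random gene subsets of the universe whose sizes are resampled
#' from the empirical distribution of the real target-set sizes -- pushes
#' each through the identical per-pathway pipeline (contingency, one-tailed
#' Fisher, FDR adjustment, weighted transform, sum), and moment-matches the
#' resulting `T` sample with a scaled chi-square (Brown-style):
#' `scale = Var(T)/(2 Mean(T))`, `df_effective = 2 Mean(T)^2 / Var(T)`.
#' The permutation statistics are stored so the same object can serve as an
#' explicit permutation null.
#'
#' @param pathways Extended pathway tibble ([extend_with_tfs()]).
#' @param target_map Target-map tibble; only target-set sizes are used.
#' @param universe Character vector from [build_universe()].
#' @param weights Per-pathway weights; defaults to `pathways$weight`.
#' @param n_permutations Number of pseudo-miRNAs (>= 100).
#' @param seed Integer seed; the same seed reproduces the null exactly.
#' @param combine_on `"adjusted"` (FDR first, the default pipeline) or
#'   `"raw"`; must match the combination setting it will calibrate.
#' @return A `mir_null` object of kind `"moment_matched"` (falls back to
#'   `"independent"` with a warning if the permutation variance is
#'   degenerate). Stored permutations allow `kind = "permutation"` use via
#'   [as_permutation_null()].
#' @export
estimate_null <- function(pathways, target_map, universe,
                          weights = pathways$weight,
                          n_permutations = 1000, seed = 1L,
                          combine_on = c("adjusted", "raw")) {
  combine_on <- match.arg(combine_on)
  stopifnot(n_permutations >= 100)
  p_sets <- lapply(pathways$extended_genes, intersect, y = universe)
  keep <- lengths(p_sets) > 0L
  p_sets <- p_sets[keep]
  weights <- weights[keep]
  if (length(p_sets) == 0L) {
    stop("no pathway has testable genes in the universe", call. = FALSE)
  }
  sizes <- lengths(target_map$targets)
  sizes <- sizes[sizes > 0L]
  if (length(sizes) == 0L) {
    stop("no non-empty target sets to resample sizes from", call. = FALSE)
  }
  n_u <- length(universe)
  sizes <- pmin(sizes, n_u)
  t_perm <- local_seed(seed, {
    perm_sizes <- sizes[sample.int(length(sizes), n_permutations,
                                   replace = TRUE)]
    vapply(perm_sizes, function(s) {
      pipeline_t_stat(sample(universe, s), p_sets, n_u, weights, combine_on)
    }, numeric(1))
  })
  m <- mean(t_perm)
  v <- stats::var(t_perm)
  if (!is.finite(v) || v < 1e-12 * max(m^2, 1)) {
    warning("degenerate permutation variance; falling back to the independent null")
    return(null_model("independent", scale = 1, df_effective = sum(weights),
                      seed = as.integer(seed)))
  }
  null_model("moment_matched",
             scale = v / (2 * m), df_effective = 2 * m^2 / v,
             t_perm = t_perm, n_permutations = n_permutations,
             seed = as.integer(seed))
}

#' Reinterpret an estimated null as an explicit permutation null
#'
#' @param null A `mir_null` from [estimate_null()] with stored permutations.
#' @return A `mir_null` of kind `"permutation"` over the same statistics.
#' @export
as_permutation_null <- function(null) {
  stopifnot(inherits(null, "mir_null"))
  if (is.null(null$t_perm)) {
    stop("null model has no stored permutation statistics", call. = FALSE)
  }
  null_model("permutation", t_perm = null$t_perm,
             n_permutations = null$n_permutations, seed = null$seed)
}

#' Rank miRNA scores and apply the significance threshold
#'
#' Retains miRNAs with combined p strictly below `alpha` (the published
#' selection used p < 0.01), sorted ascending by combined p with ties
#' broken by descending Lancaster statistic, then miRNA name.
#'
#' @param scores Tibble with columns `mirna`, `lancaster_T`, `p_combined`.
#' @param alpha Significance threshold in (0, 1); default 0.01.
#' @return The retained rows, ordered; possibly empty.
#' @export
rank_and_select <- function(scores, alpha = 0.01) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  scores |>
    dplyr::filter(.data$p_combined < alpha) |>
    dplyr::arrange(.data$p_combined, dplyr::desc(.data$lancaster_T), .data$mirna)
}

# Internal: evaluate an expression under a temporary RNG state.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
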