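#' miRNA-in-pathway enrichment analysis
#'
#' The full scoring pipeline for one target mode: builds the contingency
#' table of every miRNA-pathway pair on the target-annotated background,
#' applies the one-tailed Fisher exact test, adjusts p-values by
#' Benjamini-Hochberg FDR (within each miRNA by default), combines the
#' adjusted p-values per miRNA with the relevance-weighted Lancaster
#' statistic, and refers the statistic to the configured null.
#'
#' miRNAs with empty target sets cannot be enriched and are skipped (they
#' are reported in `dropped$mirnas`, not scored with p = 1, which would
#' distort the FDR pool). Pathways with no gene ever annotated as a target
#' are untestable and are dropped with their weights (`dropped$pathways`).
#'
#' @param target_map Target-map tibble from [load_target_map()].
#' @param pathways Extended pathway tibble from [extend_with_tfs()] (an
#'   unextended tibble is accepted: `extended_genes` then equals the core
#'   sets).
#' @param universe Background gene vector; defaults to
#'   [build_universe()] of `target_map`.
#' @param fdr_scope `"per_mirna"` (default) adjusts each miRNA's pathway
#'   p-values as one family, matching the per-miRNA combination that
#'   follows; `"global"` pools all pairs.
#' @param null_kind `"moment_matched"` (default), `"independent"`, or
#'   `"permutation"`; the latter two reuse / skip the permutation draw.
#' @param n_permutations Pseudo-miRNA draws for null estimation.
#' @param alpha Selection threshold on the combined p (strict; default
#'   0.01).
#' @param combine_on `"adjusted"` (default: FDR first, then Lancaster) or
#'   `"raw"` for sensitivity analysis.
#' @param seed Integer seed for the permutation draw.
#' @return An object of class `mir_enrich`: a list with
#'   \describe{
#'     \item{pairs}{tibble of per-pair results: `mirna`, `pathway_id`,
#'       `np_plus`, `np_minus`, `nm_plus`, `nm_minus`, `p_raw`, `p_adj`.}
#'     \item{scores}{tibble of per-miRNA results: `mirna`, `lancaster_T`,
#'       `df_nominal`, `p_combined`, `neg_log10_p`, `rank`, `selected`.}
#'     \item{null}{the `mir_null` used.}
#'     \item{dropped}{lists of skipped miRNAs and untestable pathways.}
#'     \item{params}{the configuration echo.}
#'   }
#' @examples
#' paths <- withr::local_tempdir()
#' scn <- synthetic_scenario(n_genes = 300, n_pathways = 5, n_mirnas = 20,
#'                           seed = 7)
#' files <- generate_synthetic_data(scn, paths)
#' tm <- load_target_map(files$targets_vmt, mode = "VMT")
#' pw <- load_pathways(files$pathways, files$classes)
#' pw <- extend_with_tfs(pw, read_tf_edges(files$tf_edges))
#' fit <- mir_enrich(tm, pw, null_kind = "independent")
#' tidy(fit)
#' @export
mir_enrich <- function(target_map, pathways, universe = NULL,
                       fdr_scope = c("per_mirna", "global"),
                       null_kind = c("moment_matched", "independent", "permutation"),
                       n_permutations = 1000, alpha = 0.01,
                       combine_on = c("adjusted", "raw"), seed = 1L) {
  fdr_scope <- match.arg(fdr_scope)
  null_kind <- match.arg(null_kind)
  combine_on <- match.arg(combine_on)
  stopifnot(alpha > 0, alpha < 1)
  if (is.null(universe)) universe <- build_universe(target_map)

  empty <- lengths(target_map$targets) == 0L
  dropped_mirnas <- target_map$mirna[empty]
  if (any(empty)) {
    message("mir_enrich: skipped ", sum(empty),
            " miRNA(s) with empty target sets")
  }
  tm <- target_map[!empty, ]
  if (nrow(tm) == 0L) stop("no miRNA has a non-empty target set", call. = FALSE)

  p_sets <- lapply(pathways$extended_genes, intersect, y = universe)
  testable <- lengths(p_sets) > 0L
  dropped_pathways <- pathways$pathway_id[!testable]
  if (any(!testable)) {
    message("mir_enrich: dropped ", sum(!testable),
            " untestable pathway(s) with no universe genes: ",
            paste(dropped_pathways, collapse = ", "))
  }
  pw <- pathways[testable, ]
  p_sets <- p_sets[testable]
  if (nrow(pw) == 0L) stop("no pathway has testable genes", call. = FALSE)
  weights <- pw$weight
  n_u <- length(universe)

  pairs <- purrr::map2_dfr(tm$mirna, tm$targets, function(m, targ) {
    np_plus <- vapply(p_sets, function(p) sum(p %in% targ), integer(1))
    sizes <- lengths(p_sets)
    tibble::tibble(
      mirna = m, pathway_id = pw$pathway_id,
      np_plus = np_plus, np_minus = sizes - np_plus,
      nm_plus = length(targ), nm_minus = n_u - length(targ)
    )
  })
  pairs$p_raw <- fisher_one_tailed(pairs$np_plus, pairs$np_minus,
                                   pairs$nm_plus, pairs$nm_minus)
  if (fdr_scope == "per_mirna") {
    pairs <- pairs |>
      dplyr::group_by(.data$mirna) |>
      dplyr::mutate(p_adj = fdr_adjust(.data$p_raw)) |>
      dplyr::ungroup()
  } else {
    pairs$p_adj <- fdr_adjust(pairs$p_raw)
  }

  null <- switch(null_kind,
    independent = null_model("independent", scale = 1,
                             df_effective = sum(weights)),
    moment_matched = estimate_null(pw, tm, universe, weights = weights,
                                   n_permutations = n_permutations,
                                   seed = seed, combine_on = combine_on),
    permutation = as_permutation_null(
      estimate_null(pw, tm, universe, weights = weights,
                    n_permutations = n_permutations,
                    seed = seed, combine_on = combine_on)
    )
  )

  p_col <- if (combine_on == "adjusted") "p_adj" else "p_raw"
  scores <- pairs |>
    dplyr::group_by(.data$mirna) |>
    dplyr::group_modify(function(df, key) {
      combine_lancaster(df[[p_col]], weights, null = null)
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$p_combined, dplyr::desc(.data$lancaster_T), .data$mirna) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  selected = .data$p_combined < alpha)

  structure(
    list(pairs = pairs, scores = scores, null = null,
         dropped = list(mirnas = dropped_mirnas, pathways = dropped_pathways),
         params = list(mode = attr(target_map, "mode"), fdr_scope = fdr_scope,
                       null_kind = null_kind, n_permutations = n_permutations,
                       alpha = alpha, combine_on = combine_on, seed = seed,
                       n_universe = n_u, n_pathways = nrow(pw),
                       n_mirnas = nrow(tm))),
    class = "mir_enrich"
  )
}

#' @export
print.mir_enrich <- function(x, ...) {
  p <- x$params
  cat("<mir_enrich> ", p$n_mirnas, " miRNA(s) x ", p$n_pathways,
      " pathway(s), universe ", p$n_universe, " genes\n", sep = "")
  cat("  mode: ", p$mode %||% "unspecified",
      " | FDR scope: ", p$fdr_scope,
      " | null: ", x$null$kind,
      " | combine on: ", p$combine_on, " p-values\n", sep = "")
  cat("  selected at p <", format(p$alpha), ":", sum(x$scores$selected),
      "miRNA(s)\n")
  print(utils::head(x$scores, 5))
  invisible(x)
}

#' Tidy the per-miRNA scores of an enrichment fit
#'
#' @param x A `mir_enrich` object.
#' @param ... Unused.
#' @return The per-miRNA score tibble, ranked.
#' @method tidy mir_enrich
#' @export
tidy.mir_enrich <- function(x, ...) {
  x$scores
}

#' One-row summary of an enrichment fit
#'
#' @param x A `mir_enrich` object.
#' @param ... Unused.
#' @return One-row tibble: problem sizes, null kind, effective df, and the
#'   number of selected miRNAs.
#' @method glance mir_enrich
#' @export
glance.mir_enrich <- function(x, ...) {
  tibble::tibble(
    n_mirnas = x$params$n_mirnas,
    n_pathways = x$params$n_pathways,
    n_universe = x$params$n_universe,
    null_kind = x$null$kind,
    df_effective = x$null$df_effective %||% NA_real_,
    null_scale = x$null$scale %||% NA_real_,
    alpha = x$params$alpha,
    n_selected = sum(x$scores$selected)
  )
}

#' Ranking plot of an enrichment fit
#'
#' Horizontal bar chart of `-log10(combined p)` for the top-ranked miRNAs,
#' the display used for published enrichment rankings; the selection
#' threshold is drawn as a dashed line.
#'
#' @param object A `mir_enrich` object.
#' @param top_n Number of top-ranked miRNAs to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mir_enrich
#' @export
autoplot.mir_enrich <- function(object, top_n = 30, ...) {
  df <- utils::head(object$scores, top_n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$neg_log10_p,
    y = stats::reorder(.data$mirna, .data$neg_log10_p),
    fill = .data$selected
  )) +
    ggplot2::geom_col(show.legend = TRUE) +
    ggplot2::geom_vline(xintercept = -log10(object$params$alpha),
                        linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2c7fb8", `FALSE` = "grey70"),
                               name = paste0("p < ", object$params$alpha)) +
    ggplot2::labs(
      x = expression(-log[10] ~ "combined p-value"),
      y = NULL,
      title = "miRNA enrichment ranking"
    ) +
    ggplot2::theme_minimal()
}

#' @export
plot.mir_enrich <- function(x, ...) print(autoplot(x, ...))
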