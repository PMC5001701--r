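#' Default tissue/cell vocabulary for the expression filter
#'
#' The lung-transplant setting restricts attention to miRNAs expressed in
#' lung tissue or in cell types involved in specific immunity and
#' non-specific airway inflammation; A549 cells serve as a model of
#' bronchiolo-alveolar epithelium.
#'
#' @return Character vector of seven tissue/cell labels.
#' @export
default_tissue_vocabulary <- function() {
  c("lung tissue", "B lymphocytes", "natural killer lymphocytes",
    "monocytes", "dendritic cells", "granulocytes", "A549")
}

#' Read a miRNA tissue-expression table
#'
#' Two-column tab-separated file (with header) of `(mirna, tissue)` records.
#'
#' @param path Path to the TSV file.
#' @return A tibble with character columns `mirna`, `tissue`.
#' @export
read_expression_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(tab) < 2L) {
    stop("expression table '", path, "' must have two columns (mirna, tissue)",
         call. = FALSE)
  }
  names(tab)[1:2] <- c("mirna", "tissue")
  dplyr::distinct(tibble::as_tibble(tab[, c("mirna", "tissue")]))
}

#' Read a host-gene / intragenic-miRNA table
#'
#' Two-column tab-separated file (with header) of `(host_gene, mirna)`
#' records; a miRNA encoded within a host gene is presumed co-expressed
#' with it. Host symbols are normalized.
#'
#' @param path Path to the TSV file.
#' @return A tibble with character columns `host_gene`, `mirna`.
#' @export
read_host_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(tab) < 2L) {
    stop("host table '", path, "' must have two columns (host_gene, mirna)",
         call. = FALSE)
  }
  names(tab)[1:2] <- c("host_gene", "mirna")
  tab$host_gene <- normalize_gene(tab$host_gene)
  dplyr::distinct(tibble::as_tibble(tab[, c("host_gene", "mirna")]))
}

#' Tissue-expression filter
#'
#' Retains the miRNAs with at least one expression record whose tissue
#' label lies in the active vocabulary, annotating each with its labels.
#' Filtering only decides membership; no p-value or score is altered.
#'
#' @param mirnas Character vector of miRNA names.
#' @param expression Expression tibble from [read_expression_table()].
#' @param vocabulary Active tissue vocabulary; defaults to
#'   [default_tissue_vocabulary()].
#' @return Tibble with column `mirna` and list-column `tissues`.
#' @export
expression_filter <- function(mirnas, expression,
                              vocabulary = default_tissue_vocabulary()) {
  hits <- expression |>
    dplyr::filter(.data$mirna %in% mirnas, .data$tissue %in% vocabulary) |>
    dplyr::group_by(.data$mirna) |>
    dplyr::summarise(tissues = list(sort(unique(.data$tissue))), .groups = "drop") |>
    dplyr::arrange(.data$mirna)
  hits
}

#' Intragenic host-gene filter
#'
#' Retains the miRNAs hosted by any gene (core member or extension TF) of
#' the considered pathways, annotating each with its hosting gene(s).
#'
#' @param mirnas Character vector of miRNA names.
#' @param pathways Extended pathway tibble ([extend_with_tfs()]).
#' @param hosts Host tibble from [read_host_table()].
#' @return Tibble with column `mirna` and list-column `host_genes`.
#' @export
intragenic_filter <- function(mirnas, pathways, hosts) {
  pathway_genes <- unique(unlist(pathways$extended_genes, use.names = FALSE))
  hosts |>
    dplyr::filter(.data$mirna %in% mirnas, .data$host_gene %in% pathway_genes) |>
    dplyr::group_by(.data$mirna) |>
    dplyr::summarise(host_genes = list(sort(unique(.data$host_gene))),
                     .groups = "drop") |>
    dplyr::arrange(.data$mirna)
}

#' Combine the two filter criteria into the candidate miRNA set
#'
#' The expression and intragenic criteria are combined by union (default)
#' or intersection; each candidate carries a provenance flag for the
#' criterion (or criteria) that admitted it.
#'
#' @param expr_pass Output of [expression_filter()].
#' @param intragenic_pass Output of [intragenic_filter()].
#' @param mode `"union"` (default) or `"intersection"`.
#' @return Tibble with columns `mirna`, `by_expression`, `by_intragenic`,
#'   and the annotation list-columns `tissues`, `host_genes`.
#' @export
candidate_set <- function(expr_pass, intragenic_pass,
                          mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  out <- dplyr::full_join(expr_pass, intragenic_pass, by = "mirna") |>
    dplyr::mutate(
      by_expression = !vapply(.data$tissues, is.null, logical(1)),
      by_intragenic = !vapply(.data$host_genes, is.null, logical(1))
    )
  if (mode == "intersection") {
    out <- dplyr::filter(out, .data$by_expression & .data$by_intragenic)
  }
  dplyr::arrange(
    out[, c("mirna", "by_expression", "by_intragenic", "tissues", "host_genes")],
    .data$mirna
  )
}

#' Random-pathway control experiment
#'
#' Re-runs the full enrichment pipeline on `k` pathways sampled uniformly
#' without replacement from a pathway pool (the published control used 39
#' random pathways), with relevance classes assigned by policy:
#' `"preserve_proportions"` samples class labels with the supplied A/B/C
#' proportions (random pools carry no curated class), `"all_B"` assigns the
#' neutral middle class throughout. A near-empty selection on the control
#' supports the specificity of the curated panel's result.
#'
#' @param target_map Target-map tibble from [load_target_map()].
#' @param pool Pathway pool: either a [read_gmt()] tibble or a pathway
#'   tibble with `core_genes`; any existing class is ignored.
#' @param k Number of pathways to sample (default 39).
#' @param class_policy `"preserve_proportions"` or `"all_B"`.
#' @param class_proportions Named proportions over classes for
#'   `"preserve_proportions"`; default uniform over `A`, `B`, `C`.
#' @param edges Optional TF edge tibble; if supplied the sampled pathways
#'   are TF-extended before scoring.
#' @param weights Class-to-weight map; default [default_class_weights()].
#' @param seed Integer seed controlling the sample, the class draw, and
#'   the downstream permutation null.
#' @param ... Passed on to [mir_enrich()] (e.g. `null_kind`, `alpha`).
#' @return A list of class `mir_control`: `fit` (the `mir_enrich` object),
#'   `sampled` (pathway ids drawn), `k`, `class_policy`, `seed`.
#' @export
random_control <- function(target_map, pool, k = 39,
                           class_policy = c("preserve_proportions", "all_B"),
                           class_proportions = c(A = 1, B = 1, C = 1) / 3,
                           edges = NULL, weights = default_class_weights(),
                           seed = 1L, ...) {
  class_policy <- match.arg(class_policy)
  if ("genes" %in% names(pool) && !"core_genes" %in% names(pool)) {
    pool$core_genes <- pool$genes
  }
  stopifnot(all(c("pathway_id", "core_genes") %in% names(pool)))
  if (nrow(pool) < k) {
    stop("pathway pool has ", nrow(pool), " entries; cannot sample k = ", k,
         call. = FALSE)
  }
  sampled <- local_seed(seed, {
    idx <- sample.int(nrow(pool), k)
    cls <- switch(class_policy,
      preserve_proportions = sample(names(class_proportions), k, replace = TRUE,
                                    prob = class_proportions),
      all_B = rep("B", k)
    )
    list(idx = idx, cls = cls)
  })
  pw <- pool[sampled$idx, c("pathway_id", "core_genes")]
  pw$name <- pool$name[sampled$idx] %||% pw$pathway_id
  pw$class <- sampled$cls
  pw$weight <- unname(weights[pw$class])
  pw$tf_genes <- rep(list(character(0)), nrow(pw))
  pw$extended_genes <- pw$core_genes
  pw <- tibble::as_tibble(pw[, c("pathway_id", "name", "class", "weight",
                                 "core_genes", "tf_genes", "extended_genes")])
  if (!is.null(edges)) pw <- extend_with_tfs(pw, edges)
  fit <- mir_enrich(target_map, pw, seed = seed, ...)
  structure(
    list(fit = fit, sampled = pw$pathway_id, classes = pw$class, k = k,
         class_policy = class_policy, seed = as.integer(seed)),
    class = "mir_control"
  )
}

#' @export
print.mir_control <- function(x, ...) {
  cat("<mir_control> k =", x$k, "pathways sampled (seed", x$seed,
      ", policy", x$class_policy, ")\n")
  print(x$fit)
  invisible(x)
}
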