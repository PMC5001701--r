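#' Gene symbol normalization
#'
#' All gene identifiers in mirenrich live in one flat symbol namespace and are
#' compared by exact string equality after a single normalization:
#' surrounding whitespace is stripped and the symbol is upper-cased.
#'
#' @param x Character vector of gene symbols.
#' @return Character vector of normalized symbols.
#' @examples
#' normalize_gene(c(" tp53", "Myc "))
#' @export
normalize_gene <- function(x) {
  toupper(trimws(as.character(x)))
}

#' Default relevance-class weights
#'
#' Curator-assigned pathway relevance classes map to Lancaster weights:
#' class A (highly specific) weighs 2 -- at which the per-pathway quantile
#' transform reduces to Fisher's \eqn{-2\log p} -- class B weighs 1 and
#' class C (very general pathways) weighs 0.5.
#'
#' @return Named numeric vector with entries `A`, `B`, `C`.
#' @export
default_class_weights <- function() {
  c(A = 2, B = 1, C = 0.5)
}

#' Read a GMT gene-set file
#'
#' Parses the tab-separated GMT dialect: one gene set per line, fields
#' `id`, `description`, then one or more member genes. Duplicate members
#' within a line collapse; gene symbols are normalized via [normalize_gene()].
#'
#' @param path Path to the GMT file.
#' @return A tibble with columns `pathway_id`, `name`, and list-column
#'   `genes` (character vectors of unique member symbols).
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("GMT file '", path, "' contains no gene-set lines", call. = FALSE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 3L)
  if (length(bad) > 0L) {
    stop("malformed GMT line ", bad[1], " in '", path,
         "': expected at least 3 tab-separated fields (id, description, genes...)",
         call. = FALSE)
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyNA(ids) || any(!nzchar(trimws(ids)))) {
    stop("malformed GMT line ", which(!nzchar(trimws(ids)))[1],
         ": empty pathway id", call. = FALSE)
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate pathway_id in GMT: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  genes <- lapply(fields, function(f) {
    g <- unique(normalize_gene(f[-(1:2)]))
    g <- g[nzchar(g)]
    if (length(g) == 0L) {
      stop("GMT gene set '", f[[1]], "' has no non-empty member genes",
           call. = FALSE)
    }
    g
  })
  tibble::tibble(
    pathway_id = ids,
    name = vapply(fields, `[[`, character(1), 2L),
    genes = genes
  )
}

#' Read a pathway relevance-class table
#'
#' Two-column tab-separated file (with header) mapping `pathway_id` to a
#' relevance class label in `{A, B, C}` (or the labels of a custom weight
#' vector).
#'
#' @param path Path to the TSV file.
#' @param valid_classes Character vector of admissible class labels.
#' @return A tibble with columns `pathway_id`, `class`.
#' @export
read_pathway_classes <- function(path, valid_classes = names(default_class_weights())) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(tab) < 2L) {
    stop("class table '", path, "' must have two columns (pathway_id, class)",
         call. = FALSE)
  }
  names(tab)[1:2] <- c("pathway_id", "class")
  tab$class <- trimws(tab$class)
  unknown <- setdiff(unique(tab$class), valid_classes)
  if (length(unknown) > 0L) {
    stop("unknown relevance class label(s): ", paste(unknown, collapse = ", "),
         "; expected one of {", paste(valid_classes, collapse = ", "), "}",
         call. = FALSE)
  }
  if (anyDuplicated(tab$pathway_id)) {
    stop("duplicate pathway_id in class table: ",
         paste(unique(tab$pathway_id[duplicated(tab$pathway_id)]), collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(tab[, c("pathway_id", "class")])
}

#' Load pathway records with relevance classes
#'
#' Joins a GMT gene-set file with a relevance-class table into the pathway
#' tibble used throughout the pipeline. On load, `tf_genes` is empty and
#' `extended_genes` equals `core_genes`; [extend_with_tfs()] fills in the
#' transcription-factor extension. Every pathway must have a class entry.
#'
#' @param gene_set_path Path to a GMT file of pathway gene sets.
#' @param class_table_path Path to the two-column class TSV.
#' @param weights Named numeric vector mapping class labels to positive
#'   Lancaster weights; defaults to [default_class_weights()].
#' @return A tibble with columns `pathway_id`, `name`, `class`, `weight`,
#'   and list-columns `core_genes`, `tf_genes`, `extended_genes`.
#' @examples
#' gmt <- tempfile(fileext = ".gmt")
#' writeLines("P1\tdemo\tG1\tG2\tG2", gmt)
#' cls <- tempfile(fileext = ".tsv")
#' writeLines(c("pathway_id\tclass", "P1\tA"), cls)
#' load_pathways(gmt, cls)
#' @export
load_pathways <- function(gene_set_path, class_table_path,
                          weights = default_class_weights()) {
  stopifnot(is.numeric(weights), all(weights > 0), !is.null(names(weights)))
  sets <- read_gmt(gene_set_path)
  classes <- read_pathway_classes(class_table_path, valid_classes = names(weights))
  missing <- setdiff(sets$pathway_id, classes$pathway_id)
  if (length(missing) > 0L) {
    stop("pathway(s) missing a relevance-class entry: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- dplyr::inner_join(sets, classes, by = "pathway_id")
  out$weight <- unname(weights[out$class])
  out$core_genes <- out$genes
  out$tf_genes <- lapply(seq_len(nrow(out)), function(i) character(0))
  out$extended_genes <- out$core_genes
  out$genes <- NULL
  out[, c("pathway_id", "name", "class", "weight",
          "core_genes", "tf_genes", "extended_genes")]
}

#' Read a transcription-factor edge table
#'
#' Two-column tab-separated file (with header) of regulatory edges
#' `(regulator, target)`. Duplicate edges collapse; symbols are normalized.
#'
#' @param path Path to the TSV file.
#' @return A tibble with character columns `regulator`, `target`.
#' @export
read_tf_edges <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(tab) < 2L) {
    stop("TF edge table '", path, "' must have two columns (regulator, target)",
         call. = FALSE)
  }
  names(tab)[1:2] <- c("regulator", "target")
  tab$regulator <- normalize_gene(tab$regulator)
  tab$target <- normalize_gene(tab$target)
  bad <- which(!nzchar(tab$regulator) | !nzchar(tab$target))
  if (length(bad) > 0L) {
    stop("TF edge table row ", bad[1], " has an empty regulator or target field",
         call. = FALSE)
  }
  dplyr::distinct(tibble::as_tibble(tab[, c("regulator", "target")]))
}

#' Extend pathways with upstream transcription factors
#'
#' For each pathway, adds every regulator that has at least one edge into a
#' core gene of that pathway. The extension is single-pass over core genes
#' only (TFs of TFs are not pulled in), so re-running with the same edges
#' restricted to core targets is idempotent. Core membership is never
#' modified; `extended_genes` is the set union of core and TF genes.
#'
#' @param pathways Pathway tibble from [load_pathways()].
#' @param edges Edge tibble from [read_tf_edges()] (columns `regulator`,
#'   `target`).
#' @return The pathway tibble with `tf_genes` and `extended_genes` filled.
#' @export
extend_with_tfs <- function(pathways, edges) {
  stopifnot(all(c("regulator", "target") %in% names(edges)))
  by_target <- split(edges$regulator, edges$target)
  pathways$tf_genes <- lapply(pathways$core_genes, function(core) {
    as.character(sort(unique(unlist(by_target[core], use.names = FALSE))))
  })
  pathways$extended_genes <- Map(function(core, tf) union(core, tf),
                                 pathways$core_genes, pathways$tf_genes)
  pathways
}
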