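#' Read a miRNA name-alias table
#'
#' Two-column tab-separated file (with header) mapping an old miRNA name to
#' its current name, mirroring the rename logs of miRNA nomenclature
#' databases. The mapping must be functional (one new name per old name) and
#' acyclic; aliases are applied in a single step, not chained.
#'
#' @param path Path to the TSV file.
#' @return A tibble with character columns `old_name`, `new_name`.
#' @export
read_alias_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(tab) < 2L) {
    stop("alias table '", path, "' must have two columns (old_name, new_name)",
         call. = FALSE)
  }
  names(tab)[1:2] <- c("old_name", "new_name")
  tab <- dplyr::distinct(tibble::as_tibble(tab[, c("old_name", "new_name")]))
  if (anyDuplicated(tab$old_name)) {
    stop("alias table maps an old name to multiple new names: ",
         paste(unique(tab$old_name[duplicated(tab$old_name)]), collapse = ", "),
         call. = FALSE)
  }
  # a name that is both renamed away and a rename target of another name is
  # fine; a cycle (x -> y and y -> x) is not resolvable in one pass
  cyc <- tab$old_name[tab$new_name %in% tab$old_name &
                        tab$old_name != tab$new_name]
  if (length(cyc) > 0L) {
    chained <- tab$new_name[match(cyc, tab$old_name)]
    back <- tab$new_name[match(chained, tab$old_name)]
    if (any(back == cyc, na.rm = TRUE)) {
      stop("alias table contains a rename cycle involving: ",
           paste(cyc[which(back == cyc)], collapse = ", "), call. = FALSE)
    }
  }
  tab
}

#' Apply a miRNA alias table to a vector of names
#'
#' @param names Character vector of miRNA names.
#' @param aliases Alias tibble from [read_alias_table()], or `NULL` for no
#'   renaming.
#' @return Character vector with old names replaced by their new names.
#' @export
apply_aliases <- function(names, aliases = NULL) {
  if (is.null(aliases) || nrow(aliases) == 0L) return(names)
  hit <- match(names, aliases$old_name)
  names[!is.na(hit)] <- aliases$new_name[hit[!is.na(hit)]]
  names
}

#' Load a miRNA-to-target map
#'
#' Reads a two-column tab-separated file (with header) of
#' `(mirna, gene)` annotations, applies the alias table to miRNA names, and
#' groups rows into one target set per miRNA. Rows sharing a resolved miRNA
#' name merge; duplicate target annotations collapse. The two modes carry
#' the same structure: `"VMT"` for experimentally validated targets and
#' `"CMT"` for the larger computationally predicted aggregate (assumed
#' pre-aggregated by the caller; see the methods vignette).
#'
#' @param path Path to the TSV file.
#' @param mode `"VMT"` or `"CMT"`; stored as the `mode` attribute.
#' @param aliases Optional alias tibble from [read_alias_table()].
#' @return A tibble with column `mirna` and list-column `targets`
#'   (character vectors of unique normalized gene symbols), carrying
#'   attribute `mode`.
#' @export
load_target_map <- function(path, mode = c("VMT", "CMT"), aliases = NULL) {
  mode <- match.arg(mode)
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(tab) < 2L) {
    stop("target map '", path, "' must have two columns (mirna, gene)",
         call. = FALSE)
  }
  names(tab)[1:2] <- c("mirna", "gene")
  tab$mirna <- trimws(tab$mirna)
  tab$gene <- normalize_gene(tab$gene)
  bad <- which(is.na(tab$mirna) | !nzchar(tab$mirna) |
                 is.na(tab$gene) | !nzchar(tab$gene))
  if (length(bad) > 0L) {
    stop("target map row ", bad[1], " (after header) has an empty mirna or gene field",
         call. = FALSE)
  }
  tab$mirna <- apply_aliases(tab$mirna, aliases)
  out <- tab |>
    dplyr::distinct(.data$mirna, .data$gene) |>
    dplyr::group_by(.data$mirna) |>
    dplyr::summarise(targets = list(sort(.data$gene)), .groups = "drop") |>
    dplyr::arrange(.data$mirna)
  attr(out, "mode") <- mode
  out
}

#' Derive the target universe
#'
#' The statistical background population of the contingency tables: the
#' union of the target sets of all considered miRNAs. Every per-miRNA
#' target set is a subset of this universe by construction, so the
#' background splits exactly into the miRNA's targets (`Nm+`) and the
#' remaining ever-targeted genes (`Nm-`).
#'
#' @param target_map Target-map tibble from [load_target_map()].
#' @return Sorted character vector of universe gene symbols.
#' @export
build_universe <- function(target_map) {
  stopifnot("targets" %in% names(target_map))
  genes <- sort(unique(unlist(target_map$targets, use.names = FALSE)))
  if (length(genes) == 0L) {
    stop("all target sets are empty: no statistical background exists",
         call. = FALSE)
  }
  genes
}
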