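#' Define a synthetic study scenario
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate
#' the published study conditions at desk scale: a curated panel of 39
#' pathways over three relevance classes and 349 analyzed miRNAs on a
#' background of 4000 ever-targeted genes (choices discussed in the
#' methods vignette). Gene and miRNA names are deterministic
#' (`G000001...`, `mir-0001...`) so fixtures diff cleanly; pathway ids are
#' `P001...` and relevance classes are assigned deterministically in id
#' order according to `class_proportions`, so planted pathway ids have
#' known classes.
#'
#' @param n_genes Size of the gene pool targets are drawn from.
#' @param n_pathways Number of pathways.
#' @param pathway_size_range Integer `(min, max)` of pathway sizes.
#' @param class_proportions Named proportions over classes `A`, `B`, `C`
#'   (must sum to 1).
#' @param overlap_jaccard Pairwise pathway overlap in `[0, 1)`: 0 gives
#'   disjoint pathways; positive values are hit via a shared core pool
#'   included in every pathway, sized so that two average pathways have
#'   this Jaccard index.
#' @param n_mirnas Number of miRNAs.
#' @param target_size_range Integer `(min, max)` of per-miRNA target-set
#'   sizes (validated-mode sizes; the computational mode adds 50% extra
#'   uniform targets on top, preserving the superset property).
#' @param planted Planted enrichment signal: `NULL` for a null scenario,
#'   or a tibble/data.frame with columns `mirna` (name), `pathway_ids`
#'   (list-column of pathway ids), `enrichment_odds` (sampling-odds ratio
#'   > 1 favouring genes of the planted pathways).
#' @param tf_edge_density Probability that a given (regulator, gene) pair
#'   in the regulator grid carries an edge.
#' @param expression_coverage Fraction of miRNAs present in the
#'   tissue-expression table.
#' @param intragenic_fraction Fraction of miRNAs assigned an intragenic
#'   host gene.
#' @param seed Integer seed; the same scenario and seed produce
#'   byte-identical files.
#' @return A list of class `mir_scenario`.
#' @export
synthetic_scenario <- function(n_genes = 4000, n_pathways = 39,
                               pathway_size_range = c(30, 80),
                               class_proportions = c(A = 0.3, B = 0.4, C = 0.3),
                               overlap_jaccard = 0,
                               n_mirnas = 349,
                               target_size_range = c(10, 100),
                               planted = NULL,
                               tf_edge_density = 0.05,
                               expression_coverage = 0.7,
                               intragenic_fraction = 0.3,
                               seed = 1L) {
  stopifnot(
    n_genes >= 10, n_pathways >= 1, n_mirnas >= 1,
    length(pathway_size_range) == 2L,
    pathway_size_range[1] >= 1, pathway_size_range[1] <= pathway_size_range[2],
    length(target_size_range) == 2L,
    target_size_range[1] >= 1, target_size_range[1] <= target_size_range[2],
    target_size_range[2] <= n_genes,
    overlap_jaccard >= 0, overlap_jaccard < 1,
    tf_edge_density >= 0, tf_edge_density <= 1,
    expression_coverage >= 0, expression_coverage <= 1,
    intragenic_fraction >= 0, intragenic_fraction <= 1
  )
  if (abs(sum(class_proportions) - 1) > 1e-8 || any(class_proportions < 0)) {
    stop("class_proportions must be non-negative and sum to 1", call. = FALSE)
  }
  if (!is.null(planted)) {
    planted <- tibble::as_tibble(planted)
    stopifnot(all(c("mirna", "pathway_ids", "enrichment_odds") %in% names(planted)))
    if (any(planted$enrichment_odds <= 1)) {
      stop("enrichment_odds must exceed 1 for a planted signal", call. = FALSE)
    }
    ids <- pathway_id_names(n_pathways)
    bad <- setdiff(unlist(planted$pathway_ids), ids)
    if (length(bad) > 0L) {
      stop("planted pathway id(s) do not exist: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (anyDuplicated(planted$mirna)) {
      stop("a miRNA may be planted only once", call. = FALSE)
    }
  }
  structure(
    list(n_genes = n_genes, n_pathways = n_pathways,
         pathway_size_range = as.integer(pathway_size_range),
         class_proportions = class_proportions,
         overlap_jaccard = overlap_jaccard,
         n_mirnas = n_mirnas,
         target_size_range = as.integer(target_size_range),
         planted = planted,
         tf_edge_density = tf_edge_density,
         expression_coverage = expression_coverage,
         intragenic_fraction = intragenic_fraction,
         seed = as.integer(seed)),
    class = "mir_scenario"
  )
}

# sample() treats a length-1 numeric first argument as 1:n; draw from an
# explicit integer range instead
sample_range <- function(lo, hi, n) {
  seq.int(lo, hi)[sample.int(hi - lo + 1L, n, replace = TRUE)]
}

gene_names <- function(n) sprintf("G%06d", seq_len(n))
mirna_names <- function(n) sprintf("mir-%04d", seq_len(n))
pathway_id_names <- function(n) sprintf("P%03d", seq_len(n))

# Deterministic class labels in pathway-id order: the integer allocation
# closest to the requested proportions, remainders to the largest fractions.
allocate_classes <- function(n, proportions) {
  raw <- proportions * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  rep(names(proportions), times = counts)
}

#' Generate a complete synthetic input set
#'
#' Writes every file dialect the loaders read -- pathway GMT, class table,
#' TF edges, validated (VMT) and computational (CMT) target maps,
#' tissue-expression table, host-gene table -- plus a truth table of
#' planted pairs. Background miRNAs draw their targets uniformly from the
#' gene pool. A planted miRNA of odds `r` splits its target draws
#' binomially: each of its `|T|` targets falls inside the union `P` of its
#' planted pathways' genes with probability `r|P| / (r|P| + |pool \ P|)`
#' (the sampling-weight ratio), then in-pool and out-of-pool targets are
#' drawn uniformly without replacement, so the expected in-pathway count
#' is exactly `|T| * r|P| / (r|P| + |pool \ P|)`. CMT sets are VMT sets
#' plus 50% extra uniform targets, preserving the superset property.
#'
#' @param scenario A `mir_scenario` from [synthetic_scenario()].
#' @param out_dir Output directory (created if missing).
#' @return Named list of file paths: `pathways`, `classes`, `tf_edges`,
#'   `targets_vmt`, `targets_cmt`, `expression`, `hosts`, `truth`.
#' @export
generate_synthetic_data <- function(scenario, out_dir) {
  stopifnot(inherits(scenario, "mir_scenario"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  s <- scenario
  genes <- gene_names(s$n_genes)
  mirnas <- mirna_names(s$n_mirnas)
  pids <- pathway_id_names(s$n_pathways)
  classes <- allocate_classes(s$n_pathways, s$class_proportions)

  local_seed(s$seed, {
    sizes <- sample_range(s$pathway_size_range[1], s$pathway_size_range[2],
                          s$n_pathways)
    if (s$overlap_jaccard == 0) {
      if (sum(sizes) > s$n_genes) {
        stop("infeasible scenario: disjoint pathways need sum(sizes) = ",
             sum(sizes), " <= n_genes = ", s$n_genes, call. = FALSE)
      }
      shuffled <- sample(genes)
      stops <- cumsum(sizes)
      starts <- c(1L, utils::head(stops, -1) + 1L)
      pathway_genes <- Map(function(a, b) sort(shuffled[a:b]), starts, stops)
    } else {
      j <- s$overlap_jaccard
      m_shared <- max(1L, round(2 * mean(sizes) * j / (1 + j)))
      if (m_shared >= min(sizes)) {
        stop("infeasible scenario: shared pool of ", m_shared,
             " genes (for Jaccard ", j, ") must be smaller than the minimum ",
             "pathway size ", min(sizes), call. = FALSE)
      }
      shared <- sample(genes, m_shared)
      rest <- setdiff(genes, shared)
      pathway_genes <- lapply(sizes, function(sz) {
        sort(c(shared, sample(rest, sz - m_shared)))
      })
    }

    # TF edges over a fixed regulator subset of the gene pool
    n_tfs <- max(5L, round(0.02 * s$n_genes))
    tfs <- sample(genes, n_tfs)
    grid_hit <- stats::runif(n_tfs * s$n_genes) < s$tf_edge_density
    edge_reg <- rep(tfs, each = s$n_genes)[grid_hit]
    edge_tgt <- rep(genes, times = n_tfs)[grid_hit]

    # validated-mode target sets
    planted_idx <- if (is.null(s$planted)) integer(0) else
      match(s$planted$mirna, mirnas)
    if (anyNA(planted_idx)) {
      stop("planted miRNA name(s) outside the generated set: ",
           paste(s$planted$mirna[is.na(planted_idx)], collapse = ", "),
           call. = FALSE)
    }
    vmt <- vector("list", s$n_mirnas)
    tsize <- sample_range(s$target_size_range[1], s$target_size_range[2],
                          s$n_mirnas)
    for (i in seq_len(s$n_mirnas)) {
      hit <- match(i, planted_idx)
      if (is.na(hit)) {
        vmt[[i]] <- sort(sample(genes, tsize[i]))
      } else {
        pool_in <- sort(unique(unlist(
          pathway_genes[match(s$planted$pathway_ids[[hit]], pids)]
        )))
        pool_out <- setdiff(genes, pool_in)
        r <- s$planted$enrichment_odds[hit]
        q <- r * length(pool_in) / (r * length(pool_in) + length(pool_out))
        n_in <- min(stats::rbinom(1, tsize[i], q), length(pool_in))
        vmt[[i]] <- sort(c(sample(pool_in, n_in),
                           sample(pool_out, tsize[i] - n_in)))
      }
    }
    # computational-mode supersets
    cmt <- lapply(vmt, function(t) {
      extra_n <- min(ceiling(0.5 * length(t)), s$n_genes - length(t))
      sort(c(t, sample(setdiff(genes, t), extra_n)))
    })

    vocab <- default_tissue_vocabulary()
    expressed <- mirnas[stats::runif(s$n_mirnas) < s$expression_coverage]
    expr_rows <- lapply(expressed, function(m) {
      tibble::tibble(mirna = m, tissue = sort(sample(vocab, sample(1:3, 1))))
    })
    hosted <- sort(sample(mirnas, round(s$intragenic_fraction * s$n_mirnas)))
    host_genes <- sample(genes, length(hosted), replace = TRUE)

    paths <- list(
      pathways = file.path(out_dir, "pathways.gmt"),
      classes = file.path(out_dir, "classes.tsv"),
      tf_edges = file.path(out_dir, "tf_edges.tsv"),
      targets_vmt = file.path(out_dir, "targets_vmt.tsv"),
      targets_cmt = file.path(out_dir, "targets_cmt.tsv"),
      expression = file.path(out_dir, "expression.tsv"),
      hosts = file.path(out_dir, "hosts.tsv"),
      truth = file.path(out_dir, "truth.tsv")
    )
    readr::write_lines(
      vapply(seq_along(pids), function(i) {
        paste(c(pids[i], paste0("synthetic pathway ", pids[i]),
                pathway_genes[[i]]), collapse = "\t")
      }, character(1)),
      paths$pathways
    )
    readr::write_tsv(tibble::tibble(pathway_id = pids, class = classes),
                     paths$classes, progress = FALSE)
    readr::write_tsv(tibble::tibble(regulator = edge_reg, target = edge_tgt),
                     paths$tf_edges, progress = FALSE)
    write_target_tsv <- function(sets, path) {
      readr::write_tsv(
        tibble::tibble(mirna = rep(mirnas, lengths(sets)),
                       gene = unlist(sets, use.names = FALSE)),
        path, progress = FALSE
      )
    }
    write_target_tsv(vmt, paths$targets_vmt)
    write_target_tsv(cmt, paths$targets_cmt)
    readr::write_tsv(dplyr::bind_rows(
      tibble::tibble(mirna = character(0), tissue = character(0)), expr_rows
    ), paths$expression, progress = FALSE)
    readr::write_tsv(tibble::tibble(host_gene = host_genes, mirna = hosted),
                     paths$hosts, progress = FALSE)
    truth <- if (is.null(s$planted)) {
      tibble::tibble(mirna = character(0), pathway_id = character(0),
                     enrichment_odds = numeric(0))
    } else {
      tibble::tibble(
        mirna = rep(s$planted$mirna, lengths(s$planted$pathway_ids)),
        pathway_id = unlist(s$planted$pathway_ids, use.names = FALSE),
        enrichment_odds = rep(s$planted$enrichment_odds,
                              lengths(s$planted$pathway_ids))
      )
    }
    readr::write_tsv(truth, paths$truth, progress = FALSE)
    paths
  })
}

#' Summarize recovery of the planted signal
#'
#' Joins the generator's truth table against a ranked score table and
#' reports, per planted miRNA, its rank and selection flag (rank `Inf` if
#' it was not scored at all), plus the aggregate fraction of planted
#' miRNAs landing in the top decile of the ranking.
#'
#' @param truth Path to the truth TSV or the equivalent tibble.
#' @param scores A `mir_enrich` object or its ranked score tibble.
#' @return A list with `per_mirna` (tibble: `mirna`, `rank`, `selected`),
#'   `top_decile_fraction`, and `n_scored`.
#' @export
truth_recovery_report <- function(truth, scores) {
  if (is.character(truth)) {
    truth <- readr::read_tsv(truth, col_types = readr::cols(
      mirna = readr::col_character(), pathway_id = readr::col_character(),
      enrichment_odds = readr::col_double()
    ), progress = FALSE)
  }
  if (inherits(scores, "mir_enrich")) scores <- scores$scores
  planted <- sort(unique(truth$mirna))
  n_scored <- nrow(scores)
  if (length(planted) == 0L) {
    return(list(per_mirna = tibble::tibble(mirna = character(0),
                                           rank = numeric(0),
                                           selected = logical(0)),
                top_decile_fraction = NA_real_, n_scored = n_scored))
  }
  hit <- match(planted, scores$mirna)
  per <- tibble::tibble(
    mirna = planted,
    rank = ifelse(is.na(hit), Inf, scores$rank[hit]),
    selected = !is.na(hit) & scores$selected[replace(hit, is.na(hit), 1L)]
  )
  cutoff <- ceiling(0.1 * n_scored)
  list(per_mirna = per,
       top_decile_fraction = mean(per$rank <= cutoff),
       n_scored = n_scored)
}
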