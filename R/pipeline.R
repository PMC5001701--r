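#' Read a run configuration
#'
#' A flat YAML key-value document collecting every input path and pipeline
#' switch. Recognized keys: `pathways`, `classes`, `tf_edges`,
#' `targets_vmt`, `targets_cmt`, `expression`, `hosts`, `aliases` (paths;
#' the last five optional), `mode` (`VMT`/`CMT`), `weights` (named map
#' overriding the class weights), `fdr_scope`, `null_kind`,
#' `n_permutations`, `alpha`, `filter_mode` (`union`/`intersection`),
#' `filter_position` (`pre`/`post`), `combine_on`, `seed`, `out_dir`.
#' Unset switches take the package defaults.
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @return A validated config list of class `mir_config`.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(
    mode = "VMT", fdr_scope = "per_mirna", null_kind = "moment_matched",
    n_permutations = 1000L, alpha = 0.01, filter_mode = "union",
    filter_position = "pre", combine_on = "adjusted", seed = 1L,
    out_dir = "mirenrich_out", weights = as.list(default_class_weights())
  )
  cfg <- utils::modifyList(defaults, config)
  cfg$mode <- match.arg(cfg$mode, c("VMT", "CMT"))
  cfg$fdr_scope <- match.arg(cfg$fdr_scope, c("per_mirna", "global"))
  cfg$null_kind <- match.arg(cfg$null_kind,
                             c("moment_matched", "independent", "permutation"))
  cfg$filter_mode <- match.arg(cfg$filter_mode, c("union", "intersection"))
  cfg$filter_position <- match.arg(cfg$filter_position, c("pre", "post"))
  cfg$combine_on <- match.arg(cfg$combine_on, c("adjusted", "raw"))
  stopifnot(cfg$alpha > 0, cfg$alpha < 1)
  cfg$weights <- unlist(cfg$weights)
  required <- c("pathways", "classes",
                if (cfg$mode == "VMT") "targets_vmt" else "targets_cmt")
  for (key in required) {
    if (is.null(cfg[[key]])) {
      stop("config is missing required input path '", key, "'", call. = FALSE)
    }
  }
  for (key in c("pathways", "classes", "tf_edges", "targets_vmt",
                "targets_cmt", "expression", "hosts", "aliases")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      stop("config path '", key, "' does not exist: ", cfg[[key]], call. = FALSE)
    }
  }
  structure(cfg, class = c("mir_config", "list"))
}

format_sig <- function(x, digits = 6) {
  ifelse(is.finite(x), formatC(x, digits = digits, format = "g"),
         as.character(x))
}

write_pairs_tsv <- function(pairs, path) {
  out <- pairs
  out$p_raw <- format_sig(out$p_raw)
  out$p_adj <- format_sig(out$p_adj)
  readr::write_tsv(out, path, progress = FALSE)
}

write_scores_tsv <- function(scores, path) {
  out <- scores[, c("mirna", "lancaster_T", "df_nominal", "p_combined",
                    "neg_log10_p", "rank", "selected")]
  out$lancaster_T <- format_sig(out$lancaster_T)
  out$p_combined <- format_sig(out$p_combined)
  out$neg_log10_p <- format_sig(out$neg_log10_p)
  readr::write_tsv(out, path, progress = FALSE)
}

input_hashes <- function(cfg) {
  keys <- c("pathways", "classes", "tf_edges", "targets_vmt", "targets_cmt",
            "expression", "hosts", "aliases")
  paths <- unlist(cfg[keys])
  if (length(paths) == 0L) return(list())
  as.list(unname(tools::md5sum(paths))) |> stats::setNames(names(paths))
}

write_manifest <- function(cfg, extra, path) {
  flat <- cfg[!vapply(cfg, is.null, logical(1))]
  flat$weights <- paste(names(cfg$weights), unname(cfg$weights),
                        sep = "=", collapse = ",")
  manifest <- c(list(package = "mirenrich",
                     version = as.character(utils::packageVersion("mirenrich")),
                     log_base = "10"),
                flat, list(input_md5 = input_hashes(cfg)), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
}

# Internal: load all configured inputs.
load_inputs <- function(cfg) {
  pathways <- load_pathways(cfg$pathways, cfg$classes, weights = cfg$weights)
  if (!is.null(cfg$tf_edges)) {
    pathways <- extend_with_tfs(pathways, read_tf_edges(cfg$tf_edges))
  }
  aliases <- if (!is.null(cfg$aliases)) read_alias_table(cfg$aliases)
  target_path <- if (cfg$mode == "VMT") cfg$targets_vmt else cfg$targets_cmt
  target_map <- load_target_map(target_path, mode = cfg$mode, aliases = aliases)
  expression <- if (!is.null(cfg$expression)) read_expression_table(cfg$expression)
  hosts <- if (!is.null(cfg$hosts)) read_host_table(cfg$hosts)
  list(pathways = pathways, target_map = target_map,
       expression = expression, hosts = hosts)
}

# Internal: candidate miRNA set from whichever filter inputs exist.
compute_candidates <- function(mirnas, inputs, cfg) {
  has_expr <- !is.null(inputs$expression)
  has_host <- !is.null(inputs$hosts)
  if (!has_expr && !has_host) return(NULL)
  expr_pass <- if (has_expr) {
    expression_filter(mirnas, inputs$expression)
  } else tibble::tibble(mirna = character(0), tissues = list())
  host_pass <- if (has_host) {
    intragenic_filter(mirnas, inputs$pathways, inputs$hosts)
  } else tibble::tibble(mirna = character(0), host_genes = list())
  # with only one criterion supplied, intersection against the missing one
  # would empty the set; the supplied criterion stands alone
  mode <- if (has_expr && has_host) cfg$filter_mode else "union"
  candidate_set(expr_pass, host_pass, mode = mode)
}

#' Run the end-to-end enrichment pipeline
#'
#' Orchestrates load, TF extension, filtering (before scoring by default),
#' per-pair testing, FDR, Lancaster combination, ranking, and output:
#' per-pair and per-miRNA TSVs (probabilities serialized with 6
#' significant digits; the log column is base 10) plus a JSON run manifest
#' echoing the configuration, the seed, and MD5 content hashes of every
#' input. Runs are deterministic: identical config and inputs give
#' byte-identical outputs.
#'
#' @param config Path to a YAML config or a named list ([read_run_config()]).
#' @return Invisibly, a list with the `mir_enrich` fit, the candidate
#'   table (or `NULL`), and the written file paths.
#' @export
run_enrichment <- function(config) {
  cfg <- read_run_config(config)
  inputs <- load_inputs(cfg)
  target_map <- inputs$target_map
  candidates <- compute_candidates(target_map$mirna, inputs, cfg)
  if (!is.null(candidates) && cfg$filter_position == "pre") {
    n_before <- nrow(target_map)
    keep <- target_map$mirna %in% candidates$mirna
    target_map <- target_map[keep, ]
    attr(target_map, "mode") <- cfg$mode
    message("run_enrichment: filters retained ", nrow(target_map), " of ",
            n_before, " miRNA(s) before scoring")
    if (nrow(target_map) == 0L) {
      stop("filtering removed every miRNA; nothing to score", call. = FALSE)
    }
  }
  fit <- mir_enrich(target_map, inputs$pathways,
                    fdr_scope = cfg$fdr_scope, null_kind = cfg$null_kind,
                    n_permutations = cfg$n_permutations, alpha = cfg$alpha,
                    combine_on = cfg$combine_on, seed = cfg$seed)
  scores <- fit$scores
  if (!is.null(candidates) && cfg$filter_position == "post") {
    scores <- scores[scores$mirna %in% candidates$mirna, ]
    scores$rank <- seq_len(nrow(scores))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list(pairs = file.path(cfg$out_dir, "pairs.tsv"),
                scores = file.path(cfg$out_dir, "mirna_scores.tsv"),
                manifest = file.path(cfg$out_dir, "manifest.json"))
  write_pairs_tsv(fit$pairs, files$pairs)
  write_scores_tsv(scores, files$scores)
  if (!is.null(candidates)) {
    files$candidates <- file.path(cfg$out_dir, "candidates.tsv")
    flat <- candidates |>
      dplyr::mutate(
        tissues = vapply(.data$tissues, function(x)
          paste(x %||% character(0), collapse = ";"), character(1)),
        host_genes = vapply(.data$host_genes, function(x)
          paste(x %||% character(0), collapse = ";"), character(1))
      )
    readr::write_tsv(flat, files$candidates, progress = FALSE)
  }
  write_manifest(cfg, list(
    n_mirnas_scored = nrow(fit$scores),
    n_selected = sum(scores$selected),
    dropped_mirnas = length(fit$dropped$mirnas),
    dropped_pathways = length(fit$dropped$pathways),
    null_df_effective = fit$null$df_effective %||% NA,
    null_scale = fit$null$scale %||% NA
  ), files$manifest)
  invisible(list(fit = fit, candidates = candidates, files = files))
}

#' Run the random-pathway control experiment
#'
#' Samples `k` pathways from a pool GMT, assigns relevance classes by
#' policy, and runs the configured pipeline on them, writing a control
#' report mirroring the main results schema plus the sampled pathway ids
#' and the seed.
#'
#' @param config Path to a YAML config or a named list; enrichment
#'   switches and the target-map inputs are taken from it.
#' @param pool_path Path to the pool GMT file.
#' @param k Number of pathways to sample (default 39).
#' @param class_policy Passed to [random_control()].
#' @return Invisibly, a list with the `mir_control` object and file paths.
#' @export
run_control <- function(config, pool_path, k = 39,
                        class_policy = c("preserve_proportions", "all_B")) {
  cfg <- read_run_config(config)
  class_policy <- match.arg(class_policy)
  if (!file.exists(pool_path)) {
    stop("pool GMT does not exist: ", pool_path, call. = FALSE)
  }
  pool <- read_gmt(pool_path)
  inputs <- load_inputs(cfg)
  target_map <- inputs$target_map
  candidates <- compute_candidates(target_map$mirna, inputs, cfg)
  if (!is.null(candidates) && cfg$filter_position == "pre") {
    target_map <- target_map[target_map$mirna %in% candidates$mirna, ]
    attr(target_map, "mode") <- cfg$mode
  }
  edges <- if (!is.null(cfg$tf_edges)) read_tf_edges(cfg$tf_edges)
  ctrl <- random_control(target_map, pool, k = k, class_policy = class_policy,
                         edges = edges, weights = cfg$weights, seed = cfg$seed,
                         fdr_scope = cfg$fdr_scope, null_kind = cfg$null_kind,
                         n_permutations = cfg$n_permutations, alpha = cfg$alpha,
                         combine_on = cfg$combine_on)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list(
    scores = file.path(cfg$out_dir, "control_scores.tsv"),
    sampled = file.path(cfg$out_dir, "control_pathways.tsv"),
    manifest = file.path(cfg$out_dir, "control_manifest.json")
  )
  write_scores_tsv(ctrl$fit$scores, files$scores)
  readr::write_tsv(tibble::tibble(pathway_id = ctrl$sampled,
                                  class = ctrl$classes),
                   files$sampled, progress = FALSE)
  write_manifest(cfg, list(control_k = k, control_policy = class_policy,
                           control_pool = pool_path,
                           n_selected = sum(ctrl$fit$scores$selected)),
                 files$manifest)
  invisible(list(control = ctrl, files = files))
}

#' Generate synthetic fixtures from a scenario file
#'
#' Reads a YAML scenario whose keys mirror the arguments of
#' [synthetic_scenario()] (with `planted` as a list of
#' `{mirna, pathway_ids, enrichment_odds}` entries) and writes the full
#' synthetic input set to `out_dir`.
#'
#' @param scenario_path Path to the scenario YAML.
#' @param out_dir Output directory.
#' @return Invisibly, the named list of written file paths.
#' @export
generate_fixtures <- function(scenario_path, out_dir) {
  raw <- yaml::read_yaml(scenario_path)
  if (!is.null(raw$planted)) {
    raw$planted <- tibble::tibble(
      mirna = vapply(raw$planted, `[[`, character(1), "mirna"),
      pathway_ids = lapply(raw$planted, function(x)
        as.character(x$pathway_ids)),
      enrichment_odds = vapply(raw$planted, function(x)
        as.numeric(x$enrichment_odds), numeric(1))
    )
  }
  if (!is.null(raw$class_proportions)) {
    raw$class_proportions <- unlist(raw$class_proportions)
  }
  scenario <- do.call(synthetic_scenario, raw)
  invisible(generate_synthetic_data(scenario, out_dir))
}
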