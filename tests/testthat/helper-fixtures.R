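# Shared fixture builders: everything is generated in code at test time.

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

tmp_gmt <- function(sets, env = parent.frame()) {
  # sets: named list of character vectors (names = pathway ids)
  lines <- vapply(names(sets), function(id) {
    paste(c(id, paste0(id, " description"), sets[[id]]), collapse = "\t")
  }, character(1))
  path <- withr::local_tempfile(fileext = ".gmt", .local_envir = env)
  writeLines(lines, path)
  path
}

tmp_class_table <- function(classes, env = parent.frame()) {
  # classes: named character vector pathway_id -> class
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = env)
  writeLines(c("pathway_id\tclass",
               paste(names(classes), classes, sep = "\t")), path)
  path
}

tmp_two_col <- function(col1, col2, header, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = env)
  writeLines(c(paste(header, collapse = "\t"),
               paste(col1, col2, sep = "\t")), path)
  path
}

# In-memory pathway tibble without touching disk.
make_pathways <- function(sets, classes = NULL,
                          weights = default_class_weights()) {
  ids <- names(sets)
  if (is.null(classes)) classes <- stats::setNames(rep("B", length(ids)), ids)
  tibble::tibble(
    pathway_id = ids,
    name = ids,
    class = unname(classes[ids]),
    weight = unname(weights[classes[ids]]),
    core_genes = lapply(sets, mirenrich::normalize_gene),
    tf_genes = rep(list(character(0)), length(ids)),
    extended_genes = lapply(sets, mirenrich::normalize_gene)
  )
}

# In-memory target map.
make_target_map <- function(sets, mode = "VMT") {
  out <- tibble::tibble(mirna = names(sets), targets = unname(sets))
  attr(out, "mode") <- mode
  out
}

# Independent upper-tail hypergeometric oracle by explicit pmf summation
# over binomial coefficients (no phyper / dhyper).
hyper_upper_oracle <- function(x, N, K, n) {
  ks <- max(0, n + K - N):min(K, n)
  pmf <- exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n))
  sum(pmf[ks >= x])
}

# Hand-rolled Benjamini-Hochberg step-up oracle.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

# Exact central binomial interval (99%) for a count at rate p0.
binom99 <- function(n, p0 = 0.01) {
  stats::qbinom(c(0.005, 0.995), n, p0) / n
}
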