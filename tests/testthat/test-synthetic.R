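small_scenario <- function(...) {
  args <- utils::modifyList(list(
    n_genes = 400, n_pathways = 6, pathway_size_range = c(10, 20),
    n_mirnas = 25, target_size_range = c(5, 30),
    tf_edge_density = 0.02, seed = 101L
  ), list(...))
  do.call(synthetic_scenario, args)
}

test_that("generated fixtures load through every reader and satisfy the superset property", {
  dir <- withr::local_tempdir()
  files <- generate_synthetic_data(small_scenario(), dir)
  expect_true(all(file.exists(unlist(files))))
  pw <- load_pathways(files$pathways, files$classes)
  expect_equal(nrow(pw), 6L)
  edges <- read_tf_edges(files$tf_edges)
  expect_true(all(c("regulator", "target") %in% names(edges)))
  vmt <- load_target_map(files$targets_vmt, "VMT")
  cmt <- load_target_map(files$targets_cmt, "CMT")
  expect_equal(vmt$mirna, cmt$mirna)
  for (i in seq_len(nrow(vmt))) {
    expect_true(all(vmt$targets[[i]] %in% cmt$targets[[i]]))
    expect_gt(length(cmt$targets[[i]]), length(vmt$targets[[i]]))
  }
  expr <- read_expression_table(files$expression)
  expect_true(all(expr$tissue %in% default_tissue_vocabulary()))
  hosts <- read_host_table(files$hosts)
  expect_true(all(grepl("^G\\d{6}$", hosts$host_gene)))
})

test_that("identical scenario and seed reproduce byte-identical files", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- generate_synthetic_data(small_scenario(), d1)
  f2 <- generate_synthetic_data(small_scenario(), d2)
  for (k in names(f1)) {
    expect_identical(unname(tools::md5sum(f1[[k]])),
                     unname(tools::md5sum(f2[[k]])), label = k)
  }
  d3 <- withr::local_tempdir()
  f3 <- generate_synthetic_data(small_scenario(seed = 102L), d3)
  expect_false(identical(unname(tools::md5sum(f1$targets_vmt)),
                         unname(tools::md5sum(f3$targets_vmt))))
})

test_that("zero overlap yields disjoint pathways; positive overlap hits the Jaccard target", {
  dir <- withr::local_tempdir()
  f <- generate_synthetic_data(small_scenario(n_genes = 2000), dir)
  pw <- load_pathways(f$pathways, f$classes)
  all_genes <- unlist(pw$core_genes)
  expect_equal(anyDuplicated(all_genes), 0L)

  f2 <- generate_synthetic_data(
    small_scenario(overlap_jaccard = 0.5, pathway_size_range = c(40, 40)),
    withr::local_tempdir()
  )
  pw2 <- load_pathways(f2$pathways, f2$classes)
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  pairs <- utils::combn(nrow(pw2), 2)
  js <- apply(pairs, 2, function(ix) {
    jac(pw2$core_genes[[ix[1]]], pw2$core_genes[[ix[2]]])
  })
  # shared-pool construction guarantees at least the shared fraction
  expect_true(all(js >= 0.4))
  expect_equal(mean(js), 0.5, tolerance = 0.15)
})

test_that("infeasible scenarios fail with the violated bound", {
  expect_error(
    generate_synthetic_data(
      small_scenario(n_genes = 50, pathway_size_range = c(15, 20)),
      withr::local_tempdir()
    ),
    "disjoint pathways need"
  )
  expect_error(
    generate_synthetic_data(
      small_scenario(overlap_jaccard = 0.9, pathway_size_range = c(10, 20)),
      withr::local_tempdir()
    ),
    "shared pool"
  )
  expect_error(small_scenario(planted = tibble::tibble(
    mirna = "mir-0001", pathway_ids = list("P099"), enrichment_odds = 5
  )), "do not exist")
  expect_error(small_scenario(planted = tibble::tibble(
    mirna = "mir-0001", pathway_ids = list("P001"), enrichment_odds = 1
  )), "exceed 1")
})

test_that("planted in-pathway target counts match the weighted-sampling expectation", {
  # E[np_in] = |T| * r|P| / (r|P| + |pool \ P|), averaged over seeds
  odds <- 6
  n_in <- numeric(200)
  expected <- numeric(200)
  for (s in seq_len(200)) {
    scn <- small_scenario(
      n_pathways = 4, pathway_size_range = c(15, 15), n_mirnas = 6,
      target_size_range = c(20, 20),
      planted = tibble::tibble(mirna = "mir-0001",
                               pathway_ids = list(c("P001", "P002")),
                               enrichment_odds = odds),
      seed = 7000L + s
    )
    f <- generate_synthetic_data(scn, withr::local_tempdir())
    pw <- load_pathways(f$pathways, f$classes)
    vmt <- load_target_map(f$targets_vmt, "VMT")
    pool_in <- unique(unlist(pw$core_genes[pw$pathway_id %in% c("P001", "P002")]))
    t1 <- vmt$targets[[match("mir-0001", vmt$mirna)]]
    n_in[s] <- length(intersect(t1, pool_in))
    q <- odds * length(pool_in) / (odds * length(pool_in) + 400 - length(pool_in))
    expected[s] <- 20 * q
  }
  q_bar <- mean(expected) / 20
  se <- sqrt(q_bar * (1 - q_bar) * 20 * 200) / 200  # binomial SE of the mean
  expect_lt(abs(mean(n_in) - mean(expected)), 3 * se)
  # saturation limit: huge odds with small pathways fills the planted pool
  scn_sat <- small_scenario(
    n_pathways = 4, pathway_size_range = c(10, 10), n_mirnas = 4,
    target_size_range = c(120, 120),
    planted = tibble::tibble(mirna = "mir-0002", pathway_ids = list("P001"),
                             enrichment_odds = 5000),
    seed = 77L
  )
  f <- generate_synthetic_data(scn_sat, withr::local_tempdir())
  pw <- load_pathways(f$pathways, f$classes)
  vmt <- load_target_map(f$targets_vmt, "VMT")
  t2 <- vmt$targets[[match("mir-0002", vmt$mirna)]]
  p1 <- pw$core_genes[[match("P001", pw$pathway_id)]]
  expect_equal(length(intersect(t2, p1)), min(120, length(p1)))
})

test_that("truth recovery reports ranks, handles missing miRNAs, and baselines at 0.1", {
  truth <- tibble::tibble(mirna = c("mir-0001", "mir-0002", "mir-0099"),
                          pathway_id = "P001", enrichment_odds = 5)
  scores <- tibble::tibble(
    mirna = sprintf("mir-%04d", 1:20),
    rank = 1:20,
    selected = c(TRUE, TRUE, rep(FALSE, 18)),
    p_combined = seq(0.001, 0.999, length.out = 20)
  )
  rep <- truth_recovery_report(truth, scores)
  expect_equal(rep$per_mirna$rank, c(1, 2, Inf))
  expect_equal(rep$per_mirna$selected, c(TRUE, TRUE, FALSE))
  expect_equal(rep$top_decile_fraction, 2 / 3)

  empty <- truth_recovery_report(truth[0, ], scores)
  expect_equal(nrow(empty$per_mirna), 0L)
  expect_true(is.na(empty$top_decile_fraction))

  # label shuffling leaves planted miRNAs in the top decile 10% of the time
  withr::local_seed(43)
  truth2 <- tibble::tibble(mirna = sprintf("mir-%04d", 1:5),
                           pathway_id = "P001", enrichment_odds = 5)
  fr <- replicate(400, {
    shuffled <- scores
    shuffled$mirna <- sample(shuffled$mirna)
    truth_recovery_report(truth2, shuffled)$top_decile_fraction
  })
  se <- sqrt(0.1 * 0.9 / (400 * 5))
  expect_lt(abs(mean(fr) - 0.1), 3 * se)
})
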