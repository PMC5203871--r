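test_that("compound-target generator honors promiscuity, coverage and determinism", {
  cfg <- generator_config(seed = 3, n_compounds = 11, n_targets = 40,
                          promiscuous_target_count = 4)
  ct <- generate_compound_targets(cfg)
  deg <- table(ct$target)
  expect_gte(sum(deg == 11L), 4L)
  expect_true(all(c("AR", "BACE1", "CA2", "GSTA1") %in% names(deg)[deg == 11L]))
  expect_setequal(unique(ct$compound), sprintf("C%02d", 1:11))  # every compound hits
  expect_equal(length(deg), 40L)                                 # every target hit
  expect_false(anyDuplicated(ct) > 0)

  # single compound forces degree 1 everywhere
  cfg1 <- generator_config(seed = 3, n_compounds = 1, n_targets = 10,
                           promiscuous_target_count = 0)
  expect_true(all(table(generate_compound_targets(cfg1)$target) == 1L))

  expect_identical(generate_compound_targets(cfg), generate_compound_targets(cfg))
  expect_error(generator_config(promiscuous_target_count = 50, n_targets = 10),
               "promiscuous")
})

test_that("bipartite compound counts are right-skewed", {
  cfg <- generator_config(seed = 11, n_compounds = 11, n_targets = 300,
                          promiscuous_target_count = 0)
  deg <- as.integer(table(generate_compound_targets(cfg)$target))
  # geometric-type law: singletons are the mode and the mean sits well below
  # the midpoint of [1, 11]
  expect_gt(sum(deg == 1L), sum(deg == 6L))
  expect_lt(mean(deg), 6)
})

test_that("interaction generator matches the attachment-rule edge count and is scale-free-ish", {
  cfg <- generator_config(seed = 5, n_other_proteins = 300, ppi_mean_degree = 10)
  ppi <- generate_ppi(cfg)
  n <- 300; m <- 5
  expected <- m * (m - 1) / 2 + (n - m) * m   # closed form for the attachment rule
  expect_lt(abs(nrow(ppi) - n * 10 / 2) / (n * 10 / 2), 0.05)
  expect_equal(nrow(ppi), expected)

  g <- graph_from_interactions(ppi)
  expect_gte(max(igraph::components(g)$csize) / igraph::vcount(g), 0.9)

  # heavier degree tail than a same-density Erdos-Renyi graph
  degs <- igraph::degree(g)
  expect_gte(max(degs), 3 * mean(degs))
  er_max <- vapply(1:20, function(s) {
    set.seed(s)
    max(igraph::degree(igraph::sample_gnm(n, nrow(ppi))))
  }, numeric(1))
  pa_max <- vapply(1:20, function(s) {
    cfg_s <- generator_config(seed = s, n_other_proteins = 300,
                              ppi_mean_degree = 10)
    g_s <- graph_from_interactions(generate_ppi(cfg_s))
    max(igraph::degree(g_s))
  }, numeric(1))
  expect_gt(mean(pa_max), mean(er_max))
})

test_that("interaction generator embeds anchors and degenerate configs", {
  cfg <- generator_config(seed = 2, n_other_proteins = 5, ppi_mean_degree = 2)
  ppi <- generate_ppi(cfg, anchor_nodes = character(0))
  nodes <- unique(c(ppi$protein_a, ppi$protein_b))
  expect_setequal(nodes, sprintf("P%04d", 1:5))

  ppi2 <- generate_ppi(cfg, anchor_nodes = c("AR", "ESR1"))
  expect_true(all(c("AR", "ESR1") %in% c(ppi2$protein_a, ppi2$protein_b)))
  expect_identical(generate_ppi(cfg, c("AR", "ESR1")), ppi2)
})

test_that("annotation generator plants the requested fold within 10%", {
  uni <- sprintf("G%03d", 1:200)
  hub <- uni[1:20]
  cfg <- generator_config(seed = 9, n_terms = 10, planted_term_size = 20,
                          planted_fold = 5)
  anns <- generate_annotations(cfg, uni, hub)
  expect_length(anns, 10L)
  id <- attr(anns, "planted_term_id")
  k <- length(intersect(anns[[id]]$members, hub))
  realized <- (k * 200) / (20 * 20)
  expect_lt(abs(realized - 5) / 5, 0.10)

  # null case: planted term carries about the background overlap
  cfg0 <- generator_config(seed = 9, n_terms = 10, planted_term_size = 20,
                           planted_fold = 1)
  anns0 <- generate_annotations(cfg0, uni, hub)
  k0 <- length(intersect(anns0$PLANTED$members, hub))
  expect_lte(abs(k0 - 2), 2)  # E[k] = n*K/N = 2

  # unattainable folds are rejected with the attainable maximum
  cfg_bad <- generator_config(seed = 9, planted_term_size = 20, planted_fold = 50)
  expect_error(generate_annotations(cfg_bad, uni, hub), "attainable")

  # same seed, same GMT bytes
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_gmt(generate_annotations(cfg, uni, hub), f1)
  write_gmt(generate_annotations(cfg, uni, hub), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("study bundle reproduces the target cardinalities and is byte-deterministic", {
  b <- study_bundle(1)
  expect_equal(length(unique(b$ct$compound)), 11L)
  expect_equal(length(unique(b$ct$target)), 233L)
  expect_length(b$disease, 9L)
  expect_length(intersect(b$disease, b$ct$target), 2L)
  expect_equal(length(unique(b$herbs$herb)), 6L)

  d2 <- file.path(tempdir(), "netpharm-bundle-rerun")
  p2 <- generate_study_bundle(1, d2)
  for (nm in names(p2)) {
    expect_identical(readLines(p2[[nm]], warn = FALSE),
                     readLines(b$paths[[nm]], warn = FALSE),
                     info = nm)
  }
  unlink(d2, recursive = TRUE)
})
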