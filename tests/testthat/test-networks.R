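test_that("role assignment is a partition with shared targets in both sets", {
  role <- assign_target_roles(c("A", "B", "C"), c("C", "D"))
  expect_identical(role[["C"]], "shared_target")
  expect_identical(role[["A"]], "compound_target")
  expect_identical(role[["D"]], "infertility_target")
  expect_length(role, 4L)
})

test_that("pharmacology-efficacy network mirrors the curated relations", {
  b <- study_bundle(1)
  net <- build_pharm_efficacy_network(b$pharm, b$herbs)
  expect_equal(sum(role_census(net)), igraph::vcount(net))
  # a spleen-invigorating path exists from pachyman through its SOD action
  expect_true(igraph::are_adjacent(net, "pachyman", "Increasing SOD activity"))
  expect_true(igraph::are_adjacent(net, "Increasing SOD activity",
                                   "spleen_invigorating"))
  # compounds with no reported pharmacology keep only herb edges
  expect_equal(igraph::degree(net, "pachymic_acid"),
               c(pachymic_acid = sum(b$herbs$compound == "pachymic_acid")))

  # empty pharmacology table leaves herbs and compounds only
  empty <- b$pharm[0, ]
  net0 <- build_pharm_efficacy_network(empty, b$herbs)
  expect_setequal(unique(igraph::V(net0)$role), c("herb", "compound"))

  orphan <- data.frame(compound = "unobtainium", pharmacology = "x",
                       effect = "qi_dispersing")
  expect_error(build_pharm_efficacy_network(orphan, b$herbs), "parent herb")
})

test_that("compound-target network has closed-form node and edge counts", {
  ct <- data.frame(compound = c("c1", "c1", "c2"), target = c("T1", "T2", "T1"))
  net <- build_compound_target_network(ct)
  expect_equal(igraph::vcount(net), 2L + 2L)
  expect_equal(igraph::ecount(net), 3L)
  # strictly bipartite: every edge joins a compound to a target
  el <- igraph::as_edgelist(net, names = TRUE)
  role_of <- setNames(igraph::V(net)$role, igraph::V(net)$name)
  expect_true(all(role_of[el[, 1]] != role_of[el[, 2]]))

  one <- build_compound_target_network(data.frame(compound = "c1", target = "T1"))
  expect_equal(igraph::vcount(one), 2L)
  expect_equal(igraph::ecount(one), 1L)

  # closed-form property over generated tables
  for (s in 1:5) {
    cfg <- generator_config(seed = s, n_targets = 30,
                            promiscuous_target_count = 2)
    tbl <- generate_compound_targets(cfg)
    g <- build_compound_target_network(tbl)
    expect_equal(igraph::vcount(g),
                 length(unique(tbl$compound)) + length(unique(tbl$target)))
    expect_equal(igraph::ecount(g), nrow(unique(tbl)))
  }
})

test_that("herb-target-disease network contracts compounds and keeps role census", {
  herbs <- data.frame(herb = c("h1", "h1", "h2"),
                      compound = c("c1", "c2", "c3"))
  ct <- data.frame(compound = c("c1", "c2", "c3", "c3"),
                   target = c("T1", "T1", "T2", "T3"))
  ppi <- data.frame(protein_a = c("D1", "T9"), protein_b = c("T2", "D2"),
                    score = c(0.9, 0.8))
  ppi <- canonicalize_interactions(ppi)
  net <- suppressMessages(build_herb_target_disease_network(
    herbs, ct, c("D1", "D2", "T3"), ppi = ppi))
  # compounds are gone; herb degree counts distinct targets of its compounds
  expect_false(any(igraph::V(net)$role == "compound"))
  expect_true(igraph::are_adjacent(net, "h1", "T1"))
  expect_equal(unname(igraph::degree(net, "h2")), 2L)  # T2, T3
  # T3 is shared; D1 linked via PPI; D2's only link is outside the view
  expect_identical(nodes_with_role(net, "shared_target"), "T3")
  expect_identical(nodes_with_role(net, "infertility_target"), "D1")
  expect_equal(sum(role_census(net)), igraph::vcount(net))

  # contraction consistency on generated data: a target's herb-degree equals
  # the number of herbs owning >= 1 compound hitting it
  b <- study_bundle(1)
  net3 <- suppressMessages(build_herb_target_disease_network(
    b$herbs, b$ct, b$disease, ppi = b$ppi))
  herb_of <- split(b$herbs$herb, b$herbs$compound)
  for (tg in sample(unique(b$ct$target), 20)) {
    own <- unique(unlist(herb_of[b$ct$compound[b$ct$target == tg]]))
    nb <- igraph::neighbors(net3, tg)$name
    expect_equal(sum(nb %in% unique(b$herbs$herb)), length(own), info = tg)
  }

  expect_error(build_herb_target_disease_network(herbs, ct, character(0)),
               "empty disease")

  # disease set fully inside the target set leaves no infertility role
  all_shared <- suppressMessages(build_herb_target_disease_network(
    herbs, ct, c("T1", "T2"), ppi = ppi))
  expect_length(nodes_with_role(all_shared, "infertility_target"), 0L)
})

test_that("PPI network induction keeps seeds, partners and partner-partner edges", {
  ct <- data.frame(compound = "c1", target = "S1")
  ppi <- canonicalize_interactions(data.frame(
    protein_a = c("S1", "P1", "P1", "Q1"),
    protein_b = c("P1", "P2", "S2", "Q2"),
    score = rep(0.9, 4)))
  net <- build_ppi_network(ct, "S2", ppi)
  # P1 touches seeds S1 and S2; P2 only touches the partner P1 and Q1-Q2
  # touch nothing in the seed neighborhood: both excluded
  expect_setequal(igraph::V(net)$name, c("S1", "S2", "P1"))
  expect_equal(igraph::ecount(net), 2L)

  # brute-force neighborhood-induction oracle on random instances
  for (s in 1:10) {
    set.seed(s)
    adj <- random_adjacency(10, 0.3)
    nodes <- sprintf("X%02d", 1:10)
    idx <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
    rppi <- canonicalize_interactions(data.frame(
      protein_a = nodes[idx[, 1]], protein_b = nodes[idx[, 2]],
      score = 0.9))
    seeds <- nodes[1:3]
    got <- build_ppi_network(data.frame(compound = "c", target = seeds[1:2]),
                             seeds[3], rppi)
    keep <- union(seeds, nodes[sapply(seq_along(nodes), function(i) {
      any(adj[i, 1:3] > 0)
    })])
    want_edges <- sum(adj[match(keep, nodes), match(keep, nodes)]) / 2
    expect_setequal(igraph::V(got)$name, keep)
    expect_equal(igraph::ecount(got), want_edges)
  }

  # empty PPI leaves seed nodes only
  net0 <- build_ppi_network(ct, "S2", ppi[0, ])
  expect_setequal(igraph::V(net0)$name, c("S1", "S2"))
  expect_equal(igraph::ecount(net0), 0L)
})

test_that("main-node subnetwork induces and drops isolates", {
  net <- typed_network(sprintf("N%d", 1:4), rep("other_protein", 4),
                       data.frame(a = c("N1", "N3"), b = c("N2", "N4")))
  sub <- main_node_subnetwork(net, c("N1", "N2"))
  expect_equal(igraph::vcount(sub), 2L)
  expect_equal(igraph::ecount(sub), 1L)
  # non-adjacent main nodes vanish entirely
  sub2 <- main_node_subnetwork(net, c("N1", "N3"))
  expect_equal(igraph::vcount(sub2), 0L)
  expect_error(main_node_subnetwork(net, "N9"), "not in network")

  # equality with brute-force edge filtering on small random graphs
  for (s in 1:20) {
    set.seed(s)
    adj <- random_adjacency(8, stats::runif(1, 0.2, 0.6))
    net_s <- tn_from_adj(adj)
    main <- sample(igraph::V(net_s)$name, sample(2:8, 1))
    got <- main_node_subnetwork(net_s, main)
    mi <- match(main, igraph::V(net_s)$name)
    sub_adj <- adj[mi, mi, drop = FALSE]
    keep <- rowSums(sub_adj) > 0
    expect_equal(igraph::vcount(got), sum(keep))
    expect_equal(igraph::ecount(got), sum(sub_adj[keep, keep]) / 2)
  }
})
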