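make_anns <- function(...) {
  sets <- list(...)
  out <- lapply(names(sets), function(nm) {
    list(name = nm, category = "BP", members = sets[[nm]])
  })
  names(out) <- names(sets)
  out
}

test_that("fold enrichment follows the closed form and the null case", {
  uni <- sprintf("G%03d", 1:100)
  lst <- uni[1:10]
  anns <- make_anns(T1 = c(lst[1:4], uni[97:97]))  # K=5, k=4
  res <- enrich(lst, anns, uni)
  expect_equal(res$fold_enrichment, 8)  # (4/10)/(5/100)
  expect_equal(res$k, 4L); expect_equal(res$K, 5L)

  # gene list = universe: every term at fold 1
  anns2 <- make_anns(A = uni[1:30], B = uni[11:25])
  res2 <- enrich(uni, anns2, uni)
  expect_true(all(res2$fold_enrichment == 1))

  expect_error(enrich(character(0), anns, uni), "empty gene list")
  expect_error(enrich(c(lst, "ALIEN"), anns, uni), "not contained")
})

test_that("fold enrichment is invariant under universe replication", {
  uni <- sprintf("G%03d", 1:50)
  lst <- uni[1:8]
  anns <- make_anns(T1 = uni[c(1:3, 40:44)])
  base <- enrich(lst, anns, uni)
  # replicate every universe element via suffixed twins, duplicating the
  # term membership alongside
  twin <- paste0(uni, "X")
  anns_rep <- make_anns(T1 = c(uni[c(1:3, 40:44)], paste0(uni[c(1:3, 40:44)], "X")))
  rep_res <- enrich(lst, anns_rep, c(uni, twin))
  expect_equal(rep_res$fold_enrichment, base$fold_enrichment)
})

test_that("hypergeometric p matches enumeration and is monotone in k", {
  # spot equality against the combinatorial oracle
  for (case in list(c(4, 100, 5, 10), c(3, 20, 5, 5), c(1, 12, 6, 3))) {
    expect_equal(hypergeom_tail(case[1], case[2], case[3], case[4]),
                 oracle_hyper_tail(case[1], case[2], case[3], case[4]),
                 tolerance = 1e-12)
  }
  # monotone decreasing in k at fixed (N, K, n)
  p_seq <- vapply(1:5, function(k) hypergeom_tail(k, 20, 5, 5), numeric(1))
  expect_true(all(diff(p_seq) < 0))
  # EASE variant discounts one success and is never smaller
  expect_gte(hypergeom_tail(4, 100, 5, 10, ease = TRUE),
             hypergeom_tail(4, 100, 5, 10))
})

test_that("results are ordered by p with fold and id tie-breaks, and BH is monotone", {
  uni <- sprintf("G%03d", 1:60)
  lst <- uni[1:12]
  anns <- make_anns(ZZ = uni[1:6], AA = uni[c(1:6, 31)], MM = uni[c(1:2, 31:42)])
  res <- enrich(lst, anns, uni)
  expect_equal(res$p_raw, sort(res$p_raw))
  expect_true(all(diff(res$q_bh) >= -1e-15))
  expect_true(all(res$q_bh >= res$p_raw - 1e-15))
  # identical (k, n, K, N) rows tie on p and fold; id breaks the tie
  anns_tie <- make_anns(B2 = uni[1:6], A1 = uni[1:6])
  tie <- enrich(lst, anns_tie, uni)
  expect_identical(tie$term_id, c("A1", "B2"))
})

test_that("significance filtering is strict on p and inclusive on fold", {
  res <- data.frame(term_id = c("a", "b", "c"), term_name = "x",
                    k = 3L, n = 10L, K = 5L, N = 50L,
                    fold_enrichment = c(3, 1, 0.5),
                    p_raw = c(0.046, 0.05, 0.01), q_bh = 0.1)
  kept <- filter_significant(res, p_cut = 0.05, fe_cut = 1)
  expect_setequal(kept$term_id, c("a"))  # 0.05 dropped (strict), fold 0.5 dropped
  expect_setequal(filter_significant(res, p_cut = 0.05, fe_cut = 0)$term_id,
                  c("a", "c"))
})

test_that("module partition collapses redundant terms and recovers planted structure", {
  uni <- sprintf("G%03d", 1:100)
  lst <- uni[1:20]
  # two disjoint planted halves plus a near-duplicate of the first
  anns <- make_anns(M1 = uni[1:10], M1b = uni[1:9], M2 = uni[11:20])
  res <- enrich(lst, anns, uni)
  sig <- filter_significant(res, p_cut = 0.5, fe_cut = 1)
  mods <- partition_modules(lst, sig, anns, k_modules = 2L)
  expect_setequal(names(mods), c("M1", "M2"))
  expect_setequal(mods$M1, uni[1:10])
  expect_setequal(mods$M2, uni[11:20])

  # k_modules = 1: every covered gene in one module
  mods1 <- partition_modules(lst, sig, anns, k_modules = 1L)
  expect_length(setdiff(names(mods1), "unassigned"), 1L)

  # genes covered by nothing fall into "unassigned"
  anns3 <- make_anns(M1 = uni[1:10])
  res3 <- enrich(lst, anns3, uni)
  mods3 <- suppressMessages(
    partition_modules(lst, filter_significant(res3, 0.5, 1), anns3, 4L))
  expect_setequal(mods3$unassigned, uni[11:20])
})
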