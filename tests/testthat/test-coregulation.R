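test_that("category counts are orientation-fixed and protein-disjoint", {
  calls <- make_calls(
    cond = c("c1", "c1", "c2", "c2", "c3", "c3"),
    site = rep(c("MELK_S356", "MKI67_T2085"), 3),
    direction = c("Up", "Up", "Down", "Down", "Up", "Down"))
  cc <- category_counts("MELK_S356", "MKI67_T2085", calls)
  expect_equal(cc, c(n_UmUo = 1L, n_UmDo = 1L, n_DmUo = 0L, n_DmDo = 1L))
  expect_error(category_counts("MELK_S356", "MELK_S505", calls),
               "same protein")
  # o never measured together with m -> all zeros
  expect_equal(unname(category_counts("MELK_S356", "TTK_S436", calls)),
               rep(0L, 4))
  # all conditions Unchanged at m -> all zeros
  un <- calls
  un$direction[un$site == "MELK_S356"] <- "Unchanged"
  expect_equal(unname(category_counts("MELK_S356", "MKI67_T2085", un)),
               rep(0L, 4))
})

test_that("fisher_exact_2x2 reproduces exact enumeration values", {
  expect_equal(fisher_exact_2x2(1, 1, 1, 1), 1)
  expect_equal(fisher_exact_2x2(5, 0, 0, 5), 2 / 252, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(3, 0, 0, 3), 2 / 20, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(4, 1, 0, 3), 10 / 70, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(8, 0, 0, 6), 1 / 3003, tolerance = 1e-12)
  expect_identical(fisher_exact_2x2(0, 0, 0, 0), NA_real_)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2, byrow = TRUE)),
               2 / 252, tolerance = 1e-12)
  # degenerate margins give p = 1
  expect_equal(fisher_exact_2x2(0, 0, 1, 2), 1)
})

test_that("fisher_exact_2x2 agrees with stats::fisher.test on random tables", {
  set.seed(123)
  for (i in 1:200) {
    tab <- matrix(sample(0:15, 4, replace = TRUE), 2)
    if (all(tab == 0)) next
    ours <- fisher_exact_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    ref <- stats::fisher.test(tab)$p.value
    expect_equal(ours, ref, tolerance = 1e-9)
  }
})

test_that("evidence counts tally distinct conditions and publications", {
  calls <- make_calls(
    cond = c("c1", "c1", "c2", "c2", "c3", "c3"),
    site = rep(c("MELK_S356", "TTK_S436"), 3),
    direction = c("Up", "Up", "Down", "Down", "Up", "Down"),
    pmid = c("P1", "P1", "P1", "P1", "P2", "P2"))
  expect_equal(evidence_counts("MELK_S356", "TTK_S436", calls),
               c(n_conditions = 3L, n_pmids = 2L))
  # restricted to sign-supporting events
  expect_equal(evidence_counts("MELK_S356", "TTK_S436", calls,
                               supporting_only = TRUE, sign = "positive"),
               c(n_conditions = 2L, n_pmids = 1L))
  none <- calls[calls$site == "MELK_S356", ]
  expect_equal(evidence_counts("MELK_S356", "TTK_S436", none),
               c(n_conditions = 0L, n_pmids = 0L))
})

test_that("the high-confidence gate combines FET, ratio, dominance, evidence", {
  row <- function(counts, n_cond, n_pmids) {
    tibble::tibble(
      n_UmUo = counts[1], n_UmDo = counts[2], n_DmUo = counts[3],
      n_DmDo = counts[4],
      fet_p = fisher_exact_2x2(counts[1], counts[2], counts[3], counts[4]),
      ratio_pos = positive_ratio(c(n_uu = counts[1], n_ud = counts[2],
                                   n_du = counts[3], n_dd = counts[4])),
      ratio_neg = negative_ratio(c(n_uu = counts[1], n_ud = counts[2],
                                   n_du = counts[3], n_dd = counts[4])),
      n_conditions = n_cond, n_pmids = n_pmids)
  }
  # FET p = 10/70 fails the alpha gate despite concordance
  expect_equal(call_high_confidence(row(c(4, 1, 0, 3), 5, 3)), "none")
  # perfect concordance with ample evidence
  expect_equal(call_high_confidence(row(c(8, 0, 0, 6), 14, 4)), "positive")
  # mirrored discordance
  expect_equal(call_high_confidence(row(c(0, 7, 6, 0), 13, 3)), "negative")
  # evidence gates: one publication is never enough
  expect_equal(call_high_confidence(row(c(8, 0, 0, 6), 14, 1)), "none")
  expect_equal(call_high_confidence(row(c(8, 0, 0, 6), 1, 4)), "none")
  # a pair is never both signs: scan the gate over random tables
  set.seed(5)
  for (i in 1:100) {
    r <- row(sample(0:8, 4, replace = TRUE), 10, 3)
    if (all(c(r$n_UmUo, r$n_UmDo, r$n_DmUo, r$n_DmDo) == 0)) next
    expect_true(call_high_confidence(r) %in%
                  c("positive", "negative", "none"))
  }
})

test_that("flipping all o-site calls mirrors signs and preserves FET p", {
  sim <- generate_compendium(synth_config(n_studies = 4, seed = 99,
                                          n_pos_partners = 4,
                                          n_neg_partners = 4,
                                          n_background = 4,
                                          n_profile_studies = 0))
  obs <- add_direction_calls(suppressMessages(filter_class1(sim$observations)))
  calls <- resolve_conflicts(obs)
  flip <- calls
  osel <- flip$gene_symbol != "MELK"
  flip$direction[osel] <- ifelse(flip$direction[osel] == "Up", "Down",
                                 ifelse(flip$direction[osel] == "Down", "Up",
                                        flip$direction[osel]))
  m_sites <- attr(sim$truth, "target_sites")
  a <- coregulation_scan(calls, "MELK", m_sites)
  b <- coregulation_scan(flip, "MELK", m_sites)
  merged <- dplyr::inner_join(a, b, by = c("m_site", "o_site"))
  expect_equal(nrow(merged), nrow(a))
  expect_equal(merged$fet_p.x, merged$fet_p.y)
  swap <- c(positive = "negative", negative = "positive", none = "none")
  expect_equal(unname(swap[merged$sign.x]), merged$sign.y)
})

test_that("toy compendium scan reproduces hand-derived calls", {
  res <- run_toy_pipeline()
  hc <- res$highconf
  expect_equal(nrow(hc), 19L)
  get <- function(m, o) hc[hc$m_site == m & hc$o_site == o, ]
  expect_equal(get("MELK_S356", "MKI67_T2085")$fet_p, 2 / 924,
               tolerance = 1e-12)
  expect_equal(get("MELK_S356", "MKI67_T2085")$sign, "positive")
  expect_equal(get("MELK_S356", "TTK_S436")$fet_p, 1 / 84,
               tolerance = 1e-12)
  expect_equal(get("MELK_S505", "CAMK2D_S472")$sign, "negative")
  expect_equal(get("MELK_S529", "MKI67_T2085")$fet_p, 2 / 70,
               tolerance = 1e-12)
  # SF3B1 and PTGES3 share too little evidence with S529 to be called
  expect_false(any(hc$m_site == "MELK_S529" &
                     hc$o_site %in% c("SF3B1_T303", "PTGES3_S85")))
  # uncorrelated background site is never called
  expect_false("FLNB_S2107" %in% hc$o_site)
})

test_that("venn partition decomposes set unions into disjoint regions", {
  vp <- venn_partition(list(A = c("x", "y", "z"), B = c("y", "z"), C = "z"))
  expect_equal(unname(vp$region_counts[c("A", "A&B", "A&B&C")]),
               c(1L, 1L, 1L))
  expect_equal(vp$region_members$A, "x")
  expect_equal(vp$region_members$`A&B`, "y")
  expect_equal(vp$region_members$`A&B&C`, "z")
  expect_equal(sum(vp$region_counts), 3L)  # equals union size

  same <- venn_partition(list(A = letters[1:4], B = letters[1:4],
                              C = letters[1:4]))
  expect_equal(unname(same$region_counts["A&B&C"]), 4L)
  expect_equal(sum(same$region_counts), 4L)

  disj <- venn_partition(list(A = "a", B = "b", C = "c"))
  expect_equal(unname(disj$region_counts[c("A", "B", "C")]), rep(1L, 3))
  expect_equal(unname(disj$region_counts["A&B&C"]), 0L)

  expect_error(venn_partition(list(A = "a")), "2 or 3")
  expect_error(venn_partition(list("a", "b")), "named")

  # toy positive sets: triple-core of four PsOPs plus one S356&S505 pair
  res <- run_toy_pipeline()
  hc <- res$highconf
  sets <- lapply(res$major_sites, function(s)
    hc$o_site[hc$m_site == s & hc$sign == "positive"])
  names(sets) <- res$major_sites
  vp2 <- venn_partition(sets)
  expect_equal(unname(vp2$region_counts["MELK_S356&MELK_S505&MELK_S529"]), 4L)
  expect_equal(vp2$region_members$`MELK_S356&MELK_S505`, "SF3B1_T303")
  expect_equal(sum(vp2$region_counts), 5L)
})
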