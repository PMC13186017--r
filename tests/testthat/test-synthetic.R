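test_that("the generator is reproducible and honours its seed", {
  cfg <- synth_config(n_studies = 3, seed = 42)
  a <- generate_compendium(cfg)
  b <- generate_compendium(cfg)
  expect_identical(a$observations, b$observations)
  expect_identical(a$truth, b$truth)
  c2 <- generate_compendium(synth_config(n_studies = 3, seed = 43))
  expect_false(identical(a$observations, c2$observations))
  # truth covers every generated PsOP exactly once
  psops <- unique(a$observations$site[a$observations$gene_symbol != "MELK"])
  expect_setequal(psops, a$truth$o_site)
  expect_false(anyDuplicated(a$truth$o_site) > 0)
})

test_that("full detection at concordance 1 copies the target exactly", {
  cfg <- synth_config(n_studies = 4, detect_prob = 1, n_background = 0,
                      concordance = 1, frac_low_quality = 0,
                      n_profile_studies = 0, seed = 7)
  sim <- generate_compendium(cfg)
  obs <- add_direction_calls(sim$observations)
  calls <- resolve_conflicts(obs)
  tcalls <- calls[calls$site == "MELK_S356", ]
  for (o in sim$truth$o_site[sim$truth$label == "positive"]) {
    oc <- calls[calls$site == o, ]
    merged <- dplyr::inner_join(tcalls, oc, by = "condition_key")
    inf <- merged$direction.x %in% c("Up", "Down")
    expect_equal(merged$direction.y[inf], merged$direction.x[inf])
  }
  for (o in sim$truth$o_site[sim$truth$label == "negative"]) {
    oc <- calls[calls$site == o, ]
    merged <- dplyr::inner_join(tcalls, oc, by = "condition_key")
    inf <- merged$direction.x %in% c("Up", "Down")
    flip <- ifelse(merged$direction.x == "Up", "Down", "Up")
    expect_equal(merged$direction.y[inf], flip[inf])
  }
})

test_that("observation counts follow the detection-probability binomial", {
  cfg <- synth_config(seed = 13, n_profile_studies = 0)
  sim <- generate_compendium(cfg)
  n_sites <- 3 + cfg$n_pos_partners + cfg$n_neg_partners + cfg$n_background
  n_trials <- cfg$n_studies * cfg$conditions_per_study * n_sites
  expected <- n_trials * cfg$detect_prob
  sigma <- sqrt(n_trials * cfg$detect_prob * (1 - cfg$detect_prob))
  expect_lt(abs(nrow(sim$observations) - expected), 3 * sigma)
  # intended directions survive default filtering and calling
  obs <- add_direction_calls(suppressMessages(filter_class1(sim$observations)))
  expect_true(all(obs$direction %in% c("Up", "Down", "Unchanged")))
})

test_that("recovery scoring handles perfect and empty call sets", {
  truth <- tibble::tibble(o_site = c("PPOS001_S101", "PNEG001_S102",
                                     "BKGD001_S103"),
                          o_gene = c("PPOS001", "PNEG001", "BKGD001"),
                          label = c("positive", "negative", "null"))
  attr(truth, "target_sites") <- "MELK_S356"
  perfect <- tibble::tibble(m_site = "MELK_S356",
                            o_site = c("PPOS001_S101", "PNEG001_S102"),
                            sign = c("positive", "negative"))
  rep1 <- evaluate_recovery(perfect, truth)
  expect_equal(rep1$per_sign$precision, c(1, 1))
  expect_equal(rep1$per_sign$recall, c(1, 1))
  expect_equal(rep1$fpr, 0)

  none <- perfect[0, ]
  rep2 <- evaluate_recovery(none, truth)
  expect_equal(rep2$per_sign$recall, c(0, 0))
  expect_true(all(is.na(rep2$per_sign$precision)))

  bad <- tibble::tibble(m_site = "MELK_S356", o_site = "UNKNOWN_S1",
                        sign = "positive")
  expect_error(evaluate_recovery(bad, truth), "absent from truth")
})

test_that("recall rises with concordance across a three-point grid", {
  recall_at <- function(conc) {
    cfg <- synth_config(n_studies = 6, conditions_per_study = 3,
                        n_pos_partners = 10, n_neg_partners = 10,
                        n_background = 5, concordance = conc,
                        n_profile_studies = 0, seed = 31)
    sim <- generate_compendium(cfg)
    obs <- add_direction_calls(
      suppressMessages(filter_class1(sim$observations)))
    calls <- resolve_conflicts(obs)
    scan <- coregulation_scan(calls, "MELK", cfg$target_sites)
    rep <- evaluate_recovery(scan, sim$truth)
    mean(rep$per_sign$recall)
  }
  r <- vapply(c(0.6, 0.8, 1.0), recall_at, numeric(1))
  expect_true(all(diff(r) >= -0.05))  # non-decreasing up to MC slack
  expect_gt(r[3], r[1])
})

test_that("null calibration guards its preconditions", {
  cfg <- synth_config(n_pos_partners = 0, n_neg_partners = 0,
                      n_background = 10, n_profile_studies = 0, seed = 3)
  expect_error(null_calibration(cfg, replicates = 0), "replicates")
  planted <- synth_config(n_pos_partners = 5, seed = 3)
  expect_error(null_calibration(planted, replicates = 2),
               "without planted partners")
  tiny <- synth_config(n_pos_partners = 0, n_neg_partners = 0,
                       n_background = 2, n_profile_studies = 0, seed = 3)
  expect_error(null_calibration(tiny, replicates = 1), "too few")
  out <- null_calibration(cfg, replicates = 4)
  expect_gte(out$fpr, 0)
  expect_lte(out$fpr, 1)
  expect_equal(out$n_pairs, 4 * 3 * 10)
  expect_true(out$ci[1] <= out$fpr && out$fpr <= out$ci[2])
})
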