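test_that("read_observations preserves rows and handles missing cells", {
  obs <- read_observations(toy_path("toy_compendium.tsv"), "mixed",
                           alias_map = read_alias_map(toy_path("toy_alias_map.tsv")))
  expect_equal(nrow(obs), 135L)
  # profile rows never carry quantitative fields
  prof <- obs[obs$dataset_kind == "profile", ]
  expect_true(all(is.na(prof$fold_change)))
  expect_true(all(is.na(prof$p_value)))
  # alias row was normalized on read
  expect_false(any(obs$gene_symbol == "KIAA0175"))
  expect_true("MELK_S356" %in% obs$site)

  # a small valid file round-trips through write/read identically
  tf <- withr::local_tempfile(fileext = ".tsv")
  sub <- obs[1:20, ]
  write_observations(sub, tf)
  back <- read_observations(tf, "mixed")
  expect_equal(back[names(back) != "flanking"],
               sub[names(sub) != "flanking"])
})

test_that("read_observations reports schema and parse errors precisely", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pmid\tdataset_id\tcondition_id\tgene_symbol\tresidue\tloc_prob",
               "P1\tD1\tC1\tMELK\tS\t0.9"), tf)
  expect_error(read_observations(tf, "differential"), "position")

  writeLines(c(paste("pmid", "dataset_id", "condition_id", "gene_symbol",
                     "residue", "position", "loc_prob", sep = "\t"),
               "P1\tD1\tC1\tMELK\tS\t356\tnotanumber"), tf)
  expect_error(read_observations(tf, "differential"), "loc_prob.*row 1")

  writeLines(paste("pmid", "dataset_id", "condition_id", "gene_symbol",
                   "residue", "position", "loc_prob", sep = "\t"), tf)
  expect_warning(out <- read_observations(tf, "differential"), "empty")
  expect_equal(nrow(out), 0L)
})

test_that("symbol normalization maps aliases and case-folds", {
  amap <- c(KIAA0175 = "MELK")
  expect_equal(normalize_symbol("mki67", NULL), "MKI67")
  expect_equal(normalize_symbol("KIAA0175", amap), "MELK")
  expect_equal(normalize_symbol("MELK", amap), "MELK")
  expect_equal(normalize_symbol(c("kiaa0175", "ttk"), amap),
               c("MELK", "TTK"))
  expect_error(normalize_symbol(""), "empty")
})

test_that("Class-I filter applies thresholds at the boundary and is idempotent", {
  obs <- tibble::tibble(
    pmid = "P1", dataset_id = "D1", condition_id = "C1",
    dataset_kind = "differential", gene_symbol = "MELK", residue = "S",
    position = 1:5, flanking = NA_character_,
    loc_prob = c(0.75, 0.74, 0.80, 0.95, 0.75),
    ascore = c(13, 40, 12.9, NA, 13),
    fold_change = 2, p_value = 0.01,
    site = paste0("MELK_S", 1:5))
  kept <- suppressMessages(filter_class1(obs))
  expect_equal(kept$position, c(1L, 4L, 5L))          # 0.75/13 kept, 0.74 out
  strict <- suppressMessages(filter_class1(obs, filter_config(strict_ascore = TRUE)))
  expect_equal(strict$position, c(1L, 5L))            # missing A-score rejected
  expect_equal(suppressMessages(filter_class1(kept)), kept)  # idempotent
  expect_equal(nrow(suppressMessages(filter_class1(obs[0, ]))), 0L)
})

test_that("direction calling partitions fold-change/p space", {
  expect_equal(call_direction(1.3, 0.01), "Up")
  expect_equal(call_direction(0.76, 0.04), "Down")
  expect_equal(call_direction(2.0, 0.20), "Unchanged")   # significance gate
  expect_equal(call_direction(1.0, 0.001), "Unchanged")  # dead zone
  expect_error(call_direction(-1, 0.01), "positive")
  expect_error(call_direction(NA_real_, 0.01), "missing")

  # property: exactly one of the three labels for any input
  set.seed(11)
  fc <- exp(runif(500, log(0.1), log(10)))
  p <- runif(500)
  d <- call_direction(fc, p)
  expect_true(all(d %in% c("Up", "Down", "Unchanged")))
  cfg <- filter_config()
  expect_equal(d == "Up", fc >= cfg$up_fc & p < cfg$alpha)
  expect_equal(d == "Down", fc <= cfg$down_fc & p < cfg$alpha)
})

test_that("conflict resolution collapses duplicates to one call per site", {
  base <- tibble::tibble(
    pmid = "P1", dataset_id = "D1", condition_id = "C1",
    dataset_kind = "differential", gene_symbol = "MELK", residue = "S",
    position = 356L, site = "MELK_S356")
  mk <- function(dirs) {
    obs <- base[rep(1, length(dirs)), ]
    obs$direction <- dirs
    resolve_conflicts(obs)
  }
  expect_equal(mk(c("Up", "Up"))$direction, "Up")
  expect_equal(mk(c("Up", "Down"))$direction, "Ambiguous")
  expect_equal(mk(c("Unchanged", "Up"))$direction, "Up")
  expect_equal(mk(c("Unchanged", "Unchanged"))$direction, "Unchanged")
  expect_equal(nrow(mk(c("Up", "Up", "Unchanged"))), 1L)

  # at most one row per (condition, site) on the toy compendium
  res <- run_toy_pipeline()
  keys <- paste(res$calls$condition_key, res$calls$site)
  expect_false(anyDuplicated(keys) > 0)
  # the conflicting duplicate peptides became Ambiguous
  amb <- res$calls[res$calls$site == "MELK_T415", ]
  expect_equal(amb$direction, "Ambiguous")
})
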