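#' Configuration for the synthetic compendium generator
#'
#' Parameters of the planted-structure generator used for calibration and
#' recovery benchmarking. Each study gets its own PMID (so the two-
#' publication evidence gate is meaningfully testable), each with several
#' conditions. Per condition one shared target direction is drawn; all
#' target sites carry it when detected, mirroring a tightly coupled
#' phosphosite axis. Planted positive partners copy that direction with
#' probability `concordance` (negative partners flip with the same
#' probability); background sites draw independent directions and are
#' statistically null.
#'
#' @param n_studies Number of studies (distinct PMIDs); default 10.
#' @param conditions_per_study Comparisons per study; default 4.
#' @param target Target protein symbol (default `"MELK"`).
#' @param target_sites Character vector of target site keys (default the
#'   three-site layout `MELK_S356`, `MELK_S505`, `MELK_S529`).
#' @param n_pos_partners,n_neg_partners Planted partner counts (default 20
#'   each).
#' @param n_background Independent null PsOPs (default 40).
#' @param concordance Probability `c` in \[0.5, 1\] that a planted positive
#'   partner copies the target direction (default 1).
#' @param p_up Probability a target site is Up in an informative condition
#'   (default 0.5).
#' @param detect_prob Probability any given site is measured in a condition
#'   (default 0.9).
#' @param p_target_informative Probability the target is significantly
#'   changed in a condition (default 0.8).
#' @param p_background_informative Probability a background site is
#'   significantly changed when measured (default 0.8).
#' @param frac_low_quality Fraction of rows drawn below the Class-I
#'   localization threshold, exercising the filter (default 0.05).
#' @param frac_missing_ascore Fraction of rows with missing A-score
#'   (default 0.1).
#' @param n_profile_studies Additional qualitative profiling studies
#'   (default 2).
#' @param boundary_stress If `TRUE`, fold changes are drawn at the 1.3/0.76
#'   call boundaries instead of with a safety margin.
#' @param seed Integer seed; the generator is fully reproducible given it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_studies = 10, conditions_per_study = 4,
                         target = "MELK",
                         target_sites = c("MELK_S356", "MELK_S505",
                                          "MELK_S529"),
                         n_pos_partners = 20, n_neg_partners = 20,
                         n_background = 40, concordance = 1,
                         p_up = 0.5, detect_prob = 0.9,
                         p_target_informative = 0.8,
                         p_background_informative = 0.8,
                         frac_low_quality = 0.05,
                         frac_missing_ascore = 0.1,
                         n_profile_studies = 2,
                         boundary_stress = FALSE, seed = 1L) {
  stopifnot(n_studies >= 1, conditions_per_study >= 1,
            concordance >= 0, concordance <= 1,
            p_up >= 0, p_up <= 1, detect_prob >= 0, detect_prob <= 1,
            p_target_informative >= 0, p_target_informative <= 1,
            n_pos_partners >= 0, n_neg_partners >= 0, n_background >= 0)
  if ((n_pos_partners + n_neg_partners) > 0 &&
      n_studies * conditions_per_study == 0) {
    stop("planted partners require at least one condition", call. = FALSE)
  }
  structure(as.list(environment()), class = "synth_config")
}

# direction -> (fold_change, p_value) draws; Up/Down keep a margin from the
# 1.3 / 0.76 call boundaries so the planted intent is unambiguous
.draw_quant <- function(direction, boundary_stress = FALSE) {
  n <- length(direction)
  fc <- numeric(n)
  p <- numeric(n)
  up <- direction == "Up"
  dn <- direction == "Down"
  un <- !up & !dn
  if (boundary_stress) {
    fc[up] <- 1.3
    fc[dn] <- 0.76
  } else {
    fc[up] <- exp(runif(sum(up), log(1.5), log(4)))
    fc[dn] <- exp(runif(sum(dn), log(0.25), log(0.67)))
  }
  fc[un] <- exp(runif(sum(un), log(0.8), log(1.25)))
  p[up | dn] <- runif(sum(up | dn), 1e-6, 0.01)
  p[un] <- runif(sum(un), 0.2, 1)
  list(fold_change = fc, p_value = p)
}

#' Generate a synthetic phosphoproteomics compendium with planted structure
#'
#' Produces an observation table in the exact schema of
#' [read_observations()] output, plus the planted ground truth. Fold changes
#' and p-values are drawn so that direction calling under the default
#' [filter_config()] reproduces the intended Up/Down/Unchanged states; a
#' configurable fraction of rows falls below the Class-I localization
#' threshold to exercise the filter. Fully reproducible given
#' `config$seed`.
#'
#' @param config A [synth_config()].
#' @return A list with `observations` (tibble) and `truth` (tibble with
#'   columns `o_site`, `o_gene`, `label` in `positive`/`negative`/`null`,
#'   and attribute `target_sites`).
#' @export
generate_compendium <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    ts_meta <- parse_site_key(config$target_sites)
    pos_sites <- if (config$n_pos_partners > 0)
      sprintf("PPOS%03d_S%d", seq_len(config$n_pos_partners),
              100 + seq_len(config$n_pos_partners)) else character()
    neg_sites <- if (config$n_neg_partners > 0)
      sprintf("PNEG%03d_S%d", seq_len(config$n_neg_partners),
              100 + seq_len(config$n_neg_partners)) else character()
    bg_sites <- if (config$n_background > 0)
      sprintf("BKGD%03d_S%d", seq_len(config$n_background),
              100 + seq_len(config$n_background)) else character()

    site_tab <- dplyr::bind_rows(
      tibble::tibble(site = config$target_sites, class = "target"),
      tibble::tibble(site = pos_sites, class = "pos"),
      tibble::tibble(site = neg_sites, class = "neg"),
      tibble::tibble(site = bg_sites, class = "bg"))
    site_tab <- dplyr::bind_cols(
      site_tab, parse_site_key(site_tab$site)[, c("gene_symbol", "residue",
                                                  "position")])

    conds <- tidyr::expand_grid(
      study = seq_len(config$n_studies),
      cond = seq_len(config$conditions_per_study))
    conds$pmid <- sprintf("PMID%04d", conds$study)
    conds$dataset_id <- "DS1"
    conds$condition_id <- sprintf("C%02d", conds$cond)
    n_cond <- nrow(conds)
    # one shared target direction process per condition
    informative <- runif(n_cond) < config$p_target_informative
    t_dir <- ifelse(informative,
                    ifelse(runif(n_cond) < config$p_up, "Up", "Down"),
                    "Unchanged")

    grid <- tidyr::expand_grid(ci = seq_len(n_cond),
                               si = seq_len(nrow(site_tab)))
    grid <- grid[runif(nrow(grid)) < config$detect_prob, , drop = FALSE]
    cls <- site_tab$class[grid$si]
    td <- t_dir[grid$ci]
    flip <- function(d) ifelse(d == "Up", "Down", ifelse(d == "Down", "Up", d))
    copy_mask <- runif(nrow(grid)) < config$concordance
    dir <- character(nrow(grid))
    dir[cls == "target"] <- td[cls == "target"]
    dir[cls == "pos"] <- ifelse(copy_mask[cls == "pos"], td[cls == "pos"],
                                flip(td[cls == "pos"]))
    dir[cls == "neg"] <- ifelse(copy_mask[cls == "neg"],
                                flip(td[cls == "neg"]), td[cls == "neg"])
    is_bg <- cls == "bg"
    bg_inf <- runif(sum(is_bg)) < config$p_background_informative
    dir[is_bg] <- ifelse(bg_inf,
                         ifelse(runif(sum(is_bg)) < 0.5, "Up", "Down"),
                         "Unchanged")
    # planted partners are Unchanged when the target is
    dir[cls %in% c("pos", "neg") & td == "Unchanged"] <- "Unchanged"

    q <- .draw_quant(dir, config$boundary_stress)
    n_obs <- nrow(grid)
    loc_prob <- runif(n_obs, 0.80, 1)
    low <- runif(n_obs) < config$frac_low_quality
    loc_prob[low] <- runif(sum(low), 0.30, 0.74)
    ascore <- runif(n_obs, 15, 40)
    ascore[runif(n_obs) < config$frac_missing_ascore] <- NA_real_

    obs <- tibble::tibble(
      pmid = conds$pmid[grid$ci],
      dataset_id = conds$dataset_id[grid$ci],
      condition_id = conds$condition_id[grid$ci],
      dataset_kind = "differential",
      gene_symbol = site_tab$gene_symbol[grid$si],
      residue = site_tab$residue[grid$si],
      position = site_tab$position[grid$si],
      flanking = NA_character_,
      loc_prob = loc_prob,
      ascore = ascore,
      fold_change = q$fold_change,
      p_value = q$p_value,
      site = site_tab$site[grid$si])

    if (config$n_profile_studies > 0) {
      pgrid <- tidyr::expand_grid(ps = seq_len(config$n_profile_studies),
                                  si = seq_len(nrow(site_tab)))
      pgrid <- pgrid[runif(nrow(pgrid)) < config$detect_prob, , drop = FALSE]
      np <- nrow(pgrid)
      if (np > 0) {
        prof <- tibble::tibble(
          pmid = sprintf("PMIDP%03d", pgrid$ps),
          dataset_id = "DS1",
          condition_id = "C01",
          dataset_kind = "profile",
          gene_symbol = site_tab$gene_symbol[pgrid$si],
          residue = site_tab$residue[pgrid$si],
          position = site_tab$position[pgrid$si],
          flanking = NA_character_,
          loc_prob = runif(np, 0.80, 1),
          ascore = runif(np, 15, 40),
          fold_change = NA_real_,
          p_value = NA_real_,
          site = site_tab$site[pgrid$si])
        obs <- dplyr::bind_rows(obs, prof)
      }
    }

    truth <- tibble::tibble(
      o_site = c(pos_sites, neg_sites, bg_sites),
      o_gene = parse_site_key(c(pos_sites, neg_sites,
                                bg_sites))$gene_symbol,
      label = c(rep("positive", length(pos_sites)),
                rep("negative", length(neg_sites)),
                rep("null", length(bg_sites))))
    attr(truth, "target_sites") <- config$target_sites
    list(observations = obs, truth = truth)
  })
}

#' Score pipeline recovery of planted co-regulation structure
#'
#' Compares high-confidence sign calls against the planted truth over all
#' (target site, PsOP) pairs. A planted partner is expected to be recovered
#' at every target site (the generator couples all target sites to one
#' direction process), so the truth label of a pair is its partner's label.
#'
#' @param results Scan tibble from [coregulation_scan()] computed on the
#'   generated compendium.
#' @param truth Truth tibble from [generate_compendium()].
#' @param alpha Significance level used for the null false-positive rate
#'   bookkeeping (recorded in the output).
#' @return A list of class `recovery_report`: `per_sign` tibble (`sign`,
#'   `n_true`, `n_called`, `tp`, `precision`, `recall`, `f1`; precision is
#'   `NA` when nothing was called) and `fpr` (fraction of background pairs
#'   called high-confidence) with `n_null_pairs`.
#' @export
evaluate_recovery <- function(results, truth, alpha = 0.05) {
  target_sites <- attr(truth, "target_sites")
  if (is.null(target_sites)) {
    stop("truth lacks its target_sites attribute", call. = FALSE)
  }
  unknown <- setdiff(unique(results$o_site), truth$o_site)
  if (length(unknown)) {
    stop("results contain sites absent from truth: ",
         paste(head(unknown, 3), collapse = ", "), call. = FALSE)
  }
  all_pairs <- tidyr::expand_grid(m_site = target_sites,
                                  o_site = truth$o_site)
  all_pairs <- dplyr::left_join(all_pairs, truth[, c("o_site", "label")],
                                by = "o_site")
  all_pairs <- dplyr::left_join(
    all_pairs, results[, c("m_site", "o_site", "sign")],
    by = c("m_site", "o_site"))
  all_pairs$sign <- dplyr::coalesce(all_pairs$sign, "none")

  per_sign <- lapply(c("positive", "negative"), function(sg) {
    n_true <- sum(all_pairs$label == sg)
    n_called <- sum(all_pairs$sign == sg)
    tp <- sum(all_pairs$label == sg & all_pairs$sign == sg)
    precision <- if (n_called > 0) tp / n_called else NA_real_
    recall <- if (n_true > 0) tp / n_true else NA_real_
    f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
      2 * precision * recall / (precision + recall) else NA_real_
    tibble::tibble(sign = sg, n_true = n_true, n_called = n_called, tp = tp,
                   precision = precision, recall = recall, f1 = f1)
  })
  nulls <- all_pairs[all_pairs$label == "null", , drop = FALSE]
  fpr <- if (nrow(nulls) > 0) mean(nulls$sign != "none") else NA_real_
  structure(list(per_sign = dplyr::bind_rows(per_sign), fpr = fpr,
                 n_null_pairs = nrow(nulls), alpha = alpha),
            class = "recovery_report")
}

#' Empirical false-positive rate of the high-confidence gate under the null
#'
#' Repeatedly generates compendia with no planted partners (background sites
#' only, independent of the target), runs the full scan and gate, and pools
#' the fraction of null pairs called high-confidence, with an exact binomial
#' confidence interval. Because Fisher's exact test is conservative and the
#' gate stacks ratio, dominance and evidence filters on top, this fraction
#' stays at or below `alpha`.
#'
#' @param config A [synth_config()] with `n_pos_partners = 0` and
#'   `n_neg_partners = 0`; replicate `r` uses seed `config$seed + r`.
#' @param replicates Number of generated compendia.
#' @param alpha Gate significance level.
#' @return A list of class `null_calibration`: `fpr`, `n_pairs`, `n_called`,
#'   `se` (binomial standard error at `alpha`), `ci` (exact 95% binomial
#'   interval).
#' @export
null_calibration <- function(config, replicates = 20, alpha = 0.05) {
  stopifnot(inherits(config, "synth_config"))
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  if (config$n_pos_partners > 0 || config$n_neg_partners > 0) {
    stop("null calibration requires a config without planted partners",
         call. = FALSE)
  }
  hc <- highconf_config(alpha = alpha)
  n_pairs <- 0L
  n_called <- 0L
  for (r in seq_len(replicates)) {
    cfg <- config
    cfg$seed <- config$seed + r
    sim <- generate_compendium(cfg)
    obs <- add_direction_calls(
      suppressMessages(filter_class1(sim$observations)))
    calls <- resolve_conflicts(obs)
    scan <- coregulation_scan(calls, cfg$target, cfg$target_sites, hc)
    rep_pairs <- length(cfg$target_sites) * nrow(sim$truth)
    n_pairs <- n_pairs + rep_pairs
    n_called <- n_called + sum(scan$sign != "none")
  }
  if (n_pairs < 100L) {
    stop("too few null pairs (", n_pairs,
         "); increase replicates or n_background", call. = FALSE)
  }
  ci <- as.numeric(binom.test(n_called, n_pairs)$conf.int)
  structure(list(fpr = n_called / n_pairs, n_pairs = n_pairs,
                 n_called = n_called,
                 se = sqrt(alpha * (1 - alpha) / n_pairs), ci = ci),
            class = "null_calibration")
}
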