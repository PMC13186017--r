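#' Filtering and direction-calling parameters
#'
#' Thresholds for Class-I site filtering and for calling per-condition
#' direction from fold change and significance. Defaults follow common
#' phosphoproteomics curation practice: localization probability >= 0.75 and
#' ambiguity score (A-score) >= 13 define confidently localized (Class I)
#' sites; a site is upregulated at fold change >= 1.3 and downregulated at
#' fold change <= 0.76, in both cases requiring p < 0.05.
#'
#' @param min_loc_prob Minimum localization probability, in \[0, 1\].
#' @param min_ascore Minimum A-score. Rows with a missing A-score pass the
#'   gate unless `strict_ascore = TRUE` (profiling sources often omit it).
#' @param up_fc Fold-change threshold at or above which a significant site is
#'   called Up (linear ratio scale).
#' @param down_fc Fold-change threshold at or below which a significant site
#'   is called Down. Must satisfy `down_fc < 1 < up_fc`.
#' @param alpha Significance level for the per-site differential test.
#' @param strict_ascore If `TRUE`, rows with a missing A-score are removed by
#'   [filter_class1()].
#' @param log2_fc If `TRUE`, fold changes in input files are interpreted as
#'   log2 ratios and exponentiated on read.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_loc_prob = 0.75, min_ascore = 13,
                          up_fc = 1.3, down_fc = 0.76, alpha = 0.05,
                          strict_ascore = FALSE, log2_fc = FALSE) {
  stopifnot(min_loc_prob >= 0, min_loc_prob <= 1,
            down_fc < 1, up_fc > 1, alpha > 0, alpha < 1)
  structure(list(min_loc_prob = min_loc_prob, min_ascore = min_ascore,
                 up_fc = up_fc, down_fc = down_fc, alpha = alpha,
                 strict_ascore = strict_ascore, log2_fc = log2_fc),
            class = "filter_config")
}

.obs_required <- c("pmid", "dataset_id", "condition_id", "gene_symbol",
                   "residue", "position", "loc_prob")
.obs_optional <- c("ascore", "fold_change", "p_value", "flanking",
                   "dataset_kind", "log2_flag")

#' Read a phosphosite observation table
#'
#' Reads a long-format, tab-separated compendium file: one row per phosphosite
#' observation in one experimental comparison. Required columns are `pmid`,
#' `dataset_id`, `condition_id`, `gene_symbol`, `residue`, `position` and
#' `loc_prob`; `ascore`, `fold_change`, `p_value`, `flanking`, `log2_flag`
#' and `dataset_kind` are used when present. Missing optional cells become
#' `NA`, never zeros; row order is preserved.
#'
#' Observations come in two kinds: `"differential"` rows from quantitative
#' comparisons (carrying `fold_change` and `p_value`) and `"profile"` rows
#' from qualitative profiling datasets that merely report detection.
#'
#' @param path Path to a TSV file with a header row.
#' @param dataset_kind `"differential"`, `"profile"`, or `"mixed"` (default),
#'   in which case the file must carry a `dataset_kind` column.
#' @param alias_map Optional named character vector (names = aliases) used to
#'   normalize gene symbols on read; see [normalize_symbol()].
#' @param config A [filter_config()]; its `log2_fc` flag controls fold-change
#'   interpretation (a per-row logical `log2_flag` column overrides it).
#' @return A tibble of observations with one row per input row.
#' @export
read_observations <- function(path, dataset_kind = c("mixed", "differential",
                                                     "profile"),
                              alias_map = NULL, config = filter_config()) {
  dataset_kind <- match.arg(dataset_kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing_cols <- setdiff(.obs_required, names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    warning("empty observation file: ", path, call. = FALSE)
  }
  if (dataset_kind == "mixed") {
    if (!"dataset_kind" %in% names(raw)) {
      stop("dataset_kind = \"mixed\" requires a 'dataset_kind' column",
           call. = FALSE)
    }
    kind <- raw$dataset_kind
    bad <- !kind %in% c("differential", "profile")
    if (any(bad)) {
      stop("invalid dataset_kind value(s): ",
           paste(unique(kind[bad]), collapse = ", "), call. = FALSE)
    }
  } else {
    kind <- rep(dataset_kind, nrow(raw))
  }

  opt <- function(col) if (col %in% names(raw)) raw[[col]] else
    rep(NA_character_, nrow(raw))

  obs <- tibble::tibble(
    pmid = raw$pmid,
    dataset_id = raw$dataset_id,
    condition_id = raw$condition_id,
    dataset_kind = kind,
    gene_symbol = normalize_symbol(raw$gene_symbol, alias_map),
    residue = toupper(raw$residue),
    position = parse_numeric_col(raw$position, "position"),
    flanking = opt("flanking"),
    loc_prob = parse_numeric_col(raw$loc_prob, "loc_prob"),
    ascore = parse_numeric_col(opt("ascore"), "ascore"),
    fold_change = parse_numeric_col(opt("fold_change"), "fold_change"),
    p_value = parse_numeric_col(opt("p_value"), "p_value")
  )
  if (any(is.na(obs$pmid) | !nzchar(obs$pmid))) {
    stop("pmid must be non-empty on every row", call. = FALSE)
  }
  if (!all(obs$residue %in% c("S", "T", "Y"))) {
    bad <- which(!obs$residue %in% c("S", "T", "Y"))[1]
    stop(sprintf("column 'residue': invalid value '%s' at data row %d",
                 obs$residue[bad], bad), call. = FALSE)
  }
  if (any(is.na(obs$position) | obs$position < 1 |
          obs$position != round(obs$position))) {
    bad <- which(is.na(obs$position) | obs$position < 1 |
                   obs$position != round(obs$position))[1]
    stop(sprintf("column 'position': invalid value at data row %d", bad),
         call. = FALSE)
  }
  obs$position <- as.integer(obs$position)
  if (any(!is.na(obs$loc_prob) & (obs$loc_prob < 0 | obs$loc_prob > 1))) {
    bad <- which(obs$loc_prob < 0 | obs$loc_prob > 1)[1]
    stop(sprintf("column 'loc_prob': value outside [0,1] at data row %d", bad),
         call. = FALSE)
  }

  # fold changes reported on log2 scale are exponentiated on read
  is_log2 <- rep(isTRUE(config$log2_fc), nrow(obs))
  if ("log2_flag" %in% names(raw)) {
    flag <- toupper(raw$log2_flag)
    is_log2 <- ifelse(is.na(flag) | !nzchar(flag), is_log2,
                      flag %in% c("TRUE", "T", "1", "YES"))
  }
  conv <- is_log2 & !is.na(obs$fold_change)
  obs$fold_change[conv] <- 2^obs$fold_change[conv]

  if (any(!is.na(obs$fold_change) & obs$fold_change <= 0)) {
    bad <- which(obs$fold_change <= 0)[1]
    stop(sprintf("column 'fold_change': non-positive ratio at data row %d",
                 bad), call. = FALSE)
  }
  # profile rows carry no quantitative comparison
  prof <- obs$dataset_kind == "profile"
  obs$fold_change[prof] <- NA_real_
  obs$p_value[prof] <- NA_real_
  obs$site <- site_key(obs$gene_symbol, obs$residue, obs$position)
  obs
}

#' Write a phosphosite observation table
#'
#' Inverse of [read_observations()]: writes the observation tibble as TSV so
#' that reading it back reproduces identical observations.
#'
#' @param obs Observation tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  cols <- c(.obs_required[.obs_required != "loc_prob"], "dataset_kind",
            "flanking", "loc_prob", "ascore", "fold_change", "p_value")
  readr::write_tsv(obs[, intersect(cols, names(obs))], path, progress = FALSE)
  invisible(path)
}

#' Normalize gene symbols against an alias map
#'
#' Maps legacy or alias symbols to approved symbols (HGNC-style
#' standardization). Input is uppercased first; if the uppercased symbol is a
#' key of `alias_map` the approved symbol is returned, otherwise the
#' uppercased input itself.
#'
#' @param raw_symbol Character vector of raw gene symbols; must be non-empty.
#' @param alias_map Named character vector, `names` = alias (uppercase),
#'   values = approved symbol; or `NULL` for case-folding only.
#' @return Character vector of normalized symbols.
#' @examples
#' normalize_symbol("mki67", NULL)
#' normalize_symbol("KIAA0175", c(KIAA0175 = "MELK"))
#' @export
normalize_symbol <- function(raw_symbol, alias_map = NULL) {
  if (any(is.na(raw_symbol) | !nzchar(trimws(raw_symbol)))) {
    stop("empty gene symbol", call. = FALSE)
  }
  up <- toupper(trimws(raw_symbol))
  if (is.null(alias_map) || length(alias_map) == 0L) return(up)
  hit <- match(up, toupper(names(alias_map)))
  ifelse(is.na(hit), up, unname(alias_map[hit]))
}

#' Read a two-column alias map
#'
#' @param path TSV with header columns `alias` and `approved_symbol`.
#' @return Named character vector suitable for [normalize_symbol()].
#' @export
read_alias_map <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("alias", "approved_symbol")
  if (!all(need %in% names(tab))) {
    stop("alias map must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  setNames(toupper(tab$approved_symbol), toupper(tab$alias))
}

#' Keep Class-I phosphosite observations
#'
#' Retains confidently localized sites: localization probability at or above
#' `min_loc_prob` and A-score at or above `min_ascore` (rows with a missing
#' A-score pass unless `strict_ascore` is set). The filter is total and
#' idempotent; ordering is preserved and the number of removed rows is
#' reported as a message.
#'
#' @param obs Observation tibble from [read_observations()].
#' @param config A [filter_config()].
#' @return The filtered observation tibble.
#' @export
filter_class1 <- function(obs, config = filter_config()) {
  keep_loc <- !is.na(obs$loc_prob) & obs$loc_prob >= config$min_loc_prob
  keep_asc <- if (isTRUE(config$strict_ascore)) {
    !is.na(obs$ascore) & obs$ascore >= config$min_ascore
  } else {
    is.na(obs$ascore) | obs$ascore >= config$min_ascore
  }
  keep <- keep_loc & keep_asc
  removed <- sum(!keep)
  if (removed > 0) {
    message(sprintf("filter_class1: removed %d of %d observations",
                    removed, nrow(obs)))
  }
  obs[keep, , drop = FALSE]
}

#' Call per-observation direction from fold change and p-value
#'
#' A differential observation is `Up` when its fold change is at or above
#' `up_fc` with `p < alpha`, `Down` when at or below `down_fc` with
#' `p < alpha`, and `Unchanged` otherwise (including significant fold changes
#' inside the dead zone and missing p-values).
#'
#' @param fold_change Positive numeric vector of linear ratios; must not be
#'   missing for differential rows.
#' @param p_value Numeric vector of per-site test p-values (NA treated as not
#'   significant).
#' @param config A [filter_config()].
#' @return Character vector over `"Up"`, `"Down"`, `"Unchanged"`.
#' @examples
#' call_direction(c(1.3, 0.76, 2.0, 1.0), c(0.01, 0.04, 0.2, 0.001))
#' @export
call_direction <- function(fold_change, p_value, config = filter_config()) {
  if (any(is.na(fold_change))) {
    stop("fold_change missing for differential observation", call. = FALSE)
  }
  if (any(fold_change <= 0)) {
    stop("fold_change must be positive", call. = FALSE)
  }
  sig <- !is.na(p_value) & p_value < config$alpha
  out <- rep("Unchanged", length(fold_change))
  out[sig & fold_change >= config$up_fc] <- "Up"
  out[sig & fold_change <= config$down_fc] <- "Down"
  out
}

#' Attach direction calls to an observation table
#'
#' Adds a `direction` column: differential rows are called with
#' [call_direction()]; profile rows get `NA` (they record detection only).
#'
#' @param obs Observation tibble.
#' @param config A [filter_config()].
#' @return `obs` with a `direction` column.
#' @export
add_direction_calls <- function(obs, config = filter_config()) {
  obs$direction <- NA_character_
  diff <- obs$dataset_kind == "differential"
  if (any(diff)) {
    obs$direction[diff] <- call_direction(obs$fold_change[diff],
                                          obs$p_value[diff], config)
  }
  obs
}

#' Collapse duplicate observations to one direction call per condition-site
#'
#' Several peptides (rows) may report the same site in the same comparison.
#' Groups are collapsed by (`pmid`, `dataset_id`, `condition_id`, `site`):
#' if both `Up` and `Down` occur the group is `Ambiguous` (and excluded from
#' all downstream event counting); otherwise any significant call dominates
#' `Unchanged`.
#'
#' @param obs Direction-called observation tibble (see
#'   [add_direction_calls()]); profile rows are ignored.
#' @return A condition-call tibble with one row per (condition, site):
#'   columns `pmid`, `dataset_id`, `condition_id`, `condition_key`,
#'   `dataset_key`, `site`, `gene_symbol`, `residue`, `position`, `direction`.
#' @export
resolve_conflicts <- function(obs) {
  if (!"direction" %in% names(obs)) {
    stop("observations must be direction-called first", call. = FALSE)
  }
  diff <- obs[obs$dataset_kind == "differential" & !is.na(obs$direction), ,
              drop = FALSE]
  out <- diff |>
    dplyr::group_by(.data$pmid, .data$dataset_id, .data$condition_id,
                    .data$site, .data$gene_symbol, .data$residue,
                    .data$position) |>
    dplyr::summarise(direction = {
      d <- .data$direction
      if (any(d == "Up") && any(d == "Down")) "Ambiguous"
      else if (any(d == "Up")) "Up"
      else if (any(d == "Down")) "Down"
      else "Unchanged"
    }, .groups = "drop") |>
    dplyr::mutate(
      condition_key = condition_key(.data$pmid, .data$dataset_id,
                                    .data$condition_id),
      dataset_key = dataset_key(.data$pmid, .data$dataset_id)
    ) |>
    dplyr::arrange(.data$condition_key, .data$site)
  out
}
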