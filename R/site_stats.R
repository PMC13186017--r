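#' Per-site detection frequency across datasets
#'
#' Counts, for every phosphosite of one protein, in how many distinct profile
#' datasets it was detected and in how many distinct differential datasets it
#' was significantly regulated (Up or Down). A dataset contributes at most 1
#' to each count regardless of how many conditions or peptide rows detect the
#' site; the two dataset kinds are tallied separately and summed into
#' `n_total`.
#'
#' @param calls Condition-call tibble from [resolve_conflicts()].
#' @param profile_obs Class-I-filtered observation tibble restricted (or
#'   restrictable) to `dataset_kind == "profile"`; may be `NULL`.
#' @param protein Gene symbol of the target protein.
#' @return Tibble with columns `site`, `gene_symbol`, `residue`, `position`,
#'   `n_profile`, `n_differential`, `n_total`, one row per distinct site.
#' @export
detection_frequency <- function(calls, profile_obs, protein) {
  prof <- if (is.null(profile_obs)) NULL else
    profile_obs[profile_obs$dataset_kind == "profile" &
                  profile_obs$gene_symbol == protein, , drop = FALSE]
  diff <- calls[calls$gene_symbol == protein, , drop = FALSE]
  if ((is.null(prof) || nrow(prof) == 0L) && nrow(diff) == 0L) {
    warning("protein not found in compendium: ", protein, call. = FALSE)
    return(tibble::tibble(site = character(), gene_symbol = character(),
                          residue = character(), position = integer(),
                          n_profile = integer(), n_differential = integer(),
                          n_total = integer()))
  }
  p_counts <- if (is.null(prof) || nrow(prof) == 0L) {
    tibble::tibble(site = character(), n_profile = integer())
  } else {
    prof |>
      dplyr::distinct(.data$site,
                      ds = dataset_key(.data$pmid, .data$dataset_id)) |>
      dplyr::count(.data$site, name = "n_profile")
  }
  d_counts <- diff |>
    dplyr::filter(.data$direction %in% c("Up", "Down")) |>
    dplyr::distinct(.data$site, .data$dataset_key) |>
    dplyr::count(.data$site, name = "n_differential")

  sites <- dplyr::bind_rows(
    if (!is.null(prof)) prof[, c("site", "gene_symbol", "residue", "position")],
    diff[, c("site", "gene_symbol", "residue", "position")]
  ) |> dplyr::distinct()

  sites |>
    dplyr::left_join(p_counts, by = "site") |>
    dplyr::left_join(d_counts, by = "site") |>
    dplyr::mutate(
      n_profile = dplyr::coalesce(.data$n_profile, 0L),
      n_differential = dplyr::coalesce(.data$n_differential, 0L),
      n_total = .data$n_profile + .data$n_differential
    ) |>
    dplyr::arrange(.data$position)
}

#' Select the most recurrent (major) phosphosites
#'
#' Ranks sites by recurrence and returns the top `k` whose count meets
#' `min_count`. Ties are broken by ascending sequence position, so the result
#' is stable under permutation of the input.
#'
#' @param freqs Frequency tibble from [detection_frequency()].
#' @param k Number of sites to select (default 3).
#' @param min_count Minimum recurrence count required (default 2).
#' @param rank_by `"total"` (profile + differential, default) or
#'   `"differential"`.
#' @return Character vector of up to `k` site keys, ranked.
#' @export
select_major_sites <- function(freqs, k = 3, min_count = 2,
                               rank_by = c("total", "differential")) {
  rank_by <- match.arg(rank_by)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  score <- if (rank_by == "total") freqs$n_total else freqs$n_differential
  keep <- freqs[score >= min_count, , drop = FALSE]
  score <- score[score >= min_count]
  ord <- order(-score, keep$position)
  head(keep$site[ord], k)
}

#' Read a protein domain annotation table
#'
#' @param path TSV with header columns `name`, `start`, `end` (1-based,
#'   inclusive).
#' @return Tibble of domain annotations.
#' @export
read_domains <- function(path) {
  d <- readr::read_tsv(path, col_types = readr::cols(
    name = "c", start = "i", end = "i"), progress = FALSE)
  if (!all(c("name", "start", "end") %in% names(d))) {
    stop("domain table must have columns name, start, end", call. = FALSE)
  }
  if (any(d$start < 1 | d$end < d$start)) {
    stop("domain bounds must satisfy 1 <= start <= end", call. = FALSE)
  }
  d
}

#' Build a lollipop-plot export table
#'
#' One row per site with its recurrence count, whether it is a major site,
#' and the annotated domain (if any) containing its position. The table is
#' ordered by position and is directly consumable by lollipop/track plotting
#' tools.
#'
#' @param freqs Frequency tibble from [detection_frequency()].
#' @param domains Optional domain tibble from [read_domains()].
#' @param major Character vector of major site keys.
#' @return Tibble with columns `site`, `position`, `residue`, `count`,
#'   `is_major`, `domain_name` (empty string when in no domain).
#' @export
lollipop_table <- function(freqs, domains = NULL, major = character()) {
  if (nrow(freqs) == 0L) {
    return(tibble::tibble(site = character(), position = integer(),
                          residue = character(), count = integer(),
                          is_major = logical(), domain_name = character()))
  }
  dom_of <- function(pos) {
    if (is.null(domains) || nrow(domains) == 0L) return("")
    hit <- which(domains$start <= pos & pos <= domains$end)
    if (length(hit)) domains$name[hit[1]] else ""
  }
  tibble::tibble(
    site = freqs$site,
    position = freqs$position,
    residue = freqs$residue,
    count = freqs$n_total,
    is_major = freqs$site %in% major,
    domain_name = vapply(freqs$position, dom_of, character(1))
  ) |>
    dplyr::arrange(.data$position)
}
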