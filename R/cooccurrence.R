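#' Count joint directional events for a pair of phosphosites
#'
#' Tallies, over experimental comparisons where BOTH sites carry an Up or
#' Down call, the four joint outcomes: `n_uu` (both Up), `n_ud` (first Up,
#' second Down), `n_du` (first Down, second Up) and `n_dd` (both Down).
#' Conditions where either site is Unchanged, Ambiguous or not measured are
#' skipped.
#'
#' @param site_a,site_b Rendered site keys; must differ.
#' @param calls Condition-call tibble from [resolve_conflicts()].
#' @return Named integer vector `c(n_uu, n_ud, n_du, n_dd)`.
#' @export
pair_counts <- function(site_a, site_b, calls) {
  if (identical(site_a, site_b)) {
    stop("self-pairing is undefined", call. = FALSE)
  }
  inf <- calls[calls$direction %in% c("Up", "Down") &
                 calls$site %in% c(site_a, site_b), , drop = FALSE]
  a <- inf[inf$site == site_a, c("condition_key", "direction")]
  b <- inf[inf$site == site_b, c("condition_key", "direction")]
  j <- dplyr::inner_join(a, b, by = "condition_key",
                         suffix = c("_a", "_b"))
  c(n_uu = sum(j$direction_a == "Up" & j$direction_b == "Up"),
    n_ud = sum(j$direction_a == "Up" & j$direction_b == "Down"),
    n_du = sum(j$direction_a == "Down" & j$direction_b == "Up"),
    n_dd = sum(j$direction_a == "Down" & j$direction_b == "Down"))
}

#' Positive co-regulation ratio
#'
#' The concordant-to-discordant event ratio
#' (`n_uu` + `n_dd`) / (`n_ud` + `n_du`). Returns `Inf` when the denominator
#' is zero with a positive numerator, and `NA` (undefined) when all counts
#' are zero.
#'
#' @param counts Named numeric vector or list with elements `n_uu`, `n_ud`,
#'   `n_du`, `n_dd`.
#' @return A non-negative number, `Inf`, or `NA`.
#' @examples
#' positive_ratio(c(n_uu = 2, n_ud = 1, n_du = 1, n_dd = 2))
#' @export
positive_ratio <- function(counts) {
  counts <- as.list(counts)
  num <- counts$n_uu + counts$n_dd
  den <- counts$n_ud + counts$n_du
  if (num == 0 && den == 0) return(NA_real_)
  if (den == 0) return(Inf)
  num / den
}

#' Negative co-regulation ratio
#'
#' The discordant-to-concordant event ratio
#' (`n_ud` + `n_du`) / (`n_uu` + `n_dd`), with the same sentinel conventions
#' as [positive_ratio()]. Whenever both ratios are finite and nonzero their
#' product is 1.
#'
#' @inheritParams positive_ratio
#' @return A non-negative number, `Inf`, or `NA`.
#' @export
negative_ratio <- function(counts) {
  counts <- as.list(counts)
  num <- counts$n_ud + counts$n_du
  den <- counts$n_uu + counts$n_dd
  if (num == 0 && den == 0) return(NA_real_)
  if (den == 0) return(Inf)
  num / den
}

# bounded concordance score in [-1, 1]; 0 for pairs with no informative event
concordance_score <- function(n_uu, n_ud, n_du, n_dd) {
  tot <- n_uu + n_ud + n_du + n_dd
  ifelse(tot > 0, (n_uu + n_dd - n_ud - n_du) / tot, 0)
}

#' Pairwise co-occurrence matrix for a set of phosphosites
#'
#' Computes, for every ordered site pair, the joint event counts and a
#' bounded concordance score `(concordant - discordant) / total` in
#' \[-1, 1\] (0 when a pair shares no informative condition). The score
#' matrix is symmetric; its diagonal is 1 for sites with at least one
#' informative event and 0 otherwise. Raw counts are returned alongside so
#' that alternative statistics can be recomputed.
#'
#' @param sites Character vector of at least two site keys.
#' @param calls Condition-call tibble from [resolve_conflicts()].
#' @return A list of class `cooccurrence_matrix` with elements `sites`,
#'   `score` (numeric matrix), `counts` (total informative events per pair)
#'   and `pairs` (long tibble: `site_a`, `site_b`, `n_uu`, `n_ud`, `n_du`,
#'   `n_dd`, `score`).
#' @export
cooccurrence_matrix <- function(sites, calls) {
  if (length(sites) < 2L) stop("need at least 2 sites", call. = FALSE)
  n <- length(sites)
  score <- matrix(0, n, n, dimnames = list(sites, sites))
  total <- matrix(0L, n, n, dimnames = list(sites, sites))
  informative <- vapply(sites, function(s) {
    any(calls$site == s & calls$direction %in% c("Up", "Down"))
  }, logical(1))
  diag(score) <- as.numeric(informative)
  long <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      pc <- pair_counts(sites[i], sites[j], calls)
      tot <- sum(pc)
      sc <- concordance_score(pc["n_uu"], pc["n_ud"], pc["n_du"], pc["n_dd"])
      score[i, j] <- sc
      score[j, i] <- sc   # UD/DU swap leaves concordant/discordant sums fixed
      total[i, j] <- total[j, i] <- tot
      long[[length(long) + 1L]] <- tibble::tibble(
        site_a = sites[i], site_b = sites[j],
        n_uu = pc[["n_uu"]], n_ud = pc[["n_ud"]],
        n_du = pc[["n_du"]], n_dd = pc[["n_dd"]], score = sc)
    }
  }
  structure(list(sites = sites, score = score, counts = total,
                 pairs = dplyr::bind_rows(long)),
            class = "cooccurrence_matrix")
}

#' Write co-occurrence results as TSV
#'
#' Writes the long pair table (`site_a`, `site_b`, counts, score) and a
#' square score matrix usable by heatmap tools.
#'
#' @param mat A [cooccurrence_matrix()] result.
#' @param long_path Path for the long-format TSV.
#' @param matrix_path Optional path for the square score-matrix TSV.
#' @return Paths written, invisibly.
#' @export
write_cooccurrence <- function(mat, long_path, matrix_path = NULL) {
  readr::write_tsv(mat$pairs, long_path, progress = FALSE)
  if (!is.null(matrix_path)) {
    sq <- tibble::as_tibble(mat$score, rownames = "site")
    readr::write_tsv(sq, matrix_path, progress = FALSE)
  }
  invisible(c(long_path, matrix_path))
}
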