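#' High-confidence co-regulation gate parameters
#'
#' Thresholds for designating a phosphosite on another protein (PsOP) as
#' high-confidence co-regulated with a target-protein site: Fisher's exact
#' test p below `alpha`, sign-appropriate co-regulation ratio at or above
#' `min_ratio`, evidence from at least `min_conditions` distinct experimental
#' comparisons and `min_pmids` independent publications. A dominance
#' condition (concordant events strictly outnumber discordant for a positive
#' call, and vice versa) is always applied so a permissive ratio threshold
#' cannot call a mostly-discordant pair positive.
#'
#' @param alpha FET significance level (default 0.05, unadjusted).
#' @param min_ratio Minimum sign-appropriate co-regulation ratio
#'   (default 0.15). Infinite ratios (zero discordant events) pass.
#' @param min_conditions Minimum distinct supporting conditions (default 2).
#' @param min_pmids Minimum distinct supporting publications (default 2).
#' @param adjust P-value adjustment method passed to [stats::p.adjust()]
#'   applied across all scanned pairs before gating; default `"none"` (raw
#'   FET p), `"BH"` for Benjamini-Hochberg.
#' @param strict_evidence If `TRUE`, evidence counts tally only conditions in
#'   the sign-supporting categories rather than all informative events.
#' @return A list of class `highconf_config`.
#' @export
highconf_config <- function(alpha = 0.05, min_ratio = 0.15,
                            min_conditions = 2, min_pmids = 2,
                            adjust = "none", strict_evidence = FALSE) {
  stopifnot(alpha > 0, min_ratio > 0, min_conditions > 0, min_pmids > 0)
  structure(list(alpha = alpha, min_ratio = min_ratio,
                 min_conditions = min_conditions, min_pmids = min_pmids,
                 adjust = adjust, strict_evidence = strict_evidence),
            class = "highconf_config")
}

#' Orientation-fixed joint category counts for a target-site/PsOP pair
#'
#' Counts the four joint direction categories over comparisons where both the
#' target-protein site ("m") and the other-protein site ("o") carry an Up or
#' Down call: `n_UmUo`, `n_UmDo`, `n_DmUo`, `n_DmDo`. Orientation is fixed
#' with the target site first. Pairs within the target protein belong to
#' [pair_counts()] instead.
#'
#' @param m_site Target-protein site key.
#' @param o_site Other-protein site key; must be on a different protein.
#' @param calls Condition-call tibble from [resolve_conflicts()].
#' @return Named integer vector `c(n_UmUo, n_UmDo, n_DmUo, n_DmDo)`.
#' @export
category_counts <- function(m_site, o_site, calls) {
  gm <- parse_site_key(m_site)$gene_symbol
  go <- parse_site_key(o_site)$gene_symbol
  if (identical(gm, go)) {
    stop("m and o sites are on the same protein; use pair_counts()",
         call. = FALSE)
  }
  pc <- pair_counts(m_site, o_site, calls)
  c(n_UmUo = pc[["n_uu"]], n_UmDo = pc[["n_ud"]],
    n_DmUo = pc[["n_du"]], n_DmDo = pc[["n_dd"]])
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value for the contingency table
#' `[[n11, n12], [n21, n22]]`, computed by summing all hypergeometric point
#' probabilities (given the table margins) that do not exceed the observed
#' table's probability, with a relative tolerance of 1e-7 on the comparison.
#'
#' @param n11,n12,n21,n22 Non-negative integer cell counts; alternatively
#'   `n11` may be a length-4 vector or 2x2 matrix.
#' @return The two-sided p-value in (0, 1\], or `NA` for an all-zero table.
#' @examples
#' fisher_exact_2x2(5, 0, 0, 5)  # 2/252
#' @export
fisher_exact_2x2 <- function(n11, n12 = NULL, n21 = NULL, n22 = NULL) {
  if (is.null(n12)) {
    x <- as.integer(n11)
    stopifnot(length(x) == 4L)
    n11 <- x[1]; n12 <- x[2]; n21 <- x[3]; n22 <- x[4]
  }
  cells <- c(n11, n12, n21, n22)
  if (any(is.na(cells)) || any(cells < 0)) {
    stop("cell counts must be non-negative", call. = FALSE)
  }
  if (all(cells == 0)) return(NA_real_)
  r1 <- n11 + n12
  c1 <- n11 + n21
  n <- sum(cells)
  lo <- max(0L, r1 + c1 - n)
  hi <- min(r1, c1)
  support <- lo:hi
  d <- dhyper(support, c1, n - c1, r1)
  p_obs <- dhyper(n11, c1, n - c1, r1)
  p <- sum(d[d <= p_obs * (1 + 1e-7)])
  min(p, 1)
}

#' Distinct-condition and distinct-publication evidence counts
#'
#' Counts the distinct experimental comparisons and distinct publications
#' (PMIDs) in which the pair contributes any of the four joint direction
#' events. With `supporting_only`, only conditions in the sign-supporting
#' categories (concordant for `"positive"`, discordant for `"negative"`) are
#' tallied.
#'
#' @inheritParams category_counts
#' @param supporting_only Logical; restrict to sign-supporting events.
#' @param sign `"positive"` or `"negative"`; required when
#'   `supporting_only = TRUE`.
#' @return Named integer vector `c(n_conditions, n_pmids)`.
#' @export
evidence_counts <- function(m_site, o_site, calls, supporting_only = FALSE,
                            sign = NULL) {
  inf <- calls[calls$direction %in% c("Up", "Down") &
                 calls$site %in% c(m_site, o_site), , drop = FALSE]
  a <- inf[inf$site == m_site, c("condition_key", "pmid", "direction")]
  b <- inf[inf$site == o_site, c("condition_key", "direction")]
  j <- dplyr::inner_join(a, b, by = "condition_key",
                         suffix = c("_m", "_o"))
  if (isTRUE(supporting_only)) {
    if (is.null(sign)) stop("sign required with supporting_only", call. = FALSE)
    conc <- j$direction_m == j$direction_o
    j <- if (sign == "positive") j[conc, , drop = FALSE]
         else j[!conc, , drop = FALSE]
  }
  c(n_conditions = length(unique(j$condition_key)),
    n_pmids = length(unique(j$pmid)))
}

#' Apply the high-confidence co-regulation gate
#'
#' Classifies each pair as `"positive"`, `"negative"`, or `"none"`. A pair is
#' positive iff FET p < `alpha`, positive ratio >= `min_ratio`, concordant
#' events strictly outnumber discordant, and both evidence counts are met;
#' negative iff the mirrored conditions hold with the negative ratio and
#' discordant dominance. The two calls are mutually exclusive because the
#' dominance conditions are.
#'
#' @param result Tibble (one or more rows) with columns `n_UmUo`, `n_UmDo`,
#'   `n_DmUo`, `n_DmDo`, `fet_p`, `ratio_pos`, `ratio_neg`, `n_conditions`,
#'   `n_pmids` (as produced by [coregulation_scan()]).
#' @param config A [highconf_config()].
#' @return Character vector of signs, one per row.
#' @export
call_high_confidence <- function(result, config = highconf_config()) {
  conc <- result$n_UmUo + result$n_DmDo
  disc <- result$n_UmDo + result$n_DmUo
  fet_ok <- !is.na(result$fet_p) & result$fet_p < config$alpha
  ev_ok <- result$n_conditions >= config$min_conditions &
    result$n_pmids >= config$min_pmids
  pos <- fet_ok & ev_ok & conc > disc &
    !is.na(result$ratio_pos) & result$ratio_pos >= config$min_ratio
  neg <- fet_ok & ev_ok & disc > conc &
    !is.na(result$ratio_neg) & result$ratio_neg >= config$min_ratio
  dplyr::case_when(pos ~ "positive", neg ~ "negative", .default = "none")
}

#' Scan all phosphosites on other proteins against target sites
#'
#' For every (target site, PsOP) pair sharing at least one informative
#' comparison, computes the joint category counts, the two-sided Fisher's
#' exact p for the 2x2 of target direction by PsOP direction, both
#' co-regulation ratios, the distinct-condition/publication evidence counts,
#' and the high-confidence sign call.
#'
#' @param calls Condition-call tibble from [resolve_conflicts()].
#' @param target Gene symbol of the target protein.
#' @param m_sites Character vector of target site keys to scan.
#' @param config A [highconf_config()].
#' @return Tibble with one row per evaluated pair: `m_site`, `o_site`,
#'   `n_UmUo`, `n_UmDo`, `n_DmUo`, `n_DmDo`, `fet_p`, `ratio_pos`,
#'   `ratio_neg`, `n_conditions`, `n_pmids`, `sign`, sorted by
#'   (`m_site`, `o_site`).
#' @export
coregulation_scan <- function(calls, target, m_sites,
                              config = highconf_config()) {
  inf <- calls[calls$direction %in% c("Up", "Down"), , drop = FALSE]
  m <- inf[inf$site %in% m_sites & inf$gene_symbol == target, ,
           drop = FALSE]
  o <- inf[inf$gene_symbol != target, , drop = FALSE]
  if (nrow(m) == 0L || nrow(o) == 0L) {
    return(tibble::tibble(m_site = character(), o_site = character(),
                          n_UmUo = integer(), n_UmDo = integer(),
                          n_DmUo = integer(), n_DmDo = integer(),
                          fet_p = numeric(), ratio_pos = numeric(),
                          ratio_neg = numeric(), n_conditions = integer(),
                          n_pmids = integer(), sign = character()))
  }
  ev <- dplyr::inner_join(
    m[, c("condition_key", "pmid", "site", "direction")],
    o[, c("condition_key", "site", "direction")],
    by = "condition_key", suffix = c("_m", "_o"),
    relationship = "many-to-many")
  res <- ev |>
    dplyr::group_by(m_site = .data$site_m, o_site = .data$site_o) |>
    dplyr::summarise(
      n_UmUo = sum(.data$direction_m == "Up" & .data$direction_o == "Up"),
      n_UmDo = sum(.data$direction_m == "Up" & .data$direction_o == "Down"),
      n_DmUo = sum(.data$direction_m == "Down" & .data$direction_o == "Up"),
      n_DmDo = sum(.data$direction_m == "Down" & .data$direction_o == "Down"),
      n_conditions_all = dplyr::n_distinct(.data$condition_key),
      n_pmids_all = dplyr::n_distinct(.data$pmid),
      n_cond_conc = dplyr::n_distinct(
        .data$condition_key[.data$direction_m == .data$direction_o]),
      n_pmid_conc = dplyr::n_distinct(
        .data$pmid[.data$direction_m == .data$direction_o]),
      n_cond_disc = dplyr::n_distinct(
        .data$condition_key[.data$direction_m != .data$direction_o]),
      n_pmid_disc = dplyr::n_distinct(
        .data$pmid[.data$direction_m != .data$direction_o]),
      .groups = "drop")
  res$fet_p <- vapply(seq_len(nrow(res)), function(i) {
    fisher_exact_2x2(res$n_UmUo[i], res$n_UmDo[i],
                     res$n_DmUo[i], res$n_DmDo[i])
  }, numeric(1))
  if (!identical(config$adjust, "none")) {
    res$fet_p <- p.adjust(res$fet_p, method = config$adjust)
  }
  res$ratio_pos <- vapply(seq_len(nrow(res)), function(i) {
    positive_ratio(c(n_uu = res$n_UmUo[i], n_ud = res$n_UmDo[i],
                     n_du = res$n_DmUo[i], n_dd = res$n_DmDo[i]))
  }, numeric(1))
  res$ratio_neg <- vapply(seq_len(nrow(res)), function(i) {
    negative_ratio(c(n_uu = res$n_UmUo[i], n_ud = res$n_UmDo[i],
                     n_du = res$n_DmUo[i], n_dd = res$n_DmDo[i]))
  }, numeric(1))
  if (isTRUE(config$strict_evidence)) {
    conc_dom <- (res$n_UmUo + res$n_DmDo) > (res$n_UmDo + res$n_DmUo)
    res$n_conditions <- ifelse(conc_dom, res$n_cond_conc, res$n_cond_disc)
    res$n_pmids <- ifelse(conc_dom, res$n_pmid_conc, res$n_pmid_disc)
  } else {
    res$n_conditions <- res$n_conditions_all
    res$n_pmids <- res$n_pmids_all
  }
  res <- res[, c("m_site", "o_site", "n_UmUo", "n_UmDo", "n_DmUo", "n_DmDo",
                 "fet_p", "ratio_pos", "ratio_neg", "n_conditions",
                 "n_pmids")]
  res$sign <- call_high_confidence(res, config)
  dplyr::arrange(res, .data$m_site, .data$o_site)
}

#' Disjoint Venn partition of two or three site-keyed sets
#'
#' Decomposes the union of the given sets into exact disjoint regions (7 for
#' three sets, 3 for two), keyed by the set names joined with `"&"`.
#'
#' @param sets Named list of 2 or 3 character vectors (e.g. the positive
#'   high-confidence PsOP site keys of each major target site).
#' @return A list of class `venn_partition` with `region_counts` (named
#'   integer vector) and `region_members` (named list of character vectors).
#' @examples
#' venn_partition(list(A = c("x", "y", "z"), B = c("y", "z"), C = "z"))
#' @export
venn_partition <- function(sets) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("sets must be a named list", call. = FALSE)
  }
  k <- length(sets)
  if (k < 2L || k > 3L) stop("need exactly 2 or 3 sets", call. = FALSE)
  sets <- lapply(sets, unique)
  nm <- names(sets)
  universe <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  # all non-empty subsets of the set names, smallest first
  combos <- unlist(lapply(seq_len(k), function(size) {
    asplit(utils::combn(nm, size), 2)
  }), recursive = FALSE)
  members <- lapply(combos, function(cmb) {
    inside <- rowSums(membership[, cmb, drop = FALSE]) == length(cmb)
    outside <- if (length(cmb) == k) rep(FALSE, length(universe)) else
      rowSums(membership[, setdiff(nm, cmb), drop = FALSE]) > 0
    sort(universe[inside & !outside])
  })
  labels <- vapply(combos, paste, character(1), collapse = "&")
  names(members) <- labels
  structure(list(region_counts = setNames(lengths(members), labels),
                 region_members = members),
            class = "venn_partition")
}

#' Write a Venn partition as TSV
#'
#' @param vp A [venn_partition()] result.
#' @param path Output TSV path; columns `region`, `count`, `members`
#'   (semicolon-joined).
#' @return `path`, invisibly.
#' @export
write_venn <- function(vp, path) {
  tab <- tibble::tibble(
    region = names(vp$region_counts),
    count = as.integer(vp$region_counts),
    members = vapply(vp$region_members, paste, character(1), collapse = ";"))
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}
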