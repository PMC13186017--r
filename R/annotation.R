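.resource_kinds <- c("kinase_substrate", "predicted_kinase_site",
                     "interaction", "kinase_list", "phosphatase_list")

.resource_cols <- list(
  kinase_substrate = c("kinase", "substrate"),
  predicted_kinase_site = c("kinase", "target"),
  interaction = c("gene_a", "gene_b"),
  kinase_list = "gene",
  phosphatase_list = "gene")

#' Load a flat-file annotation resource
#'
#' Reads one of the five resource kinds used for role stratification, as a
#' local TSV snapshot (database APIs are never queried, keeping runs
#' reproducible). Gene symbols are normalized with the same alias map as the
#' compendium so cross-matching is consistent; records are deduplicated on
#' all fields, and interaction edges are stored undirected (the pair is
#' sorted, so (A,B) and (B,A) collapse to one edge).
#'
#' Expected columns by kind (header required; extra columns ignored):
#' * `kinase_substrate`: `kinase`, `substrate`, optional `site` (e.g. "S216")
#' * `predicted_kinase_site`: `kinase`, optional `kinase_site`, `target`,
#'   optional `target_site`
#' * `interaction`: `gene_a`, `gene_b`
#' * `kinase_list` / `phosphatase_list`: `gene`
#'
#' A `source_tag` column, if present, carries per-record provenance;
#' otherwise the `source_tag` argument (default: file name) applies to all
#' records.
#'
#' @param path TSV file path.
#' @param kind One of `"kinase_substrate"`, `"predicted_kinase_site"`,
#'   `"interaction"`, `"kinase_list"`, `"phosphatase_list"`.
#' @param source_tag Provenance string (resource name + version).
#' @param alias_map Optional alias map (see [normalize_symbol()]).
#' @return A list of class `annot_resource` with elements `kind`, `records`
#'   (tibble) and `source_tag`.
#' @export
load_resource <- function(path, kind, source_tag = NULL, alias_map = NULL) {
  if (!kind %in% .resource_kinds) {
    stop("unknown resource kind: ", kind, call. = FALSE)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- .resource_cols[[kind]]
  if (!all(need %in% names(raw))) {
    stop(sprintf("%s resource must have columns: %s", kind,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    warning("empty resource file: ", path, call. = FALSE)
  }
  tag <- if ("source_tag" %in% names(raw)) raw$source_tag else
    rep(source_tag %||% basename(path), nrow(raw))
  norm <- function(x) normalize_symbol(x, alias_map)
  site_col <- function(col) {
    if (col %in% names(raw)) toupper(raw[[col]]) else
      rep(NA_character_, nrow(raw))
  }
  rec <- switch(kind,
    kinase_substrate = tibble::tibble(
      source_gene = norm(raw$kinase), target_gene = norm(raw$substrate),
      target_site = site_col("site"), source_tag = tag),
    predicted_kinase_site = tibble::tibble(
      source_gene = norm(raw$kinase), source_site = site_col("kinase_site"),
      target_gene = norm(raw$target), target_site = site_col("target_site"),
      source_tag = tag),
    interaction = {
      a <- norm(raw$gene_a); b <- norm(raw$gene_b)
      tibble::tibble(gene_a = pmin(a, b), gene_b = pmax(a, b),
                     source_tag = tag)
    },
    tibble::tibble(gene = norm(raw$gene), source_tag = tag))
  rec <- dplyr::distinct(rec)
  structure(list(kind = kind, records = rec,
                 source_tag = source_tag %||% basename(path)),
            class = "annot_resource")
}

# helper: residue+position part of a site key ("MELK_S356" -> "S356")
.site_rp <- function(site) sub("^.*_([STY][0-9]+)$", "\\1", site)

#' Stratify high-confidence PsOPs into functional roles
#'
#' Assigns each high-confidence pair zero or more of five roles based on the
#' loaded annotation resources:
#' * `upstream_kinase` — the PsOP's protein is recorded (predicted or
#'   experimentally validated) as a kinase of the target protein; when the
#'   record names a target site, it must match the pair's target site.
#' * `coregulated_kinase` — the PsOP's protein is in the kinase list.
#' * `phosphatase` — the PsOP's protein is in the phosphatase list.
#' * `binary_interactor` — an (undirected) interaction edge joins the PsOP's
#'   protein and the target.
#' * `substrate` — a kinase-substrate record has the target protein as kinase
#'   and the PsOP's protein as substrate.
#'
#' A PsOP may hold several roles simultaneously; adding resource records
#' never removes an assignment.
#'
#' @param highconf Tibble of scan rows with `sign != "none"` (from
#'   [coregulation_scan()]).
#' @param target Target protein gene symbol.
#' @param resources List of [load_resource()] objects.
#' @return Tibble with one row per (`m_site`, `o_site`, `role`): columns
#'   `m_site`, `o_site`, `o_gene`, `role`, `sign`, `evidence_tags`
#'   (semicolon-joined provenance).
#' @export
assign_roles <- function(highconf, target, resources) {
  stopifnot(all(vapply(resources, inherits, logical(1), "annot_resource")))
  if (nrow(highconf) && any(highconf$sign == "none")) {
    stop("assign_roles expects only high-confidence pairs (sign != 'none')",
         call. = FALSE)
  }
  byk <- split(resources, vapply(resources, `[[`, character(1), "kind"))
  recs <- function(kind) {
    if (is.null(byk[[kind]])) return(NULL)
    dplyr::bind_rows(lapply(byk[[kind]], `[[`, "records"))
  }
  pairs <- highconf
  pairs$o_gene <- parse_site_key(pairs$o_site)$gene_symbol
  out <- list()
  add <- function(idx, role, tags) {
    if (!length(idx)) return()
    out[[length(out) + 1L]] <<- tibble::tibble(
      m_site = pairs$m_site[idx], o_site = pairs$o_site[idx],
      o_gene = pairs$o_gene[idx], role = role, sign = pairs$sign[idx],
      evidence_tags = tags)
  }
  for (i in seq_len(nrow(pairs))) {
    g <- pairs$o_gene[i]
    m_rp <- .site_rp(pairs$m_site[i])
    tags <- character()
    ks <- recs("kinase_substrate")
    if (!is.null(ks)) {
      hit <- ks$source_gene == g & ks$target_gene == target &
        (is.na(ks$target_site) | ks$target_site == m_rp)
      tags <- c(tags, ks$source_tag[hit])
    }
    pk <- recs("predicted_kinase_site")
    if (!is.null(pk)) {
      hit <- pk$source_gene == g & pk$target_gene == target &
        (is.na(pk$target_site) | pk$target_site == m_rp)
      tags <- c(tags, pk$source_tag[hit])
    }
    if (length(tags)) {
      add(i, "upstream_kinase", paste(sort(unique(tags)), collapse = ";"))
    }
    kl <- recs("kinase_list")
    if (!is.null(kl) && g %in% kl$gene) {
      add(i, "coregulated_kinase",
          paste(sort(unique(kl$source_tag[kl$gene == g])), collapse = ";"))
    }
    pl <- recs("phosphatase_list")
    if (!is.null(pl) && g %in% pl$gene) {
      add(i, "phosphatase",
          paste(sort(unique(pl$source_tag[pl$gene == g])), collapse = ";"))
    }
    ia <- recs("interaction")
    if (!is.null(ia)) {
      hit <- (ia$gene_a == pmin(g, target) & ia$gene_b == pmax(g, target))
      if (any(hit)) {
        add(i, "binary_interactor",
            paste(sort(unique(ia$source_tag[hit])), collapse = ";"))
      }
    }
    if (!is.null(ks)) {
      hit <- ks$source_gene == target & ks$target_gene == g
      if (any(hit)) {
        add(i, "substrate",
            paste(sort(unique(ks$source_tag[hit])), collapse = ";"))
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(m_site = character(), o_site = character(),
                          o_gene = character(), role = character(),
                          sign = character(), evidence_tags = character()))
  }
  dplyr::bind_rows(out) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$role, .data$m_site, .data$o_site)
}

#' Core / pairwise / exclusive sharing of PsOPs across three target sites
#'
#' Partitions the PsOP site keys holding a given role and sign by which
#' target sites carry them: present at all three (`core`), at exactly one
#' pair (`pairwise`, keyed `"site1&site2"`), or at a single site
#' (`exclusive`). The three tiers are disjoint by construction and their
#' union is the set of assigned PsOPs for that role and sign.
#'
#' @param assignments Role assignment tibble from [assign_roles()].
#' @param role One of the five role labels.
#' @param sign `"positive"` or `"negative"`.
#' @param target_sites Character vector of exactly three target site keys.
#' @return A list of class `sharing_partition` with elements `core`
#'   (character vector), `pairwise` (named list) and `exclusive` (named
#'   list).
#' @export
sharing_partition <- function(assignments, role, sign, target_sites) {
  if (length(target_sites) != 3L) {
    stop("sharing_partition requires exactly three target sites",
         call. = FALSE)
  }
  sel <- assignments[assignments$role == role & assignments$sign == sign &
                       assignments$m_site %in% target_sites, , drop = FALSE]
  carried <- split(sel$m_site, sel$o_site)
  core <- character()
  pairwise <- list()
  exclusive <- list()
  pair_labels <- utils::combn(target_sites, 2, paste, collapse = "&")
  for (lab in pair_labels) pairwise[[lab]] <- character()
  for (s in target_sites) exclusive[[s]] <- character()
  for (o in names(carried)) {
    at <- target_sites[target_sites %in% carried[[o]]]
    if (length(at) == 3L) core <- c(core, o)
    else if (length(at) == 2L) {
      lab <- paste(at, collapse = "&")
      pairwise[[lab]] <- c(pairwise[[lab]], o)
    } else if (length(at) == 1L) {
      exclusive[[at]] <- c(exclusive[[at]], o)
    }
  }
  structure(list(core = sort(core),
                 pairwise = lapply(pairwise, sort),
                 exclusive = lapply(exclusive, sort)),
            class = "sharing_partition")
}
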