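#' Assemble the signed, role-annotated co-regulation network
#'
#' Nodes are phosphosites (target sites plus high-confidence PsOPs); edges
#' are the high-confidence pairs, signed `"positive"` or `"negative"` and
#' carrying the FET p, the sign-appropriate ratio and the evidence counts.
#' Role assignments are aggregated per PsOP node as a sorted
#' semicolon-joined list. Self-loops cannot arise because pairs always join
#' a target site to another protein's site. Each published role-stratified
#' network view is a filter of this one graph by role and sign.
#'
#' @param highconf Tibble of scan rows with `sign != "none"`; duplicate
#'   (`m_site`, `o_site`) pairs are an error.
#' @param roles Optional role assignment tibble from [assign_roles()].
#' @param target_sites Optional character vector of target site keys to
#'   include as nodes even when they have no edges.
#' @return A list of class `coreg_network` with tibbles `nodes` (`id`,
#'   `gene_symbol`, `residue`, `position`, `node_class`, `roles`) and
#'   `edges` (`from`, `to`, `sign`, `fet_p`, `ratio`, `n_conditions`,
#'   `n_pmids`), both deterministically sorted.
#' @export
build_network <- function(highconf, roles = NULL, target_sites = NULL) {
  if (nrow(highconf) && any(highconf$sign == "none")) {
    stop("build_network expects only high-confidence pairs", call. = FALSE)
  }
  key <- paste(highconf$m_site, highconf$o_site)
  if (anyDuplicated(key)) {
    stop("duplicate (m_site, o_site) pairs in input", call. = FALSE)
  }
  m_ids <- sort(unique(c(highconf$m_site, target_sites)))
  o_ids <- sort(setdiff(unique(highconf$o_site), m_ids))
  role_of <- function(id) {
    if (is.null(roles) || nrow(roles) == 0L) return("")
    paste(sort(unique(roles$role[roles$o_site == id])), collapse = ";")
  }
  ids <- c(m_ids, o_ids)
  meta <- parse_site_key(ids)
  nodes <- tibble::tibble(
    id = ids,
    gene_symbol = meta$gene_symbol,
    residue = meta$residue,
    position = meta$position,
    node_class = c(rep("target_site", length(m_ids)),
                   rep("psop", length(o_ids))),
    roles = vapply(ids, role_of, character(1), USE.NAMES = FALSE)
  ) |> dplyr::arrange(.data$node_class == "psop", .data$id)
  edges <- tibble::tibble(
    from = highconf$m_site,
    to = highconf$o_site,
    sign = highconf$sign,
    fet_p = highconf$fet_p,
    ratio = ifelse(highconf$sign == "positive", highconf$ratio_pos,
                   highconf$ratio_neg),
    n_conditions = highconf$n_conditions,
    n_pmids = highconf$n_pmids
  ) |> dplyr::arrange(.data$from, .data$to)
  if (!all(edges$from %in% nodes$id) || !all(edges$to %in% nodes$id)) {
    stop("edge references unknown node", call. = FALSE)
  }
  structure(list(nodes = nodes, edges = edges), class = "coreg_network")
}

#' Collapse a site-level network to protein level
#'
#' Merges PsOP nodes of the same protein into one node; parallel edges of
#' the same sign between a target site and a protein collapse to the edge
#' with the smallest FET p.
#'
#' @param net A [build_network()] result.
#' @return A `coreg_network` whose PsOP node ids are gene symbols.
#' @export
collapse_to_protein <- function(net) {
  map <- ifelse(net$nodes$node_class == "psop", net$nodes$gene_symbol,
                net$nodes$id)
  names(map) <- net$nodes$id
  nodes <- net$nodes |>
    dplyr::mutate(id = unname(map[.data$id])) |>
    dplyr::group_by(.data$id, .data$gene_symbol, .data$node_class) |>
    dplyr::summarise(
      residue = NA_character_, position = NA_integer_,
      roles = paste(sort(unique(unlist(strsplit(.data$roles, ";",
                                                fixed = TRUE)))),
                    collapse = ";"),
      .groups = "drop") |>
    dplyr::arrange(.data$node_class == "psop", .data$id)
  edges <- net$edges |>
    dplyr::mutate(to = unname(map[.data$to])) |>
    dplyr::group_by(.data$from, .data$to, .data$sign) |>
    dplyr::slice_min(.data$fet_p, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$from, .data$to)
  structure(list(nodes = nodes, edges = edges), class = "coreg_network")
}

#' Write a co-regulation network to standard formats
#'
#' `"graphml"` writes a single GraphML file with typed node/edge attributes
#' (via igraph). `"sif"` writes a simple-interaction-format file with
#' relation tokens `coreg_pos` / `coreg_neg` plus sidecar node and edge
#' attribute TSVs. `"node_edge_tsv"` writes the node and edge tables as TSV.
#' Output is byte-stable for identical input (node and edge order is
#' sorted upstream; no timestamps are written).
#'
#' @param net A [build_network()] result.
#' @param format `"graphml"`, `"sif"`, or `"node_edge_tsv"`.
#' @param path Output path: a file path for `"graphml"`, a base path
#'   (extension added) for the other formats.
#' @return Character vector of files written, invisibly.
#' @export
write_network <- function(net, format = c("graphml", "sif", "node_edge_tsv"),
                          path) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- as_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  base <- sub("\\.(sif|tsv)$", "", path)
  nodes_f <- paste0(base, "_nodes.tsv")
  edges_f <- paste0(base, "_edges.tsv")
  readr::write_tsv(net$nodes, nodes_f, progress = FALSE)
  if (format == "sif") {
    sif_f <- paste0(base, ".sif")
    rel <- ifelse(net$edges$sign == "positive", "coreg_pos", "coreg_neg")
    lines <- paste(net$edges$from, rel, net$edges$to)
    writeLines(lines, sif_f)
    readr::write_tsv(net$edges, edges_f, progress = FALSE)
    return(invisible(c(sif_f, nodes_f, edges_f)))
  }
  readr::write_tsv(net$edges, edges_f, progress = FALSE)
  invisible(c(nodes_f, edges_f))
}

#' Convert a co-regulation network to an igraph object
#'
#' @param net A [build_network()] result.
#' @return A directed igraph graph (edges run target site -> PsOP) with the
#'   node and edge attributes of `net`.
#' @export
as_igraph <- function(net) {
  nodes <- as.data.frame(net$nodes)
  nodes$position <- ifelse(is.na(nodes$position), -1L, nodes$position)
  nodes$residue <- ifelse(is.na(nodes$residue), "", nodes$residue)
  igraph::graph_from_data_frame(as.data.frame(net$edges), directed = TRUE,
                                vertices = nodes)
}
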