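#' Render a phosphosite key
#'
#' Phosphosites are identified throughout the package by the rendered key
#' `"SYMBOL_R###"` (e.g. `"MELK_S356"`): HGNC gene symbol, residue letter
#' (S, T or Y) and 1-based position on the canonical protein sequence.
#'
#' @param gene_symbol Character vector of (already normalized) gene symbols.
#' @param residue Character vector of residue letters, each one of S, T, Y.
#' @param position Integer vector of 1-based canonical positions (>= 1).
#' @return Character vector of rendered site keys.
#' @examples
#' site_key("MELK", "S", 356)
#' @export
site_key <- function(gene_symbol, residue, position) {
  stopifnot(length(gene_symbol) == length(residue),
            length(residue) == length(position))
  if (any(is.na(gene_symbol) | !nzchar(gene_symbol))) {
    stop("gene_symbol must be non-empty", call. = FALSE)
  }
  if (!all(residue %in% c("S", "T", "Y"))) {
    stop("residue must be one of S, T, Y", call. = FALSE)
  }
  position <- as.integer(position)
  if (any(is.na(position) | position < 1L)) {
    stop("position must be a positive integer", call. = FALSE)
  }
  paste0(gene_symbol, "_", residue, position)
}

#' Parse rendered site keys back into their components
#'
#' @param key Character vector of keys of the form `"SYMBOL_R###"`.
#' @return A tibble with columns `site`, `gene_symbol`, `residue`, `position`.
#' @examples
#' parse_site_key(c("MELK_S356", "MKI67_T2085"))
#' @export
parse_site_key <- function(key) {
  m <- regmatches(key, regexec("^(.+)_([STY])([0-9]+)$", key))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) {
    stop("malformed site key(s): ", paste(key[bad], collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    site = key,
    gene_symbol = vapply(m, `[`, character(1), 2L),
    residue = vapply(m, `[`, character(1), 3L),
    position = as.integer(vapply(m, `[`, character(1), 4L))
  )
}

# unique experimental-comparison identifier (condition level, the atomic
# comparison unit; a dataset may contain several conditions)
condition_key <- function(pmid, dataset_id, condition_id) {
  paste(pmid, dataset_id, condition_id, sep = "|")
}

# dataset-level identifier used for detection-frequency deduplication
dataset_key <- function(pmid, dataset_id) {
  paste(pmid, dataset_id, sep = "|")
}

# run code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# numeric parser that reports the offending data row (1-based, excluding header)
parse_numeric_col <- function(x, col) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & nzchar(x) & is.na(out))
  if (length(bad)) {
    stop(sprintf("column '%s': unparseable value '%s' at data row %d",
                 col, x[bad[1]], bad[1]), call. = FALSE)
  }
  out
}
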