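# shared fixtures and independent oracles for the test suite

toy_path <- function(f) {
  p <- system.file("extdata", f, package = "phoscoreg")
  if (!nzchar(p)) stop("missing bundled fixture: ", f)
  p
}

toy_resources <- function() {
  list(kinase_substrate = toy_path("toy_kinase_substrate.tsv"),
       predicted_kinase_site = toy_path("toy_predicted_kinase_site.tsv"),
       interaction = toy_path("toy_interaction.tsv"),
       kinase_list = toy_path("toy_kinase_list.tsv"),
       phosphatase_list = toy_path("toy_phosphatase_list.tsv"))
}

toy_config <- function(outdir) {
  pipeline_config(toy_path("toy_compendium.tsv"), outdir = outdir,
                  target = "MELK", resources = toy_resources(),
                  alias_map = toy_path("toy_alias_map.tsv"),
                  domains = toy_path("toy_domains.tsv"),
                  log_level = "quiet")
}

# build a condition-call table from a compact (condition, site, direction)
# description; one pmid per condition unless given explicitly
make_calls <- function(cond, site, direction, pmid = NULL) {
  meta <- parse_site_key(site)
  tibble::tibble(
    pmid = pmid %||% paste0("PMID_", cond),
    dataset_id = "DS1",
    condition_id = cond,
    site = site,
    gene_symbol = meta$gene_symbol,
    residue = meta$residue,
    position = meta$position,
    direction = direction,
    condition_key = paste(pmid %||% paste0("PMID_", cond), "DS1", cond,
                          sep = "|"),
    dataset_key = paste(pmid %||% paste0("PMID_", cond), "DS1", sep = "|"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent two-sided FET oracle: exhaustive hypergeometric enumeration
# with choose() arithmetic (exact integers for the margins exercised here)
fet_enum_oracle <- function(a, b, c, d) {
  if (a + b + c + d == 0) return(NA_real_)
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  lo <- max(0, r1 + c1 - n)
  hi <- min(r1, c1)
  w <- vapply(lo:hi, function(x) choose(c1, x) * choose(n - c1, r1 - x),
              numeric(1))
  pr <- w / choose(n, r1)
  pobs <- (choose(c1, a) * choose(n - c1, r1 - a)) / choose(n, r1)
  sum(pr[pr <= pobs * (1 + 1e-12)])
}

# naive per-condition loop for joint event counting (oracle for pair_counts)
pair_counts_naive <- function(site_a, site_b, calls) {
  conds <- unique(calls$condition_key)
  out <- c(n_uu = 0L, n_ud = 0L, n_du = 0L, n_dd = 0L)
  for (ck in conds) {
    da <- calls$direction[calls$condition_key == ck & calls$site == site_a]
    db <- calls$direction[calls$condition_key == ck & calls$site == site_b]
    if (length(da) != 1 || length(db) != 1) next
    if (!da %in% c("Up", "Down") || !db %in% c("Up", "Down")) next
    lab <- paste0("n_", tolower(substr(da, 1, 1)), tolower(substr(db, 1, 1)))
    out[lab] <- out[lab] + 1L
  }
  out
}

# random direction-call table over k conditions for two or more sites
random_calls <- function(sites, k, seed) {
  set.seed(seed)
  grid <- expand.grid(cond = sprintf("C%02d", seq_len(k)), site = sites,
                      stringsAsFactors = FALSE)
  keep <- runif(nrow(grid)) < 0.85
  grid <- grid[keep, , drop = FALSE]
  dirs <- sample(c("Up", "Down", "Unchanged"), nrow(grid), replace = TRUE)
  make_calls(grid$cond, grid$site, dirs)
}

run_toy_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      out <- file.path(tempdir(), "toy_pipeline_out")
      cache <<- suppressMessages(suppressWarnings(
        run_pipeline(toy_config(out))))
    }
    cache
  }
})
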