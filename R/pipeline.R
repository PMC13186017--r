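#' Configuration for a full pipeline run
#'
#' Bundles input paths, the target protein, thresholds and output location
#' for [run_pipeline()].
#'
#' @param compendium Path to the observation TSV (mixed `dataset_kind`
#'   column, or all-differential).
#' @param outdir Output directory (created if absent).
#' @param target Target protein gene symbol.
#' @param resources Named list of annotation resource paths; recognized
#'   names: `kinase_substrate`, `predicted_kinase_site`, `interaction`,
#'   `kinase_list`, `phosphatase_list`. `NULL` skips role annotation.
#' @param alias_map Optional path to a two-column alias TSV.
#' @param domains Optional path to a domain annotation TSV.
#' @param filter A [filter_config()].
#' @param highconf A [highconf_config()].
#' @param k,min_count Major-site selection parameters (see
#'   [select_major_sites()]).
#' @param sites Optional explicit character vector of target site keys;
#'   overrides selection.
#' @param seed Integer seed for any sampling-based diagnostics (the analysis
#'   path itself is seed-free).
#' @param log_level `"info"` (stage messages) or `"quiet"`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(compendium, outdir, target = "MELK",
                            resources = NULL, alias_map = NULL,
                            domains = NULL, filter = filter_config(),
                            highconf = highconf_config(), k = 3,
                            min_count = 2, sites = NULL, seed = 1L,
                            log_level = c("info", "quiet")) {
  structure(list(compendium = compendium, outdir = outdir, target = target,
                 resources = resources, alias_map = alias_map,
                 domains = domains, filter = filter, highconf = highconf,
                 k = k, min_count = min_count, sites = sites,
                 seed = as.integer(seed),
                 log_level = match.arg(log_level)),
            class = "pipeline_config")
}

#' Run the full co-regulation analysis pipeline
#'
#' Executes the stages in order — ingest (read, normalize, Class-I filter,
#' direction-call, conflict-resolve), sites (detection frequency, major-site
#' selection, lollipop table), cooccur (within-protein co-occurrence),
#' coreg (PsOP scan, Venn partitions), annotate (role stratification) and
#' network (signed graph export) — writing stage TSVs, GraphML/SIF network
#' files, a plain-text log and a JSON manifest of row counts and parameters
#' to `config$outdir`. The run is deterministic given identical inputs and
#' configuration: outputs carry no timestamps and all tables are sorted.
#' Any stage error aborts the run naming the stage.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the principal in-memory artifacts:
#'   `observations`, `calls`, `freqs`, `major_sites`, `cooccurrence`,
#'   `scan`, `highconf`, `roles`, `network`, `manifest`, `outdir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  note <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    if (config$log_level == "info") message(line)
  }
  stages <- list()
  stage <- function(name, rows_in, rows_out, params = NULL) {
    stages[[name]] <<- list(rows_in = rows_in, rows_out = rows_out,
                            params = params)
    note(sprintf("stage %s: rows_in=%d rows_out=%d", name, rows_in, rows_out))
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage %s failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  out_path <- function(f) file.path(config$outdir, f)
  outputs <- character()
  emit <- function(tab, f) {
    readr::write_tsv(tab, out_path(f), progress = FALSE)
    outputs <<- c(outputs, f)
  }

  # -- ingest -----------------------------------------------------------
  ing <- run_stage("ingest", {
    amap <- if (!is.null(config$alias_map)) read_alias_map(config$alias_map)
    obs <- read_observations(config$compendium, "mixed", alias_map = amap,
                             config = config$filter)
    n_raw <- nrow(obs)
    obs <- suppressMessages(filter_class1(obs, config$filter))
    obs <- add_direction_calls(obs, config$filter)
    calls <- resolve_conflicts(obs)
    list(obs = obs, calls = calls, n_raw = n_raw, amap = amap)
  })
  stage("ingest", ing$n_raw, nrow(ing$obs),
        list(min_loc_prob = config$filter$min_loc_prob,
             min_ascore = config$filter$min_ascore,
             up_fc = config$filter$up_fc, down_fc = config$filter$down_fc,
             alpha = config$filter$alpha))
  emit(ing$obs, "class1_observations.tsv")
  emit(ing$calls, "condition_calls.tsv")

  # -- sites ------------------------------------------------------------
  st <- run_stage("sites", {
    profile_obs <- ing$obs[ing$obs$dataset_kind == "profile", , drop = FALSE]
    freqs <- detection_frequency(ing$calls, profile_obs, config$target)
    if (!is.null(config$sites)) {
      note("stage sites: explicit site list supplied, selection skipped")
      major <- config$sites
    } else {
      major <- select_major_sites(freqs, config$k, config$min_count)
    }
    doms <- if (!is.null(config$domains)) read_domains(config$domains)
    lolli <- lollipop_table(freqs, doms, major)
    list(freqs = freqs, major = major, lolli = lolli)
  })
  stage("sites", nrow(st$freqs), length(st$major),
        list(k = config$k, min_count = config$min_count,
             explicit = !is.null(config$sites)))
  emit(st$freqs, "site_frequencies.tsv")
  emit(st$lolli, "lollipop.tsv")
  note(paste("major sites:", paste(st$major, collapse = ", ")))

  # -- cooccur ----------------------------------------------------------
  cooc <- run_stage("cooccur", {
    own <- sort(unique(ing$calls$site[ing$calls$gene_symbol ==
                                        config$target]))
    if (length(own) >= 2L) cooccurrence_matrix(own, ing$calls) else NULL
  })
  if (!is.null(cooc)) {
    stage("cooccur", length(cooc$sites), nrow(cooc$pairs))
    readr::write_tsv(cooc$pairs, out_path("cooccurrence_long.tsv"),
                     progress = FALSE)
    sq <- tibble::as_tibble(cooc$score, rownames = "site")
    readr::write_tsv(sq, out_path("cooccurrence_matrix.tsv"),
                     progress = FALSE)
    outputs <- c(outputs, "cooccurrence_long.tsv", "cooccurrence_matrix.tsv")
  } else {
    stage("cooccur", 0L, 0L)
    note("stage cooccur: fewer than 2 target sites with calls, skipped")
  }

  # -- coreg ------------------------------------------------------------
  cr <- run_stage("coreg", {
    scan <- coregulation_scan(ing$calls, config$target, st$major,
                              config$highconf)
    hc <- scan[scan$sign != "none", , drop = FALSE]
    venns <- list()
    if (length(st$major) == 3L) {
      for (sg in c("positive", "negative")) {
        sets <- lapply(st$major, function(s) hc$o_site[hc$m_site == s &
                                                         hc$sign == sg])
        names(sets) <- st$major
        venns[[sg]] <- venn_partition(sets)
      }
    }
    list(scan = scan, hc = hc, venns = venns)
  })
  stage("coreg", nrow(cr$scan), nrow(cr$hc),
        list(alpha = config$highconf$alpha,
             min_ratio = config$highconf$min_ratio,
             min_conditions = config$highconf$min_conditions,
             min_pmids = config$highconf$min_pmids))
  emit(cr$scan, "coregulation.tsv")
  for (sg in names(cr$venns)) {
    f <- paste0("venn_", sg, ".tsv")
    write_venn(cr$venns[[sg]], out_path(f))
    outputs <- c(outputs, f)
  }

  # -- annotate ---------------------------------------------------------
  roles <- run_stage("annotation", {
    if (is.null(config$resources) || length(config$resources) == 0L) {
      note("stage annotation: no resources configured, skipped")
      NULL
    } else {
      res <- lapply(names(config$resources), function(kind) {
        load_resource(config$resources[[kind]], kind, alias_map = ing$amap)
      })
      assign_roles(cr$hc, config$target, res)
    }
  })
  if (!is.null(roles)) {
    stage("annotation", nrow(cr$hc), nrow(roles))
    emit(roles, "roles.tsv")
  } else {
    stage("annotation", nrow(cr$hc), 0L)
  }

  # -- network ----------------------------------------------------------
  net <- run_stage("network", {
    n <- build_network(cr$hc, roles, target_sites = st$major)
    write_network(n, "graphml", out_path("network.graphml"))
    write_network(n, "sif", out_path("network.sif"))
    n
  })
  stage("network", nrow(cr$hc), nrow(net$edges))
  outputs <- c(outputs, "network.graphml", "network.sif",
               "network_nodes.tsv", "network_edges.tsv")

  manifest <- list(
    tool = "phoscoreg",
    target = config$target,
    major_sites = as.list(st$major),
    seed = config$seed,
    stages = stages,
    outputs = as.list(sort(unique(outputs)))
  )
  jsonlite::write_json(manifest, out_path("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, out_path("run.log"))

  invisible(list(observations = ing$obs, calls = ing$calls,
                 freqs = st$freqs, major_sites = st$major,
                 cooccurrence = cooc, scan = cr$scan, highconf = cr$hc,
                 roles = roles, network = net, manifest = manifest,
                 outdir = config$outdir))
}
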