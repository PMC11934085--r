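#' Deterministic config hash
#'
#' 32-bit polynomial hash of the deparsed configuration, used to stamp
#' every output file so a report can be traced to the exact run settings.
#'
#' @param x any R object.
#' @return An 8-character lowercase hex string.
#' @export
config_hash <- function(x) {
  s <- paste(deparse(x, control = c("keepNA", "niceNames")), collapse = "")
  sprintf("%08x", as.integer(stable_hash_int(s)))
}

#' Read a pipeline run configuration
#'
#' YAML with keys: `tables` (list of `{path, marker}`), `sample_metadata`,
#' `otu_metadata`, `diet_records` (paths), `subsets` (list of subset-spec
#' fields), `ensemble_groups` (list of marker-name vectors; markers within a
#' group are ensembled, groups are concatenated), `min_prevalence`,
#' `index_scope` (`subset` or `global`), `inference` (fields of
#' [cooc_config()]), `keystone_k`, `output_dir`, `seed`.
#'
#' @param path YAML file path.
#' @return The validated config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a config list.
#' @export
validate_run_config <- function(cfg) {
  for (key in c("tables", "sample_metadata", "subsets", "output_dir"))
    if (is.null(cfg[[key]])) stop("config missing key: ", key)
  for (t in cfg$tables)
    if (!file.exists(t$path)) stop("OTU table not found: ", t$path)
  if (!file.exists(cfg$sample_metadata))
    stop("sample metadata not found: ", cfg$sample_metadata)
  if (!is.null(cfg$diet_records) && !file.exists(cfg$diet_records))
    stop("diet records not found: ", cfg$diet_records)
  if (!is.null(cfg$otu_metadata) && !file.exists(cfg$otu_metadata))
    stop("OTU metadata not found: ", cfg$otu_metadata)
  if (is.null(cfg$seed)) cfg$seed <- 1
  if (is.null(cfg$min_prevalence)) cfg$min_prevalence <- 0.25
  if (is.null(cfg$index_scope)) cfg$index_scope <- "subset"
  if (!cfg$index_scope %in% c("subset", "global"))
    stop("index_scope must be 'subset' or 'global'")
  if (is.null(cfg$keystone_k)) cfg$keystone_k <- 10
  cfg
}

build_subset_specs <- function(subsets) {
  lapply(subsets, function(s)
    subset_spec(name = s$name, kind = s$kind,
                months = s$months,
                threshold_m = s$threshold_m,
                side = if (is.null(s$side)) "nearshore" else s$side))
}

# index one subset: filter each marker table, index it, ensemble within
# groups, concatenate groups
index_subset <- function(tables, groups, min_prevalence) {
  filtered <- lapply(tables, prevalence_filter,
                     min_prevalence = min_prevalence)
  group_tabs <- lapply(groups, function(markers) {
    idx <- lapply(filtered[markers], compute_edna_index)
    Reduce(ensemble_index, idx)
  })
  concat_index_tables(group_tabs)
}

#' Run the full analysis pipeline
#'
#' For each configured subset: restrict samples, prevalence-filter each
#' marker table, compute eDNA indices (within the subset by default),
#' ensemble/concatenate markers, infer the co-occurrence network, build the
#' food web from the diet records, assign trophic levels, compute topology
#' reports for both graphs, match trophic interactions, and rank keystones.
#' Then compares networks across subsets. All outputs (edge tables, GraphML,
#' JSON reports, log) go to `output_dir`; a rerun with the same config is
#' byte-identical.
#'
#' @param cfg config list (see [read_run_config()]) or a YAML path.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with per-subset results and the comparison
#'   report.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  cfg <- validate_run_config(cfg)
  t0 <- proc.time()[["elapsed"]]
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg[setdiff(names(cfg), "output_dir")])
  log_path <- file.path(cfg$output_dir, "pipeline.log")
  log_lines <- character()
  say <- function(fmt, ...) {
    msg <- sprintf(paste0("[%7.1fs] ", fmt),
                   proc.time()[["elapsed"]] - t0, ...)
    log_lines <<- c(log_lines, msg)
    if (!quiet) message(msg)
  }
  say("run config hash %s, seed %d", hash, cfg$seed)

  tables <- lapply(cfg$tables, function(t) read_otu_table(t$path, t$marker))
  names(tables) <- vapply(cfg$tables, `[[`, "", "marker")
  meta <- read_sample_metadata(cfg$sample_metadata)
  diet <- if (!is.null(cfg$diet_records)) read_diet_records(cfg$diet_records)
          else NULL
  ometa <- if (!is.null(cfg$otu_metadata)) read_otu_metadata(cfg$otu_metadata)
           else NULL
  groups <- if (!is.null(cfg$ensemble_groups)) cfg$ensemble_groups
            else as.list(names(tables))
  specs <- build_subset_specs(cfg$subsets)
  inf_cfg_fields <- if (!is.null(cfg$inference)) cfg$inference else list()
  subsets <- list()
  for (spec in specs) {
    say("subset '%s': subsetting and indexing", spec$name)
    sub_tabs <- lapply(tables, subset_samples, meta = meta, spec = spec)
    index <- if (cfg$index_scope == "global") {
      full <- index_subset(tables, groups, cfg$min_prevalence)
      keep <- intersect(colnames(full$values),
                        sample_ids(sub_tabs[[1]]))
      new_index_table(full$values[, keep, drop = FALSE],
                      full$comp[, keep, drop = FALSE], full$provenance)
    } else index_subset(sub_tabs, groups, cfg$min_prevalence)
    inf_cfg <- do.call(cooc_config, c(
      inf_cfg_fields[setdiff(names(inf_cfg_fields), "seed")],
      list(seed = pair_seed(cfg$seed, "subset", spec$name))))
    say("subset '%s': inferring network over %d OTUs x %d samples",
        spec$name, nrow(index$values), ncol(index$values))
    net <- infer_network(index, inf_cfg)
    say("subset '%s': %d edges from %d candidates",
        spec$name, nrow(net$edges), net$n_candidates)
    web <- NULL; tmatch <- NULL
    if (!is.null(diet)) {
      web <- suppressWarnings(build_metaweb(diet, rownames(index$values)))
      if (!is.null(ometa)) web <- assign_trophic_levels(web, ometa)
      tmatch <- trophic_match(net, web)
    }
    cent <- centralities(net)
    subsets[[spec$name]] <- list(
      spec = spec, index = index, network = net, web = web,
      trophic = tmatch,
      topology_network = topology_report(net),
      topology_web = if (!is.null(web)) topology_report(web) else NULL,
      keystones = keystones(cent, k = cfg$keystone_k))
    # outputs
    pre <- file.path(cfg$output_dir, spec$name)
    write_edge_table(net, paste0(pre, "_edges.tsv"))
    write_graphml(net, paste0(pre, "_network.graphml"))
    if (!is.null(web)) {
      write_food_web(web, paste0(pre, "_foodweb.tsv"))
      write_graphml(web, paste0(pre, "_foodweb.graphml"))
    }
  }
  say("comparing %d subsets", length(subsets))
  comp <- if (length(subsets) >= 2) comparison_report(
    networks = lapply(subsets, `[[`, "network"),
    webs = if (!is.null(diet)) lapply(subsets, `[[`, "web") else NULL,
    indices = lapply(subsets, `[[`, "index"),
    k = cfg$keystone_k) else NULL
  report <- list(
    config_hash = hash,
    seed = cfg$seed,
    subsets = lapply(subsets, function(s) list(
      n_samples = ncol(s$index$values),
      n_otus = nrow(s$index$values),
      topology_network = topology_report_json(s$topology_network),
      topology_web = if (!is.null(s$topology_web))
        topology_report_json(s$topology_web) else NULL,
      trophic = if (!is.null(s$trophic))
        s$trophic[c("n_trophic", "fraction", "percent")] else NULL,
      keystones = s$keystones$otu_id)),
    comparison = if (!is.null(comp)) unclass(comp) else NULL)
  jsonlite::write_json(report, file.path(cfg$output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("wrote %s", file.path(cfg$output_dir, "report.json"))
  writeLines(c(sprintf("# config %s", hash), log_lines), log_path)
  invisible(list(subsets = subsets, comparison = comp, report = report,
                 config_hash = hash))
}
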