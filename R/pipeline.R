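# End-to-end orchestration: ingest -> coverage -> annotate -> enzymes ->
# infer -> summarise -> capacity, with a hashed run manifest so reruns
# are auditable.

#' Default run configuration
#'
#' Returns the full default configuration; supplied values override
#' defaults field by field. All defaults are recorded in the run
#' manifest so a run's effective parameters are auditable.
#'
#' @param ... Named overrides (see fields in the returned list).
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    # inputs: either a synthetic spec or file paths
    synthetic = list(seed = 1, growth_rate = 1.0),
    proteome = NULL,            # path to proteome TSV
    bonds = NULL,               # named list of bond-table paths
    cysteines = NULL,           # path to cysteine-position table
    locations = NULL,           # path to location table
    condition_label = NULL, growth_rate = NULL,
    # constants and thresholds
    density = 3e6, compartment_fraction = 0.2,
    min_sources = 1,
    accumulation_threshold = 0.005, doubling_slack = 0.05,
    f_futile = 1/3, f_success = 1/3, f_reduce = 1/3,
    capacity_categories = c("cat1", "cat2", "cat3"),
    out_dir = "dsbfold_run"
  )
  overrides <- list(...)
  if (length(overrides) == 1 && is.list(overrides[[1]]) &&
      is.null(names(overrides))) {
    overrides <- overrides[[1]]
  }
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  if (cfg$accumulation_threshold <= 0 || cfg$accumulation_threshold >= 1 ||
      cfg$doubling_slack <= 0 || cfg$doubling_slack >= 1) {
    stop("thresholds must lie in (0, 1)")
  }
  paths <- unlist(cfg[c("proteome", "bonds", "cysteines", "locations")])
  if (length(paths)) {
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      stop("input path(s) not found: ", paste(missing, collapse = ", "))
    }
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file with `run_config` fields.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configs requires the yaml package")
  }
  run_config(yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Executes the stage sequence ingest -> coverage -> annotate -> enzymes
#' -> infer -> summarise -> capacity on either synthetic or file inputs,
#' writes each stage's table under `out_dir`, and finishes with a
#' manifest recording the effective configuration and the MD5 hash of
#' every output. Identical configuration and inputs give identical
#' manifests.
#'
#' @param config A `run_config` (or a list of overrides).
#' @return Invisibly, a list with the stage outputs and the manifest
#'   path.
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  emit <- function(obj, name, writer) {
    path <- file.path(config$out_dir, name)
    writer(obj, path)
    outputs <<- c(outputs, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline halted in stage '%s': %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # -- ingest ----------------------------------------------------------
  ing <- stage("ingest", {
    if (!is.null(config$proteome)) {
      proteome <- read_proteome_table(config$proteome,
                                      condition_label = config$condition_label %||% "run",
                                      growth_rate = config$growth_rate)
      bonds <- Map(function(path, src) read_bond_table(path, source = src),
                   config$bonds, names(config$bonds))
      cys <- read.delim(config$cysteines, stringsAsFactors = FALSE)
      loc <- read.delim(config$locations, stringsAsFactors = FALSE)
      list(proteome = proteome, bonds = bonds, cys = cys, loc = loc)
    } else {
      spec <- do.call(synthetic_spec, config$synthetic)
      proteome <- generate_proteome(spec)
      ann <- generate_disulfide_annotations(spec, proteome)
      list(proteome = proteome, bonds = ann$bond_tables,
           cys = ann$cys_table, loc = ann$location_table)
    }
  })

  # -- coverage --------------------------------------------------------
  cov <- stage("coverage", coverage_report(ing$proteome, config$density))
  emit(cov, "coverage.tsv", write_coverage_report)
  if (!cov$passes) {
    warning("proteome coverage below 50%; downstream results are not trustworthy")
  }

  # -- annotate --------------------------------------------------------
  ann <- stage("annotate", {
    records <- merge_bond_sources(ing$bonds)
    records <- confidence_filter(records, config$min_sources)
    profiles <- disulfide_profiles(records, ing$cys, ing$loc)
    peri <- periplasmic_subset(profiles)
    demand <- suppressMessages(folding_demand(peri, ing$proteome))
    list(records = records, profiles = peri, demand = demand)
  })
  emit(ann$demand, "category_summary.tsv", write_category_summary)

  # -- enzymes ---------------------------------------------------------
  enz <- stage("enzymes", extract_dsb_levels(ing$proteome))
  emit(enz, "dsb_levels.tsv", function(o, p) {
    write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE)
  })

  # -- infer -----------------------------------------------------------
  condition <- stage("infer", {
    folding_condition(ann$demand, enz, ing$proteome$growth_rate,
                      total_protein = sum(ing$proteome$abundances),
                      compartment_fraction = config$compartment_fraction)
  })
  params <- stage("infer", infer_minimal_rates(
    condition,
    accumulation_threshold = config$accumulation_threshold,
    doubling_slack = config$doubling_slack,
    f_futile = config$f_futile, f_success = config$f_success,
    f_reduce = config$f_reduce))
  rates <- stage("infer", rate_table_row(params, condition))
  emit(rates, "rates.tsv", function(o, p) write_rate_table(o, p, summary = FALSE))

  # -- capacity --------------------------------------------------------
  cap <- stage("capacity", capacity_table(
    list(condition), list(params),
    categories = config$capacity_categories,
    threshold = config$accumulation_threshold))
  emit(cap, "capacity.tsv", write_capacity_table)

  # -- manifest --------------------------------------------------------
  manifest_path <- file.path(config$out_dir, "manifest.txt")
  cfg_lines <- vapply(names(config), function(nm) {
    sprintf("config.%s = %s", nm,
            paste(format(unlist(config[[nm]])), collapse = ", "))
  }, "")
  hashes <- tools::md5sum(outputs)
  manifest <- c("# dsbfold run manifest", cfg_lines, "",
                sprintf("%s  %s", hashes, basename(names(hashes))))
  writeLines(manifest, manifest_path)
  invisible(list(proteome = ing$proteome, coverage = cov, demand = ann$demand,
                 enzymes = enz, condition = condition, params = params,
                 rates = rates, capacity = cap, manifest = manifest_path,
                 outputs = outputs))
}
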