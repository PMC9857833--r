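# File-to-file workflow drivers wiring the stages together:
# simulate -> phenotype/bulks -> filter -> ED association -> regions,
# plus the expression classification stage. Each run writes a
# machine-readable run-metadata JSON (parameters, seed, input checksums)
# and logs progress with message() so tabular outputs never carry log text.

#' Default run configuration
#'
#' A nested list understood by [run_simulate()], [run_associate()],
#' [run_expression()] and [run_pipeline()]. Override entries directly or
#' via a YAML file ([read_run_config()]).
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed governing every random step.
#' @return A nested configuration list.
#' @export
default_run_config <- function(out_dir = "bsr_out", seed = 1L) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    sim = simulation_config(rng_seed = as.integer(seed)),
    filter = filter_config(),
    ed = list(k = 5, mode = "sliding_window", window_size_bp = 1e6,
              step_bp = 1e5, merge_gap_bp = 1e6, center_stat = "median",
              multiplier = 5, include_indels = FALSE),
    expression = list(fold = 2, min_expr = 0.1),
    paths = list(variants = NULL, genes = NULL, counts = NULL,
                 high_sample = NULL, low_sample = NULL)
  )
}

#' Read a run configuration from YAML
#'
#' Entries present in the file override the defaults; everything else keeps
#' its default. The `sim` block is re-validated through
#' [simulation_config()].
#'
#' @param path Path to a YAML file.
#' @param seed Seed used when the file does not set one.
#' @return A run-configuration list.
#' @export
read_run_config <- function(path, seed = 1L) {
  raw <- yaml::read_yaml(path)
  cfg <- default_run_config(seed = raw$seed %||% seed)
  if (!is.null(raw$out_dir)) cfg$out_dir <- raw$out_dir
  if (!is.null(raw$sim)) {
    cfg$sim <- do.call(simulation_config,
                       modifyList(list(rng_seed = cfg$seed), raw$sim))
  }
  if (!is.null(raw$filter)) {
    cfg$filter <- do.call(filter_config, raw$filter)
  }
  for (block in c("ed", "expression", "paths")) {
    if (!is.null(raw[[block]])) {
      cfg[[block]] <- modifyList(cfg[[block]], raw[[block]])
    }
  }
  cfg
}

.ensure_dir <- function(path) {
  if (!dir.exists(path)) {
    dir.create(path, recursive = TRUE)
    message("created output directory ", path)
  }
  path
}

.write_run_metadata <- function(config, out_dir, stage, inputs = character()) {
  checksums <- if (length(inputs) > 0) {
    as.list(tools::md5sum(inputs))
  } else {
    NULL
  }
  meta <- list(
    stage = stage,
    seed = config$seed,
    parameters = config[setdiff(names(config), "paths")],
    input_checksums = checksums,
    package_version = as.character(utils::packageVersion("edbsa"))
  )
  path <- file.path(out_dir, paste0("run_metadata_", stage, ".json"))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE,
                       force = TRUE, digits = NA)
  invisible(path)
}

#' Simulation stage: population, bulks, pooled counts, truth
#'
#' Writes `phenotypes.tsv`, `bulks.tsv`, `variants.tsv` and `truth.json`
#' (QTL location, effect and seed, for recovery scoring) into the output
#' directory.
#'
#' @param config A run-configuration list ([default_run_config()]).
#' @return Invisibly, a list with the in-memory phenotypes, truth, design,
#'   variants and the written paths.
#' @export
run_simulate <- function(config = default_run_config()) {
  out <- .ensure_dir(config$out_dir)
  message("simulate: seed ", config$seed)
  sim_cfg <- config$sim
  if (is.null(sim_cfg$rng_seed)) sim_cfg$rng_seed <- config$seed
  pop <- simulate_population(sim_cfg)
  design <- select_bulks(pop$phenotypes, sim_cfg$n_per_bulk)
  variants <- simulate_bulk_counts(pop$truth, design)

  paths <- list(
    phenotypes = file.path(out, "phenotypes.tsv"),
    bulks = file.path(out, "bulks.tsv"),
    variants = file.path(out, "variants.tsv"),
    truth = file.path(out, "truth.json")
  )
  readr::write_tsv(pop$phenotypes, paths$phenotypes, progress = FALSE)
  write_bulks_tsv(design, pop$phenotypes, paths$bulks)
  write_variants_tsv(variants, paths$variants)
  jsonlite::write_json(
    list(qtl = pop$truth$qtl[c("chrom", "pos_bp", "effect")],
         seed = sim_cfg$rng_seed,
         n_markers = nrow(pop$truth$markers),
         population_type = sim_cfg$population_type),
    paths$truth, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  .write_run_metadata(config, out, "simulate")
  message("simulate: ", nrow(pop$phenotypes), " plants, ",
          nrow(variants), " loci written to ", out)
  invisible(list(phenotypes = pop$phenotypes, truth = pop$truth,
                 design = design, variants = variants, paths = paths))
}

#' Association stage: filter, ED profile, threshold, regions
#'
#' Reads the variant table (`config$paths$variants`, or the simulation
#' stage's `variants.tsv` in `out_dir`), optional gene models
#' (`config$paths$genes`, GFF3), filters, scores, fits the profile,
#' computes the threshold and extracts annotated candidate regions. Writes
#' `profile.tsv`, `threshold.tsv`, `regions.tsv`, `regions.bed` and
#' `filter_report.tsv`.
#'
#' @param config A run-configuration list.
#' @return Invisibly, a list with profile, threshold, regions, the filter
#'   report and retained loci.
#' @export
run_associate <- function(config = default_run_config()) {
  out <- .ensure_dir(config$out_dir)
  vpath <- config$paths$variants %||% file.path(out, "variants.tsv")
  if (!file.exists(vpath)) {
    stop("variant input not found: ", vpath, call. = FALSE)
  }
  variants <- read_variants(vpath,
                            high_sample = config$paths$high_sample,
                            low_sample = config$paths$low_sample)
  genes <- if (!is.null(config$paths$genes)) {
    read_gene_models(config$paths$genes)
  }

  fl <- filter_variants(variants, config$filter)
  message("associate: ", fl$report$n_input, " loci in, ",
          fl$report$n_retained, " retained")
  if (fl$report$n_retained == 0) {
    stop("no loci retained after filtering", call. = FALSE)
  }

  ed <- config$ed
  scores <- ed_scores(fl$retained, k = ed$k,
                      include_indels = isTRUE(ed$include_indels))
  if (nrow(scores) == 0) {
    stop("no loci retained after filtering", call. = FALSE)
  }
  profile <- fit_profile(scores, mode = ed$mode,
                         window_size_bp = ed$window_size_bp,
                         step_bp = ed$step_bp)
  thr <- compute_threshold(profile, center_stat = ed$center_stat,
                           multiplier = ed$multiplier)
  regions <- extract_regions(profile, thr, merge_gap_bp = ed$merge_gap_bp)
  regions <- annotate_regions(regions, genes = genes, loci = fl$retained)
  message("associate: threshold ", signif(thr$threshold, 6), ", ",
          nrow(regions), " region(s)")

  write_profile_tsv(profile, file.path(out, "profile.tsv"))
  readr::write_tsv(
    tibble(center_stat = thr$center_stat, center_value = thr$center_value,
           sd = thr$sd, multiplier = thr$multiplier,
           threshold = thr$threshold),
    file.path(out, "threshold.tsv"), progress = FALSE
  )
  write_regions_tsv(regions, file.path(out, "regions.tsv"))
  write_regions_bed(regions, file.path(out, "regions.bed"))
  write_filter_report(fl$report, file.path(out, "filter_report.tsv"))
  .write_run_metadata(config, out, "associate", inputs = vpath)
  invisible(list(profile = profile, threshold = thr, regions = regions,
                 report = fl$report, retained = fl$retained))
}

#' Expression stage: FPKM and fold-change categories
#'
#' Reads a counts TSV (feature_id, length_bp, count_high, count_low) from
#' `config$paths$counts`, classifies expression and writes
#' `expression.tsv` plus `expression_tally.tsv`; the tally is also printed.
#'
#' @param config A run-configuration list.
#' @return Invisibly, the `bsr_expression` result.
#' @export
run_expression <- function(config = default_run_config()) {
  out <- .ensure_dir(config$out_dir)
  cpath <- config$paths$counts
  if (is.null(cpath) || !file.exists(cpath)) {
    stop("expression counts input not found: ",
         cpath %||% "(not configured)", call. = FALSE)
  }
  counts <- readr::read_tsv(cpath, col_types = readr::cols(
    feature_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  if (!"length_bp" %in% names(counts)) {
    stop("counts table must carry a length_bp column", call. = FALSE)
  }
  res <- classify_expression(counts, fold = config$expression$fold,
                             min_expr = config$expression$min_expr)
  readr::write_tsv(res$records, file.path(out, "expression.tsv"),
                   progress = FALSE)
  readr::write_tsv(
    tibble(category = names(res$tally), n = unname(res$tally)),
    file.path(out, "expression_tally.tsv"), progress = FALSE
  )
  .write_run_metadata(config, out, "expression", inputs = cpath)
  print(res)
  invisible(res)
}

#' Run the full pipeline
#'
#' Simulation followed by association on the simulated variant table; the
#' expression stage runs when `config$paths$counts` is set.
#'
#' @param config A run-configuration list.
#' @return Invisibly, a list with the simulate and associate (and possibly
#'   expression) results.
#' @export
run_pipeline <- function(config = default_run_config()) {
  sim <- run_simulate(config)
  config$paths$variants <- config$paths$variants %||% sim$paths$variants
  assoc <- run_associate(config)
  expr <- if (!is.null(config$paths$counts)) run_expression(config)
  invisible(list(simulate = sim, associate = assoc, expression = expr))
}
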