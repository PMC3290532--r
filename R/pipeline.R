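# Pipeline composition: a structured config describes two species'
# synthetic genomes and library parameters plus screening / scanner /
# profiler settings; run_pipeline() ties the stages together and emits a
# reproducibility manifest.

#' Read and validate a pipeline configuration
#'
#' The YAML config carries a `seed`, one or two `species` blocks (name,
#' `genome_size_bp` or `genome_size_pg` + `bp_per_pg`, `n_clones`,
#' `insert_mean`, `insert_sd`, and a list of family blocks realised through
#' [repeat_family()]), a `panel` block (probes as family/sequence pairs or
#' a FASTA path), and optional `thresholds`, `microsat` and `profile`
#' blocks whose entries override the corresponding function defaults.
#'
#' @param path YAML file.
#' @return validated config object of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such config file: %s", path))
  validate_run_config(yaml::read_yaml(path), dir = dirname(path))
}

validate_run_config <- function(cfg, dir = ".") {
  if (is.null(cfg$seed)) abort("config needs a `seed`")
  if (is.null(cfg$species) || length(cfg$species) < 1) {
    abort("config needs at least one `species` block")
  }
  cfg$species <- lapply(cfg$species, function(sp) {
    if (is.null(sp$name)) abort("every species block needs a `name`")
    if (is.null(sp$genome_size_bp)) {
      if (is.null(sp$genome_size_pg)) {
        abort(sprintf("species %s: need `genome_size_bp` or `genome_size_pg`",
                      sp$name))
      }
      sp$genome_size_bp <- pg_to_bp(sp$genome_size_pg,
                                    sp$bp_per_pg %||% 0.978e9)
    }
    if (is.null(sp$n_clones) || sp$n_clones < 0) {
      abort(sprintf("species %s: need non-negative `n_clones`", sp$name))
    }
    sp$insert_mean <- sp$insert_mean %||% 603
    sp$insert_sd <- sp$insert_sd %||% 150
    sp$families <- sp$families %||% list()
    sp
  })
  if (!is.null(cfg$panel) && is.character(cfg$panel)) {
    p <- cfg$panel
    if (!file.exists(p)) p <- file.path(dir, cfg$panel)
    if (!file.exists(p)) abort(sprintf("panel FASTA not found: %s", cfg$panel))
    cfg$panel <- p
  }
  th <- cfg$thresholds %||% list()
  if (!is.null(th$min_identity) &&
      (th$min_identity <= 0.5 || th$min_identity > 1)) {
    abort("thresholds: `min_identity` must lie in (0.5, 1]")
  }
  structure(cfg, class = "run_config")
}

config_families <- function(sp) {
  if (length(sp$families) == 0) {
    return(NULL)
  }
  dplyr::bind_rows(lapply(sp$families, function(f) {
    repeat_family(
      name = f$name, category = f$category, consensus = f$consensus,
      copies = f$copies, units_per_array = f$units_per_array %||% 1L,
      structure = if (!is.null(f$structure)) dplyr::bind_rows(f$structure),
      solo_ltr_fraction = f$solo_ltr_fraction %||% 0,
      divergence = f$divergence %||% 0
    )
  }))
}

#' Run the full repeat-landscape pipeline
#'
#' For every species block: build the synthetic genome, sample its clone
#' library, screen the library against the probe panel, and estimate
#' per-family abundances (element sizes taken from the placement truth:
#' mean placed element length per family). With two species a comparison
#' table is built over the panel's families; microsatellites are scanned on
#' every genome. All randomness derives from the single config seed, so a
#' rerun with the same config is identical; the result carries a manifest
#' (config hash, parameters, package version) and `write_results()` lays
#' the bundle out as TSV/JSON files.
#'
#' @param config a `run_config` from [read_run_config()], or a list with
#'   the same structure.
#' @param out_dir optional directory; when given, results are written there
#'   via [write_results()].
#' @return object of class `pipeline_result`: list with per-species
#'   `genomes`, `libraries`, `screens`, `estimates`; `table` (two species)
#'   or `NULL`; `microsat` summaries; and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "run_config")) config <- validate_run_config(config)
  panel <- config$panel
  if (is.character(panel)) panel <- read_probe_panel(panel)
  if (!is.null(panel) && !inherits(panel, "probe_panel")) {
    panel <- probe_panel(vapply(panel, `[[`, character(1), "family"),
                         vapply(panel, `[[`, character(1), "sequence"))
  }
  th <- config$thresholds %||% list()
  ms <- config$microsat %||% list()
  stage <- function(name, sp_name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("pipeline stage `%s` failed for species %s: %s",
                    name, sp_name, conditionMessage(e)))
    })
  }
  species <- lapply(config$species, function(sp) {
    seed_sp <- derive_seed(config$seed, sp$name)
    genome <- stage("simulate", sp$name, {
      build_genome(genome_spec(sp$genome_size_bp,
                               families = config_families(sp),
                               background_gc = sp$background_gc %||% 0.36,
                               seed = seed_sp))
    })
    lib <- stage("sample_library", sp$name, {
      sample_clone_library(genome, sp$n_clones, insert_mean = sp$insert_mean,
                           insert_sd = sp$insert_sd, seed = seed_sp)
    })
    screen <- NULL
    estimates <- NULL
    if (!is.null(panel)) {
      screen <- stage("screen", sp$name, {
        assign_clones(lib, panel,
                      min_identity = th$min_identity %||% 0.8,
                      min_overlap_bp = th$min_overlap_bp %||% 100,
                      seed_length = th$seed_length %||% 11)
      })
      sizes <- tidy(genome) |>
        dplyr::mutate(len = .data$end - .data$start) |>
        dplyr::group_by(.data$family) |>
        dplyr::summarise(mean_element_bp = mean(.data$len), .groups = "drop")
      missing <- setdiff(hit_counts(screen)$family, sizes$family)
      if (length(missing) > 0) {
        sizes <- dplyr::bind_rows(
          sizes, tibble(family = missing, mean_element_bp = 0))
      }
      estimates <- stage("estimate", sp$name, {
        estimate_abundance(screen, sizes,
                           n_clones = attr(lib, "n_clones"),
                           genome_size_bp = sp$genome_size_bp,
                           f = coverage_fraction(lib))
      })
    }
    microsat <- stage("microsat", sp$name, {
      runs <- scan_microsatellites(
        stats::setNames(genome$sequence, sp$name),
        unit_min = ms$unit_min %||% 2, unit_max = ms$unit_max %||% 4,
        min_units = ms$min_units %||% 3)
      summarize_runs(runs, nchar(genome$sequence),
                     focus_motifs = ms$focus_motifs)
    })
    list(name = sp$name, genome = genome, library = lib, screen = screen,
         estimates = estimates, microsat = microsat)
  })
  names(species) <- vapply(config$species, `[[`, character(1), "name")
  table <- NULL
  if (length(species) >= 2 && !is.null(panel)) {
    hier <- pipeline_hierarchy(panel)
    table <- build_table(species[[1]]$estimates, species[[2]]$estimates,
                         hierarchy = hier)
  }
  manifest <- list(
    package = "repeatscape",
    version = as.character(utils::packageVersion("repeatscape")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    species = names(species),
    n_panel_probes = if (is.null(panel)) 0L else nrow(panel),
    parameters = list(thresholds = th, microsat = ms)
  )
  res <- structure(
    list(species = species, table = table, manifest = manifest,
         config = config),
    class = "pipeline_result")
  if (!is.null(out_dir)) write_results(res, out_dir)
  res
}

# Flat hierarchy over the panel's families plus a rollup root, for configs
# that do not describe the full survey category tree.
pipeline_hierarchy <- function(panel) {
  fams <- unique(panel$family)
  repeat_hierarchy(node = c("All repetitive elements", fams),
                   parent = c(NA, rep("All repetitive elements", length(fams))))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d species (%s), seed %s, config %s\n",
              length(x$species), paste(names(x$species), collapse = ", "),
              x$manifest$seed, substr(x$manifest$config_hash, 1, 8)))
  if (!is.null(x$table)) print(x$table)
  invisible(x)
}

#' Write a pipeline result bundle to disk
#'
#' Per species: per-family estimates, screening assignments and counts, and
#' microsatellite summaries as TSV; plus `comparison_table.tsv` (two
#' species) and `manifest.json`. Every table is accompanied by the config
#' hash in the manifest; nothing is written if the result is not a
#' `pipeline_result`.
#'
#' @param result a `pipeline_result`.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(result, out_dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (sp in result$species) {
    stem <- file.path(out_dir, gsub("[^A-Za-z0-9_.-]", "_", sp$name))
    if (!is.null(sp$screen)) {
      write_screen_result(sp$screen, stem)
      readr::write_tsv(sp$estimates, paste0(stem, "_estimates.tsv"))
    }
    readr::write_tsv(sp$microsat$by_motif, paste0(stem, "_microsat.tsv"))
  }
  if (!is.null(result$table)) {
    readr::write_tsv(as_tibble(result$table),
                     file.path(out_dir, "comparison_table.tsv"))
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
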