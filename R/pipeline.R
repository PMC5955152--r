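#' Run configuration
#'
#' Assembles and validates the configuration for an end-to-end run. Values
#' may come from a YAML file with flat keys mirroring these arguments;
#' explicit arguments override file values.
#'
#' @param config_file Optional YAML file path.
#' @param ... Named overrides (e.g. `viability`, `tables`, `axis_mode`,
#'   `fdr_max`, `fpkm_min`, `fc_min`, `call_threshold`, `out_dir`, `seed`).
#' @return A named list of class `"run_config"`.
#' @export
run_config <- function(config_file = NULL, ...) {
  cfg <- list(axis_mode = "log10_dose", call_threshold = 0.1,
              fdr_max = 0.05, fpkm_min = 1, fc_min = 2,
              out_dir = ".", seed = 1L)
  if (!is.null(config_file)) {
    if (!file.exists(config_file)) {
      stop("config file not found: ", config_file, call. = FALSE)
    }
    file_cfg <- yaml::read_yaml(config_file)
    cfg[names(file_cfg)] <- file_cfg
  }
  overrides <- list(...)
  overrides <- overrides[!vapply(overrides, is.null, logical(1))]
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "run_config")
}

write_json_summary <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Run the panel synergy screen end to end
#'
#' Reads a viability plate table, runs [synergy_screen()], and writes a
#' per-line synergy CSV plus a JSON summary embedding the resolved
#' configuration, package version and per-line dose grids. Reruns with the
#' same inputs and configuration are deterministic.
#'
#' @param config A [run_config()] with at least `viability` (input path) and
#'   `out_dir`.
#' @return The `synergy_screen` object, invisibly; side effect: writes
#'   `synergy.csv` and `screen_summary.json` under `out_dir`.
#' @export
run_screen <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$viability)) {
    stop("screen stage: config must name a 'viability' input table",
         call. = FALSE)
  }
  if (!file.exists(config$viability)) {
    stop("screen stage: viability table not found: ", config$viability,
         call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  plates <- read_viability_table(config$viability)
  scr <- synergy_screen(plates, axis_mode = config$axis_mode,
                        call_threshold = config$call_threshold)
  csv_path <- file.path(config$out_dir, "synergy.csv")
  utils::write.table(scr$scores, csv_path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  dose_grids <- lapply(scr$curves, function(cl) cl$single$doses)
  summary_path <- file.path(config$out_dir, "screen_summary.json")
  write_json_summary(list(
    tool = "synercurve",
    version = as.character(utils::packageVersion("synercurve")),
    config = unclass(config),
    n_lines = length(scr$curves),
    n_scores = nrow(scr$scores),
    n_called = scr$n_called,
    call_threshold = scr$call_threshold,
    dose_grids = dose_grids
  ), summary_path)
  invisible(scr)
}

#' Run the differential-expression set analysis end to end
#'
#' Reads one to three DE tables (agent A, agent B, combination), filters
#' them at both the standard (`fc_min`) and lenient (1.5) fold-change
#' thresholds, and writes a JSON report with per-condition up/down counts,
#' Venn region counts and the unique-to-combination gene list, plus plain
#' gene-list text files per region. With a single table only the counts are
#' reported.
#'
#' @param config A [run_config()] with `tables` (character vector of 1-3
#'   paths, in agent A / agent B / combination order), the filter thresholds
#'   and `out_dir`.
#' @return The report list, invisibly; side effect: writes
#'   `desets_report.json` and gene-list files under `out_dir`.
#' @export
run_desets <- function(config) {
  stopifnot(inherits(config, "run_config"))
  paths <- config$tables
  if (is.null(paths) || length(paths) < 1L) {
    stop("desets stage: config must name 1-3 DE 'tables'", call. = FALSE)
  }
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    stop("desets stage: table not found: ", missing[1], call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cond_names <- if (length(paths) == 3L) c("agent_a", "agent_b", "combo")
    else paste0("condition_", seq_along(paths))
  tables <- mapply(function(p, nm) read_de_table(p, condition = nm),
                   paths, cond_names, SIMPLIFY = FALSE)
  spec_std <- filter_spec(config$fdr_max, config$fpkm_min, config$fc_min)
  spec_len <- filter_spec(config$fdr_max, config$fpkm_min, 1.5)
  count_block <- function(tab, nm) {
    gs2 <- filter_de(tab, spec_std, condition = nm)
    gs15 <- filter_de(tab, spec_len, condition = nm)
    list(fc2 = list(up = length(gs2$up), down = length(gs2$down)),
         fc1.5 = list(up = length(gs15$up), down = length(gs15$down)))
  }
  report <- list(
    tool = "synercurve",
    version = as.character(utils::packageVersion("synercurve")),
    config = unclass(config),
    counts = stats::setNames(
      mapply(count_block, tables, cond_names, SIMPLIFY = FALSE), cond_names)
  )
  sets <- lapply(seq_along(tables), function(i)
    filter_de(tables[[i]], spec_std, condition = cond_names[i]))
  if (length(sets) >= 2L) {
    vc <- do.call(overlap, sets)
    report$venn_regions <- as.list(vc$region_counts)
    report$venn_union <- vc$n_union
    if (all(vapply(sets, function(s)
        length(members(s)), integer(1)) > 0) &&
        vc$n_union == sum(vapply(sets, function(s) length(members(s)),
                                 integer(1)))) {
      warning("DE tables share no gene identifiers; zero overlaps",
              call. = FALSE)
    }
  }
  if (length(sets) == 3L) {
    utc <- unique_to_combination(sets[[1]], sets[[2]], sets[[3]])
    report$unique_to_combination <- list(
      up = utc$up, down = utc$down,
      n_up = length(utc$up), n_down = length(utc$down))
    writeLines(sort(members(utc)),
               file.path(config$out_dir, "unique_to_combination.txt"))
  }
  for (s in sets) {
    writeLines(c(paste0("+", sort(s$up)), paste0("-", sort(s$down))),
               file.path(config$out_dir,
                         paste0("genes_", s$condition, ".txt")))
  }
  write_json_summary(report, file.path(config$out_dir, "desets_report.json"))
  invisible(report)
}
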