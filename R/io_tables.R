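#' @title Delimited-table input/output
#' @description Readers and writers for the two table dialects the pipeline
#'   consumes: viability plate readouts and per-gene differential-expression
#'   tables (a generic dialect and the Cuffdiff `gene_exp.diff` dialect).
#'   Parsing is locale-independent (decimal point only) and the delimiter is
#'   auto-detected between comma and tab unless given.
#' @name io_tables
NULL

VIABILITY_COLUMNS <- c("cell_line", "primary_drug", "primary_dose_uM",
                       "secondary_drug", "secondary_dose_nM", "schedule",
                       "replicate", "signal")

DE_COLUMNS <- c("gene_id", "fpkm_control", "fpkm_treated", "log2_fc",
                "p_value", "fdr")

# Detect comma vs tab from the header line.
detect_delim <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0L) stop("empty file: ", path, call. = FALSE)
  n_tab <- lengths(regmatches(header, gregexpr("\t", header, fixed = TRUE)))
  n_com <- lengths(regmatches(header, gregexpr(",", header, fixed = TRUE)))
  if (n_tab >= n_com) "\t" else ","
}

read_delim_table <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) delim <- detect_delim(path)
  utils::read.table(path, header = TRUE, sep = delim, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "", na.strings = c("NA", ""),
                    colClasses = "character", fileEncoding = "UTF-8")
}

# Parse a dose column that may carry unit suffixes ("5 nM", "0.5uM") into a
# single target unit. Bare numbers are assumed already in the target unit.
parse_dose <- function(x, target_unit = c("nM", "uM"), column = "dose") {
  target_unit <- match.arg(target_unit)
  x_chr <- trimws(as.character(x))
  out <- numeric(length(x_chr))
  for (i in seq_along(x_chr)) {
    v <- x_chr[i]
    if (is.na(v)) { out[i] <- NA_real_; next }
    m <- regmatches(v, regexec("^([-+0-9.eE]+)\\s*(nM|uM|µM)?$", v))[[1]]
    if (length(m) == 0L) {
      stop(sprintf("cannot parse %s value '%s' (row %d)", column, v, i),
           call. = FALSE)
    }
    val <- suppressWarnings(as.numeric(m[2]))
    if (is.na(val)) {
      stop(sprintf("cannot parse %s value '%s' (row %d)", column, v, i),
           call. = FALSE)
    }
    unit <- if (m[3] == "") target_unit else sub("µ", "u", m[3])
    scale <- if (unit == target_unit) 1 else if (unit == "uM") 1e3 else 1e-3
    out[i] <- val * scale
  }
  out
}

parse_num <- function(x, column, allow_inf = FALSE) {
  x_chr <- trimws(tolower(as.character(x)))
  out <- suppressWarnings(as.numeric(x_chr))
  if (allow_inf) {
    out[x_chr %in% c("inf", "+inf", "infinity")] <- Inf
    out[x_chr %in% c("-inf", "-infinity")] <- -Inf
    # Cuffdiff sometimes emits the largest double for infinite fold changes
    out[is.finite(out) & abs(out) >= 1.79769e+308] <-
      sign(out[is.finite(out) & abs(out) >= 1.79769e+308]) * Inf
  }
  bad <- which(is.na(out) & !is.na(x_chr) & x_chr != "nan" & x_chr != "na")
  if (length(bad) > 0L) {
    stop(sprintf("unparseable numeric value '%s' in column '%s' (row %d)",
                 x[bad[1]], column, bad[1]), call. = FALSE)
  }
  out
}

#' Read a viability plate table
#'
#' Reads a delimited (comma or tab) table of 96-well viability readouts.
#' Expected columns: `cell_line`, `primary_drug`, `primary_dose_uM`,
#' `secondary_drug`, `secondary_dose_nM`, `schedule`, `replicate`, and either
#' `signal` (raw luminescence) or `viability` (pre-normalized fractions; the
#' rows are then flagged as normalized). Dose cells may carry `nM`/`uM`
#' suffixes; they are converted to the column's declared unit.
#'
#' @param path Path to the file.
#' @param delim Field delimiter; `NULL` auto-detects comma vs tab.
#' @param normalized Override for the normalized flag; `NULL` infers it from
#'   the presence of a `viability` column.
#' @return A data frame with the canonical columns plus `is_normalized`.
#' @export
read_viability_table <- function(path, delim = NULL, normalized = NULL) {
  raw <- read_delim_table(path, delim)
  has_viab <- "viability" %in% names(raw)
  signal_col <- if (has_viab) "viability" else "signal"
  required <- c(setdiff(VIABILITY_COLUMNS, "signal"), signal_col)
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(
    cell_line = as.character(raw$cell_line),
    primary_drug = as.character(raw$primary_drug),
    primary_dose_uM = parse_dose(raw$primary_dose_uM, "uM", "primary_dose_uM"),
    secondary_drug = as.character(raw$secondary_drug),
    secondary_dose_nM = parse_dose(raw$secondary_dose_nM, "nM",
                                   "secondary_dose_nM"),
    schedule = as.character(raw$schedule),
    replicate = parse_num(raw$replicate, "replicate"),
    signal = parse_num(raw[[signal_col]], signal_col),
    stringsAsFactors = FALSE
  )
  for (col in c("primary_dose_uM", "secondary_dose_nM", "signal")) {
    bad <- which(!is.na(out[[col]]) & out[[col]] < 0)
    if (length(bad) > 0L) {
      stop(sprintf("negative %s in row %d", col, bad[1]), call. = FALSE)
    }
  }
  bad_rep <- which(!is.na(out$replicate) & out$replicate < 1)
  if (length(bad_rep) > 0L) {
    stop(sprintf("replicate < 1 in row %d", bad_rep[1]), call. = FALSE)
  }
  out$is_normalized <- if (is.null(normalized)) has_viab else isTRUE(normalized)
  out
}

#' Write a viability plate table
#'
#' @param records Data frame as returned by [read_viability_table()].
#' @param path Output path.
#' @param delim Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_viability_table <- function(records, path, delim = ",") {
  out <- records[, intersect(VIABILITY_COLUMNS, names(records)), drop = FALSE]
  utils::write.table(out, path, sep = delim, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a differential-expression table
#'
#' Reads per-gene differential-expression records in one of two dialects:
#' `"generic"` (columns `gene_id`, `fpkm_control`, `fpkm_treated`, `log2_fc`,
#' `p_value`, `fdr`, optional `condition`) or `"cuffdiff"` (the
#' `gene_exp.diff` layout produced by Cuffdiff, mapping `value_1`/`value_2`
#' to the control/treated FPKM, `log2(fold_change)` to `log2_fc` and
#' `q_value` to `fdr`). The fold-change strings `"inf"`/`"-inf"` parse to
#' +/- infinity, the convention for genes expressed in only one condition
#' (e.g. 0 FPKM against 10 FPKM). Duplicate `gene_id`s keep the first
#' occurrence with a warning.
#'
#' @param path Path to the file.
#' @param dialect `"generic"` or `"cuffdiff"`.
#' @param delim Field delimiter; `NULL` auto-detects comma vs tab.
#' @param condition Optional condition label attached to every record.
#' @return A data frame of DE records.
#' @export
read_de_table <- function(path, dialect = c("generic", "cuffdiff"),
                          delim = NULL, condition = NULL) {
  dialect <- match.arg(dialect)
  raw <- read_delim_table(path, delim)
  if (dialect == "cuffdiff") {
    fc_col <- intersect(c("log2(fold_change)", "log2.fold_change."),
                        names(raw))[1]
    required <- c("gene_id", "value_1", "value_2", "p_value", "q_value")
    if (is.na(fc_col)) required <- c(required, "log2(fold_change)")
    missing <- setdiff(required, names(raw))
    if (length(missing) > 0L) {
      stop("missing cuffdiff column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    cond <- if (!is.null(condition)) condition
      else if (all(c("sample_1", "sample_2") %in% names(raw)))
        paste(raw$sample_1, raw$sample_2, sep = "_vs_")
      else NA_character_
    out <- data.frame(
      gene_id = as.character(raw$gene_id),
      fpkm_control = parse_num(raw$value_1, "value_1"),
      fpkm_treated = parse_num(raw$value_2, "value_2"),
      log2_fc = parse_num(raw[[fc_col]], fc_col, allow_inf = TRUE),
      p_value = parse_num(raw$p_value, "p_value"),
      fdr = parse_num(raw$q_value, "q_value"),
      condition = cond,
      stringsAsFactors = FALSE
    )
  } else {
    missing <- setdiff(DE_COLUMNS, names(raw))
    if (length(missing) > 0L) {
      stop("missing mandatory column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    cond <- if (!is.null(condition)) condition
      else if ("condition" %in% names(raw)) as.character(raw$condition)
      else NA_character_
    out <- data.frame(
      gene_id = as.character(raw$gene_id),
      fpkm_control = parse_num(raw$fpkm_control, "fpkm_control"),
      fpkm_treated = parse_num(raw$fpkm_treated, "fpkm_treated"),
      log2_fc = parse_num(raw$log2_fc, "log2_fc", allow_inf = TRUE),
      p_value = parse_num(raw$p_value, "p_value"),
      fdr = parse_num(raw$fdr, "fdr"),
      condition = cond,
      stringsAsFactors = FALSE
    )
  }
  validate_de_table(out)
  dup <- duplicated(out$gene_id)
  if (any(dup)) {
    warning(sum(dup), " duplicated gene_id(s); keeping first occurrence",
            call. = FALSE)
    out <- out[!dup, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

validate_de_table <- function(x) {
  bad <- which(x$fpkm_control < 0 | x$fpkm_treated < 0)
  if (length(bad) > 0L) {
    stop("negative FPKM in row ", bad[1], call. = FALSE)
  }
  bad_p <- which(!is.na(x$p_value) & (x$p_value < 0 | x$p_value > 1))
  if (length(bad_p) > 0L) {
    stop("p_value outside [0,1] in row ", bad_p[1], call. = FALSE)
  }
  invisible(x)
}

#' Write a differential-expression table (generic dialect)
#'
#' Numeric fields are written with enough digits for a lossless round trip;
#' infinite fold changes are written as the literal strings `"inf"`/`"-inf"`.
#'
#' @param table DE data frame (as from [read_de_table()]).
#' @param path Output path.
#' @param delim Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_de_table <- function(table, path, delim = "\t") {
  fmt <- function(x) {
    out <- sprintf("%.15g", x)
    out[is.infinite(x) & x > 0] <- "inf"
    out[is.infinite(x) & x < 0] <- "-inf"
    out[is.na(x)] <- "NA"
    out
  }
  cols <- c("gene_id", "fpkm_control", "fpkm_treated", "log2_fc",
            "p_value", "fdr")
  out <- data.frame(
    gene_id = table$gene_id,
    fpkm_control = fmt(table$fpkm_control),
    fpkm_treated = fmt(table$fpkm_treated),
    log2_fc = fmt(table$log2_fc),
    p_value = fmt(table$p_value),
    fdr = fmt(table$fdr),
    stringsAsFactors = FALSE
  )
  if ("condition" %in% names(table) && !all(is.na(table$condition))) {
    out$condition <- table$condition
    cols <- c(cols, "condition")
  }
  utils::write.table(out[, cols], path, sep = delim, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
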