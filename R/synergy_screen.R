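#' Screen a cell-line panel for combination synergy
#'
#' The central entry point of the package. Takes a viability plate table
#' covering a panel of cell lines, each with a secondary-drug (e.g.
#' panobinostat) dose-response arm alone and in combination with one or more
#' pretreatment agents (e.g. an EZH2 inhibitor), and computes one synergy
#' score per (cell line, pretreatment agent): the relative decrease in the
#' trapezoidal area under the anchored survival curve ([delta_ausc()]).
#'
#' Arms are identified by `primary_drug`: rows whose `primary_drug` is
#' missing, empty, `"none"` or `"CTRL"` (case-insensitive), or whose
#' `primary_dose_uM` is 0, form the single-agent arm; every other distinct
#' `primary_drug` value forms one combination arm. Wells of the single-agent
#' arm at secondary dose 0 are the untreated (media) controls used to
#' normalize all signals of that cell line; each curve is then anchored to
#' its own zero-secondary-dose point before integration, so the pretreatment
#' agent's single-agent toxicity does not enter the score.
#'
#' @param plates Plate-record data frame as returned by
#'   [read_viability_table()] or [simulate_viability_panel()].
#' @param axis_mode Integration axis, see [ausc()].
#' @param call_threshold Relative AUSC decrease above which a line is called
#'   synergistic in the summary (reporting convenience only; default 0.1).
#' @param clip If `TRUE`, anchored survival values above 1 are clipped to 1
#'   before integration (exploratory use; default keeps them, since clipping
#'   biases the area).
#' @return An object of class `"synergy_screen"`: a list with `scores` (a
#'   data frame sorted by descending `delta_ausc_rel`), `curves` (the
#'   anchored curves per line), `axis_mode`, `call_threshold`, `n_called`.
#' @seealso [delta_ausc()], [simulate_viability_panel()], [run_screen()]
#' @examples
#' plates <- simulate_viability_panel(n_lines = 4, synergy_lines = 1:2,
#'                                    seed = 42)
#' scr <- synergy_screen(plates)
#' summary(scr)
#' coef(scr)
#' @export
synergy_screen <- function(plates, axis_mode = c("log10_dose", "index"),
                           call_threshold = 0.1, clip = FALSE) {
  axis_mode <- match.arg(axis_mode)
  stopifnot(is.data.frame(plates), nrow(plates) > 0)
  lines <- unique(plates$cell_line)
  scores <- list()
  curves <- list()
  for (cl in lines) {
    p <- plates[plates$cell_line == cl, , drop = FALSE]
    is_single <- is_single_arm(p)
    single_rows <- p[is_single, , drop = FALSE]
    if (nrow(single_rows) == 0L ||
        length(unique(single_rows$secondary_dose_nM)) < 2L) {
      warning("cell line ", cl, " lacks a single-agent curve; skipped",
              call. = FALSE)
      next
    }
    ctrl <- single_rows[single_rows$secondary_dose_nM == 0, , drop = FALSE]
    sec <- unique(single_rows$secondary_drug)
    sec <- sec[!is.na(sec) & sec != ""][1]
    single_curve <- normalize_viability(
      single_rows, control = if (nrow(ctrl) > 0) ctrl else NULL,
      condition = paste0("CTRL+", sec))
    single_curve <- maybe_clip(anchor_normalize(single_curve), clip)
    curves[[cl]] <- list(single = single_curve)
    combo_drugs <- setdiff(unique(p$primary_drug[!is_single]), NA)
    for (drug in combo_drugs) {
      combo_rows <- p[!is_single & p$primary_drug == drug, , drop = FALSE]
      combo_curve <- normalize_viability(
        combo_rows, control = if (nrow(ctrl) > 0) ctrl else NULL,
        condition = paste0(drug, "+", sec))
      combo_curve <- maybe_clip(anchor_normalize(combo_curve), clip)
      curves[[cl]][[drug]] <- combo_curve
      sc <- delta_ausc(single_curve, combo_curve, axis_mode, ezh2i = drug)
      scores[[length(scores) + 1L]] <- as.data.frame(sc)
    }
  }
  scores_df <- if (length(scores) > 0) do.call(rbind, scores) else
    data.frame(cell_line = character(), ezh2i = character(),
               ausc_single = numeric(), ausc_combo = numeric(),
               delta_ausc_abs = numeric(), delta_ausc_rel = numeric(),
               axis_mode = character(), n_doses = integer(),
               stringsAsFactors = FALSE)
  scores_df <- scores_df[order(-scores_df$delta_ausc_rel), , drop = FALSE]
  rownames(scores_df) <- NULL
  structure(
    list(scores = scores_df, curves = curves, axis_mode = axis_mode,
         call_threshold = call_threshold,
         n_called = sum(scores_df$delta_ausc_rel > call_threshold)),
    class = "synergy_screen"
  )
}

is_single_arm <- function(p) {
  drug <- tolower(trimws(ifelse(is.na(p$primary_drug), "", p$primary_drug)))
  no_drug <- drug %in% c("", "none", "ctrl", "media", "dmso")
  no_dose <- !is.na(p$primary_dose_uM) & p$primary_dose_uM == 0
  no_drug | (no_dose & !is.na(p$primary_dose_uM))
}

maybe_clip <- function(curve, clip) {
  if (isTRUE(clip)) curve$survival <- pmin(curve$survival, 1)
  curve
}

#' @export
print.synergy_screen <- function(x, ...) {
  cat(sprintf("Synergy screen: %d score(s) across %d cell line(s), %s axis\n",
              nrow(x$scores), length(x$curves), x$axis_mode))
  cat(sprintf("%d line(s) called synergistic at delta-AUSC(rel) > %g\n\n",
              x$n_called, x$call_threshold))
  df <- x$scores
  df$ausc_single <- signif(df$ausc_single, 4)
  df$ausc_combo <- signif(df$ausc_combo, 4)
  df$delta_ausc_abs <- signif(df$delta_ausc_abs, 4)
  df$delta_ausc_rel <- signif(df$delta_ausc_rel, 4)
  print(utils::head(df, 10), row.names = FALSE)
  if (nrow(df) > 10) cat("... (", nrow(df) - 10, " more)\n", sep = "")
  invisible(x)
}

#' @export
summary.synergy_screen <- function(object, ...) {
  s <- object$scores$delta_ausc_rel
  out <- list(
    n_scores = nrow(object$scores),
    n_called = object$n_called,
    call_threshold = object$call_threshold,
    mean_delta_ausc_rel = if (length(s)) mean(s) else NA_real_,
    median_delta_ausc_rel = if (length(s)) stats::median(s) else NA_real_,
    range_delta_ausc_rel = if (length(s)) range(s) else c(NA_real_, NA_real_),
    axis_mode = object$axis_mode
  )
  class(out) <- "summary.synergy_screen"
  out
}

#' @export
print.summary.synergy_screen <- function(x, ...) {
  cat("Panel synergy summary (relative AUSC decrease)\n")
  cat(sprintf("  scores: %d; called synergistic (> %g): %d\n",
              x$n_scores, x$call_threshold, x$n_called))
  cat(sprintf("  mean: %0.4f  median: %0.4f  range: [%0.4f, %0.4f]\n",
              x$mean_delta_ausc_rel, x$median_delta_ausc_rel,
              x$range_delta_ausc_rel[1], x$range_delta_ausc_rel[2]))
  invisible(x)
}

#' @export
coef.synergy_screen <- function(object, ...) {
  stats::setNames(object$scores$delta_ausc_rel,
                  paste(object$scores$cell_line, object$scores$ezh2i,
                        sep = ":"))
}

#' @export
as.data.frame.synergy_screen <- function(x, ...) x$scores

#' Bar plot of per-line synergy scores
#'
#' @param x A `synergy_screen` object.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.synergy_screen <- function(x, ...) {
  if (nrow(x$scores) == 0L) {
    stop("nothing to plot: empty screen", call. = FALSE)
  }
  vals <- x$scores$delta_ausc_rel
  graphics::barplot(vals,
                    names.arg = paste(x$scores$cell_line, x$scores$ezh2i),
                    las = 2, cex.names = 0.7,
                    ylab = "relative AUSC decrease",
                    main = "Combination synergy across panel", ...)
  graphics::abline(h = x$call_threshold, lty = 2)
  invisible(x)
}
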