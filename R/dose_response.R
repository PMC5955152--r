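#' Construct a survival curve
#'
#' A survival curve holds the mean viability fraction (and SEM across
#' biological replicates) at each secondary-drug dose for one cell line and
#' treatment arm. Doses must be strictly increasing; a leading zero dose is
#' permitted and serves as the anchor for [anchor_normalize()].
#'
#' @param doses Strictly increasing dose vector (nM); first element may be 0.
#' @param survival Mean viability fractions, same length as `doses`. Values
#'   above 1 are permitted (they occur before anchor normalization).
#' @param sem Standard errors of the mean; `NA` when a dose has a single
#'   replicate. Defaults to all `NA`.
#' @param cell_line,condition Labels.
#' @param n_replicates Number of biological replicates behind the means.
#' @return An object of class `"survival_curve"`.
#' @export
survival_curve <- function(doses, survival, sem = rep(NA_real_, length(doses)),
                           cell_line = NA_character_,
                           condition = NA_character_, n_replicates = 1L) {
  doses <- as.numeric(doses)
  survival <- as.numeric(survival)
  sem <- as.numeric(sem)
  if (length(doses) < 2L) {
    stop("a survival curve needs at least 2 dose points", call. = FALSE)
  }
  if (length(survival) != length(doses) || length(sem) != length(doses)) {
    stop("doses, survival and sem must have equal length", call. = FALSE)
  }
  if (any(diff(doses) <= 0)) {
    stop("doses must be strictly increasing", call. = FALSE)
  }
  if (any(doses < 0)) stop("doses must be >= 0", call. = FALSE)
  if (any(survival < 0)) stop("survival must be >= 0", call. = FALSE)
  structure(
    list(cell_line = as.character(cell_line),
         condition = as.character(condition),
         doses = doses, survival = survival, sem = sem,
         n_replicates = as.integer(n_replicates)),
    class = "survival_curve"
  )
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("Survival curve: %s / %s (%d replicates)\n",
              x$cell_line, x$condition, x$n_replicates))
  print(data.frame(dose_nM = x$doses, survival = signif(x$survival, 4),
                   sem = signif(x$sem, 3)), row.names = FALSE)
  invisible(x)
}

#' Normalize raw viability signals to untreated controls
#'
#' Converts raw plate signals for one treatment arm into a survival curve:
#' each replicate well is divided by the mean control (untreated) signal,
#' then the normalized replicates are averaged per dose, with SEM computed
#' across the normalized replicate values. Pre-normalized records
#' (`is_normalized`) skip the division.
#'
#' @param records Plate-record data frame (one cell line, one arm) with
#'   columns `secondary_dose_nM`, `replicate`, `signal` (and optionally
#'   `cell_line`, `is_normalized`).
#' @param control Either a data frame of untreated control wells, a positive
#'   scalar (the mean control signal), or `NULL`, in which case the dose-0
#'   rows of `records` serve as the control (or 1 if already normalized).
#' @param condition Condition label for the curve.
#' @return A [survival_curve()].
#' @export
normalize_viability <- function(records, control = NULL, condition = NA) {
  if (nrow(records) == 0L) stop("no records", call. = FALSE)
  is_norm <- isTRUE(records$is_normalized[1])
  ctrl_mean <-
    if (is.numeric(control) && length(control) == 1L) control
    else if (is.data.frame(control)) mean(control$signal)
    else if (is_norm) 1
    else mean(records$signal[records$secondary_dose_nM == 0])
  if (!is.finite(ctrl_mean) || ctrl_mean <= 0) {
    stop("control signal is zero, absent or non-finite; cannot normalize",
         call. = FALSE)
  }
  doses <- sort(unique(records$secondary_dose_nM))
  if (length(doses) < 2L) {
    stop("need at least 2 distinct secondary doses", call. = FALSE)
  }
  frac <- records$signal / ctrl_mean
  mu <- tapply(frac, records$secondary_dose_nM, mean)
  se <- tapply(frac, records$secondary_dose_nM, function(v) {
    if (length(v) < 2L) NA_real_ else stats::sd(v) / sqrt(length(v))
  })
  ord <- order(as.numeric(names(mu)))
  survival_curve(
    doses = as.numeric(names(mu))[ord],
    survival = as.numeric(mu)[ord],
    sem = as.numeric(se)[ord],
    cell_line = if ("cell_line" %in% names(records)) records$cell_line[1] else NA,
    condition = condition,
    n_replicates = max(table(records$secondary_dose_nM))
  )
}

#' Anchor a survival curve to its zero-dose point
#'
#' Divides every survival value (and SEM) by the zero-secondary-dose
#' survival, so the returned curve starts at exactly 1. This isolates the
#' shape of the secondary-drug response from any toxicity of the
#' pretreatment agent, and is idempotent.
#'
#' @param curve A [survival_curve()] containing a dose-0 point with
#'   positive survival.
#' @return The anchored [survival_curve()].
#' @export
anchor_normalize <- function(curve) {
  stopifnot(inherits(curve, "survival_curve"))
  i0 <- which(curve$doses == 0)
  if (length(i0) == 0L) {
    stop("curve has no zero-dose point to anchor to", call. = FALSE)
  }
  s0 <- curve$survival[i0[1]]
  if (!is.finite(s0) || s0 <= 0) {
    stop("zero-dose survival must be positive to anchor", call. = FALSE)
  }
  curve$survival <- curve$survival / s0
  curve$survival[i0[1]] <- 1  # exact by construction
  curve$sem <- curve$sem / s0
  curve
}

# Composite trapezoid over ordered (x, y) pairs.
trapezoid <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2)
}

#' Area under the survival curve (AUSC)
#'
#' Integrates a survival curve by the trapezoidal method. With
#' `axis_mode = "log10_dose"` the x-axis is log10 of the dose, which treats
#' the serial-dilution dose grid as evenly spaced; the zero-dose point is
#' excluded from the integration grid (its information is carried by the
#' anchor normalization). With `axis_mode = "index"` the x-axis is the
#' 0-based point index over all points.
#'
#' @param curve A [survival_curve()].
#' @param axis_mode `"log10_dose"` (default) or `"index"`.
#' @return The non-negative area (survival x axis units).
#' @export
ausc <- function(curve, axis_mode = c("log10_dose", "index")) {
  stopifnot(inherits(curve, "survival_curve"))
  axis_mode <- match.arg(axis_mode)
  if (axis_mode == "log10_dose") {
    keep <- curve$doses > 0
    if (sum(keep) < 2L) {
      stop("log10_dose mode needs >= 2 nonzero-dose points", call. = FALSE)
    }
    x <- log10(curve$doses[keep])
    y <- curve$survival[keep]
  } else {
    if (length(curve$doses) < 2L) {
      stop("need >= 2 points to integrate", call. = FALSE)
    }
    x <- seq_along(curve$doses) - 1
    y <- curve$survival
  }
  trapezoid(x, y)
}

#' Synergy score: relative AUSC decrease between two curves
#'
#' Quantifies combination synergy as the decrease in the area under the
#' survival curve between the single-agent curve and the combination curve,
#' reported both absolutely and relative to the single-agent AUSC. Positive
#' relative decreases indicate synergy (the combination curve lies below the
#' single-agent curve); negative values indicate apparent antagonism, which
#' anchor normalization can produce for lines strongly sensitive to the
#' pretreatment agent alone. Both curves must share the identical
#' secondary-dose grid and should be anchored ([anchor_normalize()]) first.
#'
#' @param single_agent,combination [survival_curve()]s on the same dose grid.
#' @param axis_mode Integration axis, see [ausc()].
#' @param ezh2i Label for the combination's pretreatment agent; defaults to
#'   the combination curve's condition label.
#' @return An object of class `"synergy_score"`: a list with `cell_line`,
#'   `ezh2i`, `ausc_single`, `ausc_combo`, `delta_ausc_abs`,
#'   `delta_ausc_rel`, `axis_mode`, `n_doses`.
#' @export
delta_ausc <- function(single_agent, combination,
                       axis_mode = c("log10_dose", "index"),
                       ezh2i = combination$condition) {
  stopifnot(inherits(single_agent, "survival_curve"),
            inherits(combination, "survival_curve"))
  axis_mode <- match.arg(axis_mode)
  if (length(single_agent$doses) != length(combination$doses) ||
      any(abs(single_agent$doses - combination$doses) >
          1e-9 * pmax(1, abs(single_agent$doses)))) {
    stop("single-agent and combination curves must share the same dose grid",
         call. = FALSE)
  }
  a_single <- ausc(single_agent, axis_mode)
  a_combo <- ausc(combination, axis_mode)
  if (a_single <= 0) {
    stop("single-agent AUSC is zero; relative decrease undefined",
         call. = FALSE)
  }
  structure(
    list(cell_line = single_agent$cell_line,
         ezh2i = as.character(ezh2i),
         ausc_single = a_single,
         ausc_combo = a_combo,
         delta_ausc_abs = a_single - a_combo,
         delta_ausc_rel = (a_single - a_combo) / a_single,
         axis_mode = axis_mode,
         n_doses = length(single_agent$doses)),
    class = "synergy_score"
  )
}

#' @export
print.synergy_score <- function(x, ...) {
  cat(sprintf(
    "Synergy score [%s / %s]: AUSC %0.4f -> %0.4f, relative decrease %0.4f (%s axis)\n",
    x$cell_line, x$ezh2i, x$ausc_single, x$ausc_combo, x$delta_ausc_rel,
    x$axis_mode))
  invisible(x)
}

#' @export
as.data.frame.synergy_score <- function(x, ...) {
  data.frame(cell_line = x$cell_line, ezh2i = x$ezh2i,
             ausc_single = x$ausc_single, ausc_combo = x$ausc_combo,
             delta_ausc_abs = x$delta_ausc_abs,
             delta_ausc_rel = x$delta_ausc_rel,
             axis_mode = x$axis_mode, n_doses = x$n_doses,
             stringsAsFactors = FALSE)
}

#' Relative densitometry of a histone-mark western blot
#'
#' Computes relative methylation from simultaneous quantification of a
#' histone mark (e.g. H3K27me3) and total histone H3 on the same blot: the
#' treated mark/total ratio divided by the same ratio in the untreated
#' reference, so 1.0 means no change from untreated.
#'
#' @param treated Numeric pair `c(mark_signal, total_h3_signal)` for the
#'   treated condition.
#' @param untreated_ref Numeric pair for the untreated reference.
#' @param condition Optional condition label.
#' @return A list with `condition`, `h3k27me3_signal`, `h3_total_signal` and
#'   `relative_methylation`.
#' @export
densitometry <- function(treated, untreated_ref, condition = NA_character_) {
  if (length(treated) != 2L || length(untreated_ref) != 2L) {
    stop("treated and untreated_ref must each be a (mark, total-H3) pair",
         call. = FALSE)
  }
  if (any(c(treated, untreated_ref) < 0)) {
    stop("signals must be >= 0", call. = FALSE)
  }
  if (treated[2] <= 0 || untreated_ref[2] <= 0) {
    stop("total-H3 signals must be positive", call. = FALSE)
  }
  ref_ratio <- untreated_ref[1] / untreated_ref[2]
  if (ref_ratio <= 0) {
    stop("untreated mark/total ratio must be positive", call. = FALSE)
  }
  list(condition = as.character(condition),
       h3k27me3_signal = treated[1],
       h3_total_signal = treated[2],
       relative_methylation = (treated[1] / treated[2]) / ref_ratio)
}
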