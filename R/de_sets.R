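#' Differential-expression filter specification
#'
#' Thresholds for calling a gene differentially expressed: FDR strictly
#' below `fdr_max`, at least one FPKM value (control or treated) at or above
#' `fpkm_min`, and linear fold-change magnitude at or above `fc_min`
#' (`fc_min = 2` corresponds to `|log2 FC| >= 1`; infinite fold changes
#' always satisfy the fold-change criterion).
#'
#' @param fdr_max FDR cutoff, strict (default 0.05).
#' @param fpkm_min Minimum FPKM for the larger of control/treated,
#'   inclusive (default 1).
#' @param fc_min Linear fold-change magnitude threshold, inclusive,
#'   must be >= 1 (default 2; 1.5 gives the lenient variant).
#' @return A list of class `"filter_spec"`.
#' @export
filter_spec <- function(fdr_max = 0.05, fpkm_min = 1, fc_min = 2) {
  if (fdr_max < 0 || fdr_max > 1) stop("fdr_max must be in [0,1]", call. = FALSE)
  if (fpkm_min < 0) stop("fpkm_min must be >= 0", call. = FALSE)
  if (fc_min < 1) stop("fc_min must be >= 1", call. = FALSE)
  structure(list(fdr_max = fdr_max, fpkm_min = fpkm_min, fc_min = fc_min),
            class = "filter_spec")
}

#' Construct a gene set with direction labels
#'
#' @param up,down Character vectors of gene identifiers; must be disjoint.
#' @param condition Condition label.
#' @return A list of class `"gene_set"` with `condition`, `up`, `down`.
#' @export
gene_set <- function(up = character(), down = character(),
                     condition = NA_character_) {
  up <- unique(as.character(up))
  down <- unique(as.character(down))
  if (length(intersect(up, down)) > 0L) {
    stop("up and down sets must be disjoint", call. = FALSE)
  }
  structure(list(condition = as.character(condition), up = up, down = down),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("Gene set [%s]: %d up, %d down (%d total)\n",
              x$condition, length(x$up), length(x$down),
              length(x$up) + length(x$down)))
  invisible(x)
}

#' Members of a gene set regardless of direction
#' @param x A [gene_set()].
#' @return Character vector `union(up, down)`.
#' @export
members <- function(x) {
  stopifnot(inherits(x, "gene_set"))
  union(x$up, x$down)
}

#' Filter a differential-expression table into a directional gene set
#'
#' A gene passes when its FDR is strictly below `spec$fdr_max`, the larger
#' of its control/treated FPKM is at least `spec$fpkm_min`, and its linear
#' fold-change magnitude `2^|log2_fc|` is at least `spec$fc_min` (infinite
#' log2 fold changes — genes expressed in only one condition — always pass
#' the fold-change criterion). The sign of `log2_fc` routes the gene to the
#' up or down set; passing genes with `log2_fc == 0` have no direction and
#' are excluded with a message. Genes with zero FPKM in both conditions are
#' dropped before filtering (undefined fold change, cannot reach the FPKM
#' floor when `fpkm_min > 0`).
#'
#' @param table DE data frame (see [read_de_table()]).
#' @param spec A [filter_spec()].
#' @param condition Label for the resulting set; defaults to the table's
#'   condition column when present.
#' @return A [gene_set()].
#' @export
filter_de <- function(table, spec = filter_spec(), condition = NULL) {
  stopifnot(inherits(spec, "filter_spec"))
  if (nrow(table) == 0L) stop("empty DE table", call. = FALSE)
  if (is.null(condition)) {
    condition <- if ("condition" %in% names(table)) table$condition[1]
      else NA_character_
  }
  t <- table[!(table$fpkm_control == 0 & table$fpkm_treated == 0), ,
             drop = FALSE]
  pass_fdr <- !is.na(t$fdr) & t$fdr < spec$fdr_max
  pass_fpkm <- pmax(t$fpkm_control, t$fpkm_treated) >= spec$fpkm_min
  pass_fc <- is.infinite(t$log2_fc) | (2^abs(t$log2_fc) >= spec$fc_min)
  pass <- pass_fdr & pass_fpkm & pass_fc & !is.na(t$log2_fc)
  zero_dir <- pass & t$log2_fc == 0
  if (any(zero_dir)) {
    message(sum(zero_dir),
            " gene(s) passed thresholds with log2 FC = 0; excluded",
            " (no direction)")
  }
  gene_set(up = t$gene_id[pass & t$log2_fc > 0],
           down = t$gene_id[pass & t$log2_fc < 0],
           condition = condition)
}

#' Venn region counts between gene sets
#'
#' Counts every exclusive Venn region among two or three gene sets. With
#' `direction_aware = TRUE` a gene is counted as present in a set only by
#' its signed membership (so a gene up in one set and down in another falls
#' in different regions); otherwise membership in `up` or `down` suffices.
#' Region names join the participating labels with `"&"` (e.g. `"A&B"` is
#' the region in A and B but not in any other set).
#'
#' @param ... Two or three [gene_set()] objects.
#' @param direction_aware Logical (default `FALSE`).
#' @return An object of class `"venn_counts"`: list with `labels`,
#'   `region_counts` (named integer vector over all non-empty label
#'   subsets), `n_union` and `direction_aware`.
#' @export
overlap <- function(..., direction_aware = FALSE) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "gene_set")) {
    sets <- sets[[1]]
  }
  if (length(sets) < 2L || length(sets) > 3L) {
    stop("overlap() takes two or three gene sets", call. = FALSE)
  }
  lapply(sets, function(s) stopifnot(inherits(s, "gene_set")))
  labels <- vapply(sets, function(s) s$condition, character(1))
  if (anyNA(labels) || any(duplicated(labels))) {
    labels <- make.unique(ifelse(is.na(labels),
                                 LETTERS[seq_along(sets)], labels))
  }
  elems <- lapply(sets, function(s) {
    if (direction_aware) c(paste0("+", s$up), paste0("-", s$down))
    else members(s)
  })
  universe <- unique(unlist(elems))
  memb <- vapply(elems, function(e) universe %in% e,
                 logical(length(universe)))
  if (length(universe) == 0L) {
    memb <- matrix(logical(0), nrow = 0, ncol = length(sets))
  }
  if (is.null(dim(memb))) memb <- matrix(memb, nrow = length(universe))
  k <- length(sets)
  region_counts <- integer(0)
  subset_masks <- seq_len(2^k - 1)
  for (mask in subset_masks) {
    in_subset <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1)))
    name <- paste(labels[in_subset], collapse = "&")
    match_rows <- apply(memb, 1, function(r) all(r == in_subset))
    region_counts[name] <- sum(match_rows)
  }
  structure(
    list(labels = labels, region_counts = region_counts,
         n_union = length(universe), direction_aware = direction_aware),
    class = "venn_counts"
  )
}

#' @export
print.venn_counts <- function(x, ...) {
  cat(sprintf("Venn regions over {%s}%s — union size %d\n",
              paste(x$labels, collapse = ", "),
              if (x$direction_aware) " (direction-aware)" else "",
              x$n_union))
  for (nm in names(x$region_counts)) {
    cat(sprintf("  %-30s %d\n", nm, x$region_counts[[nm]]))
  }
  invisible(x)
}

#' Number of genes shared between two gene sets
#'
#' Convenience accessor over [overlap()]: the size of the intersection of
#' the two sets (direction-aware or not).
#'
#' @param a,b [gene_set()] objects.
#' @param direction_aware Logical.
#' @return Integer count.
#' @export
shared_count <- function(a, b, direction_aware = FALSE) {
  if (direction_aware) {
    length(intersect(a$up, b$up)) + length(intersect(a$down, b$down))
  } else {
    length(intersect(members(a), members(b)))
  }
}

#' Genes unique to the combination condition
#'
#' Returns the members of the combination set absent from either
#' single-agent set (single-agent membership is tested on `up | down`,
#' ignoring direction). Direction labels are inherited from the combination.
#'
#' @param agent_a,agent_b,combo [gene_set()]s from the same cell line and
#'   threshold specification.
#' @return A [gene_set()] labelled `"<combo>_unique"`.
#' @export
unique_to_combination <- function(agent_a, agent_b, combo) {
  stopifnot(inherits(agent_a, "gene_set"), inherits(agent_b, "gene_set"),
            inherits(combo, "gene_set"))
  seen <- union(members(agent_a), members(agent_b))
  gene_set(up = setdiff(combo$up, seen),
           down = setdiff(combo$down, seen),
           condition = paste0(combo$condition, "_unique"))
}

#' Persistence of differential expression between two time points
#'
#' Direction-aware accounting of how much of an earlier gene set reappears
#' at a later sampling time of the same treatment: shared up and down
#' counts, and the fraction of the earlier set retained (same gene, same
#' direction) in the later set. An empty earlier set yields `NA` for the
#' fraction.
#'
#' @param earlier,later [gene_set()]s at two sampling times.
#' @return List with `shared_up`, `shared_down`, `n_earlier`, `n_later`,
#'   `retained_fraction`.
#' @export
persistence_report <- function(earlier, later) {
  stopifnot(inherits(earlier, "gene_set"), inherits(later, "gene_set"))
  shared_up <- length(intersect(earlier$up, later$up))
  shared_down <- length(intersect(earlier$down, later$down))
  n_earlier <- length(earlier$up) + length(earlier$down)
  list(
    shared_up = shared_up,
    shared_down = shared_down,
    n_earlier = n_earlier,
    n_later = length(later$up) + length(later$down),
    retained_fraction = if (n_earlier == 0L) NA_real_
      else (shared_up + shared_down) / n_earlier
  )
}
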