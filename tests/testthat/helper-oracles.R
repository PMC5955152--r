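# Independent oracles, deliberately coded without touching package internals.

# Brute-force Venn region counts: for each element of the union, find its
# membership pattern and tally patterns.
brute_venn <- function(sets) {
  universe <- unique(unlist(sets))
  k <- length(sets)
  counts <- integer(0)
  for (mask in seq_len(2^k - 1)) {
    in_subset <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1)))
    name <- paste(names(sets)[in_subset], collapse = "&")
    n <- 0L
    for (el in universe) {
      pattern <- vapply(sets, function(s) el %in% s, logical(1))
      if (all(pattern == in_subset)) n <- n + 1L
    }
    counts[name] <- n
  }
  counts
}

# Brute-force Benjamini-Hochberg adjusted p-values via the sorted-rank
# definition with a running minimum from the largest p down.
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- 1
  for (i in n:1) {
    running <- min(running, n * p[o[i]] / i)
    adj[o[i]] <- running
  }
  adj
}

# A random directional gene set over a shared namespace.
random_gene_set <- function(genes, p_in = 0.3, condition = "X") {
  chosen <- genes[stats::runif(length(genes)) < p_in]
  up <- chosen[stats::runif(length(chosen)) < 0.5]
  gene_set(up = up, down = setdiff(chosen, up), condition = condition)
}

write_temp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Minimal viability table text: one cell line, single-agent arm only.
viability_csv_lines <- function(doses = c(0, 5, 10),
                                signals = c(10000, 8000, 5000),
                                signal_col = "signal") {
  c(paste("cell_line,primary_drug,primary_dose_uM,secondary_drug",
          "secondary_dose_nM,schedule,replicate", signal_col, sep = ","),
    sprintf("L1,none,0,pan,%s,simultaneous,1,%s", doses, signals))
}
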