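#' Hill dose-response specification
#'
#' Parameters of the sigmoidal (Hill) kill model the viability simulator
#' uses: survival at dose d is `1 - emax * d^h / (d^h + ec50^h)`. Defaults
#' describe a potent HDAC-inhibitor-like response on a two-fold serial
#' dilution: near-complete kill at the top dose, midpoint at 10 nM,
#' moderately steep slope, 5% multiplicative plate noise, biological
#' triplicates.
#'
#' @param emax Maximal kill fraction in `[0, 1]`.
#' @param ec50 Dose of half-maximal kill (nM), > 0.
#' @param hill Hill slope, > 0.
#' @param noise_sigma Standard deviation of multiplicative lognormal well
#'   noise (0 = noiseless).
#' @param n_replicates Biological replicates per well condition, >= 1.
#' @param doses Increasing dose grid (nM) including 0.
#' @return A list of class `"hill_spec"`.
#' @export
hill_spec <- function(emax = 0.95, ec50 = 10, hill = 1.5, noise_sigma = 0.05,
                      n_replicates = 3L,
                      doses = c(0, 1.25, 2.5, 5, 10, 20, 40, 80)) {
  if (emax < 0 || emax > 1) stop("emax must be in [0,1]", call. = FALSE)
  if (ec50 <= 0) stop("ec50 must be > 0", call. = FALSE)
  if (hill <= 0) stop("hill must be > 0", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  doses <- sort(unique(as.numeric(doses)))
  if (doses[1] != 0) stop("doses must include 0", call. = FALSE)
  structure(list(emax = emax, ec50 = ec50, hill = hill,
                 noise_sigma = noise_sigma,
                 n_replicates = as.integer(n_replicates), doses = doses),
            class = "hill_spec")
}

#' Combination-treatment specification
#'
#' Extends a [hill_spec()] with the two effects a pretreatment agent can
#' have: a uniform viability loss of its own (`pretreat_kill`, which anchor
#' normalization must cancel) and a left shift of the secondary drug's
#' potency (`potency_shift`, the fold reduction of EC50 in pretreated
#' lines; 1 means no synergy).
#'
#' @param base A [hill_spec()].
#' @param potency_shift Fold reduction of EC50 in the combination arm of
#'   synergistic lines, >= 1.
#' @param pretreat_kill Fraction of viability lost to the pretreatment agent
#'   alone, in `[0, 1)`.
#' @return A list of class `"combo_spec"`.
#' @export
combo_spec <- function(base = hill_spec(), potency_shift = 4,
                       pretreat_kill = 0.2) {
  stopifnot(inherits(base, "hill_spec"))
  if (potency_shift < 1) stop("potency_shift must be >= 1", call. = FALSE)
  if (pretreat_kill < 0 || pretreat_kill >= 1) {
    stop("pretreat_kill must be in [0,1)", call. = FALSE)
  }
  structure(list(base = base, potency_shift = potency_shift,
                 pretreat_kill = pretreat_kill),
            class = "combo_spec")
}

#' Closed-form Hill survival
#'
#' @param dose Dose vector (nM).
#' @param emax,ec50,hill Hill parameters.
#' @return Survival fraction at each dose.
#' @export
hill_survival <- function(dose, emax, ec50, hill) {
  1 - emax * dose^hill / (dose^hill + ec50^hill)
}

#' Simulate a viability plate panel with optional planted synergy
#'
#' Generates raw CellTiter-Glo-like luminescence wells for a panel of cell
#' lines, each with a single-agent arm (secondary drug alone) and a
#' combination arm (secondary drug after pretreatment). Well survival is
#' `(1 - pretreat_kill[combo arm]) * hill(dose; ec50_eff) * exp(eps)` with
#' `eps ~ N(0, noise_sigma^2)`; `ec50_eff = ec50 / potency_shift` applies
#' only to the combination arm of lines listed in `synergy_lines`. Dose-0
#' wells of the single-agent arm double as the untreated (media) controls.
#' Output is deterministic given `seed`.
#'
#' @param spec A [combo_spec()].
#' @param n_lines Number of cell lines.
#' @param synergy_lines Integer indices (in `1:n_lines`) of lines that carry
#'   the planted potency shift; default all lines.
#' @param seed Integer RNG seed.
#' @param primary_drug,secondary_drug Labels for the two agents.
#' @param baseline_signal Mean luminescence of an untreated well.
#' @return A plate-record data frame in the viability table dialect
#'   (columns as in [read_viability_table()]), with attribute
#'   `"synergy_lines"` naming the planted lines.
#' @export
simulate_viability_panel <- function(spec = combo_spec(), n_lines = 24,
                                     synergy_lines = seq_len(n_lines),
                                     seed = 1L,
                                     primary_drug = "EZH2i",
                                     secondary_drug = "panobinostat",
                                     baseline_signal = 20000) {
  stopifnot(inherits(spec, "combo_spec"))
  if (length(synergy_lines) > 0 &&
      (min(synergy_lines) < 1 || max(synergy_lines) > n_lines)) {
    stop("synergy_lines must index into 1:n_lines", call. = FALSE)
  }
  b <- spec$base
  set.seed(as.integer(seed))
  line_names <- sprintf("HMCL%02d", seq_len(n_lines))
  rows <- vector("list", n_lines * 2L)
  for (i in seq_len(n_lines)) {
    synergistic <- i %in% synergy_lines
    for (arm in c("single", "combo")) {
      is_combo <- arm == "combo"
      ec50_eff <- if (is_combo && synergistic) b$ec50 / spec$potency_shift
        else b$ec50
      pre <- if (is_combo) 1 - spec$pretreat_kill else 1
      grid <- expand.grid(dose = b$doses, replicate = seq_len(b$n_replicates),
                          KEEP.OUT.ATTRS = FALSE)
      mu <- pre * hill_survival(grid$dose, b$emax, ec50_eff, b$hill)
      eps <- if (b$noise_sigma > 0)
        stats::rnorm(nrow(grid), 0, b$noise_sigma) else 0
      rows[[(i - 1L) * 2L + 1L + is_combo]] <- data.frame(
        cell_line = line_names[i],
        primary_drug = if (is_combo) primary_drug else "none",
        primary_dose_uM = if (is_combo) 2 else 0,
        secondary_drug = secondary_drug,
        secondary_dose_nM = grid$dose,
        schedule = "pretreat_4d",
        replicate = grid$replicate,
        signal = baseline_signal * mu * exp(eps),
        is_normalized = FALSE,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "synergy_lines") <- line_names[intersect(seq_len(n_lines),
                                                     synergy_lines)]
  out
}

#' Differential-expression simulation specification
#'
#' Parameters of the three-condition DE-table generator. Genes are
#' partitioned into blocks: perturbed by agent A (up/down), perturbed by
#' agent B (up/down), perturbed only by the combination (split evenly
#' up/down), and null. A fraction `frac_shared_combo` of each single
#' agent's effects is retained in the combination table, emulating the
#' nesting of single-agent effects inside the combination that motivates
#' the unique-to-combination analysis. Defaults give roughly two thirds of
#' the combination's differentially expressed genes unique to the
#' combination.
#'
#' @param n_genes Number of genes.
#' @param frac_up_a,frac_down_a Fractions of genes up-/down-regulated by
#'   agent A.
#' @param frac_up_b,frac_down_b Same for agent B (small by default: at the
#'   doses modelled the second agent perturbs few genes on its own).
#' @param frac_shared_combo Fraction of each single agent's effect genes
#'   retained in the combination table.
#' @param frac_unique_combo Fraction of genes perturbed only in the
#'   combination.
#' @param effect_log2fc Mean planted `|log2 FC|` for perturbed genes.
#' @param baseline_fpkm_log_mean,baseline_fpkm_log_sd Lognormal (natural
#'   log) parameters of baseline expression.
#' @param dispersion Standard error of the observed log2 FC (per-gene noise
#'   scale; the simulated test statistic is `observed_lfc / dispersion`).
#' @param seed Integer RNG seed.
#' @return A list of class `"de_sim_spec"`.
#' @export
de_sim_spec <- function(n_genes = 10000, frac_up_a = 0.035,
                        frac_down_a = 0.035, frac_up_b = 0.005,
                        frac_down_b = 0.005, frac_shared_combo = 0.9,
                        frac_unique_combo = 0.15, effect_log2fc = 2,
                        baseline_fpkm_log_mean = log(10),
                        baseline_fpkm_log_sd = 1.2, dispersion = 0.25,
                        seed = 1L) {
  fr <- c(frac_up_a, frac_down_a, frac_up_b, frac_down_b, frac_unique_combo)
  if (any(fr < 0) || any(fr > 1) || frac_shared_combo < 0 ||
      frac_shared_combo > 1) {
    stop("fractions must lie in [0,1]", call. = FALSE)
  }
  if (sum(fr) > 1) {
    stop("effect fractions sum to more than 1; no null genes left",
         call. = FALSE)
  }
  if (effect_log2fc <= 0) stop("effect_log2fc must be > 0", call. = FALSE)
  if (dispersion <= 0) stop("dispersion must be > 0", call. = FALSE)
  structure(list(
    n_genes = as.integer(n_genes), frac_up_a = frac_up_a,
    frac_down_a = frac_down_a, frac_up_b = frac_up_b,
    frac_down_b = frac_down_b, frac_shared_combo = frac_shared_combo,
    frac_unique_combo = frac_unique_combo, effect_log2fc = effect_log2fc,
    baseline_fpkm_log_mean = baseline_fpkm_log_mean,
    baseline_fpkm_log_sd = baseline_fpkm_log_sd, dispersion = dispersion,
    seed = as.integer(seed)), class = "de_sim_spec")
}

# One simulated DE table: observed log2 FC = true log2 FC + N(0, dispersion);
# the simulated test statistic z = observed/dispersion gives exactly uniform
# p-values for null genes; FDR by Benjamini-Hochberg.
simulate_de_condition <- function(gene_id, fpkm_control, true_lfc,
                                  dispersion, condition) {
  obs_lfc <- true_lfc + stats::rnorm(length(gene_id), 0, dispersion)
  z <- obs_lfc / dispersion
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(
    gene_id = gene_id,
    fpkm_control = fpkm_control,
    fpkm_treated = fpkm_control * 2^obs_lfc,
    log2_fc = obs_lfc,
    p_value = p,
    fdr = stats::p.adjust(p, method = "BH"),
    condition = condition,
    stringsAsFactors = FALSE
  )
}

#' Simulate three-condition differential-expression tables
#'
#' Generates DE tables for agent A, agent B and the combination, with
#' planted effect genes per [de_sim_spec()] and ground-truth membership
#' returned alongside. Null genes have mean-zero observed log2 fold change
#' and exactly uniform p-values; planted genes carry effects of mean
#' magnitude `effect_log2fc` (jittered by 10% of the effect) and
#' correspondingly small p-values. The FDR column is the Benjamini-Hochberg
#' adjustment within each table.
#'
#' @param spec A [de_sim_spec()].
#' @return A list with `agent_a`, `agent_b`, `combo` (DE data frames in the
#'   generic dialect) and `truth` (lists of planted gene ids: `a_up`,
#'   `a_down`, `b_up`, `b_down`, `combo_unique_up`, `combo_unique_down`,
#'   `combo_retained_a`, `combo_retained_b`, `null`).
#' @export
simulate_de_tables <- function(spec = de_sim_spec()) {
  stopifnot(inherits(spec, "de_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_genes
  gene_id <- sprintf("G%05d", seq_len(n))
  fpkm_control <- stats::rlnorm(n, spec$baseline_fpkm_log_mean,
                                spec$baseline_fpkm_log_sd)

  # Disjoint category assignment by a seeded shuffle
  n_a_up <- round(spec$frac_up_a * n)
  n_a_dn <- round(spec$frac_down_a * n)
  n_b_up <- round(spec$frac_up_b * n)
  n_b_dn <- round(spec$frac_down_b * n)
  n_uni <- round(spec$frac_unique_combo * n)
  perm <- sample.int(n)
  take <- function(k) {
    idx <- perm[seq_len(k)]
    perm <<- perm[-seq_len(k)]
    idx
  }
  idx_a_up <- take(n_a_up); idx_a_dn <- take(n_a_dn)
  idx_b_up <- take(n_b_up); idx_b_dn <- take(n_b_dn)
  idx_uni <- take(n_uni)
  idx_uni_up <- idx_uni[seq_len(floor(n_uni / 2))]
  idx_uni_dn <- setdiff(idx_uni, idx_uni_up)
  idx_null <- perm

  effect <- function(idx, sign) {
    mag <- spec$effect_log2fc *
      (1 + stats::rnorm(length(idx), 0, 0.1))
    sign * pmax(mag, 0.1)
  }
  lfc_a <- numeric(n)
  lfc_a[idx_a_up] <- effect(idx_a_up, +1)
  lfc_a[idx_a_dn] <- effect(idx_a_dn, -1)
  lfc_b <- numeric(n)
  lfc_b[idx_b_up] <- effect(idx_b_up, +1)
  lfc_b[idx_b_dn] <- effect(idx_b_dn, -1)

  retain <- function(idx) {
    k <- round(spec$frac_shared_combo * length(idx))
    if (k == 0L) integer(0) else sample(idx, k)
  }
  kept_a <- retain(c(idx_a_up, idx_a_dn))
  kept_b <- retain(c(idx_b_up, idx_b_dn))
  lfc_c <- numeric(n)
  lfc_c[kept_a] <- lfc_a[kept_a]
  lfc_c[kept_b] <- lfc_b[kept_b]
  lfc_c[idx_uni_up] <- effect(idx_uni_up, +1)
  lfc_c[idx_uni_dn] <- effect(idx_uni_dn, -1)

  out <- list(
    agent_a = simulate_de_condition(gene_id, fpkm_control, lfc_a,
                                    spec$dispersion, "agent_a"),
    agent_b = simulate_de_condition(gene_id, fpkm_control, lfc_b,
                                    spec$dispersion, "agent_b"),
    combo = simulate_de_condition(gene_id, fpkm_control, lfc_c,
                                  spec$dispersion, "combo"),
    truth = list(
      a_up = gene_id[idx_a_up], a_down = gene_id[idx_a_dn],
      b_up = gene_id[idx_b_up], b_down = gene_id[idx_b_dn],
      combo_unique_up = gene_id[idx_uni_up],
      combo_unique_down = gene_id[idx_uni_dn],
      combo_retained_a = gene_id[kept_a],
      combo_retained_b = gene_id[kept_b],
      null = gene_id[idx_null]
    )
  )
  out
}
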