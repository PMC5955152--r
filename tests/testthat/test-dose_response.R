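make_records <- function(doses, signals, replicates = 1L, cell_line = "L1") {
  data.frame(cell_line = cell_line, secondary_dose_nM = doses,
             replicate = replicates, signal = signals,
             stringsAsFactors = FALSE)
}

test_that("normalization divides by the mean control signal", {
  rec <- make_records(c(0, 5, 10), c(10000, 8000, 5000))
  curve <- normalize_viability(rec)
  expect_equal(curve$survival, c(1.0, 0.8, 0.5))
  expect_equal(curve$doses, c(0, 5, 10))
})

test_that("normalization is invariant to rescaling all signals", {
  rec <- make_records(c(0, 5, 10, 20), c(10000, 9000, 6000, 2000))
  scaled <- rec
  scaled$signal <- scaled$signal * 3.7
  expect_equal(normalize_viability(rec)$survival,
               normalize_viability(scaled)$survival)
})

test_that("SEM is computed across replicate-wise normalized values", {
  rec <- make_records(c(0, 0, 5, 5), c(10000, 10000, 8000, 8400),
                      replicates = c(1, 2, 1, 2))
  curve <- normalize_viability(rec)
  expect_equal(curve$survival[2], 0.82)
  expect_equal(curve$sem[2], 0.02)
})

test_that("normalization guards its preconditions", {
  expect_error(normalize_viability(make_records(c(0, 5), c(0, 100))),
               "control")
  expect_error(normalize_viability(make_records(c(5, 5), c(90, 95)),
                                   control = 100),
               "2 distinct")
})

test_that("anchor normalization rescales to the zero-dose point", {
  curve <- survival_curve(c(0, 5, 10), c(0.6, 0.48, 0.30))
  anchored <- anchor_normalize(curve)
  expect_equal(anchored$survival, c(1.0, 0.8, 0.5))
})

test_that("anchor normalization is idempotent", {
  curve <- survival_curve(c(0, 5, 10), c(0.6, 0.48, 0.30))
  once <- anchor_normalize(curve)
  twice <- anchor_normalize(once)
  expect_identical(once$survival, twice$survival)
})

test_that("anchoring requires a positive zero-dose point", {
  expect_error(anchor_normalize(survival_curve(c(1, 10), c(1, 0.5))),
               "zero-dose")
  expect_error(anchor_normalize(survival_curve(c(0, 10), c(0, 0.5))),
               "positive")
})

test_that("AUSC of a constant curve equals height times axis span", {
  flat <- survival_curve(c(1, 10, 100, 1000), rep(1, 4))
  expect_equal(ausc(flat, "log10_dose"), 3.0)
  half <- survival_curve(c(1, 10, 100), rep(0.5, 3))
  expect_equal(ausc(half, "log10_dose"), 1.0)
})

test_that("AUSC reproduces hand-computed trapezoid sums", {
  curve <- survival_curve(c(1, 10, 100, 1000), c(1.0, 0.8, 0.5, 0.2))
  expect_equal(ausc(curve, "log10_dose"), 1.90)
  expect_equal(ausc(survival_curve(c(0, 1), c(1, 0)), "index"), 0.5)
})

test_that("log10 mode drops the zero dose and needs two nonzero points", {
  with0 <- survival_curve(c(0, 1, 10), c(1, 0.9, 0.4))
  without0 <- survival_curve(c(1, 10), c(0.9, 0.4))
  expect_equal(ausc(with0), ausc(without0))
  expect_error(ausc(survival_curve(c(0, 10), c(1, 0.4))), "nonzero")
})

test_that("AUSC matches an independent trapezoid oracle on random curves", {
  skip_if_not_installed("pracma")
  set.seed(11)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    doses <- sort(10^runif(n, -1, 3))
    y <- runif(n, 0, 1.2)
    curve <- survival_curve(doses, y)
    expect_equal(ausc(curve, "log10_dose"),
                 pracma::trapz(log10(doses), y), tolerance = 1e-12)
    expect_equal(ausc(curve, "index"),
                 pracma::trapz(seq_len(n) - 1, y), tolerance = 1e-12)
  }
})

test_that("identical curves score zero synergy", {
  curve <- survival_curve(c(1, 10, 100), c(1, 0.7, 0.3), cell_line = "L1")
  sc <- delta_ausc(curve, curve)
  expect_equal(sc$delta_ausc_rel, 0)
  expect_equal(sc$delta_ausc_abs, 0)
})

test_that("relative AUSC decrease matches the hand-computed value", {
  single <- survival_curve(c(1, 10, 100), c(1, 1, 1))
  combo <- survival_curve(c(1, 10, 100), c(1, 0, 0))
  sc <- delta_ausc(single, combo)
  expect_equal(sc$ausc_single, 2.0)
  expect_equal(sc$ausc_combo, 0.5)
  expect_equal(sc$delta_ausc_rel, 0.75)
})

test_that("a pointwise-dominated combination curve never scores negative", {
  set.seed(23)
  for (i in 1:25) {
    n <- sample(3:8, 1)
    doses <- sort(10^runif(n, 0, 3))
    s_single <- runif(n, 0.2, 1.2)
    s_combo <- s_single * runif(n, 0, 1)
    sc <- delta_ausc(survival_curve(doses, s_single),
                     survival_curve(doses, s_combo))
    expect_gte(sc$delta_ausc_rel, 0)
  }
})

test_that("synergy scoring guards grids and degenerate areas", {
  a <- survival_curve(c(1, 10, 100), c(1, 0.5, 0.2))
  b <- survival_curve(c(1, 10, 200), c(1, 0.5, 0.2))
  expect_error(delta_ausc(a, b), "dose grid")
  zero <- survival_curve(c(1, 10, 100), c(0, 0, 0))
  expect_error(delta_ausc(zero, a), "zero")
})

test_that("relative densitometry normalizes the mark/total ratio", {
  expect_equal(densitometry(c(0.5, 1.0), c(1.0, 1.0))$relative_methylation,
               0.5)
  expect_equal(densitometry(c(0.7, 1.3), c(0.7, 1.3))$relative_methylation,
               1.0)
  expect_equal(densitometry(c(0.3, 0.6), c(0.9, 0.6))$relative_methylation,
               1 / 3)
  expect_error(densitometry(c(0.3, 0), c(0.9, 0.6)), "total-H3")
  expect_error(densitometry(c(0.3, 0.6), c(0, 0.6)), "ratio")
})
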