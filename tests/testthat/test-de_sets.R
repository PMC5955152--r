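de_row <- function(gene_id, fdr, fpkm_c, fpkm_t, lfc) {
  data.frame(gene_id = gene_id, fpkm_control = fpkm_c, fpkm_treated = fpkm_t,
             log2_fc = lfc, p_value = fdr / 2, fdr = fdr,
             stringsAsFactors = FALSE)
}

test_that("the three-threshold filter routes genes by direction", {
  tab <- rbind(de_row("r1", 0.01, 5, 20, 2),
               de_row("r2", 0.20, 5, 20, 2),
               de_row("r3", 0.01, 5, 7, 0.49),
               de_row("r4", 0.01, 0.2, 0.8, 2),
               de_row("r5", 0.01, 8, 2, -2))
  gs <- filter_de(tab, filter_spec())
  expect_equal(gs$up, "r1")
  expect_equal(gs$down, "r5")
})

test_that("infinite fold changes always satisfy the fold-change criterion", {
  tab <- rbind(de_row("on", 0.01, 0, 10, Inf),
               de_row("off", 0.01, 10, 0, -Inf))
  gs <- filter_de(tab, filter_spec())
  expect_equal(gs$up, "on")
  expect_equal(gs$down, "off")
})

test_that("FDR is strict and FPKM inclusive at their boundaries", {
  tab <- rbind(de_row("at_fdr", 0.05, 5, 20, 2),
               de_row("at_fpkm", 0.01, 0.2, 1, 2.4),
               de_row("at_fc", 0.01, 5, 10, 1))
  gs <- filter_de(tab, filter_spec())
  expect_false("at_fdr" %in% members(gs))
  expect_true("at_fpkm" %in% gs$up)
  expect_true("at_fc" %in% gs$up)
})

test_that("directionless passing genes are excluded with a message", {
  tab <- rbind(de_row("flat", 0.01, 5, 5, 0),
               de_row("up", 0.01, 5, 20, 2))
  # a zero log2 FC can only pass the thresholds when fc_min is at its floor
  expect_message(gs <- filter_de(tab, filter_spec(fc_min = 1)),
                 "no direction")
  expect_equal(members(gs), "up")
})

test_that("relaxing any threshold never shrinks the passing set", {
  set.seed(31)
  for (i in 1:20) {
    n <- 200
    tab <- data.frame(
      gene_id = sprintf("g%03d", 1:n),
      fpkm_control = rlnorm(n, 1, 1.5),
      fpkm_treated = rlnorm(n, 1, 1.5),
      log2_fc = rnorm(n, 0, 1.5),
      p_value = runif(n),
      fdr = runif(n),
      stringsAsFactors = FALSE
    )
    base <- members(filter_de(tab, filter_spec(0.05, 1, 2)))
    relaxed <- list(filter_spec(0.2, 1, 2), filter_spec(0.05, 0.5, 2),
                    filter_spec(0.05, 1, 1.5))
    for (sp in relaxed) {
      expect_true(all(base %in% members(filter_de(tab, sp))))
    }
  }
})

test_that("pairwise overlap counts shared and exclusive regions", {
  a <- gene_set(up = c("A", "B"), down = "C", condition = "a")
  b <- gene_set(up = c("B", "D"), down = "C", condition = "b")
  vc <- overlap(a, b)
  expect_equal(unname(vc$region_counts[["a&b"]]), 2L)
  expect_equal(sum(vc$region_counts), vc$n_union)
  expect_equal(shared_count(a, b), 2L)
  disjoint <- overlap(gene_set(up = "x", condition = "a"),
                      gene_set(up = "y", condition = "b"))
  expect_equal(unname(disjoint$region_counts[["a&b"]]), 0L)
  expect_equal(sum(disjoint$region_counts), 2L)
})

test_that("direction-aware overlap separates discordant genes", {
  a <- gene_set(up = "g1", down = "g2", condition = "a")
  b <- gene_set(up = c("g1", "g2"), condition = "b")
  expect_equal(shared_count(a, b, direction_aware = TRUE), 1L)
  expect_equal(shared_count(a, b, direction_aware = FALSE), 2L)
  vc <- overlap(a, b, direction_aware = TRUE)
  expect_equal(unname(vc$region_counts[["a&b"]]), 1L)
})

test_that("Venn regions match brute-force enumeration on random 3-set instances", {
  set.seed(41)
  genes <- sprintf("g%04d", 1:300)
  for (i in 1:25) {
    sets <- list(A = random_gene_set(genes, 0.2, "A"),
                 B = random_gene_set(genes, 0.3, "B"),
                 C = random_gene_set(genes, 0.4, "C"))
    vc <- overlap(sets$A, sets$B, sets$C)
    expected <- brute_venn(lapply(sets, members))
    expect_equal(as.integer(vc$region_counts[names(expected)]),
                 unname(expected))
    expect_equal(sum(vc$region_counts), vc$n_union)
  }
})

test_that("unique-to-combination is the set difference from both agents", {
  combo <- gene_set(up = c("g1", "g2", "g3"), down = c("g4", "g5"),
                    condition = "combo")
  a <- gene_set(up = "g1", condition = "a")
  b <- gene_set(down = "g2", condition = "b")
  u <- unique_to_combination(a, b, combo)
  expect_setequal(members(u), c("g3", "g4", "g5"))
  expect_equal(u$up, "g3")
  subset_case <- unique_to_combination(combo, b, combo)
  expect_equal(length(members(subset_case)), 0L)
})

test_that("unique-to-combination partitions the combination set disjointly", {
  set.seed(43)
  genes <- sprintf("g%04d", 1:500)
  for (i in 1:20) {
    a <- random_gene_set(genes, 0.2, "a")
    b <- random_gene_set(genes, 0.1, "b")
    combo <- random_gene_set(genes, 0.4, "combo")
    u <- unique_to_combination(a, b, combo)
    expected <- setdiff(members(combo), union(members(a), members(b)))
    expect_setequal(members(u), expected)
    shared_part <- intersect(members(combo), union(members(a), members(b)))
    expect_setequal(c(members(u), shared_part), members(combo))
    expect_length(intersect(members(u), shared_part), 0)
    expect_length(intersect(u$up, u$down), 0)
  }
})

test_that("persistence report counts direction-aware retention", {
  e <- gene_set(up = c("a", "b"), condition = "d1")
  l <- gene_set(up = c("a", "b", "c"), condition = "d4")
  expect_equal(persistence_report(e, l)$retained_fraction, 1.0)
  flipped <- gene_set(up = "b", down = "a", condition = "d4")
  expect_equal(persistence_report(e, flipped)$retained_fraction, 0.5)
  empty <- gene_set(condition = "d1")
  expect_true(is.na(persistence_report(empty, l)$retained_fraction))
})

test_that("gene sets reject overlapping direction labels", {
  expect_error(gene_set(up = "g1", down = "g1"), "disjoint")
})
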