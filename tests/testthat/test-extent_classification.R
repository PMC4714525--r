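test_that("chi-square on the value balance matches hand substitution", {
  r <- ratio_chi_square(40, 60)
  expect_equal(r$chi2, 4)                      # (10^2/50) * 2
  expect_equal(r$p_value, stats::pchisq(4, 1, lower.tail = FALSE))
  r <- ratio_chi_square(100, 100)
  expect_equal(r$chi2, 0)
  expect_equal(r$p_value, 1)
  r <- ratio_chi_square(232.23, 75.65)         # printed grouping means
  expect_equal(round(r$chi2, 2), 25.86)
  expect_lt(r$p_value, 1e-6)
  expect_error(ratio_chi_square(0, 0), "both values zero")
})

test_that("chi-square is symmetric and monotone in the imbalance", {
  set.seed(31)
  a <- stats::runif(200, 0, 500)
  b <- stats::runif(200, 0, 500)
  expect_equal(ratio_chi_square(a, b)$chi2, ratio_chi_square(b, a)$chi2)
  d <- seq(0, 0.49, by = 0.01)
  chi <- ratio_chi_square(50 * (1 + d), 50 * (1 - d))$chi2
  expect_true(all(diff(chi) > 0))
})

test_that("extent categories follow the alpha rule and direction", {
  q <- quant_row(c("eq", "low", "hi", "border", "un"),
                 mfpkm = c(100, 40, 75, 55, 0),
                 fpkm = c(100, 60, 25, 45, 10),
                 m6a_count = c(8, 8, 8, 8, 0))
  calls <- classify_extent(q)
  expect_equal(nrow(calls), 4L)                # unmethylated excluded
  got <- stats::setNames(calls$category, calls$transcript_id)
  expect_equal(got[["eq"]], "Equivalent")
  expect_equal(got[["low"]], "Low")            # p ~ 0.0455 < 0.05
  expect_equal(got[["hi"]], "High")
  expect_equal(got[["border"]], "Equivalent")  # chi2 = 1, p ~ 0.317
})

test_that("category tabulation reproduces published percentage arithmetic", {
  path <- system.file("extdata", "extent_category_counts.tsv",
                      package = "m6aquant")
  ref <- read_table(path)
  out <- extent_percentages(ref[, c("replicate", "organ", "high", "low",
                                    "equivalent")])
  body <- out[out$organ != "average", ]
  m <- match(paste(ref$replicate, ref$organ),
             paste(body$replicate, body$organ))
  # printed-precision agreement; one cell is a known last-digit artifact
  expect_true(all(abs(body$high_pct[m] - ref$high_pct) <= 0.1))
  expect_true(all(abs(body$low_pct[m] - ref$low_pct) <= 0.1))
  expect_true(all(abs(body$equivalent_pct[m] - ref$equivalent_pct) <= 0.1))
  exact <- !(ref$replicate == 1 & ref$organ == "Flowers")
  expect_equal(body$equivalent_pct[m][exact], ref$equivalent_pct[exact])
  # percentages sum to 100 within rounding
  sums <- body$high_pct + body$low_pct + body$equivalent_pct
  expect_true(all(abs(sums - 100) <= 0.1))
  # one call -> 100%
  one <- tabulate_extent(classify_extent(quant_row("x", 90, 10)))
  expect_equal(one$high_pct[one$organ != "average"], 100)
})

test_that("expression tertiles split, average and ratio correctly", {
  set.seed(32)
  mk <- function(n, fpkm_mu, ratio_mu, prefix) {
    fpkm <- fpkm_mu + stats::runif(n, -1, 1)
    quant_row(sprintf("%s%02d", prefix, 1:n),
              mfpkm = fpkm * (ratio_mu + stats::runif(n, -0.1, 0.1)),
              fpkm = fpkm)
  }
  q <- rbind(mk(7, 100, 2, "a"), mk(7, 30, 5, "b"), mk(6, 5, 10, "c"))
  g <- grouping_summary(q)
  expect_equal(g$groups$grouping, c("High", "Moderate", "Low"))
  expect_equal(g$groups$n, c(7, 7, 6))         # remainder to earlier groups
  expect_equal(g$groups$ratio,
               g$groups$mean_mfpkm / g$groups$mean_fpkm)
  expect_true(all(g$t_tests$p_value < 0.01))   # planted ratio separation
  # degenerate input flags the t-test rather than crashing
  qd <- quant_row(sprintf("t%d", 1:6), mfpkm = 50, fpkm = 50)
  gd <- grouping_summary(qd)
  expect_equal(gd$groups$ratio, rep(1, 3))
  expect_true(all(is.na(gd$t_tests$p_value)))
  expect_error(grouping_summary(quant_row("x", 1, 1)), "at least 3")
})

test_that("extensive-methylation filter applies all three thresholds and replicates", {
  mk <- function(rep) {
    q <- quant_row(c("pass", "lowfold", "lowreads", "flaky"),
                   mfpkm = c(1200, 500, 1200, 1200),
                   fpkm = c(100, 100, 100, 100),
                   m6a_count = c(50, 50, 10, ifelse(rep == 1, 50, 10)),
                   replicate = rep)
    calls <- classify_extent(q)
    calls$fdr <- 1e-15                          # deep-significance regime
    calls
  }
  calls <- rbind(mk(1), mk(2))
  sets <- call_extensively_methylated(calls)
  # fold >= 10 and reads >= 30 in both replicates: only "pass" survives
  expect_equal(sets$leaves, "pass")
  expect_equal(intersect_organs(list(c("a", "b"), c("b", "c"), c("b"))), "b")
})

test_that("planted extreme methylation is recovered by the extensive filter", {
  # strong-contrast preset: typical transcripts at low methylation level so
  # the extreme group realizes MFPKM:FPKM ratios beyond the fold-10 filter
  p <- sim_params(n_transcripts = 300, depth = 1.5e5, seed = 33,
                  organs = "leaves", replicates = 1,
                  meth_base = 0.05, frac_extreme = 0.07, dm_fraction = 0)
  ref <- generate_reference(p)
  libs <- simulate_libraries(ref, p, assays = c("m6A", "mRNA"))
  q <- quantify(libs$leaves_rep1_m6A, libs$leaves_rep1_mRNA, ref$models)
  calls <- classify_extent(q)
  sets <- call_extensively_methylated(calls)
  tr <- ref$truth$transcripts
  planted <- tr$transcript_id[tr$extent_group == "extreme"]
  expect_gte(length(planted), 10)
  expect_gte(mean(planted %in% sets$leaves), 0.9)
})
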