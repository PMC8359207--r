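# The qsip() estimator and its methods.

test_that("identical treatments give MWE 0 and no active calls", {
  counts <- cmat(c(10, 40, 10,   5, 20, 30,
                   10, 40, 10,   5, 20, 30),
                 c("O1", "O2"),
                 c("U1", "U2", "U3", "L1", "L2", "L3"))
  u <- tiny_profile("IU", isotope = "unlabelled", prefix = "U")
  l <- tiny_profile("IL", isotope = "labelled", prefix = "L")
  fit <- qsip(otu_count_table(counts), u, l)
  expect_equal(fit$results$mwe, c(0, 0), tolerance = 1e-12)
  expect_false(any(fit$results$active))
  expect_equal(fit$results$delta_w, c(0, 0), tolerance = 1e-12)
})

test_that("OTUs absent from one member are excluded with a reason", {
  counts <- cmat(c(10, 40, 10,   0, 0, 0,
                   10, 40, 10,   5, 20, 30,
                   0, 0, 0,      5, 20, 30),
                 c("O1", "O2", "O3"),
                 c("U1", "U2", "U3", "L1", "L2", "L3"))
  u <- tiny_profile("IU", isotope = "unlabelled", prefix = "U")
  l <- tiny_profile("IL", isotope = "labelled", prefix = "L")
  fit <- qsip(otu_count_table(counts), u, l)
  expect_identical(fit$results$otu_id, "O2")
  expect_identical(fit$excluded$reason[fit$excluded$otu_id == "O1"],
                   "absent_in_labelled")
  expect_identical(fit$excluded$reason[fit$excluded$otu_id == "O3"],
                   "absent_in_unlabelled")
})

test_that("pair validation rejects mismatched members", {
  sim <- noiseless_sim()
  other <- tiny_profile("IX", substrate = "PRO", isotope = "labelled",
                        prefix = "Z")
  expect_error(qsip(sim$counts, sim$unlabelled, other), "substrate")
  expect_error(qsip(sim$counts, sim$labelled, sim$labelled), "isotope")
})

test_that("MWE is invariant under uniform rescaling of copy numbers", {
  sim <- noiseless_sim()
  fit1 <- qsip(sim$counts, sim$unlabelled, sim$labelled)
  # scaling a whole member's read counts leaves relative abundances, hence
  # copies up to a common factor, hence every MWE, unchanged
  scaled <- sim$counts
  lab_cols <- sim$labelled$fractions$sample_id
  scaled$counts[, lab_cols] <- scaled$counts[, lab_cols] * 5
  fit2 <- qsip(scaled, sim$unlabelled, sim$labelled)
  expect_equal(coef(fit2), coef(fit1), tolerance = 1e-12)
  # and the WAD -> MWE chain itself is scale-free in the copy vector
  dens <- sim$labelled$fractions$density
  copies <- sim$counts$counts["OTU_0003", lab_cols]
  expect_equal(weighted_average_density(copies * 1e3, dens),
               weighted_average_density(copies, dens))
})

test_that("carbon-only mode reproduces single-isotope qSIP behaviour", {
  sim <- noiseless_sim()
  fit <- qsip(sim$counts, sim$unlabelled, sim$labelled, isotopes = "C")
  r <- fit$results
  # the maximum increment is the carbon term alone...
  expect_equal(r$m_heavymax - r$m_light, carbon_max_increment(r$gc))
  # ...so the same density shift maps to a larger excess than in CN mode
  cn <- qsip(sim$counts, sim$unlabelled, sim$labelled)$results
  shifted <- r$mwe > 1e-6
  expect_true(all(r$mwe[shifted] > cn$mwe[shifted]))
  ratio <- (cn$m_heavymax - cn$m_light) / (r$m_heavymax - r$m_light)
  expect_equal(r$mwe, cn$mwe * ratio, tolerance = 1e-12)
})

test_that("fit methods expose estimates, summaries and curves", {
  sim <- noiseless_sim()
  fit <- qsip(sim$counts, sim$unlabelled, sim$labelled)
  expect_named(coef(fit), fit$results$otu_id)
  s <- summary(fit)
  expect_s3_class(s, "summary.qsip")
  expect_equal(s$n_active, sum(fit$results$active))
  expect_output(print(fit), "Active at MWE")
  expect_output(print(s), "Weighted average density")
  pdf(NULL)
  on.exit(dev.off())
  cur <- plot(fit, "OTU_0004")
  expect_equal(max(cur$normalized[cur$treatment == "labelled"]), 1)
})

test_that("fraction bootstrap brackets the point estimate", {
  truth <- simulation_truth(10, true_mwe = 0.3, seed = 2)
  sim <- simulate_gradient_pair(truth, reads_per_sample = 5e4, seed = 2)
  fit <- qsip(sim$counts, sim$unlabelled, sim$labelled)
  bs <- qsip_bootstrap(fit, n_boot = 99, seed = 3)
  expect_equal(nrow(bs), nrow(fit$results))
  ok <- bs$n_valid > 50
  expect_true(all(bs$mwe_lo[ok] <= bs$mwe[ok] + 0.02))
  expect_true(all(bs$mwe_hi[ok] >= bs$mwe[ok] - 0.02))
  # intervals are wide (a band spans only ~4 of 13 fractions) but bounded
  expect_lt(stats::median(bs$mwe_hi[ok] - bs$mwe_lo[ok]), 0.6)
})

test_that("pipeline runs end-to-end from files and is deterministic", {
  truth <- simulation_truth(30, true_mwe = rep(c(0, 0.4), 15), seed = 5)
  sim <- simulate_gradient_pair(truth, reads_per_sample = 2e4, seed = 5)
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  out1 <- file.path(dir, "out1"); out2 <- file.path(dir, "out2")
  fits <- suppressMessages(
    qsip_pipeline(paths[["fractions"]], paths[["otu"]], paths[["taxonomy"]],
                  outdir = out1))
  expect_named(fits, "DOM")
  res <- read_qsip_results(file.path(out1, "qsip_results_DOM.tsv"))
  expect_gt(nrow(res), 0)
  expect_true(any(res$active))
  suppressMessages(
    qsip_pipeline(paths[["fractions"]], paths[["otu"]], paths[["taxonomy"]],
                  outdir = out2))
  expect_identical(readLines(file.path(out1, "qsip_results_DOM.tsv")),
                   readLines(file.path(out2, "qsip_results_DOM.tsv")))
})
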