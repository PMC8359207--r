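# Readers, writers and the data model.

test_that("fraction metadata reads into one profile per incubation", {
  path <- write_metadata_file(default_metadata_df(13))
  profiles <- read_fraction_metadata(path)
  expect_length(profiles, 1)
  p <- profiles[["INC1"]]
  expect_s3_class(p, "gradient_profile")
  expect_equal(nrow(p$fractions), 13)
  expect_equal(p$substrate, "DOM")
  expect_equal(p$fractions$density[1], 1.78)
  expect_equal(p$dna_loaded, 4)  # default DNA load
})

test_that("tab-separated metadata and optional columns are handled", {
  df <- default_metadata_df(5)
  df$dna_loaded_ug <- 4
  df$dna_extracted_ug <- 8
  df$volume_filtered_l <- 10
  path <- write_metadata_file(df, sep = "\t")
  p <- read_fraction_metadata(path)[["INC1"]]
  expect_equal(p$dna_extracted, 8)
  expect_equal(p$volume_filtered, 10)
})

test_that("header-only metadata gives an empty list", {
  path <- write_metadata_file(default_metadata_df(0))
  expect_identical(read_fraction_metadata(path), list())
})

test_that("metadata format errors name the column or line", {
  df <- default_metadata_df(5)
  bad <- df[setdiff(names(df), "density_g_per_ml")]
  expect_error(read_fraction_metadata(write_metadata_file(bad)),
               "density_g_per_ml")
  df2 <- default_metadata_df(5)
  df2$density_g_per_ml <- as.character(df2$density_g_per_ml)
  df2$density_g_per_ml[3] <- "abc"   # file line 4 (after header)
  expect_error(read_fraction_metadata(write_metadata_file(df2)), "line 4")
})

test_that("profile invariants are enforced", {
  expect_error(tiny_profile(densities = c(1.9, 1.7, 1.66)), "CsCl range")
  expect_error(tiny_profile(totals = c(-1, 10, 10)), "non-negative")
  expect_error(tiny_profile(totals = c(0, 0, 10)), "fewer than 3")
  fr <- data.frame(sample_id = c("a", "b", "c"),
                   fraction_index = c(1, 1, 2),
                   density = c(1.7, 1.71, 1.72),
                   total_copies = c(1, 1, 1))
  expect_error(gradient_profile("X", "DOM", "unlabelled", fr),
               "duplicate fraction_index")
})

test_that("OTU tables parse both layouts, attach taxonomy, reject bad input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("otu_id\tS1\tS2", "OTU_1\t5\t0", "OTU_2\t1\t2",
               "OTU_3\t0\t7"), path)
  taxpath <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("otu_id\tlineage",
               "OTU_1\tBacteria;Proteobacteria;Gammaproteobacteria",
               "OTU_2\tArchaea;Woesearchaeota"), taxpath)
  expect_warning(tab <- read_otu_table(path, taxpath), "Unassigned")
  expect_equal(unname(colSums(tab$counts)), c(6, 9))
  expect_equal(unname(tab$taxonomy["OTU_3"]), "Unassigned")
  expect_match(tab$taxonomy[["OTU_1"]], "Gammaproteobacteria")

  # transposed layout: samples in rows
  tpath <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tOTU_1\tOTU_2\tOTU_3", "S1\t5\t1\t0",
               "S2\t0\t2\t7"), tpath)
  tab2 <- read_otu_table(tpath)
  expect_equal(tab2$counts, tab$counts, ignore_attr = FALSE)

  # duplicate OTU id
  dpath <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("otu_id\tS1", "OTU_1\t5", "OTU_1\t2"), dpath)
  expect_error(read_otu_table(dpath), "OTU_1")

  # fractional counts
  fpath <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("otu_id\tS1", "OTU_1\t2.5"), fpath)
  expect_error(read_otu_table(fpath), "fractional")

  expect_error(otu_count_table(cmat(c(-1, 2), "OTU_1", c("S1", "S2"))),
               "non-negative")
})

test_that("results write/read round-trips values to 1e-9", {
  sim <- noiseless_sim()
  fit <- qsip(sim$counts, sim$unlabelled, sim$labelled)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_qsip_results(fit, path)
  back <- read_qsip_results(path)
  expect_equal(names(back), names(fit$results))
  for (col in c("w_light", "w_lab", "delta_w", "gc", "m_light", "m_lab",
                "m_heavymax", "mwe", "copies_labelled"))
    expect_equal(back[[col]], fit$results[[col]], tolerance = 1e-9)
  expect_identical(back$active, fit$results$active)
  expect_identical(back$otu_id, fit$results$otu_id)

  # empty result set writes a header-only file
  empty <- fit
  empty$results <- fit$results[0, ]
  write_qsip_results(empty, path)
  expect_equal(nrow(read_qsip_results(path)), 0)
})

test_that("simulated experiments round-trip through the file formats", {
  truth <- simulation_truth(6, seed = 7)
  sim <- simulate_gradient_pair(truth, reads_per_sample = 1000, seed = 7)
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  expect_true(all(file.exists(paths)))
  profiles <- read_fraction_metadata(paths[["fractions"]])
  expect_length(profiles, 2)
  expect_equal(profiles[["DOM_unlabelled"]]$fractions$total_copies,
               sim$unlabelled$fractions$total_copies, tolerance = 1e-9)
  tab <- read_otu_table(paths[["otu"]], paths[["taxonomy"]])
  expect_identical(tab$counts, sim$counts$counts)
  expect_identical(tab$taxonomy, sim$counts$taxonomy)
})
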