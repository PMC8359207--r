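# Small in-code fixtures shared across test files.

# a 3-fraction profile with round numbers
tiny_profile <- function(incubation_id = "INC_U", substrate = "DOM",
                         isotope = "unlabelled",
                         densities = c(1.74, 1.70, 1.66),
                         totals = c(1000, 4000, 2000),
                         prefix = "U", ...) {
  gradient_profile(
    incubation_id, substrate, isotope,
    fractions = data.frame(
      sample_id = paste0(prefix, seq_along(densities)),
      fraction_index = seq_along(densities),
      density = densities,
      total_copies = totals),
    ...)
}

# counts matrix with named dims
cmat <- function(values, otus, samples) {
  matrix(values, nrow = length(otus), ncol = length(samples), byrow = TRUE,
         dimnames = list(otus, samples))
}

# write a fraction metadata file (csv) and return its path
write_metadata_file <- function(df, sep = ",") {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

default_metadata_df <- function(n = 13, incubation_id = "INC1",
                                isotope = "unlabelled") {
  m <- max(n, 1L)
  df <- data.frame(
    sample_id = paste0("S", seq_len(m)),
    incubation_id = incubation_id,
    substrate = "DOM",
    isotope = isotope,
    fraction_index = seq_len(m),
    density_g_per_ml = seq(1.78, 1.66, length.out = m),
    total_16s_copies = rep(1e5, m))
  utils::head(df, n)
}

# a small analytic (noiseless) simulated pair for fit-level tests
noiseless_sim <- function(n = 12, mwe = rep(c(0, 0.14, 0.5, 1), 3),
                          gc = seq(0.3, 0.7, length.out = n), seed = 1) {
  truth <- simulation_truth(n, gc = gc, true_mwe = mwe,
                            rel_abundance = rep(1, n), seed = seed)
  simulate_gradient_pair(truth, density_range = c(1.64, 1.80),
                         qpcr_cv = 0, analytic = TRUE, seed = seed)
}
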