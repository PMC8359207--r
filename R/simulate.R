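#' Buoyant density of unlabelled DNA from GC content
#'
#' Forward linear relation \eqn{\rho = 1.646057 + 0.083506\,G}; the exact
#' inverse of \code{\link{gc_from_light_density}}.
#'
#' @param gc GC content, proportion in \[0, 1\].
#' @return Buoyant density in g ml^-1.
#' @export
density_from_gc <- function(gc) {
  check_gc(gc)
  qsip_constants$density_intercept + qsip_constants$density_slope * gc
}

#' Ground truth for a simulated gradient experiment
#'
#' Per-OTU ground truth consumed by \code{\link{simulate_gradient_pair}}.
#' Defaults describe a plausible anoxic-water community: GC contents uniform
#' over \[0.3, 0.7\], lognormal abundance spectrum, no label uptake unless
#' \code{true_mwe} (or the per-element atom fraction excesses) is supplied.
#'
#' @param n_otus number of OTUs.
#' @param gc GC proportions (recycled; default drawn uniform on
#'   \code{gc_range}).
#' @param true_mwe true molecular weight excess in \[0, 1\] (recycled,
#'   default 0). Used in \code{mode = "mwe"}.
#' @param afe_c,afe_n per-element atom fraction excesses in \[0, 1\]
#'   (recycled, default 0). Used in \code{mode = "per_element"}.
#' @param rel_abundance relative abundances; normalised to sum to 1
#'   (default lognormal, sdlog 1).
#' @param band_sigma Gaussian band width in density units (g ml^-1,
#'   default 0.006: a band spans roughly 3--4 of 13 fractions).
#' @param gc_range range for default GC draws.
#' @param seed integer seed for the default random draws.
#' @return Data frame of class \code{"simulation_truth"}: \code{otu_id},
#'   \code{gc}, \code{true_mwe}, \code{afe_c}, \code{afe_n},
#'   \code{rel_abundance}, \code{band_sigma}.
#' @export
simulation_truth <- function(n_otus, gc = NULL, true_mwe = 0, afe_c = 0,
                             afe_n = 0, rel_abundance = NULL,
                             band_sigma = 0.006, gc_range = c(0.3, 0.7),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(gc)) gc <- stats::runif(n_otus, gc_range[1], gc_range[2])
  if (is.null(rel_abundance))
    rel_abundance <- stats::rlnorm(n_otus, sdlog = 1)
  gc <- rep_len(gc, n_otus)
  true_mwe <- rep_len(true_mwe, n_otus)
  afe_c <- rep_len(afe_c, n_otus)
  afe_n <- rep_len(afe_n, n_otus)
  check_gc(gc)
  if (any(true_mwe < 0 | true_mwe > 1))
    stop("`true_mwe` must lie in [0, 1]", call. = FALSE)
  if (any(afe_c < 0 | afe_c > 1) || any(afe_n < 0 | afe_n > 1))
    stop("atom fraction excesses must lie in [0, 1]", call. = FALSE)
  if (any(rel_abundance < 0) || sum(rel_abundance) <= 0)
    stop("`rel_abundance` must be non-negative with positive sum",
         call. = FALSE)
  out <- data.frame(
    otu_id = sprintf("OTU_%04d", seq_len(n_otus)),
    gc = gc,
    true_mwe = true_mwe,
    afe_c = afe_c,
    afe_n = afe_n,
    rel_abundance = rel_abundance / sum(rel_abundance),
    band_sigma = rep_len(band_sigma, n_otus),
    stringsAsFactors = FALSE)
  class(out) <- c("simulation_truth", "data.frame")
  out
}

#' Expected labelled-treatment buoyant density
#'
#' The forward model: place the unlabelled band at
#' \code{\link{density_from_gc}}, convert label uptake into a molecular
#' weight gain, and scale density proportionally to molecular weight,
#' \eqn{W_{lab} = W_{light} \, M_{lab} / M_{light}}.
#'
#' In \code{mode = "mwe"} the gain is \code{true_mwe} times the maximum
#' dual-isotope increment; in \code{mode = "per_element"} it is
#' \code{afe_c} times the carbon maximum plus \code{afe_n} times the
#' nitrogen maximum.
#'
#' @param gc GC proportion.
#' @param true_mwe molecular weight excess in \[0, 1\] (mode \code{"mwe"}).
#' @param afe_c,afe_n per-element atom fraction excesses (mode
#'   \code{"per_element"}).
#' @param mode \code{"mwe"} (default) or \code{"per_element"}.
#' @param max_heavy_mode passed to \code{\link{max_heavy_mw_dual}} in mode
#'   \code{"mwe"}.
#' @return Expected labelled buoyant density in g ml^-1; strictly
#'   increasing in the degree of labelling.
#' @export
expected_labelled_density <- function(gc, true_mwe = 0, afe_c = 0, afe_n = 0,
                                      mode = c("mwe", "per_element"),
                                      max_heavy_mode = c("printed",
                                                         "per_element")) {
  mode <- match.arg(mode)
  max_heavy_mode <- match.arg(max_heavy_mode)
  w_light <- density_from_gc(gc)
  m_light <- light_molecular_weight(gc)
  m_lab <- if (mode == "mwe") {
    m_heavymax <- max_heavy_mw_dual(gc, m_light, mode = max_heavy_mode)
    m_light + true_mwe * (m_heavymax - m_light)
  } else {
    m_light + afe_c * carbon_max_increment(gc) +
      afe_n * nitrogen_max_increment(gc)
  }
  w_light * m_lab / m_light
}

# Gaussian band mass per fraction bin; outer bins absorb the tails so each
# band's masses sum to exactly 1.
.band_masses <- function(centre, sigma, edges) {
  n <- length(edges) - 1L
  lo <- c(-Inf, edges[2:n])
  hi <- c(edges[2:n], Inf)
  stats::pnorm(hi, centre, sigma) - stats::pnorm(lo, centre, sigma)
}

#' Simulate a paired unlabelled/labelled gradient experiment
#'
#' Forward-simulates the full measurement process for one treatment pair:
#' each OTU's DNA forms a Gaussian band in the CsCl gradient centred at its
#' expected buoyant density (unlabelled: from GC; labelled: shifted by label
#' uptake via \code{\link{expected_labelled_density}}), band mass is
#' integrated over equal-width density bins via the Gaussian CDF, sequencing
#' draws multinomial read counts per fraction at finite depth, and qPCR
#' totals receive multiplicative lognormal noise. Fully reproducible from
#' \code{seed}.
#'
#' Fraction densities are the bin midpoints; \code{fraction_index} 1 is the
#' heaviest fraction, following collection order. The outermost bins absorb
#' the band tails, so per-OTU masses sum exactly to the OTU's total
#' abundance; choose \code{density_range} wide enough that bands sit well
#' inside the gradient.
#'
#' @param truth a \code{\link{simulation_truth}} data frame.
#' @param n_fractions number of fractions (default 13).
#' @param density_range gradient span in g ml^-1 (default
#'   \code{c(1.660, 1.780)}, centred near a 1.725 loading density).
#' @param reads_per_sample sequencing depth per fraction-sample
#'   (default 1e5).
#' @param qpcr_total true total 16S copies loaded per gradient
#'   (default 1e7).
#' @param qpcr_cv coefficient of variation of qPCR totals (default 0.10;
#'   0 disables noise).
#' @param mode \code{"mwe"} or \code{"per_element"} labelling model.
#' @param max_heavy_mode maximum-increment convention for mode
#'   \code{"mwe"}.
#' @param analytic if \code{TRUE}, bypass multinomial sampling and store
#'   exact expected copy masses as the count table (non-integer), enabling
#'   exact round-trip tests.
#' @param substrate substrate label for the simulated pair (default
#'   \code{"DOM"}).
#' @param seed integer seed; identical seeds give identical output.
#' @return List of class \code{"sip_simulation"}: \code{unlabelled} and
#'   \code{labelled} \code{\link{gradient_profile}}s, \code{counts}
#'   (\code{\link{otu_count_table}} over all 2 x n_fractions samples),
#'   \code{truth} (echo), and \code{config}.
#' @export
simulate_gradient_pair <- function(truth, n_fractions = 13,
                                   density_range = c(1.660, 1.780),
                                   reads_per_sample = 1e5,
                                   qpcr_total = 1e7, qpcr_cv = 0.10,
                                   mode = c("mwe", "per_element"),
                                   max_heavy_mode = c("printed",
                                                      "per_element"),
                                   analytic = FALSE, substrate = "DOM",
                                   seed = NULL) {
  mode <- match.arg(mode)
  max_heavy_mode <- match.arg(max_heavy_mode)
  stopifnot(inherits(truth, "data.frame"))
  if (n_fractions < 3) stop("`n_fractions` must be at least 3", call. = FALSE)
  if (length(density_range) != 2L || diff(density_range) <= 0)
    stop("`density_range` must be increasing", call. = FALSE)
  if (reads_per_sample < 0 || qpcr_total <= 0 || qpcr_cv < 0)
    stop("invalid simulation configuration", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  edges <- seq(density_range[1], density_range[2], length.out = n_fractions + 1)
  centres <- (edges[-1] + edges[-length(edges)]) / 2
  n_otus <- nrow(truth)

  centre_u <- density_from_gc(truth$gc)
  centre_l <- expected_labelled_density(truth$gc, truth$true_mwe,
                                        truth$afe_c, truth$afe_n,
                                        mode = mode,
                                        max_heavy_mode = max_heavy_mode)

  one_treatment <- function(centre, isotope) {
    # copy mass per OTU per fraction (OTU x fraction)
    mass <- t(vapply(seq_len(n_otus), function(i)
      .band_masses(centre[i], truth$band_sigma[i], edges),
      numeric(n_fractions)))
    mass <- mass * truth$rel_abundance * qpcr_total
    tot_true <- colSums(mass)
    tot_meas <- if (qpcr_cv > 0) {
      sdlog <- sqrt(log(1 + qpcr_cv^2))
      tot_true * stats::rlnorm(n_fractions, meanlog = -sdlog^2 / 2,
                               sdlog = sdlog)
    } else tot_true
    counts <- if (analytic) {
      mass
    } else {
      vapply(seq_len(n_fractions), function(k) {
        if (tot_true[k] <= 0 || reads_per_sample == 0)
          integer(n_otus)
        else as.integer(stats::rmultinom(1, reads_per_sample,
                                         mass[, k] / tot_true[k]))
      }, integer(n_otus))
    }
    counts <- matrix(counts, nrow = n_otus)
    tag <- if (isotope == "labelled") "lab" else "unlab"
    sample_ids <- sprintf("%s_%s_F%02d", substrate, tag,
                          seq_len(n_fractions))
    rownames(counts) <- truth$otu_id
    colnames(counts) <- sample_ids
    profile <- gradient_profile(
      incubation_id = paste(substrate, isotope, sep = "_"),
      substrate = substrate, isotope = isotope,
      fractions = data.frame(
        sample_id = sample_ids,
        # fraction 1 = heaviest collected
        fraction_index = rank(-centres),
        density = centres,
        total_copies = tot_meas,
        stringsAsFactors = FALSE))
    list(profile = profile, counts = counts)
  }

  u <- one_treatment(centre_u, "unlabelled")
  l <- one_treatment(centre_l, "labelled")
  taxonomy <- synthetic_taxonomy(truth$otu_id)
  counts <- otu_count_table(cbind(u$counts, l$counts), taxonomy,
                            check_integer = !analytic)
  structure(list(unlabelled = u$profile, labelled = l$profile,
                 counts = counts, truth = truth,
                 config = list(n_fractions = n_fractions,
                               density_range = density_range,
                               reads_per_sample = reads_per_sample,
                               qpcr_total = qpcr_total, qpcr_cv = qpcr_cv,
                               mode = mode, max_heavy_mode = max_heavy_mode,
                               analytic = analytic, substrate = substrate,
                               seed = seed)),
            class = "sip_simulation")
}

# deterministic synthetic lineages: 8 bacterial phyla + 1 archaeal, cycled
synthetic_taxonomy <- function(otu_ids) {
  n <- length(otu_ids)
  idx <- (seq_len(n) - 1L) %% 9L + 1L
  lineage <- ifelse(idx == 9L,
    "Archaea;SynWoesearchaeota;SynClass_A1",
    sprintf("Bacteria;SynPhylum_%02d;SynClass_B%02d", idx, idx))
  stats::setNames(lineage, otu_ids)
}

#' Write a simulated experiment to disk
#'
#' Emits exactly the file formats the readers consume: fraction metadata
#' CSV (\code{\link{read_fraction_metadata}}), OTU count TSV and taxonomy
#' TSV (\code{\link{read_otu_table}}), plus the ground-truth TSV and a
#' plain-text run manifest (seed and configuration).
#'
#' @param sim a \code{\link{simulate_gradient_pair}} result.
#' @param dir output directory (created if needed).
#' @return Named character vector of the five file paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "sip_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fractions = file.path(dir, "fraction_metadata.csv"),
             otu = file.path(dir, "otu_counts.tsv"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             truth = file.path(dir, "truth.tsv"),
             manifest = file.path(dir, "manifest.txt"))
  meta <- do.call(rbind, lapply(list(sim$unlabelled, sim$labelled),
    function(p) data.frame(sample_id = p$fractions$sample_id,
                           incubation_id = p$incubation_id,
                           substrate = p$substrate, isotope = p$isotope,
                           fraction_index = p$fractions$fraction_index,
                           density_g_per_ml =
                             sprintf("%.15g", p$fractions$density),
                           total_16s_copies =
                             sprintf("%.15g", p$fractions$total_copies),
                           stringsAsFactors = FALSE)))
  utils::write.csv(meta, paths["fractions"], row.names = FALSE, quote = FALSE)
  cnt <- data.frame(otu_id = rownames(sim$counts$counts),
                    sim$counts$counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(cnt, paths["otu"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(otu_id = names(sim$counts$taxonomy),
               lineage = unname(sim$counts$taxonomy)),
    paths["taxonomy"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg <- sim$config
  writeLines(c(sprintf("dualsip %s",
                       as.character(utils::packageVersion("dualsip"))),
               paste0(names(cfg), ": ",
                      vapply(cfg, function(v) paste(format(v), collapse = " "),
                             character(1)))),
             paths["manifest"])
  invisible(paths)
}

#' Estimator recovery experiment
#'
#' Validation harness: simulates paired gradients over a grid of true MWE
#' values (and optionally sequencing depths), runs the full qSIP estimator
#' on each replicate, and aggregates bias, RMSE and active/inactive
#' classification accuracy against ground truth.
#'
#' @param true_mwe grid of true MWE values, assigned to OTUs by recycling
#'   (default \code{c(0, 0.05, 0.3, 0.5)}).
#' @param n_otus OTUs per simulated community (default 200).
#' @param reads_per_sample one or more sequencing depths (default 1e5).
#' @param qpcr_cv qPCR noise CV (default 0.10).
#' @param n_seeds replicate simulations per depth (default 3).
#' @param seed base seed; replicate r at depth d uses
#'   \code{seed + r - 1} offsets.
#' @param threshold activity cutoff for the accuracy column (default 0.14).
#' @param ... further arguments to \code{\link{simulate_gradient_pair}}
#'   (e.g. \code{density_range}, \code{n_fractions}).
#' @return Data frame with one row per (true_mwe, depth): \code{true_mwe},
#'   \code{depth}, \code{bias}, \code{rmse}, \code{accuracy}, \code{n}
#'   (OTU-replicates aggregated).
#' @export
recovery_experiment <- function(true_mwe = c(0, 0.05, 0.3, 0.5),
                                n_otus = 200, reads_per_sample = 1e5,
                                qpcr_cv = 0.10, n_seeds = 3, seed = 1,
                                threshold = 0.14, ...) {
  rows <- list()
  for (depth in reads_per_sample) {
    per_seed <- lapply(seq_len(n_seeds), function(r) {
      s <- seed + r - 1L
      truth <- simulation_truth(n_otus, true_mwe = rep_len(true_mwe, n_otus),
                                seed = s)
      sim <- simulate_gradient_pair(truth, reads_per_sample = depth,
                                    qpcr_cv = qpcr_cv, seed = s + 10000L, ...)
      fit <- suppressWarnings(qsip(sim$counts, sim$unlabelled, sim$labelled,
                                   threshold = threshold))
      merge(fit$results[c("otu_id", "mwe")],
            truth[c("otu_id", "true_mwe")], by = "otu_id")
    })
    est <- do.call(rbind, per_seed)
    for (tm in sort(unique(true_mwe))) {
      e <- est[est$true_mwe == tm, ]
      err <- e$mwe - e$true_mwe
      rows[[length(rows) + 1L]] <- data.frame(
        true_mwe = tm, depth = depth,
        bias = mean(err), rmse = sqrt(mean(err^2)),
        accuracy = mean((e$mwe >= threshold) == (tm >= threshold)),
        n = nrow(e))
    }
  }
  do.call(rbind, rows)
}
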