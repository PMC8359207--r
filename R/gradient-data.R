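#' Construct a gradient profile
#'
#' One incubation's ordered set of CsCl density fractions: per-fraction
#' buoyant densities (refractometer readings) and total 16S rRNA gene copies
#' (qPCR). Densities are taken as measured; no gradient shape is re-fitted.
#'
#' @param incubation_id single string identifying the incubation.
#' @param substrate substrate label, e.g. \code{"DOM"} or \code{"PRO"}.
#' @param isotope \code{"unlabelled"} or \code{"labelled"}.
#' @param fractions data frame with columns \code{sample_id},
#'   \code{fraction_index} (1-based; by collection convention 1 = heaviest,
#'   but all statistics are density-weighted so ordering is labelling only),
#'   \code{density} (g ml^-1) and \code{total_copies}.
#' @param dna_loaded micrograms of DNA loaded on the gradient (default 4).
#' @param dna_extracted,volume_filtered optional: micrograms of DNA extracted
#'   from the incubation filter and litres of water filtered, needed only by
#'   \code{\link{prokaryote_abundance_per_litre}}.
#' @return An object of class \code{"gradient_profile"}.
#' @export
gradient_profile <- function(incubation_id, substrate, isotope, fractions,
                             dna_loaded = 4, dna_extracted = NA_real_,
                             volume_filtered = NA_real_) {
  isotope <- match.arg(isotope, c("unlabelled", "labelled"))
  need <- c("sample_id", "fraction_index", "density", "total_copies")
  miss <- setdiff(need, names(fractions))
  if (length(miss))
    stop("`fractions` is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  fractions <- as.data.frame(fractions)[need]
  fractions$sample_id <- as.character(fractions$sample_id)
  if (anyDuplicated(fractions$fraction_index))
    stop("duplicate fraction_index in incubation '", incubation_id, "'",
         call. = FALSE)
  bad <- fractions$density < qsip_constants$density_min |
         fractions$density > qsip_constants$density_max
  if (any(bad, na.rm = TRUE))
    stop(sprintf("density outside plausible CsCl range [%.2f, %.2f] in incubation '%s'",
                 qsip_constants$density_min, qsip_constants$density_max,
                 incubation_id), call. = FALSE)
  if (any(fractions$total_copies < 0, na.rm = TRUE))
    stop("total_copies must be non-negative in incubation '", incubation_id,
         "'", call. = FALSE)
  if (sum(fractions$total_copies > 0, na.rm = TRUE) < 3L)
    stop("incubation '", incubation_id,
         "' has fewer than 3 fractions with positive copy totals; ",
         "a weighted average density would not be meaningful", call. = FALSE)
  fractions <- fractions[order(fractions$fraction_index), , drop = FALSE]
  rownames(fractions) <- NULL
  structure(list(incubation_id = as.character(incubation_id),
                 substrate = as.character(substrate),
                 isotope = isotope,
                 fractions = fractions,
                 dna_loaded = dna_loaded,
                 dna_extracted = dna_extracted,
                 volume_filtered = volume_filtered),
            class = "gradient_profile")
}

#' @export
print.gradient_profile <- function(x, ...) {
  cat(sprintf("Gradient profile '%s' (%s, %s): %d fractions, density %.4f-%.4f g/ml\n",
              x$incubation_id, x$substrate, x$isotope, nrow(x$fractions),
              min(x$fractions$density), max(x$fractions$density)))
  invisible(x)
}

# sniff separator of a delimited text file from its header line
.sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read fraction metadata
#'
#' Reads a comma- or tab-separated table (auto-detected) of gradient
#' fractions, one row per fraction-sample, and groups rows into
#' \code{\link{gradient_profile}} objects by incubation.
#'
#' Required columns: \code{sample_id}, \code{incubation_id},
#' \code{substrate}, \code{isotope}, \code{fraction_index},
#' \code{density_g_per_ml}, \code{total_16s_copies}. Optional columns
#' \code{dna_loaded_ug}, \code{dna_extracted_ug}, \code{volume_filtered_l}
#' (constant within an incubation) populate the corresponding profile fields.
#'
#' @param path path to the metadata file.
#' @return Named list of \code{gradient_profile} objects (names =
#'   incubation ids); empty list for a header-only file.
#' @export
read_fraction_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- .sniff_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          strip.white = TRUE, comment.char = "",
                          quote = "\"")
  need <- c("sample_id", "incubation_id", "substrate", "isotope",
            "fraction_index", "density_g_per_ml", "total_16s_copies")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("fraction metadata is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L) return(list())

  num_col <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !(df[[col]] %in% c("", "NA")))
    if (length(bad))
      stop(sprintf("non-numeric %s on line %d: '%s'", col, bad[1] + 1L,
                   df[[col]][bad[1]]), call. = FALSE)
    v
  }
  df$fraction_index <- num_col("fraction_index")
  df$density_g_per_ml <- num_col("density_g_per_ml")
  df$total_16s_copies <- num_col("total_16s_copies")

  opt <- function(col, i, default = NA_real_) {
    if (!col %in% names(df)) return(default)
    v <- suppressWarnings(as.numeric(df[[col]][i][1]))
    if (is.na(v)) default else v
  }
  out <- lapply(split(seq_len(nrow(df)), df$incubation_id), function(i) {
    gradient_profile(
      incubation_id = df$incubation_id[i][1],
      substrate = df$substrate[i][1],
      isotope = df$isotope[i][1],
      fractions = data.frame(sample_id = df$sample_id[i],
                             fraction_index = df$fraction_index[i],
                             density = df$density_g_per_ml[i],
                             total_copies = df$total_16s_copies[i],
                             stringsAsFactors = FALSE),
      dna_loaded = opt("dna_loaded_ug", i, 4),
      dna_extracted = opt("dna_extracted_ug", i),
      volume_filtered = opt("volume_filtered_l", i))
  })
  out[unique(df$incubation_id)]
}

#' Construct an OTU count table
#'
#' Integer read counts per OTU per fraction-sample, with SILVA-style
#' taxonomy attached.
#'
#' @param counts numeric matrix, OTUs in rows (rownames = OTU ids), samples
#'   in columns (colnames = sample ids matching fraction metadata).
#' @param taxonomy named character vector or two-column data frame
#'   (\code{otu_id}, \code{lineage}) of semicolon-delimited lineages. OTUs
#'   without taxonomy get lineage \code{"Unassigned"} with a warning.
#' @param check_integer require integer counts (default TRUE; the simulator's
#'   analytic mode disables this to carry exact expected abundances).
#' @return An object of class \code{"otu_table"}: list with elements
#'   \code{counts} (matrix) and \code{taxonomy} (named character vector
#'   aligned to rows).
#' @export
otu_count_table <- function(counts, taxonomy = NULL, check_integer = TRUE) {
  counts <- as.matrix(counts)
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts))))
    stop("`counts` must have OTU ids as rownames and sample ids as colnames",
         call. = FALSE)
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate OTU id: ",
         rownames(counts)[duplicated(rownames(counts))][1], call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample id in OTU table", call. = FALSE)
  if (any(counts < 0, na.rm = TRUE))
    stop("counts must be non-negative", call. = FALSE)
  if (check_integer && any(counts != round(counts), na.rm = TRUE))
    stop("counts must be integers", call. = FALSE)

  if (is.data.frame(taxonomy)) {
    tx <- stats::setNames(as.character(taxonomy[[2]]),
                          as.character(taxonomy[[1]]))
  } else if (is.null(taxonomy)) {
    tx <- character(0)
  } else tx <- taxonomy
  lineage <- tx[rownames(counts)]
  missing_tax <- is.na(lineage)
  if (any(missing_tax) && length(tx)) {
    warning(sum(missing_tax),
            " OTU(s) absent from taxonomy; lineage set to 'Unassigned'",
            call. = FALSE)
  }
  lineage[missing_tax] <- "Unassigned"
  names(lineage) <- rownames(counts)
  structure(list(counts = counts, taxonomy = lineage), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d OTUs x %d samples, %s reads total\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Read an OTU table with taxonomy
#'
#' Reads a tab-separated OTU table (classic layout: first column
#' \code{otu_id}, remaining columns samples; the transposed layout with a
#' leading \code{sample_id} column is auto-detected) and a two-column
#' taxonomy file (\code{otu_id}, semicolon-delimited lineage).
#'
#' @param path path to the OTU count TSV.
#' @param taxonomy_path path to the taxonomy TSV; \code{NULL} to skip.
#' @return An \code{\link{otu_count_table}} object.
#' @export
read_otu_table <- function(path, taxonomy_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, comment.char = "",
                          quote = "\"", stringsAsFactors = FALSE)
  first <- names(df)[1]
  if (identical(first, "sample_id")) {            # transposed layout
    samples <- as.character(df[[1]])
    m <- t(as.matrix(df[-1]))
    colnames(m) <- samples
  } else {
    if (!identical(first, "otu_id") && !grepl("OTU", first, ignore.case = TRUE))
      stop("OTU table header must start with 'otu_id' (or 'sample_id' for ",
           "the transposed layout); got '", first, "'", call. = FALSE)
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids))
      stop("duplicate OTU id: ", ids[duplicated(ids)][1], call. = FALSE)
    m <- as.matrix(df[-1])
    rownames(m) <- ids
  }
  if (!is.numeric(m)) stop("OTU table contains non-numeric cells", call. = FALSE)
  if (any(m != round(m))) stop("OTU table contains fractional counts", call. = FALSE)

  tx <- NULL
  if (!is.null(taxonomy_path)) {
    if (!file.exists(taxonomy_path))
      stop("file not found: ", taxonomy_path, call. = FALSE)
    txdf <- utils::read.table(taxonomy_path, sep = "\t", header = TRUE,
                              check.names = FALSE, comment.char = "",
                              quote = "\"", stringsAsFactors = FALSE)
    if (ncol(txdf) < 2)
      stop("taxonomy file must have two columns (otu_id, lineage)",
           call. = FALSE)
    tx <- txdf[, 1:2]
  }
  otu_count_table(m, tx)
}

# results table column order shared by writer and reader
.result_cols <- c("otu_id", "substrate", "w_light", "w_lab", "delta_w", "gc",
                  "m_light", "m_lab", "m_heavymax", "mwe", "active",
                  "copies_labelled", "copies_unlabelled", "lineage")

#' Write per-OTU qSIP results to TSV
#'
#' Writes the per-OTU results of a fit (or a results data frame) to a
#' tab-separated file at full double precision, so that
#' \code{\link{read_qsip_results}} round-trips values to better than 1e-9.
#'
#' @param results a \code{\link{qsip}} fit or its \code{$results} data frame.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_qsip_results <- function(results, path) {
  if (inherits(results, "qsip")) results <- results$results
  df <- results[intersect(.result_cols, names(results))]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.15g", v))
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write results to '", path, "': ",
                              conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read a qSIP results TSV
#'
#' @param path path written by \code{\link{write_qsip_results}}.
#' @return Data frame of per-OTU results.
#' @export
read_qsip_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, comment.char = "",
                          quote = "\"", stringsAsFactors = FALSE)
  if ("active" %in% names(df)) df$active <- as.logical(df$active)
  df
}
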