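#' Remove singleton OTUs
#'
#' Drops OTUs whose total read count across all samples equals 1. This is the
#' filtering rule for water-column (non-gradient) amplicon data sets; for
#' fraction-resolved incubation data use \code{\link{filter_min_count}}.
#'
#' @param table an \code{\link{otu_count_table}}.
#' @return Filtered table (surviving counts unchanged).
#' @export
drop_singletons <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  keep <- rowSums(table$counts) != 1
  subset_otus(table, keep)
}

#' Remove low-count OTUs within one incubation
#'
#' Drops OTUs with fewer than \code{min_total} reads summed over the
#' incubation's fraction-samples (strictly less than: an OTU totalling
#' exactly \code{min_total} is kept). The default of 13 matches one read per
#' fraction of a 13-fraction gradient. The rule is applied per incubation:
#' pass the profile whose fraction columns define the scope.
#'
#' @param table an \code{\link{otu_count_table}}.
#' @param profile a \code{\link{gradient_profile}} identifying the
#'   incubation's fraction-sample columns, or a character vector of sample
#'   ids; \code{NULL} uses all columns.
#' @param min_total minimum read total (default 13).
#' @return Filtered table.
#' @export
filter_min_count <- function(table, profile = NULL, min_total = 13) {
  stopifnot(inherits(table, "otu_table"))
  if (!is.numeric(min_total) || length(min_total) != 1L || min_total < 0)
    stop("`min_total` must be a single non-negative number", call. = FALSE)
  cols <- scope_samples(table, profile)
  tot <- rowSums(table$counts[, cols, drop = FALSE])
  subset_otus(table, tot >= min_total)
}

#' Remove OTUs by taxonomic label
#'
#' Drops OTUs whose lineage contains any of the given taxon labels
#' (case-insensitive substring match at any rank, tolerant of SILVA rank
#' prefixes such as \code{"D_1__Cyanobacteria"}). The default removes
#' Cyanobacteria, which in substrate-amended incubations cannot be separated
#' from residual substrate (algal) DNA.
#'
#' @param table an \code{\link{otu_count_table}}.
#' @param labels character vector of taxon names (default
#'   \code{"Cyanobacteria"}); an empty vector is the identity.
#' @return Filtered table; the number removed is reported via
#'   \code{message()}.
#' @export
drop_taxa <- function(table, labels = "Cyanobacteria") {
  stopifnot(inherits(table, "otu_table"))
  if (length(labels) == 0L) return(table)
  hit <- Reduce(`|`, lapply(labels, function(lab)
    grepl(lab, table$taxonomy, ignore.case = TRUE, fixed = FALSE)))
  if (sum(hit) > 0)
    message(sum(hit), " OTU(s) removed matching taxa: ",
            paste(labels, collapse = ", "))
  subset_otus(table, !hit)
}

#' Convert read counts to relative abundances
#'
#' Divides each sample column by its read total. All-zero columns stay zero
#' and are flagged with a warning.
#'
#' @param table an \code{\link{otu_count_table}}.
#' @return An abundance table: same structure with \code{kind = "relative"};
#'   every non-empty column sums to 1.
#' @export
to_relative <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  sums <- colSums(table$counts)
  empty <- sums == 0
  if (any(empty))
    warning(sum(empty), " all-zero sample column(s) left at zero: ",
            paste(colnames(table$counts)[empty], collapse = ", "),
            call. = FALSE)
  denom <- ifelse(empty, 1, sums)
  rel <- sweep(table$counts, 2, denom, `/`)
  out <- table
  out$counts <- rel
  attr(out, "kind") <- "relative"
  out
}

#' Convert relative abundances to absolute 16S copy numbers
#'
#' Multiplies each fraction-sample's relative abundances by that fraction's
#' qPCR total, so column sums equal the measured totals. Only the profile's
#' fraction-sample columns are returned.
#'
#' @param rel a relative abundance table from \code{\link{to_relative}}.
#' @param profile the \code{\link{gradient_profile}} supplying per-fraction
#'   \code{total_copies}; every profile sample must be a column of
#'   \code{rel}.
#' @return Abundance table with \code{kind = "copies"}, columns restricted
#'   and ordered to the profile's fractions.
#' @export
to_copies <- function(rel, profile) {
  stopifnot(inherits(rel, "otu_table"), inherits(profile, "gradient_profile"))
  if (!identical(attr(rel, "kind"), "relative"))
    stop("`rel` must be a relative abundance table (see to_relative())",
         call. = FALSE)
  ids <- profile$fractions$sample_id
  missing <- setdiff(ids, colnames(rel$counts))
  if (length(missing))
    stop("no abundance column for fraction sample(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  m <- rel$counts[, ids, drop = FALSE]
  m <- sweep(m, 2, profile$fractions$total_copies, `*`)
  out <- rel
  out$counts <- m
  attr(out, "kind") <- "copies"
  out
}

#' Estimated prokaryote abundance per litre
#'
#' Scales the qPCR copy total of a gradient back to the incubation water:
#' (sum of per-fraction totals) x (DNA extracted / DNA loaded) / volume
#' filtered. These are estimates, not absolute abundances; the dominant
#' error is the DNA yield of the extraction.
#'
#' @param profile a \code{\link{gradient_profile}} with \code{dna_extracted}
#'   (ug) and \code{volume_filtered} (litres) set.
#' @return 16S rRNA gene copies per litre.
#' @export
prokaryote_abundance_per_litre <- function(profile) {
  stopifnot(inherits(profile, "gradient_profile"))
  if (is.na(profile$dna_extracted) || is.na(profile$volume_filtered))
    stop("profile needs `dna_extracted` and `volume_filtered` for a ",
         "per-litre estimate", call. = FALSE)
  if (!isTRUE(profile$dna_loaded > 0))
    stop("`dna_loaded` must be positive", call. = FALSE)
  if (!isTRUE(profile$volume_filtered > 0))
    stop("`volume_filtered` must be positive", call. = FALSE)
  sum(profile$fractions$total_copies) *
    (profile$dna_extracted / profile$dna_loaded) / profile$volume_filtered
}

# --- internal helpers -------------------------------------------------------

subset_otus <- function(table, keep) {
  table$counts <- table$counts[keep, , drop = FALSE]
  table$taxonomy <- table$taxonomy[keep]
  table
}

# resolve a profile / character vector / NULL to column names of the table
scope_samples <- function(table, profile) {
  if (is.null(profile)) return(colnames(table$counts))
  ids <- if (inherits(profile, "gradient_profile"))
    profile$fractions$sample_id else as.character(profile)
  missing <- setdiff(ids, colnames(table$counts))
  if (length(missing))
    stop("sample(s) not in OTU table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  ids
}

# split a semicolon lineage into cleaned rank names (SILVA prefixes removed)
lineage_ranks <- function(lineage) {
  parts <- strsplit(lineage, ";", fixed = TRUE)
  lapply(parts, function(p) {
    p <- trimws(p)
    sub("^[A-Za-z]_?[0-9]*__", "", p)
  })
}
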