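#' Per-taxon activity table
#'
#' Groups the active OTUs of a fit by (domain, phylum, class) and reports,
#' per group, the number of active OTUs, their total read counts over the
#' labelled incubation's fraction-samples, and the percentage of all active
#' OTUs they represent. Rows are ordered Bacteria before Archaea (other
#' domains after), alphabetically within.
#'
#' "Total sequences" are read counts of active OTUs in the labelled
#' incubation, not qPCR copy numbers.
#'
#' @param fit a \code{\link{qsip}} fit.
#' @param counts the \code{\link{otu_count_table}} the fit was made from
#'   (supplies read counts for the labelled samples).
#' @return Data frame: \code{domain}, \code{phylum}, \code{class},
#'   \code{n_active_otus}, \code{total_sequences}, \code{percent_active}.
#'   The percent column sums to 100 (up to rounding); zero active OTUs give
#'   an empty table.
#' @export
activity_table <- function(fit, counts) {
  stopifnot(inherits(fit, "qsip"), inherits(counts, "otu_table"))
  act <- fit$results[fit$results$active, , drop = FALSE]
  if (nrow(act) == 0L)
    return(data.frame(domain = character(), phylum = character(),
                      class = character(), n_active_otus = integer(),
                      total_sequences = numeric(),
                      percent_active = numeric()))
  ranks <- lineage_ranks(act$lineage)
  pick <- function(p, i) if (length(p) >= i && nzchar(p[i])) p[i] else "Unassigned"
  dom <- vapply(ranks, pick, "", i = 1L)
  phy <- vapply(ranks, pick, "", i = 2L)
  cls <- vapply(ranks, pick, "", i = 3L)
  lab_cols <- intersect(fit$sample_ids$labelled, colnames(counts$counts))
  reads <- rowSums(counts$counts[act$otu_id, lab_cols, drop = FALSE])

  key <- paste(dom, phy, cls, sep = "\r")
  agg <- lapply(split(seq_len(nrow(act)), key), function(i) {
    data.frame(domain = dom[i][1], phylum = phy[i][1], class = cls[i][1],
               n_active_otus = length(i),
               total_sequences = sum(reads[i]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out$percent_active <- 100 * out$n_active_otus / nrow(act)
  dom_order <- match(out$domain, c("Bacteria", "Archaea"))
  dom_order[is.na(dom_order)] <- 3L
  out <- out[order(dom_order, out$phylum, out$class), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percentage of OTUs shared between two sets
#'
#' \eqn{100 |A \cap B| / |D|} where the denominator set \eqn{D} is the
#' union (default), set A, or set B.
#'
#' @param set_a,set_b character vectors of OTU ids.
#' @param denominator \code{"union"} (default), \code{"set_a"} or
#'   \code{"set_b"}.
#' @return Percentage shared.
#' @export
shared_otu_fraction <- function(set_a, set_b,
                                denominator = c("union", "set_a", "set_b")) {
  denominator <- match.arg(denominator)
  a <- unique(set_a); b <- unique(set_b)
  d <- switch(denominator, union = union(a, b), set_a = a, set_b = b)
  if (length(d) == 0L)
    stop("shared fraction undefined: empty denominator set", call. = FALSE)
  100 * length(intersect(a, b)) / length(d)
}

#' Community-level weighted average density
#'
#' Mean of the per-OTU labelled-treatment weighted average densities
#' (\code{w_lab}) over either the active subset or all analysed OTUs,
#' weighted by labelled copy numbers or unweighted. Comparing the active
#' community's (copy-weighted) density to the all-OTU mean shows the
#' community-level density shift induced by label uptake.
#'
#' @param fit a \code{\link{qsip}} fit.
#' @param which \code{"active"} (default) or \code{"all"}.
#' @param weighting \code{"copies"} (default) or \code{"unweighted"}.
#' @return Density in g ml^-1.
#' @export
community_weighted_density <- function(fit, which = c("active", "all"),
                                       weighting = c("copies", "unweighted")) {
  stopifnot(inherits(fit, "qsip"))
  which <- match.arg(which)
  weighting <- match.arg(weighting)
  r <- fit$results
  if (which == "active") r <- r[r$active, , drop = FALSE]
  if (nrow(r) == 0L)
    stop("community density undefined: empty OTU selection", call. = FALSE)
  if (weighting == "copies")
    stats::weighted.mean(r$w_lab, r$copies_labelled)
  else mean(r$w_lab)
}

#' Partition labelled-incubation copies into active and total
#'
#' Sums the labelled incubation's 16S copies over the active OTUs and over
#' all analysed OTUs: the share of standing 16S copies attributable to taxa
#' that took up the label.
#'
#' @param fit a \code{\link{qsip}} fit.
#' @return Named numeric vector \code{c(copies_active, copies_total)};
#'   \code{copies_active <= copies_total}, and the partition is additive
#'   over disjoint OTU subsets.
#' @export
labelled_copy_partition <- function(fit) {
  stopifnot(inherits(fit, "qsip"))
  r <- fit$results
  c(copies_active = sum(r$copies_labelled[r$active]),
    copies_total = sum(r$copies_labelled))
}

#' Per-OTU gradient curves
#'
#' Extracts one OTU's copy-number-versus-density series for both treatments,
#' raw and normalised to each treatment's maximum (range (0, 1\]) --- the
#' plot-ready form of a per-OTU gradient panel.
#'
#' @param fit a \code{\link{qsip}} fit.
#' @param otu_id OTU identifier present in the fit.
#' @return Data frame: \code{otu_id}, \code{treatment}, \code{density},
#'   \code{copies}, \code{normalized}.
#' @export
gradient_profile_curves <- function(fit, otu_id) {
  stopifnot(inherits(fit, "qsip"))
  if (!otu_id %in% rownames(fit$copies$unlabelled))
    stop("OTU '", otu_id, "' not present in fit", call. = FALSE)
  one <- function(treat) {
    v <- fit$copies[[treat]][otu_id, ]
    if (all(v == 0))
      stop("OTU '", otu_id, "' has an all-zero ", treat, " series",
           call. = FALSE)
    data.frame(otu_id = otu_id, treatment = treat,
               density = fit$densities[[treat]],
               copies = unname(v), normalized = unname(v / max(v)),
               stringsAsFactors = FALSE)
  }
  rbind(one("unlabelled"), one("labelled"))
}
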