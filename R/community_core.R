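#' Community analysis configuration
#'
#' Decision thresholds for the amplicon-side rules: taxa with mean relative
#' abundance below \code{abundance_threshold_pct} in every year are excluded,
#' and a taxon belongs to a year's core community when it is present in at
#' least \code{prevalence_threshold} of that year's samples.
#'
#' @param abundance_threshold_pct Percent; default 0.1.
#' @param prevalence_threshold Fraction in (0, 1]; default 0.80.
#' @return A list of class \code{community_config}.
#' @export
community_config <- function(abundance_threshold_pct = 0.1,
                             prevalence_threshold = 0.80) {
  if (abundance_threshold_pct < 0)
    stop_("community_config: abundance threshold must be >= 0")
  if (prevalence_threshold <= 0 || prevalence_threshold > 1)
    stop_("community_config: prevalence threshold must be in (0, 1]")
  structure(list(abundance_threshold_pct = abundance_threshold_pct,
                 prevalence_threshold = prevalence_threshold),
            class = "community_config")
}

#' Per-sample relative abundance
#'
#' Converts a samples x taxa count matrix into per-sample percentages; each
#' row sums to 100.
#'
#' @param counts Non-negative matrix, samples in rows (named), taxa in columns.
#' @return Matrix of percentages with the same dimnames.
#' @export
relative_abundance <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (any(counts < 0)) stop_("relative_abundance: negative count")
  tot <- rowSums(counts)
  zero <- which(tot == 0)
  if (length(zero))
    stop_("relative_abundance: sample with zero total reads: ",
          rownames(counts)[zero[1]] %||% zero[1])
  sweep(counts, 1, tot, "/") * 100
}

.year_means <- function(ra, years) {
  yrs <- sort(unique(years))
  m <- vapply(yrs, function(y)
    colMeans(ra[years == y, , drop = FALSE]), numeric(ncol(ra)))
  if (is.null(dim(m))) m <- matrix(m, nrow = ncol(ra),
                                   dimnames = list(colnames(ra), NULL))
  colnames(m) <- as.character(yrs)
  m  # taxa x years
}

#' Exclude persistently low-abundance taxa
#'
#' A taxon is retained when its mean relative abundance reaches the abundance
#' threshold in at least one year; it is excluded only when it stays below the
#' threshold in every year.
#'
#' @param ra Percent matrix from \code{\link{relative_abundance}}.
#' @param years Per-sample year labels (same length as \code{nrow(ra)}).
#' @param cfg A \code{\link{community_config}}.
#' @return Character vector of retained taxon ids.
#' @export
filter_low_abundance <- function(ra, years, cfg = community_config()) {
  if (length(years) != nrow(ra))
    stop_("filter_low_abundance: years must match samples")
  ym <- .year_means(ra, years)
  keep <- apply(ym >= cfg$abundance_threshold_pct, 1, any)
  colnames(ra)[keep]
}

#' Per-year core taxa by prevalence
#'
#' A taxon is in a year's core when the fraction of that year's samples in
#' which it is present (count > 0) is at least the prevalence threshold
#' (inclusive comparison).
#'
#' @param counts Samples x taxa count matrix.
#' @param years Per-sample year labels.
#' @param cfg A \code{\link{community_config}}.
#' @return Named list (one element per year) of core taxon id vectors.
#' @export
core_taxa <- function(counts, years, cfg = community_config()) {
  if (length(years) != nrow(counts))
    stop_("core_taxa: years must match samples")
  yrs <- sort(unique(years))
  out <- lapply(yrs, function(y) {
    sel <- years == y
    if (!any(sel)) stop_("core_taxa: year ", y, " has no samples")
    prev <- colMeans(counts[sel, , drop = FALSE] > 0)
    colnames(counts)[prev >= cfg$prevalence_threshold]
  })
  stats::setNames(out, as.character(yrs))
}

#' Culture-collection recovery estimate
#'
#' For each year, the amplicon-detected genus set is the set of taxa whose
#' mean relative abundance in that year reaches the abundance threshold; the
#' recovery estimate is the percentage of those detected genera that are also
#' present in the culture collection.
#'
#' @param cultured_genera Character vector of genera in the culture collection.
#' @param ra Percent matrix from \code{\link{relative_abundance}}.
#' @param years Per-sample year labels.
#' @param cfg A \code{\link{community_config}}.
#' @return Named numeric vector of recovery percentages, one per year.
#' @export
recovery_estimate <- function(cultured_genera, ra, years,
                              cfg = community_config()) {
  ym <- .year_means(ra, years)
  vapply(colnames(ym), function(y) {
    detected <- rownames(ym)[ym[, y] >= cfg$abundance_threshold_pct]
    if (length(detected) == 0)
      stop_("recovery_estimate: no taxa detected in year ", y)
    100 * length(intersect(cultured_genera, detected)) / length(detected)
  }, numeric(1))
}
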