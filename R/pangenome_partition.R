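#' Binary presence/absence from gene counts
#'
#' @param mat An \code{\link{og_matrix}} or a plain counts matrix.
#' @return Integer matrix with the same axes, entries in \{0, 1\}
#'   (presence = count > 0).
#' @export
presence_from_counts <- function(mat) {
  counts <- if (inherits(mat, "og_matrix")) mat$counts else as.matrix(mat)
  p <- (counts > 0) + 0L
  dimnames(p) <- dimnames(counts)
  p
}

#' Soft-core orthogroups
#'
#' An orthogroup belongs to the soft core when its occupancy fraction is at
#' least \code{core_occupancy} (inclusive). Occupancy is counted over
#' isolates by default; with \code{groups} supplied, over distinct group
#' labels having at least one presence (the "per species/genus" variant).
#'
#' @param presence Binary matrix from \code{\link{presence_from_counts}}.
#' @param core_occupancy Occupancy fraction tau in (0, 1]; default 0.95.
#' @param groups Optional per-isolate group labels to count occupancy over
#'   groups instead of isolates.
#' @return Character vector of core orthogroup ids.
#' @export
soft_core <- function(presence, core_occupancy = 0.95, groups = NULL) {
  if (core_occupancy <= 0 || core_occupancy > 1)
    stop_("soft_core: core_occupancy must be in (0, 1]")
  if (nrow(presence) == 0) stop_("soft_core: no isolates")
  if (is.null(groups)) {
    occ <- colMeans(presence > 0)
  } else {
    if (length(groups) != nrow(presence))
      stop_("soft_core: groups must match isolates")
    gp <- rowsum((presence > 0) + 0, groups)
    occ <- colMeans(gp > 0)
  }
  colnames(presence)[occ >= core_occupancy]
}

#' Partition orthogroups into soft core, group-combination sets and unclassified
#'
#' Reproduces the strict source-combination partition: soft-core orthogroups
#' (isolate-level occupancy >= \code{core_occupancy}) are removed first; each
#' remaining orthogroup is a candidate for the combination C of groups in
#' which it has at least one presence (and, by construction, is absent from
#' all isolates of every group outside C). It is actually assigned to C only
#' when it is present in at least \code{strict_fraction} of the isolates of
#' every group in C; otherwise it is unclassified. \code{strict_fraction = 0}
#' gives the plain any-presence rule. Isolates without metadata are dropped
#' with a warning; the resulting core, combination sets and unclassified set
#' are pairwise disjoint and jointly exhaustive.
#'
#' @param mat An \code{\link{og_matrix}} or presence/counts matrix.
#' @param metadata An \code{isolate_metadata} data frame.
#' @param group_key Metadata column to group by: \code{"source"} or
#'   \code{"genus"}.
#' @param core_occupancy Soft-core occupancy threshold; default 0.95.
#' @param strict_fraction Within-group occupancy required for combination
#'   membership; default 0.95.
#' @return A list of class \code{og_partition} with \code{core} (character),
#'   \code{combos} (named list, names are sorted group labels joined by
#'   \code{"+"}) and \code{unclassified} (character).
#' @export
partition_by_group <- function(mat, metadata, group_key = c("source", "genus"),
                               core_occupancy = 0.95, strict_fraction = 0.95) {
  group_key <- match.arg(group_key)
  presence <- presence_from_counts(mat)
  common <- intersect(rownames(presence), metadata$isolate_id)
  missing <- setdiff(rownames(presence), metadata$isolate_id)
  if (length(missing)) {
    warning("partition_by_group: dropping ", length(missing),
            " isolate(s) without metadata")
    presence <- presence[common, , drop = FALSE]
  }
  groups <- metadata[[group_key]][match(rownames(presence), metadata$isolate_id)]
  sizes <- table(groups)
  if (any(sizes == 0)) stop_("partition_by_group: group with 0 isolates")
  core <- soft_core(presence, core_occupancy)
  rest <- setdiff(colnames(presence), core)
  combos <- list()
  unclassified <- character(0)
  if (length(rest)) {
    sub <- presence[, rest, drop = FALSE]
    gcount <- rowsum(sub, groups)                  # groups x orthogroups
    gfrac <- gcount / as.vector(sizes[rownames(gcount)])
    pat <- gcount > 0
    keys <- apply(pat, 2, function(p)
      paste(sort(rownames(gcount)[p]), collapse = "+"))
    strict_ok <- vapply(seq_along(rest), function(j) {
      p <- pat[, j]
      any(p) && all(gfrac[p, j] >= strict_fraction)
    }, logical(1))
    unclassified <- rest[!strict_ok]
    assigned <- rest[strict_ok]
    combos <- split(assigned, keys[strict_ok])
  }
  res <- structure(list(core = core, combos = combos,
                        unclassified = unclassified,
                        group_key = group_key,
                        core_occupancy = core_occupancy,
                        strict_fraction = strict_fraction),
                   class = "og_partition")
  stopifnot(identical(sort(c(res$core, unlist(res$combos, use.names = FALSE),
                             res$unclassified)),
                      sort(colnames(presence))))
  res
}

#' @export
print.og_partition <- function(x, ...) {
  cat(sprintf(
    "og_partition by %s: %d core, %d combination sets (%d orthogroups), %d unclassified\n",
    x$group_key, length(x$core), length(x$combos),
    length(unlist(x$combos, use.names = FALSE)), length(x$unclassified)))
  invisible(x)
}

#' Flatten a partition to a table
#'
#' @param x An \code{og_partition}.
#' @return Data frame with columns \code{orthogroup_id} and \code{category}
#'   (\code{"core"}, a \code{"+"}-joined group combination, or
#'   \code{"unclassified"}).
#' @export
partition_table <- function(x) {
  rows <- c(list(data.frame(orthogroup_id = x$core,
                            category = rep("core", length(x$core)))),
            lapply(names(x$combos), function(k)
              data.frame(orthogroup_id = x$combos[[k]], category = k)),
            list(data.frame(orthogroup_id = x$unclassified,
                            category = rep("unclassified",
                                           length(x$unclassified)))))
  do.call(rbind, rows)
}

#' Pangenome assignment summary statistics
#'
#' Totals of gene assignment to orthogroups. Percentages are reported to one
#' decimal (half-up); internal computation stays at full precision.
#'
#' @param mat An \code{\link{og_matrix}}.
#' @return A list of class \code{pangenome_summary}: \code{total_genes},
#'   \code{assigned_genes}, \code{unassigned_genes}, \code{n_orthogroups},
#'   \code{pct_assigned}, \code{mean_og_size}.
#' @export
pangenome_summary <- function(mat) {
  stopifnot(inherits(mat, "og_matrix"))
  assigned <- sum(as.numeric(mat$counts))
  unassigned <- sum(as.numeric(mat$unassigned))
  total <- assigned + unassigned
  n_og <- ncol(mat$counts)
  if (n_og == 0 && assigned > 0)
    stop_("pangenome_summary: assigned genes with zero orthogroups")
  structure(list(
    total_genes = total,
    assigned_genes = assigned,
    unassigned_genes = unassigned,
    n_orthogroups = n_og,
    pct_assigned = round_half_up(100 * assigned / total, 1),
    mean_og_size = if (n_og > 0) round_half_up(assigned / n_og, 1) else NA_real_
  ), class = "pangenome_summary")
}

#' @export
print.pangenome_summary <- function(x, ...) {
  cat(sprintf(
    "%s genes; %s (%.1f%%) assigned to %s orthogroups (mean size %.1f); %s unassigned\n",
    format(x$total_genes, big.mark = ","),
    format(x$assigned_genes, big.mark = ","), x$pct_assigned,
    format(x$n_orthogroups, big.mark = ","), x$mean_og_size,
    format(x$unassigned_genes, big.mark = ",")))
  invisible(x)
}
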