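#' Enrichment analysis configuration
#'
#' @param alpha Significance level for the BH-adjusted p-values; default 0.05.
#' @param deviation_threshold_pct Minimum absolute percent deviation from the
#'   core expectation, \code{D = 100 * (p_obs / p_core - 1)}, for a category
#'   to be called over/under-represented; default 50.
#' @param min_gene_support Minimum number of genes in the category across the
#'   comparison (target + core) below which a record is marked
#'   \code{"low-support"} instead of being classified; default 200.
#' @param adjust_scope \code{"per-set"} (BH across the categories of each
#'   target set) or \code{"global"} (BH across all sets at once, applied by
#'   \code{\link{enrich_sets}}).
#' @return A list of class \code{enrichment_config}.
#' @export
enrichment_config <- function(alpha = 0.05, deviation_threshold_pct = 50,
                              min_gene_support = 200,
                              adjust_scope = c("per-set", "global")) {
  if (alpha <= 0 || alpha >= 1) stop_("enrichment_config: alpha must be in (0,1)")
  if (deviation_threshold_pct <= 0)
    stop_("enrichment_config: deviation threshold must be positive")
  structure(list(alpha = alpha,
                 deviation_threshold_pct = deviation_threshold_pct,
                 min_gene_support = min_gene_support,
                 adjust_scope = match.arg(adjust_scope)),
            class = "enrichment_config")
}

#' Gene counts per COG category for an orthogroup set
#'
#' Counts at the gene level: a gene carrying k category letters contributes 1
#' to each of the k letters; genes with an empty COG set contribute only to
#' the total.
#'
#' @param og_set Character vector of orthogroup ids.
#' @param ann A \code{gene_annotations} object.
#' @return List with \code{counts} (named integer vector per letter, sorted)
#'   and \code{total} (number of genes in the set).
#' @export
category_gene_counts <- function(og_set, ann) {
  rows <- ann$orthogroup_id %in% og_set
  letters_all <- unlist(ann$cog[rows], use.names = FALSE)
  if (length(letters_all) == 0)
    return(list(counts = stats::setNames(integer(0), character(0)),
                total = sum(rows)))
  counts <- table(letters_all)
  counts <- stats::setNames(as.integer(counts), names(counts))
  list(counts = counts[order(names(counts))], total = sum(rows))
}

#' COG category enrichment of an orthogroup set against the soft core
#'
#' For every category letter observed in the target or core gene pools, a 2x2
#' contingency table of gene counts (in/out of the category, target vs core)
#' is tested with \code{\link{fisher_exact}}; p-values are BH-adjusted across
#' the categories of this set. The percent deviation from the core expectation
#' \code{D = 100 * (p_obs / p_core - 1)} and the representation
#' \code{R = D + 100} are both reported, along with the log-odds ratio. A
#' category is classified \code{"over"} when \code{D} exceeds the deviation
#' threshold with adjusted p below alpha, \code{"under"} for the mirror case,
#' \code{"low-support"} when fewer than \code{min_gene_support} genes carry
#' the category across the comparison, and \code{"ns"} otherwise.
#'
#' @param target Character vector of orthogroup ids (e.g. a unique or shared
#'   set from \code{\link{partition_by_group}}).
#' @param core Character vector of soft-core orthogroup ids; a warning is
#'   issued if the sets overlap.
#' @param ann A \code{gene_annotations} object.
#' @param cfg An \code{\link{enrichment_config}}.
#' @param set_label Label recorded in the output rows.
#' @return Data frame with one row per category: cells \code{a,b,c,d},
#'   \code{odds_ratio}, \code{log_odds_ratio}, \code{haldane}, \code{p},
#'   \code{p_adj}, \code{deviation_pct}, \code{representation_pct},
#'   \code{n_genes}, \code{class}.
#' @export
enrich_vs_core <- function(target, core, ann, cfg = enrichment_config(),
                           set_label = "target") {
  if (length(intersect(target, core)))
    warning("enrich_vs_core: target and core sets overlap")
  tg <- category_gene_counts(target, ann)
  cg <- category_gene_counts(core, ann)
  if (cg$total == 0) stop_("enrich_vs_core: core has no annotated genes")
  if (tg$total == 0) stop_("enrich_vs_core: target has no genes")
  cats <- sort(union(names(tg$counts), names(cg$counts)))
  if (length(cats) == 0)
    stop_("enrich_vs_core: no COG categories in either set")
  a <- ifelse(is.na(tg$counts[cats]), 0L, tg$counts[cats])
  cc <- ifelse(is.na(cg$counts[cats]), 0L, cg$counts[cats])
  b <- tg$total - a
  d <- cg$total - cc
  tests <- lapply(seq_along(cats), function(i)
    fisher_exact(a[i], b[i], cc[i], d[i]))
  p <- vapply(tests, `[[`, numeric(1), "p_value")
  p_adj <- bh_adjust(p)
  p_obs <- a / tg$total
  p_core <- cc / cg$total
  D <- ifelse(p_core > 0, 100 * (p_obs / p_core - 1),
              ifelse(p_obs > 0, Inf, NaN))
  cls <- character(length(cats))
  for (i in seq_along(cats)) {
    cls[i] <- if (a[i] + cc[i] < cfg$min_gene_support) "low-support"
    else if (!is.nan(D[i]) && p_adj[i] < cfg$alpha &&
             D[i] > cfg$deviation_threshold_pct) "over"
    else if (!is.nan(D[i]) && p_adj[i] < cfg$alpha &&
             D[i] < -cfg$deviation_threshold_pct) "under"
    else "ns"
  }
  data.frame(set_label = set_label, category = cats,
             a = as.integer(a), b = as.integer(b),
             c = as.integer(cc), d = as.integer(d),
             odds_ratio = vapply(tests, `[[`, numeric(1), "odds_ratio"),
             log_odds_ratio = vapply(tests, `[[`, numeric(1), "log_odds_ratio"),
             haldane = vapply(tests, `[[`, logical(1), "haldane"),
             p = p, p_adj = p_adj,
             deviation_pct = D, representation_pct = D + 100,
             n_genes = as.integer(a), class = cls,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Enrichment of several orthogroup sets with a shared adjustment scope
#'
#' Runs \code{\link{enrich_vs_core}} for every named set; with
#' \code{adjust_scope = "global"} the BH correction (and the resulting
#' classification) is recomputed across all sets jointly.
#'
#' @param sets Named list of orthogroup id vectors.
#' @param core,ann,cfg As in \code{\link{enrich_vs_core}}.
#' @return One data frame with all records.
#' @export
enrich_sets <- function(sets, core, ann, cfg = enrichment_config()) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  res <- do.call(rbind, lapply(names(sets), function(nm)
    enrich_vs_core(sets[[nm]], core, ann, cfg, set_label = nm)))
  if (cfg$adjust_scope == "global") {
    res$p_adj <- bh_adjust(res$p)
    res$class <- ifelse(
      res$class == "low-support", "low-support",
      ifelse(!is.nan(res$deviation_pct) & res$p_adj < cfg$alpha &
               res$deviation_pct > cfg$deviation_threshold_pct, "over",
      ifelse(!is.nan(res$deviation_pct) & res$p_adj < cfg$alpha &
               res$deviation_pct < -cfg$deviation_threshold_pct, "under", "ns")))
  }
  res
}
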