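#' Per-genus differential orthogroups (target source vs all others)
#'
#' Within one genus, compares per-isolate gene counts of every orthogroup
#' between the target-source isolates and all other isolates with the
#' Mann-Whitney U test, BH-adjusts across the tested orthogroups, and calls
#' the direction from the group means. Orthogroups with no gene in any isolate
#' of the genus are skipped before adjustment (they carry no information and
#' would only inflate the multiplicity burden); \code{test_all = TRUE} keeps
#' them.
#'
#' @param mat An \code{\link{og_matrix}} or counts matrix.
#' @param metadata An \code{isolate_metadata} data frame.
#' @param genus Genus to analyse.
#' @param target_source Source label defining the target group; default
#'   \code{"leaf"}.
#' @param alpha Significance level on the adjusted p-values; default 0.05.
#' @param test_all Keep all-zero orthogroups in the test set; default FALSE.
#' @param exact_max Use the exact rank permutation distribution when the genus
#'   has at most this many isolates (the per-source group sizes of such panels
#'   are small enough that the exact tail is both affordable and more accurate
#'   than the normal approximation); the tie-corrected normal approximation is
#'   used above it. Default 30.
#' @return Data frame of class \code{differential_result}: one row per tested
#'   orthogroup with means, direction, U, p, p_adj and \code{significant}.
#' @export
differential_orthogroups <- function(mat, metadata, genus,
                                     target_source = "leaf", alpha = 0.05,
                                     test_all = FALSE, exact_max = 30) {
  counts <- if (inherits(mat, "og_matrix")) mat$counts else as.matrix(mat)
  md <- metadata[metadata$genus == genus, , drop = FALSE]
  md <- md[md$isolate_id %in% rownames(counts), , drop = FALSE]
  tgt <- md$isolate_id[md$source == target_source]
  oth <- md$isolate_id[md$source != target_source]
  if (length(tgt) < 2 || length(oth) < 2)
    stop_("differential_orthogroups: genus ", genus, " has ", length(tgt),
          " ", target_source, " and ", length(oth),
          " other isolates; need >= 2 in each")
  sub <- counts[c(tgt, oth), , drop = FALSE]
  nz <- colSums(sub) > 0
  if (!test_all) {
    n_skip <- sum(!nz)
    if (n_skip) message("differential_orthogroups: skipping ", n_skip,
                        " all-zero orthogroup(s) in ", genus)
    sub <- sub[, nz, drop = FALSE]
  }
  n1 <- length(tgt)
  mode <- if (n1 + length(oth) <= exact_max) "exact" else "normal"
  ogs <- colnames(sub)
  U <- numeric(length(ogs)); p <- numeric(length(ogs))
  m_t <- numeric(length(ogs)); m_o <- numeric(length(ogs))
  for (j in seq_along(ogs)) {
    x <- sub[seq_len(n1), j]
    y <- sub[-seq_len(n1), j]
    tst <- mann_whitney_u(x, y, mode = mode)
    U[j] <- tst$statistic; p[j] <- tst$p_value
    m_t[j] <- mean(x); m_o[j] <- mean(y)
  }
  p_adj <- bh_adjust(p)
  res <- data.frame(orthogroup_id = ogs, genus = genus,
                    mean_count_target = m_t, mean_count_other = m_o,
                    direction = ifelse(m_t > m_o, "enriched", "depleted"),
                    U = U, p = p, p_adj = p_adj,
                    significant = p_adj < alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("differential_result", "data.frame")
  res
}

# insert-absorb construction of a compact letter display from the set of
# significant pairs: start with one letter covering all groups; for each
# significant pair split every letter containing both; absorb subsets.
.letter_display <- function(groups, sig_pairs) {
  sets <- list(groups)
  for (pr in sig_pairs) {
    out <- list()
    for (s in sets) {
      if (all(pr %in% s)) {
        out <- c(out, list(setdiff(s, pr[1])), list(setdiff(s, pr[2])))
      } else out <- c(out, list(s))
    }
    # absorb: drop sets contained in another set
    keep <- rep(TRUE, length(out))
    for (i in seq_along(out)) for (j in seq_along(out)) {
      if (i != j && keep[i] && keep[j] && all(out[[i]] %in% out[[j]]) &&
          (length(out[[i]]) < length(out[[j]]) || i > j))
        keep[i] <- FALSE
    }
    sets <- out[keep]
  }
  # order sets by first member's position in the group order for determinism
  first_pos <- vapply(sets, function(s) min(match(s, groups)), numeric(1))
  sets <- sets[order(first_pos)]
  lab <- stats::setNames(rep("", length(groups)), groups)
  for (i in seq_along(sets))
    lab[sets[[i]]] <- paste0(lab[sets[[i]]], letters[i])
  lab
}

#' Pairwise group comparison of a per-isolate metric with a letter display
#'
#' All pairwise Mann-Whitney U tests between groups (e.g. genome size or
#' glycoside-hydrolase count across isolation sources), Bonferroni-corrected
#' over the number of pairs, summarized as a compact letter display: two
#' groups share a letter iff their pairwise adjusted p-value is >= alpha.
#' Singleton groups are excluded with a warning.
#'
#' @param values Numeric per-isolate metric.
#' @param groups Per-isolate group labels (same length).
#' @param alpha Significance level; default 0.05.
#' @param mode Mann-Whitney mode passed through; default \code{"auto"}.
#' @return List with \code{pairwise} (data frame: group1, group2, U, p, p_adj,
#'   significant) and \code{letters} (named character vector).
#' @export
compare_group_metric <- function(values, groups, alpha = 0.05, mode = "auto") {
  if (length(values) != length(groups))
    stop_("compare_group_metric: values and groups differ in length")
  tab <- table(groups)
  singles <- names(tab)[tab < 2]
  if (length(singles)) {
    warning("compare_group_metric: excluding singleton group(s) ",
            paste(singles, collapse = ", "))
    keep <- !(groups %in% singles)
    values <- values[keep]; groups <- groups[keep]
  }
  glev <- unique(groups)
  if (length(glev) < 2)
    stop_("compare_group_metric: need >= 2 groups with >= 2 members")
  pairs <- utils::combn(glev, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    tst <- mann_whitney_u(values[groups == pr[1]], values[groups == pr[2]],
                          mode = mode)
    data.frame(group1 = pr[1], group2 = pr[2], U = tst$statistic,
               p = tst$p_value, stringsAsFactors = FALSE)
  })
  pw <- do.call(rbind, rows)
  pw$p_adj <- bonferroni_adjust(pw$p)
  pw$significant <- pw$p_adj < alpha
  sig_pairs <- lapply(which(pw$significant), function(i)
    c(pw$group1[i], pw$group2[i]))
  lett <- .letter_display(glev, sig_pairs)
  # consistency: groups sharing a letter are never significantly different
  for (i in which(pw$significant)) {
    stopifnot(!any(strsplit(lett[pw$group1[i]], "")[[1]] %in%
                     strsplit(lett[pw$group2[i]], "")[[1]]))
  }
  list(pairwise = pw, letters = lett)
}
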