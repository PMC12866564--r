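#' Fisher's exact test for a 2x2 contingency table
#'
#' Exact two-sided test of independence in a 2x2 table, computed from the
#' hypergeometric distribution of the upper-left cell given fixed margins.
#' The two-sided p-value follows the "method of small p-values": it sums the
#' probabilities of all tables (with the same margins) whose probability does
#' not exceed that of the observed table, with a relative tolerance of 1e-7
#' for floating-point ties. The odds ratio is the unconditional sample
#' estimate \code{(a*d)/(b*c)}; when a zero cell makes it degenerate the
#' log-odds ratio is computed with the Haldane-Anscombe 0.5 correction and
#' flagged.
#'
#' @param a,b,c,d Non-negative integer cell counts. \code{a,b} form the first
#'   row (e.g. a target gene set in / out of a functional category), \code{c,d}
#'   the second (the reference, e.g. soft-core genes in / out).
#' @return A list with elements \code{odds_ratio}, \code{log_odds_ratio},
#'   \code{haldane} (logical; TRUE when the 0.5 correction was used for the
#'   LOR), \code{p_value} and \code{method}.
#' @examples
#' fisher_exact(10, 90, 5, 195)
#' @export
fisher_exact <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) stop_("fisher_exact: negative cell count")
  if (any(cells != floor(cells))) stop_("fisher_exact: non-integer cell count")
  m <- a + b   # row 1 total
  n <- c + d   # row 2 total
  k <- a + c   # column 1 total
  if (m == 0 || n == 0)
    stop_("fisher_exact: a+b and c+d must both be positive")

  ad <- a * d; bc <- b * c
  or <- if (bc == 0) {
    if (ad == 0) NaN else Inf
  } else ad / bc
  haldane <- (a == 0 || b == 0 || c == 0 || d == 0)
  lor <- if (haldane) {
    log(((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5)))
  } else log(or)

  # hypergeometric support for the a-cell given the margins
  lo <- max(0L, k - n)
  hi <- min(k, m)
  x <- lo:hi
  logp <- lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  logp_obs <- logp[x == a]
  p <- sum(exp(logp[logp <= logp_obs + log(1 + 1e-7)]))
  list(odds_ratio = or, log_odds_ratio = lor, haldane = haldane,
       p_value = min(1, p), method = "fisher.exact")
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment: for p-values sorted ascending,
#' \code{adj[i] = min_{j >= i}(p[j] * m / j)}, capped at 1, returned in the
#' original input order.
#'
#' @param p Numeric vector of p-values in \code{[0, 1]}.
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_("bh_adjust: p-values outside [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Bonferroni adjustment
#'
#' @param p Numeric vector of p-values.
#' @return \code{pmin(1, p * length(p))}.
#' @export
bonferroni_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop_("bonferroni_adjust: p-values outside [0, 1]")
  pmin(1, p * length(p))
}

# Exact permutation distribution of the rank-sum under relabelling of the
# pooled (possibly tied) observations. Works on doubled midranks so all sums
# are integers; returns the two-sided tail probability for the observed U.
# Equivalent to enumerating all choose(n1+n2, n1) labelings, but computed by
# dynamic programming over (subset size, rank sum).
mwu_exact_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))           # midranks
  d <- as.integer(round(2 * r))  # doubled -> integers
  smax <- sum(sort(d, decreasing = TRUE)[seq_len(n1)])
  # counts[k+1, s+1] = number of size-k subsets with doubled rank sum s
  counts <- matrix(0, nrow = n1 + 1, ncol = smax + 1)
  counts[1, 1] <- 1
  for (di in d) {
    kmax <- n1  # update rows top-down is unnecessary: matrix copy semantics
    upd <- counts[seq_len(kmax), seq_len(smax + 1 - di), drop = FALSE]
    counts[2:(kmax + 1), (di + 1):(smax + 1)] <-
      counts[2:(kmax + 1), (di + 1):(smax + 1)] + upd
  }
  dist <- counts[n1 + 1, ]
  s_vals <- 0:smax
  center <- n1 * (N + 1)              # doubled E[rank sum]
  s_obs <- as.integer(round(2 * sum(r[seq_len(n1)])))
  dev <- abs(s_obs - center)
  tail <- sum(dist[abs(s_vals - center) >= dev - 1e-9])
  tail / choose(N, n1)
}

#' Mann-Whitney U rank-sum test
#'
#' Two-sample two-sided rank test. The statistic is
#' \code{U = #\{(x_i, y_j): x_i > y_j\} + 0.5 * #ties}. In \code{"exact"} mode
#' the p-value comes from the permutation distribution of U over all
#' relabellings of the observed (possibly tied) pooled values — the two-sided
#' tail is \code{P(|U - n1*n2/2| >= |U_obs - n1*n2/2|)}, which is well defined
#' because the permutation distribution is symmetric about \code{n1*n2/2}. In
#' \code{"normal"} mode the tie-corrected normal approximation with continuity
#' correction is used. \code{"auto"} picks exact when \code{n1 + n2 <= 12}.
#'
#' @param x,y Numeric samples (non-empty).
#' @param mode One of \code{"auto"}, \code{"exact"}, \code{"normal"}.
#' @return A list with \code{statistic} (U for the first sample),
#'   \code{p_value} and \code{method}.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))          # U = 0, exact p = 1/3
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0)
    stop_("mann_whitney_u: empty sample")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (mode == "auto") mode <- if (N <= 12) "exact" else "normal"
  if (mode == "exact") {
    p <- mwu_exact_p(x, y)
    method <- "mann-whitney.exact"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- max(0, abs(U - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-z))
    }
    method <- "mann-whitney.normal"
  }
  list(statistic = U, p_value = p, method = method)
}

#' ROC curve and AUC from scores and binary labels
#'
#' AUC is the fraction of (positive, negative) pairs ranked correctly, with
#' ties counting one half — the normalized Mann-Whitney U statistic. ROC
#' points are computed by sweeping the decision threshold over the distinct
#' score values (ties advance jointly).
#'
#' @param scores Numeric vector of classifier scores (higher = more positive).
#' @param labels Binary labels (0/1 or logical), both classes present.
#' @return A list with \code{auc} and \code{roc}, a data frame of
#'   \code{fpr}/\code{tpr} points from (0,0) to (1,1).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    stop_("roc_auc: scores and labels differ in length")
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0)
    stop_("roc_auc: both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  o <- order(scores, decreasing = TRUE)
  ls <- labels[o]; ss <- scores[o]
  grp_end <- !duplicated(ss, fromLast = TRUE)  # last index of each tie block
  tpr <- cumsum(ls == 1)[grp_end] / npos
  fpr <- cumsum(ls == 0)[grp_end] / nneg
  roc <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  list(auc = auc, roc = roc)
}
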