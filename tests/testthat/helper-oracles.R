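# Independent brute-force oracles used to validate the analytical kernels.
# These deliberately take the slow, obviously-correct route and share no code
# with the implementations they check.

# two-sided Fisher p by direct enumeration of the hypergeometric densities
# (stats::dhyper, not the package's own log-choose arithmetic)
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  x <- max(0, k - n):min(k, m)
  dens <- dhyper(x, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(dens[dens <= p_obs * (1 + 1e-7)])
}

# exact two-sided Mann-Whitney p by full enumeration of all labelings
oracle_mwu <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x); N <- length(pool)
  r <- rank(pool)
  u_of <- function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2
  U_obs <- u_of(seq_len(n1))
  center <- n1 * length(y) / 2
  subs <- combn(N, n1)
  U_all <- apply(subs, 2, u_of)
  list(U = U_obs,
       p = mean(abs(U_all - center) >= abs(U_obs - center) - 1e-9))
}

# AUC by explicit pairwise comparison
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# partition by testing every non-empty group subset per orthogroup
oracle_partition <- function(presence, groups, tau = 0.95, strict = 0.95) {
  glev <- sort(unique(groups))
  core <- colnames(presence)[colMeans(presence > 0) >= tau]
  subsets <- unlist(lapply(seq_along(glev), function(k)
    combn(glev, k, simplify = FALSE)), recursive = FALSE)
  assign_one <- function(og) {
    pres <- presence[, og] > 0
    for (S in subsets) {
      in_S <- groups %in% S
      ok <- all(vapply(S, function(g) {
        sel <- groups == g
        any(pres[sel]) && mean(pres[sel]) >= strict
      }, logical(1))) && !any(pres[!in_S])
      if (ok) return(paste(S, collapse = "+"))
    }
    "unclassified"
  }
  rest <- setdiff(colnames(presence), core)
  cats <- vapply(rest, assign_one, "")
  list(core = core, assignment = cats)
}

# random AND/OR KO tree (depth-limited) plus an independent direct evaluator
random_ko_tree <- function(depth = 3, pool = sprintf("K%05d", 1:30)) {
  if (depth == 0 || runif(1) < 0.4)
    return(list(type = "ko", ko = sample(pool, 1), optional = FALSE))
  kids <- lapply(seq_len(sample(2:3, 1)), function(i)
    random_ko_tree(depth - 1, pool))
  list(type = sample(c("and", "or"), 1), children = kids, optional = FALSE)
}

oracle_tree_score <- function(node, kos) {
  if (node$type == "ko") return(if (node$ko %in% kos) 1 else 0)
  vals <- unlist(lapply(node$children, oracle_tree_score, kos = kos))
  if (node$type == "and") sum(vals) / length(vals) else max(vals)
}

count_tree_leaves <- function(node) {
  if (node$type == "ko") return(1L)
  sum(vapply(node$children, count_tree_leaves, integer(1)))
}

# small helper to write fixture text files
write_fixture <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
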