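test_that("fisher_exact reproduces worked examples and reference values", {
  f <- fisher_exact(10, 90, 5, 195)
  expect_equal(f$odds_ratio, 10 * 195 / (90 * 5))
  expect_equal(f$p_value, oracle_fisher_p(10, 90, 5, 195), tolerance = 1e-12)
  expect_equal(f$p_value, stats::fisher.test(matrix(c(10, 5, 90, 195), 2))$p.value,
               tolerance = 1e-8)

  sym <- fisher_exact(5, 5, 5, 5)
  expect_equal(sym$odds_ratio, 1)
  expect_equal(sym$p_value, 1)

  deg <- fisher_exact(2, 0, 0, 2)
  expect_identical(deg$odds_ratio, Inf)
  expect_equal(deg$p_value, 1 / 3)   # P(a=2) = P(a=0) = 1/6
  expect_true(deg$haldane)

  expect_true(is.nan(fisher_exact(0, 2, 0, 2)$odds_ratio))
  expect_error(fisher_exact(-1, 1, 1, 1), "negative")
  expect_error(fisher_exact(0, 0, 1, 1), "positive")
})

test_that("fisher_exact equals hypergeometric enumeration across table space", {
  # exhaustive over all valid tables with total n <= 16
  for (n in 2:16) {
    parts <- expand.grid(a = 0:n, b = 0:n, c = 0:n)
    parts$d <- n - parts$a - parts$b - parts$c
    parts <- parts[parts$d >= 0 & parts$a + parts$b > 0 & parts$c + parts$d > 0, ]
    p_impl <- mapply(function(a, b, c, d) fisher_exact(a, b, c, d)$p_value,
                     parts$a, parts$b, parts$c, parts$d)
    p_orac <- mapply(oracle_fisher_p, parts$a, parts$b, parts$c, parts$d)
    expect_lt(max(abs(p_impl - pmin(p_orac, 1))), 1e-10)
  }
  # random tables with totals up to 60
  set.seed(42)
  for (i in 1:400) {
    n <- sample(4:60, 1)
    cuts <- sort(sample(0:n, 3, replace = TRUE))
    a <- cuts[1]; b <- cuts[2] - cuts[1]; c <- cuts[3] - cuts[2]; d <- n - cuts[3]
    if (a + b == 0 || c + d == 0) next
    expect_equal(fisher_exact(a, b, c, d)$p_value,
                 min(1, oracle_fisher_p(a, b, c, d)), tolerance = 1e-10)
  }
})

test_that("bh_adjust matches the step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.04, 0.03)), c(0.015, 0.04, 0.04))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  set.seed(7)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, p.adjust(p, "BH"))
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})

test_that("bonferroni_adjust caps at one and matches the reference", {
  expect_equal(bonferroni_adjust(rep(0.01, 3)), rep(0.03, 3))
  expect_equal(bonferroni_adjust(c(0.5, 0.6)), c(1, 1))
  expect_equal(bonferroni_adjust(0.3), 0.3)
  set.seed(8)
  p <- runif(25)
  expect_equal(bonferroni_adjust(p), p.adjust(p, "bonferroni"))
})

test_that("mann_whitney_u exact mode reproduces enumeration on worked examples", {
  m <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(m$statistic, 0)
  expect_equal(m$p_value, 1 / 3)

  tied <- mann_whitney_u(c(2, 2, 2), c(2, 2, 2))
  expect_equal(tied$statistic, 9 / 2)
  expect_equal(tied$p_value, 1)

  m2 <- mann_whitney_u(c(1, 3, 5), c(2, 4, 6))
  expect_equal(m2$statistic, 3)
  expect_equal(m2$p_value, 0.7)   # enumeration of all C(6,3) = 20 labelings

  m3 <- mann_whitney_u(c(5, 5, 5), c(1, 1, 1))
  expect_equal(m3$statistic, 9)
  expect_equal(m3$p_value, 0.1)

  expect_error(mann_whitney_u(numeric(0), 1:3), "empty")
})

test_that("exact Mann-Whitney equals full labeling enumeration, ties included", {
  set.seed(11)
  for (i in 1:60) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- sample(0:4, n1, replace = TRUE)   # heavy ties
    y <- sample(0:4, n2, replace = TRUE)
    got <- mann_whitney_u(x, y, mode = "exact")
    want <- oracle_mwu(x, y)
    expect_equal(got$statistic, want$U)
    expect_equal(got$p_value, want$p, tolerance = 1e-12)
  }
})

test_that("normal approximation is sane and close to exact at moderate n", {
  set.seed(12)
  for (i in 1:20) {
    x <- rnorm(6); y <- rnorm(6, 1)
    pe <- mann_whitney_u(x, y, mode = "exact")$p_value
    pn <- mann_whitney_u(x, y, mode = "normal")$p_value
    expect_lt(abs(pe - pn), 0.05)
  }
  # identical samples: degenerate variance handled
  expect_equal(mann_whitney_u(rep(1, 15), rep(1, 15), mode = "normal")$p_value, 1)
})

test_that("roc_auc matches the pairwise-count oracle and the U statistic", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0))$auc, 0.5)
  expect_equal(roc_auc(c(0.8, 0.4, 0.6, 0.2), c(1, 1, 0, 0))$auc, 0.75)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
  set.seed(13)
  for (i in 1:30) {
    n <- sample(4:20, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.5))
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    got <- roc_auc(scores, labels)$auc
    expect_equal(got, oracle_auc(scores, labels))
    # AUC is the normalized Mann-Whitney U of positive scores
    U <- mann_whitney_u(scores[labels == 1], scores[labels == 0],
                        mode = "normal")$statistic
    expect_equal(got, U / (sum(labels == 1) * sum(labels == 0)))
  }
  # ROC endpoints and monotonicity
  r <- roc_auc(runif(20), c(1, 0, rbinom(18, 1, 0.5)))$roc
  expect_equal(unlist(r[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(r[nrow(r), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
})
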