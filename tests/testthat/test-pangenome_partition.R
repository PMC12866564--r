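make_presence <- function(mat) {
  rownames(mat) <- paste0("i", seq_len(nrow(mat)))
  colnames(mat) <- paste0("OG", seq_len(ncol(mat)))
  mat
}

test_that("presence is count > 0 and idempotent", {
  m <- make_presence(rbind(c(0L, 7L), c(2L, 0L)))
  p <- presence_from_counts(m)
  expect_equal(unname(p), rbind(c(0L, 1L), c(1L, 0L)))
  expect_equal(presence_from_counts(p), p)
  expect_equal(unname(colSums(p)), c(1, 1))
})

test_that("soft core applies an inclusive occupancy fraction", {
  pres <- matrix(0L, 128, 2, dimnames = list(paste0("i", 1:128), c("OG122", "OG121")))
  pres[1:122, 1] <- 1L   # 122/128 = 0.953 >= 0.95
  pres[1:121, 2] <- 1L   # 121/128 = 0.945 <  0.95
  expect_equal(soft_core(pres), "OG122")
  allp <- matrix(1L, 10, 1, dimnames = list(paste0("i", 1:10), "OGall"))
  expect_equal(soft_core(allp, core_occupancy = 1), "OGall")
  # tau = 1 equals the strict core
  pres2 <- make_presence(matrix(rbinom(50, 1, 0.8), 5))
  expect_setequal(soft_core(pres2, 1),
                  colnames(pres2)[colSums(pres2) == nrow(pres2)])
  # monotone: raising tau never adds orthogroups
  set.seed(21)
  pres3 <- make_presence(matrix(rbinom(400, 1, 0.9), 20))
  taus <- c(0.5, 0.75, 0.9, 0.95, 1)
  cores <- lapply(taus, function(t) soft_core(pres3, t))
  for (i in seq_len(length(cores) - 1))
    expect_true(all(cores[[i + 1]] %in% cores[[i]]))
})

test_that("group-level occupancy counts distinct groups", {
  pres <- make_presence(rbind(c(1L), c(0L), c(1L), c(0L)))
  groups <- c("A", "A", "B", "B")
  # present in both groups -> group occupancy 1
  expect_equal(soft_core(pres, 0.95, groups), "OG1")
  pres[3, 1] <- 0L   # now only group A -> occupancy 0.5
  expect_equal(length(soft_core(pres, 0.95, groups)), 0L)
})

test_that("strict combination partition assigns unique and shared sets", {
  md <- data.frame(isolate_id = paste0("i", 1:6),
                   genus = "G",
                   source = rep(c("A", "B", "C"), each = 2),
                   stringsAsFactors = FALSE)
  pres <- matrix(0L, 6, 3,
                 dimnames = list(paste0("i", 1:6), c("OGa", "OGab", "OGnone")))
  pres[1, 1] <- 1L               # only i1 (group A)
  pres[c(1, 3), 2] <- 1L         # i1 (A) and i3 (B)
  part <- partition_by_group(pres, md, "source", strict_fraction = 0)
  expect_equal(part$combos[["A"]], "OGa")
  expect_equal(part$combos[["A+B"]], "OGab")
  expect_true("OGnone" %in% part$unclassified)
  # with the strict 0.95 rule, half-present groups are unclassified
  strictp <- partition_by_group(pres, md, "source", strict_fraction = 0.95)
  expect_true(all(c("OGa", "OGab") %in% strictp$unclassified))
})

test_that("partition equals brute-force subset matching on random fixtures", {
  set.seed(31)
  for (rep in 1:4) {
    g <- sample(3:5, 1)
    n_per <- sample(2:3, 1)
    n_iso <- g * n_per
    groups <- rep(LETTERS[1:g], each = n_per)
    pres <- matrix(rbinom(n_iso * 50, 1, 0.45), n_iso, 50)
    rownames(pres) <- paste0("i", 1:n_iso)
    colnames(pres) <- sprintf("OG%03d", 1:50)
    md <- data.frame(isolate_id = rownames(pres), genus = "G",
                     source = groups, stringsAsFactors = FALSE)
    for (strict in c(0, 0.95)) {
      part <- partition_by_group(pres, md, "source", strict_fraction = strict)
      want <- oracle_partition(pres, groups, 0.95, strict)
      expect_setequal(part$core, want$core)
      got_cat <- setNames(rep("unclassified", 50), colnames(pres))
      got_cat[part$core] <- "core"
      for (k in names(part$combos)) got_cat[part$combos[[k]]] <- k
      expect_equal(got_cat[names(want$assignment)],
                   setNames(want$assignment, names(want$assignment)))
      # disjoint-union invariant
      all_ids <- c(part$core, unlist(part$combos, use.names = FALSE),
                   part$unclassified)
      expect_equal(sort(all_ids), sort(colnames(pres)))
      expect_equal(anyDuplicated(all_ids), 0L)
    }
  }
})

test_that("isolate order never changes the partition", {
  set.seed(32)
  pres <- matrix(rbinom(120, 1, 0.5), 12, 10)
  rownames(pres) <- paste0("i", 1:12)
  colnames(pres) <- paste0("OG", 1:10)
  md <- data.frame(isolate_id = rownames(pres), genus = "G",
                   source = rep(c("A", "B", "C"), 4), stringsAsFactors = FALSE)
  p1 <- partition_by_group(pres, md, "source")
  perm <- sample(12)
  p2 <- partition_by_group(pres[perm, ], md, "source")
  expect_setequal(p1$core, p2$core)
  expect_equal(lapply(p1$combos[sort(names(p1$combos))], sort),
               lapply(p2$combos[sort(names(p2$combos))], sort))
  expect_setequal(p1$unclassified, p2$unclassified)
})

test_that("pangenome summary reproduces the printed assignment statistics", {
  # 682,566 of 690,814 genes in 25,903 orthogroups -> 98.8%, mean size 26.4
  n_og <- 25903L
  counts <- matrix(rep(682566L %/% n_og, n_og), 1,
                   dimnames = list("pool", sprintf("OG%05d", 1:n_og)))
  counts[1, seq_len(682566L %% n_og)] <- counts[1, seq_len(682566L %% n_og)] + 1L
  s <- pangenome_summary(og_matrix(counts, c(pool = 690814L - 682566L)))
  expect_equal(s$total_genes, 690814)
  expect_equal(s$pct_assigned, 98.8)
  expect_equal(s$mean_og_size, 26.4)

  # 853,022 genes (99.4%) across 18,563 orthogroups, 5,003 unassigned
  n_og2 <- 18563L
  counts2 <- matrix(rep(853022L %/% n_og2, n_og2), 1,
                    dimnames = list("pool", sprintf("OG%05d", 1:n_og2)))
  counts2[1, seq_len(853022L %% n_og2)] <- counts2[1, seq_len(853022L %% n_og2)] + 1L
  s2 <- pangenome_summary(og_matrix(counts2, c(pool = 5003L)))
  expect_equal(s2$pct_assigned, 99.4)

  one <- og_matrix(matrix(7L, 1, 1, dimnames = list("i", "OG1")))
  s3 <- pangenome_summary(one)
  expect_equal(s3$pct_assigned, 100)
  expect_equal(s3$mean_og_size, 7)
})
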