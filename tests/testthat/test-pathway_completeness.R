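test_that("the definition grammar parses with the stated precedences", {
  d <- parse_pathway_definition("K00001 K00002,K00003")
  expect_equal(d$root$type, "and")
  expect_equal(d$root$children[[1]]$ko, "K00001")
  expect_equal(d$root$children[[2]]$type, "or")

  d2 <- parse_pathway_definition("(K00001,K00002) K00003+K00004")
  expect_equal(d2$root$type, "and")
  expect_equal(d2$root$children[[1]]$type, "or")
  expect_equal(d2$root$children[[2]]$type, "and")
  expect_equal(vapply(d2$root$children[[2]]$children, `[[`, "", "ko"),
               c("K00003", "K00004"))

  d3 <- parse_pathway_definition("K00001 -K00005")
  expect_true(d3$root$children[[2]]$optional)
  expect_equal(pathway_completeness(d3, "K00001"), 100)
  expect_equal(pathway_completeness(d3, character(0)), 0)

  expect_error(parse_pathway_definition("K00001 (K00002"), "expected '\\)'")
  expect_error(parse_pathway_definition("K0001x"), "malformed KO")
  expect_error(parse_pathway_definition("   "), "empty")
  expect_error(parse_pathway_definition("K00001 ) K00002"), "position")
})

test_that("completeness is mean-over-AND, max-over-OR", {
  d <- parse_pathway_definition("K00001 K00002,K00003")
  expect_equal(pathway_completeness(d, c("K00001", "K00003")), 100)
  d4 <- parse_pathway_definition("K00001 K00002 K00003 K00004")
  expect_equal(pathway_completeness(d4, c("K00001", "K00002")), 50)
  # all-optional definitions have no score
  dall <- parse_pathway_definition("-K00001 -K00002")
  expect_true(is.na(pathway_completeness(dall, "K00001")))
})

test_that("parser and scorer agree with an independent tree evaluator", {
  set.seed(61)
  pool <- sprintf("K%05d", 1:30)
  for (i in 1:50) {
    tree <- random_ko_tree(depth = sample(2:4, 1), pool = pool)
    if (count_tree_leaves(tree) > 12) next
    txt <- unparse_pathway_definition(tree)
    d <- parse_pathway_definition(txt)
    # round trip: reparsing the serialization reproduces the tree
    expect_identical(d$root, tree)
    for (j in 1:4) {
      kos <- sample(pool, sample(0:12, 1))
      expect_equal(pathway_completeness(d, kos),
                   100 * oracle_tree_score(tree, kos))
    }
  }
})

test_that("adding a KO never decreases any completeness score", {
  set.seed(62)
  pool <- sprintf("K%05d", 1:20)
  for (i in 1:15) {
    tree <- random_ko_tree(depth = 3, pool = pool)
    d <- parse_pathway_definition(unparse_pathway_definition(tree))
    kos <- sample(pool, 5)
    base <- pathway_completeness(d, kos)
    for (extra in setdiff(pool, kos)[1:5])
      expect_gte(pathway_completeness(d, c(kos, extra)), base)
    expect_true(base >= 0 && base <= 100)
  }
})

test_that("the completeness matrix scores per-isolate KO unions", {
  ann <- gene_annotation_map(
    gene_id = c("g1", "g2", "g3", "g4"),
    isolate_id = c("i1", "i1", "i2", "i3"),
    orthogroup_id = c("OG1", "OG2", "OG1", "OG3"),
    cog = rep(list(character(0)), 4),
    ko = list("K00001", c("K00002", "K00003"), "K00001", character(0)))
  defs <- list(
    P1 = parse_pathway_definition("K00001 K00002", "P1"),
    P2 = parse_pathway_definition("K00009", "P2"))
  cm <- completeness_matrix(defs, ann)
  expect_equal(cm["i1", "P1"], 100)
  expect_equal(cm["i2", "P1"], 50)
  expect_equal(cm["i3", "P1"], 0)   # empty KO set
  expect_equal(unname(cm[, "P2"]), c(0, 0, 0))
  # restriction to an orthogroup set drops the other genes' KOs
  cm_r <- completeness_matrix(defs, ann, restrict_to = "OG1")
  expect_equal(cm_r["i1", "P1"], 50)
  # superset isolate scores 100 everywhere
  sup <- gene_annotation_map("g9", "iSup", "OG1", list(character(0)),
                             list(c("K00001", "K00002", "K00009")))
  cms <- completeness_matrix(defs, sup)
  expect_equal(unname(cms["iSup", ]), c(100, 100))
})

test_that("per-source completeness comparison flags the planted pathway", {
  cfg <- simulation_config(seed = 9, n_core_ogs = 200, n_genus_ogs = 50,
                           n_shared_accessory = 20, n_planted_source_ogs = 0,
                           n_source_unique_ogs = 10, n_pathways = 5,
                           dropout = 0)
  sim <- simulate_study(cfg)
  cm <- completeness_matrix(sim$pathways, sim$annotations)
  md <- sim$metadata
  # planted pathway complete only in target-source isolates
  leaf <- md$isolate_id[md$source == "leaf"]
  expect_true(all(cm[leaf, sim$truth$planted_pathway_id] == 100))
  expect_true(all(cm[setdiff(rownames(cm), leaf),
                     sim$truth$planted_pathway_id] < 100))
  res <- compare_completeness_by_source(cm, md, "leaf")
  pl <- res[res$pathway_id == sim$truth$planted_pathway_id, ]
  expect_true(all(pl$direction == "enriched"))
  expect_true(any(pl$significant))
})
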