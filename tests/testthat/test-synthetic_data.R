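test_that("zero-noise configurations are recovered exactly", {
  cfg <- simulation_config(
    seed = 1, genera = list(G1 = c(leaf = 2, soil = 2), G2 = c(leaf = 2, soil = 2),
                            G3 = c(leaf = 2, soil = 2), G4 = c(leaf = 2, soil = 2)),
    n_core_ogs = 100, n_genus_ogs = 10, n_shared_accessory = 0,
    n_planted_source_ogs = 0, n_source_unique_ogs = 0, dropout = 0,
    n_pathways = 0)
  sim <- simulate_study(cfg, with_annotations = FALSE)
  got <- soft_core(presence_from_counts(sim$matrix))
  expect_setequal(got, sim$truth$core)
  # genus backbones are confined to their genus
  for (g in names(sim$truth$genus_backbones)) {
    ogs <- sim$truth$genus_backbones[[g]]
    outside <- sim$metadata$isolate_id[sim$metadata$genus != g]
    expect_equal(sum(sim$matrix$counts[outside, ogs]), 0L)
  }
})

test_that("planted structures are consistent with the emitted matrix", {
  cfg <- simulation_config(seed = 12, n_core_ogs = 200, n_genus_ogs = 50,
                           n_shared_accessory = 30, n_planted_source_ogs = 20,
                           n_source_unique_ogs = 10, dropout = 0)
  sim <- simulate_study(cfg, with_annotations = FALSE)
  m <- sim$matrix$counts
  expect_true(all(unlist(sim$truth[c("core", "planted_source_ogs",
                                     "source_unique_ogs")]) %in% colnames(m)))
  tgt <- sim$metadata$isolate_id[sim$metadata$source == cfg$target_source]
  oth <- setdiff(rownames(m), tgt)
  # source-unique orthogroups never appear outside the target source
  expect_equal(sum(m[oth, sim$truth$source_unique_ogs]), 0L)
  expect_true(all(m[tgt, sim$truth$source_unique_ogs] > 0))
  # planted shift raises target-source counts by about the stated effect
  shift <- mean(m[tgt, sim$truth$planted_source_ogs]) -
    mean(m[oth, sim$truth$planted_source_ogs])
  expect_gt(shift, cfg$planted_effect - 1)
  expect_lt(shift, cfg$planted_effect + 1)
  # zero-dropout core occupancy meets the soft-core threshold
  expect_true(all(colMeans(m[, sim$truth$core] > 0) >= 0.95))
})

test_that("the same seed reproduces the study byte for byte", {
  cfg <- simulation_config(seed = 33, n_core_ogs = 60, n_genus_ogs = 20,
                           n_shared_accessory = 10, n_planted_source_ogs = 5,
                           n_source_unique_ogs = 5, n_pathways = 3)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  s1 <- simulate_study(cfg, dir = d1)
  s2 <- simulate_study(cfg, dir = d2)
  expect_identical(s1$matrix$counts, s2$matrix$counts)
  expect_identical(s1$truth, s2$truth)
  for (f in c("genecounts.tsv", "metadata.tsv", "pathways.tsv", "truth.tsv",
              "annotations.tsv")) {
    l1 <- readLines(file.path(d1, f)); l2 <- readLines(file.path(d2, f))
    expect_identical(l1[-1], l2[-1])   # first line is the provenance stamp
  }
})

test_that("emitted files parse cleanly back through the readers", {
  cfg <- simulation_config(seed = 14, n_core_ogs = 80, n_genus_ogs = 20,
                           n_shared_accessory = 10, n_planted_source_ogs = 5,
                           n_source_unique_ogs = 5, n_pathways = 4)
  d <- file.path(tempdir(), "simC")
  sim <- simulate_study(cfg, dir = d)
  m <- read_genecount_table(file.path(d, "genecounts.tsv"))
  expect_identical(m$counts[rownames(sim$matrix$counts),
                            colnames(sim$matrix$counts)],
                   sim$matrix$counts)
  md <- read_metadata(file.path(d, "metadata.tsv"))
  expect_equal(md$isolate_id, sim$metadata$isolate_id)
  ann <- read_annotations(file.path(d, "annotations.tsv"))
  expect_equal(nrow(ann), nrow(sim$annotations))
  expect_identical(ann$cog, sim$annotations$cog)
  expect_identical(ann$ko, sim$annotations$ko)
  expect_true(validate_annotations(ann, m))
  defs <- read_pathway_definitions(file.path(d, "pathways.tsv"))
  expect_equal(names(defs), names(sim$pathways))
  for (k in names(defs))
    expect_identical(defs[[k]]$root, sim$pathways[[k]]$root)
  # total gene conservation: annotations row count equals matrix gene count
  expect_equal(nrow(ann), sum(m$counts))
})

test_that("the ASV table realizes its designated core and rare taxa", {
  cfg <- simulation_config(seed = 44)
  asv <- simulate_asv_table(cfg)
  core <- core_taxa(asv$counts, asv$years)
  for (y in names(core))
    expect_setequal(core[[y]], asv$truth$core_taxa)
  ra <- relative_abundance(asv$counts)
  kept <- filter_low_abundance(ra, asv$years)
  expect_length(intersect(kept, asv$truth$low_abundance_taxa), 0)
  expect_setequal(kept, asv$truth$retained_taxa)
  asv2 <- simulate_asv_table(cfg)
  expect_identical(asv$counts, asv2$counts)
})
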