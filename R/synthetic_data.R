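# 23 COG functional category letters (single-letter classes)
.cog_letters <- c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J", "K", "L",
                  "M", "N", "O", "P", "Q", "T", "U", "V", "W", "Y", "Z")

#' Synthetic study configuration
#'
#' Parameters of the seeded synthetic genome-feature study: a multi-genus
#' isolate panel with a shared soft core, genus-specific orthogroup backbones,
#' shared accessory orthogroups, planted source-associated orthogroups with an
#' additive gene-count shift, orthogroups unique to the target source, gene
#' annotations with COG letters (one category can be planted at a fold-change
#' over its baseline frequency in the source-unique orthogroups) and KO sets
#' arranged so that one designated pathway is complete only in target-source
#' isolates.
#'
#' @param seed Integer seed; the same seed yields byte-identical outputs.
#' @param genera Named list: per genus, a named integer vector of isolate
#'   counts per source. The default is four genera of 15 isolates each
#'   (4 leaf, 3 flower, 3 soil, 3 human, 2 water), about 60 isolates in total.
#' @param n_core_ogs Soft-core orthogroups present in every isolate before
#'   dropout; default 1200.
#' @param n_genus_ogs Genus-backbone orthogroups per genus (present only
#'   within the genus); default 600.
#' @param n_shared_accessory Accessory orthogroups present in a random half of
#'   all isolates; default 300.
#' @param n_planted_source_ogs Orthogroups present everywhere whose counts are
#'   shifted by \code{planted_effect} in target-source isolates; default 50.
#' @param planted_effect Additive count shift lambda: target-source isolates
#'   carry \code{lambda} extra gene copies on top of the baseline count model;
#'   default 5.
#' @param n_source_unique_ogs Orthogroups present only in target-source
#'   isolates (these carry the planted COG bias and the planted pathway KOs);
#'   default 50.
#' @param target_source Source label receiving the planted signal; default
#'   \code{"leaf"}.
#' @param baseline_mu Poisson mean of present-cell gene counts (counts are
#'   \code{1 + Poisson(mu - 1)} so presence implies at least one gene);
#'   default 2.
#' @param dropout Probability that a present cell is zeroed; default 0.02.
#' @param cog_baseline Named numeric vector of baseline COG letter
#'   frequencies; defaults to a mildly decreasing profile over the 23 letters.
#' @param planted_cog_category,planted_cog_fold Category letter planted in
#'   source-unique orthogroup genes at \code{fold} times its baseline
#'   frequency; defaults \code{"Q"} and 3.
#' @param unannotated_prob Probability a gene has no COG letter; default 0.1.
#' @param multi_letter_prob Probability a COG-annotated gene carries a second
#'   letter; default 0.1.
#' @param n_pathways Number of pathway definitions emitted (the first is the
#'   planted one when \code{n_source_unique_ogs >= 4}); default 10.
#' @param n_ko_pool Size of the background KO pool; default 60.
#' @param asv Amplicon-table parameters: \code{n_samples} (named per year),
#'   \code{n_taxa}, \code{n_core}, \code{n_low}, see
#'   \code{\link{simulate_asv_table}}.
#' @return A list of class \code{simulation_config}.
#' @export
simulation_config <- function(seed = 1,
                              genera = NULL,
                              n_core_ogs = 1200,
                              n_genus_ogs = 600,
                              n_shared_accessory = 300,
                              n_planted_source_ogs = 50,
                              planted_effect = 5,
                              n_source_unique_ogs = 50,
                              target_source = "leaf",
                              baseline_mu = 2,
                              dropout = 0.02,
                              cog_baseline = NULL,
                              planted_cog_category = "Q",
                              planted_cog_fold = 3,
                              unannotated_prob = 0.1,
                              multi_letter_prob = 0.1,
                              n_pathways = 10,
                              n_ko_pool = 60,
                              asv = NULL) {
  if (is.null(genera)) {
    per <- c(leaf = 4L, flower = 3L, soil = 3L, human = 3L, water = 2L)
    genera <- list(Aurellia = per, Brunnera = per, Candira = per,
                   Dorsia = per)
  }
  if (is.null(cog_baseline)) {
    w <- rev(seq_along(.cog_letters)) + 5
    cog_baseline <- stats::setNames(w / sum(w), .cog_letters)
  }
  if (is.null(asv))
    asv <- list(n_samples = c("2020" = 30L, "2021" = 30L),
                n_taxa = 40L, n_core = 6L, n_low = 8L)
  stopifnot(n_core_ogs >= 0, n_genus_ogs >= 0, n_shared_accessory >= 0,
            n_planted_source_ogs >= 0, n_source_unique_ogs >= 0,
            baseline_mu >= 1, dropout >= 0, dropout < 1,
            planted_cog_category %in% names(cog_baseline))
  structure(list(seed = as.integer(seed), genera = genera,
                 n_core_ogs = n_core_ogs, n_genus_ogs = n_genus_ogs,
                 n_shared_accessory = n_shared_accessory,
                 n_planted_source_ogs = n_planted_source_ogs,
                 planted_effect = planted_effect,
                 n_source_unique_ogs = n_source_unique_ogs,
                 target_source = target_source,
                 baseline_mu = baseline_mu, dropout = dropout,
                 cog_baseline = cog_baseline,
                 planted_cog_category = planted_cog_category,
                 planted_cog_fold = planted_cog_fold,
                 unannotated_prob = unannotated_prob,
                 multi_letter_prob = multi_letter_prob,
                 n_pathways = n_pathways, n_ko_pool = n_ko_pool,
                 asv = asv),
            class = "simulation_config")
}

# present-cell gene counts: at least one gene, Poisson-distributed copies
.rtpois <- function(n, mu) 1L + stats::rpois(n, max(mu - 1, 0))

# random pathway definition over a KO pool: 2-5 space-separated steps, each
# either a single KO, an OR of 2-3 KOs, or a '+' complex of 2 KOs
.random_definition <- function(pool) {
  n_steps <- sample(2:5, 1)
  steps <- vapply(seq_len(n_steps), function(i) {
    kind <- sample(c("ko", "or", "plus"), 1, prob = c(0.5, 0.3, 0.2))
    if (kind == "ko") sample(pool, 1)
    else if (kind == "or") paste(sample(pool, sample(2:3, 1)), collapse = ",")
    else paste(sample(pool, 2), collapse = "+")
  }, "")
  paste(steps, collapse = " ")
}

#' Simulate a synthetic comparative-genomics study
#'
#' Generates a seeded synthetic study matching the input dialects the package
#' reads: an orthogroup gene-count matrix with genus backbones, a shared soft
#' core, planted source-shifted orthogroups and source-unique orthogroups;
#' per-gene COG/KO annotations with a planted COG category bias; isolate
#' metadata; and pathway definitions of which the first is complete only in
#' target-source isolates. Ground-truth sets are returned for recovery tests.
#'
#' @param cfg A \code{\link{simulation_config}}.
#' @param dir Optional directory: when given, the study is written as
#'   \code{genecounts.tsv} (OrthoFinder dialect, with \code{Total} column),
#'   \code{annotations.tsv} (eggNOG-mapper dialect plus \code{isolate} and
#'   \code{orthogroup} columns), \code{metadata.tsv}, \code{pathways.tsv} and
#'   \code{truth.tsv}.
#' @param with_annotations Generate the per-gene annotation table (the most
#'   expensive part); set FALSE when only the count matrix is needed.
#' @return A list with \code{matrix} (\code{\link{og_matrix}}),
#'   \code{metadata}, \code{annotations} (or NULL), \code{pathways} (named
#'   list of \code{pathway_definition}), \code{truth} (ground-truth sets) and
#'   \code{files} (paths, when \code{dir} was given).
#' @export
simulate_study <- function(cfg = simulation_config(), dir = NULL,
                           with_annotations = TRUE) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)

  # ---- metadata ----
  iso <- list()
  for (g in names(cfg$genera)) {
    per <- cfg$genera[[g]]
    for (s in names(per)) {
      n <- per[[s]]
      if (n > 0)
        iso[[length(iso) + 1L]] <- data.frame(
          genus = g, source = s,
          isolate_id = sprintf("%s_%s_%02d", g, s, seq_len(n)),
          stringsAsFactors = FALSE)
    }
  }
  md <- do.call(rbind, iso)
  md$species <- paste0(md$genus, "_sp")
  md$year <- NA_integer_
  md$cluster <- NA_character_
  md <- md[, c("isolate_id", "genus", "species", "source", "year", "cluster")]
  class(md) <- c("isolate_metadata", "data.frame")
  n_iso <- nrow(md)
  is_target <- md$source == cfg$target_source
  if (cfg$n_source_unique_ogs > 0 && !any(is_target))
    stop_("simulate_study: no isolates of target source ", cfg$target_source)

  # ---- orthogroup blocks ----
  n_genera <- length(cfg$genera)
  blocks <- c(core = cfg$n_core_ogs,
              stats::setNames(rep(cfg$n_genus_ogs, n_genera),
                              paste0("genus:", names(cfg$genera))),
              accessory = cfg$n_shared_accessory,
              planted = cfg$n_planted_source_ogs,
              unique = cfg$n_source_unique_ogs)
  n_og <- sum(blocks)
  if (n_og == 0) stop_("simulate_study: no orthogroups configured")
  og_ids <- sprintf("OG%06d", seq_len(n_og))
  block_of <- rep(names(blocks), blocks)
  counts <- matrix(0L, nrow = n_iso, ncol = n_og,
                   dimnames = list(md$isolate_id, og_ids))
  mu <- cfg$baseline_mu

  fill <- function(rows, cols, mu) {
    counts[rows, cols] <<- .rtpois(length(rows) * length(cols), mu)
  }
  core_cols <- which(block_of == "core")
  if (length(core_cols)) fill(seq_len(n_iso), core_cols, mu)
  for (g in names(cfg$genera)) {
    cols <- which(block_of == paste0("genus:", g))
    rows <- which(md$genus == g)
    if (length(cols) && length(rows)) fill(rows, cols, mu)
  }
  acc_cols <- which(block_of == "accessory")
  if (length(acc_cols)) {
    pres <- matrix(stats::runif(n_iso * length(acc_cols)) < 0.5,
                   nrow = n_iso)
    vals <- .rtpois(sum(pres), mu)
    block <- matrix(0L, nrow = n_iso, ncol = length(acc_cols))
    block[pres] <- vals
    counts[, acc_cols] <- block
  }
  planted_cols <- which(block_of == "planted")
  if (length(planted_cols)) {
    fill(which(!is_target), planted_cols, mu)
    nt <- sum(is_target)
    counts[which(is_target), planted_cols] <-
      .rtpois(nt * length(planted_cols), mu) +
      as.integer(cfg$planted_effect)
  }
  uniq_cols <- which(block_of == "unique")
  if (length(uniq_cols)) fill(which(is_target), uniq_cols, mu)
  if (cfg$dropout > 0) {
    drop <- matrix(stats::runif(length(counts)) < cfg$dropout,
                   nrow = n_iso)
    counts[drop] <- 0L
  }
  mat <- og_matrix(counts)

  truth <- list(
    core = og_ids[block_of == "core"],
    genus_backbones = stats::setNames(
      lapply(names(cfg$genera), function(g)
        og_ids[block_of == paste0("genus:", g)]), names(cfg$genera)),
    shared_accessory = og_ids[block_of == "accessory"],
    planted_source_ogs = og_ids[block_of == "planted"],
    source_unique_ogs = og_ids[block_of == "unique"],
    planted_cog_category = cfg$planted_cog_category,
    planted_pathway_id = NA_character_)

  # ---- pathways and orthogroup -> KO map ----
  pool <- sprintf("K%05d", seq_len(cfg$n_ko_pool))
  og_ko <- stats::setNames(vector("list", n_og), og_ids)
  defs <- list()
  if (cfg$n_pathways > 0) {
    start <- 1L
    if (cfg$n_source_unique_ogs >= 4) {
      planted_kos <- sprintf("K%05d", 90001:90004)
      for (i in 1:4) og_ko[[og_ids[uniq_cols[i]]]] <- planted_kos[i]
      defs[["PW00001"]] <- parse_pathway_definition(
        paste(planted_kos, collapse = " "), "PW00001", "planted pathway")
      truth$planted_pathway_id <- "PW00001"
      start <- 2L
    }
    for (i in seq(from = start, length.out = cfg$n_pathways - start + 1L)) {
      id <- sprintf("PW%05d", i)
      defs[[id]] <- parse_pathway_definition(.random_definition(pool), id,
                                             paste("background pathway", i))
    }
    # scatter the background KO pool over core orthogroups
    if (length(core_cols)) {
      host <- sample(core_cols, length(pool), replace = TRUE)
      for (i in seq_along(pool)) {
        og <- og_ids[host[i]]
        og_ko[[og]] <- c(og_ko[[og]], pool[i])
      }
    }
  }

  # ---- gene-level annotations ----
  ann <- NULL
  if (with_annotations) {
    pres_idx <- which(counts > 0, arr.ind = TRUE)
    k <- counts[pres_idx]
    gene_iso <- rep(md$isolate_id[pres_idx[, 1]], k)
    gene_og <- rep(og_ids[pres_idx[, 2]], k)
    n_genes <- length(gene_iso)
    gene_id <- sprintf("g%07d", seq_len(n_genes))
    in_unique <- gene_og %in% truth$source_unique_ogs
    base_p <- cfg$cog_baseline
    bias_p <- base_p
    bias_p[cfg$planted_cog_category] <-
      bias_p[cfg$planted_cog_category] * cfg$planted_cog_fold
    bias_p <- bias_p / sum(bias_p)
    first <- character(n_genes)
    first[!in_unique] <- sample(names(base_p), sum(!in_unique),
                                replace = TRUE, prob = base_p)
    if (any(in_unique))
      first[in_unique] <- sample(names(bias_p), sum(in_unique),
                                 replace = TRUE, prob = bias_p)
    unann <- stats::runif(n_genes) < cfg$unannotated_prob
    second_on <- !unann & stats::runif(n_genes) < cfg$multi_letter_prob
    second <- sample(names(base_p), n_genes, replace = TRUE, prob = base_p)
    cog <- vector("list", n_genes)
    cog[!unann] <- as.list(first[!unann])
    w2 <- which(second_on & second != first)
    cog[w2] <- Map(c, first[w2], second[w2])
    cog[unann] <- list(character(0))
    ko <- og_ko[gene_og]
    ko[vapply(ko, is.null, logical(1))] <- list(character(0))
    names(ko) <- NULL
    ann <- gene_annotation_map(gene_id, gene_iso, gene_og, cog, ko)
  }

  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(
      genecounts = file.path(dir, "genecounts.tsv"),
      annotations = if (with_annotations) file.path(dir, "annotations.tsv"),
      metadata = file.path(dir, "metadata.tsv"),
      pathways = file.path(dir, "pathways.tsv"),
      truth = file.path(dir, "truth.tsv"))
    gc_df <- data.frame(Orthogroup = og_ids, t(counts),
                        Total = colSums(counts), check.names = FALSE)
    write_table(gc_df, files$genecounts, seed = cfg$seed)
    write_table(md, files$metadata, seed = cfg$seed)
    pw_df <- data.frame(
      pathway_id = names(defs),
      name = vapply(defs, `[[`, "", "name"),
      definition = vapply(defs, unparse_pathway_definition, ""))
    write_table(pw_df, files$pathways, seed = cfg$seed)
    tt <- rbind(
      data.frame(orthogroup_id = truth$core, truth = "core"),
      data.frame(orthogroup_id = truth$planted_source_ogs, truth = "planted"),
      data.frame(orthogroup_id = truth$source_unique_ogs, truth = "unique"))
    write_table(tt, files$truth, seed = cfg$seed)
    if (with_annotations) {
      con <- file(files$annotations, open = "wt", encoding = "UTF-8")
      writeLines(provenance_line(cfg$seed), con)
      writeLines("#query\tCOG_category\tKEGG_ko\tisolate\torthogroup", con)
      cogs <- vapply(ann$cog, function(v)
        if (length(v)) paste(v, collapse = "") else "-", "")
      kos <- vapply(ann$ko, function(v)
        if (length(v)) paste(paste0("ko:", v), collapse = ",") else "-", "")
      writeLines(paste(ann$gene_id, cogs, kos, ann$isolate_id,
                       ann$orthogroup_id, sep = "\t"), con)
      close(con)
    }
  }

  list(matrix = mat, metadata = md, annotations = ann, pathways = defs,
       truth = truth, files = files)
}

#' Simulate an amplicon (ASV) genus count table with year structure
#'
#' Emulates the two-year community-profiling design: designated core taxa are
#' present in every sample of every year (prevalence 1 >= the 0.8 core rule),
#' mid-abundance taxa are present in 60 percent of each year's samples with
#' read counts that keep their mean relative abundance above the 0.1 percent
#' filter, and designated low-abundance taxa appear in 10 percent of samples
#' with single reads, keeping them below the filter in both years.
#'
#' @param cfg A \code{\link{simulation_config}} (only \code{seed} and
#'   \code{asv} are used).
#' @return List with \code{counts} (samples x taxa), \code{years} (per-sample
#'   labels) and \code{truth} (core, low-abundance and retained taxon sets).
#' @export
simulate_asv_table <- function(cfg = simulation_config()) {
  set.seed(cfg$seed + 1L)
  a <- cfg$asv
  n_core <- a$n_core; n_low <- a$n_low
  n_mid <- a$n_taxa - n_core - n_low
  stopifnot(n_mid >= 0)
  taxa <- c(sprintf("CoreGenus%02d", seq_len(n_core)),
            sprintf("Genus%02d", seq_len(n_mid)),
            sprintf("RareGenus%02d", seq_len(n_low)))
  kind <- rep(c("core", "mid", "low"), c(n_core, n_mid, n_low))
  years <- rep(names(a$n_samples), a$n_samples)
  samples <- sprintf("S%s_%02d", years, unlist(lapply(a$n_samples, seq_len)))
  counts <- matrix(0L, nrow = length(samples), ncol = length(taxa),
                   dimnames = list(samples, taxa))
  # per-taxon expected reads per present sample
  lam <- numeric(length(taxa))
  lam[kind == "core"] <- stats::runif(n_core, 500, 3000)
  lam[kind == "mid"] <- stats::runif(n_mid, 60, 400)
  for (y in unique(years)) {
    rows <- which(years == y)
    n <- length(rows)
    for (j in seq_along(taxa)) {
      present <- switch(kind[j],
        core = rows,
        mid = sample(rows, floor(0.6 * n)),
        low = sample(rows, max(1L, floor(0.1 * n))))
      counts[present, j] <- if (kind[j] == "low") 1L
        else .rtpois(length(present), lam[j])
    }
  }
  truth <- list(core_taxa = taxa[kind == "core"],
                low_abundance_taxa = taxa[kind == "low"],
                retained_taxa = taxa[kind != "low"])
  list(counts = counts, years = years, truth = truth)
}

#' Simulate a separable classification panel
#'
#' A multi-genus panel in which one orthogroup feature carries extra gene
#' copies exactly in the target-class isolates, identically in every genus —
#' an origin signal that generalizes across taxa. Used to verify that the
#' leave-one-genus-out harness attains perfect accuracy when a universal
#' signal exists.
#'
#' @param seed Integer seed.
#' @param n_genera Number of genera; default 4.
#' @param n_per_genus Isolates per genus (half labelled 1); default 16.
#' @param n_noise Uninformative Poisson(2) count features; default 10.
#' @param effect Extra copies of the informative feature in class-1 isolates;
#'   default 5.
#' @return List with \code{X} (isolates x features), \code{y} (binary labels),
#'   \code{groups} (genus labels) and \code{informative_feature}.
#' @export
simulate_separable_panel <- function(seed = 1, n_genera = 4, n_per_genus = 16,
                                     n_noise = 10, effect = 5) {
  set.seed(seed)
  n <- n_genera * n_per_genus
  groups <- rep(LETTERS[seq_len(n_genera)], each = n_per_genus)
  half <- n_per_genus %/% 2
  y <- rep(rep(c(1L, 0L), c(half, n_per_genus - half)), n_genera)
  X <- matrix(stats::rpois(n * n_noise, 2), n, n_noise)
  X <- cbind(ifelse(y == 1, effect, 0L), X)
  colnames(X) <- sprintf("OG%03d", seq_len(ncol(X)))
  rownames(X) <- sprintf("iso%03d", seq_len(n))
  list(X = X, y = y, groups = groups, informative_feature = "OG001")
}

#' Simulate a genus-confounded classification panel
#'
#' One genus is predominantly target-class while the others are predominantly
#' not, and the only informative feature marks that genus rather than the
#' class — taxonomy confounded with origin. A classifier looks accurate under
#' within-panel cross-validation but fails to generalize when the confounded
#' genus is held out, mirroring the drop from reference to leave-one-genus-out
#' performance seen when taxonomic identity dominates orthogroup variation.
#'
#' @param seed Integer seed.
#' @param n_genera Number of genera; default 4.
#' @param n_per_genus Isolates per genus; default 16.
#' @param n_noise Uninformative Poisson(2) count features; default 10.
#' @param effect Extra copies of the genus-marker feature; default 5.
#' @return As \code{\link{simulate_separable_panel}}; the first genus
#'   (\code{"A"}) is the confounded one (12/16 of its isolates in class 1,
#'   4/16 in the others).
#' @export
simulate_confounded_panel <- function(seed = 1, n_genera = 4,
                                      n_per_genus = 16, n_noise = 10,
                                      effect = 5) {
  set.seed(seed)
  n <- n_genera * n_per_genus
  groups <- rep(LETTERS[seq_len(n_genera)], each = n_per_genus)
  hi <- round(0.75 * n_per_genus)
  lo <- n_per_genus - hi
  y <- c(rep(c(1L, 0L), c(hi, lo)),
         rep(rep(c(1L, 0L), c(lo, hi)), n_genera - 1))
  X <- matrix(stats::rpois(n * n_noise, 2), n, n_noise)
  X <- cbind(ifelse(groups == "A", effect, 0L) + stats::rpois(n, 1), X)
  colnames(X) <- sprintf("OG%03d", seq_len(ncol(X)))
  rownames(X) <- sprintf("iso%03d", seq_len(n))
  list(X = X, y = y, groups = groups, informative_feature = "OG001")
}
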