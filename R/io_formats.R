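#' Construct an orthogroup gene-count matrix
#'
#' The central container of the package: a non-negative integer matrix of
#' per-isolate gene counts per orthogroup, oriented isolates x orthogroups
#' (every statistic groups by isolate), plus an optional per-isolate count of
#' genes that were not placed in any orthogroup.
#'
#' @param counts Integer matrix, isolates in rows (rownames = isolate ids),
#'   orthogroups in columns (colnames = orthogroup ids).
#' @param unassigned Optional named integer vector of unassigned gene counts
#'   per isolate; missing isolates default to 0.
#' @return An object of class \code{og_matrix}: a list with \code{counts} and
#'   \code{unassigned}.
#' @export
og_matrix <- function(counts, unassigned = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    if (nrow(counts) > 0)
      stop_("og_matrix: counts must have isolate rownames")
    rownames(counts) <- character(0)
  }
  if (is.null(colnames(counts))) {
    if (ncol(counts) > 0)
      stop_("og_matrix: counts must have orthogroup colnames")
    colnames(counts) <- character(0)
  }
  if (anyDuplicated(rownames(counts)))
    stop_("og_matrix: duplicate isolate id")
  if (anyDuplicated(colnames(counts)))
    stop_("og_matrix: duplicate orthogroup id")
  if (any(counts < 0)) stop_("og_matrix: negative gene count")
  if (any(counts != floor(counts))) stop_("og_matrix: non-integer gene count")
  storage.mode(counts) <- "integer"
  ua <- stats::setNames(rep(0L, nrow(counts)), rownames(counts))
  if (!is.null(unassigned)) {
    if (is.null(names(unassigned)))
      stop_("og_matrix: unassigned must be named by isolate id")
    bad <- setdiff(names(unassigned), rownames(counts))
    if (length(bad))
      stop_("og_matrix: unassigned names not in matrix: ", paste(bad, collapse = ", "))
    if (any(unassigned < 0)) stop_("og_matrix: negative unassigned count")
    ua[names(unassigned)] <- as.integer(unassigned)
  }
  structure(list(counts = counts, unassigned = ua), class = "og_matrix")
}

#' @export
print.og_matrix <- function(x, ...) {
  cat(sprintf("og_matrix: %d isolates x %d orthogroups; %d assigned genes, %d unassigned\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts), sum(x$unassigned)))
  invisible(x)
}

# strict integer conversion used by the readers
.as_count <- function(v, what) {
  suppressWarnings(n <- as.numeric(v))
  bad <- is.na(n) | n != floor(n)
  if (any(bad))
    stop_(what, ": non-integer cell value '", v[which(bad)[1]], "'")
  as.integer(n)
}

.read_tsv_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines[!startsWith(lines, "#") & nzchar(lines)]
}

#' Read an orthogroup gene-count table (OrthoFinder dialect)
#'
#' Parses a tab-separated table with a first column of orthogroup identifiers
#' (\code{Orthogroup}), one column per isolate, and an optional trailing
#' \code{Total} column which, when present, is validated against the row sum
#' and dropped. The table is transposed to the internal isolates x orthogroups
#' orientation.
#'
#' @param path Path to the TSV file. Lines starting with \code{#} are skipped.
#' @param unassigned Optional: either a named integer vector or the path to a
#'   two-column sidecar TSV (isolate, count) of unassigned gene counts.
#' @return An \code{\link{og_matrix}}.
#' @export
read_genecount_table <- function(path, unassigned = NULL) {
  lines <- .read_tsv_lines(path)
  if (length(lines) == 0) stop_("read_genecount_table: empty file ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  has_total <- length(header) > 1 && header[length(header)] == "Total"
  iso_cols <- header[-1]
  if (has_total) iso_cols <- iso_cols[-length(iso_cols)]
  if (anyDuplicated(iso_cols))
    stop_("read_genecount_table: duplicate isolate column")
  body <- lines[-1]
  og_ids <- character(0)
  mat <- matrix(0L, nrow = 0, ncol = length(iso_cols))
  if (length(body)) {
    fields <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != length(header)))
      stop_("read_genecount_table: row with ", nf[which(nf != length(header))[1]],
            " fields, expected ", length(header))
    og_ids <- vapply(fields, `[[`, "", 1L)
    dup <- og_ids[duplicated(og_ids)]
    if (length(dup))
      stop_("read_genecount_table: duplicate orthogroup id ", dup[1])
    cells <- do.call(rbind, lapply(fields, function(f) f[-1]))
    if (has_total) {
      totals <- .as_count(cells[, ncol(cells)], "read_genecount_table")
      cells <- cells[, -ncol(cells), drop = FALSE]
    }
    mat <- matrix(.as_count(as.vector(cells), "read_genecount_table"),
                  nrow = length(og_ids))
    if (has_total) {
      rs <- rowSums(mat)
      bad <- which(rs != totals)
      if (length(bad))
        stop_("read_genecount_table: Total mismatch for orthogroup ",
              og_ids[bad[1]], " (stated ", totals[bad[1]], ", row sum ",
              rs[bad[1]], ")")
    }
  }
  rownames(mat) <- og_ids
  colnames(mat) <- iso_cols
  ua <- NULL
  if (!is.null(unassigned)) {
    if (is.character(unassigned) && length(unassigned) == 1 && file.exists(unassigned)) {
      sl <- .read_tsv_lines(unassigned)
      sf <- strsplit(sl[-1], "\t", fixed = TRUE)
      ua <- stats::setNames(.as_count(vapply(sf, `[[`, "", 2L), "unassigned sidecar"),
                            vapply(sf, `[[`, "", 1L))
    } else ua <- unassigned
  }
  og_matrix(t(mat), unassigned = ua)
}

#' Read an eggNOG-mapper style annotation table
#'
#' Parses the \code{.annotations} dialect: lines starting with \code{#} are
#' comments (the header row itself may be a \code{#}-prefixed line containing
#' \code{query}), columns are addressed by name, missing values are \code{-}.
#' \code{COG_category} strings are split into single-letter sets and
#' \code{KEGG_ko} entries have their \code{ko:} prefixes stripped. Optional
#' \code{isolate} and \code{orthogroup} columns (emitted by the synthetic
#' study generator and by orthogroup-joined exports) populate the gene-to-
#' isolate/orthogroup mapping; genes without an orthogroup carry the
#' distinguished value \code{"UNASSIGNED"}.
#'
#' @param path Path to the annotations TSV.
#' @return A data frame of class \code{gene_annotations} with columns
#'   \code{gene_id}, \code{isolate_id}, \code{orthogroup_id}, and list-columns
#'   \code{cog} (character vectors of category letters) and \code{ko}
#'   (character vectors of KO identifiers).
#' @export
read_annotations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  is_comment <- startsWith(lines, "#")
  header <- NULL
  # eggNOG emits the header as a comment line starting '#query'
  hc <- which(is_comment &
                vapply(lines, function(l)
                  "query" %in% strsplit(sub("^#+\\s*", "", l), "\t", fixed = TRUE)[[1]],
                  logical(1)))
  if (length(hc)) {
    header <- strsplit(sub("^#+\\s*", "", lines[hc[length(hc)]]), "\t", fixed = TRUE)[[1]]
    body <- lines[!is_comment]
  } else {
    body <- lines[!is_comment]
    if (length(body) == 0) {
      warning("read_annotations: no header or data rows in ", path)
      return(gene_annotation_map(character(0), character(0), character(0),
                                 list(), list()))
    }
    header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
    body <- body[-1]
  }
  required <- c("query", "COG_category", "KEGG_ko")
  missing_cols <- setdiff(required, header)
  if (length(missing_cols))
    stop_("read_annotations: missing required column(s) ",
          paste(missing_cols, collapse = ", "), "; found: ",
          paste(header, collapse = ", "))
  if (length(body) == 0) {
    warning("read_annotations: no annotation rows in ", path)
    return(gene_annotation_map(character(0), character(0), character(0),
                               list(), list()))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  col <- function(name) {
    i <- match(name, header)
    vapply(fields, function(f) if (length(f) >= i) f[i] else "-", "")
  }
  cog_raw <- col("COG_category")
  cog <- lapply(cog_raw, function(s)
    if (s == "-" || s == "") character(0) else strsplit(s, "")[[1]])
  ko_raw <- col("KEGG_ko")
  ko <- lapply(ko_raw, function(s) {
    if (s == "-" || s == "") return(character(0))
    sub("^ko:", "", strsplit(s, ",", fixed = TRUE)[[1]])
  })
  iso <- if ("isolate" %in% header) col("isolate") else rep(NA_character_, length(fields))
  og <- if ("orthogroup" %in% header) col("orthogroup") else rep("UNASSIGNED", length(fields))
  og[og == "-" | og == ""] <- "UNASSIGNED"
  gene_annotation_map(col("query"), iso, og, cog, ko)
}

#' Construct a gene annotation map
#'
#' Bridges orthogroups to function: one row per gene with its isolate, its
#' orthogroup (or \code{"UNASSIGNED"}), its set of COG category letters and
#' its set of KO identifiers.
#'
#' @param gene_id,isolate_id,orthogroup_id Character vectors (recycled checks
#'   apply); gene ids must be unique within isolate.
#' @param cog,ko Lists of character vectors (possibly empty per gene).
#' @return A data frame of class \code{gene_annotations}.
#' @export
gene_annotation_map <- function(gene_id, isolate_id, orthogroup_id, cog, ko) {
  n <- length(gene_id)
  if (length(isolate_id) != n || length(orthogroup_id) != n ||
      length(cog) != n || length(ko) != n)
    stop_("gene_annotation_map: field lengths differ")
  if (n > 0 && anyDuplicated(paste(isolate_id, gene_id, sep = "\r")))
    stop_("gene_annotation_map: duplicate gene id within isolate")
  ann <- data.frame(gene_id = as.character(gene_id),
                    isolate_id = as.character(isolate_id),
                    orthogroup_id = as.character(orthogroup_id),
                    stringsAsFactors = FALSE)
  ann$cog <- cog
  ann$ko <- ko
  class(ann) <- c("gene_annotations", "data.frame")
  ann
}

#' Check annotation/matrix consistency
#'
#' Verifies that every non-UNASSIGNED orthogroup id in the annotation map
#' exists in the companion orthogroup matrix.
#'
#' @param ann A \code{gene_annotations} object.
#' @param mat An \code{og_matrix}.
#' @return Invisibly TRUE; errors otherwise.
#' @export
validate_annotations <- function(ann, mat) {
  ogs <- setdiff(unique(ann$orthogroup_id), "UNASSIGNED")
  bad <- setdiff(ogs, colnames(mat$counts))
  if (length(bad))
    stop_("validate_annotations: orthogroup(s) absent from matrix: ",
          paste(utils::head(bad, 5), collapse = ", "))
  invisible(TRUE)
}

#' Default isolation-source vocabulary
#' @return Character vector of the source labels used throughout.
#' @export
default_sources <- function() c("leaf", "flower", "soil", "human", "water")

#' Read an isolate metadata table
#'
#' Tab-separated with a header; required columns \code{isolate_id},
#' \code{genus}, \code{source}; optional \code{species}, \code{year},
#' \code{cluster}. \code{-} denotes a missing value. Source labels are
#' validated against the vocabulary.
#'
#' @param path Path to the metadata TSV (\code{#} lines skipped).
#' @param sources Allowed source vocabulary.
#' @param allow_new_sources If TRUE, labels outside \code{sources} are
#'   accepted instead of raising an error.
#' @return A data frame of class \code{isolate_metadata}.
#' @export
read_metadata <- function(path, sources = default_sources(),
                          allow_new_sources = FALSE) {
  lines <- .read_tsv_lines(path)
  if (length(lines) == 0) stop_("read_metadata: empty file ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  required <- c("isolate_id", "genus", "source")
  missing_cols <- setdiff(required, header)
  if (length(missing_cols))
    stop_("read_metadata: missing column(s) ", paste(missing_cols, collapse = ", "))
  fields <- strsplit(lines[-1], "\t", fixed = TRUE)
  col <- function(name, default = NA_character_) {
    i <- match(name, header)
    if (is.na(i)) return(rep(default, length(fields)))
    v <- vapply(fields, function(f) if (length(f) >= i) f[i] else "-", "")
    v[v == "-"] <- NA_character_
    v
  }
  md <- data.frame(isolate_id = col("isolate_id"), genus = col("genus"),
                   species = col("species"), source = col("source"),
                   year = suppressWarnings(as.integer(col("year"))),
                   cluster = col("cluster"), stringsAsFactors = FALSE)
  if (anyDuplicated(md$isolate_id))
    stop_("read_metadata: duplicate isolate_id ",
          md$isolate_id[duplicated(md$isolate_id)][1])
  unknown <- setdiff(md$source, sources)
  if (length(unknown) && !allow_new_sources)
    stop_("read_metadata: unknown source label(s) ",
          paste(unknown, collapse = ", "),
          " (use allow_new_sources = TRUE to accept)")
  class(md) <- c("isolate_metadata", "data.frame")
  md
}

#' Write a result table as TSV with a provenance header
#'
#' Writes a data frame as a tab-separated table (UTF-8, \code{-} for missing
#' values) preceded by a \code{#}-prefixed provenance line. Round-trip stable
#' with the package readers for string/integer fields.
#'
#' @param records Data frame to write. List-columns are collapsed with commas.
#' @param path Output path.
#' @param seed Seed recorded in the provenance line (or NA).
#' @return Invisibly, \code{path}.
#' @export
write_table <- function(records, path, seed = NA) {
  df <- as.data.frame(records)
  for (j in seq_along(df)) {
    if (is.list(df[[j]]))
      df[[j]] <- vapply(df[[j]], function(v)
        if (length(v) == 0) "-" else paste(v, collapse = ","), "")
  }
  for (j in seq_along(df)) {
    v <- as.character(df[[j]])
    v[is.na(v)] <- "-"
    df[[j]] <- v
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(provenance_line(seed), con)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  if (nrow(df))
    writeLines(do.call(paste, c(unname(df), sep = "\t")), con)
  invisible(path)
}
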