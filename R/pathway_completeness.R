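# ---- KEGG-module-style definition grammar -----------------------------------
# space  = AND (lowest precedence)
# comma  = OR  (binds tighter than space)
# '+'    = AND within a complex (binds tightest)
# '()'   group; a leading '-' marks the following unit optional (pruned
# before scoring). KO leaves match K followed by five digits.

.tokenize_definition <- function(text) {
  toks <- list(); i <- 1L; n <- nchar(text)
  push <- function(type, value, pos) {
    toks[[length(toks) + 1L]] <<- list(type = type, value = value, pos = pos)
  }
  while (i <= n) {
    ch <- substr(text, i, i)
    if (ch == " ") {
      # collapse runs of spaces into one AND separator
      j <- i
      while (j <= n && substr(text, j, j) == " ") j <- j + 1L
      push("space", " ", i); i <- j
    } else if (ch %in% c("(", ")", ",", "+", "-")) {
      push(ch, ch, i); i <- i + 1L
    } else if (ch == "K") {
      tok <- substr(text, i, i + 5L)
      if (!grepl("^K[0-9]{5}$", tok))
        stop_("parse_pathway_definition: malformed KO token at position ", i,
              ": '", substr(text, i, min(n, i + 5L)), "'")
      push("ko", tok, i); i <- i + 6L
    } else {
      stop_("parse_pathway_definition: unexpected character '", ch,
            "' at position ", i)
    }
  }
  toks
}

#' Parse a pathway definition string
#'
#' Parses the KEGG-module definition syntax into an AND/OR expression tree
#' over KO identifiers. Space-separated units are required steps (AND, lowest
#' precedence), comma separates alternatives (OR), \code{+} joins subunits of
#' a complex (AND, tightest), parentheses group, and a leading \code{-} marks
#' the following unit optional — optional units are pruned before scoring.
#'
#' @param text Definition string, e.g. \code{"K00001 K00002,K00003"}.
#' @param pathway_id,name Optional identifiers stored with the definition.
#' @return An object of class \code{pathway_definition} with the expression
#'   tree in \code{$root} and the optional-pruned tree in \code{$pruned}
#'   (NULL when the definition is all-optional).
#' @export
parse_pathway_definition <- function(text, pathway_id = NA_character_,
                                     name = NA_character_) {
  text <- unname(text)
  pathway_id <- unname(pathway_id)
  name <- unname(name)
  if (!nzchar(trimws(text)))
    stop_("parse_pathway_definition: empty definition")
  toks <- .tokenize_definition(trimws(text))
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  advance <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }
  expect <- function(type) {
    t <- peek()
    if (is.null(t) || t$type != type)
      stop_("parse_pathway_definition: expected '", type, "' at position ",
            if (is.null(t)) nchar(text) + 1L else t$pos)
    advance()
  }
  parse_unit <- function() {
    t <- peek()
    if (is.null(t)) stop_("parse_pathway_definition: unexpected end of definition")
    optional <- FALSE
    if (t$type == "-") { advance(); optional <- TRUE; t <- peek() }
    if (is.null(t)) stop_("parse_pathway_definition: dangling '-' at end")
    node <- if (t$type == "(") {
      advance()
      inner <- parse_space()
      expect(")")
      inner
    } else if (t$type == "ko") {
      advance()
      list(type = "ko", ko = t$value, optional = FALSE)
    } else {
      stop_("parse_pathway_definition: unexpected '", t$value,
            "' at position ", t$pos)
    }
    node$optional <- optional
    node
  }
  parse_plus <- function() {
    nodes <- list(parse_unit())
    while (!is.null(peek()) && peek()$type == "+") {
      advance()
      nodes <- c(nodes, list(parse_unit()))
    }
    if (length(nodes) == 1) nodes[[1]]
    else list(type = "and", children = nodes, optional = FALSE)
  }
  parse_comma <- function() {
    nodes <- list(parse_plus())
    while (!is.null(peek()) && peek()$type == ",") {
      advance()
      nodes <- c(nodes, list(parse_plus()))
    }
    if (length(nodes) == 1) nodes[[1]]
    else list(type = "or", children = nodes, optional = FALSE)
  }
  parse_space <- function() {
    nodes <- list(parse_comma())
    while (!is.null(peek()) && peek()$type == "space") {
      advance()
      if (is.null(peek()) || peek()$type == ")") break
      nodes <- c(nodes, list(parse_comma()))
    }
    if (length(nodes) == 1) nodes[[1]]
    else list(type = "and", children = nodes, optional = FALSE)
  }
  root <- parse_space()
  t <- peek()
  if (!is.null(t))
    stop_("parse_pathway_definition: unexpected '", t$value, "' at position ",
          t$pos, if (t$type == ")") " (unbalanced parentheses)" else "")
  structure(list(pathway_id = pathway_id, name = name, root = root,
                 pruned = .prune_optional(root)),
            class = "pathway_definition")
}

.prune_optional <- function(node) {
  if (is.null(node) || isTRUE(node$optional)) return(NULL)
  if (node$type == "ko") return(node)
  kids <- Filter(Negate(is.null), lapply(node$children, .prune_optional))
  if (length(kids) == 0) return(NULL)
  node$children <- kids
  node
}

#' Serialize a pathway definition tree back to definition syntax
#'
#' Inverse of \code{\link{parse_pathway_definition}} up to insertion of
#' explicit parentheses: the output reparses to an identical tree.
#'
#' @param def A \code{pathway_definition} or a bare tree node.
#' @return Definition string.
#' @export
unparse_pathway_definition <- function(def) {
  node <- if (inherits(def, "pathway_definition")) def$root else def
  emit <- function(n) {
    body <- if (n$type == "ko") {
      n$ko
    } else if (n$type == "and") {
      paste(vapply(n$children, function(k) {
        s <- emit(k)
        if (k$type == "and") paste0("(", s, ")") else s
      }, ""), collapse = " ")
    } else {  # or
      paste(vapply(n$children, function(k) {
        s <- emit(k)
        if (k$type != "ko") paste0("(", s, ")") else s
      }, ""), collapse = ",")
    }
    if (isTRUE(n$optional)) {
      if (n$type == "ko") paste0("-", body) else paste0("-(", body, ")")
    } else body
  }
  emit(node)
}

#' Pathway completeness of a KO set
#'
#' Recursive completeness in percent: a KO leaf scores 1 when present in the
#' set, an AND node the arithmetic mean of its children, an OR node the
#' maximum; optional units are excluded. An all-optional definition has no
#' score and returns NA.
#'
#' @param def A \code{pathway_definition}.
#' @param kos Character vector of KO identifiers present in a genome.
#' @return Completeness in \code{[0, 100]}, or NA for an all-optional
#'   definition.
#' @export
pathway_completeness <- function(def, kos) {
  stopifnot(inherits(def, "pathway_definition"))
  if (is.null(def$pruned)) return(NA_real_)
  score <- function(n) {
    switch(n$type,
           ko = as.numeric(n$ko %in% kos),
           and = mean(vapply(n$children, score, numeric(1))),
           or = max(vapply(n$children, score, numeric(1))))
  }
  100 * score(def$pruned)
}

#' Read pathway definitions from a 3-column TSV
#'
#' Columns: \code{pathway_id}, \code{name}, \code{definition}.
#'
#' @param path Path to the TSV (\code{#} lines skipped).
#' @return Named list of \code{pathway_definition} objects.
#' @export
read_pathway_definitions <- function(path) {
  lines <- .read_tsv_lines(path)
  if (length(lines) == 0) stop_("read_pathway_definitions: empty file ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  need <- c("pathway_id", "name", "definition")
  if (!all(need %in% header))
    stop_("read_pathway_definitions: columns must include ",
          paste(need, collapse = ", "))
  fields <- strsplit(lines[-1], "\t", fixed = TRUE)
  defs <- lapply(fields, function(f) {
    v <- stats::setNames(f[match(need, header)], need)
    parse_pathway_definition(v["definition"], v["pathway_id"], v["name"])
  })
  stats::setNames(defs, vapply(defs, `[[`, "", "pathway_id"))
}

#' Per-isolate KO sets from gene annotations
#'
#' The KO set of an isolate is the union of the KO sets of its genes,
#' optionally restricted to genes whose orthogroup belongs to a supplied set.
#'
#' @param ann A \code{gene_annotations} object.
#' @param restrict_to Optional character vector of orthogroup ids.
#' @return Named list of KO id vectors, one per isolate.
#' @export
isolate_ko_sets <- function(ann, restrict_to = NULL) {
  rows <- if (is.null(restrict_to)) rep(TRUE, nrow(ann))
  else ann$orthogroup_id %in% restrict_to
  sub <- ann[rows, , drop = FALSE]
  tapply(sub$ko, sub$isolate_id, function(l) unique(unlist(l)),
         simplify = FALSE)
}

#' Completeness matrix: isolates x pathways
#'
#' @param defs Named list of \code{pathway_definition} objects.
#' @param ann A \code{gene_annotations} object.
#' @param restrict_to Optional orthogroup set restriction (see
#'   \code{\link{isolate_ko_sets}}).
#' @param isolates Optional isolate ids fixing row order (isolates without
#'   genes score from an empty KO set).
#' @return Numeric matrix of completeness percentages (NA for all-optional
#'   definitions), isolates in rows, pathways in columns.
#' @export
completeness_matrix <- function(defs, ann, restrict_to = NULL,
                                isolates = NULL) {
  kosets <- isolate_ko_sets(ann, restrict_to)
  if (is.null(isolates)) isolates <- sort(unique(ann$isolate_id))
  m <- matrix(NA_real_, nrow = length(isolates), ncol = length(defs),
              dimnames = list(isolates, names(defs)))
  for (i in seq_along(isolates)) {
    kos <- kosets[[isolates[i]]] %||% character(0)
    for (j in seq_along(defs))
      m[i, j] <- pathway_completeness(defs[[j]], kos)
  }
  m
}

#' Compare pathway completeness between the target source and each other source
#'
#' For every pathway, the target-source isolates' completeness values are
#' compared with each other source's values by the Mann-Whitney U test, with
#' Bonferroni correction across all pathway x source-pair tests.
#'
#' @param cm Completeness matrix from \code{\link{completeness_matrix}}.
#' @param metadata An \code{isolate_metadata} data frame.
#' @param target_source Source label; default \code{"leaf"}.
#' @param alpha Significance level; default 0.05.
#' @param mode Mann-Whitney mode; default \code{"auto"}.
#' @return Data frame: pathway, other source, group means, U, p, p_adj,
#'   significant, direction.
#' @export
compare_completeness_by_source <- function(cm, metadata,
                                           target_source = "leaf",
                                           alpha = 0.05, mode = "auto") {
  src <- metadata$source[match(rownames(cm), metadata$isolate_id)]
  tgt_rows <- which(src == target_source)
  if (length(tgt_rows) < 2)
    stop_("compare_completeness_by_source: fewer than 2 ", target_source,
          " isolates")
  others <- setdiff(unique(src), target_source)
  others <- others[vapply(others, function(s) sum(src == s) >= 2, logical(1))]
  if (length(others) == 0)
    stop_("compare_completeness_by_source: no other source with >= 2 isolates")
  rows <- list()
  for (pw in colnames(cm)) {
    x <- cm[tgt_rows, pw]
    if (all(is.na(x))) next
    for (s in others) {
      y <- cm[src == s, pw]
      tst <- mann_whitney_u(x, y, mode = mode)
      rows[[length(rows) + 1L]] <- data.frame(
        pathway_id = pw, other_source = s,
        mean_target = mean(x), mean_other = mean(y),
        U = tst$statistic, p = tst$p_value, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$p_adj <- bonferroni_adjust(res$p)
  res$significant <- res$p_adj < alpha
  res$direction <- ifelse(res$mean_target > res$mean_other,
                          "enriched", "depleted")
  res
}
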