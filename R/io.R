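#' Read a tab-separated relation table
#'
#' Generic reader for the two-or-more column relation tables the pipeline
#' consumes (herb-compound, compound-target, ...). The file must be
#' UTF-8 TSV with a header row whose column names match `schema` exactly
#' and in order. Fields are whitespace-trimmed; empty lines are skipped.
#'
#' @param path file path.
#' @param schema character vector of expected column names.
#' @return data.frame of character columns named after `schema`, rows in
#'   file order.
#' @export
read_relation_table <- function(path, schema) {
  stopifnot(is.character(schema), length(schema) >= 1L)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("file is empty: ", path, call. = FALSE)
  header <- trimws(strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]])
  if (anyDuplicated(header)) {
    stop("duplicate column in header: ",
         paste(header[duplicated(header)], collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(schema, header)
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "),
         " in ", path, call. = FALSE)
  }
  idx <- match(schema, header)
  body <- lines[-1L]
  out <- lapply(seq_along(schema), function(j) character(length(body)))
  names(out) <- schema
  if (length(body)) {
    fields <- strsplit(body, "\t", fixed = TRUE)
    for (j in seq_along(schema)) {
      out[[j]] <- vapply(
        fields,
        function(f) if (length(f) >= idx[j]) trimws(f[[idx[j]]]) else "",
        character(1)
      )
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Read a herb-compound table
#'
#' Columns `herb`, `compound`. Duplicate pairs are rejected; a compound may
#' belong to several herbs.
#'
#' @param path file path.
#' @return data.frame with columns `herb`, `compound`.
#' @export
read_herb_compound_table <- function(path) {
  tbl <- read_relation_table(path, c("herb", "compound"))
  if (any(!nzchar(tbl$herb)) || any(!nzchar(tbl$compound))) {
    stop("empty herb or compound id", call. = FALSE)
  }
  if (anyDuplicated(tbl)) stop("duplicate (herb, compound) pair", call. = FALSE)
  tbl
}

#' Read a compound-target table
#'
#' Columns `compound`, `target`. Target gene symbols are uppercased on
#' ingestion; duplicate pairs (after normalization) collapse to one.
#'
#' @param path file path.
#' @param herbs optional herb-compound table; when given, every compound must
#'   appear in it (referential integrity across the input bundle).
#' @return data.frame with columns `compound`, `target`.
#' @export
read_compound_target_table <- function(path, herbs = NULL) {
  tbl <- read_relation_table(path, c("compound", "target"))
  if (any(!nzchar(tbl$compound)) || any(!nzchar(tbl$target))) {
    stop("empty compound or target id", call. = FALSE)
  }
  tbl$target <- toupper(tbl$target)
  tbl <- tbl[!duplicated(tbl), , drop = FALSE]
  rownames(tbl) <- NULL
  if (!is.null(herbs)) {
    orphan <- setdiff(unique(tbl$compound), unique(herbs$compound))
    if (length(orphan)) {
      stop("compound(s) absent from herb table: ",
           paste(orphan, collapse = ", "), call. = FALSE)
    }
  }
  tbl
}

#' Read a disease-target list
#'
#' One gene symbol per line (a single-column file without header is accepted,
#' as is a headed single-column TSV with column `target`). Symbols are
#' uppercased and de-duplicated.
#'
#' @param path file path.
#' @return character vector of unique uppercase gene symbols.
#' @export
read_disease_targets <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) && identical(tolower(lines[[1L]]), "target")) {
    lines <- lines[-1L]
  }
  if (!length(lines)) stop("empty disease-target list: ", path, call. = FALSE)
  unique(toupper(lines))
}

#' Read a scored interaction table
#'
#' Three tab-separated columns `protein_a`, `protein_b`, `combined_score`
#' (header required). Interactions are kept only when the score is
#' strictly greater than `min_score`; pairs are canonicalized
#' (lexicographic order), duplicates collapse keeping the maximum score,
#' and self-interactions are dropped with a message stating the count.
#'
#' @param path file path.
#' @param min_score retain interactions with score strictly above this value
#'   (default 0.4, the conventional medium-confidence cut for STRING-style
#'   combined scores).
#' @return data.frame with columns `protein_a`, `protein_b` (canonical
#'   order), `score`.
#' @export
read_scored_interactions <- function(path, min_score = 0.4) {
  tbl <- read_relation_table(path, c("protein_a", "protein_b", "combined_score"))
  score <- suppressWarnings(as.numeric(tbl$combined_score))
  if (anyNA(score)) {
    # +1 for the header line so the number matches the file
    bad <- which(is.na(score))[1L]
    stop("unparseable score at line ", bad + 1L, ": '",
         tbl$combined_score[bad], "'", call. = FALSE)
  }
  canonicalize_interactions(
    data.frame(
      protein_a = toupper(tbl$protein_a),
      protein_b = toupper(tbl$protein_b),
      score = score,
      stringsAsFactors = FALSE
    ),
    min_score = min_score
  )
}

#' Canonicalize a scored interaction set
#'
#' Idempotent normalizer behind [read_scored_interactions()]: drops
#' self-interactions (with a message), stores each unordered pair
#' lexicographically, collapses duplicates keeping the maximum score and
#' applies the strict score filter.
#'
#' @param ppi data.frame with columns `protein_a`, `protein_b`, `score`.
#' @param min_score strict lower bound on retained scores; `NULL` or `-Inf`
#'   disables filtering.
#' @return canonical data.frame sorted by (protein_a, protein_b).
#' @export
canonicalize_interactions <- function(ppi, min_score = NULL) {
  stopifnot(all(c("protein_a", "protein_b", "score") %in% names(ppi)))
  a <- as.character(ppi$protein_a)
  b <- as.character(ppi$protein_b)
  s <- as.numeric(ppi$score)
  self <- a == b
  if (any(self)) {
    message("dropped ", sum(self), " self-interaction(s)")
    a <- a[!self]; b <- b[!self]; s <- s[!self]
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  if (length(lo)) {
    key <- paste(lo, hi, sep = "\r")
    s <- as.numeric(tapply(s, key, max))
    keys <- names(tapply(seq_along(key), key, `[`, 1L))
    parts <- strsplit(keys, "\r", fixed = TRUE)
    lo <- vapply(parts, `[[`, character(1), 1L)
    hi <- vapply(parts, `[[`, character(1), 2L)
  }
  out <- data.frame(protein_a = lo, protein_b = hi, score = s,
                    stringsAsFactors = FALSE)
  if (!is.null(min_score) && is.finite(min_score)) {
    out <- out[out$score > min_score, , drop = FALSE]
  }
  out <- out[order(out$protein_a, out$protein_b, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write scored interactions as TSV
#'
#' @param ppi canonical interaction data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scored_interactions <- function(ppi, path) {
  df <- data.frame(protein_a = ppi$protein_a, protein_b = ppi$protein_b,
                   combined_score = sprintf("%.6f", ppi$score))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a network in SIF format
#'
#' One line per edge `source<TAB>relation<TAB>target`; the relation label
#' defaults to `"pp"`. Isolated nodes are emitted as single-column lines so
#' no node is lost. Edges are written in canonical (lexicographic endpoint,
#' then pair) order so identical networks always serialize to identical
#' bytes.
#'
#' @param net typed network.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(net, path) {
  validate_typed_network(net)
  lines <- character(0)
  if (igraph::ecount(net) > 0) {
    el <- igraph::as_edgelist(net, names = TRUE)
    rel <- igraph::E(net)$relation
    if (is.null(rel)) rel <- rep("pp", nrow(el))
    rel[is.na(rel)] <- "pp"
    lo <- pmin(el[, 1L], el[, 2L]); hi <- pmax(el[, 1L], el[, 2L])
    o <- order(lo, hi, method = "radix")
    lines <- paste(lo[o], rel[o], hi[o], sep = "\t")
  }
  iso <- igraph::V(net)$name[igraph::degree(net) == 0]
  if (length(iso)) lines <- c(lines, sort(iso, method = "radix"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a SIF file back into a typed network
#'
#' Roles are not part of SIF; they are restored from `roles` (a named
#' character vector, e.g. re-read from the node-attribute TSV written by
#' [write_node_attributes()]), defaulting to `"other_protein"`.
#'
#' @param path SIF file.
#' @param roles optional named character vector node id -> role.
#' @param name graph name.
#' @return typed network.
#' @export
read_sif <- function(path, roles = NULL, name = "network") {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_f <- lengths(fields)
  if (any(!n_f %in% c(1L, 3L))) stop("malformed SIF line", call. = FALSE)
  edges <- do.call(rbind, lapply(fields[n_f == 3L], function(f) f[c(1L, 3L, 2L)]))
  nodes <- unique(c(unlist(lapply(fields[n_f == 1L], `[[`, 1L)),
                    if (!is.null(edges)) c(edges[, 1L], edges[, 2L])))
  role <- if (is.null(roles)) rep("other_protein", length(nodes)) else {
    r <- unname(roles[nodes])
    r[is.na(r)] <- "other_protein"
    r
  }
  typed_network(nodes, role,
                if (!is.null(edges)) data.frame(a = edges[, 1L], b = edges[, 2L],
                                                relation = edges[, 3L]),
                name = name)
}

#' Write per-node centrality records
#'
#' TSV with columns `node`, `role`, `degree`, `betweenness`, `closeness`,
#' `is_main`; real columns fixed to 6 decimals; rows sorted by descending
#' degree, ties broken by node id, so output is byte-stable.
#'
#' @param records data.frame as returned by [centrality_records()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_node_attributes <- function(records, path) {
  stopifnot(nrow(records) > 0)
  o <- order(-records$degree, records$node, method = "radix")
  records <- records[o, , drop = FALSE]
  df <- data.frame(
    node = records$node,
    role = records$role,
    degree = records$degree,
    betweenness = sprintf("%.6f", records$betweenness),
    closeness = sprintf("%.6f", records$closeness),
    is_main = records$is_main
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read node attributes written by [write_node_attributes()]
#'
#' @param path TSV path.
#' @return data.frame with typed columns.
#' @export
read_node_attributes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  df$is_main <- as.logical(df$is_main)
  df
}

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one set per line, tab-separated
#' `term<TAB>description<TAB>member...` with at least one member.
#'
#' @param path GMT file.
#' @return annotation collection: named list (term id) of lists with fields
#'   `name`, `category`, `members` (unique uppercase character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (i in seq_along(lines)) {
    f <- trimws(strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]])
    f <- f[nzchar(f) | seq_along(f) <= 2L]
    if (length(f) < 3L) {
      stop("GMT line ", i, " has no members", call. = FALSE)
    }
    id <- f[[1L]]
    if (id %in% names(out)) stop("duplicate term id: ", id, call. = FALSE)
    out[[id]] <- list(name = f[[2L]], category = "BP",
                      members = unique(toupper(f[-(1:2)])))
  }
  out
}

#' Write an annotation collection as GMT
#'
#' Terms are written sorted by id and members sorted within a term so output
#' is byte-stable; round-trips through [read_gmt()] preserve member sets.
#'
#' @param anns annotation collection (see [read_gmt()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(anns, path) {
  ids <- sort(names(anns), method = "radix")
  lines <- vapply(ids, function(id) {
    a <- anns[[id]]
    paste(c(id, a$name, sort(a$members, method = "radix")), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a typed network as GraphML
#'
#' Role labels travel as the `role` vertex attribute, so the network is
#' fully recoverable with [read_graphml()].
#'
#' @param net typed network.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  validate_typed_network(net)
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}

#' Read a GraphML file written by [write_graphml()]
#'
#' @param path GraphML file.
#' @return typed network (validated).
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  g <- igraph::as_undirected(g, mode = "each")
  validate_typed_network(g)
}

#' Read a compound-pharmacology-effect table
#'
#' Columns `compound`, `pharmacology`, `effect`; the traditional effect must
#' come from the closed three-value set `qi_dispersing`, `blood_nourishing`,
#' `spleen_invigorating`. Compounds with no reported pharmacology are simply
#' absent from the table.
#'
#' @param path TSV path.
#' @return data.frame with the three columns.
#' @export
read_pharm_efficacy_table <- function(path) {
  tbl <- read_relation_table(path, c("compound", "pharmacology", "effect"))
  ok <- c("qi_dispersing", "blood_nourishing", "spleen_invigorating")
  bad <- setdiff(unique(tbl$effect), ok)
  if (length(bad)) {
    stop("unknown traditional effect(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(tbl)) stop("duplicate pharmacology row", call. = FALSE)
  tbl
}
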