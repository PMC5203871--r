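#' Over-representation analysis with fold enrichment
#'
#' For each annotation term with at least one member in the gene list,
#' computes the 2x2 overlap counts (k = list members annotated, n = list
#' size, K = universe members annotated, N = universe size), fold
#' enrichment `(k/n)/(K/N)`, the upper-tail hypergeometric
#' `P(X >= k)` and Benjamini-Hochberg q-values across all tested terms.
#' Annotation members outside the universe are ignored (a message reports
#' how many were dropped). Results are sorted by raw p ascending, ties by
#' descending fold enrichment then term id.
#'
#' @param gene_list character vector of query gene symbols (subset of
#'   `universe`).
#' @param annotations annotation collection (see [read_gmt()]).
#' @param universe character vector of background gene symbols.
#' @param ease use the conservative EASE-style variant that tests
#'   `P(X >= k)` with one success removed (k-1); default `FALSE`, the plain
#'   hypergeometric tail.
#' @return data.frame with columns `term_id`, `term_name`, `k`, `n`, `K`,
#'   `N`, `fold_enrichment`, `p_raw`, `q_bh`.
#' @export
enrich <- function(gene_list, annotations, universe, ease = FALSE) {
  gene_list <- unique(toupper(gene_list))
  universe <- unique(toupper(universe))
  if (!length(gene_list)) stop("empty gene list", call. = FALSE)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  outside <- setdiff(gene_list, universe)
  if (length(outside)) {
    stop("gene list not contained in universe: ",
         paste(utils::head(outside, 5L), collapse = ", "), call. = FALSE)
  }
  n <- length(gene_list)
  N <- length(universe)
  dropped <- 0L
  rows <- lapply(names(annotations), function(id) {
    members <- unique(toupper(annotations[[id]]$members))
    in_univ <- members[members %in% universe]
    dropped <<- dropped + (length(members) - length(in_univ))
    K <- length(in_univ)
    k <- sum(gene_list %in% in_univ)
    if (k < 1L) return(NULL)
    data.frame(
      term_id = id,
      term_name = annotations[[id]]$name,
      k = k, n = n, K = K, N = N,
      fold_enrichment = (k * N) / (n * K),
      p_raw = hypergeom_tail(k, N, K, n, ease = ease),
      stringsAsFactors = FALSE
    )
  })
  if (dropped > 0) message("ignored ", dropped, " annotation member(s) outside the universe")
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    return(data.frame(term_id = character(0), term_name = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), fold_enrichment = numeric(0),
                      p_raw = numeric(0), q_bh = numeric(0)))
  }
  res$q_bh <- stats::p.adjust(res$p_raw, method = "BH")
  o <- order(res$p_raw, -res$fold_enrichment, res$term_id, method = "radix")
  res <- res[o, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for X hypergeometric with `K` annotated among `N`, drawing
#' `n`. With `ease = TRUE` one observed success is discounted
#' (`P(X >= k - 1)` bounded away from the trivial k = 0 case), the
#' conservative variant popularized by annotation servers.
#'
#' @param k observed overlap.
#' @param N universe size.
#' @param K annotated in universe.
#' @param n list size.
#' @param ease logical.
#' @return probability in (0, 1].
#' @export
hypergeom_tail <- function(k, N, K, n, ease = FALSE) {
  if (ease) k <- pmax(k - 1L, 0L)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Filter enrichment results on significance and effect size
#'
#' Retains terms with raw p strictly below `p_cut` and fold enrichment at
#' or above `fe_cut`.
#'
#' @param results data.frame from [enrich()].
#' @param p_cut strict raw-p threshold (default 0.05).
#' @param fe_cut inclusive fold-enrichment threshold (default 1).
#' @return filtered data.frame, order preserved.
#' @export
filter_significant <- function(results, p_cut = 0.05, fe_cut = 1) {
  keep <- results$p_raw < p_cut & results$fold_enrichment >= fe_cut
  out <- results[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition a gene list into functional modules
#'
#' Greedy, significance-ordered module assignment: walk the (already
#' filtered) results from most to least significant, absorbing a term into
#' an earlier kept term when the Jaccard overlap of their list-restricted
#' member sets exceeds 0.5; stop once `k_modules` non-redundant terms are
#' kept (fewer are returned, with a message, when the results cannot supply
#' that many). Each gene is then assigned to the kept term with the
#' smallest p covering it; genes covered by no kept term fall into the
#' `"unassigned"` module.
#'
#' @param gene_list character vector of genes to partition.
#' @param results significance-filtered data.frame from [enrich()].
#' @param annotations annotation collection the results came from (member
#'   sets are needed for coverage).
#' @param k_modules number of modules to aim for (>= 1).
#' @return named list module label (term id) -> character vector of genes;
#'   possibly including an `"unassigned"` element.
#' @export
partition_modules <- function(gene_list, results, annotations, k_modules = 4L) {
  stopifnot(k_modules >= 1L)
  gene_list <- unique(toupper(gene_list))
  kept <- character(0)
  kept_members <- list()
  for (i in seq_len(nrow(results))) {
    id <- results$term_id[i]
    mem <- intersect(unique(toupper(annotations[[id]]$members)), gene_list)
    if (!length(mem)) next
    redundant <- any(vapply(kept_members, function(m) {
      length(intersect(m, mem)) / length(union(m, mem)) > 0.5
    }, logical(1)))
    if (redundant) next
    kept <- c(kept, id)
    kept_members[[id]] <- mem
    if (length(kept) >= k_modules) break
  }
  if (length(kept) < k_modules) {
    message("only ", length(kept), " non-redundant term(s) available (asked for ",
            k_modules, ")")
  }
  assign <- setNames(rep(NA_character_, length(gene_list)), gene_list)
  # results are p-ordered, so walking kept terms in order assigns best-p first
  for (id in kept) {
    free <- names(assign)[is.na(assign) & names(assign) %in% kept_members[[id]]]
    assign[free] <- id
  }
  modules <- split(names(assign), assign)
  un <- names(assign)[is.na(assign)]
  if (length(un)) modules[["unassigned"]] <- un
  modules[c(kept[kept %in% names(modules)],
            if (length(un)) "unassigned")]
}

#' Write enrichment results as TSV
#'
#' Fold enrichment fixed to 3 decimals, p and q in 3-significant-figure
#' scientific notation; optional module column.
#'
#' @param results data.frame from [enrich()].
#' @param path output path.
#' @param modules optional module partition from [partition_modules()].
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(results, path, modules = NULL) {
  df <- data.frame(
    term_id = results$term_id,
    term_name = results$term_name,
    k = results$k, n = results$n, K = results$K, N = results$N,
    fold_enrichment = sprintf("%.3f", results$fold_enrichment),
    p_raw = sprintf("%.3g", results$p_raw),
    q_bh = sprintf("%.3g", results$q_bh)
  )
  if (!is.null(modules)) {
    gene2mod <- unlist(lapply(names(modules), function(m) {
      setNames(rep(m, length(modules[[m]])), modules[[m]])
    }))
    df$module <- ifelse(df$term_id %in% names(modules), df$term_id, "")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
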