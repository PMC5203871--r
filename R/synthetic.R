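#' Generator configuration
#'
#' Bundles every knob of the synthetic-data generators. Defaults are the
#' study-scale cardinalities of the six-herb formula analysis this package
#' models: 6 herbs, 11 active compounds, 233 predicted targets of which 4
#' are promiscuous (hit by every compound), 9 disease targets of which 2
#' overlap the predicted set, and 1259 additional interacting proteins.
#'
#' @param seed integer seed; identical configs generate identical bytes.
#' @param n_herbs,n_compounds,n_targets,n_disease_targets,n_shared_targets,
#'   n_other_proteins cardinalities of the generated tables.
#' @param ppi_mean_degree target mean degree of the interaction graph
#'   before score filtering (preferential attachment uses
#'   `m = round(ppi_mean_degree / 2)` edges per added node).
#' @param promiscuous_target_count number of targets hit by all compounds.
#' @param target_skew_q geometric decay of the per-target compound count
#'   for non-promiscuous targets (right-skewed, truncated to
#'   `[1, n_compounds]`); the default 0.855 gives a mean of about 4.5
#'   compounds per target at the default scale.
#' @param n_terms,planted_term_size,planted_fold annotation-collection
#'   shape: number of gene-set terms, members per term, and the fold
#'   enrichment the planted term realizes (within 10%).
#' @param n_hubs,hub_attach_frac when `n_hubs > 0` the interaction
#'   generator overlays that many planted hubs, each wired to
#'   `hub_attach_frac` of all nodes, and records them as ground truth.
#' @return validated list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_herbs = 6L, n_compounds = 11L,
                             n_targets = 233L, n_disease_targets = 9L,
                             n_shared_targets = 2L, n_other_proteins = 1259L,
                             ppi_mean_degree = 106, promiscuous_target_count = 4L,
                             target_skew_q = 0.855,
                             n_terms = 50L, planted_term_size = 40L,
                             planted_fold = 4,
                             n_hubs = 0L, hub_attach_frac = 0.6) {
  cfg <- list(seed = as.integer(seed), n_herbs = as.integer(n_herbs),
              n_compounds = as.integer(n_compounds),
              n_targets = as.integer(n_targets),
              n_disease_targets = as.integer(n_disease_targets),
              n_shared_targets = as.integer(n_shared_targets),
              n_other_proteins = as.integer(n_other_proteins),
              ppi_mean_degree = ppi_mean_degree,
              promiscuous_target_count = as.integer(promiscuous_target_count),
              target_skew_q = target_skew_q,
              n_terms = as.integer(n_terms),
              planted_term_size = as.integer(planted_term_size),
              planted_fold = planted_fold,
              n_hubs = as.integer(n_hubs), hub_attach_frac = hub_attach_frac)
  counts <- cfg[c("n_herbs", "n_compounds", "n_targets", "n_disease_targets",
                  "n_shared_targets", "n_other_proteins",
                  "promiscuous_target_count", "n_terms", "planted_term_size",
                  "n_hubs")]
  if (any(unlist(counts) < 0)) stop("negative count in config", call. = FALSE)
  if (cfg$n_shared_targets > min(cfg$n_targets, cfg$n_disease_targets)) {
    stop("n_shared_targets exceeds min(n_targets, n_disease_targets)",
         call. = FALSE)
  }
  if (cfg$promiscuous_target_count > cfg$n_targets) {
    stop("promiscuous_target_count exceeds n_targets", call. = FALSE)
  }
  if (cfg$planted_fold < 1) stop("planted_fold must be >= 1", call. = FALSE)
  if (cfg$target_skew_q <= 0 || cfg$target_skew_q >= 1) {
    stop("target_skew_q must lie in (0, 1)", call. = FALSE)
  }
  class(cfg) <- "generator_config"
  cfg
}

# symbols reused for the promiscuous targets so fixtures read naturally
PROMISCUOUS_SYMBOLS <- c("AR", "BACE1", "CA2", "GSTA1")

#' Generate a compound-target table
#'
#' Emulates a pharmacophore-mapping result: `promiscuous_target_count`
#' targets are hit by every compound; the remaining targets receive a
#' compound count drawn from a truncated geometric law on
#' `[1, n_compounds]` (right-skewed: most targets are hit by few
#' compounds). Every compound hits at least one target and every target is
#' hit by at least one compound.
#'
#' @param cfg generator config.
#' @param compounds optional compound ids (default `C01`, `C02`, ...).
#' @param targets optional target symbols (default: the promiscuous symbols
#'   then `T0005`-style tokens).
#' @return data.frame with columns `compound`, `target`.
#' @export
generate_compound_targets <- function(cfg, compounds = NULL, targets = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  if (cfg$n_compounds < 1L || cfg$n_targets < 1L) {
    stop("need at least one compound and one target", call. = FALSE)
  }
  set.seed(cfg$seed + 101L)
  if (is.null(compounds)) compounds <- sprintf("C%02d", seq_len(cfg$n_compounds))
  if (is.null(targets)) {
    npro <- cfg$promiscuous_target_count
    pro <- c(PROMISCUOUS_SYMBOLS, sprintf("PROM%02d", seq_len(max(0, npro - 4L))))
    pro <- pro[seq_len(npro)]
    targets <- c(pro, sprintf("T%04d", seq_len(cfg$n_targets - npro)))
  }
  stopifnot(length(compounds) == cfg$n_compounds,
            length(targets) == cfg$n_targets)
  npro <- cfg$promiscuous_target_count
  rows <- vector("list", cfg$n_targets)
  degs <- if (cfg$n_targets > npro) {
    k <- seq_len(cfg$n_compounds)
    sample(k, cfg$n_targets - npro, replace = TRUE,
           prob = cfg$target_skew_q^(k - 1))
  } else integer(0)
  for (i in seq_len(cfg$n_targets)) {
    hit <- if (i <= npro) compounds else {
      sort(sample(compounds, degs[i - npro]))
    }
    rows[[i]] <- data.frame(compound = hit, target = targets[i])
  }
  out <- do.call(rbind, rows)
  # every compound must hit >= 1 target; wire misses to the first target
  miss <- setdiff(compounds, unique(out$compound))
  if (length(miss)) {
    out <- rbind(out, data.frame(compound = miss, target = targets[1L]))
  }
  out$target <- toupper(out$target)
  out <- out[!duplicated(out), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate a scored interaction table
#'
#' A preferential-attachment (scale-free) graph over the anchor proteins
#' plus `n_other_proteins` novel proteins, with anchors placed first so
#' they sit in the well-connected early core. Scores are i.i.d. uniform on
#' (0.15, 1), so a strict 0.4 cut removes 25/85 = 29.4% of edges in
#' expectation. With `n_hubs > 0`, planted hub nodes wired to
#' `hub_attach_frac` of all nodes are overlaid on a sparse background and
#' recorded in the `"hub_set"` attribute of the result.
#'
#' @param cfg generator config.
#' @param anchor_nodes character vector of protein symbols to embed
#'   (typically compound targets plus disease targets); may be empty.
#' @return canonical data.frame of columns `protein_a`, `protein_b`,
#'   `score` with attribute `hub_set` (character, possibly empty).
#' @export
generate_ppi <- function(cfg, anchor_nodes = character(0)) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed + 202L)
  anchor_nodes <- unique(toupper(anchor_nodes))
  hubs <- if (cfg$n_hubs > 0) sprintf("HUB%02d", seq_len(cfg$n_hubs)) else character(0)
  others <- if (cfg$n_other_proteins > 0) {
    sprintf("P%04d", seq_len(cfg$n_other_proteins))
  } else character(0)
  nodes <- c(hubs, anchor_nodes, others)
  n <- length(nodes)
  empty <- data.frame(protein_a = character(0), protein_b = character(0),
                      score = numeric(0))
  attr(empty, "hub_set") <- hubs
  if (n < 2L) return(empty)
  m <- max(1L, min(n - 1L, as.integer(round(cfg$ppi_mean_degree / 2))))
  if (cfg$n_hubs > 0) {
    # sparse scale-free background plus dense planted hubs
    g <- igraph::sample_pa(n, m = m, directed = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
    k_hub <- max(1L, floor(cfg$hub_attach_frac * n))
    hub_el <- do.call(rbind, lapply(seq_len(cfg$n_hubs), function(h) {
      cbind(h, sample(setdiff(seq_len(n), h), k_hub))
    }))
    el <- rbind(el, hub_el)
  } else {
    g <- igraph::sample_pa(n, m = m, directed = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
  }
  df <- data.frame(protein_a = nodes[el[, 1L]], protein_b = nodes[el[, 2L]],
                   score = stats::runif(nrow(el), 0.15, 1.0))
  out <- suppressMessages(canonicalize_interactions(df))
  attr(out, "hub_set") <- hubs
  out
}

#' Generate a gene-set annotation collection with one planted term
#'
#' Builds `n_terms` gene sets over `universe`: one planted term whose
#' overlap with `hub_set` is sized so that its realized fold enrichment
#' (with `hub_set` as the query list and `universe` as background) equals
#' `cfg$planted_fold` within 10%, and `n_terms - 1` terms sampled uniformly
#' from the universe. The planted term id is carried in the
#' `"planted_term_id"` attribute.
#'
#' @param cfg generator config.
#' @param universe character vector of background symbols.
#' @param hub_set character vector, subset of `universe`, the list the
#'   signal is planted for.
#' @return annotation collection (see [read_gmt()]).
#' @export
generate_annotations <- function(cfg, universe, hub_set) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed + 303L)
  universe <- unique(toupper(universe))
  hub_set <- unique(toupper(hub_set))
  if (!all(hub_set %in% universe)) {
    stop("hub_set must be a subset of the universe", call. = FALSE)
  }
  N <- length(universe); n <- length(hub_set); K <- cfg$planted_term_size
  if (K > N) stop("planted_term_size exceeds universe", call. = FALSE)
  k <- as.integer(round(cfg$planted_fold * n * K / N))
  k_max <- min(n, K)
  if (k > k_max) {
    stop(sprintf(
      "planted_fold %.2f unattainable; maximum attainable is %.2f",
      cfg$planted_fold, (k_max * N) / (n * K)), call. = FALSE)
  }
  k <- max(k, 1L)
  realized <- (k * N) / (n * K)
  if (abs(realized - cfg$planted_fold) / cfg$planted_fold > 0.10) {
    stop(sprintf(
      "rounding pushes realized fold %.2f more than 10%% from requested %.2f; adjust sizes",
      realized, cfg$planted_fold), call. = FALSE)
  }
  planted <- c(sample(hub_set, k), sample(setdiff(universe, hub_set), K - k))
  anns <- list(PLANTED = list(name = "planted signal term", category = "BP",
                              members = sort(planted)))
  for (i in seq_len(max(0L, cfg$n_terms - 1L))) {
    anns[[sprintf("RAND%03d", i)]] <- list(
      name = sprintf("background term %03d", i), category = "BP",
      members = sort(sample(universe, min(K, N))))
  }
  attr(anns, "planted_term_id") <- "PLANTED"
  anns
}

# The curated compound -> pharmacology -> traditional-effect relations
# shipped with the package (one compound vocabulary shared with the
# generated tables; compounds with no reported pharmacology are absent).
pharm_efficacy_fixture <- function() {
  path <- system.file("extdata", "pharm_efficacy.tsv", package = "netpharm")
  read_pharm_efficacy_table(path)
}

# Fixed study-scale herb -> compound assignment (6 herbs, 12 compounds; the
# compound-target table uses 11 of them -- one saponin never mapped to any
# target, mirroring a compound that fails pharmacophore mapping).
study_herb_compounds <- function() {
  data.frame(
    herb = c("chaihu", "chaihu", "chaihu",
             "danggui", "danggui",
             "baishao",
             "baizhu", "baizhu", "baizhu",
             "fuling", "fuling",
             "gancao"),
    compound = c("saikosaponin_a", "saikosaponin_d", "longispinogenin",
                 "ferulic_acid", "ligustilide",
                 "paeoniflorin",
                 "atractylol", "atractylenolide_i", "atractylenolide_iii",
                 "pachyman", "pachymic_acid",
                 "glycyrrhizin"),
    stringsAsFactors = FALSE
  )
}

study_network_compounds <- function() {
  setdiff(study_herb_compounds()$compound, "longispinogenin")
}

study_disease_targets <- function() {
  # 2 shared with the predicted-target set, 7 disease-only; the last one is
  # engineered to have no surviving interaction with the target set
  list(shared = c("ESR1", "PGR"),
       only = c("FSHR", "LHCGR", "GNRHR", "PRLR", "DRD2", "CYP19A1"),
       isolated = "AMHR2")
}

#' Write the full study-scale input bundle
#'
#' Generates and writes the six input files at the study-scale
#' cardinalities (6 herbs, 11 mapped compounds, 233 targets with 4
#' promiscuous ones, 9 disease targets with 2 shared, 1259 other
#' proteins), engineered so the downstream networks reproduce the printed
#' censuses: every other protein keeps at least one above-threshold
#' interaction with a seed protein, exactly one disease-only target has no
#' surviving interaction with the target set (so it appears in the PPI
#' view but not in the herb-target-disease view), and the annotation
#' collection carries one planted list-level term plus four disjoint
#' module terms over the high-degree core. Same seed, same bytes.
#'
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @return invisible named list of file paths (`herbs`, `compound_targets`,
#'   `disease_targets`, `ppi`, `annotations`, `pharm_efficacy`).
#' @export
generate_study_bundle <- function(seed, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  herbs <- study_herb_compounds()
  compounds <- study_network_compounds()
  dz <- study_disease_targets()
  named_targets <- c(PROMISCUOUS_SYMBOLS, dz$shared,
                     "ESR2", "INSR", "ERBB4", "MAOA", "LYZ")
  cfg <- generator_config(seed = seed)
  targets <- c(named_targets,
               sprintf("T%04d", seq_len(cfg$n_targets - length(named_targets))))
  ct <- generate_compound_targets(cfg, compounds = compounds, targets = targets)

  disease <- c(dz$only, dz$isolated, dz$shared)
  anchors <- c(dz$only, dz$isolated, unique(ct$target))  # disease-only first: early core
  ppi <- generate_ppi(cfg, anchor_nodes = anchors)
  ppi <- engineer_bundle_ppi(ppi, seeds = unique(c(anchors, disease)),
                             target_set = unique(ct$target),
                             disease_set = disease, isolated = dz$isolated,
                             seed = seed)

  # annotation collection: planted list-level term, four disjoint module
  # terms over the high-degree core, and random background terms
  filtered <- ppi[ppi$score > 0.4, , drop = FALSE]
  universe <- unique(c(ct$target, disease, filtered$protein_a, filtered$protein_b))
  gene_list <- unique(c(ct$target, disease))
  anns <- generate_annotations(cfg, universe = universe, hub_set = gene_list)
  deg <- table(c(filtered$protein_a, filtered$protein_b))
  core <- names(sort(deg, decreasing = TRUE))[seq_len(min(120L, length(deg)))]
  set.seed(seed + 404L)
  for (mi in 1:4) {
    anns[[sprintf("MOD%d", mi)]] <- list(
      name = sprintf("module process %d", mi), category = "BP",
      members = sort(core[seq.int(30L * (mi - 1L) + 1L, min(30L * mi, length(core)))]))
  }

  paths <- list(
    herbs = file.path(dir, "herbs.tsv"),
    compound_targets = file.path(dir, "compound_targets.tsv"),
    disease_targets = file.path(dir, "disease_targets.txt"),
    ppi = file.path(dir, "ppi.tsv"),
    annotations = file.path(dir, "annotations.gmt"),
    pharm_efficacy = file.path(dir, "pharm_efficacy.tsv")
  )
  utils::write.table(herbs, paths$herbs, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ct, paths$compound_targets, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(c("target", disease), paths$disease_targets, useBytes = TRUE)
  write_scored_interactions(ppi, paths$ppi)
  write_gmt(anns, paths$annotations)
  file.copy(system.file("extdata", "pharm_efficacy.tsv", package = "netpharm"),
            paths$pharm_efficacy, overwrite = TRUE)
  invisible(paths)
}

# Deterministic post-pass that makes the random interaction table satisfy
# the structural guarantees the study-scale censuses need.
engineer_bundle_ppi <- function(ppi, seeds, target_set, disease_set, isolated,
                                seed) {
  set.seed(seed + 505L)
  a <- ppi$protein_a; b <- ppi$protein_b; s <- ppi$score
  tgt_univ <- unique(c(target_set, disease_set))

  # (1) the engineered-isolated disease target loses every interaction with
  #     the target universe (scores pushed under the cut) ...
  iso_edge <- (a == isolated & b %in% tgt_univ) | (b == isolated & a %in% tgt_univ)
  s[iso_edge] <- stats::runif(sum(iso_edge), 0.15, 0.399)
  # ... but keeps at least one surviving interaction with an other protein
  iso_other <- (a == isolated & !(b %in% tgt_univ)) |
    (b == isolated & !(a %in% tgt_univ))
  if (!any(iso_other & s > 0.4)) {
    idx <- which(iso_other)
    if (length(idx)) s[idx[1L]] <- stats::runif(1, 0.401, 1)
  }

  # (2) every remaining disease-only target keeps >= 1 surviving
  #     interaction with the target universe (its ticket into the
  #     herb-target-disease view)
  for (d in setdiff(setdiff(disease_set, target_set), isolated)) {
    hit <- ((a == d & b %in% tgt_univ) | (b == d & a %in% tgt_univ))
    if (!any(hit & s > 0.4)) {
      idx <- which(hit)
      if (length(idx)) s[idx[1L]] <- stats::runif(1, 0.401, 1)
    }
  }

  # (3) every other protein keeps >= 1 surviving interaction with a seed
  other_a <- !(a %in% seeds); other_b <- !(b %in% seeds)
  seed_edge <- xor(other_a, other_b)  # one endpoint seed, one other
  surv <- s > 0.4
  other_of <- ifelse(other_a, a, b)
  covered <- unique(other_of[seed_edge & surv])
  all_others <- unique(c(a[other_a], b[other_b]))
  for (p in setdiff(all_others, covered)) {
    idx <- which(seed_edge & other_of == p)
    if (length(idx)) {
      s[idx[1L]] <- stats::runif(1, 0.401, 1)
    } else {
      a <- c(a, p); b <- c(b, sample(seeds, 1L))
      s <- c(s, stats::runif(1, 0.401, 1))
    }
  }
  suppressMessages(canonicalize_interactions(
    data.frame(protein_a = a, protein_b = b, score = s)))
}

#' Pick a role-census main-node set from a network
#'
#' Selects, per role, the requested number of highest-degree nodes (ties
#' broken by node id). Used to engineer a main-node set with a prescribed
#' role census whose induced subgraph is interaction-dense.
#'
#' @param net typed network.
#' @param census named integer vector role -> count.
#' @return character vector of node ids.
#' @export
top_nodes_by_role <- function(net, census) {
  validate_typed_network(net)
  deg <- igraph::degree(net)
  nm <- igraph::V(net)$name
  role <- igraph::V(net)$role
  unlist(lapply(names(census), function(r) {
    i <- which(role == r)
    if (length(i) < census[[r]]) {
      stop("not enough nodes with role ", r, call. = FALSE)
    }
    i <- i[order(-deg[i], nm[i], method = "radix")]
    nm[i[seq_len(census[[r]])]]
  }), use.names = FALSE)
}
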