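#' Pipeline configuration
#'
#' Collects every run-level constant: input locations (or a generator seed
#' when inputs are to be synthesized), the interaction score threshold, the
#' enrichment cuts and the module count.
#'
#' @param out_dir output directory for all artifacts.
#' @param input_dir directory holding the six input files (names as written
#'   by [generate_study_bundle()]); `NULL` means generate them under
#'   `out_dir/inputs` from `seed`.
#' @param seed integer seed for generation and any sampling.
#' @param score_threshold strict lower bound on interaction scores
#'   (default 0.4).
#' @param p_cut,fe_cut significance cuts for [filter_significant()].
#' @param k_modules number of functional modules (default 4).
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, input_dir = NULL, seed = 1L,
                            score_threshold = 0.4, p_cut = 0.05, fe_cut = 1,
                            k_modules = 4L) {
  if (score_threshold < 0 || score_threshold > 1) {
    stop("score_threshold must lie in [0, 1]", call. = FALSE)
  }
  if (k_modules < 1) stop("k_modules must be >= 1", call. = FALSE)
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    stop("input_dir does not exist: ", input_dir, call. = FALSE)
  }
  structure(list(out_dir = out_dir, input_dir = input_dir,
                 seed = as.integer(seed), score_threshold = score_threshold,
                 p_cut = p_cut, fe_cut = fe_cut,
                 k_modules = as.integer(k_modules)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()].
#'
#' @param path YAML file.
#' @return `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

bundle_paths <- function(dir) {
  list(herbs = file.path(dir, "herbs.tsv"),
       compound_targets = file.path(dir, "compound_targets.tsv"),
       disease_targets = file.path(dir, "disease_targets.txt"),
       ppi = file.path(dir, "ppi.tsv"),
       annotations = file.path(dir, "annotations.gmt"),
       pharm_efficacy = file.path(dir, "pharm_efficacy.tsv"))
}

#' Validate an input bundle
#'
#' Cross-file referential checks: files present and non-empty, compounds of
#' the target table covered by the herb table, symbol normalization, and
#' the shared-target census. Fatal issues abort a run; warnings are
#' reported but tolerated.
#'
#' @param cfg `pipeline_config` whose `input_dir` is set.
#' @return list with `fatal` and `warning` character vectors plus a
#'   `counts` list (compound, target, disease and shared-target censuses).
#' @export
validate_inputs <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"), !is.null(cfg$input_dir))
  p <- bundle_paths(cfg$input_dir)
  fatal <- character(0); warn <- character(0)
  missing <- !vapply(p, file.exists, logical(1))
  if (any(missing)) {
    return(list(fatal = paste("missing input file:", unlist(p)[missing]),
                warning = warn, counts = list()))
  }
  herbs <- tryCatch(read_herb_compound_table(p$herbs), error = function(e) e)
  if (inherits(herbs, "error")) {
    return(list(fatal = conditionMessage(herbs), warning = warn, counts = list()))
  }
  ct_raw <- read_relation_table(p$compound_targets, c("compound", "target"))
  if (!nrow(ct_raw)) fatal <- c(fatal, "empty compound-target table")
  if (any(ct_raw$target != toupper(ct_raw$target))) {
    warn <- c(warn, "lowercase target symbols normalized to uppercase")
  }
  ct <- tryCatch(read_compound_target_table(p$compound_targets, herbs = herbs),
                 error = function(e) e)
  if (inherits(ct, "error")) {
    return(list(fatal = c(fatal, conditionMessage(ct)), warning = warn,
                counts = list()))
  }
  dz_raw <- readLines(p$disease_targets, warn = FALSE)
  if (any(dz_raw != toupper(dz_raw))) {
    warn <- c(warn, "lowercase disease symbols normalized to uppercase")
  }
  disease <- read_disease_targets(p$disease_targets)
  shared <- intersect(unique(ct$target), disease)
  counts <- list(n_herbs = length(unique(herbs$herb)),
                 n_compounds = length(unique(ct$compound)),
                 n_targets = length(unique(ct$target)),
                 n_disease_targets = length(disease),
                 n_shared_targets = length(shared))
  list(fatal = fatal, warning = warn, counts = counts)
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' generate/load -> build networks (1)-(4) -> centrality for (2)-(4) ->
#' main-node selection on the PPI network -> direct-interaction hub
#' subnetwork -> over-representation analysis of the target list and of
#' the main nodes -> functional-module partition. Every artifact is
#' written under `cfg$out_dir` (SIF + GraphML for networks, TSV for
#' tables, JSON for thresholds) and listed, with md5 content hashes, in
#' the returned manifest (also written as `manifest.json`). The run is a
#' pure function of (config, seed): identical configs give identical
#' hashes.
#'
#' @param cfg `pipeline_config`.
#' @return invisible manifest list (`artifacts` name -> md5, `counts` of
#'   every census the analysis prints, `thresholds`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out <- cfg$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  stage <- "inputs"
  manifest <- list(artifacts = list(), counts = list(), thresholds = list())
  art <- function(name, path) manifest$artifacts[[name]] <<- unname(tools::md5sum(path))
  tryCatch({
    if (is.null(cfg$input_dir)) {
      cfg$input_dir <- file.path(out, "inputs")
      generate_study_bundle(cfg$seed, cfg$input_dir)
    }
    rep <- validate_inputs(cfg)
    if (length(rep$fatal)) {
      stop(paste(rep$fatal, collapse = "; "), call. = FALSE)
    }
    p <- bundle_paths(cfg$input_dir)
    herbs <- read_herb_compound_table(p$herbs)
    ct <- read_compound_target_table(p$compound_targets, herbs = herbs)
    disease <- read_disease_targets(p$disease_targets)
    ppi <- read_scored_interactions(p$ppi, min_score = cfg$score_threshold)
    anns <- read_gmt(p$annotations)
    pharm <- read_pharm_efficacy_table(p$pharm_efficacy)

    stage <- "network_construction"
    nets <- list(
      pharmacology_efficacy = build_pharm_efficacy_network(pharm, herbs),
      compound_target = build_compound_target_network(ct),
      herb_target_disease = suppressMessages(
        build_herb_target_disease_network(herbs, ct, disease, ppi = ppi)),
      ppi = build_ppi_network(ct, disease, ppi)
    )
    for (nm in names(nets)) {
      write_sif(nets[[nm]], file.path(out, paste0(nm, ".sif")))
      write_graphml(nets[[nm]], file.path(out, paste0(nm, ".graphml")))
      art(paste0(nm, ".sif"), file.path(out, paste0(nm, ".sif")))
      art(paste0(nm, ".graphml"), file.path(out, paste0(nm, ".graphml")))
      manifest$counts[[nm]] <- list(
        nodes = igraph::vcount(nets[[nm]]),
        edges = igraph::ecount(nets[[nm]]),
        roles = as.list(role_census(nets[[nm]]))
      )
    }

    stage <- "topology"
    for (nm in c("compound_target", "herb_target_disease", "ppi")) {
      rec <- centrality_records(nets[[nm]])
      f <- file.path(out, paste0(nm, "_centrality.tsv"))
      write_node_attributes(rec, f)
      art(basename(f), f)
      if (nm == "ppi") {
        sel <- select_main_nodes(rec)
        manifest$thresholds <- as.list(sel$thresholds)
        manifest$counts$main_nodes <- length(sel$main_nodes)
        writeLines(sort(sel$main_nodes), file.path(out, "main_nodes.txt"),
                   useBytes = TRUE)
        art("main_nodes.txt", file.path(out, "main_nodes.txt"))
        write_json_artifact(as.list(sel$thresholds),
                            file.path(out, "thresholds.json"))
        art("thresholds.json", file.path(out, "thresholds.json"))
        main <- sel$main_nodes
      }
    }

    stage <- "subnetwork"
    sub <- main_node_subnetwork(nets$ppi, main)
    write_sif(sub, file.path(out, "main_subnetwork.sif"))
    write_graphml(sub, file.path(out, "main_subnetwork.graphml"))
    art("main_subnetwork.sif", file.path(out, "main_subnetwork.sif"))
    art("main_subnetwork.graphml", file.path(out, "main_subnetwork.graphml"))
    manifest$counts$main_subnetwork <- list(
      nodes = igraph::vcount(sub), edges = igraph::ecount(sub),
      roles = as.list(role_census(sub)))

    stage <- "enrichment"
    ann_genes <- unique(toupper(unlist(lapply(anns, `[[`, "members"))))
    universe <- intersect(ann_genes, igraph::V(nets$ppi)$name)
    lists <- list(
      targets = intersect(nodes_with_role(
        nets$herb_target_disease,
        c("compound_target", "shared_target", "infertility_target")), universe),
      main_nodes = intersect(main, universe)
    )
    results <- list()
    for (nm in names(lists)) {
      res <- suppressMessages(enrich(lists[[nm]], anns, universe))
      results[[nm]] <- res
      f <- file.path(out, paste0("enrichment_", nm, ".tsv"))
      write_enrichment(res, f)
      art(basename(f), f)
    }

    stage <- "modules"
    sig <- filter_significant(results$main_nodes, p_cut = cfg$p_cut,
                              fe_cut = cfg$fe_cut)
    modules <- suppressMessages(
      partition_modules(lists$main_nodes, sig, anns,
                        k_modules = cfg$k_modules))
    mod_df <- data.frame(
      gene = unlist(modules, use.names = FALSE),
      module = rep(names(modules), lengths(modules)))
    mod_df <- mod_df[order(mod_df$module, mod_df$gene, method = "radix"), ]
    f <- file.path(out, "modules.tsv")
    utils::write.table(mod_df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    art("modules.tsv", f)
    manifest$counts$modules <- length(setdiff(names(modules), "unassigned"))
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  manifest$artifacts <- manifest$artifacts[order(names(manifest$artifacts))]
  write_json_artifact(manifest, file.path(out, "manifest.json"))
  invisible(manifest)
}
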