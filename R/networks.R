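#' Partition target symbols into roles
#'
#' A protein hit by compounds and also listed for the disease is a
#' `shared_target`; hit by compounds only, a `compound_target`; listed for
#' the disease only, an `infertility_target`. The three roles partition the
#' union of the two sets.
#'
#' @param compound_targets character vector of compound-target symbols.
#' @param disease_targets character vector of disease-target symbols.
#' @return named character vector symbol -> role.
#' @export
assign_target_roles <- function(compound_targets, disease_targets) {
  ct <- unique(toupper(compound_targets))
  dt <- unique(toupper(disease_targets))
  all <- union(ct, dt)
  role <- ifelse(all %in% ct & all %in% dt, "shared_target",
                 ifelse(all %in% ct, "compound_target", "infertility_target"))
  names(role) <- all
  role
}

#' Build the pharmacology-efficacy network
#'
#' Four-layer network linking herbs to their active compounds, compounds to
#' their reported pharmacological actions, and those actions to the
#' formula's traditional effects (qi-dispersing, blood-nourishing,
#' spleen-invigorating). Compounds with no reported pharmacology appear
#' with their herb edge(s) only.
#'
#' @param tbl pharmacology table (see [read_pharm_efficacy_table()]).
#' @param herbs herb-compound table.
#' @return typed network with roles herb/compound/pharmacology/effect.
#' @export
build_pharm_efficacy_network <- function(tbl, herbs) {
  orphan <- setdiff(unique(tbl$compound), unique(herbs$compound))
  if (length(orphan)) {
    stop("compound(s) without a parent herb: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  herb_ids <- unique(herbs$herb)
  compound_ids <- unique(herbs$compound)
  pharm_ids <- unique(tbl$pharmacology)
  effect_ids <- unique(tbl$effect)
  nodes <- c(herb_ids, compound_ids, pharm_ids, effect_ids)
  roles <- c(rep("herb", length(herb_ids)),
             rep("compound", length(compound_ids)),
             rep("pharmacology", length(pharm_ids)),
             rep("effect", length(effect_ids)))
  e_hc <- data.frame(a = herbs$herb, b = herbs$compound, relation = "contains")
  e_cp <- if (nrow(tbl)) unique(data.frame(a = tbl$compound,
                                           b = tbl$pharmacology,
                                           relation = "exerts"))
  e_pe <- if (nrow(tbl)) unique(data.frame(a = tbl$pharmacology, b = tbl$effect,
                                           relation = "supports"))
  typed_network(nodes, roles, rbind(e_hc, e_cp, e_pe),
                name = "pharmacology_efficacy")
}

#' Build the compound-target bipartite network
#'
#' One node per compound and per predicted target, one edge per distinct
#' (compound, target) pair.
#'
#' @param ct compound-target table.
#' @return typed network with roles compound/compound_target.
#' @export
build_compound_target_network <- function(ct) {
  compounds <- unique(ct$compound)
  targets <- unique(ct$target)
  typed_network(
    c(compounds, targets),
    c(rep("compound", length(compounds)),
      rep("compound_target", length(targets))),
    data.frame(a = ct$compound, b = ct$target, relation = "targets"),
    name = "compound_target"
  )
}

#' Build the herb-target-disease network
#'
#' Compounds are contracted out: each herb links directly to the union of
#' its compounds' predicted targets (relation `"herb"`, the gray links of a
#' formula-level view). Disease targets also hit by compounds take the
#' `shared_target` role. Interactions between disease-side targets and the
#' target set (relation `"ppi"`, the black links) are injected from the
#' score-filtered interaction table; disease targets left without any such
#' interaction would be isolated and are dropped with a message -- a
#' disease target enters this view only through an actual interaction.
#'
#' @param herbs herb-compound table.
#' @param ct compound-target table.
#' @param disease character vector of disease-target symbols (non-empty).
#' @param ppi optional canonical score-filtered interaction data.frame used
#'   for the disease-target links; `NULL` means no such links.
#' @return typed network with roles herb/compound_target/
#'   infertility_target/shared_target.
#' @export
build_herb_target_disease_network <- function(herbs, ct, disease, ppi = NULL) {
  if (length(disease) == 0) stop("empty disease-target set", call. = FALSE)
  disease <- unique(toupper(disease))
  targets <- unique(ct$target)
  role <- assign_target_roles(targets, disease)

  # herb -> union of its compounds' targets
  comp_by_herb <- split(herbs$compound, herbs$herb)
  tgt_by_comp <- split(ct$target, ct$compound)
  e_herb <- do.call(rbind, lapply(names(comp_by_herb), function(h) {
    tg <- unique(unlist(tgt_by_comp[comp_by_herb[[h]]], use.names = FALSE))
    if (is.null(tg) || !length(tg)) return(NULL)
    data.frame(a = h, b = tg, relation = "herb")
  }))

  # black links: filtered PPI between disease-side targets and the target set
  e_ppi <- NULL
  if (!is.null(ppi) && nrow(ppi)) {
    in_univ <- ppi$protein_a %in% names(role) & ppi$protein_b %in% names(role)
    touches_disease <- ppi$protein_a %in% disease | ppi$protein_b %in% disease
    keep <- in_univ & touches_disease
    if (any(keep)) {
      e_ppi <- data.frame(a = ppi$protein_a[keep], b = ppi$protein_b[keep],
                          relation = "ppi")
    }
  }

  herb_ids <- unique(herbs$herb)
  linked <- unique(c(e_ppi$a, e_ppi$b))
  pure_disease <- setdiff(disease, targets)
  dropped <- setdiff(pure_disease, linked)
  if (length(dropped)) {
    message("dropped ", length(dropped),
            " disease target(s) with no interaction in this view: ",
            paste(dropped, collapse = ", "))
  }
  keep_symbols <- c(targets, setdiff(pure_disease, dropped))
  nodes <- c(herb_ids, keep_symbols)
  roles <- c(rep("herb", length(herb_ids)), unname(role[keep_symbols]))
  typed_network(nodes, roles, rbind(e_herb, e_ppi),
                name = "herb_target_disease")
}

#' Build the PPI network around compound and disease targets
#'
#' Seed set = compound targets union disease targets. The network is induced
#' over the seeds plus every protein interacting with at least one seed in
#' the (already score-filtered) interaction table; all interactions among
#' included proteins are kept, including those between two non-seed
#' partners. Seeds are always retained as nodes even if none of their
#' interactions survived filtering; non-seed proteins take the
#' `other_protein` role.
#'
#' @param ct compound-target table.
#' @param disease character vector of disease-target symbols.
#' @param ppi canonical score-filtered interaction data.frame.
#' @return typed network with roles compound_target/infertility_target/
#'   shared_target/other_protein.
#' @export
build_ppi_network <- function(ct, disease, ppi) {
  disease <- unique(toupper(disease))
  targets <- unique(ct$target)
  seeds <- union(targets, disease)
  role <- assign_target_roles(targets, disease)

  partners <- character(0)
  edges <- NULL
  if (!is.null(ppi) && nrow(ppi)) {
    seed_edge <- ppi$protein_a %in% seeds | ppi$protein_b %in% seeds
    partners <- setdiff(unique(c(ppi$protein_a[seed_edge],
                                 ppi$protein_b[seed_edge])), seeds)
    keep_nodes <- c(seeds, partners)
    both_in <- ppi$protein_a %in% keep_nodes & ppi$protein_b %in% keep_nodes
    if (any(both_in)) {
      edges <- data.frame(a = ppi$protein_a[both_in],
                          b = ppi$protein_b[both_in], relation = "pp")
    }
  }
  nodes <- c(seeds, partners)
  roles <- c(unname(role[seeds]), rep("other_protein", length(partners)))
  typed_network(nodes, roles, edges, name = "ppi")
}

#' Induced subnetwork of the main nodes
#'
#' Induces the subgraph on the given main-node set and then removes nodes
#' left without any direct interaction, so the result is the
#' direct-interaction network among hubs.
#'
#' @param net typed network.
#' @param main character vector of node ids, subset of the network's nodes.
#' @return typed network (possibly empty).
#' @export
main_node_subnetwork <- function(net, main) {
  validate_typed_network(net)
  missing <- setdiff(main, igraph::V(net)$name)
  if (length(missing)) {
    stop("main node(s) not in network: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  sub <- igraph::induced_subgraph(net, vids = main)
  iso <- igraph::V(sub)[igraph::degree(sub) == 0]
  sub <- igraph::delete_vertices(sub, iso)
  sub$name <- paste0(net$name, "_main")
  validate_typed_network(sub)
}

#' Build a plain interaction graph
#'
#' Turns a canonical scored-interaction table into a typed network whose
#' nodes all carry `other_protein` (or roles supplied by name).
#'
#' @param ppi canonical interaction data.frame.
#' @param roles optional named character vector node -> role.
#' @param name graph name.
#' @return typed network.
#' @export
graph_from_interactions <- function(ppi, roles = NULL, name = "ppi") {
  nodes <- unique(c(ppi$protein_a, ppi$protein_b))
  r <- rep("other_protein", length(nodes))
  if (!is.null(roles)) {
    hit <- nodes %in% names(roles)
    r[hit] <- unname(roles[nodes[hit]])
  }
  edges <- if (nrow(ppi)) data.frame(a = ppi$protein_a, b = ppi$protein_b,
                                     relation = "pp")
  typed_network(nodes, r, edges, name = name)
}
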