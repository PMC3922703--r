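## Co-presence networks: core networks from normalized intensities
## (Pearson correlation across a group's samples), non-core pathway
## sub-networks from binary presence profiles (phi coefficient). Edges are
## positive associations at or above a threshold; modules are connected
## components by default.

#' Build a co-presence network over core genes
#'
#' Nodes are core genes; an edge joins two genes whose normalized
#' intensities across the group's samples have a positive Pearson
#' correlation of at least `min_abs_corr`. Genes with constant intensity
#' remain isolated nodes.
#'
#' @param normalized Relative-abundance matrix.
#' @param core_genes Character vector of core gene ids.
#' @param group_samples Sample ids of the group (at least 3).
#' @param min_abs_corr Correlation threshold in (0, 1].
#' @param annotation Optional annotation data frame to attach categories.
#' @param group Group label stored on the network (e.g., "H").
#' @return Object of class `"copresence_network"` with `nodes` (data
#'   frame: `gene_id`, `kind`, `category`), `edges` (data frame: `from`,
#'   `to`, `score`), `group`, `pathway_scope`, `modules` (NULL until
#'   [detect_modules()]).
#' @export
build_core_network <- function(normalized, core_genes, group_samples,
                               min_abs_corr = 0.8, annotation = NULL,
                               group = NA_character_) {
  if (length(group_samples) < 3L)
    stop("at least 3 samples required to build a network", call. = FALSE)
  if (!length(core_genes)) stop("core gene set is empty", call. = FALSE)
  m <- t(normalized[core_genes, group_samples, drop = FALSE])
  new_copresence_network(m, kind = "core", min_abs_corr = min_abs_corr,
                         annotation = annotation, group = group,
                         pathway_scope = NA_character_)
}

#' Build a non-core co-presence sub-network on a metabolic pathway group
#'
#' Nodes are non-core genes of the chosen pathway group (Carbon, AA or
#' Nitrogen; see [pathway_group_of()]); the association between two genes
#' is the phi coefficient of their 0/1 presence profiles across the
#' group's samples, and only positive associations at or above the
#' threshold become edges. Genes present in all or none of the group's
#' samples are isolated.
#'
#' @param noncore_binary Non-core gene x sample 0/1 matrix.
#' @param annotation Annotation data frame with `gene_id` and
#'   `pathway_group`.
#' @param pathway_group One of `"Carbon"`, `"AA"`, `"Nitrogen"`.
#' @param group_samples Sample ids of the group.
#' @param min_abs_corr Phi threshold in (0, 1].
#' @param group Group label stored on the network.
#' @return A `"copresence_network"` (see [build_core_network()]).
#' @export
build_noncore_subnetwork <- function(noncore_binary, annotation, pathway_group,
                                     group_samples, min_abs_corr = 0.8,
                                     group = NA_character_) {
  if (!pathway_group %in% c("Carbon", "AA", "Nitrogen"))
    stop("unknown pathway group: ", pathway_group, call. = FALSE)
  scope <- annotation$gene_id[annotation$pathway_group == pathway_group]
  genes <- intersect(rownames(noncore_binary), scope)
  if (!length(genes))
    stop("no non-core genes in pathway group ", pathway_group, call. = FALSE)
  m <- t(noncore_binary[genes, group_samples, drop = FALSE])
  new_copresence_network(m, kind = "noncore", min_abs_corr = min_abs_corr,
                         annotation = annotation, group = group,
                         pathway_scope = pathway_group)
}

## Shared construction: columns of `m` are genes, rows samples. Pearson on
## binary profiles equals the phi coefficient, so one code path serves
## both network kinds.
new_copresence_network <- function(m, kind, min_abs_corr, annotation,
                                   group, pathway_scope) {
  genes <- colnames(m)
  sds <- apply(m, 2, sd)
  r <- suppressWarnings(cor(m))  # constant genes give NA rows
  r[is.na(r)] <- 0
  diag(r) <- 0
  keep <- which(upper.tri(r) & r >= min_abs_corr & r > 0, arr.ind = TRUE)
  edges <- data.frame(from = genes[keep[, 1]], to = genes[keep[, 2]],
                      score = r[keep], stringsAsFactors = FALSE)
  ord <- order(edges$from, edges$to)
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  cat_of <- if (!is.null(annotation))
    setNames(annotation$category, annotation$gene_id) else NULL
  nodes <- data.frame(gene_id = genes,
                      kind = kind,
                      category = if (is.null(cat_of)) NA_character_
                                 else unname(cat_of[genes]),
                      constant = sds == 0,
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, modules = NULL,
                 group = group, pathway_scope = pathway_scope,
                 min_abs_corr = min_abs_corr),
            class = "copresence_network")
}

#' @export
print.copresence_network <- function(x, ...) {
  cat(sprintf("copresence_network (%s%s): %d nodes, %d edges, threshold %.2f%s\n",
              x$nodes$kind[1] %||% "?",
              if (!is.na(x$pathway_scope)) paste0(", ", x$pathway_scope) else "",
              nrow(x$nodes), nrow(x$edges), x$min_abs_corr,
              if (!is.null(x$modules)) sprintf(", %d modules",
                                               length(unique(x$modules))) else ""))
  invisible(x)
}

#' Detect modules in a co-presence network
#'
#' By default modules are the connected components of the thresholded
#' graph; `method = "greedy"` uses greedy modularity optimization
#' instead. Isolated nodes (no edges) receive no module. Module ids are
#' deterministic: numbered by decreasing size, ties broken by the
#' lexicographically smallest member gene id.
#'
#' @param network A `"copresence_network"`.
#' @param method `"components"` or `"greedy"`.
#' @return The network with its `modules` element set (named integer
#'   vector, gene id to module id).
#' @export
detect_modules <- function(network, method = c("components", "greedy")) {
  method <- match.arg(method)
  stopifnot(inherits(network, "copresence_network"))
  linked <- sort(unique(c(network$edges$from, network$edges$to)))
  if (!length(linked)) {
    network$modules <- setNames(integer(0), character(0))
    return(network)
  }
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                     vertices = data.frame(name = linked))
  member <- if (method == "components") {
    igraph::components(g)$membership
  } else {
    igraph::membership(igraph::cluster_fast_greedy(g))
  }
  ## renumber deterministically: by size desc, then smallest gene id
  split_genes <- split(names(member), member)
  sizes <- lengths(split_genes)
  mins <- vapply(split_genes, min, character(1))
  ord <- order(-sizes, mins)
  new_id <- setNames(seq_along(ord), names(split_genes)[ord])
  network$modules <- setNames(as.integer(new_id[as.character(member)]),
                              names(member))
  network
}

#' Summarize a co-presence network
#'
#' @param network A `"copresence_network"` with modules assigned.
#' @return List with `n_modules`, `n_nodes`, `n_edges`,
#'   `largest_module_nodes`, `largest_module_edges`, `module_sizes`
#'   (named integer vector) and `top_categories` (up to 5 most frequent
#'   node categories, when annotated).
#' @export
summarize_network <- function(network) {
  stopifnot(inherits(network, "copresence_network"))
  if (is.null(network$modules))
    network <- detect_modules(network)
  mods <- network$modules
  n_modules <- length(unique(mods))
  largest_nodes <- 0L; largest_edges <- 0L
  module_sizes <- integer(0)
  if (n_modules > 0) {
    module_sizes <- table(mods)
    largest <- names(mods)[mods == 1L]
    largest_nodes <- length(largest)
    e <- network$edges
    largest_edges <- sum(e$from %in% largest & e$to %in% largest)
  }
  top <- character(0)
  if (!all(is.na(network$nodes$category))) {
    tab <- sort(table(network$nodes$category), decreasing = TRUE)
    top <- names(head(tab, 5))
  }
  list(n_modules = n_modules,
       n_nodes = nrow(network$nodes),
       n_edges = nrow(network$edges),
       largest_module_nodes = largest_nodes,
       largest_module_edges = largest_edges,
       module_sizes = as.integer(module_sizes),
       top_categories = top)
}

#' Gene overlap between the largest modules of two networks
#'
#' Reports the shared genes of the two largest modules as a percentage of
#' the smaller module.
#'
#' @param net_a,net_b Networks with modules assigned.
#' @return List with `n_shared`, `size_a`, `size_b`,
#'   `percentage_of_smaller`.
#' @export
module_overlap <- function(net_a, net_b) {
  for (nm in c("a", "b")) {
    net <- if (nm == "a") net_a else net_b
    if (is.null(net$modules)) stop("modules not assigned; run detect_modules()",
                                   call. = FALSE)
  }
  ga <- names(net_a$modules)[net_a$modules == 1L]
  gb <- names(net_b$modules)[net_b$modules == 1L]
  shared <- length(intersect(ga, gb))
  smaller <- min(length(ga), length(gb))
  list(n_shared = shared, size_a = length(ga), size_b = length(gb),
       percentage_of_smaller = if (smaller > 0) round(100 * shared / smaller, 1)
                               else NA_real_)
}

#' Write a network as edge-list and node TSV files
#'
#' @param network A `"copresence_network"` with modules assigned.
#' @param prefix File-path prefix; writes `<prefix>_edges.tsv` and
#'   `<prefix>_nodes.tsv`.
#' @return Invisibly, the files written.
#' @export
write_network <- function(network, prefix) {
  if (is.null(network$modules)) network <- detect_modules(network)
  e <- network$edges
  e$module <- network$modules[e$from]
  nd <- network$nodes
  nd$module <- unname(network$modules[nd$gene_id])
  files <- c(write_table_tsv(e, paste0(prefix, "_edges.tsv")),
             write_table_tsv(nd, paste0(prefix, "_nodes.tsv")))
  invisible(files)
}
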