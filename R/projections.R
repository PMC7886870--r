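#' Metabolite-centric projection of a metabolic model
#'
#' One of the two projections of the bipartite graph represented by the
#' stoichiometric matrix: nodes are metabolites, and two metabolites are
#' adjacent iff they co-occur in the stoichiometry of at least one
#' reaction.  Coefficient sign and magnitude are ignored; the method is
#' topological.
#'
#' @param model a [metabolic_model].
#' @return An undirected simple [igraph::igraph] whose vertices carry a
#'   `type = "metabolite"` attribute.
#' @export
metabolite_graph <- function(model) {
  edges <- lapply(model$reactions, function(r) {
    ids <- sort(unique(names(r$stoichiometry)))
    if (length(ids) < 2L) return(NULL)
    t(utils::combn(ids, 2L))
  })
  build_graph(model$metabolites$id, do.call(rbind, edges), "metabolite")
}

#' Identify currency metabolites by degree percentile
#'
#' High-degree hub metabolites (H2O, ATP, cofactors) connect most of the
#' network and obscure pathway structure; they are trimmed before the
#' reaction-centric graph is recomputed.  The fraction removed is a scan
#' parameter: typical analyses retain 90 to 98 percent of metabolites,
#' i.e. remove the top 2 to 10 percent by degree.
#'
#' Exactly `ceiling(pct/100 * n)` metabolites are removed.  Ranking is by
#' descending degree with ties at the boundary broken by ascending
#' lexicographic id, so scans are deterministic and currency sets are
#' nested across percentages.
#'
#' @param mgraph metabolite-centric graph from [metabolite_graph()].
#' @param pct percentage of metabolites to remove, in \[0, 100\].
#' @param model optional [metabolic_model]; required for `degree = "bipartite"`.
#' @param degree `"projection"` ranks by degree in the metabolite-centric
#'   graph (distinct co-occurring metabolites, the default); `"bipartite"`
#'   ranks by the number of reactions a metabolite participates in.
#' @return An object of class `currency_set` with fields `removed`
#'   (metabolite ids), `pct_removed` and `degree_cutoff` (degree of the
#'   lowest-degree removed metabolite, NA when none removed).
#' @export
currency_metabolites <- function(mgraph, pct, model = NULL,
                                 degree = c("projection", "bipartite")) {
  degree <- match.arg(degree)
  if (!is.numeric(pct) || length(pct) != 1L || is.na(pct) || pct < 0 || pct > 100)
    stop("pct must be a percentage in [0, 100]", call. = FALSE)
  ids <- igraph::V(mgraph)$name
  deg <- if (degree == "projection") {
    igraph::degree(mgraph)
  } else {
    if (is.null(model)) stop("degree = 'bipartite' requires the model", call. = FALSE)
    vapply(ids, function(m) {
      sum(vapply(model$reactions, function(r) m %in% names(r$stoichiometry), logical(1)))
    }, numeric(1))
  }
  n <- length(ids)
  k <- ceiling(pct / 100 * n)
  ord <- order(-deg, ids)
  removed <- if (k > 0L) ids[ord[seq_len(k)]] else character(0)
  structure(
    list(removed = removed,
         pct_removed = pct,
         degree_cutoff = if (k > 0L) as.integer(min(deg[match(removed, ids)])) else NA_integer_),
    class = "currency_set")
}

#' @export
print.currency_set <- function(x, ...) {
  cat(sprintf("Currency set: %d metabolite(s) removed (%.3g%%), degree cutoff %s\n",
              length(x$removed), x$pct_removed,
              ifelse(is.na(x$degree_cutoff), "-", x$degree_cutoff)))
  invisible(x)
}

#' Reaction-centric projection after currency-metabolite removal
#'
#' Nodes are reactions; two reactions are adjacent iff they share at least
#' one metabolite that is not in the removed currency set.
#'
#' @param model a [metabolic_model].
#' @param removed a `currency_set` from [currency_metabolites()], a
#'   character vector of metabolite ids, or NULL for no removal.
#' @return An undirected simple igraph with `type = "reaction"` vertices.
#' @export
reaction_graph <- function(model, removed = NULL) {
  if (inherits(removed, "currency_set")) removed <- removed$removed
  removed <- removed %||% character(0)
  unknown <- setdiff(removed, model$metabolites$id)
  if (length(unknown))
    stop("removed set contains unknown metabolites: ", toString(unknown), call. = FALSE)
  rids <- names(model$reactions)
  # invert: metabolite -> reactions containing it, then clique per metabolite
  met2rxn <- list()
  for (r in model$reactions) {
    for (m in setdiff(names(r$stoichiometry), removed))
      met2rxn[[m]] <- c(met2rxn[[m]], r$id)
  }
  edges <- lapply(met2rxn, function(rs) {
    rs <- sort(unique(rs))
    if (length(rs) < 2L) return(NULL)
    t(utils::combn(rs, 2L))
  })
  build_graph(rids, do.call(rbind, unname(edges)), "reaction")
}

#' Gene-centric metabolic network
#'
#' Evaluates the gene-reaction associations on a reaction-centric graph:
#' nodes are all genes annotated to any reaction of the model; two genes
#' are adjacent iff (a) they annotate the same reaction, or (b) they
#' annotate reactions adjacent in the reaction graph.  Rule (a) can be
#' disabled; genes of one reaction are maximally metabolically coupled, so
#' it is on by default.
#'
#' @param model a [metabolic_model].
#' @param rgraph reaction-centric graph built from the same model.
#' @param same_reaction include rule (a) same-reaction gene pairs (default TRUE).
#' @return An undirected simple igraph with `type = "gene"` vertices.
#' @export
gene_graph <- function(model, rgraph, same_reaction = TRUE) {
  assoc <- lapply(model$reactions, `[[`, "genes")
  genes <- sort(unique(unlist(assoc, use.names = FALSE)))
  if (!length(genes))
    stop("no gene-centric network derivable: model has no gene associations", call. = FALSE)
  edges <- list()
  if (same_reaction) {
    edges <- lapply(assoc, function(g) {
      g <- sort(unique(g))
      if (length(g) < 2L) return(NULL)
      t(utils::combn(g, 2L))
    })
  }
  el <- igraph::as_edgelist(rgraph)
  cross <- lapply(seq_len(nrow(el)), function(i) {
    g1 <- assoc[[el[i, 1L]]]
    g2 <- assoc[[el[i, 2L]]]
    if (!length(g1) || !length(g2)) return(NULL)
    as.matrix(expand.grid(g1, g2, stringsAsFactors = FALSE))
  })
  build_graph(genes, do.call(rbind, c(unname(edges), cross)), "gene")
}

# Assemble an undirected simple igraph from a node id vector and an edge
# matrix (2 columns, may be NULL); drops self-loops and duplicates.
build_graph <- function(nodes, edge_mat, type) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (!is.null(edge_mat) && nrow(edge_mat)) {
    keep <- edge_mat[, 1L] != edge_mat[, 2L]
    edge_mat <- edge_mat[keep, , drop = FALSE]
    if (nrow(edge_mat))
      g <- igraph::add_edges(g, t(matrix(match(edge_mat, nodes), ncol = 2L)))
  }
  g <- igraph::simplify(g)
  igraph::V(g)$type <- type
  igraph::V(g)$degree <- igraph::degree(g)
  g
}

#' Export a graph as a two-column TSV edge list
#' @param graph an igraph.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  utils::write.table(data.frame(from = el[, 1L], to = el[, 2L]),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a graph as GraphML
#' @param graph an igraph (node attributes `type` and `degree` are carried).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}
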