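# Shared fixtures and independent brute-force oracles.  The oracles never
# call the projection/clustering code they check: they enumerate pairs and
# triangles directly from the model / edge list.

# 2-reaction toy: R1: A + ATP -> B + ADP {G1};  R2: B -> C {G2, G3}
toy_model <- function() {
  metabolic_model(
    data.frame(id = c("A", "ATP", "B", "ADP", "C"), stringsAsFactors = FALSE),
    list(R1 = list(id = "R1", stoichiometry = c(A = -1, ATP = -1, B = 1, ADP = 1),
                   reversible = FALSE, genes = "G1"),
         R2 = list(id = "R2", stoichiometry = c(B = -1, C = 1),
                   reversible = FALSE, genes = c("G2", "G3"))))
}

# canonical sorted "a|b" edge keys of an igraph
edge_keys <- function(g) {
  el <- igraph::as_edgelist(g)
  if (!nrow(el)) return(character(0))
  sort(apply(el, 1, function(r) paste(sort(r), collapse = "|")))
}

pair_keys <- function(mat) {
  if (is.null(mat) || !nrow(mat)) return(character(0))
  sort(unique(apply(mat, 1, function(r) paste(sort(r), collapse = "|"))))
}

# nested-loop projection constructions
oracle_metabolite_edges <- function(model) {
  out <- NULL
  for (r in model$reactions) {
    ids <- unique(names(r$stoichiometry))
    for (i in seq_along(ids)) for (j in seq_along(ids))
      if (i < j) out <- rbind(out, c(ids[i], ids[j]))
  }
  pair_keys(out)
}

oracle_reaction_edges <- function(model, removed) {
  rids <- names(model$reactions)
  out <- NULL
  for (i in seq_along(rids)) for (j in seq_along(rids)) {
    if (i >= j) next
    mi <- setdiff(names(model$reactions[[i]]$stoichiometry), removed)
    mj <- setdiff(names(model$reactions[[j]]$stoichiometry), removed)
    if (length(intersect(mi, mj))) out <- rbind(out, c(rids[i], rids[j]))
  }
  pair_keys(out)
}

oracle_gene_edges <- function(model, removed) {
  rids <- names(model$reactions)
  out <- NULL
  for (r in model$reactions) {
    g <- unique(r$genes)
    for (i in seq_along(g)) for (j in seq_along(g))
      if (i < j) out <- rbind(out, c(g[i], g[j]))
  }
  for (i in seq_along(rids)) for (j in seq_along(rids)) {
    if (i >= j) next
    mi <- setdiff(names(model$reactions[[i]]$stoichiometry), removed)
    mj <- setdiff(names(model$reactions[[j]]$stoichiometry), removed)
    if (!length(intersect(mi, mj))) next
    for (a in model$reactions[[i]]$genes) for (b in model$reactions[[j]]$genes)
      if (a != b) out <- rbind(out, c(a, b))
  }
  pair_keys(out)
}

# triangle-enumeration clustering oracle on an induced node set
oracle_avg_clustering <- function(graph, members) {
  members <- intersect(members, igraph::V(graph)$name)
  if (!length(members)) return(0)
  keys <- edge_keys(igraph::induced_subgraph(graph, members))
  has_edge <- function(a, b) paste(sort(c(a, b)), collapse = "|") %in% keys
  local <- vapply(members, function(v) {
    nb <- setdiff(members[vapply(members, function(u) u != v && has_edge(u, v), logical(1))], v)
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      if (has_edge(nb[i], nb[j])) tri <- tri + 1
    tri / (k * (k - 1) / 2)
  }, numeric(1))
  mean(local)
}

random_named_gnp <- function(n, p, seed) {
  g <- with_test_seed(seed, igraph::sample_gnp(n, p))
  igraph::V(g)$name <- sprintf("N%04d", seq_len(n))
  g
}

with_test_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# vectorized permutation null for the two-group log-rank statistic;
# independent of survival::survdiff
perm_logrank_p <- function(times, events, grp, B = 10000, seed = 1) {
  ut <- sort(unique(times[events == 1]))
  R <- outer(ut, times, function(t, x) as.numeric(x >= t))
  E <- outer(ut, times, function(t, x) as.numeric(x == t)) * rep(events, each = length(ut))
  ni <- rowSums(R); di <- rowSums(E)
  chi2_of <- function(G) {
    O <- E %*% G; N1 <- R %*% G
    oe <- colSums(O - di * N1 / ni)
    v <- colSums(di * (ni - di) / pmax(ni - 1, 1) * N1 * (ni - N1) / ni^2)
    ifelse(v > 0, oe^2 / v, 0)
  }
  obs <- chi2_of(matrix(grp, ncol = 1))
  perm <- with_test_seed(seed, sapply(seq_len(B), function(b) sample(grp)))
  mean(chi2_of(perm) >= obs - 1e-12)
}

small_random_model <- function(seed) {
  with_test_seed(seed, {
    n_rxn <- sample(5:30, 1)
    simulate_model(n_metabolites = 20, n_reactions = n_rxn, n_genes = 15,
                   n_currency = 2, reaction_size = c(2, 2),
                   currency_prob = 0.4, genes_per_reaction = c(1, 3),
                   seed = seed + 5000)
  })
}

# gene network used by several coherence tests: default model, hub tier removed
default_gene_network <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- simulate_model(seed = 42)
      cur <- currency_metabolites(metabolite_graph(m), 3)
      cache <<- gene_graph(m, reaction_graph(m, cur))
    }
    cache
  }
})
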