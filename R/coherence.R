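#' Select differentially expressed genes by threshold
#'
#' Keeps genes with `|log2fc| > log2fc_min` and p below `p_max`, both
#' strict inequalities, so a fold-change of exactly 2 is excluded at the
#' `|FC| > 2` (log2fc_min = 1) threshold.  With `p_mode = "adjusted"`,
#' records with missing adjusted p are excluded.
#'
#' @param table a `de_table`.
#' @param log2fc_min non-negative log2 fold-change threshold.
#' @param p_max p-value threshold in \[0,1\].
#' @param p_mode `"raw"` filters on the raw p-value, `"adjusted"` on padj.
#' @return An object of class `gene_set`: fields `genes`, `log2fc_min`,
#'   `p_max`, `p_mode`.
#' @export
select_genes <- function(table, log2fc_min = 1, p_max = 0.05,
                         p_mode = c("raw", "adjusted")) {
  p_mode <- match.arg(p_mode)
  stopifnot(is.numeric(log2fc_min), log2fc_min >= 0, p_max >= 0, p_max <= 1)
  p <- if (p_mode == "raw") table$pvalue else table$padj
  keep <- abs(table$log2fc) > log2fc_min & !is.na(p) & p < p_max
  structure(list(genes = table$gene[keep],
                 log2fc_min = log2fc_min, p_max = p_max, p_mode = p_mode),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("Gene set: %d gene(s) (|log2FC| > %g, %s p < %g)\n",
              length(x$genes), x$log2fc_min, x$p_mode, x$p_max))
  invisible(x)
}

#' Average clustering coefficient of a spanned subgraph
#'
#' Induces the subgraph on `members` intersected with the network nodes and
#' returns the mean local clustering coefficient: for each node, the
#' fraction of its neighbour pairs that are themselves adjacent, with 0 for
#' nodes of degree below 2.  Returns c = 0 when the induced graph is empty.
#'
#' @param network an undirected simple igraph.
#' @param members node ids (character) or a `gene_set`.
#' @return List with `c` (mean local clustering in \[0,1\]) and `n_mapped`
#'   (members found in the network).
#' @export
avg_clustering <- function(network, members) {
  if (inherits(members, "gene_set")) members <- members$genes
  mapped <- intersect(unique(members), igraph::V(network)$name)
  if (!length(mapped)) return(list(c = 0, n_mapped = 0L))
  sub <- igraph::induced_subgraph(network, mapped)
  A <- igraph::as_adjacency_matrix(sub, sparse = FALSE)
  list(c = mean_local_clustering(A), n_mapped = length(mapped))
}

# Mean local clustering from a dense 0/1 adjacency matrix.
# diag(A^3)[i] counts twice the triangles through i.
mean_local_clustering <- function(A) {
  k <- .rowSums(A, nrow(A), ncol(A))
  closed <- .rowSums((A %*% A) * A, nrow(A), ncol(A))  # = diag(A %*% A %*% A)
  denom <- k * (k - 1)
  mean(ifelse(denom > 0, closed / denom, 0))
}

#' Metabolic network coherence (MC) of a gene set
#'
#' The coherence of a gene set S on a gene-centric metabolic network G is
#' the z-score of the average clustering coefficient C of the subgraph of G
#' spanned by S, computed against a null model of random gene sets of the
#' same size drawn uniformly without replacement from the network nodes.
#' MC says how many standard deviations away from randomness the observed
#' clustering is.
#'
#' The null standard deviation uses the sample (n-1) estimator.  When the
#' null is degenerate (sd = 0, e.g. S covers the whole network) or fewer
#' than 3 set genes map onto the network, MC is reported as 0 with the
#' `degenerate` flag set rather than NaN, keeping scan grids rectangular.
#'
#' @param network gene-centric igraph from [gene_graph()].
#' @param genes a `gene_set` or character vector of gene symbols.
#' @param n_random number of null draws (default 1000, stabilising the null
#'   sd estimate to roughly 2 percent).
#' @param seed RNG seed; the same seed reproduces the result bit-for-bit.
#' @param null `"all"` draws null sets from all network nodes (default);
#'   `"measured"` restricts the pool to `measured` genes present in the
#'   network, for sensitivity analysis.
#' @param measured character vector of measured genes (required for
#'   `null = "measured"`).
#' @return Object of class `coherence`: `c_obs`, `n_mapped`, `n_unmapped`,
#'   `null_mean`, `null_sd`, `mc`, `n_random`, `seed`, `degenerate`.
#' @export
coherence_z <- function(network, genes, n_random = 1000, seed = 1234,
                        null = c("all", "measured"), measured = NULL) {
  null <- match.arg(null)
  if (inherits(genes, "gene_set")) genes <- genes$genes
  stopifnot(n_random >= 2)
  nodes <- igraph::V(network)$name
  mapped <- intersect(unique(genes), nodes)
  n_mapped <- length(mapped)
  if (n_mapped == 0L)
    stop("gene set disjoint from network", call. = FALSE)
  pool <- if (null == "all") nodes else {
    if (is.null(measured)) stop("null = 'measured' requires 'measured'", call. = FALSE)
    intersect(unique(measured), nodes)
  }
  if (length(pool) < n_mapped)
    stop("null pool smaller than the mapped gene set", call. = FALSE)
  A <- igraph::as_adjacency_matrix(network, sparse = FALSE)
  idx_obs <- match(mapped, nodes)
  c_obs <- mean_local_clustering(A[idx_obs, idx_obs, drop = FALSE])
  pool_idx <- match(pool, nodes)
  null_c <- with_seed(seed, {
    vapply(seq_len(n_random), function(i) {
      s <- pool_idx[sample.int(length(pool_idx), n_mapped)]
      mean_local_clustering(A[s, s, drop = FALSE])
    }, numeric(1))
  })
  null_mean <- mean(null_c)
  null_sd <- stats::sd(null_c)
  degenerate <- (null_sd == 0) || (n_mapped < 3L)
  structure(
    list(c_obs = c_obs, n_mapped = n_mapped,
         n_unmapped = length(unique(genes)) - n_mapped,
         null_mean = null_mean, null_sd = null_sd,
         mc = if (degenerate) 0 else (c_obs - null_mean) / null_sd,
         n_random = as.integer(n_random), seed = as.integer(seed),
         degenerate = degenerate),
    class = "coherence")
}

#' @export
print.coherence <- function(x, ...) {
  cat("Metabolic network coherence\n")
  cat(sprintf("  genes mapped: %d (%d unmapped)\n", x$n_mapped, x$n_unmapped))
  cat(sprintf("  observed C:   %.4f\n", x$c_obs))
  cat(sprintf("  null C:       %.4f (sd %.4f, %d draws, seed %d)\n",
              x$null_mean, x$null_sd, x$n_random, x$seed))
  cat(sprintf("  MC (z-score): %.4f%s\n", x$mc,
              if (x$degenerate) "  [degenerate null]" else ""))
  invisible(x)
}

#' Coherence scan over fold-change thresholds and currency percentages
#'
#' For every combination of currency-removal percentage and log2
#' fold-change threshold, rebuilds the currency set, reaction graph and
#' gene graph, selects the gene set and computes its coherence.  Each cell
#' uses a seed derived from the base seed XOR the cell index, so any cell
#' can be reproduced by a standalone [coherence_z()] call.
#'
#' @param model a [metabolic_model].
#' @param table a `de_table`.
#' @param fc_thresholds ascending log2 |FC| cutoffs.
#' @param currency_pcts ascending currency-removal percentages.
#' @param n_random,seed,p_max,p_mode passed to gene selection and scoring.
#' @return Object of class `coherence_scan`: `mc` and `c_obs` matrices
#'   (rows = thresholds, cols = percentages), `cells` (per-cell `coherence`
#'   or NULL when no gene mapped), `cell_seeds`, `argmax` (indices of the
#'   maximal non-degenerate MC) and the axes.
#' @export
coherence_scan <- function(model, table, fc_thresholds = c(1, 2, 3),
                           currency_pcts = c(2, 5, 10), n_random = 1000,
                           seed = 1234, p_max = 0.05,
                           p_mode = c("raw", "adjusted")) {
  p_mode <- match.arg(p_mode)
  stopifnot(length(fc_thresholds) > 0, length(currency_pcts) > 0)
  nt <- length(fc_thresholds); np <- length(currency_pcts)
  mc <- c_obs <- matrix(NA_real_, nt, np,
                        dimnames = list(fc_thresholds, currency_pcts))
  cells <- vector("list", nt * np)
  dim(cells) <- c(nt, np)
  cell_seeds <- matrix(NA_integer_, nt, np)
  mgraph <- metabolite_graph(model)
  for (pj in seq_len(np)) {
    cur <- currency_metabolites(mgraph, currency_pcts[pj])
    rg <- reaction_graph(model, cur)
    gg <- gene_graph(model, rg)
    for (ti in seq_len(nt)) {
      cell_seed <- bitwXor(as.integer(seed), (pj - 1L) * nt + ti)
      cell_seeds[ti, pj] <- cell_seed
      gs <- select_genes(table, fc_thresholds[ti], p_max, p_mode)
      res <- if (length(intersect(gs$genes, igraph::V(gg)$name)) == 0L) {
        NULL  # empty mapped set: degenerate cell, not fatal
      } else {
        coherence_z(gg, gs, n_random = n_random, seed = cell_seed)
      }
      cells[ti, pj] <- list(res)
      mc[ti, pj] <- if (is.null(res)) 0 else res$mc
      c_obs[ti, pj] <- if (is.null(res)) 0 else res$c_obs
    }
  }
  ok <- !vapply(cells, function(r) is.null(r) || r$degenerate, logical(1))
  dim(ok) <- dim(mc)
  argmax <- if (any(ok)) {
    cand <- which(ok & mc == max(mc[ok]), arr.ind = TRUE)
    cand[1L, , drop = TRUE]
  } else NULL
  structure(list(mc = mc, c_obs = c_obs, cells = cells,
                 cell_seeds = cell_seeds, argmax = argmax,
                 fc_thresholds = fc_thresholds, currency_pcts = currency_pcts,
                 n_random = as.integer(n_random), seed = as.integer(seed),
                 p_max = p_max, p_mode = p_mode),
            class = "coherence_scan")
}

#' @export
print.coherence_scan <- function(x, ...) {
  cat("Coherence scan (MC; rows = log2|FC| thresholds, cols = % currency removed)\n")
  print(round(x$mc, 4))
  if (!is.null(x$argmax))
    cat(sprintf("maximum MC = %.4f at log2|FC| > %g, %g%% removed\n",
                x$mc[x$argmax[1L], x$argmax[2L]],
                x$fc_thresholds[x$argmax[1L]], x$currency_pcts[x$argmax[2L]]))
  invisible(x)
}

#' @export
as.matrix.coherence_scan <- function(x, ...) x$mc

#' Heatmap of a coherence scan
#' @param x a `coherence_scan`.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.coherence_scan <- function(x, ...) {
  graphics::image(x = seq_along(x$fc_thresholds), y = seq_along(x$currency_pcts),
                  z = x$mc, xlab = "log2|FC| threshold",
                  ylab = "% currency metabolites removed", axes = FALSE,
                  col = grDevices::hcl.colors(64, "RdBu", rev = TRUE),
                  main = "Metabolic network coherence", ...)
  graphics::axis(1, seq_along(x$fc_thresholds), x$fc_thresholds)
  graphics::axis(2, seq_along(x$currency_pcts), x$currency_pcts)
  graphics::box()
  invisible(x)
}

#' Write a coherence scan as TSV plus a JSON diagnostics sidecar
#'
#' The TSV holds the MC matrix (rows = fold-change thresholds, columns =
#' currency percentages); the JSON carries per-cell diagnostics (raw C,
#' null mean/sd, mapped counts, seed, degeneracy flag).
#'
#' @param scan a `coherence_scan`.
#' @param tsv_path,json_path output paths.
#' @return `tsv_path`, invisibly.
#' @export
write_scan <- function(scan, tsv_path, json_path = NULL) {
  tab <- data.frame(log2fc_threshold = scan$fc_thresholds,
                    round(scan$mc, 6), check.names = FALSE)
  names(tab)[-1L] <- paste0("pct_", scan$currency_pcts)
  utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path)) {
    cells <- list()
    for (ti in seq_along(scan$fc_thresholds)) {
      for (pj in seq_along(scan$currency_pcts)) {
        r <- scan$cells[[ti, pj]]
        cells[[length(cells) + 1L]] <- c(
          list(log2fc_threshold = scan$fc_thresholds[ti],
               currency_pct = scan$currency_pcts[pj],
               seed = scan$cell_seeds[ti, pj]),
          if (is.null(r)) list(degenerate = TRUE, n_mapped = 0, mc = 0)
          else r[c("c_obs", "n_mapped", "n_unmapped", "null_mean",
                   "null_sd", "mc", "degenerate")])
      }
    }
    jsonlite::write_json(list(n_random = scan$n_random, seed = scan$seed,
                              p_max = scan$p_max, p_mode = scan$p_mode,
                              cells = cells),
                         json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(tsv_path)
}

#' Extract the annotated subnetwork spanned by a gene set
#'
#' Induces the subgraph on the mapped set genes and annotates each node
#' with its regulation sign (up iff log2fc > 0) and each edge as
#' co-regulated (same endpoint signs) or inverse-regulated.
#'
#' @param network gene-centric igraph.
#' @param genes a `gene_set` or character vector.
#' @param table the `de_table` the genes were selected from.
#' @return Object of class `annotated_subnetwork` wrapping an igraph with
#'   vertex attribute `sign` in \{up, down\} and edge attribute `kind` in
#'   \{co, inverse\}.
#' @export
extract_subnetwork <- function(network, genes, table) {
  if (inherits(genes, "gene_set")) genes <- genes$genes
  mapped <- intersect(unique(genes), igraph::V(network)$name)
  missing_genes <- setdiff(mapped, table$gene)
  if (length(missing_genes))
    stop("cannot sign genes absent from the DE table: ",
         toString(missing_genes), call. = FALSE)
  sub <- igraph::induced_subgraph(network, mapped)
  lfc <- table$log2fc[match(igraph::V(sub)$name, table$gene)]
  igraph::V(sub)$sign <- ifelse(lfc > 0, "up", "down")
  el <- igraph::as_edgelist(sub)
  if (nrow(el)) {
    s <- igraph::V(sub)$sign
    names(s) <- igraph::V(sub)$name
    igraph::E(sub)$kind <- ifelse(s[el[, 1L]] == s[el[, 2L]], "co", "inverse")
  }
  structure(list(graph = sub), class = "annotated_subnetwork")
}

#' @export
print.annotated_subnetwork <- function(x, ...) {
  g <- x$graph
  cat(sprintf("Annotated subnetwork: %d gene(s) (%d up, %d down), %d edge(s)",
              igraph::vcount(g), sum(igraph::V(g)$sign == "up"),
              sum(igraph::V(g)$sign == "down"), igraph::ecount(g)))
  if (igraph::ecount(g))
    cat(sprintf(" (%d co-regulated, %d inverse)",
                sum(igraph::E(g)$kind == "co"), sum(igraph::E(g)$kind == "inverse")))
  cat("\n")
  invisible(x)
}

#' Write an annotated subnetwork as GraphML
#' @param x an `annotated_subnetwork`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_subnetwork <- function(x, path) {
  igraph::write_graph(x$graph, path, format = "graphml")
  invisible(path)
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
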