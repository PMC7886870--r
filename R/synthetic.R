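#' Simulate a genome-scale metabolic model with currency-metabolite hubs
#'
#' Emulates the structure the projection pipeline expects from a real
#' genome-scale model: a bipartite metabolite-reaction graph in which a few
#' designated hub metabolites (the synthetic analogue of H2O, ATP and other
#' cofactors) participate in a large fraction of reactions, while the
#' remaining metabolites are drawn uniformly.  Stoichiometric coefficients
#' are +/-1 (topology is all that matters downstream) and genes are
#' assigned uniformly to reactions.
#'
#' @param n_metabolites,n_reactions,n_genes sizes (defaults 200/300/250).
#' @param n_currency number of designated hub metabolites (default 6);
#'   hubs are the first `n_currency` metabolite ids.
#' @param reaction_size integer range (min, max) of non-hub metabolites per
#'   reaction; min must be >= 2.  The default (2, 2) gives each reaction a
#'   substrate/product backbone pair plus its cofactor hubs, about four
#'   participants on average, matching curated genome-scale models.
#' @param currency_prob probability that a reaction includes each hub
#'   independently (default 0.3).
#' @param genes_per_reaction integer range (min, max) of genes per reaction.
#' @param seed RNG seed; the generator is a pure function of its arguments.
#' @return A validated [metabolic_model]; attribute `hubs` holds the hub
#'   metabolite ids.
#' @export
simulate_model <- function(n_metabolites = 200, n_reactions = 300,
                           n_genes = 250, n_currency = 6,
                           reaction_size = c(2, 2), currency_prob = 0.3,
                           genes_per_reaction = c(1, 3), seed = 42) {
  stopifnot(n_currency < n_metabolites, reaction_size[1] >= 2,
            currency_prob >= 0, currency_prob <= 1)
  if (reaction_size[2] > n_metabolites - n_currency)
    stop("reaction_size max exceeds the number of non-hub metabolites", call. = FALSE)
  met_ids <- sprintf("M%04d", seq_len(n_metabolites))
  hubs <- met_ids[seq_len(n_currency)]
  non_hubs <- setdiff(met_ids, hubs)
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  rxns <- with_seed(seed, {
    lapply(seq_len(n_reactions), function(i) {
      k <- sample(reaction_size[1]:reaction_size[2], 1L)
      mets <- sample(non_hubs, k)
      if (n_currency > 0) {
        inc <- stats::runif(n_currency) < currency_prob
        mets <- c(mets, hubs[inc])
      }
      coeff <- stats::setNames(sample(c(-1, 1), length(mets), replace = TRUE), mets)
      coeff[1L] <- -1  # at least one substrate
      ng <- sample(genes_per_reaction[1]:genes_per_reaction[2], 1L)
      list(id = sprintf("R%04d", i),
           stoichiometry = coeff,
           reversible = stats::runif(1) < 0.3,
           genes = sort(sample(gene_ids, ng)))
    })
  })
  names(rxns) <- vapply(rxns, `[[`, character(1), "id")
  model <- metabolic_model(
    data.frame(id = met_ids,
               name = ifelse(met_ids %in% hubs, "currency hub", "metabolite"),
               compartment = "c", stringsAsFactors = FALSE),
    rxns)
  attr(model, "hubs") <- hubs
  model
}

#' Simulate a differential-expression table with a planted coherent cluster
#'
#' Plants a connected, network-adjacent cluster of regulated genes: the
#' cluster is grown breadth-first from a random seed gene inside a
#' component of sufficient size, guaranteeing the connected, high-clustering
#' target the coherence statistic is designed to detect.  Planted genes get
#' `log2fc ~ sign * Normal(effect, 0.5)` with a random sign per gene and
#' `p ~ Uniform(0, p_planted)`; background genes get
#' `log2fc ~ Normal(0, noise_sd)` and `p ~ Uniform(0, 1)`.  Adjusted
#' p-values are Benjamini-Hochberg.
#'
#' @param network gene-centric igraph (the table covers its nodes).
#' @param cluster_size planted gene count (default 12, >= 3).
#' @param effect mean |log2fc| of planted genes (default 4).
#' @param noise_sd background log2fc standard deviation (default 0.5).
#' @param p_planted p-value cap for planted genes (default 0.01).
#' @param seed RNG seed.
#' @return A `de_table` over all network genes; attribute `planted` holds
#'   the planted gene ids.
#' @export
simulate_de <- function(network, cluster_size = 12, effect = 4,
                        noise_sd = 0.5, p_planted = 0.01, seed = 42) {
  stopifnot(cluster_size >= 3, effect >= 0, noise_sd > 0)
  comp <- igraph::components(network)
  big <- which(comp$csize >= cluster_size)
  if (!length(big))
    stop("no connected component with at least ", cluster_size, " genes", call. = FALSE)
  genes <- igraph::V(network)$name
  with_seed(seed, {
    comp_id <- if (length(big) == 1L) big else sample(big, 1L)
    pool <- genes[comp$membership == comp_id]
    root <- sample(pool, 1L)
    bfs_order <- igraph::bfs(network, root = root, unreachable = FALSE)$order
    planted <- igraph::V(network)$name[stats::na.omit(as.integer(bfs_order))][seq_len(cluster_size)]
    is_planted <- genes %in% planted
    sign_p <- sample(c(-1, 1), sum(is_planted), replace = TRUE)
    lfc <- stats::rnorm(length(genes), 0, noise_sd)
    lfc[is_planted] <- sign_p * stats::rnorm(sum(is_planted), effect, 0.5)
    p <- stats::runif(length(genes))
    p[is_planted] <- stats::runif(sum(is_planted), 0, p_planted)
    tab <- de_table(genes, lfc, p, stats::p.adjust(p, "BH"))
    attr(tab, "planted") <- planted
    tab
  })
}

#' Simulate a survival cohort with a ratio-dependent hazard
#'
#' Emulates a TCGA-style cohort: per-gene log-normal RSEM expression,
#' exponential latent death times whose rate decreases with the
#' standardized log expression ratio of two genes (high ratio = better
#' prognosis), and independent exponential censoring.  Observed time is the
#' minimum of death and censoring, rounded to 0.1 months with a floor of
#' 0.1; the event flag is 1 when death came first.  A +1 pseudocount keeps
#' the latent log-ratio defined at zero expression; the analysis path never
#' uses pseudocounts and keeps the exclusion/infinity conventions instead.
#'
#' @param n_patients cohort size (default 300, >= 20).
#' @param expr_meanlog named per-gene meanlog of the log-normal expression.
#' @param expr_sdlog per-gene sdlog (scalar recycled, default 1.5).
#' @param beta log-hazard coefficient on the standardized log ratio
#'   (default 1; 0 = no signal).
#' @param base_hazard baseline death rate in events/month (default 0.02).
#' @param censor_hazard censoring rate in censorings/month (default 0.01).
#' @param ratio_genes numerator and denominator genes of the latent ratio
#'   (default GCK over HK2).
#' @param seed RNG seed.
#' @return A `cohort`; attribute `truth` records beta and the ratio genes.
#' @export
simulate_cohort <- function(n_patients = 300,
                            expr_meanlog = c(GCK = 1.5, HK2 = 5, HK1 = 4, HK3 = 2),
                            expr_sdlog = 1.5, beta = 1, base_hazard = 0.02,
                            censor_hazard = 0.01,
                            ratio_genes = c("GCK", "HK2"), seed = 42) {
  stopifnot(n_patients >= 20, base_hazard > 0, censor_hazard > 0,
            all(ratio_genes %in% names(expr_meanlog)))
  genes <- names(expr_meanlog)
  sdlog <- rep_len(expr_sdlog, length(genes))
  with_seed(seed, {
    expr <- sapply(seq_along(genes), function(i)
      stats::rlnorm(n_patients, expr_meanlog[i], sdlog[i]))
    colnames(expr) <- genes
    z <- log((expr[, ratio_genes[1]] + 1) / (expr[, ratio_genes[2]] + 1))
    z <- as.numeric(scale(z))
    death <- stats::rexp(n_patients, rate = base_hazard * exp(-beta * z))
    cens <- stats::rexp(n_patients, rate = censor_hazard)
    os <- pmax(round(pmin(death, cens), 1), 0.1)
    d <- data.frame(sample_id = sprintf("P%04d", seq_len(n_patients)),
                    os_months = os,
                    event = as.integer(death <= cens),
                    stringsAsFactors = FALSE)
    d <- cbind(d, as.data.frame(expr))
    out <- cohort(d)
    attr(out, "truth") <- list(beta = beta, ratio_genes = ratio_genes,
                               base_hazard = base_hazard,
                               censor_hazard = censor_hazard)
    out
  })
}
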