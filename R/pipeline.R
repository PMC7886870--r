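#' Run the coherence analysis end to end and write result files
#'
#' Loads a model and a differential-expression table, runs the coherence
#' scan, extracts the annotated subnetwork at the grid maximum, and writes
#' `scan.tsv`, `scan.json`, `subnetwork.graphml` and `provenance.json` to
#' `out_dir`.  Outputs are byte-identical across runs with the same inputs
#' and configuration.
#'
#' @param model_path model JSON (or SBML when `sbml = TRUE`).
#' @param de_path differential-expression TSV.
#' @param out_dir output directory (created if needed).
#' @param fc_thresholds,currency_pcts,n_random,seed,p_max,p_mode scan
#'   parameters, see [coherence_scan()].
#' @param sbml read the model as SBML instead of JSON.
#' @return The `coherence_scan`, invisibly.
#' @export
run_coherence <- function(model_path, de_path, out_dir,
                          fc_thresholds = c(1, 2, 3),
                          currency_pcts = c(2, 5, 10),
                          n_random = 1000, seed = 1234, p_max = 0.05,
                          p_mode = "raw", sbml = FALSE) {
  model <- if (sbml) read_model_sbml(model_path) else read_model_json(model_path)
  de <- read_de_table(de_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scan <- coherence_scan(model, de, fc_thresholds, currency_pcts,
                         n_random, seed, p_max, p_mode)
  write_scan(scan, file.path(out_dir, "scan.tsv"), file.path(out_dir, "scan.json"))
  if (!is.null(scan$argmax)) {
    ti <- scan$argmax[1L]; pj <- scan$argmax[2L]
    mgraph <- metabolite_graph(model)
    cur <- currency_metabolites(mgraph, currency_pcts[pj])
    gg <- gene_graph(model, reaction_graph(model, cur))
    gs <- select_genes(de, fc_thresholds[ti], p_max, p_mode)
    write_subnetwork(extract_subnetwork(gg, gs, de),
                     file.path(out_dir, "subnetwork.graphml"))
  }
  write_provenance(out_dir,
                   config = list(command = "coherence",
                                 fc_thresholds = fc_thresholds,
                                 currency_pcts = currency_pcts,
                                 n_random = n_random, seed = seed,
                                 p_max = p_max, p_mode = p_mode),
                   inputs = c(model = model_path, de_table = de_path))
  invisible(scan)
}

#' Run the survival stratification analysis and write result files
#'
#' For each requested marker (a gene symbol or a `NUM/DEN` expression
#' ratio), runs the optimal-cutoff stratification and writes
#' `<name>_stratification.json`, `<name>_km.tsv` and `<name>_groups.tsv`.
#' Spearman rank correlations between each marker and overall survival on
#' the uncensored subset are written to `correlations.json`.  Dropped and
#' excluded patients are always reported.
#'
#' @param cohort_path cohort TSV.
#' @param markers character vector, e.g. `c("HK2", "GCK", "GCK/HK2")`.
#' @param out_dir output directory.
#' @param min_group_frac per-group minimum fraction, see
#'   [best_cutoff_stratify()].
#' @return Named list of `strat_result`s, invisibly.
#' @export
run_survival <- function(cohort_path, markers, out_dir, min_group_frac = 0.2) {
  stopifnot(length(markers) > 0)
  coh <- read_cohort(cohort_path)
  if (nrow(coh) == 0L) stop("cohort is empty after filtering", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  unc <- uncensored(coh)
  results <- list()
  correlations <- list()
  for (mk in markers) {
    mv <- parse_marker(coh, mk)
    res <- best_cutoff_stratify(coh, mv, min_group_frac)
    results[[mk]] <- res
    tag <- gsub("/", "_over_", mk)
    jsonlite::write_json(
      list(marker = res$marker_name, cutoff = res$cutoff,
           chi2 = res$chi2, p = res$p,
           n_high = length(res$high_group), n_low = length(res$low_group),
           median_high = res$median_high, median_low = res$median_low,
           delta_median = res$delta_median,
           n_cutoffs_scanned = res$n_cutoffs_scanned,
           excluded = res$excluded),
      file.path(out_dir, paste0(tag, "_stratification.json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
    write_km_curves(res, file.path(out_dir, paste0(tag, "_km.tsv")))
    utils::write.table(
      data.frame(sample_id = c(res$high_group, res$low_group),
                 group = rep(c("high", "low"),
                             c(length(res$high_group), length(res$low_group)))),
      file.path(out_dir, paste0(tag, "_groups.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(unc) >= 3L) {
      mvu <- parse_marker(unc, mk)
      ok <- is.finite(mvu$values)
      if (sum(ok) >= 3L && stats::var(mvu$values[ok]) > 0) {
        ct <- spearman_test(mvu$values[ok],
                            unc$os_months[match(names(mvu$values)[ok], unc$sample_id)])
        correlations[[mk]] <- list(marker = mk, rho = ct$rho, p = ct$p, n = ct$n)
      }
    }
  }
  jsonlite::write_json(unname(correlations),
                       file.path(out_dir, "correlations.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_provenance(out_dir,
                   config = list(command = "survival", markers = markers,
                                 min_group_frac = min_group_frac,
                                 n_dropped_os = attr(coh, "n_dropped")),
                   inputs = c(cohort = cohort_path))
  invisible(results)
}

parse_marker <- function(coh, mk) {
  if (grepl("/", mk, fixed = TRUE)) {
    parts <- strsplit(mk, "/", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("ratio marker must be NUM/DEN: ", mk, call. = FALSE)
    ratio_values(coh, parts[1], parts[2])
  } else {
    marker_values(coh, mk)
  }
}

#' Generate a complete synthetic study and write its files
#'
#' Writes `model.json`, `de_table.tsv`, `cohort.tsv`, a ground-truth
#' sidecar `truth.json` (planted genes, hub metabolites, true hazard
#' coefficient) and `provenance.json`.  Sub-generators use seeds derived
#' from `seed` (+0, +1, +2), so every file is reproducible from one value.
#'
#' @param out_dir output directory.
#' @param seed base RNG seed.
#' @param currency_pct removal percentage used to build the gene network
#'   the DE cluster is planted on (default 3, which strips exactly the
#'   generator's designated hub tier at the default model sizes).
#' @param model_args,de_args,cohort_args named lists of overrides for
#'   [simulate_model()], [simulate_de()] and [simulate_cohort()].
#' @return Paths of the written files, invisibly.
#' @export
run_simulate <- function(out_dir, seed = 42, currency_pct = 3,
                         model_args = list(), de_args = list(),
                         cohort_args = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  model <- do.call(simulate_model, c(model_args, list(seed = seed)))
  cur <- currency_metabolites(metabolite_graph(model), currency_pct)
  gg <- gene_graph(model, reaction_graph(model, cur))
  de <- do.call(simulate_de, c(de_args, list(network = gg, seed = seed + 1)))
  coh <- do.call(simulate_cohort, c(cohort_args, list(seed = seed + 2)))
  paths <- c(model = file.path(out_dir, "model.json"),
             de_table = file.path(out_dir, "de_table.tsv"),
             cohort = file.path(out_dir, "cohort.tsv"),
             truth = file.path(out_dir, "truth.json"))
  write_model_json(model, paths["model"])
  write_de_table(de, paths["de_table"])
  write_cohort(coh, paths["cohort"])
  jsonlite::write_json(list(hubs = attr(model, "hubs"),
                            planted_genes = attr(de, "planted"),
                            truth = attr(coh, "truth"),
                            currency_pct = currency_pct),
                       paths["truth"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_provenance(out_dir,
                   config = list(command = "simulate", seed = seed,
                                 currency_pct = currency_pct,
                                 model_args = model_args, de_args = de_args,
                                 cohort_args = cohort_args),
                   inputs = character(0))
  invisible(paths)
}

# Machine-readable run record: resolved configuration, package version and
# input checksums.  Deliberately no timestamp: outputs must be
# byte-identical across reruns with the same config and seed.
write_provenance <- function(out_dir, config, inputs) {
  jsonlite::write_json(
    list(package = "metcoherence",
         version = as.character(utils::packageVersion("metcoherence")),
         config = config,
         input_md5 = as.list(tools::md5sum(inputs))),
    file.path(out_dir, "provenance.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}
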