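#' Read a metabolic model from JSON
#'
#' The JSON dialect is a top-level object with `"metabolites"`:
#' `[{"id","name","compartment"}]` and `"reactions"`:
#' `[{"id", "stoichiometry": {met_id: coeff}, "reversible": bool,
#' "genes": [symbol, ...]}]`.  Gene symbols are upper-cased on load so they
#' match differential-expression tables from other sources.
#'
#' @param path path to a model JSON file.
#' @return A validated [metabolic_model].
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("malformed model JSON '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (is.null(doc$metabolites) || is.null(doc$reactions))
    stop("model JSON must contain 'metabolites' and 'reactions' arrays", call. = FALSE)
  mets <- data.frame(
    id = vapply(doc$metabolites, function(m) as.character(m$id %||% NA_character_), character(1)),
    name = vapply(doc$metabolites, function(m) as.character(m$name %||% NA_character_), character(1)),
    compartment = vapply(doc$metabolites, function(m) as.character(m$compartment %||% NA_character_), character(1)),
    stringsAsFactors = FALSE)
  rxns <- lapply(doc$reactions, function(r) {
    if (is.null(r$id)) stop("reaction record without 'id' in ", path, call. = FALSE)
    s <- unlist(r$stoichiometry)
    if (!is.numeric(s) && length(s))
      stop("reaction '", r$id, "': non-numeric stoichiometry", call. = FALSE)
    list(id = as.character(r$id),
         stoichiometry = s,
         reversible = isTRUE(r$reversible),
         genes = toupper(unlist(r$genes, use.names = FALSE) %||% character(0)))
  })
  names(rxns) <- vapply(rxns, `[[`, character(1), "id")
  metabolic_model(mets, rxns)
}

#' Write a metabolic model to JSON
#'
#' Inverse of [read_model_json()]; `read_model_json(write_model_json(m))`
#' reproduces `m` exactly.
#'
#' @param model a `metabolic_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  validate_model(model)
  doc <- list(
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
      m <- model$metabolites[i, ]
      out <- list(id = m$id)
      if (!is.na(m$name)) out$name <- m$name
      if (!is.na(m$compartment)) out$compartment <- m$compartment
      out
    }),
    reactions = unname(lapply(model$reactions, function(r) {
      list(id = r$id,
           stoichiometry = as.list(r$stoichiometry),
           reversible = r$reversible,
           genes = as.list(r$genes))
    })))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a metabolic model from SBML
#'
#' Minimal read-only importer for SBML level 2/3: species become
#' metabolites, reactions keep reactant coefficients negative and product
#' coefficients positive.  Gene associations are taken from level-3 `fbc`
#' gene-product associations or from `GENE_ASSOCIATION:` notes, and the
#' boolean AND/OR structure is flattened to the set of all mentioned gene
#' symbols: the coherence method uses only set membership, so isozyme vs
#' complex structure is irrelevant here.  Reactions without parseable gene
#' annotations are retained with an empty gene set and a warning.
#'
#' @param path path to an SBML file.
#' @return A validated [metabolic_model].
#' @export
read_model_sbml <- function(path) {
  if (!file.exists(path)) stop("SBML file not found: ", path, call. = FALSE)
  doc <- xml2::read_xml(path)
  # namespace-agnostic XPaths: core SBML and the fbc extension use
  # different namespaces across levels
  ln <- function(tag) sprintf("*[local-name()='%s']", tag)
  species <- xml2::xml_find_all(doc, sprintf(".//%s/%s", ln("listOfSpecies"), ln("species")))
  if (!length(species)) stop("SBML file has no species", call. = FALSE)
  mets <- data.frame(
    id = xml2::xml_attr(species, "id"),
    name = xml2::xml_attr(species, "name"),
    compartment = xml2::xml_attr(species, "compartment"),
    stringsAsFactors = FALSE)

  # fbc v2: map geneProduct ids to labels for resolving geneProductRef
  gp <- xml2::xml_find_all(doc, sprintf(".//%s", ln("geneProduct")))
  gp_label <- stats::setNames(xml2::xml_attr(gp, "label"), xml2::xml_attr(gp, "id"))

  rx_nodes <- xml2::xml_find_all(doc, sprintf(".//%s/%s", ln("listOfReactions"), ln("reaction")))
  if (!length(rx_nodes)) stop("SBML file has no reactions", call. = FALSE)
  n_missing <- 0L
  rxns <- lapply(rx_nodes, function(node) {
    rid <- xml2::xml_attr(node, "id")
    side <- function(xp, sign) {
      refs <- xml2::xml_find_all(node, xp)
      st <- xml2::xml_attr(refs, "stoichiometry")
      st <- ifelse(is.na(st), 1, as.numeric(st))
      stats::setNames(sign * st, xml2::xml_attr(refs, "species"))
    }
    lhs <- side(sprintf("./%s/%s", ln("listOfReactants"), ln("speciesReference")), -1)
    rhs <- side(sprintf("./%s/%s", ln("listOfProducts"), ln("speciesReference")), +1)
    ids <- union(names(lhs), names(rhs))
    s <- vapply(ids, function(i) {
      v <- sum(lhs[names(lhs) == i]) + sum(rhs[names(rhs) == i])
      # a species on both sides with equal stoichiometry nets to zero; keep
      # the product-side coefficient so connectivity is preserved
      if (v == 0) sum(rhs[names(rhs) == i]) else v
    }, numeric(1))
    genes <- sbml_gene_set(node, gp_label)
    if (is.null(genes)) {
      n_missing <<- n_missing + 1L
      genes <- character(0)
    }
    list(id = rid,
         stoichiometry = s,
         reversible = isTRUE(xml2::xml_attr(node, "reversible") == "true"),
         genes = toupper(genes))
  })
  names(rxns) <- vapply(rxns, `[[`, character(1), "id")
  if (n_missing > 0L)
    warning(n_missing, " reaction(s) without parseable gene associations; retained with empty gene sets",
            call. = FALSE)
  metabolic_model(mets, rxns)
}

# Extract the flattened gene symbol set for one SBML reaction node, or NULL
# when no annotation is present.
sbml_gene_set <- function(node, gp_label) {
  refs <- xml2::xml_find_all(node, ".//*[local-name()='geneProductRef']")
  if (length(refs)) {
    ids <- xml2::xml_attr(refs, "geneProduct")
    lab <- gp_label[ids]
    lab[is.na(lab)] <- ids[is.na(lab)]
    return(unique(unname(lab)))
  }
  notes <- xml2::xml_text(xml2::xml_find_all(node, ".//*[local-name()='notes']"))
  m <- regmatches(notes, regexpr("GENE_ASSOCIATION:[^<\n]*", notes))
  if (length(m)) {
    rule <- sub("GENE_ASSOCIATION:", "", m[[1]])
    syms <- regmatches(rule, gregexpr("[A-Za-z0-9_.-]+", rule))[[1]]
    syms <- setdiff(syms, c("and", "or", "AND", "OR"))
    if (length(syms)) return(unique(syms))
  }
  NULL
}

#' Read a differential-expression table
#'
#' Tab-separated file with header columns `gene`, `log2fc`, `pvalue` and
#' optionally `padj` (`.` or empty for missing).  This is the shape of a
#' DESeq2 result export; differential-expression calling itself is out of
#' scope and consumed as input.
#'
#' @param path path to the TSV file.
#' @return A `de_table`: data frame with columns gene (upper-cased),
#'   log2fc, pvalue, padj.
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) stop("DE table not found: ", path, call. = FALSE)
  d <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ".", ""))
  need <- c("gene", "log2fc", "pvalue")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    stop("DE table missing required columns: ", toString(missing_cols), call. = FALSE)
  if (!"padj" %in% names(d)) d$padj <- NA_real_
  for (col in c("log2fc", "pvalue", "padj")) {
    if (!is.numeric(d[[col]])) {
      bad <- which(!is.na(d[[col]]) & is.na(suppressWarnings(as.numeric(d[[col]]))))
      stop("DE table: non-numeric '", col, "' at line ", bad[1] + 1L, call. = FALSE)
    }
  }
  de_table(d$gene, d$log2fc, d$pvalue, d$padj)
}

#' Construct a differential-expression table
#'
#' @param gene character vector of gene symbols (upper-cased, must be unique).
#' @param log2fc finite log2 fold-changes.
#' @param pvalue raw p-values in \[0,1\].
#' @param padj adjusted p-values in \[0,1\] or NA.
#' @return A data frame of class `de_table`.
#' @export
de_table <- function(gene, log2fc, pvalue, padj = NA_real_) {
  gene <- toupper(as.character(gene))
  d <- data.frame(gene = gene, log2fc = as.numeric(log2fc),
                  pvalue = as.numeric(pvalue), padj = as.numeric(padj),
                  stringsAsFactors = FALSE)
  dup <- unique(d$gene[duplicated(d$gene)])
  if (length(dup)) stop("duplicated genes in DE table: ", toString(dup), call. = FALSE)
  if (any(!is.finite(d$log2fc)))
    stop("DE table: log2fc must be finite for all genes", call. = FALSE)
  bad_p <- d$pvalue < 0 | d$pvalue > 1 | is.na(d$pvalue)
  if (any(bad_p))
    stop("DE table: pvalue outside [0,1] for: ", toString(d$gene[bad_p]), call. = FALSE)
  bad_q <- !is.na(d$padj) & (d$padj < 0 | d$padj > 1)
  if (any(bad_q))
    stop("DE table: padj outside [0,1] for: ", toString(d$gene[bad_q]), call. = FALSE)
  class(d) <- c("de_table", "data.frame")
  d
}

#' Write a differential-expression table
#' @param de a `de_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  out <- as.data.frame(de)
  out$padj <- ifelse(is.na(out$padj), ".", format(out$padj, digits = 17, scientific = FALSE, trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a survival cohort table
#'
#' Tab-separated file with header `sample_id`, `os_months`, `event` and one
#' column per gene (RSEM-scale non-negative expression).  Rows with missing
#' or non-positive overall survival are dropped with a message: patients who
#' died when biopsied (overall survival 0 months or unspecified) carry no
#' survival information.
#'
#' @param path path to the TSV file.
#' @return A `cohort`: data frame with columns sample_id, os_months, event,
#'   then upper-cased gene columns; attribute `n_dropped` counts removed rows.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "os_months", "event")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    stop("cohort missing required columns: ", toString(missing_cols), call. = FALSE)
  genes <- setdiff(names(d), need)
  names(d)[match(genes, names(d))] <- toupper(genes)
  cohort(d)
}

#' Construct a survival cohort
#'
#' @param data data frame with columns `sample_id`, `os_months`, `event`
#'   and one numeric column per gene.  Rows with `os_months` missing or
#'   `<= 0` are dropped (count reported via a message and the `n_dropped`
#'   attribute).  Negative expression is a hard error: RSEM values are
#'   non-negative by definition.
#' @return A data frame of class `cohort`.
#' @export
cohort <- function(data) {
  d <- as.data.frame(data, stringsAsFactors = FALSE)
  drop <- is.na(d$os_months) | d$os_months <= 0
  n_dropped <- sum(drop)
  if (n_dropped > 0L) {
    message("cohort: dropped ", n_dropped, " patient(s) with missing or non-positive overall survival")
    d <- d[!drop, , drop = FALSE]
  }
  dup <- unique(d$sample_id[duplicated(d$sample_id)])
  if (length(dup)) stop("duplicated sample ids in cohort: ", toString(dup), call. = FALSE)
  if (!all(d$event %in% c(0, 1)))
    stop("cohort: event must be 0 (censored) or 1 (death observed)", call. = FALSE)
  genes <- cohort_genes_internal(d)
  for (g in genes) {
    v <- d[[g]]
    if (!is.numeric(v)) stop("cohort: expression column '", g, "' is not numeric", call. = FALSE)
    if (any(is.na(v)) || any(v < 0))
      stop("cohort: expression column '", g, "' has negative or missing values", call. = FALSE)
  }
  rownames(d) <- NULL
  structure(d, n_dropped = n_dropped, class = c("cohort", "data.frame"))
}

cohort_genes_internal <- function(d) setdiff(names(d), c("sample_id", "os_months", "event"))

#' Gene columns of a cohort
#' @param x a `cohort`.
#' @return Character vector of gene symbols carried as expression columns.
#' @export
cohort_genes <- function(x) cohort_genes_internal(x)

#' Write a cohort table
#' @param x a `cohort`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
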