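#' Construct a genome-scale metabolic model
#'
#' A metabolic model is the bipartite metabolite-reaction structure encoded
#' by a stoichiometric matrix, together with the gene-reaction associations
#' used to derive a gene-centric network.  Stoichiometric coefficients are
#' kept as signed reals but only co-membership (topology) is used downstream.
#'
#' @param metabolites data frame with columns `id` (required, unique,
#'   non-empty) and optionally `name` and `compartment`.
#' @param reactions named list; each element a list with fields
#'   `id` (matching its name), `stoichiometry` (named numeric vector,
#'   metabolite id -> signed non-zero coefficient), `reversible` (logical,
#'   parsed but unused downstream) and `genes` (character vector of gene
#'   symbols, possibly empty).  Gene symbols are upper-cased.
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  if (!"name" %in% names(metabolites)) metabolites$name <- NA_character_
  if (!"compartment" %in% names(metabolites)) metabolites$compartment <- NA_character_
  model <- structure(
    list(metabolites = metabolites[, c("id", "name", "compartment")],
         reactions = reactions),
    class = "metabolic_model")
  validate_model(model)
}

#' Validate a metabolic model
#'
#' Checks every structural invariant: non-empty unique metabolite and
#' reaction ids, non-empty stoichiometries with non-zero coefficients, no
#' dangling metabolite references, non-empty gene symbols.
#'
#' @param model a `metabolic_model`.
#' @return The model, invisibly unchanged, or an error describing every
#'   violated invariant.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  mets <- model$metabolites
  rxns <- model$reactions
  problems <- character(0)
  if (nrow(mets) < 1L) problems <- c(problems, "model must contain at least one metabolite")
  if (length(rxns) < 1L) problems <- c(problems, "model must contain at least one reaction")
  if (any(!nzchar(mets$id)) || anyNA(mets$id))
    problems <- c(problems, "metabolite ids must be non-empty")
  dup <- unique(mets$id[duplicated(mets$id)])
  if (length(dup))
    problems <- c(problems, sprintf("duplicated metabolite ids: %s", toString(dup)))
  rids <- vapply(rxns, function(r) r$id %||% NA_character_, character(1))
  if (anyNA(rids) || any(!nzchar(rids)))
    problems <- c(problems, "reaction ids must be non-empty")
  dupr <- unique(rids[duplicated(rids)])
  if (length(dupr))
    problems <- c(problems, sprintf("duplicated reaction ids: %s", toString(dupr)))
  for (r in rxns) {
    s <- r$stoichiometry
    if (length(s) == 0L) {
      problems <- c(problems, sprintf("reaction '%s': empty stoichiometry", r$id))
      next
    }
    if (is.null(names(s)) || any(!nzchar(names(s))))
      problems <- c(problems, sprintf("reaction '%s': unnamed stoichiometry entries", r$id))
    if (any(!is.finite(s)) || any(s == 0))
      problems <- c(problems, sprintf("reaction '%s': zero or non-finite coefficients", r$id))
    dangling <- setdiff(names(s), mets$id)
    if (length(dangling))
      problems <- c(problems,
                    sprintf("reaction '%s': unknown metabolite ids: %s", r$id, toString(dangling)))
    g <- r$genes
    if (length(g) && (anyNA(g) || any(!nzchar(g))))
      problems <- c(problems, sprintf("reaction '%s': empty gene symbols", r$id))
  }
  if (length(problems))
    stop("invalid metabolic model:\n  ", paste(problems, collapse = "\n  "), call. = FALSE)
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("Metabolic model: %d metabolites, %d reactions, %d genes\n",
              nrow(x$metabolites), length(x$reactions), length(model_genes(x))))
  invisible(x)
}

#' All gene symbols associated with any reaction of a model
#'
#' @param model a `metabolic_model`.
#' @return Sorted character vector of distinct gene symbols.
#' @export
model_genes <- function(model) {
  sort(unique(unlist(lapply(model$reactions, `[[`, "genes"), use.names = FALSE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
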