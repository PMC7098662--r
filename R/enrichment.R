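#' Term over-representation tests
#'
#' `term_for_term()` is the classical one-sided hypergeometric test of each
#' term's study count against the population. `parent_child_union()`
#' conditions each term on the union of its parents: the "population" for
#' term t is restricted to genes annotated to at least one parent of t, which
#' discounts enrichment inherited from a parent term. In both modes
#' annotations are first propagated to ancestors (true-path rule) and
#' p-values are Bonferroni-corrected over the terms actually tested.
#'
#' @param study character vector of study gene ids (a subset of `population`).
#' @param population character vector: the background gene universe. The
#'   cluster analyses of this package test each cluster against the whole
#'   periodic program — pass that as `population`.
#' @param ann annotation tibble with columns `gene_id`, `term`.
#' @param ont a `cyclo_ontology`; required for `parent_child_union()` and for
#'   propagation.
#' @param propagate propagate annotations up the DAG before testing.
#' @param alpha significance level on the Bonferroni-corrected p (default 0.05).
#' @return A tibble per tested term: `term`, `name`, `study_count`,
#'   `study_size`, `population_count`, `population_size` (conditioned
#'   denominators in the parent-child mode), `p_value`, `p_bonferroni`,
#'   `significant`.
#' @export
term_for_term <- function(study, population, ann, ont = NULL,
                          propagate = !is.null(ont), alpha = 0.05) {
  check_enrichment_inputs(study, population)
  if (propagate) ann <- propagate_annotations(ann, ont)
  ann <- filter(ann, .data$gene_id %in% population)
  n_pop <- length(population)
  n_study <- length(study)
  by_term <- split(ann$gene_id, ann$term)
  rows <- imap(by_term, function(genes, term) {
    m <- length(unique(genes))
    k <- length(intersect(genes, study))
    tibble(term = term,
           study_count = k, study_size = n_study,
           population_count = m, population_size = n_pop,
           p_value = phyper(k - 1, m, n_pop - m, n_study, lower.tail = FALSE))
  })
  finish_enrichment(bind_rows(rows), ont, alpha)
}

#' @rdname term_for_term
#' @export
parent_child_union <- function(study, population, ann, ont, alpha = 0.05) {
  check_enrichment_inputs(study, population)
  ann <- propagate_annotations(ann, ont)
  ann <- filter(ann, .data$gene_id %in% population)
  by_term <- split(ann$gene_id, ann$term)
  study_ann <- filter(ann, .data$gene_id %in% study)
  by_term_study <- split(study_ann$gene_id, study_ann$term)
  roots <- names(keep(ont$parents, ~ length(.x) == 0))
  tested <- setdiff(intersect(ont$terms$id, names(by_term)), roots)
  if (length(setdiff(names(by_term), tested)) > 0) {
    inform(paste0("not tested (root or unannotated): ",
                  paste(setdiff(names(by_term), tested), collapse = ", ")))
  }
  rows <- map(tested, function(t) {
    pa <- ont$parents[[t]]
    pa_pop <- unique(unlist(by_term[pa]))          # genes annotated to any parent
    pa_study <- intersect(pa_pop, study)
    m_t <- length(unique(by_term[[t]]))            # term genes (subset of pa_pop)
    k_t <- length(unique(by_term_study[[t]] %||% character()))
    tibble(term = t,
           study_count = k_t, study_size = length(pa_study),
           population_count = m_t, population_size = length(pa_pop),
           p_value = phyper(k_t - 1, m_t, length(pa_pop) - m_t,
                            length(pa_study), lower.tail = FALSE))
  })
  finish_enrichment(bind_rows(rows), ont, alpha)
}

check_enrichment_inputs <- function(study, population) {
  if (length(setdiff(study, population)) > 0) {
    abort("`study` must be a subset of `population`")
  }
  if (length(study) == 0) abort("empty study set")
}

finish_enrichment <- function(out, ont, alpha) {
  if (nrow(out) == 0) return(mutate(out, p_bonferroni = numeric(), significant = logical()))
  nm <- if (is.null(ont)) tibble(id = character(), name = character()) else ont$terms
  out |>
    left_join(rename(nm, term = "id"), by = "term") |>
    mutate(p_bonferroni = pmin(.data$p_value * nrow(out), 1),
           significant = .data$p_bonferroni < alpha) |>
    select("term", "name", dplyr::everything()) |>
    arrange(.data$p_value)
}
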