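# Cross-species comparison of periodic transcriptional programs at the
# orthogroup level. For a species pair the null expectation for the number of
# orthogroups periodic in both is A_exp = p1 * p2 / C, where C counts the
# orthogroups the two species share and p1, p2 their periodic orthogroups
# within C; the one-sided test uses X ~ Binomial(C, (p1/C)(p2/C)), the unique
# binomial on the common universe with mean A_exp.

#' Orthogroups containing at least one periodic gene of a species
#'
#' @param universe long orthogroup table: tibble `orthogroup`, `species`,
#'   `gene_id`.
#' @param species species label to extract.
#' @param periodic_genes character vector of that species' periodic gene ids.
#' @return Character vector of periodic orthogroup ids. Periodic genes
#'   mapping to no orthogroup contribute nothing (their count is reported via
#'   a message).
#' @export
periodic_orthogroups <- function(universe, species, periodic_genes) {
  if (!species %in% universe$species) {
    abort(paste0("species not in orthogroup table: ", species))
  }
  sp <- filter(universe, .data$species == !!species)
  unmapped <- setdiff(periodic_genes, sp$gene_id)
  if (length(unmapped) > 0) {
    inform(sprintf("%d periodic genes of %s map to no orthogroup",
                   length(unmapped), species))
  }
  sort(unique(sp$orthogroup[sp$gene_id %in% periodic_genes]))
}

#' Species universe of orthogroups
#'
#' @rdname periodic_orthogroups
#' @export
species_orthogroups <- function(universe, species) {
  sort(unique(universe$orthogroup[universe$species == species]))
}

overlap_row <- function(c_set, periodic_a, periodic_b, method, label_a, label_b) {
  C <- length(c_set)
  if (C == 0) abort("the two species share no orthogroups (C = 0)")
  p1 <- length(intersect(periodic_a, c_set))
  p2 <- length(intersect(periodic_b, c_set))
  shared <- length(intersect(intersect(periodic_a, periodic_b), c_set))
  a_exp <- p1 * p2 / C
  p <- if (p1 == 0 || p2 == 0) 1 else {
    if (method == "binomial") {
      pbinom(shared - 1, C, (p1 / C) * (p2 / C), lower.tail = FALSE)
    } else {
      fisher.test(matrix(c(shared, p1 - shared, p2 - shared,
                           C - p1 - p2 + shared), 2, byrow = TRUE),
                  alternative = "greater")$p.value
    }
  }
  tibble(a = label_a, b = label_b, C = C, p1 = p1, p2 = p2,
         shared = shared, a_exp = a_exp, p_value = p, method = method)
}

#' Test whether two species share more periodic orthogroups than chance
#'
#' @param periodic_a,periodic_b character vectors: each species' periodic
#'   orthogroup ids.
#' @param universe_a,universe_b character vectors: each species' full
#'   orthogroup ids (from one joint orthology inference).
#' @param method `"binomial"` (default, see above) or `"fisher"` (one-sided
#'   hypergeometric on the 2x2 of p1 x p2 within C) as a sensitivity check.
#' @param labels length-2 character vector naming the pair in the output.
#' @return A one-row tibble: `C`, `p1`, `p2`, `shared`, `a_exp`, `p_value`.
#' @export
pairwise_overlap_test <- function(periodic_a, periodic_b, universe_a, universe_b,
                                  method = c("binomial", "fisher"),
                                  labels = c("A", "B")) {
  method <- match.arg(method)
  if (length(setdiff(periodic_a, universe_a)) > 0 ||
      length(setdiff(periodic_b, universe_b)) > 0) {
    abort("periodic orthogroups must lie within their species' universe")
  }
  overlap_row(intersect(universe_a, universe_b), periodic_a, periodic_b,
              method, labels[1], labels[2])
}

#' Overlap test on one-to-one orthologue pairs
#'
#' Same statistic with C = the number of one-to-one pairs and periodicity
#' counted at the gene level.
#'
#' @param pairs tibble with columns `gene_a`, `gene_b`; must be a bijection
#'   (no gene repeated on either side).
#' @param periodic_a,periodic_b character vectors of periodic gene ids per
#'   species.
#' @inheritParams pairwise_overlap_test
#' @export
one_to_one_overlap_test <- function(pairs, periodic_a, periodic_b,
                                    method = c("binomial", "fisher"),
                                    labels = c("A", "B")) {
  method <- match.arg(method)
  stopifnot(all(c("gene_a", "gene_b") %in% names(pairs)))
  if (anyDuplicated(pairs$gene_a) || anyDuplicated(pairs$gene_b)) {
    dup <- c(pairs$gene_a[duplicated(pairs$gene_a)],
             pairs$gene_b[duplicated(pairs$gene_b)])
    abort(paste0("duplicated gene in one-to-one pair list: ",
                 paste(unique(dup), collapse = ", ")))
  }
  pair_id <- paste(pairs$gene_a, pairs$gene_b, sep = "\r")
  per_a <- pair_id[pairs$gene_a %in% periodic_a]
  per_b <- pair_id[pairs$gene_b %in% periodic_b]
  overlap_row(pair_id, per_a, per_b, method, labels[1], labels[2])
}

#' Orthogroups periodic in every species
#'
#' The conserved core: orthogroups present in all species and periodic in at
#' least one dataset of every species.
#'
#' @param universe long orthogroup table (`orthogroup`, `species`, `gene_id`).
#' @param periodic_sets named list (one entry per species) of lists of
#'   periodic orthogroup id vectors, one per dataset of that species.
#' @return Character vector of core orthogroup ids.
#' @export
core_conserved_set <- function(universe, periodic_sets) {
  if (length(periodic_sets) < 2) abort("need at least 2 species")
  if (any(lengths(periodic_sets) == 0)) {
    abort(paste0("species with zero datasets: ",
                 paste(names(periodic_sets)[lengths(periodic_sets) == 0],
                       collapse = ", ")))
  }
  present_all <- Reduce(intersect,
                        lapply(names(periodic_sets),
                               function(sp) species_orthogroups(universe, sp)))
  periodic_any <- lapply(periodic_sets, function(sets) unique(unlist(sets)))
  sort(Reduce(intersect, c(list(present_all), periodic_any)))
}

#' Cap a species' periodic gene list at a fraction of its genome
#'
#' Keeps at most `floor(threshold * total)` of the best-ranked genes — the
#' correction for genome size applied before cross-species comparison
#' (10% for human cells and yeasts, 5% for *A. thaliana*).
#'
#' @param ranked tibble with columns `gene_id` and `rank` (ascending = best),
#'   already ordered or not.
#' @param total total number of genes in the species.
#' @param threshold maximum periodic fraction, in (0, 1].
#' @return Tibble with the retained genes, ordered by rank.
#' @export
apply_species_threshold <- function(ranked, total, threshold) {
  stopifnot(all(c("gene_id", "rank") %in% names(ranked)))
  if (nrow(ranked) == 0) abort("empty ranked gene list")
  assert_scalar_number(threshold, "threshold", min = 1e-12, max = 1)
  keep <- floor(threshold * total)
  ranked |> arrange(.data$rank) |> head(keep)
}
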