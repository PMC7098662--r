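#' Combine the two periodicity tests by rank sums
#'
#' Adjusts each test's p-values for multiple testing across genes
#' (Benjamini--Hochberg by default), assigns each gene a rank per test on the
#' adjusted values (ascending; ties broken by raw p, then lexicographic gene
#' id), and sums the two ranks into the final periodicity rank — smaller
#' means more confidently periodic.
#'
#' @param pvals a tibble with columns `gene_id`, `p_jtk`, `p_rain` (the output
#'   of joining [jtk_test()] and [rain_test()]); missing p-values are rejected.
#' @param adjust `"BH"` (default) or `"bonferroni"` — which adjustment the
#'   ranks are computed on.
#' @return The input plus `q_jtk`, `q_rain`, `rank_jtk`, `rank_rain`,
#'   `combined_rank`. Each rank column is a permutation of `1..n_genes`.
#' @export
rank_and_combine <- function(pvals, adjust = c("BH", "bonferroni")) {
  adjust <- match.arg(adjust)
  need <- c("gene_id", "p_jtk", "p_rain")
  if (!all(need %in% names(pvals))) {
    abort("`pvals` needs columns gene_id, p_jtk, p_rain")
  }
  if (anyNA(pvals$p_jtk) || anyNA(pvals$p_rain)) {
    bad <- pvals$gene_id[is.na(pvals$p_jtk) | is.na(pvals$p_rain)]
    abort(paste0("missing p-values for: ", paste(head(bad, 5), collapse = ", ")))
  }
  pvals |>
    mutate(q_jtk = p.adjust(.data$p_jtk, method = adjust),
           q_rain = p.adjust(.data$p_rain, method = adjust),
           rank_jtk = rank_with_ties(.data$q_jtk, .data$gene_id, .data$p_jtk),
           rank_rain = rank_with_ties(.data$q_rain, .data$gene_id, .data$p_rain),
           combined_rank = .data$rank_jtk + .data$rank_rain)
}

#' Selection rule for the periodic gene set
#'
#' The replicate-consistency selection: genes must rank within `loose` by
#' combined rank in *both* replicates, and the `strict` best of those
#' candidates by the averaged dataset's combined rank are selected. Genes can
#' be forced in or out by hand (the study added its cyclin A orthologue,
#' CAOG_04719T0, despite an average rank of 1916).
#'
#' @param loose loose per-replicate combined-rank cutoff (default 2000).
#' @param strict cutoff on the averaged dataset (default 800); `strict <= loose`.
#' @param manual_include,manual_exclude character vectors of gene ids.
#' @return A list of class `selection_rule`.
#' @export
selection_rule <- function(loose = 2000, strict = 800,
                           manual_include = character(), manual_exclude = character()) {
  if (strict > loose) abort("`strict` cutoff must not exceed `loose`")
  structure(list(loose = loose, strict = strict,
                 manual_include = as.character(manual_include),
                 manual_exclude = as.character(manual_exclude)),
            class = "selection_rule")
}

#' Select the periodic gene set across replicates
#'
#' @param table_rep1,table_rep2,table_avg ranked tables from
#'   [rank_and_combine()] over the same gene universe (the two replicates and
#'   their average).
#' @param rule a [selection_rule()].
#' @return `table_avg` with logical columns `candidate` (within the loose
#'   cutoff in both replicates) and `selected`.
#' @export
select_periodic <- function(table_rep1, table_rep2, table_avg,
                            rule = selection_rule()) {
  universe <- table_avg$gene_id
  for (tab in list(table_rep1, table_rep2)) {
    if (!setequal(tab$gene_id, universe)) {
      abort("all three tables must cover the same gene universe")
    }
  }
  missing_inc <- setdiff(rule$manual_include, universe)
  if (length(missing_inc) > 0) {
    abort(paste0("manual_include genes absent from the universe: ",
                 paste(missing_inc, collapse = ", ")))
  }
  loose1 <- table_rep1$gene_id[table_rep1$combined_rank <= rule$loose]
  loose2 <- table_rep2$gene_id[table_rep2$combined_rank <= rule$loose]
  out <- table_avg |>
    mutate(candidate = .data$gene_id %in% loose1 & .data$gene_id %in% loose2)
  cand <- out |> filter(.data$candidate) |> arrange(.data$combined_rank)
  top <- head(cand$gene_id, rule$strict)
  sel <- setdiff(union(top, rule$manual_include), rule$manual_exclude)
  mutate(out, selected = .data$gene_id %in% sel)
}
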