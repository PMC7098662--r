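#' Detect periodically expressed genes from replicate time courses
#'
#' The full detection pipeline: drop genes below the expression floor (mean
#' over the series must exceed `threshold` tpm in every replicate), run the
#' cosine-correlation and umbrella tests on each replicate and on the
#' replicate average, combine the two tests by rank sums per dataset, and
#' apply the replicate-consistency selection rule.
#'
#' Both tests are rank-based, so they are applied to tpm directly; z-scoring
#' would not change any rank.
#'
#' @param rep1,rep2 replicate time-course tibbles over the same time grid.
#' @param params a [periodicity_params()].
#' @param rule a [selection_rule()].
#' @param threshold expression floor in tpm (default 1).
#' @return An object of class `cyclo_periodicity`: a list with the ranked
#'   tables `rep1`, `rep2`, `average` (the latter carrying `candidate` and
#'   `selected` flags), the character vector `selected`, and the settings
#'   used. `tidy()` returns the average table; `glance()` a one-row summary.
#' @export
detect_periodic <- function(rep1, rep2, params = periodicity_params(),
                            rule = selection_rule(), threshold = 1) {
  validate_timecourse(rep1)
  validate_timecourse(rep2)
  if (!setequal(rep1$gene_id, rep2$gene_id)) {
    abort("replicates must share a gene universe before filtering")
  }
  rep2 <- rep2[match(rep1$gene_id, rep2$gene_id), , drop = FALSE]
  keep <- rowMeans(timecourse_matrix(rep1)) > threshold &
    rowMeans(timecourse_matrix(rep2)) > threshold
  rep1 <- rep1[keep, , drop = FALSE]
  rep2 <- rep2[keep, , drop = FALSE]
  avg <- average_replicates(list(rep1, rep2))
  run_one <- function(tc) {
    inner_join(jtk_test(tc, params),
               rain_test(tc, params), by = "gene_id",
               suffix = c("_jtk", "_rain")) |>
      rank_and_combine()
  }
  t1 <- run_one(rep1)
  t2 <- run_one(rep2)
  ta <- run_one(avg)
  ta <- select_periodic(t1, t2, ta, rule)
  structure(list(rep1 = t1, rep2 = t2, average = ta,
                 selected = ta$gene_id[ta$selected],
                 params = params, rule = rule, threshold = threshold,
                 n_genes = nrow(ta)),
            class = "cyclo_periodicity")
}

#' @export
print.cyclo_periodicity <- function(x, ...) {
  cat("Periodicity detection over", x$n_genes, "expressed genes\n")
  cat("  cosine periods:", paste(x$params$periods, collapse = ","),
      "samples; umbrella period:", x$params$rain_period, "samples\n")
  cat("  selection: loose", x$rule$loose, "/ strict", x$rule$strict, "->",
      length(x$selected), "periodic genes\n")
  invisible(x)
}
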