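#' Expression time-course tables
#'
#' A time course is an ordinary tibble whose first column is `gene_id` and
#' whose remaining columns are expression values (tpm) at successive sampling
#' times, named `t<hours>` (e.g. `t2.00`, `t2.75`, ... for samples taken every
#' 45 minutes from 2 h after release). All functions in the package take and
#' return this shape so calls chain with the pipe.
#'
#' @param genes character vector of gene identifiers (no duplicates).
#' @param values numeric matrix, genes x times, non-negative unless
#'   `nonnegative = FALSE` (z-scored profiles are dimensionless and signed).
#' @param times numeric vector of sampling times in hours, strictly increasing.
#' @param nonnegative if `TRUE` (the default, for tpm), negative values are
#'   rejected with their coordinates.
#' @return A tibble with columns `gene_id`, then one column per time point.
#' @examples
#' tc <- timecourse(c("g1", "g2"), rbind(c(1, 2, 3), c(4, 5, 6)), c(2, 2.75, 3.5))
#' timecourse_times(tc)
#' @export
timecourse <- function(genes, values, times, nonnegative = TRUE) {
  values <- as.matrix(values)
  if (anyDuplicated(genes)) {
    abort(paste0("duplicate gene ids: ",
                 paste(unique(genes[duplicated(genes)]), collapse = ", ")))
  }
  if (length(times) != ncol(values)) {
    abort("`times` length must equal the number of value columns")
  }
  if (is.unsorted(times, strictly = TRUE)) {
    abort("`times` must be strictly increasing")
  }
  if (nrow(values) != length(genes)) {
    abort("`values` must have one row per gene")
  }
  if (any(!is.finite(values)) || (nonnegative && any(values < 0))) {
    bad <- which(!is.finite(values) | (nonnegative & values < 0), arr.ind = TRUE)[1, ]
    abort(sprintf("negative or non-finite expression at gene %s, time %s",
                  genes[bad[1]], format(times[bad[2]])))
  }
  out <- as_tibble(values, .name_repair = "minimal")
  names(out) <- time_labels(times)
  bind_cols(tibble(gene_id = as.character(genes)), out)
}

time_labels <- function(times) sprintf("t%.2f", times)

#' @rdname timecourse
#' @param tc a time-course tibble.
#' @export
timecourse_times <- function(tc) {
  validate_timecourse(tc)
  as.numeric(sub("^t", "", names(tc)[-1]))
}

#' @rdname timecourse
#' @export
timecourse_matrix <- function(tc) {
  validate_timecourse(tc)
  m <- as.matrix(tc[, -1, drop = FALSE])
  rownames(m) <- tc$gene_id
  m
}

validate_timecourse <- function(tc) {
  if (!is.data.frame(tc) || ncol(tc) < 2 || names(tc)[1] != "gene_id") {
    abort("expected a time-course tibble: `gene_id` column followed by `t<hours>` columns")
  }
  tlab <- names(tc)[-1]
  tt <- suppressWarnings(as.numeric(sub("^t", "", tlab)))
  if (any(is.na(tt)) || is.unsorted(tt, strictly = TRUE)) {
    abort("time columns must be named t<hours> with strictly increasing times")
  }
  if (anyDuplicated(tc$gene_id)) {
    abort(paste0("duplicate gene ids: ",
                 paste(unique(tc$gene_id[duplicated(tc$gene_id)]), collapse = ", ")))
  }
  invisible(tc)
}

#' Drop genes below an expression floor
#'
#' Retains genes whose mean tpm over the whole series is strictly above
#' `threshold` (default 1 tpm), the standard floor for calling a transcript
#' expressed in this kind of time course.
#'
#' @param tc a time-course tibble.
#' @param threshold tpm floor; genes with mean expression `> threshold` are kept.
#' @return The filtered time course, gene order preserved.
#' @export
filter_expressed <- function(tc, threshold = 1) {
  validate_timecourse(tc)
  assert_scalar_number(threshold, "threshold", min = 0)
  keep <- rowMeans(timecourse_matrix(tc)) > threshold
  if (!any(keep)) {
    warn(sprintf("no genes exceed mean expression %s tpm", format(threshold)))
  }
  tc[keep, , drop = FALSE]
}

#' Z-score each gene's profile over time
#'
#' Centers each row to mean zero and scales to unit standard deviation,
#' using the population convention (divide by n). The result is dimensionless;
#' applying the function twice is the identity. Constant rows carry no shape
#' information and are rejected by name — remove them first (e.g. with
#' [filter_expressed()]).
#'
#' @param tc a time-course tibble.
#' @return The normalized time course.
#' @export
zscore_normalize <- function(tc) {
  validate_timecourse(tc)
  m <- timecourse_matrix(tc)
  mu <- rowMeans(m)
  centered <- m - mu
  sdev <- sqrt(rowMeans(centered^2))
  if (any(sdev == 0)) {
    abort(paste0("constant expression rows cannot be z-scored: ",
                 paste(rownames(m)[sdev == 0], collapse = ", ")))
  }
  timecourse(tc$gene_id, centered / sdev, timecourse_times(tc), nonnegative = FALSE)
}

#' Average replicate time courses
#'
#' Element-wise arithmetic mean of two or more replicate matrices sharing
#' the same genes and time grid.
#'
#' @param tcs list of time-course tibbles with identical gene sets and times.
#' @return A single averaged time course.
#' @export
average_replicates <- function(tcs) {
  stopifnot(is.list(tcs), length(tcs) >= 2)
  walk(tcs, validate_timecourse)
  ref_genes <- tcs[[1]]$gene_id
  ref_times <- timecourse_times(tcs[[1]])
  for (tc in tcs[-1]) {
    diff <- c(setdiff(ref_genes, tc$gene_id), setdiff(tc$gene_id, ref_genes))
    if (length(diff) > 0) {
      abort(paste0("replicates disagree on genes: ", paste(diff, collapse = ", ")))
    }
    if (!isTRUE(all.equal(ref_times, timecourse_times(tc)))) {
      abort("replicates disagree on the time grid")
    }
  }
  mats <- map(tcs, function(tc) timecourse_matrix(tc)[ref_genes, , drop = FALSE])
  timecourse(ref_genes, Reduce(`+`, mats) / length(mats), ref_times)
}
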