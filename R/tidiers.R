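#' Tidiers and plots for fitted objects
#'
#' `tidy()` returns the per-gene table, `glance()` a one-row run summary,
#' `autoplot()` a ggplot: the rank-rank scatter of the two tests for a
#' detection result, and the per-cluster mean wave profiles for a clustering.
#'
#' @param x a `cyclo_periodicity` or `cyclo_clusters` object.
#' @param ... unused.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.cyclo_periodicity <- function(x, ...) x$average

#' @rdname tidiers
#' @export
glance.cyclo_periodicity <- function(x, ...) {
  tibble(n_genes = x$n_genes,
         n_candidates = sum(x$average$candidate),
         n_selected = length(x$selected),
         loose = x$rule$loose, strict = x$rule$strict,
         n_perm = x$params$n_perm)
}

#' @rdname tidiers
#' @export
tidy.cyclo_clusters <- function(x, ...) {
  left_join(x$assignment, x$clusters, by = "cluster")
}

#' @rdname tidiers
#' @export
glance.cyclo_clusters <- function(x, ...) {
  tibble(k = x$k, method = x$method,
         n_genes = nrow(x$assignment),
         min_size = min(x$clusters$size),
         max_size = max(x$clusters$size))
}

#' @rdname tidiers
#' @export
autoplot.cyclo_periodicity <- function(x, ...) {
  ggplot2::ggplot(x$average,
                  ggplot2::aes(x = .data$rank_jtk, y = .data$rank_rain,
                               colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "cosine-test rank", y = "umbrella-test rank",
                  colour = "periodic") +
    ggplot2::theme_minimal()
}

#' @rdname tidiers
#' @export
autoplot.cyclo_clusters <- function(x, ...) {
  prof <- x$profiles |>
    tidyr::pivot_longer(-"gene_id", names_to = "time", values_to = "z") |>
    mutate(hours = as.numeric(sub("^t", "", .data$time)),
           cluster = as.integer(sub("^cluster", "", .data$gene_id)))
  lab <- x$clusters |>
    mutate(title = paste0("cluster ", .data$cluster,
                          ifelse(is.na(.data$phase_label), "",
                                 paste0(" (", .data$phase_label, ")")),
                          ", n=", .data$size))
  prof <- left_join(prof, select(lab, "cluster", "title"), by = "cluster")
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$hours, y = .data$z)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~title) +
    ggplot2::labs(x = "hours post-release", y = "mean z-scored expression") +
    ggplot2::theme_minimal()
}

#' Heatmap of gene-age enrichment per cluster
#'
#' @param enr the tibble returned by [age_enrichment()].
#' @param alpha significance level on the Bonferroni p for the asterisks.
#' @return A ggplot.
#' @export
plot_age_enrichment <- function(enr, alpha = 0.05) {
  enr <- mutate(enr,
                log2_ratio = log2(pmax(.data$ratio, 1e-3)),
                star = ifelse(.data$p_bonferroni < alpha, "*", ""))
  ggplot2::ggplot(enr, ggplot2::aes(x = factor(.data$age), y = .data$cluster,
                                    fill = .data$log2_ratio)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$star)) +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    ggplot2::labs(x = "age class", y = "cluster", fill = "log2 enrichment") +
    ggplot2::theme_minimal()
}
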