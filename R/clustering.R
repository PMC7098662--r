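#' Group periodic genes into temporal expression waves
#'
#' Agglomerative clustering of z-scored expression profiles (Euclidean
#' distance) cut to exactly `k` groups, or seeded k-means with restarts.
#' Clusters are re-indexed by ascending peak time of their mean profile, so
#' cluster 1 always peaks earliest.
#'
#' @param profiles a z-scored time-course tibble restricted to the selected
#'   periodic genes (typically the replicate average).
#' @param k number of clusters (default 5 temporal waves).
#' @param linkage agglomeration rule: `"complete"` (default), `"average"`, or
#'   `"ward.D2"`.
#' @return An object of class `cyclo_clusters`: list with `assignment`
#'   (tibble `gene_id`, `cluster`), `clusters` (tibble `cluster`, `size`,
#'   `peak_hours`, `phase_label`), `profiles` (cluster mean profiles, one row
#'   per cluster), `method`, and `k`.
#' @export
hierarchical_clusters <- function(profiles, k = 5, linkage = c("complete", "average", "ward.D2")) {
  linkage <- match.arg(linkage)
  m <- cluster_input(profiles, k)
  cl <- cutree(hclust(dist(m), method = linkage), k = k)
  finish_clusters(profiles, cl, k, paste0("hierarchical/", linkage))
}

#' @rdname hierarchical_clusters
#' @param seed integer seed for the k-means initialization.
#' @param nstart number of random restarts; the best within-cluster sum of
#'   squares wins.
#' @export
kmeans_clusters <- function(profiles, k = 5, seed = 1L, nstart = 25) {
  m <- cluster_input(profiles, k)
  cl <- with_seed(sub_seed(seed, 37L), kmeans(m, centers = k, nstart = nstart,
                                              iter.max = 100)$cluster)
  finish_clusters(profiles, cl, k, "kmeans")
}

cluster_input <- function(profiles, k) {
  validate_timecourse(profiles)
  if (k < 1 || k > nrow(profiles)) abort("`k` must be between 1 and the number of genes")
  timecourse_matrix(profiles)
}

finish_clusters <- function(profiles, cl, k, method) {
  m <- timecourse_matrix(profiles)
  times <- timecourse_times(profiles)
  means <- t(vapply(seq_len(k), function(g) colMeans(m[cl == g, , drop = FALSE]),
                    numeric(ncol(m))))
  peak <- times[max.col(means, ties.method = "first")]
  # re-index so cluster 1 peaks earliest
  ord <- order(peak)
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  cl <- relabel[cl]
  means <- means[ord, , drop = FALSE]
  peak <- peak[ord]
  sizes <- tabulate(cl, nbins = k)
  if (any(sizes == 0)) abort("clustering produced an empty cluster")
  structure(list(
    assignment = tibble(gene_id = profiles$gene_id, cluster = cl),
    clusters = tibble(cluster = seq_len(k), size = sizes, peak_hours = peak,
                      phase_label = NA_character_),
    profiles = timecourse(paste0("cluster", seq_len(k)), means, times,
                          nonnegative = FALSE),
    method = method, k = k), class = "cyclo_clusters")
}

#' @export
print.cyclo_clusters <- function(x, ...) {
  cat("Temporal clustering (", x$method, "), k = ", x$k, "\n", sep = "")
  print(x$clusters)
  invisible(x)
}

#' Agreement matrix between two clusterings
#'
#' Entry (i, j) is the number of genes shared by cluster i of `a` and cluster
#' j of `b`, divided by the size of the smaller of the two clusters; 1 means
#' one cluster is contained in the other.
#'
#' @param a,b `cyclo_clusters` objects (or tibbles with `gene_id`, `cluster`)
#'   over the same gene universe.
#' @return A numeric matrix, rows = clusters of `a`, columns = clusters of `b`.
#' @export
cluster_agreement <- function(a, b) {
  a <- if (inherits(a, "cyclo_clusters")) a$assignment else a
  b <- if (inherits(b, "cyclo_clusters")) b$assignment else b
  if (!setequal(a$gene_id, b$gene_id)) abort("clusterings cover different genes")
  b <- b[match(a$gene_id, b$gene_id), ]
  ka <- max(a$cluster)
  kb <- max(b$cluster)
  if (any(tabulate(a$cluster, ka) == 0) || any(tabulate(b$cluster, kb) == 0)) {
    abort("empty cluster in input")
  }
  joint <- table(factor(a$cluster, levels = seq_len(ka)),
                 factor(b$cluster, levels = seq_len(kb)))
  mins <- outer(tabulate(a$cluster, ka), tabulate(b$cluster, kb), pmin)
  unclass(joint / mins)
}

#' Cell-cycle phase windows
#'
#' Hour ranges (post-release) used to label each temporal cluster with the
#' cell-cycle stage at its expression peak. The defaults follow the
#' synchronized-culture staging: G1/S 2--3.5 h, S 3.5--5.75 h, G2/M
#' 6.5--7.25 h, M 9.5--11 h, and G1 wrapping from 11 h through the end of the
#' series back to 2 h. A window whose `start` exceeds its `end` wraps.
#'
#' @return A tibble with columns `phase_label`, `start`, `end`.
#' @export
default_phase_windows <- function() {
  tibble(phase_label = c("G1/S", "S", "G2/M", "M", "G1"),
         start = c(2, 3.5, 6.5, 9.5, 11),
         end = c(3.5, 5.75, 7.25, 11, 2))
}

#' Label clusters by the cell-cycle stage of their expression peak
#'
#' @param clust a `cyclo_clusters` object.
#' @param phase_windows a tibble of windows as in [default_phase_windows()].
#' @return `clust` with `phase_label` filled in; a peak falling outside all
#'   windows is labelled `"unassigned"` with a warning.
#' @export
assign_phase_labels <- function(clust, phase_windows = default_phase_windows()) {
  stopifnot(inherits(clust, "cyclo_clusters"))
  label_one <- function(peak) {
    for (r in seq_len(nrow(phase_windows))) {
      s <- phase_windows$start[r]
      e <- phase_windows$end[r]
      hit <- if (s <= e) peak >= s & peak <= e else peak >= s | peak <= e
      if (hit) return(phase_windows$phase_label[r])
    }
    warn(sprintf("cluster peak at %.2f h falls outside all phase windows", peak))
    "unassigned"
  }
  clust$clusters$phase_label <- map_chr(clust$clusters$peak_hours, label_one)
  clust$assignment <- clust$assignment |>
    select(-dplyr::any_of("phase_label")) |>
    left_join(select(clust$clusters, "cluster", "phase_label"), by = "cluster")
  clust
}
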