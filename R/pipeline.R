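#' End-to-end pipeline configuration
#'
#' Aggregates file paths and parameters for [run_pipeline()]. Only `rep1`,
#' `rep2` and `out_dir` are required; downstream stages run when their inputs
#' are supplied (and can be forced off via `stages`). All thresholds default
#' to the values of the reference analysis: 1 tpm floor, cosine periods
#' 14--16 samples, umbrella period 16, 0.75 h interval, loose/strict cutoffs
#' 2000/800, k = 5 clusters.
#'
#' @param rep1,rep2 paths to the replicate expression TSVs.
#' @param out_dir output directory (created if needed).
#' @param stages character subset of `c("detect", "cluster", "age",
#'   "enrich", "compare")`; defaults to every stage whose inputs are present.
#' @param threshold expression floor (tpm).
#' @param params a [periodicity_params()].
#' @param rule a [selection_rule()].
#' @param k,linkage clustering settings.
#' @param phase_windows peak-time windows, as [default_phase_windows()].
#' @param tree path to a newick species tree (age stage).
#' @param orthogroups path to an OrthoFinder-style orthogroup TSV.
#' @param focal_species tip label of the focal species.
#' @param node_ages optional path to a node-to-age TSV; otherwise ages are
#'   numbered along the focal lineage.
#' @param annotation path to a two-column gene/term TSV (enrich stage).
#' @param ontology path to an OBO file.
#' @param periodic_lists named character vector of per-species periodic
#'   gene-list paths (compare stage).
#' @param seed master seed; every stochastic stage draws a named sub-seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(rep1, rep2, out_dir, stages = NULL, threshold = 1,
                            params = periodicity_params(),
                            rule = selection_rule(), k = 5,
                            linkage = "complete",
                            phase_windows = default_phase_windows(),
                            tree = NULL, orthogroups = NULL,
                            focal_species = NULL, node_ages = NULL,
                            annotation = NULL, ontology = NULL,
                            periodic_lists = NULL, seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

stage_abort <- function(stage, msg) {
  abort(paste0("stage `", stage, "` failed: ", msg), class = "cyclo_stage_error")
}

write_result_tsv <- function(x, path, settings) {
  header <- paste0("# ", paste(names(settings), unlist(lapply(settings, paste, collapse = ";")),
                               sep = "=", collapse = " "))
  writeLines(header, path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Detection (both rank tests on each replicate and their average, rank-sum
#' combination, replicate-consistency selection), temporal clustering with
#' phase labels, Dollo gene ages with per-cluster age enrichment, term
#' enrichment of each cluster against the periodic program, and cross-species
#' periodic-orthogroup overlap tests. Each stage's table is written to
#' `out_dir` with a parameter header, plus a JSON run manifest; given the
#' same config and seed the outputs are reproduced exactly.
#'
#' @param config a [pipeline_config()].
#' @return A list bundle with elements `detection`, `clusters`, `ages`,
#'   `age_enrichment`, `term_enrichment`, `overlap`, and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  have <- function(x) !is.null(x)
  stages <- cfg$stages %||% c("detect", "cluster",
                              if (have(cfg$tree) && have(cfg$orthogroups)) "age",
                              if (have(cfg$annotation) && have(cfg$ontology)) "enrich",
                              if (have(cfg$orthogroups) && have(cfg$periodic_lists)) "compare")
  bundle <- list()
  manifest <- list(seed = cfg$seed, stages = stages,
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   r_version = as.character(getRversion()),
                   settings = list(threshold = cfg$threshold,
                                   periods = cfg$params$periods,
                                   rain_period = cfg$params$rain_period,
                                   interval = cfg$params$interval,
                                   n_perm = cfg$params$n_perm,
                                   loose = cfg$rule$loose, strict = cfg$rule$strict,
                                   manual_include = cfg$rule$manual_include,
                                   k = cfg$k, linkage = cfg$linkage))

  # -- detect ---------------------------------------------------------------
  rep1 <- read_expression_tsv(cfg$rep1)
  rep2 <- read_expression_tsv(cfg$rep2)
  cfg$params$seed <- sub_seed(cfg$seed, 1L)
  det <- detect_periodic(rep1, rep2, cfg$params, cfg$rule, cfg$threshold)
  bundle$detection <- det
  write_result_tsv(det$average, file.path(cfg$out_dir, "periodicity.tsv"),
                   manifest$settings)

  # -- cluster --------------------------------------------------------------
  if ("cluster" %in% stages) {
    avg <- average_replicates(list(
      rep1[rep1$gene_id %in% det$average$gene_id, ],
      rep2[rep2$gene_id %in% det$average$gene_id, ]))
    prof <- zscore_normalize(avg[avg$gene_id %in% det$selected, ])
    cl <- hierarchical_clusters(prof, k = cfg$k, linkage = cfg$linkage) |>
      assign_phase_labels(cfg$phase_windows)
    bundle$clusters <- cl
    write_result_tsv(cl$assignment, file.path(cfg$out_dir, "clusters.tsv"),
                     manifest$settings)
    write_result_tsv(cl$profiles, file.path(cfg$out_dir, "cluster_profiles.tsv"),
                     manifest$settings)
  }

  # -- age ------------------------------------------------------------------
  if ("age" %in% stages) {
    if (!have(cfg$tree)) stage_abort("gene_age", "no species tree supplied (`tree`)")
    if (!have(cfg$orthogroups)) stage_abort("gene_age", "no orthogroup table supplied")
    if (!have(cfg$focal_species)) stage_abort("gene_age", "no focal species supplied")
    tree <- label_tree_nodes(ape::read.tree(cfg$tree))
    uni <- read_orthogroups_tsv(cfg$orthogroups)
    ages_map <- if (have(cfg$node_ages)) read_node_age_map(cfg$node_ages) else
      node_age_map(tree, cfg$focal_species)
    ages <- assign_ages(uni, tree, cfg$focal_species, ages_map,
                        all_genes = det$average$gene_id)
    bundle$ages <- ages
    if (!is.null(bundle$clusters)) {
      bundle$age_enrichment <- age_enrichment(bundle$clusters$assignment, ages,
                                              background = det$average$gene_id)
      write_result_tsv(bundle$age_enrichment,
                       file.path(cfg$out_dir, "age_enrichment.tsv"),
                       manifest$settings)
    }
  }

  # -- enrich ---------------------------------------------------------------
  if ("enrich" %in% stages) {
    if (!have(cfg$annotation) || !have(cfg$ontology)) {
      stage_abort("enrichment", "need both `annotation` and `ontology`")
    }
    ann_raw <- readr::read_tsv(cfg$annotation, col_names = c("gene_id", "term"),
                               col_types = "cc", progress = FALSE)
    ont <- read_obo(cfg$ontology)
    pop <- det$selected   # each cluster against the whole periodic program
    enr <- list()
    if (!is.null(bundle$clusters)) {
      for (cl_id in unique(bundle$clusters$assignment$cluster)) {
        genes <- bundle$clusters$assignment$gene_id[
          bundle$clusters$assignment$cluster == cl_id]
        enr[[as.character(cl_id)]] <-
          parent_child_union(genes, pop, ann_raw, ont) |>
          mutate(cluster = cl_id)
      }
    }
    bundle$term_enrichment <- bind_rows(enr)
    write_result_tsv(bundle$term_enrichment,
                     file.path(cfg$out_dir, "term_enrichment.tsv"),
                     manifest$settings)
  }

  # -- compare --------------------------------------------------------------
  if ("compare" %in% stages) {
    if (!have(cfg$orthogroups) || !have(cfg$periodic_lists)) {
      stage_abort("comparative", "need `orthogroups` and `periodic_lists`")
    }
    uni <- read_orthogroups_tsv(cfg$orthogroups)
    lists <- map(cfg$periodic_lists, read_gene_list)
    if (have(cfg$focal_species)) {
      lists[[cfg$focal_species]] <- det$selected
    }
    per_og <- imap(lists, ~ periodic_orthogroups(uni, .y, .x))
    uni_og <- map(names(lists), ~ species_orthogroups(uni, .x))
    names(uni_og) <- names(lists)
    pairs <- utils::combn(names(lists), 2, simplify = FALSE)
    bundle$overlap <- bind_rows(map(pairs, function(pr) {
      pairwise_overlap_test(per_og[[pr[1]]], per_og[[pr[2]]],
                            uni_og[[pr[1]]], uni_og[[pr[2]]], labels = pr)
    }))
    write_result_tsv(bundle$overlap, file.path(cfg$out_dir, "overlap_tests.tsv"),
                     manifest$settings)
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  manifest$outputs <- list.files(cfg$out_dir)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  bundle$manifest <- manifest
  bundle
}
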