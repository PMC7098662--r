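# Gene ages by Dollo parsimony: under a single-gain, losses-only model the
# most parsimonious origin of a gene family is the most recent common
# ancestor of the species that still possess it. Trees are `ape::phylo`
# objects; internal nodes must be (or will be) uniquely labelled.

#' Ensure every internal node of a tree is labelled
#'
#' @param tree an `ape::phylo` rooted tree.
#' @return The tree with missing internal-node labels filled as `n<number>`.
#' @export
label_tree_nodes <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  nn <- tree$Nnode
  lab <- tree$node.label %||% rep(NA_character_, nn)
  missing <- is.na(lab) | lab == ""
  lab[missing] <- paste0("n", which(missing) + length(tree$tip.label))
  if (anyDuplicated(c(tree$tip.label, lab))) abort("tree node labels are not unique")
  tree$node.label <- lab
  tree
}

node_label <- function(tree, node) {
  c(tree$tip.label, tree$node.label)[node]
}

#' Dollo-parsimony origin of a gene family
#'
#' @param presence character vector of species possessing the family.
#' @param tree a rooted, node-labelled `ape::phylo` tree (see
#'   [label_tree_nodes()]).
#' @return The label of the origin node: the MRCA of the presence set, or the
#'   leaf itself for a single-species family.
#' @export
dollo_origin <- function(presence, tree) {
  tree <- label_tree_nodes(tree)
  presence <- unique(as.character(presence))
  if (length(presence) == 0) abort("presence set is empty")
  unknown <- setdiff(presence, tree$tip.label)
  if (length(unknown) > 0) {
    abort(paste0("species not in tree: ", paste(unknown, collapse = ", ")))
  }
  if (length(presence) == 1) return(presence)
  node_label(tree, ape::getMRCA(tree, presence))
}

#' Age classes along the focal species' lineage
#'
#' Numbers the ancestors of the focal leaf from 0 (the leaf itself:
#' species-specific families) up to the root, optionally attaching named age
#' labels — for the *Capsaspora* tree these are 0 "Capsaspora-specific",
#' 1 "Filozoa", 2 "Holozoa", 3 "Opisthokonta", 4 "Unikonta",
#' 5 "Paneukaryotic".
#'
#' @param tree a rooted `ape::phylo` tree.
#' @param focal_species tip label of the focal species.
#' @param age_labels optional character vector of labels, one per age class
#'   from 0 upward.
#' @return A tibble with columns `node`, `age`, `age_label`.
#' @export
node_age_map <- function(tree, focal_species, age_labels = NULL) {
  tree <- label_tree_nodes(tree)
  if (!focal_species %in% tree$tip.label) {
    abort(paste0("focal species not in tree: ", focal_species))
  }
  tip <- match(focal_species, tree$tip.label)
  root <- length(tree$tip.label) + 1L
  path <- rev(ape::nodepath(tree, root, tip)) # tip first, root last
  ages <- seq_along(path) - 1L
  lab <- if (is.null(age_labels)) as.character(ages) else {
    if (length(age_labels) < length(path)) abort("not enough age labels for the focal lineage")
    age_labels[ages + 1L]
  }
  tibble(node = node_label(tree, path), age = ages, age_label = lab)
}

#' Assign Dollo ages to orthogroups and genes
#'
#' Every orthogroup containing the focal species is dated at the MRCA of the
#' species present in it; the focal species' member genes inherit that age.
#' Focal genes mapped to no orthogroup are age 0 (species-specific).
#' Orthogroups without a focal member carry no focal age and are skipped.
#'
#' @param universe a long orthogroup table: tibble with columns `orthogroup`,
#'   `species`, `gene_id` (see [read_orthogroups_tsv()]).
#' @param tree a rooted `ape::phylo` species tree.
#' @param focal_species tip label of the focal species.
#' @param ages a node-to-age map as from [node_age_map()].
#' @param all_genes optional character vector of the focal species' full gene
#'   set; genes absent from every orthogroup are added with age 0.
#' @return A list of class `cyclo_ages`: `orthogroups` (tibble `orthogroup`,
#'   `origin`, `age`) and `genes` (tibble `gene_id`, `orthogroup`, `age`,
#'   `age_label`).
#' @export
assign_ages <- function(universe, tree, focal_species, ages = NULL,
                        all_genes = NULL) {
  stopifnot(all(c("orthogroup", "species", "gene_id") %in% names(universe)))
  tree <- label_tree_nodes(tree)
  ages <- ages %||% node_age_map(tree, focal_species)
  og_presence <- universe |>
    distinct(.data$orthogroup, .data$species) |>
    group_by(.data$orthogroup) |>
    summarise(presence = list(.data$species), .groups = "drop")
  has_focal <- map_lgl(og_presence$presence, ~ focal_species %in% .x)
  if (any(!has_focal)) {
    inform(sprintf("%d orthogroups without a %s member were skipped",
                   sum(!has_focal), focal_species))
  }
  og_presence <- og_presence[has_focal, ]
  origin <- map_chr(og_presence$presence, dollo_origin, tree = tree)
  # the focal leaf's own label stands for age 0
  origin[origin == focal_species] <- ages$node[ages$age == 0]
  unknown <- setdiff(unique(origin), ages$node)
  if (length(unknown) > 0) {
    abort(paste0("origin nodes missing from the age map: ",
                 paste(unknown, collapse = ", ")))
  }
  og_tab <- tibble(orthogroup = og_presence$orthogroup, origin = origin) |>
    left_join(ages, by = c(origin = "node"))
  genes <- universe |>
    filter(.data$species == focal_species) |>
    select("gene_id", "orthogroup") |>
    left_join(select(og_tab, "orthogroup", "age", "age_label"), by = "orthogroup") |>
    filter(!is.na(.data$age))
  if (!is.null(all_genes)) {
    orphan <- setdiff(all_genes, genes$gene_id)
    genes <- bind_rows(genes,
                       tibble(gene_id = orphan, orthogroup = NA_character_,
                              age = 0L,
                              age_label = ages$age_label[ages$age == 0]))
  }
  if (anyDuplicated(genes$gene_id)) {
    abort("a focal gene maps to more than one orthogroup")
  }
  structure(list(orthogroups = og_tab, genes = genes), class = "cyclo_ages")
}

#' Gene-age enrichment of clusters
#'
#' For each cluster and age class, a 2x2 contingency table (in cluster or
#' not, this age or other) is tested with a two-sided Fisher exact test
#' against the background gene set; p-values are Bonferroni-corrected over
#' all cluster-by-age cells tested in the run. The enrichment ratio is the
#' cluster's frequency of the age divided by the background frequency, with
#' direction taken from the odds ratio.
#'
#' @param clusters a named list of gene-id character vectors, or a tibble
#'   with `gene_id` and `cluster` columns.
#' @param ages a `cyclo_ages` object, or a tibble with `gene_id` and `age`.
#' @param background character vector: the full gene universe the clusters
#'   are contrasted against (e.g. the whole transcriptome).
#' @return A tibble with one row per cluster x age: counts, `ratio`,
#'   `odds_ratio`, `direction`, `p_value`, `p_bonferroni`.
#' @export
age_enrichment <- function(clusters, ages, background) {
  if (is.data.frame(clusters)) {
    clusters <- split(clusters$gene_id, clusters$cluster)
  }
  if (inherits(ages, "cyclo_ages")) ages <- ages$genes
  if (any(lengths(clusters) == 0)) abort("empty cluster in input")
  age_of <- setNames(ages$age, ages$gene_id)
  if (!all(background %in% names(age_of))) {
    abort("every background gene needs an age")
  }
  bg_age <- age_of[background]
  n <- length(background)
  rows <- list()
  for (cl in names(clusters)) {
    in_cl <- background %in% clusters[[cl]]
    for (a in sort(unique(bg_age))) {
      this_age <- bg_age == a
      k11 <- sum(in_cl & this_age)
      k12 <- sum(in_cl & !this_age)
      k21 <- sum(!in_cl & this_age)
      k22 <- sum(!in_cl & !this_age)
      ft <- fisher.test(matrix(c(k11, k12, k21, k22), 2, byrow = TRUE))
      ratio <- (k11 / (k11 + k12)) / ((k11 + k21) / n)
      rows[[length(rows) + 1L]] <- tibble(
        cluster = cl, age = a,
        in_cluster = k11, cluster_other = k12,
        background_age = k11 + k21, background_total = n,
        ratio = ratio, odds_ratio = unname(ft$estimate),
        direction = ifelse(ratio >= 1, "enriched", "depleted"),
        p_value = ft$p.value)
    }
  }
  out <- bind_rows(rows)
  mutate(out, p_bonferroni = pmin(.data$p_value * nrow(out), 1))
}
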