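#' Configuration of the synthetic time-course generator
#'
#' The stated world mirrors the synchronized-culture design the analysis
#' assumes: 16 samples every 0.75 h starting 2 h after release (a window of
#' 2--13.25 h spanning one full cell cycle of roughly 11 h), two replicate
#' cultures sharing the deterministic signal but with independent noise, and
#' about 10% of genes periodic. Periodic genes follow a damped cosine —
#' amplitude decays at rate `damping_rate` per hour, emulating progressive
#' loss of synchrony — on top of a log-normal baseline, with i.i.d. Gaussian
#' noise, clipped at zero. A fraction of the non-periodic genes drift
#' linearly, to exercise specificity against monotone trends.
#'
#' @param n_genes number of genes.
#' @param periodic_fraction fraction of genes that oscillate.
#' @param n_timepoints,t_start_hours,interval_hours sampling design.
#' @param period_hours oscillation period (one cycle over the window).
#' @param damping_rate amplitude decay, per hour (>= 0). Not quantified by
#'   any measurement — a free parameter of the stated world.
#' @param noise_sd Gaussian noise standard deviation, tpm scale.
#' @param amplitude_snr oscillation amplitude as a multiple of `noise_sd`.
#' @param baseline_meanlog,baseline_sdlog log-normal baseline parameters.
#' @param drift_fraction fraction of non-periodic genes given a linear trend.
#' @param drift_snr total drift over the window, as a multiple of `noise_sd`.
#' @param replicate_count number of replicate cultures.
#' @param seed integer seed; the generator is bit-reproducible given the seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2000, periodic_fraction = 0.1,
                              n_timepoints = 16, t_start_hours = 2,
                              interval_hours = 0.75, period_hours = 11,
                              damping_rate = 0.05, noise_sd = 5,
                              amplitude_snr = 3, baseline_meanlog = log(50),
                              baseline_sdlog = 1, drift_fraction = 0.1,
                              drift_snr = 3, replicate_count = 2, seed = 1L) {
  assert_scalar_number(periodic_fraction, "periodic_fraction", 0, 1)
  assert_scalar_number(n_timepoints, "n_timepoints", min = 4)
  assert_scalar_number(interval_hours, "interval_hours", min = 1e-9)
  assert_scalar_number(damping_rate, "damping_rate", min = 0)
  assert_scalar_number(noise_sd, "noise_sd", min = 0)
  structure(as.list(environment()), class = "simulation_config")
}

#' Simulate replicate expression time courses with known ground truth
#'
#' @param config a [simulation_config()].
#' @return A list of class `cyclo_simulation`: `replicates` (list of
#'   time-course tibbles), `truth` (tibble `gene_id`, `is_periodic`,
#'   `amplitude`, `phase_hours`, `baseline`, `period_hours`, `drift`,
#'   `constant`), and `config`. Replicates share baselines, amplitudes and
#'   phases; only the noise differs.
#' @export
simulate_timecourse <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  times <- cfg$t_start_hours + cfg$interval_hours * (seq_len(cfg$n_timepoints) - 1)
  with_seed(cfg$seed, {
    n <- cfg$n_genes
    gene_id <- sprintf("g%05d", seq_len(n))
    n_per <- round(cfg$periodic_fraction * n)
    is_periodic <- seq_len(n) <= n_per   # planted first; ids are arbitrary labels
    # with zero noise the SNR is read as an absolute tpm amplitude, so a
    # noiseless world still carries its oscillation
    amp_unit <- if (cfg$noise_sd > 0) cfg$noise_sd else 1
    amplitude <- ifelse(is_periodic, cfg$amplitude_snr * amp_unit, 0)
    phase <- ifelse(is_periodic, runif(n, 0, cfg$period_hours), NA_real_)
    baseline <- rlnorm(n, cfg$baseline_meanlog, cfg$baseline_sdlog)
    window <- diff(range(times))
    drifting <- !is_periodic & (runif(n) < cfg$drift_fraction)
    drift <- ifelse(drifting,
                    sample(c(-1, 1), n, replace = TRUE) *
                      cfg$drift_snr * cfg$noise_sd / window,
                    0)
    damp <- exp(-cfg$damping_rate * (times - cfg$t_start_hours))
    signal <- baseline +
      ifelse(is_periodic, amplitude, 0) *
        cos(2 * pi * outer(ifelse(is_periodic, -phase, 0), times, `+`) /
              cfg$period_hours) *
        rep(damp, each = n) * is_periodic +
      outer(drift, times - cfg$t_start_hours)
    replicates <- lapply(seq_len(cfg$replicate_count), function(r) {
      noise <- matrix(rnorm(n * length(times), 0, cfg$noise_sd), n)
      timecourse(gene_id, pmax(signal + noise, 0), times)
    })
    truth <- tibble(gene_id = gene_id, is_periodic = is_periodic,
                    amplitude = amplitude, phase_hours = phase,
                    baseline = baseline, period_hours = cfg$period_hours,
                    drift = drift,
                    constant = cfg$noise_sd == 0 & amplitude == 0 & drift == 0)
    structure(list(replicates = replicates, truth = truth, config = cfg),
              class = "cyclo_simulation")
  })
}

#' Simulate an orthogroup universe with optional planted shared periodicity
#'
#' Under the null (`shared_periodic_excess = 0`) each species' periodic
#' labels are drawn independently, so cross-species overlap tests should be
#' calibrated. A positive excess forces that fraction of orthogroups to be
#' present and periodic in every species.
#'
#' @param n_species number of species (>= 2).
#' @param n_orthogroups number of orthogroups.
#' @param presence_prob probability an orthogroup is present in a species.
#' @param periodic_prob probability a present orthogroup is periodic in a
#'   species; recycled to `n_species`.
#' @param shared_periodic_excess fraction of orthogroups planted as periodic
#'   in all species.
#' @param seed integer seed.
#' @return A list: `universe` (long tibble `orthogroup`, `species`,
#'   `gene_id`), `periodic` (named list of periodic gene-id vectors per
#'   species), `truth` (tibble `orthogroup`, `planted_shared`).
#' @export
simulate_orthogroup_universe <- function(n_species = 5, n_orthogroups = 5000,
                                         presence_prob = 0.7,
                                         periodic_prob = 0.1,
                                         shared_periodic_excess = 0,
                                         seed = 1L) {
  if (n_species < 2) abort("need at least 2 species")
  assert_scalar_number(presence_prob, "presence_prob", 0, 1)
  assert_scalar_number(shared_periodic_excess, "shared_periodic_excess", 0, 1)
  periodic_prob <- rep_len(periodic_prob, n_species)
  stopifnot(all(periodic_prob >= 0 & periodic_prob <= 1))
  species <- sprintf("sp%d", seq_len(n_species))
  og <- sprintf("OG%06d", seq_len(n_orthogroups))
  n_shared <- round(shared_periodic_excess * n_orthogroups)
  with_seed(seed, {
    rows <- list()
    periodic <- setNames(vector("list", n_species), species)
    for (s in seq_len(n_species)) {
      present <- runif(n_orthogroups) < presence_prob
      is_per <- present & (runif(n_orthogroups) < periodic_prob[s])
      if (n_shared > 0) {
        present[seq_len(n_shared)] <- TRUE
        is_per[seq_len(n_shared)] <- TRUE
      }
      gene <- sprintf("%s_%s", species[s], og[present])
      rows[[s]] <- tibble(orthogroup = og[present], species = species[s],
                          gene_id = gene)
      periodic[[s]] <- sprintf("%s_%s", species[s], og[is_per])
    }
    list(universe = bind_rows(rows), periodic = periodic,
         truth = tibble(orthogroup = og,
                        planted_shared = seq_len(n_orthogroups) <= n_shared))
  })
}

#' Simulate a gene family's presence/absence history on a species tree
#'
#' The family originates at `origin_node` and is then lost independently
#' along each descending branch with probability `loss_prob`; a loss removes
#' the whole clade below. Branches on the path from the origin to the focal
#' species never lose the family, so it stays observable in the focal
#' species.
#'
#' @param tree a rooted `ape::phylo` tree.
#' @param origin_node label of the node (or tip) where the family arises.
#' @param focal_species tip label of the focal species; must descend from
#'   `origin_node`.
#' @param loss_prob per-branch loss probability.
#' @param seed integer seed.
#' @return A list: `presence` (character vector of tips retaining the
#'   family, always including `focal_species`) and `origin` (the recorded
#'   true origin label).
#' @export
simulate_family_history <- function(tree, origin_node, focal_species,
                                    loss_prob = 0.2, seed = 1L) {
  tree <- label_tree_nodes(tree)
  assert_scalar_number(loss_prob, "loss_prob", 0, 1)
  ntip <- length(tree$tip.label)
  labels <- c(tree$tip.label, tree$node.label)
  origin <- match(origin_node, labels)
  if (is.na(origin)) abort(paste0("origin node not in tree: ", origin_node))
  tip <- match(focal_species, tree$tip.label)
  if (is.na(tip)) abort(paste0("focal species not in tree: ", focal_species))
  protected <- if (origin == tip) tip else {
    path <- tryCatch(ape::nodepath(tree, origin, tip),
                     error = function(e) NULL)
    if (is.null(path) || path[1] != origin) {
      abort("focal species does not descend from the origin node")
    }
    path
  }
  children <- split(tree$edge[, 2], tree$edge[, 1])
  with_seed(seed, {
    presence <- character()
    recurse <- function(node) {
      if (node <= ntip) {
        presence <<- c(presence, tree$tip.label[node])
        return(invisible())
      }
      for (child in children[[as.character(node)]]) {
        lost <- !(child %in% protected) && runif(1) < loss_prob
        if (!lost) recurse(child)
      }
    }
    recurse(origin)
    list(presence = sort(presence), origin = labels[origin])
  })
}
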