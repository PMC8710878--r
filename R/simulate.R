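#' Simulate a random ultrametric tree
#'
#' Draws a random coalescent tree (which is ultrametric by construction) and
#' rescales it to unit depth. Tip labels are \code{sp01, sp02, ...}.
#'
#' @param n_species number of tips, at least 2.
#' @param seed integer seed; the same seed always yields the same tree.
#' @return a \code{phylo} object of depth 1.
#' @export
simulate_tree <- function(n_species, seed = 1L) {
  stopifnot(n_species >= 2)
  set.seed(seed)
  tree <- ape::rcoal(n_species,
                     tip.label = sprintf("sp%02d", seq_len(n_species)))
  depth <- max(tip_depths(tree))
  tree$edge.length <- tree$edge.length / depth
  tree
}

TASK_LEVELS <- c("controlled_array", "sequential", "simultaneous")

# comparison pairs common in the quantity-discrimination literature,
# ratios spanning roughly 1.1-3 so Weber fractions in [0.1, 1] are
# identifiable from accuracy
DEFAULT_PAIR_POOL <- rbind(
  c(1, 2), c(1, 3), c(2, 3), c(2, 4), c(2, 6), c(3, 4), c(3, 9),
  c(4, 5), c(4, 8), c(5, 6), c(6, 8), c(8, 10), c(9, 10), c(10, 12), c(10, 15)
)

#' Configuration for the synthetic-data generator
#'
#' Bundles the structural scale (species, studies, subjects, trials), the
#' true generative parameters and the quantity-pair pool used by
#' \code{\link{simulate_dataset}}. Defaults describe a desk-scale study: 8
#' species, 6 studies, 5 subjects per species, 50 trials per subject, grand
#' Weber fraction 0.4, moderate phylogenetic signal and realistic
#' between-study / between-subject / between-task spread on the log-w scale.
#' The \code{"paper33"} preset reproduces the structural footprint of a
#' large literature compilation — 33 species, 49 studies, 672 subjects —
#' for smoke tests at full scale.
#'
#' @param n_species,n_studies structural counts.
#' @param subjects_per_species integer range \code{c(lo, hi)}, sampled per
#'   species (or an explicit length-\code{n_species} vector).
#' @param trials_per_subject integer range \code{c(lo, hi)} (or explicit).
#' @param task_mix named proportions over the three paradigms; must sum to 1.
#' @param beta0 true grand mean of log Weber fraction.
#' @param beta1 true effect of the (standard-normal) species predictor.
#' @param lambda true phylogenetic-signal parameter in [0, 1].
#' @param sigma_species,sigma_study,sigma_subject,sigma_task true effect
#'   scales on log w.
#' @param pair_pool two-column matrix of (n1, n2) comparison pairs.
#' @param seed integer seed.
#' @param preset \code{NULL} or \code{"paper33"}.
#' @return a \code{sim_config} list.
#' @export
simulation_config <- function(n_species = 8, n_studies = 6,
                              subjects_per_species = c(5, 5),
                              trials_per_subject = c(50, 50),
                              task_mix = c(controlled_array = 0.4,
                                           sequential = 0.3,
                                           simultaneous = 0.3),
                              beta0 = log(0.4), beta1 = 0, lambda = 0.8,
                              sigma_species = 0.4, sigma_study = 0.2,
                              sigma_subject = 0.2, sigma_task = 0.15,
                              pair_pool = DEFAULT_PAIR_POOL,
                              seed = 1L, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, "paper33")
    # 33 species, 49 studies, 672 subjects: 20 subjects/species + 12 extras
    n_species <- 33
    n_studies <- 49
    subjects_per_species <- rep(20L, 33)
    subjects_per_species[seq_len(12)] <- 21L
  }
  stopifnot(n_species >= 2, n_studies >= 1,
            abs(sum(task_mix) - 1) < 1e-8,
            lambda >= 0, lambda <= 1,
            sigma_species >= 0, sigma_study >= 0,
            sigma_subject >= 0, sigma_task >= 0,
            ncol(pair_pool) == 2, all(pair_pool >= 1))
  structure(list(
    n_species = n_species, n_studies = n_studies,
    subjects_per_species = subjects_per_species,
    trials_per_subject = trials_per_subject,
    task_mix = task_mix, beta0 = beta0, beta1 = beta1, lambda = lambda,
    sigma_species = sigma_species, sigma_study = sigma_study,
    sigma_subject = sigma_subject, sigma_task = sigma_task,
    pair_pool = pair_pool, seed = as.integer(seed)
  ), class = "sim_config")
}

range_draw <- function(spec, n) {
  if (length(spec) == n && n > 2) return(as.integer(spec))
  if (length(spec) == 1L) spec <- c(spec, spec)
  vals <- seq(spec[1], spec[2])
  if (length(vals) == 1L) return(rep(as.integer(vals), n))
  sample(vals, n, replace = TRUE)
}

#' Simulate a trial table, predictor table and ground truth
#'
#' Generates data with exactly the statistical structure the hierarchical
#' model assumes. Species effects are drawn multivariate normal with
#' correlation M = lambda * V + (1 - lambda) * I scaled by
#' \code{sigma_species}; study, subject and task effects are independent
#' normals with their own scales; the per-species predictor x is standard
#' normal; each trial's log Weber fraction is
#' beta0 + beta1 * x + species + study + subject + task, and its binary
#' outcome is Bernoulli with success probability
#' \code{\link{predict_accuracy}}(n1, n2, w). Studies each carry one task
#' paradigm; subjects are nested in species (labelled
#' \code{species/subject}) and assigned to one study.
#'
#' @param tree a \code{phylo} with at least \code{config$n_species} tips
#'   (the first \code{n_species} tips are used).
#' @param config a \code{sim_config} from \code{\link{simulation_config}}.
#' @return list with \code{trials} (data frame: species, subject, study,
#'   task, n1, n2, correct), \code{predictors} (species, x), and
#'   \code{truth} (the generative parameter values, including the realized
#'   species/study/subject/task effects).
#' @export
simulate_dataset <- function(tree, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  species <- tree$tip.label[seq_len(config$n_species)]
  cov <- tree_to_correlation(tree, species)
  M <- lambda_mix(cov, config$lambda)$M
  eg <- eigen(M, symmetric = TRUE)
  L <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), nrow(M))
  u_species <- config$sigma_species * as.vector(L %*% stats::rnorm(length(species)))
  names(u_species) <- species

  x <- stats::rnorm(length(species))
  names(x) <- species

  studies <- sprintf("study%02d", seq_len(config$n_studies))
  u_study <- stats::rnorm(config$n_studies, 0, config$sigma_study)
  names(u_study) <- studies
  study_task <- sample(TASK_LEVELS, config$n_studies, replace = TRUE,
                       prob = config$task_mix)
  names(study_task) <- studies
  u_task <- stats::rnorm(3, 0, config$sigma_task)
  names(u_task) <- TASK_LEVELS

  n_subj <- range_draw(config$subjects_per_species, config$n_species)
  # spread studies over species so every study is used at least once
  rows <- list()
  u_subject <- numeric(0)
  study_cycle <- rep(studies, length.out = sum(n_subj))
  k <- 0L
  for (i in seq_along(species)) {
    for (s in seq_len(n_subj[i])) {
      k <- k + 1L
      subj <- sprintf("%s/subj%02d", species[i], s)
      study <- study_cycle[k]
      u_s <- stats::rnorm(1, 0, config$sigma_subject)
      u_subject[subj] <- u_s
      nt <- range_draw(config$trials_per_subject, 1L)
      pair <- config$pair_pool[sample.int(nrow(config$pair_pool), nt, replace = TRUE), ,
                               drop = FALSE]
      lw <- config$beta0 + config$beta1 * x[[species[i]]] + u_species[[species[i]]] +
        u_study[[study]] + u_s + u_task[[study_task[[study]]]]
      p <- predict_accuracy(pair[, 1], pair[, 2], exp(lw))
      rows[[k]] <- data.frame(
        species = species[i], subject = subj, study = study,
        task = study_task[[study]], n1 = pair[, 1], n2 = pair[, 2],
        correct = as.integer(stats::runif(nt) < p),
        stringsAsFactors = FALSE
      )
    }
  }
  trials <- do.call(rbind, rows)
  rownames(trials) <- NULL
  list(
    trials = trials,
    predictors = data.frame(species = species, x = unname(x),
                            stringsAsFactors = FALSE),
    truth = list(beta0 = config$beta0, beta1 = config$beta1,
                 lambda = config$lambda,
                 sigma_species = config$sigma_species,
                 sigma_study = config$sigma_study,
                 sigma_subject = config$sigma_subject,
                 sigma_task = config$sigma_task,
                 u_species = u_species, u_study = u_study,
                 u_subject = u_subject, u_task = u_task, x = x)
  )
}
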