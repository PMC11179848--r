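# Stochastic forward Wright-Fisher engine: the brute-force oracle for
# the transition-matrix model and the genotype source for synthetic
# cohorts. Sites are unlinked; one RNG stream per run, controlled by
# `seed`.

#' Simulate one site forward through a demographic trajectory
#'
#' Per generation: deterministic selection update of the derived
#' frequency (same formula as [wf_transition_matrix()]), then
#' `Binomial(2N, q')` sampling of the next-generation copy count. At an
#' epoch boundary the current count is resampled into the new `2N` by
#' one generation of binomial sampling.
#'
#' @param j0 Initial derived copy count, `0 <= j0 <= 2N` of the first
#'   epoch.
#' @param traj A [demographic_trajectory()].
#' @param sc A [selection_class()] (only `s` and `h` are used).
#' @param seed Optional integer seed.
#' @return A list of class `site_trajectory`: `counts` (copy count per
#'   generation, starting at `j0`), `N` (size per generation),
#'   `absorbed` (`"lost"`, `"fixed"`, or `"segregating"`), `seed`.
#' @export
simulate_site <- function(j0, traj, sc, seed = NULL) {
  stopifnot(is_demographic_trajectory(traj), inherits(sc, "selection_class"))
  if (!is.null(seed)) set.seed(seed)
  N0 <- traj$N[1L]
  if (!is.finite(j0) || j0 < 0 || j0 > 2 * N0 || j0 != round(j0)) {
    stop("`j0` must be an integer in [0, 2N] of the first epoch",
         call. = FALSE)
  }
  j <- as.integer(j0)
  counts <- integer(sum(traj$duration) + 1L)
  sizes <- integer(length(counts))
  counts[1L] <- j
  sizes[1L] <- N0
  t <- 1L
  N_cur <- N0
  for (e in seq_len(nrow(traj))) {
    N_new <- traj$N[e]
    if (N_new != N_cur) {
      j <- stats::rbinom(1L, 2L * N_new, j / (2 * N_cur))
      N_cur <- N_new
    }
    for (g in seq_len(traj$duration[e])) {
      if (j > 0L && j < 2L * N_cur) {
        qp <- wf_selection_update(j / (2 * N_cur), sc$s, sc$h)
        j <- stats::rbinom(1L, 2L * N_cur, qp)
      }
      t <- t + 1L
      counts[t] <- j
      sizes[t] <- N_cur
    }
  }
  absorbed <- if (j == 0L) "lost" else if (j == 2L * N_cur) "fixed"
              else "segregating"
  structure(list(counts = counts[seq_len(t)], N = sizes[seq_len(t)],
                 absorbed = absorbed, seed = seed),
            class = "site_trajectory")
}

#' Monte-Carlo estimate of the equilibrium segregating burden
#'
#' Independent oracle for [msd_equilibrium()]. Because the stationary
#' segregating density is the superposition of all past injection
#' cohorts, the equilibrium burden per diploid genome satisfies
#' `n_seg = 2 lam E[S]`, where `S = sum_t j_t` is the copy count of a
#' single new mutation (entering at one copy) summed over its
#' segregating lifetime. Each replicate simulates one mutation's
#' Wright-Fisher lifetime at constant size `N`; the fraction of
#' replicates absorbed at `2N` estimates the fixation probability.
#'
#' @param N Diploid population size.
#' @param sc A [selection_class()].
#' @param reps Number of replicate mutation lifetimes (`>= 1000`
#'   recommended for stable standard errors).
#' @param seed Optional integer seed.
#' @param max_gen Safety cap on lifetime length (default `1000 + 800 N`,
#'   far beyond the neutral conditional fixation time `~4N`). Unabsorbed
#'   replicates at the cap are counted with their accumulated sum and
#'   flagged.
#' @return A list: `n_seg` and `n_seg_se` (mean and Monte-Carlo SE),
#'   `p_fix` and `p_fix_se`, `reps`, `unabsorbed`, `seed`.
#' @export
sim_equilibrium_burden <- function(N, sc, reps = 10000, seed = NULL,
                                   max_gen = NULL) {
  stopifnot(inherits(sc, "selection_class"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(max_gen)) max_gen <- 1000 + 800 * N
  two_n <- 2L * N
  j <- rep(1L, reps)
  S <- numeric(reps)
  fixed <- logical(reps)
  active <- seq_len(reps)
  gen <- 0L
  while (length(active) > 0L && gen < max_gen) {
    S[active] <- S[active] + j[active]
    qp <- wf_selection_update(j[active] / two_n, sc$s, sc$h)
    j[active] <- stats::rbinom(length(active), two_n, qp)
    fixed[active[j[active] == two_n]] <- TRUE
    active <- active[j[active] > 0L & j[active] < two_n]
    gen <- gen + 1L
  }
  unabsorbed <- length(active)
  if (unabsorbed > 0L) {
    warning(unabsorbed, " replicate(s) still segregating at the ",
            max_gen, "-generation cap; burden slightly underestimated")
  }
  contrib <- 2 * sc$lam * S
  list(n_seg = mean(contrib),
       n_seg_se = stats::sd(contrib) / sqrt(reps),
       p_fix = mean(fixed),
       p_fix_se = stats::sd(fixed) / sqrt(reps),
       reps = reps, unabsorbed = unabsorbed, seed = seed)
}

#' Stochastic burden trajectory for replicate populations
#'
#' Forward-simulates whole populations of unlinked sites: standing
#' variation is initialized by Poisson-sampling site counts from the
#' matrix MSD equilibrium density at the ancestral size, and
#' `Poisson(2 N lam)` new mutations enter at one copy each generation.
#' Reports the mean and Monte-Carlo standard error across replicate
#' populations of the per-individual segregating burden
#' `sum(j) / N` and of the fixed burden (net of the ancestral
#' equilibrium fixation flux, as in [evolve_burden()]).
#'
#' @param traj A [demographic_trajectory()].
#' @param sc A [selection_class()].
#' @param reps Number of replicate populations.
#' @param seed Optional integer seed.
#' @param record_every Record one time point every this many
#'   generations (default auto, at most ~500 rows).
#' @param max_states Guard for the matrix equilibrium used to
#'   initialize standing variation.
#' @return A tibble with columns `generation`, `time_before_present`,
#'   `N`, `n_seg`, `n_seg_se`, `n_fixed`, `n_fixed_se`, `n_total`,
#'   `n_total_se`.
#' @export
simulate_burden <- function(traj, sc, reps = 20, seed = NULL,
                            record_every = NULL,
                            max_states = .GENLOAD_MAX_STATES) {
  stopifnot(is_demographic_trajectory(traj), inherits(sc, "selection_class"))
  if (!is.null(seed)) set.seed(seed)
  eq <- msd_equilibrium(ancestral_N(traj), sc, max_states = max_states)
  total_gen <- sum(traj$duration)
  if (is.null(record_every)) {
    record_every <- max(1L, ceiling(total_gen / 500))
  }
  rec_gens <- seq(0L, total_gen, by = record_every)
  nseg_mat <- matrix(NA_real_, length(rec_gens), reps)
  nfix_mat <- matrix(NA_real_, length(rec_gens), reps)
  N_at <- integer(length(rec_gens))

  for (r in seq_len(reps)) {
    N_cur <- eq$N
    # Poisson realization of the equilibrium density: site counts per bin
    n_per_bin <- stats::rpois(length(eq$mass), eq$mass)
    j <- rep.int(seq_along(eq$mass), n_per_bin)
    fixed_cum <- 0
    gen <- 0L
    ri <- 1L
    nseg_mat[1L, r] <- sum(j) / N_cur
    nfix_mat[1L, r] <- 0
    N_at[1L] <- N_cur
    for (e in seq_len(nrow(traj))) {
      N_new <- traj$N[e]
      if (N_new != N_cur) {
        if (length(j)) {
          j <- stats::rbinom(length(j), 2L * N_new, j / (2 * N_cur))
          fixed_cum <- fixed_cum + sum(j == 2L * N_new)
          j <- j[j > 0L & j < 2L * N_new]
        }
        N_cur <- N_new
      }
      for (g in seq_len(traj$duration[e])) {
        if (length(j)) {
          qp <- wf_selection_update(j / (2 * N_cur), sc$s, sc$h)
          j <- stats::rbinom(length(j), 2L * N_cur, qp)
          fixed_cum <- fixed_cum + sum(j == 2L * N_cur)
          j <- j[j > 0L & j < 2L * N_cur]
        }
        j <- c(j, rep.int(1L, stats::rpois(1L, 2 * N_cur * sc$lam)))
        gen <- gen + 1L
        if (gen %% record_every == 0L) {
          ri <- ri + 1L
          nseg_mat[ri, r] <- sum(j) / N_cur
          nfix_mat[ri, r] <- 2 * (fixed_cum - eq$fix_flux * gen)
          N_at[ri] <- N_cur
        }
      }
    }
  }
  se <- function(m) apply(m, 1L, stats::sd) / sqrt(reps)
  out <- tibble::tibble(
    generation = rec_gens,
    time_before_present = total_gen - rec_gens,
    N = N_at,
    n_seg = rowMeans(nseg_mat),
    n_seg_se = se(nseg_mat),
    n_fixed = rowMeans(nfix_mat),
    n_fixed_se = se(nfix_mat)
  )
  out$n_total <- out$n_seg + out$n_fixed
  out$n_total_se <- sqrt(out$n_seg_se^2 + out$n_fixed_se^2)
  out
}

#' Simulate terminal allele frequencies and diploid genotypes
#'
#' Genotype source for synthetic cohorts. For each selection class, a
#' budget of sites is drawn from the segregating MSD equilibrium
#' density at the ancestral size, each site is forward-simulated
#' through the remaining epochs of the trajectory, and diploid
#' genotypes are drawn as `Binomial(2, q)` per individual
#' (Hardy-Weinberg within the terminal population). Sites fixed or
#' lost along the way keep `q = 1` / `q = 0`.
#'
#' @param traj A [demographic_trajectory()].
#' @param classes A named list of [selection_class()] objects; names
#'   are effect-class labels.
#' @param site_budgets Named integer vector (same names as `classes`):
#'   number of sites per class.
#' @param n_individuals Number of diploid individuals to genotype.
#' @param seed Optional integer seed.
#' @param max_states Guard for the matrix equilibrium.
#' @return A list: `sites` (tibble with `effect_class`, `q`), and
#'   `genotypes` (integer matrix, sites x individuals, values 0/1/2).
#' @export
simulate_diploid_cohort <- function(traj, classes, site_budgets,
                                    n_individuals, seed = NULL,
                                    max_states = .GENLOAD_MAX_STATES) {
  stopifnot(is_demographic_trajectory(traj))
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(names(site_budgets) %in% names(classes)))
  q_list <- list()
  class_list <- list()
  for (cl in names(site_budgets)) {
    n_sites <- site_budgets[[cl]]
    if (n_sites <= 0) next
    sc <- classes[[cl]]
    q_list[[cl]] <- simulate_class_frequencies(traj, sc, n_sites,
                                               max_states = max_states)
    class_list[[cl]] <- rep(cl, n_sites)
  }
  q <- unlist(q_list, use.names = FALSE)
  sites <- tibble::tibble(
    effect_class = unlist(class_list, use.names = FALSE),
    q = q
  )
  geno <- matrix(
    stats::rbinom(length(q) * n_individuals, 2L, rep(q, n_individuals)),
    nrow = length(q), ncol = n_individuals
  )
  list(sites = sites, genotypes = geno)
}

# Terminal frequencies of `n_sites` segregating-at-equilibrium sites
# pushed through the trajectory's post-ancestral epochs. Uses the
# current RNG stream (no seed argument; callers seed once).
simulate_class_frequencies <- function(traj, sc, n_sites,
                                       max_states = .GENLOAD_MAX_STATES) {
  eq <- msd_equilibrium(ancestral_N(traj), sc, max_states = max_states)
  probs <- eq$mass / sum(eq$mass)
  j <- sample.int(length(eq$mass), n_sites, replace = TRUE, prob = probs)
  N_cur <- eq$N
  # the first epoch is the equilibrium epoch itself: the sampled counts
  # already represent its stationary state, so evolution starts at the
  # first size change
  for (e in seq_len(nrow(traj))[-1L]) {
    N_new <- traj$N[e]
    if (N_new != N_cur) {
      j <- stats::rbinom(n_sites, 2L * N_new, j / (2 * N_cur))
      N_cur <- N_new
    }
    two_n <- 2L * N_cur
    for (g in seq_len(traj$duration[e])) {
      seg <- j > 0L & j < two_n
      if (!any(seg)) break
      qp <- wf_selection_update(j[seg] / two_n, sc$s, sc$h)
      j[seg] <- stats::rbinom(sum(seg), two_n, qp)
    }
  }
  j / (2 * N_cur)
}
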