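# Deterministic Wright-Fisher transition-matrix engine.
#
# State space: derived-copy counts j = 0..2N in a diploid population of
# size N. Counts 0 and 2N are absorbing (loss / fixation). All burden
# quantities are densities per unit mutational influx and are exactly
# linear in lam.

# Default guard on dense matrix size (number of states 2N + 1).
.GENLOAD_MAX_STATES <- 4001L

# session cache for equilibrium solves (deterministic; keyed on all
# inputs) -- repeated cohort generation reuses them
.eq_cache <- new.env(parent = emptyenv())

#' Deterministic selection update of the derived allele frequency
#'
#' One generation of viability selection with genotype fitnesses
#' 1, 1 - hs, 1 - s. In the random-mating case (`F = 0`), with `q` the
#' derived frequency and `p = 1 - q`, the marginal fitnesses are
#' `w_der = p (1 - hs) + q (1 - s)` and `w_anc = p + q (1 - hs)`, and
#' the post-selection frequency is `q' = q w_der / w_bar` with
#' `w_bar = p w_anc + q w_der`. With population inbreeding `F > 0`,
#' genotype frequencies follow the inbred Hardy-Weinberg proportions
#' `p^2 + Fpq`, `2pq(1 - F)`, `q^2 + Fpq`: autozygosity exposes
#' recessive alleles as homozygotes, which is the engine of genetic
#' purging under inbreeding.
#'
#' @param q Derived allele frequency (vectorized).
#' @param s,h Selection and dominance coefficients.
#' @param F Population inbreeding coefficient in `[0, 1]` (default 0,
#'   random mating).
#' @return Post-selection derived frequency `q'`.
#' @export
wf_selection_update <- function(q, s, h, F = 0) {
  p <- 1 - q
  if (F == 0) {
    w_der <- p * (1 - h * s) + q * (1 - s)
    w_anc <- p + q * (1 - h * s)
    w_bar <- p * w_anc + q * w_der
    if (any(w_bar <= 0)) {
      stop("mean fitness is non-positive at some frequency; invalid (s, h)",
           call. = FALSE)
    }
    return(q * w_der / w_bar)
  }
  stopifnot(F >= 0, F <= 1)
  f_het <- 2 * p * q * (1 - F)
  f_hom <- q^2 + F * p * q
  w_bar <- 1 - f_het * h * s - f_hom * s
  if (any(w_bar <= 0)) {
    stop("mean fitness is non-positive at some frequency; invalid (s, h, F)",
         call. = FALSE)
  }
  (f_hom * (1 - s) + 0.5 * f_het * (1 - h * s)) / w_bar
}

#' Wright-Fisher transition matrix with selection and dominance
#'
#' Row `j` (copy count `j`, `j = 0..2N`) holds Binomial(2N, q')
#' probabilities over next-generation counts, where `q'` is the
#' deterministic selection update of `q = j / 2N`. States 0 and 2N are
#' absorbing.
#'
#' @param N Diploid population size (`N >= 2`).
#' @param sc A [selection_class()].
#' @param max_states Guard on the dense matrix dimension; populations
#'   with `2N + 1` states above this must go through
#'   [rescale_scenario()] or the stochastic simulator.
#' @param F Population inbreeding coefficient passed to
#'   [wf_selection_update()] (default 0).
#' @return A dense `(2N + 1) x (2N + 1)` row-stochastic matrix.
#' @examples
#' T <- wf_transition_matrix(5, selection_class(0.1, 0.25))
#' all.equal(rowSums(T), rep(1, 11))
#' @export
wf_transition_matrix <- function(N, sc, max_states = .GENLOAD_MAX_STATES,
                                 F = 0) {
  stopifnot(inherits(sc, "selection_class"))
  N <- .check_N(N, max_states)
  two_n <- 2L * N
  # the boundary states are absorbing by construction; the selection
  # update is only evaluated on interior states (at q = 1 with s = 1
  # mean fitness is zero, but the state never leaves anyway)
  q <- (1:(two_n - 1L)) / two_n
  qp <- wf_selection_update(q, sc$s, sc$h, F)
  Tm <- matrix(0, two_n + 1L, two_n + 1L)
  for (j in seq_len(two_n - 1L)) {
    Tm[j + 1L, ] <- stats::dbinom(0:two_n, two_n, qp[j])
  }
  Tm[1L, 1L] <- 1
  Tm[two_n + 1L, two_n + 1L] <- 1
  Tm
}

.check_N <- function(N, max_states = .GENLOAD_MAX_STATES) {
  if (!is.finite(N) || N < 2 || N != round(N)) {
    stop("`N` must be an integer >= 2", call. = FALSE)
  }
  if (2 * N + 1 > max_states) {
    stop("2N + 1 = ", 2 * N + 1, " states exceeds the dense-matrix guard (",
         max_states, "); rescale the scenario (see rescale_scenario()) or ",
         "use the stochastic simulator", call. = FALSE)
  }
  as.integer(N)
}

#' Fixation probability from each segregating copy count
#'
#' Absorption probability into the fixed state `j = 2N`, solved from the
#' transition matrix by `(I - T_tt) u = t_fix` on the transient states.
#' For `s = 0` the classical result `u(j) = j / 2N` holds exactly.
#'
#' @inheritParams wf_transition_matrix
#' @return Numeric vector `u` of length `2N - 1`; `u[j]` is the fixation
#'   probability from `j` copies, `j = 1..2N-1`.
#' @export
fixation_probability <- function(N, sc, max_states = .GENLOAD_MAX_STATES) {
  N <- .check_N(N, max_states)
  Tm <- wf_transition_matrix(N, sc, max_states)
  idx <- 2:(2L * N)                       # transient states 1..2N-1
  Ttt <- Tm[idx, idx, drop = FALSE]
  tfix <- Tm[idx, 2L * N + 1L]
  as.vector(solve(diag(nrow(Ttt)) - Ttt, tfix))
}

#' Mutation-selection-drift equilibrium of the segregating density
#'
#' Stationary density of segregating derived-copy counts under a
#' constant influx of `2 N lam` new mutations per generation, each
#' entering at copy count 1 (`lam` is the haploid genomic influx of the
#' class). Solved directly as `(I - t(T_tt)) m = influx e_1` on the
#' transient states; a damped fixed-point iteration is available as a
#' fallback.
#'
#' @inheritParams wf_transition_matrix
#' @param influx Total new mutations entering the population per
#'   generation. Defaults to `2 * N * sc$lam` (the genomic convention);
#'   pass `2 * N * u` for a per-site interpretation with per-site
#'   mutation rate `u`.
#' @param method `"solve"` (direct, default) or `"iterate"` (fixed
#'   point, relative tolerance 1e-10, capped at 1e6 generations).
#' @return An object of class `allele_frequency_state`: list with
#'   elements `N`, `mass` (density over counts `1..2N-1`), `fixed_mass`,
#'   `lost_mass` (both 0 at equilibrium by convention), `fix_flux` and
#'   `lost_flux` (per-generation absorption fluxes at equilibrium),
#'   `influx`, `n_seg` (expected segregating derived alleles per diploid
#'   genome, `sum(j * mass) / N`), and `sc`.
#' @examples
#' eq <- msd_equilibrium(100, selection_class(0.01, 0.25))
#' eq$n_seg
#' @export
msd_equilibrium <- function(N, sc, influx = NULL,
                            method = c("solve", "iterate"),
                            max_states = .GENLOAD_MAX_STATES) {
  method <- match.arg(method)
  N <- .check_N(N, max_states)
  stopifnot(inherits(sc, "selection_class"))
  if (is.null(influx)) influx <- 2 * N * sc$lam
  key <- paste(N, sc$s, sc$h, influx, method, sep = "|")
  if (!is.null(.eq_cache[[key]])) return(.eq_cache[[key]])
  Tm <- wf_transition_matrix(N, sc, max_states)
  idx <- 2:(2L * N)
  Ttt <- Tm[idx, idx, drop = FALSE]
  tfix <- Tm[idx, 2L * N + 1L]
  tlost <- Tm[idx, 1L]
  b <- c(influx, rep(0, length(idx) - 1L))
  if (method == "solve") {
    m <- as.vector(solve(diag(length(idx)) - t(Ttt), b))
  } else {
    m <- b
    tol <- 1e-10
    cap <- 1e6
    Tt <- t(Ttt)
    for (it in seq_len(cap)) {
      m_new <- as.vector(Tt %*% m) + b
      if (max(abs(m_new - m)) <= tol * max(m_new, 1e-300)) {
        m <- m_new
        break
      }
      m <- m_new
      if (it == cap) {
        stop("msd_equilibrium: fixed-point iteration did not converge in ",
             format(cap, scientific = FALSE), " generations (N = ", N,
             ", s = ", sc$s, ", h = ", sc$h, ")", call. = FALSE)
      }
    }
  }
  if (min(m) < -1e-9 * max(m)) {
    stop("msd_equilibrium: negative stationary mass; numerical failure",
         call. = FALSE)
  }
  m <- pmax(m, 0)
  j <- seq_along(idx)                     # copy counts 1..2N-1
  res <- structure(
    list(N = N, mass = m,
         fixed_mass = 0, lost_mass = 0,
         fix_flux = sum(m * tfix), lost_flux = sum(m * tlost),
         influx = influx,
         n_seg = sum(j * m) / N,
         mean_frequency = sum(j * m) / (2 * N),
         sc = sc),
    class = "allele_frequency_state")
  .eq_cache[[key]] <- res
  res
}

#' Equilibrium mean derived frequency at a recurrently mutating site
#'
#' Stationary mean derived allele frequency of a single site under
#' Wright-Fisher sampling, selection, and two-way mutation at rate `u`
#' per allele copy per generation. Unlike the linear-influx density of
#' [msd_equilibrium()] (which superposes independent mutation lineages
#' and is the right object for genome-wide burdens at small per-site
#' rates), this chain treats the site's total frequency as one Markov
#' state, so it remains exact when the equilibrium frequency is not
#' small. In the deterministic limit the mean approaches `u / (h s)`
#' for partially dominant selection (`4 N h s >> 1`) and `sqrt(u / s)`
#' for fully recessive selection (`h = 0`, `4 N s >> 1`, weak drift at
#' the balance frequency).
#'
#' @inheritParams wf_transition_matrix
#' @param u Per-site mutation rate per generation (applied
#'   symmetrically in both directions, which regularizes the boundaries
#'   without affecting the balance frequency when `u` is small relative
#'   to selection).
#' @return Mean derived allele frequency under the stationary
#'   distribution.
#' @export
equilibrium_mean_frequency <- function(N, sc, u,
                                       max_states = .GENLOAD_MAX_STATES) {
  stopifnot(inherits(sc, "selection_class"))
  N <- .check_N(N, max_states)
  if (!is.finite(u) || u <= 0 || u >= 0.5) {
    stop("`u` must lie in (0, 0.5)", call. = FALSE)
  }
  two_n <- 2L * N
  q <- (0:two_n) / two_n
  qp <- wf_selection_update(q, sc$s, sc$h)
  qm <- qp * (1 - u) + (1 - qp) * u
  P <- matrix(0, two_n + 1L, two_n + 1L)
  for (j in 0:two_n) {
    P[j + 1L, ] <- stats::dbinom(0:two_n, two_n, qm[j + 1L])
  }
  # stationary distribution: t(P) pi = pi with sum(pi) = 1
  A <- t(P) - diag(two_n + 1L)
  A[two_n + 1L, ] <- 1
  b <- c(rep(0, two_n), 1)
  pi_st <- solve(A, b)
  sum(q * pi_st)
}

#' Evolve the deleterious burden along a demographic trajectory
#'
#' Starting from the MSD equilibrium at the ancestral size, iterates the
#' Wright-Fisher transition matrix one generation at a time, injecting
#' `2 N lam` new mutations per generation, and remapping the copy-count
#' density by binomial resampling whenever the population size changes.
#' Reports, per recorded generation:
#' \describe{
#'   \item{n_seg}{expected segregating derived alleles per diploid
#'     genome, `sum(j * mass_j) / N`.}
#'   \item{n_fixed}{expected derived alleles per genome from sites fixed
#'     since the start, net of the ancestral equilibrium fixation flux
#'     (2 copies per fixed site; the constant ancestral flux is
#'     subtracted so the pre-decline baseline is flat and changes
#'     reflect demography).}
#'   \item{n_total}{`n_seg + n_fixed`.}
#' }
#'
#' @param eq An [msd_equilibrium()] state built at the trajectory's
#'   ancestral size with the same selection class.
#' @param traj A [demographic_trajectory()].
#' @param sc The [selection_class()] used to build `eq`.
#' @param record_every Record one row every this many generations
#'   (default auto: at most ~2000 rows).
#' @param max_states Dense-matrix guard, as in [wf_transition_matrix()].
#' @return A tibble of class `burden_prediction` with columns
#'   `generation` (forward time, 0 = start of the ancestral epoch),
#'   `time_before_present` (descending to 0), `N`, `n_seg`, `n_fixed`,
#'   `n_total`. Attribute `conservation_error` holds the maximum
#'   relative mass-conservation error observed.
#' @export
evolve_burden <- function(eq, traj, sc, record_every = NULL,
                          max_states = .GENLOAD_MAX_STATES) {
  stopifnot(inherits(eq, "allele_frequency_state"),
            is_demographic_trajectory(traj),
            inherits(sc, "selection_class"))
  if (eq$N != ancestral_N(traj)) {
    stop("`eq` was built at N = ", eq$N, " but the trajectory's ancestral ",
         "size is ", ancestral_N(traj), call. = FALSE)
  }
  if (!isTRUE(all.equal(c(eq$sc$s, eq$sc$h), c(sc$s, sc$h)))) {
    stop("`eq` was built with a different selection class", call. = FALSE)
  }
  total_gen <- sum(traj$duration)
  if (is.null(record_every)) {
    record_every <- max(1L, ceiling(total_gen / 2000))
  }

  m <- eq$mass
  N_cur <- eq$N
  baseline_flux <- eq$fix_flux
  fixed_cum <- 0
  lost_cum <- 0
  injected_cum <- 0
  seg0 <- sum(m)                      # standing mass at t = 0
  cons_err <- 0

  op <- .wf_operators(N_cur, sc, max_states)
  n_rows <- floor(total_gen / record_every) + 1L
  rec <- matrix(NA_real_, n_rows, 4L)  # generation, N, n_seg, n_fixed
  jvec <- seq_len(2L * N_cur - 1L)
  rec[1L, ] <- c(0, N_cur, sum(jvec * m) / N_cur, 0)
  row_i <- 1L
  gen <- 0L

  for (e in seq_len(nrow(traj))) {
    N_new <- traj$N[e]
    if (N_new != N_cur) {
      remap <- .remap_mass(m, N_cur, N_new)
      fixed_cum <- fixed_cum + remap$fixed
      lost_cum <- lost_cum + remap$lost
      m <- remap$mass
      N_cur <- N_new
      op <- .wf_operators(N_cur, sc, max_states)
      jvec <- seq_len(2L * N_cur - 1L)
    }
    influx <- 2 * N_cur * sc$lam
    for (g in seq_len(traj$duration[e])) {
      fixed_cum <- fixed_cum + sum(m * op$tfix)
      lost_cum <- lost_cum + sum(m * op$tlost)
      m <- as.vector(op$Tt %*% m)
      m[1L] <- m[1L] + influx
      injected_cum <- injected_cum + influx
      gen <- gen + 1L
      tot_in <- seg0 + injected_cum
      cons_err <- max(cons_err,
                      abs(sum(m) + fixed_cum + lost_cum - tot_in) / tot_in)
      if (gen %% record_every == 0L) {
        row_i <- row_i + 1L
        rec[row_i, ] <- c(gen, N_cur, sum(jvec * m) / N_cur,
                          2 * (fixed_cum - baseline_flux * gen))
      }
    }
  }

  out <- tibble::tibble(
    generation = rec[seq_len(row_i), 1L],
    time_before_present = total_gen - rec[seq_len(row_i), 1L],
    N = rec[seq_len(row_i), 2L],
    n_seg = rec[seq_len(row_i), 3L],
    n_fixed = rec[seq_len(row_i), 4L]
  )
  out$n_total <- out$n_seg + out$n_fixed
  structure(out,
            class = c("burden_prediction", class(out)),
            conservation_error = cons_err,
            trajectory = trajectory_name(traj),
            s = sc$s, h = sc$h, lam = sc$lam)
}

# Terminal copy-count density (per unit lam) of mutations arising
# after the ancestral epoch: starts from zero mass and injects
# 2 N per generation through the post-ancestral epochs. Deterministic;
# cached (the generator reuses it across seeds). Also accumulates the
# fixed mass (sites fixed by the end).
.terminal_influx_density <- function(traj, sc, F = 0,
                                     max_states = .GENLOAD_MAX_STATES) {
  key <- paste("influx", rlang::hash(list(traj$N, traj$duration,
                                          sc$s, sc$h, F)), sep = "|")
  if (!is.null(.eq_cache[[key]])) return(.eq_cache[[key]])
  N_cur <- ancestral_N(traj)
  m <- numeric(2L * N_cur - 1L)
  fixed <- 0
  op <- NULL
  for (e in seq_len(nrow(traj))[-1L]) {
    N_new <- traj$N[e]
    if (N_new != N_cur) {
      r <- .remap_mass(m, N_cur, N_new)
      m <- r$mass
      fixed <- fixed + r$fixed
      N_cur <- N_new
      op <- NULL
    }
    if (is.null(op)) op <- .wf_operators(N_cur, sc, max_states, F)
    for (g in seq_len(traj$duration[e])) {
      fixed <- fixed + sum(m * op$tfix)
      m <- as.vector(op$Tt %*% m)
      m[1L] <- m[1L] + 2 * N_cur
    }
  }
  res <- list(mass = m, fixed = fixed, N = N_cur)
  .eq_cache[[key]] <- res
  res
}

# Transposed transient block and absorption columns for one size.
.wf_operators <- function(N, sc, max_states = .GENLOAD_MAX_STATES, F = 0) {
  Tm <- wf_transition_matrix(N, sc, max_states, F)
  idx <- 2:(2L * N)
  list(Tt = t(Tm[idx, idx, drop = FALSE]),
       tfix = Tm[idx, 2L * N + 1L],
       tlost = Tm[idx, 1L])
}

# Binomial resampling of a copy-count density from size N_old to N_new:
# each old count j (frequency q = j / 2N_old) is redrawn as
# Binomial(2N_new, q) -- one generation of sampling into the new
# population. Mass landing on 0 / 2N_new is absorbed.
.remap_mass <- function(m, N_old, N_new) {
  q <- seq_len(2L * N_old - 1L) / (2 * N_old)
  two_new <- 2L * N_new
  # R[j, k] = P(old count j -> new count k), k = 0..2N_new
  R <- outer(q, 0:two_new, function(qq, k) stats::dbinom(k, two_new, qq))
  w <- as.vector(m %*% R)
  list(mass = w[2:two_new], lost = w[1L], fixed = w[two_new + 1L])
}

#' Rescale a scenario to a smaller population size
#'
#' Divides every epoch size by `c = max(N) / target_max_N`, multiplies
#' `s` and `lam` by `c`, and divides durations by `c`, preserving the
#' diffusion-scale quantities (`4 N s`, durations in units of `N`
#' generations, per-epoch total influx) so that `n_seg` and `n_fixed`
#' trajectories are approximately invariant. The approximation degrades
#' as scaled `s` approaches 1 (selection per generation is no longer
#' weak) or scaled `N` becomes small (boundary effects).
#'
#' @param traj A [demographic_trajectory()].
#' @param sc A [selection_class()].
#' @param target_max_N Desired maximum diploid size after rescaling.
#' @return A list with elements `traj`, `sc`, and `report` (a list with
#'   the factor `c` and the scaled parameters).
#' @examples
#' rs <- rescale_scenario(demographic_trajectory(c(5000, 500), c(100, 100)),
#'                        selection_class(0.01, 0.25), target_max_N = 500)
#' rs$report$factor  # 10
#' @export
rescale_scenario <- function(traj, sc, target_max_N) {
  stopifnot(is_demographic_trajectory(traj), inherits(sc, "selection_class"))
  cfac <- max(traj$N) / target_max_N
  if (cfac <= 1) {
    return(list(traj = traj, sc = sc,
                report = list(factor = 1, s = sc$s, lam = sc$lam,
                              note = "no rescaling needed")))
  }
  s_new <- sc$s * cfac
  if (s_new > 1 || s_new * sc$h > 1) {
    stop("rescaling factor ", cfac, " would push s to ", s_new,
         " (> 1); choose a larger target_max_N", call. = FALSE)
  }
  N_new <- pmax(2L, as.integer(round(traj$N / cfac)))
  dur_new <- pmax(1L, as.integer(round(traj$duration / cfac)))
  traj_new <- demographic_trajectory(
    N_new, dur_new, name = paste0(trajectory_name(traj), "_x", cfac))
  sc_new <- selection_class(s_new, sc$h, sc$lam * cfac)
  list(traj = traj_new, sc = sc_new,
       report = list(
         factor = cfac, s = s_new, lam = sc_new$lam,
         note = paste0("4Ns preserved; durations in units of N generations ",
                       "preserved; expect O(s') per-generation selection ",
                       "error with s' = ", signif(s_new, 3))))
}

#' Burden predictions over a grid of selection parameters
#'
#' Runs [evolve_burden()] for every combination of trajectory, `s`, and
#' `h`. Defaults follow the standard deleterious-class grid: weakly
#' (s = 0.001), mildly (s = 0.01), and strongly (s = 0.1) deleterious
#' effects crossed with highly recessive (h = 0.05), partially
#' recessive (h = 0.25), and roughly additive (h = 0.45) dominance,
#' at haploid genomic influx `lam = 1`.
#'
#' @param trajectories A named list of [demographic_trajectory()]s (a
#'   single trajectory is accepted).
#' @param s_values,h_values Grids of selection and dominance
#'   coefficients.
#' @param lam Haploid genomic influx (predictions are linear in `lam`).
#' @param record_every Passed to [evolve_burden()].
#' @param max_states Dense-matrix guard.
#' @return A long tibble with columns `trajectory`, `s`, `h`,
#'   `generation`, `time_before_present`, `log10_gen_bp`
#'   (`log10(time_before_present)`, `NA` at 0), `N`, `n_seg`,
#'   `n_fixed`, `n_total`.
#' @export
predict_grid <- function(trajectories,
                         s_values = c(0.001, 0.01, 0.1),
                         h_values = c(0.05, 0.25, 0.45),
                         lam = 1,
                         record_every = NULL,
                         max_states = .GENLOAD_MAX_STATES) {
  if (is_demographic_trajectory(trajectories)) {
    trajectories <- stats::setNames(list(trajectories),
                                    trajectory_name(trajectories))
  }
  if (is.null(names(trajectories))) {
    names(trajectories) <- vapply(trajectories, trajectory_name, "")
  }
  out <- list()
  for (tn in names(trajectories)) {
    traj <- trajectories[[tn]]
    for (s in s_values) {
      # one equilibrium per (s, h); reuse across nothing else
      for (h in h_values) {
        sc <- selection_class(s, h, lam)
        eq <- msd_equilibrium(ancestral_N(traj), sc, max_states = max_states)
        bp <- evolve_burden(eq, traj, sc, record_every = record_every,
                            max_states = max_states)
        bp$trajectory <- tn
        bp$s <- s
        bp$h <- h
        out[[length(out) + 1L]] <- tibble::as_tibble(bp)
      }
    }
  }
  res <- dplyr::bind_rows(out)
  res$log10_gen_bp <- ifelse(res$time_before_present > 0,
                             log10(res$time_before_present), NA_real_)
  dplyr::select(res, "trajectory", "s", "h", "generation",
                "time_before_present", "log10_gen_bp", "N",
                "n_seg", "n_fixed", "n_total")
}

#' Convert generations before present to years
#'
#' Presentation helper: the model's time axis is in generations; the
#' calendar axis uses a generation time `g` (default 50 years, a
#' long-lived conifer).
#'
#' @param generations Generations before present.
#' @param g Generation time in years.
#' @return Years before present.
#' @export
generations_to_years <- function(generations, g = 50) {
  generations * g
}
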