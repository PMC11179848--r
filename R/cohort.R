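# Synthetic cohort generator: fully specified diploid test cohorts with
# recorded ground truth (frequencies, effect classes, outgroup alleles,
# implanted autozygous tracts, missingness), standing in for real
# resequencing data so every downstream stage is testable.

#' Default two-cohort generator configuration
#'
#' Desk-scale emulation of a rare/widespread species pair: a
#' "rare" cohort of 32 individuals whose population declined through a
#' long bottleneck and never recovered, and a "widespread" cohort of 51
#' individuals whose population recovered after the shared ancestral
#' decline. Both cohorts descend from a common ancestral equilibrium at
#' `N = 1000`, so between-cohort contrasts reflect their divergent
#' recent histories. Purging in the rare cohort is driven primarily by
#' its higher population inbreeding coefficient (`inbreeding = 0.25`
#' vs 0.05), which exposes recessive deleterious alleles as
#' (auto)homozygotes in the frequency dynamics; the decline epochs are
#' long relative to the purging timescale `1/(s(h + F(1-h)))` but
#' moderate relative to neutral drift `4N`, the regime in which the
#' deleterious-to-synonymous burden ratio falls in the declining
#' population.
#'
#' Effect classes and their `(s, h)`: synonymous (0, 0.5; neutral),
#' tolerated (0.001, 0.35), deleterious (0.1, 0.05; strongly recessive),
#' lof (0.3, 0.02; severe and nearly fully recessive). Site budgets are
#' the expected number of segregating sites of a class in the ancestral
#' equilibrium population; post-split mutational influx is scaled
#' consistently (see [generate_cohort()]). Defaults give ~4-7 variant
#' rows per kb so that individual heterozygous-site density suffices
#' for ROH inference. Implanted autozygosity targets average 0.22 of
#' the genome for the rare cohort and 0.12 for the widespread one (the
#' contrast observed between inbred rare conifers and widespread
#' relatives), with per-individual spread so inbreeding varies within
#' cohorts.
#'
#' @param n_rare,n_widespread Cohort sizes.
#' @param contig_length,n_contigs Contig layout (default 4 x 5 Mb;
#'   per-base-normalized statistics make absolute scale irrelevant, so
#'   the genome is kept small while the variant density is kept
#'   realistic for ROH work).
#' @param site_budgets Named vector of per-class ancestral segregating
#'   site counts.
#' @param missing_rate Missing-genotype rate (missing completely at
#'   random).
#' @param outgroup_divergence Per-outgroup-branch substitution
#'   probability used to mutate the true ancestral allele into each of
#'   the two outgroup alleles.
#' @param roh_het_error Heterozygote error rate inside implanted
#'   autozygous tracts.
#' @return A config list understood by [generate_cohort()].
#' @export
default_cohort_config <- function(n_rare = 32L, n_widespread = 51L,
                                  contig_length = 5e6, n_contigs = 4L,
                                  site_budgets = c(synonymous = 60000L,
                                                   tolerated = 25000L,
                                                   deleterious = 30000L,
                                                   lof = 10000L),
                                  missing_rate = 0.02,
                                  outgroup_divergence = 0.05,
                                  roh_het_error = 0.001) {
  list(
    populations = list(
      rare = list(
        species = "rare", n = n_rare,
        trajectory = demographic_trajectory(
          N = c(1000L, 400L, 150L), duration = c(50L, 800L, 150L),
          name = "rare"),
        inbreeding = 0.25,
        f_roh_range = c(0.15, 0.29)
      ),
      widespread = list(
        species = "widespread", n = n_widespread,
        trajectory = demographic_trajectory(
          N = c(1000L, 700L, 1000L), duration = c(50L, 800L, 150L),
          name = "widespread"),
        inbreeding = 0.05,
        f_roh_range = c(0.05, 0.19)
      )
    ),
    classes = list(
      synonymous = selection_class(0, 0.5),
      tolerated = selection_class(0.001, 0.35),
      deleterious = selection_class(0.1, 0.05),
      lof = selection_class(0.3, 0.02)
    ),
    site_budgets = site_budgets,
    contigs = tibble::tibble(
      name = paste0("ctg", seq_len(n_contigs)),
      length = rep(contig_length, n_contigs)
    ),
    missing_rate = missing_rate,
    outgroup_divergence = outgroup_divergence,
    # implant minimum sits above the 100 kb ROH retention threshold so
    # that truth tracts cannot straddle the caller boundary class
    roh = list(min_length = 1.5e5, mean_length = 5e5, max_length = 3e6,
               het_error = roh_het_error, exposure_gens = 10)
  )
}

#' Generate a synthetic diploid cohort with ground truth
#'
#' Per-site derived-allele frequencies come from two sources, mirroring
#' how standing variation is actually composed:
#' \itemize{
#'   \item \emph{Ancestral standing sites} (one per unit of the class
#'     budget) have initial copy counts sampled from the shared
#'     ancestral MSD equilibrium density and are forward-simulated
#'     (stochastic Wright-Fisher) through each population's trajectory,
#'     so the two cohorts are correlated at these shared sites.
#'   \item \emph{Post-split mutations} arise along each trajectory at
#'     the class's implied influx rate (`budget / equilibrium
#'     segregating count`, so budgets and influx are consistent);
#'     their terminal copy-count distribution is computed exactly with
#'     the transition-matrix engine (influx-only density), and a
#'     Poisson-realized number of private sites is sampled from it for
#'     each population.
#' }
#' Sites lost everywhere are dropped. Genotypes are Hardy-Weinberg
#' within each population; autozygous (ROH) tracts are then implanted
#' to per-individual target fractions ([implant_roh()]); two outgroup
#' allele columns substitute the true ancestral allele with probability
#' `outgroup_divergence` independently per outgroup; finally
#' missing-completely-at-random genotype dropout is applied.
#' Deterministic given `(config, seed)`.
#'
#' @param config A config list as produced by [default_cohort_config()].
#' @param seed Integer seed.
#' @return An object of class `cohort_dataset`: a list with elements
#'   `contigs`, `sites`, `genotypes` (sites x individuals integer
#'   matrix, `NA` = missing), `individuals`, and `truth` (list:
#'   `seed`, `config`, `q` per population, implanted `roh` tibble,
#'   achieved per-individual `f_roh`).
#' @export
generate_cohort <- function(config = default_cohort_config(), seed = 1L) {
  stopifnot(is.list(config), length(config$populations) >= 1)
  if (any(config$contigs$length <= 0)) {
    stop("config error: zero-length contig", call. = FALSE)
  }
  budgets <- config$site_budgets
  if (any(budgets < 0) || sum(budgets) < 1) {
    stop("config error: infeasible site budgets", call. = FALSE)
  }
  if (!all(names(budgets) %in% names(config$classes))) {
    stop("config error: site budget for unknown class", call. = FALSE)
  }
  set.seed(seed)

  anc_N <- vapply(config$populations,
                  function(p) ancestral_N(p$trajectory), integer(1))
  if (length(unique(anc_N)) != 1) {
    stop("config error: populations must share the ancestral size ",
         "(they descend from one equilibrium)", call. = FALSE)
  }
  pops <- names(config$populations)
  eqs <- lapply(config$classes[names(budgets)], function(sc) {
    msd_equilibrium(anc_N[[1]], sc)
  })

  # ancestral standing sites: shared origin, independent evolution
  effect_class <- rep(names(budgets), budgets)
  n_stand <- length(effect_class)
  j0 <- integer(n_stand)
  for (cl in names(budgets)) {
    idx <- which(effect_class == cl)
    probs <- eqs[[cl]]$mass / sum(eqs[[cl]]$mass)
    j0[idx] <- sample.int(length(probs), length(idx),
                          replace = TRUE, prob = probs)
  }
  q_pop <- lapply(pops, function(pn) {
    pop <- config$populations[[pn]]
    q <- numeric(n_stand)
    for (cl in names(budgets)) {
      idx <- which(effect_class == cl)
      q[idx] <- .evolve_counts(j0[idx], pop$trajectory,
                               config$classes[[cl]],
                               F = pop$inbreeding %||% 0)
    }
    q
  })
  names(q_pop) <- pops

  # post-split private mutations, sampled from the exact influx-only
  # terminal density of each (class, trajectory)
  for (pn in pops) {
    pop <- config$populations[[pn]]
    for (cl in names(budgets)) {
      sc <- config$classes[[cl]]
      lam_cl <- budgets[[cl]] / sum(eqs[[cl]]$mass)
      dens <- .terminal_influx_density(pop$trajectory, sc,
                                       F = pop$inbreeding %||% 0)
      expected <- lam_cl * dens$mass
      n_new <- stats::rpois(1L, sum(expected))
      n_fix <- stats::rpois(1L, lam_cl * dens$fixed)
      if (n_new + n_fix == 0L) next
      qn <- if (n_new > 0L) {
        sample.int(length(expected), n_new, replace = TRUE,
                   prob = expected / sum(expected)) / (2 * dens$N)
      } else numeric(0)
      qn <- c(qn, rep(1, n_fix))
      n_new <- n_new + n_fix
      effect_class <- c(effect_class, rep(cl, n_new))
      for (p2 in pops) {
        q_pop[[p2]] <- c(q_pop[[p2]], if (p2 == pn) qn else numeric(n_new))
      }
    }
  }
  n_sites <- length(effect_class)

  # drop sites lost in every population (not variants)
  alive <- Reduce(`+`, q_pop) > 0
  effect_class <- effect_class[alive]
  q_pop <- lapply(q_pop, function(q) q[alive])
  n_sites <- sum(alive)

  # coordinates: sites spread over contigs proportionally to length
  contigs <- config$contigs
  contig_of <- sample(rep(seq_len(nrow(contigs)),
                          times = .round_budget(contigs$length, n_sites)))
  pos <- integer(n_sites)
  for (ci in seq_len(nrow(contigs))) {
    idx <- which(contig_of == ci)
    # unsorted draw: site identity (standing vs private) must be
    # independent of coordinate; rows are sorted afterwards
    pos[idx] <- sample.int(contigs$length[ci], length(idx))
  }
  ord <- order(contig_of, pos)
  contig_of <- contig_of[ord]
  pos <- pos[ord]
  effect_class <- effect_class[ord]
  for (pn in names(q_pop)) q_pop[[pn]] <- q_pop[[pn]][ord]

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  anc <- ref  # derived allele is ALT by construction; recorded as truth
  out1 <- .mutate_outgroup(anc, config$outgroup_divergence)
  out2 <- .mutate_outgroup(anc, config$outgroup_divergence)

  individuals <- dplyr::bind_rows(lapply(names(config$populations),
    function(pn) {
      pop <- config$populations[[pn]]
      tibble::tibble(
        id = sprintf("%s_%02d", pn, seq_len(pop$n)),
        population = pn, species = pop$species)
    }))

  geno <- matrix(NA_integer_, n_sites, nrow(individuals),
                 dimnames = list(NULL, individuals$id))
  for (pn in names(config$populations)) {
    cols <- which(individuals$population == pn)
    q <- q_pop[[pn]]
    geno[, cols] <- stats::rbinom(n_sites * length(cols), 2L,
                                  rep(q, length(cols)))
  }

  sites <- tibble::tibble(
    site_id = seq_len(n_sites),
    contig = contigs$name[contig_of],
    pos = pos,
    ref = unname(ref), alt = unname(alt),
    effect_class = effect_class,
    anc_truth = unname(anc),
    out1 = out1, out2 = out2
  )

  dataset <- structure(
    list(contigs = contigs, sites = sites, genotypes = geno,
         individuals = individuals,
         truth = list(seed = seed, config = config, q = q_pop,
                      roh = tibble::tibble(individual = character(),
                                           contig = character(),
                                           start = integer(),
                                           end = integer()),
                      f_roh = stats::setNames(rep(0, nrow(individuals)),
                                              individuals$id))),
    class = "cohort_dataset")

  # implant autozygous tracts to per-individual targets
  targets <- numeric(nrow(individuals))
  for (pn in names(config$populations)) {
    cols <- which(individuals$population == pn)
    rng <- config$populations[[pn]]$f_roh_range %||% c(0, 0)
    targets[cols] <- stats::runif(length(cols), rng[1], rng[2])
  }
  dataset <- implant_roh(dataset, targets,
                         min_length = config$roh$min_length,
                         mean_length = config$roh$mean_length,
                         max_length = config$roh$max_length,
                         het_error = config$roh$het_error,
                         exposure_gens = config$roh$exposure_gens %||% 10)

  # missingness last (missing completely at random)
  if (config$missing_rate > 0) {
    drop <- stats::runif(length(dataset$genotypes)) < config$missing_rate
    dataset$genotypes[drop] <- NA_integer_
  }
  validate_cohort(dataset)
  dataset
}

# forward-simulate copy counts through post-ancestral epochs (current
# RNG stream)
.evolve_counts <- function(j, traj, sc, F = 0) {
  N_cur <- ancestral_N(traj)
  for (e in seq_len(nrow(traj))[-1L]) {
    N_new <- traj$N[e]
    if (N_new != N_cur) {
      j <- stats::rbinom(length(j), 2L * N_new, j / (2 * N_cur))
      N_cur <- N_new
    }
    two_n <- 2L * N_cur
    for (g in seq_len(traj$duration[e])) {
      seg <- j > 0L & j < two_n
      if (!any(seg)) break
      qp <- wf_selection_update(j[seg] / two_n, sc$s, sc$h, F)
      j[seg] <- stats::rbinom(sum(seg), two_n, qp)
    }
  }
  j / (2 * N_cur)
}

.round_budget <- function(weights, total) {
  raw <- weights / sum(weights) * total
  n <- floor(raw)
  rem <- total - sum(n)
  if (rem > 0) {
    extra <- order(raw - n, decreasing = TRUE)[seq_len(rem)]
    n[extra] <- n[extra] + 1L
  }
  as.integer(n)
}

.mutate_outgroup <- function(anc, divergence) {
  bases <- c("A", "C", "G", "T")
  hit <- stats::runif(length(anc)) < divergence
  out <- anc
  if (any(hit)) {
    out[hit] <- vapply(anc[hit],
                       function(b) sample(setdiff(bases, b), 1L), "")
  }
  out
}

#' Implant autozygous (ROH) tracts into a cohort
#'
#' For each individual, draws non-overlapping genomic intervals
#' (lengths exponential with mean `mean_length`, truncated to
#' `[min_length, max_length]`; contigs chosen proportionally to length)
#' until the covered genome fraction reaches the individual's target;
#' the final tract is trimmed so the achieved fraction lands on the
#' target (up to the minimum tract length).
#' Inside each tract, genotypes are forced homozygous: the shared
#' allele is derived with probability
#' `q (1-s)^G / (q (1-s)^G + 1-q)`, where `G = exposure_gens` is the
#' effective number of generations the tract lineage has been exposed
#' to homozygous selection (a tract is identical by descent from an
#' ancestor ~tract-age generations back, and a derived homozygote must
#' have survived viability selection in every one of them; `G` is a
#' conservative effective value, since mutation also arises within the
#' tract lineage). Autozygosity thus depletes deleterious derived
#' homozygotes inside tracts relative to Hardy-Weinberg; for neutral
#' classes the probability reduces to `q`. With probability
#' `het_error` a tract genotype is left heterozygous instead (caller
#' error knob). Truth intervals (1-based inclusive) and achieved
#' fractions are recorded.
#'
#' @param dataset A `cohort_dataset`.
#' @param targets Per-individual target genome fractions in `[0, 0.9]`
#'   (recycled if length 1).
#' @param min_length,mean_length,max_length Tract length distribution
#'   in bp.
#' @param het_error Per-site heterozygote error rate inside tracts.
#' @param exposure_gens Effective generations of homozygous selection
#'   inside tracts (default 10).
#' @param max_tries Placement attempts per individual before giving up
#'   (a warning reports the achieved fraction).
#' @return The dataset with modified genotypes and `truth$roh`,
#'   `truth$f_roh` filled in.
#' @export
implant_roh <- function(dataset, targets, min_length = 1e5,
                        mean_length = 4e5, max_length = 3e6,
                        het_error = 0.001, exposure_gens = 10,
                        max_tries = 2000L) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  n_ind <- nrow(dataset$individuals)
  targets <- rep_len(targets, n_ind)
  if (any(targets < 0 | targets > 0.9)) {
    stop("ROH targets must lie in [0, 0.9]", call. = FALSE)
  }
  genome_len <- sum(dataset$contigs$length)
  site_contig <- dataset$sites$contig
  site_pos <- dataset$sites$pos
  cls <- dataset$sites$effect_class
  s_of_class <- vapply(dataset$truth$config$classes, `[[`, numeric(1), "s")

  # per-site derived frequency within the individual's own population
  pop_of <- dataset$individuals$population
  roh_rows <- list()
  achieved <- numeric(n_ind)

  for (i in seq_len(n_ind)) {
    if (targets[i] <= 0) next
    q <- dataset$truth$q[[pop_of[i]]]
    ivs <- list()
    covered <- 0
    tries <- 0L
    while (covered / genome_len < targets[i] && tries < max_tries) {
      tries <- tries + 1L
      ci <- sample.int(nrow(dataset$contigs), 1L,
                       prob = dataset$contigs$length)
      len <- round(min(max(stats::rexp(1L, 1 / mean_length), min_length),
                       max_length))
      # trim the final tract so the achieved fraction lands on target
      remaining <- round(targets[i] * genome_len - covered)
      if (len > remaining && remaining >= min_length) len <- remaining
      if (len >= dataset$contigs$length[ci]) next
      start <- sample.int(dataset$contigs$length[ci] - len, 1L)
      end <- start + len - 1L
      cname <- dataset$contigs$name[ci]
      # keep a 50 kb buffer between tracts so that implanted tracts
      # remain individually resolvable (adjacent real ROH would merge)
      clash <- any(vapply(ivs, function(iv) {
        iv$contig == cname && iv$start <= end + 5e4 &&
          iv$end >= start - 5e4
      }, logical(1)))
      if (clash) next
      ivs[[length(ivs) + 1L]] <- list(contig = cname, start = start,
                                      end = end)
      covered <- covered + len

      in_iv <- which(site_contig == cname & site_pos >= start &
                       site_pos <= end)
      if (length(in_iv)) {
        qq <- q[in_iv]
        s_site <- s_of_class[cls[in_iv]]
        w <- (1 - s_site)^exposure_gens
        p_der <- qq * w / (qq * w + (1 - qq))
        g <- 2L * stats::rbinom(length(in_iv), 1L, p_der)
        err <- stats::runif(length(in_iv)) < het_error
        g[err] <- 1L
        dataset$genotypes[in_iv, i] <- g
      }
    }
    achieved[i] <- covered / genome_len
    if (achieved[i] < targets[i] - 0.01) {
      warning("individual ", dataset$individuals$id[i],
              ": reached F_ROH ", signif(achieved[i], 3),
              " of target ", signif(targets[i], 3))
    }
    if (length(ivs)) {
      roh_rows[[length(roh_rows) + 1L]] <- tibble::tibble(
        individual = dataset$individuals$id[i],
        contig = vapply(ivs, `[[`, "", "contig"),
        start = vapply(ivs, function(x) as.integer(x$start), integer(1)),
        end = vapply(ivs, function(x) as.integer(x$end), integer(1))
      )
    }
  }
  dataset$truth$roh <- if (length(roh_rows)) dplyr::bind_rows(roh_rows)
                       else dataset$truth$roh
  dataset$truth$f_roh <- stats::setNames(achieved, dataset$individuals$id)
  dataset$truth$roh_params <- list(min_length = min_length,
                                   mean_length = mean_length,
                                   max_length = max_length,
                                   het_error = het_error,
                                   exposure_gens = exposure_gens,
                                   targets = targets)
  dataset
}

#' Validate a cohort dataset's structural invariants
#'
#' Checks: positions strictly increasing within each contig; genotype
#' matrix dimensions consistent with sites and individuals; genotype
#' values in `{0, 1, 2, NA}`; effect classes partition sites; every
#' implanted ROH interval is free of heterozygous genotypes beyond the
#' stated error rate.
#'
#' @param dataset A `cohort_dataset`.
#' @param het_tol Tolerated heterozygote fraction inside truth tracts
#'   (default 0.05: far above binomial noise around the error knob in
#'   short tracts, far below the ~0.2 typical of non-autozygous
#'   sequence, so only structural violations trip it).
#' @return Invisibly `TRUE`; stops with a message on violation.
#' @export
validate_cohort <- function(dataset, het_tol = NULL) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  s <- dataset$sites
  for (cn in unique(s$contig)) {
    p <- s$pos[s$contig == cn]
    if (any(diff(p) <= 0)) {
      stop("positions not strictly increasing on ", cn, call. = FALSE)
    }
  }
  if (nrow(dataset$genotypes) != nrow(s) ||
      ncol(dataset$genotypes) != nrow(dataset$individuals)) {
    stop("genotype matrix dimensions inconsistent", call. = FALSE)
  }
  g <- dataset$genotypes
  if (!all(g[!is.na(g)] %in% 0:2)) {
    stop("genotypes outside {0, 1, 2, NA}", call. = FALSE)
  }
  if (!all(s$effect_class %in% names(dataset$truth$config$classes))) {
    stop("unknown effect class present", call. = FALSE)
  }
  if (is.null(het_tol)) {
    eps <- dataset$truth$roh_params$het_error %||% 0.001
    het_tol <- max(20 * eps, 0.05)
  }
  roh <- dataset$truth$roh
  if (nrow(roh)) {
    for (k in seq_len(nrow(roh))) {
      i <- match(roh$individual[k], dataset$individuals$id)
      idx <- which(s$contig == roh$contig[k] & s$pos >= roh$start[k] &
                     s$pos <= roh$end[k])
      gg <- g[idx, i]
      gg <- gg[!is.na(gg)]
      if (length(gg) >= 50 && mean(gg == 1L) > het_tol) {
        stop("ROH tract ", k, " of ", roh$individual[k],
             " contains heterozygote fraction ", signif(mean(gg == 1L), 3),
             call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("<cohort_dataset>", nrow(x$sites), "sites x",
      nrow(x$individuals), "individuals;",
      nrow(x$contigs), "contigs (",
      format(sum(x$contigs$length), big.mark = ","), "bp );",
      nrow(x$truth$roh), "implanted ROH tracts; seed",
      x$truth$seed, "\n")
  invisible(x)
}
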