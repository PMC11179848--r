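#' Piecewise-constant demographic trajectory
#'
#' A demographic trajectory is an ordered list of epochs, each with a
#' constant diploid effective population size `N` held for `duration`
#' generations. The first epoch is the ancestral equilibrium epoch: the
#' population is assumed to sit at mutation-selection-drift (MSD)
#' equilibrium at that size before the remaining epochs unfold.
#'
#' @param N Integer vector of diploid effective sizes, one per epoch
#'   (all `>= 2`).
#' @param duration Integer vector of epoch durations in generations
#'   (all `>= 1`). The first entry is the number of generations the
#'   ancestral epoch is run for in [evolve_burden()] (the state is
#'   already at equilibrium, so this simply extends the flat baseline).
#' @param name Optional trajectory label carried into output tables.
#'
#' @return An object of class `demographic_trajectory`: a tibble with
#'   columns `epoch`, `N`, `duration`, plus attributes `ancestral_N`
#'   and `name`.
#'
#' @examples
#' # equilibrium at N = 500, then a 10-fold bottleneck held 300 generations
#' demographic_trajectory(N = c(500, 50), duration = c(100, 300))
#' @export
demographic_trajectory <- function(N, duration, name = "trajectory") {
  if (length(N) != length(duration) || length(N) < 1) {
    stop("`N` and `duration` must be non-empty vectors of equal length",
         call. = FALSE)
  }
  if (any(!is.finite(N)) || any(N < 2) || any(N != round(N))) {
    stop("all epoch sizes `N` must be integers >= 2", call. = FALSE)
  }
  if (any(!is.finite(duration)) || any(duration < 1) ||
      any(duration != round(duration))) {
    stop("all epoch `duration`s must be integers >= 1", call. = FALSE)
  }
  out <- tibble::tibble(
    epoch = seq_along(N),
    N = as.integer(N),
    duration = as.integer(duration)
  )
  structure(out,
            class = c("demographic_trajectory", class(out)),
            ancestral_N = as.integer(N[[1]]),
            name = name)
}

#' @rdname demographic_trajectory
#' @param x Object to test or print.
#' @export
is_demographic_trajectory <- function(x) {
  inherits(x, "demographic_trajectory")
}

#' Read a trajectory from a plain-text epoch table
#'
#' Expects a whitespace- or tab-delimited file with a header and columns
#' `epoch`, `N`, `duration` (generations). Demography inferred by
#' coalescent tools must be discretized by the user into such epochs.
#'
#' @param path File path.
#' @param name Trajectory label; defaults to the file name.
#' @return A [demographic_trajectory()].
#' @export
read_trajectory <- function(path, name = NULL) {
  tab <- utils::read.table(path, header = TRUE)
  need <- c("epoch", "N", "duration")
  if (!all(need %in% names(tab))) {
    stop("trajectory table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tab <- tab[order(tab$epoch), , drop = FALSE]
  demographic_trajectory(tab$N, tab$duration,
                         name = name %||% basename(path))
}

ancestral_N <- function(traj) attr(traj, "ancestral_N")
trajectory_name <- function(traj) attr(traj, "name") %||% "trajectory"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Selection class of a mutation category
#'
#' Bundles the homozygous selection coefficient `s`, the dominance
#' coefficient `h`, and the haploid genomic mutation influx `lam`
#' (new mutations per haploid genome per generation) for one category
#' of mutations. Genotype fitnesses are 1, 1 - hs, 1 - s for the
#' ancestral homozygote, heterozygote, and derived homozygote.
#'
#' @param s Homozygous deleterious effect, `0 <= s <= 1`.
#' @param h Dominance coefficient, `0 <= h <= 1`.
#' @param lam Haploid genomic influx of new mutations per generation
#'   (default 1). All burden predictions are linear in `lam`.
#' @return An object of class `selection_class` (a named list).
#' @examples
#' selection_class(s = 0.1, h = 0.05)
#' @export
selection_class <- function(s, h, lam = 1) {
  if (!is.finite(s) || s < 0 || s > 1) {
    stop("`s` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.finite(h) || h < 0 || h > 1) {
    stop("`h` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.finite(lam) || lam < 0) stop("`lam` must be >= 0", call. = FALSE)
  if (1 - h * s < 0 || 1 - s < 0) {
    stop("fitnesses 1 - hs and 1 - s must be nonnegative", call. = FALSE)
  }
  structure(list(s = s, h = h, lam = lam), class = "selection_class")
}

#' Inbreeding-purging coefficient
#'
#' The per-copy purging strength `d = s (1 - 2h) / 2` summarizing how
#' much more strongly a partially recessive deleterious allele is
#' selected against when exposed as a homozygote under inbreeding.
#' Additive mutations (h = 0.5) have `d = 0`; fully recessive ones have
#' `d = s / 2`. Exposed as a diagnostic; the burden predictions
#' themselves use full Wright-Fisher numerics.
#'
#' @param sc A [selection_class()].
#' @return The dimensionless purging coefficient `d`.
#' @examples
#' purging_coefficient(selection_class(0.1, 0))    # 0.05
#' purging_coefficient(selection_class(0.1, 0.5))  # 0
#' @export
purging_coefficient <- function(sc) {
  stopifnot(inherits(sc, "selection_class"))
  sc$s * (1 - 2 * sc$h) / 2
}
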