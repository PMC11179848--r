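# Runs of homozygosity: a two-state (autozygous / non-autozygous)
# hidden Markov model over per-site genotype emissions, decoded by
# Viterbi, plus the F_ROH genomic inbreeding coefficient.

#' Detect runs of homozygosity per individual
#'
#' Two-state HMM along each contig. Emissions: a heterozygous genotype
#' has probability `eps` in the autozygous state (the error knob) and
#' `2 p q` (Hardy-Weinberg, from empirical population allele
#' frequencies at the site, floored at `het_floor`) in the
#' non-autozygous state; missing genotypes emit nothing but still
#' accumulate transition distance. Transitions are distance-dependent:
#' switching probability `1 - exp(-rate * d)` per direction over `d`
#' bp, with separate rates out of (`rate_out`, ~1 / expected tract
#' length) and into (`rate_in`, controls the autozygosity prior)
#' autozygous state. Viterbi segments spanning first to last autozygous
#' site are reported; segments shorter than `min_length` are dropped
#' and the `> 1 Mb` subclass (recent inbreeding) is labeled.
#'
#' @param dataset A `cohort_dataset` (sites must be position-sorted
#'   within contigs; [validate_cohort()] guarantees this for generated
#'   data).
#' @param min_length Minimum retained segment length in bp (default
#'   100 kb).
#' @param eps Heterozygote emission probability inside autozygous
#'   tracts.
#' @param rate_out Per-bp switch rate autozygous -> non-autozygous
#'   (default `2e-6`, mean tract ~500 kb).
#' @param rate_in Per-bp switch rate non-autozygous -> autozygous
#'   (default `5e-7`; stationary autozygosity prior
#'   `rate_in / (rate_in + rate_out)` = 0.2).
#' @param het_floor Floor on the non-autozygous heterozygote emission
#'   probability (guards monomorphic-in-population sites).
#' @param long_threshold Length above which a segment is labeled as
#'   the recent-inbreeding class (default 1 Mb).
#' @return A tibble of segments: `individual`, `population`, `contig`,
#'   `start`, `end` (bp, 1-based inclusive), `length`, `n_sites`,
#'   `long` (`TRUE` if `length > long_threshold`).
#' @export
detect_roh <- function(dataset, min_length = 1e5, eps = 0.001,
                       rate_out = 2e-6, rate_in = 5e-7,
                       het_floor = 1e-3, long_threshold = 1e6) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  inds <- dataset$individuals
  g <- dataset$genotypes
  # HW heterozygote probability per site within each population
  phet <- matrix(NA_real_, nrow(g), nrow(inds))
  for (pn in unique(inds$population)) {
    cols <- which(inds$population == pn)
    gp <- g[, cols, drop = FALSE]
    n_allele <- 2 * rowSums(!is.na(gp))
    p <- rowSums(gp, na.rm = TRUE) / pmax(n_allele, 1L)
    phet[, cols] <- pmax(2 * p * (1 - p), het_floor)
  }

  segs <- list()
  for (ci in seq_len(nrow(dataset$contigs))) {
    cn <- dataset$contigs$name[ci]
    rows <- which(dataset$sites$contig == cn)
    if (length(rows) < 2) next
    pos <- dataset$sites$pos[rows]
    if (is.unsorted(pos, strictly = TRUE)) {
      stop("sites are not position-sorted on ", cn, call. = FALSE)
    }
    n_sites <- length(rows)
    n_ind <- nrow(inds)
    gg <- g[rows, , drop = FALSE]
    ph <- phet[rows, , drop = FALSE]
    het <- gg == 1L
    # log emissions; 0 for missing genotypes (no information)
    eA <- ifelse(is.na(het), 0, ifelse(het, log(eps), log1p(-eps)))
    eN <- ifelse(is.na(het), 0, ifelse(het, log(ph), log1p(-ph)))

    d <- diff(pos)
    p_out <- -expm1(-rate_out * d)   # A -> N
    p_in <- -expm1(-rate_in * d)     # N -> A
    lAA <- log1p(-p_out); lAN <- log(p_out)
    lNA <- log(p_in); lNN <- log1p(-p_in)

    prior_a <- rate_in / (rate_in + rate_out)
    vA <- log(prior_a) + eA[1L, ]
    vN <- log1p(-prior_a) + eN[1L, ]
    bpA <- matrix(FALSE, n_sites, n_ind)  # TRUE: predecessor was A
    bpN <- matrix(FALSE, n_sites, n_ind)
    for (t in 2:n_sites) {
      fromA <- vA + lAA[t - 1L]
      fromN <- vN + lNA[t - 1L]
      bpA[t, ] <- fromA >= fromN
      vA_new <- pmax(fromA, fromN) + eA[t, ]
      fromA2 <- vA + lAN[t - 1L]
      fromN2 <- vN + lNN[t - 1L]
      bpN[t, ] <- fromA2 > fromN2
      vN <- pmax(fromA2, fromN2) + eN[t, ]
      vA <- vA_new
    }
    state <- matrix(FALSE, n_sites, n_ind)  # TRUE = autozygous
    state[n_sites, ] <- vA > vN
    for (t in n_sites:2) {
      st <- state[t, ]
      state[t - 1L, ] <- ifelse(st, bpA[t, ], bpN[t, ])
    }

    for (i in seq_len(n_ind)) {
      r <- rle(state[, i])
      ends_idx <- cumsum(r$lengths)
      starts_idx <- ends_idx - r$lengths + 1L
      auto <- which(r$values)
      if (!length(auto)) next
      # the true breakpoint lies between the boundary autozygous site
      # and its non-autozygous neighbour: extend to the midpoint
      # (unbiased segment length instead of a half-gap shortfall per
      # edge); runs are separated by >= 1 site, so no overlap arises
      si <- starts_idx[auto]
      ei <- ends_idx[auto]
      prev_gap <- ifelse(si > 1L, pos[si] - pos[pmax(si - 1L, 1L)], 0L)
      next_gap <- ifelse(ei < n_sites,
                         pos[pmin(ei + 1L, n_sites)] - pos[ei], 0L)
      st_pos <- pos[si] - floor(prev_gap / 2)
      en_pos <- pos[ei] + floor(next_gap / 2)
      len <- en_pos - st_pos + 1L
      keep <- len >= min_length
      if (!any(keep)) next
      segs[[length(segs) + 1L]] <- tibble::tibble(
        individual = inds$id[i],
        population = inds$population[i],
        contig = cn,
        start = st_pos[keep],
        end = en_pos[keep],
        length = len[keep],
        n_sites = (ends_idx[auto] - starts_idx[auto] + 1L)[keep],
        long = len[keep] > long_threshold)
    }
  }
  if (!length(segs)) {
    return(tibble::tibble(individual = character(),
                          population = character(), contig = character(),
                          start = integer(), end = integer(),
                          length = integer(), n_sites = integer(),
                          long = logical()))
  }
  dplyr::bind_rows(segs)
}

#' Genomic inbreeding coefficient F_ROH
#'
#' Fraction of the genome covered by ROH segments, per individual.
#' `length_class = "all"` uses every retained segment (the >= 100 kb
#' class when segments come from [detect_roh()] defaults);
#' `length_class = "long"` restricts to the recent-inbreeding class
#' (`long == TRUE`, > 1 Mb). Overlapping segments within one
#' individual violate the segment invariant and raise an error.
#'
#' @param segments Segment tibble from [detect_roh()] (or truth
#'   intervals with at least `individual`, `contig`, `start`, `end`).
#' @param genome_length Total genome length in bp.
#' @param length_class `"all"` or `"long"`.
#' @param individuals Optional character vector of individuals to
#'   report (individuals without segments get `f_roh = 0`).
#' @return A tibble `individual`, `f_roh`.
#' @export
f_roh <- function(segments, genome_length, length_class = c("all", "long"),
                  individuals = NULL) {
  length_class <- match.arg(length_class)
  stopifnot(genome_length > 0)
  segments <- tibble::as_tibble(segments)
  if (!nrow(segments)) {
    return(tibble::tibble(individual = individuals %||% character(),
                          f_roh = rep(0, length(individuals %||% character()))))
  }
  if (length_class == "long") {
    if (!"long" %in% names(segments)) {
      segments$long <- (segments$end - segments$start + 1) > 1e6
    }
    segments <- segments[segments$long, , drop = FALSE]
  }
  # overlap invariant per individual and contig
  if (nrow(segments)) {
    chk <- dplyr::group_by(segments, .data$individual, .data$contig)
    chk <- dplyr::arrange(chk, .data$start, .by_group = TRUE)
    bad <- dplyr::summarise(chk,
      overlap = dplyr::n() > 1 &&
        any(.data$start[-1] <= .data$end[-dplyr::n()]),
      .groups = "drop")
    if (any(bad$overlap)) {
      stop("overlapping ROH segments for individual ",
           bad$individual[which(bad$overlap)[1L]], call. = FALSE)
    }
  }
  res <- dplyr::summarise(
    dplyr::group_by(segments, .data$individual),
    f_roh = sum(.data$end - .data$start + 1) / genome_length,
    .groups = "drop")
  if (!is.null(individuals)) {
    res <- dplyr::left_join(tibble::tibble(individual = individuals),
                            res, by = "individual")
    res$f_roh[is.na(res$f_roh)] <- 0
  }
  res
}
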