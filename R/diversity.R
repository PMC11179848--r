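# Diversity statistics: windowed nucleotide diversity, individual
# heterozygosity, the pi_0/pi_4 purifying-selection index, and LD
# decay.

# per-site unbiased pairwise diversity 2*p*q*n/(n-1) over observed
# alleles within a set of genotype columns; returns a vector over sites
# (0 where monomorphic, NA where nothing is called)
.site_pi <- function(g) {
  n_called <- rowSums(!is.na(g))
  n_allele <- 2 * n_called
  p <- rowSums(g, na.rm = TRUE) / pmax(n_allele, 1L)
  pi <- ifelse(n_allele >= 2,
               2 * p * (1 - p) * n_allele / (n_allele - 1), NA_real_)
  pi[n_allele == 0L] <- NA_real_
  pi
}

#' Windowed nucleotide diversity
#'
#' Average pairwise diversity per base pair in sliding windows:
#' `pi = sum over variable sites of 2 p q n/(n-1)`, divided by the
#' window length (monomorphic positions contribute zero; synthetic
#' cohorts are fully callable). Computed per population. A window whose
#' sites are all uncalled is flagged `NA`; windows without sites have
#' `pi = 0`.
#'
#' @param dataset A `cohort_dataset`.
#' @param window,step Window length and slide in bp (defaults 100 kb /
#'   10 kb).
#' @param populations Populations to compute (default all).
#' @return A tibble: `population`, `contig`, `start`, `end`, `n_sites`,
#'   `pi`.
#' @export
windowed_pi <- function(dataset, window = 1e5, step = 1e4,
                        populations = NULL) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  populations <- populations %||% unique(dataset$individuals$population)
  out <- list()
  for (pn in populations) {
    cols <- which(dataset$individuals$population == pn)
    pi_site <- .site_pi(dataset$genotypes[, cols, drop = FALSE])
    for (ci in seq_len(nrow(dataset$contigs))) {
      cn <- dataset$contigs$name[ci]
      clen <- dataset$contigs$length[ci]
      rows <- which(dataset$sites$contig == cn)
      pos <- dataset$sites$pos[rows]
      vals <- pi_site[rows]
      called <- !is.na(vals)
      starts <- seq(1, max(1, clen - window + 1), by = step)
      ends <- pmin(starts + window - 1, clen)
      # cumulative sums over sorted positions for O(1) window queries
      cs <- c(0, cumsum(ifelse(called, vals, 0)))
      cn_sites <- c(0, cumsum(rep(1, length(pos))))
      cn_called <- c(0, cumsum(as.numeric(called)))
      lo <- findInterval(starts - 0.5, pos)
      hi <- findInterval(ends + 0.5, pos)
      n_sites <- cn_sites[hi + 1] - cn_sites[lo + 1]
      n_called <- cn_called[hi + 1] - cn_called[lo + 1]
      pi_sum <- cs[hi + 1] - cs[lo + 1]
      pi <- pi_sum / (ends - starts + 1)
      pi[n_sites > 0 & n_called == 0] <- NA_real_
      out[[length(out) + 1L]] <- tibble::tibble(
        population = pn, contig = cn, start = starts, end = ends,
        n_sites = as.integer(n_sites), pi = pi)
    }
  }
  dplyr::bind_rows(out)
}

#' Population mean nucleotide diversity
#'
#' Genome-wide `pi` per population: summed per-site diversity over the
#' total genome length (equivalently, the site-count-weighted mean of
#' the windowed values at step = window).
#'
#' @param dataset A `cohort_dataset`.
#' @return A tibble `population`, `pi`.
#' @export
population_pi <- function(dataset) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  glen <- sum(dataset$contigs$length)
  out <- lapply(unique(dataset$individuals$population), function(pn) {
    cols <- which(dataset$individuals$population == pn)
    pi_site <- .site_pi(dataset$genotypes[, cols, drop = FALSE])
    tibble::tibble(population = pn,
                   pi = sum(pi_site, na.rm = TRUE) / glen)
  })
  dplyr::bind_rows(out)
}

#' Individual whole-genome heterozygosity
#'
#' Count of heterozygous genotypes divided by the callable genome
#' length -- a per-bp rate on the same scale as `pi`. Also reports the
#' method-of-moments inbreeding coefficient
#' `F_het = 1 - O(het) / E(het)`, with `E(het)` the Hardy-Weinberg
#' expectation from population allele frequencies at the individual's
#' called sites.
#'
#' @param dataset A `cohort_dataset`.
#' @param callable_length Callable genome length in bp (default: total
#'   contig length; synthetic cohorts are fully callable).
#' @return A tibble: `individual`, `population`, `n_het`,
#'   `heterozygosity`, `f_het`.
#' @export
individual_heterozygosity <- function(dataset, callable_length = NULL) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  callable_length <- callable_length %||% sum(dataset$contigs$length)
  if (callable_length <= 0) {
    stop("callable genome length must be positive", call. = FALSE)
  }
  g <- dataset$genotypes
  inds <- dataset$individuals
  # HW expected heterozygosity per site within each population
  ehet <- matrix(NA_real_, nrow(g), nrow(inds))
  for (pn in unique(inds$population)) {
    cols <- which(inds$population == pn)
    gp <- g[, cols, drop = FALSE]
    n_allele <- 2 * rowSums(!is.na(gp))
    p <- rowSums(gp, na.rm = TRUE) / pmax(n_allele, 1L)
    ehet[, cols] <- 2 * p * (1 - p)
  }
  n_het <- colSums(g == 1L, na.rm = TRUE)
  e_het <- colSums(ehet * !is.na(g), na.rm = TRUE)
  tibble::tibble(
    individual = inds$id,
    population = inds$population,
    n_het = as.integer(n_het),
    heterozygosity = n_het / callable_length,
    f_het = ifelse(e_het > 0, 1 - n_het / e_het, NA_real_)
  )
}

#' Diversity ratio of 0-fold to 4-fold degenerate sites
#'
#' Mean per-site pairwise diversity restricted to each degeneracy
#' class, per population, and their ratio `pi_0 / pi_4` -- an index of
#' purifying selection (lower = stronger constraint on amino-acid
#' changing sites).
#'
#' @param dataset A `cohort_dataset`.
#' @param degmap A tibble `contig`, `pos`, `fold` from
#'   [classify_degeneracy()] or [effect_class_degmap()].
#' @return A tibble: `population`, `pi0`, `pi4`, `n0`, `n4`, `ratio`
#'   (`NA` with a warning if a class is empty).
#' @export
pi_ratio_0fold_4fold <- function(dataset, degmap) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  key <- paste(dataset$sites$contig, dataset$sites$pos)
  fold <- degmap$fold[match(key, paste(degmap$contig, degmap$pos))]
  rows0 <- which(fold == "0")
  rows4 <- which(fold == "4")
  if (!length(rows4) || !length(rows0)) {
    warning("empty 0-fold or 4-fold class; ratio undefined")
  }
  out <- lapply(unique(dataset$individuals$population), function(pn) {
    cols <- which(dataset$individuals$population == pn)
    pi_site <- .site_pi(dataset$genotypes[, cols, drop = FALSE])
    pi0 <- mean(pi_site[rows0], na.rm = TRUE)
    pi4 <- mean(pi_site[rows4], na.rm = TRUE)
    tibble::tibble(population = pn, pi0 = pi0, pi4 = pi4,
                   n0 = length(rows0), n4 = length(rows4),
                   ratio = ifelse(is.finite(pi4) && pi4 > 0,
                                  pi0 / pi4, NA_real_))
  })
  dplyr::bind_rows(out)
}

#' Linkage-disequilibrium decay
#'
#' Genotype-dosage `r^2` between intra-contig site pairs within
#' `max_dist`, averaged in distance bins, per population. For large
#' cohorts the pair set is randomly subsampled to `max_pairs` pairs
#' (missing dosages are replaced by the site mean before correlation).
#' Also reports the distance at which the binned mean first falls to
#' half of its maximum.
#'
#' @param dataset A `cohort_dataset`.
#' @param max_dist Maximum pair distance in bp (default 1000 kb).
#' @param bin_width Distance bin width in bp.
#' @param max_pairs Pair subsample cap per population.
#' @param populations Populations to compute (default all).
#' @param min_maf Sites at or below this minor allele frequency are
#'   excluded (monomorphic pairs are undefined).
#' @return A list: `bins` (tibble `population`, `dist`, `mean_r2`,
#'   `n_pairs`) and `half_decay` (tibble `population`,
#'   `half_decay_dist`).
#' @export
ld_decay <- function(dataset, max_dist = 1e6, bin_width = 2e4,
                     max_pairs = 2e5, populations = NULL,
                     min_maf = 0.05) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  populations <- populations %||% unique(dataset$individuals$population)
  bins_out <- list()
  hd_out <- list()
  for (pn in populations) {
    cols <- which(dataset$individuals$population == pn)
    g <- dataset$genotypes[, cols, drop = FALSE]
    n_called <- rowSums(!is.na(g))
    p <- rowSums(g, na.rm = TRUE) / (2 * pmax(n_called, 1L))
    usable <- pmin(p, 1 - p) > min_maf & n_called >= 4
    pairs_i <- integer(0)
    pairs_j <- integer(0)
    for (cn in unique(dataset$sites$contig)) {
      rows <- which(dataset$sites$contig == cn & usable)
      if (length(rows) < 2) next
      pos <- dataset$sites$pos[rows]
      n_this <- ceiling(max_pairs * length(rows) / sum(usable))
      ii <- sample.int(length(rows), n_this, replace = TRUE)
      hi <- findInterval(pos[ii] + max_dist, pos)
      span <- hi - ii
      ok <- span >= 1
      ii <- ii[ok]
      jj <- ii + 1L + floor(stats::runif(sum(ok)) * span[ok])
      pairs_i <- c(pairs_i, rows[ii])
      pairs_j <- c(pairs_j, rows[jj])
    }
    if (!length(pairs_i)) next
    z <- g
    rm_idx <- is.na(z)
    if (any(rm_idx)) {
      mu <- rowMeans(z, na.rm = TRUE)
      z[rm_idx] <- mu[row(z)[rm_idx]]
    }
    z <- z - rowMeans(z)
    sdv <- sqrt(rowMeans(z^2))
    keep <- sdv[pairs_i] > 0 & sdv[pairs_j] > 0
    pairs_i <- pairs_i[keep]
    pairs_j <- pairs_j[keep]
    r <- rowMeans(z[pairs_i, , drop = FALSE] * z[pairs_j, , drop = FALSE]) /
      (sdv[pairs_i] * sdv[pairs_j])
    d <- abs(dataset$sites$pos[pairs_j] - dataset$sites$pos[pairs_i])
    bin <- pmin(floor(d / bin_width), ceiling(max_dist / bin_width) - 1)
    agg <- tapply(r^2, bin, mean)
    cnt <- tapply(r^2, bin, length)
    bt <- tibble::tibble(
      population = pn,
      dist = (as.numeric(names(agg)) + 0.5) * bin_width,
      mean_r2 = as.numeric(agg),
      n_pairs = as.integer(cnt))
    bins_out[[pn]] <- bt
    peak <- max(bt$mean_r2)
    below <- bt$dist[bt$mean_r2 <= peak / 2]
    hd_out[[pn]] <- tibble::tibble(
      population = pn,
      half_decay_dist = if (length(below)) min(below) else NA_real_)
  }
  list(bins = dplyr::bind_rows(bins_out),
       half_decay = dplyr::bind_rows(hd_out))
}
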