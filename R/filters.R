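# Record- and site-level filters: GATK-style hard filters on variant
# annotations, MAF/missingness site filters, and greedy windowed LD
# pruning.

#' GATK-style hard filtering of variant records
#'
#' Removes a record if ANY clause triggers:
#' `QUAL < 30 || DP < 5 || QD < 2.0 || MQ < 40.0 || FS > 60.0 ||
#' SOR > 3.0 || MQRankSum < -12.5 || ReadPosRankSum < -8.0`.
#' A missing (`NA`) annotation passes its clause; the log records how
#' often each clause fired and how often it was skipped for absence.
#' Boundary semantics are exactly as written: a value equal to a `<`
#' threshold passes (e.g. `QUAL = 30` is retained, `QUAL = 29.9`
#' removed).
#'
#' @param records Data frame with any of the annotation columns named
#'   above; other columns are carried through.
#' @param thresholds Named list overriding the default cutoffs.
#' @return A list: `kept` (surviving records), `removed`, and `log`
#'   (tibble `clause`, `n_failed`, `n_missing`).
#' @export
apply_hard_filters <- function(records,
                               thresholds = list(QUAL = 30, DP = 5,
                                                 QD = 2.0, MQ = 40.0,
                                                 FS = 60.0, SOR = 3.0,
                                                 MQRankSum = -12.5,
                                                 ReadPosRankSum = -8.0)) {
  records <- tibble::as_tibble(records)
  clauses <- list(
    QUAL = function(x) x < thresholds$QUAL,
    DP = function(x) x < thresholds$DP,
    QD = function(x) x < thresholds$QD,
    MQ = function(x) x < thresholds$MQ,
    FS = function(x) x > thresholds$FS,
    SOR = function(x) x > thresholds$SOR,
    MQRankSum = function(x) x < thresholds$MQRankSum,
    ReadPosRankSum = function(x) x < thresholds$ReadPosRankSum
  )
  fail_any <- rep(FALSE, nrow(records))
  log_rows <- list()
  for (ann in names(clauses)) {
    if (!ann %in% names(records)) {
      log_rows[[ann]] <- tibble::tibble(clause = ann, n_failed = 0L,
                                        n_missing = nrow(records))
      next
    }
    x <- records[[ann]]
    fails <- clauses[[ann]](x)
    n_missing <- sum(is.na(fails))
    fails[is.na(fails)] <- FALSE   # absent annotation passes the clause
    fail_any <- fail_any | fails
    log_rows[[ann]] <- tibble::tibble(clause = ann,
                                      n_failed = sum(fails),
                                      n_missing = n_missing)
  }
  list(kept = records[!fail_any, , drop = FALSE],
       removed = records[fail_any, , drop = FALSE],
       log = dplyr::bind_rows(log_rows))
}

#' Minor-allele-frequency and missingness site filters
#'
#' Removes sites with minor allele frequency `<= maf_max_excluded`
#' (computed over non-missing alleles; invariant sites have MAF 0 and
#' are removed) or per-site missing-genotype rate
#' `>= missing_rate_max`. Boundary semantics: equality triggers
#' removal on both clauses.
#'
#' @param dataset A `cohort_dataset`.
#' @param maf_max_excluded MAF at or below which a site is removed
#'   (default 0.05).
#' @param missing_rate_max Missing rate at or above which a site is
#'   removed (default 0.10).
#' @return The filtered dataset; attribute `site_filter_log` holds a
#'   list with per-clause removal counts.
#' @export
site_filters <- function(dataset, maf_max_excluded = 0.05,
                         missing_rate_max = 0.10) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  g <- dataset$genotypes
  n_called <- rowSums(!is.na(g))
  # exact fraction (avoids 1 - 9/10 != 0.1 float asymmetry at the boundary)
  miss_rate <- (ncol(g) - n_called) / ncol(g)
  p_alt <- rowSums(g, na.rm = TRUE) / (2 * pmax(n_called, 1L))
  maf <- pmin(p_alt, 1 - p_alt)
  maf[n_called == 0L] <- 0
  drop_maf <- maf <= maf_max_excluded
  drop_miss <- miss_rate >= missing_rate_max
  keep <- !(drop_maf | drop_miss)
  out <- subset_sites(dataset, which(keep))
  attr(out, "site_filter_log") <- list(
    n_input = nrow(g),
    n_removed_maf = sum(drop_maf),
    n_removed_missing = sum(drop_miss),
    n_kept = sum(keep)
  )
  out
}

#' Subset a cohort dataset to a set of site rows
#'
#' @param dataset A `cohort_dataset`.
#' @param idx Integer site row indices to keep (in order).
#' @return The subset dataset (truth frequencies subset in parallel).
#' @export
subset_sites <- function(dataset, idx) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  dataset$sites <- dataset$sites[idx, , drop = FALSE]
  dataset$genotypes <- dataset$genotypes[idx, , drop = FALSE]
  dataset$truth$q <- lapply(dataset$truth$q, function(q) q[idx])
  dataset
}

#' Greedy windowed LD pruning
#'
#' Within each sliding window of `window` variants (per contig), any
#' pair with squared genotype-dosage correlation `r^2 > r2_max` has its
#' later member (larger position) removed; the window then slides by
#' `step` variants. Defaults 100 / 10 / 0.2 follow common practice for
#' pruning before structure analyses. Deterministic: ties broken by
#' removing the later site.
#'
#' @param dataset A `cohort_dataset`.
#' @param window Window size in variants.
#' @param step Slide in variants.
#' @param r2_max Pruning threshold on `r^2`.
#' @return Integer vector of retained site rows (into
#'   `dataset$sites`); apply with [subset_sites()].
#' @export
ld_prune <- function(dataset, window = 100L, step = 10L, r2_max = 0.2) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  g <- dataset$genotypes
  keep <- rep(TRUE, nrow(g))
  for (cn in unique(dataset$sites$contig)) {
    rows <- which(dataset$sites$contig == cn)
    if (length(rows) < 2) next
    starts <- seq(1L, max(1L, length(rows) - 1L), by = step)
    for (w0 in starts) {
      win <- rows[w0:min(w0 + window - 1L, length(rows))]
      win <- win[keep[win]]
      if (length(win) < 2) next
      cc <- suppressWarnings(
        stats::cor(t(g[win, , drop = FALSE]),
                   use = "pairwise.complete.obs"))
      cc[is.na(cc)] <- 0
      r2 <- cc^2
      for (a in seq_len(length(win) - 1L)) {
        if (!keep[win[a]]) next
        hits <- which(r2[a, ] > r2_max)
        hits <- hits[hits > a]
        if (length(hits)) keep[win[hits]] <- FALSE
      }
    }
  }
  which(keep)
}
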