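# Derived-allele burden statistics: outgroup-parsimony polarization,
# the derived-count rule, and normalized load ratios stratified by
# zygosity and by ROH membership.

#' Polarize sites into ancestral and derived alleles
#'
#' Outgroup parsimony. Strict mode (default): the ancestral allele is
#' the allele carried by both outgroups when they agree and match one
#' of the two ingroup alleles; outgroup conflicts, double mismatches,
#' and double missing leave the site unpolarized (excluded from burden
#' counts). Relaxed mode additionally accepts a single informative
#' outgroup when the other is missing (flagged `single_outgroup`);
#' disagreeing outgroups remain unpolarized.
#'
#' @param dataset A `cohort_dataset` (uses `sites$out1`, `sites$out2`).
#' @param mode `"strict"` or `"relaxed"`.
#' @return A tibble: `site_id`, `polarized`, `derived_is_alt`,
#'   `anc_allele`, `flag` (`"ok"`, `"single_outgroup"`,
#'   `"outgroup_conflict"`, `"outgroup_mismatch"`,
#'   `"outgroup_missing"`).
#' @export
polarize_sites <- function(dataset, mode = c("strict", "relaxed")) {
  mode <- match.arg(mode)
  s <- dataset$sites
  o1 <- s$out1
  o2 <- s$out2
  valid1 <- !is.na(o1) & (o1 == s$ref | o1 == s$alt)
  valid2 <- !is.na(o2) & (o2 == s$ref | o2 == s$alt)
  present1 <- !is.na(o1)
  present2 <- !is.na(o2)

  anc <- rep(NA_character_, nrow(s))
  flag <- rep("ok", nrow(s))

  agree <- present1 & present2 & o1 == o2
  conflict <- present1 & present2 & o1 != o2
  both_missing <- !present1 & !present2

  strict_ok <- agree & valid1
  anc[strict_ok] <- o1[strict_ok]
  flag[conflict] <- "outgroup_conflict"
  flag[agree & !valid1] <- "outgroup_mismatch"
  flag[both_missing] <- "outgroup_missing"

  if (mode == "relaxed") {
    only1 <- present1 & !present2 & valid1
    only2 <- present2 & !present1 & valid2
    anc[only1] <- o1[only1]
    anc[only2] <- o2[only2]
    flag[only1 | only2] <- "single_outgroup"
    flag[present1 & !present2 & !valid1] <- "outgroup_mismatch"
    flag[present2 & !present1 & !valid2] <- "outgroup_mismatch"
  } else {
    one_missing <- xor(present1, present2)
    flag[one_missing] <- "outgroup_missing"
  }

  tibble::tibble(
    site_id = s$site_id,
    polarized = !is.na(anc),
    derived_is_alt = ifelse(is.na(anc), NA, anc == s$ref),
    anc_allele = anc,
    flag = flag
  )
}

#' Derived-allele count of a genotype
#'
#' The burden counting rule: a homozygous-derived genotype carries 2
#' derived alleles, a heterozygote 1, a homozygous-ancestral 0; missing
#' genotypes contribute nothing (excluded from numerators and
#' denominators alike).
#'
#' @param genotype Integer genotype(s) coded as ALT dosage 0/1/2 (`NA`
#'   = missing).
#' @param derived_is_alt Logical (recycled): is the derived allele the
#'   ALT allele at this site? `NA` (unpolarized) is an error --
#'   unpolarized sites must be excluded upstream.
#' @return Integer derived-allele count(s) in `{0, 1, 2, NA}`.
#' @export
count_derived <- function(genotype, derived_is_alt) {
  if (any(is.na(derived_is_alt))) {
    stop("count_derived() reached an unpolarized site; filter on ",
         "`polarized` first", call. = FALSE)
  }
  derived_is_alt <- rep_len(derived_is_alt, length(genotype))
  ifelse(derived_is_alt, genotype, 2L - genotype)
}

# internal: derived-count matrix (sites x individuals) over polarized
# sites only, plus the matching site table rows
.derived_matrix <- function(dataset, polarization) {
  keep <- which(polarization$polarized)
  dia <- polarization$derived_is_alt[keep]
  g <- dataset$genotypes[keep, , drop = FALSE]
  d <- g
  flip <- which(!dia)
  if (length(flip)) d[flip, ] <- 2L - d[flip, , drop = FALSE]
  list(d = d, sites = dataset$sites[keep, , drop = FALSE])
}

#' Zygosity-stratified derived-load ratios per individual
#'
#' For every individual and functional class, counts derived alleles at
#' heterozygous sites (1 per het site) and at homozygous-derived sites
#' (2 per site), and normalizes each by the corresponding derived
#' synonymous count: `r_het = het_c / het_syn`,
#' `r_hom = 2 hom_c / (2 hom_syn)`. Ratios with a zero synonymous
#' denominator are `NA`. Unpolarized sites and missing genotypes are
#' excluded throughout.
#'
#' @param dataset A `cohort_dataset`.
#' @param polarization Output of [polarize_sites()].
#' @param classes Functional classes to report (default tolerated,
#'   deleterious, lof).
#' @param synonymous_class Name of the normalizing class.
#' @return A tibble (`load_summary`): `individual`, `population`,
#'   `species`, `class`, `n_het`, `n_hom_sites`, `derived_het`,
#'   `derived_hom`, `syn_het`, `syn_hom`, `ratio_het`, `ratio_hom`.
#' @export
load_ratios <- function(dataset, polarization,
                        classes = c("tolerated", "deleterious", "lof"),
                        synonymous_class = "synonymous") {
  stopifnot(inherits(dataset, "cohort_dataset"))
  dm <- .derived_matrix(dataset, polarization)
  cls <- dm$sites$effect_class
  inds <- dataset$individuals
  count_by <- function(rows) {
    d <- dm$d[rows, , drop = FALSE]
    list(het = unname(colSums(d == 1L, na.rm = TRUE)),
         hom = unname(colSums(d == 2L, na.rm = TRUE)))
  }
  syn <- count_by(which(cls == synonymous_class))
  out <- lapply(classes, function(cl) {
    cc <- count_by(which(cls == cl))
    tibble::tibble(
      individual = inds$id,
      population = inds$population,
      species = inds$species,
      class = cl,
      n_het = as.integer(cc$het),
      n_hom_sites = as.integer(cc$hom),
      derived_het = as.integer(cc$het),
      derived_hom = 2L * as.integer(cc$hom),
      syn_het = as.integer(syn$het),
      syn_hom = 2L * as.integer(syn$hom),
      ratio_het = ifelse(syn$het > 0, cc$het / syn$het, NA_real_),
      ratio_hom = ifelse(syn$hom > 0, cc$hom / syn$hom, NA_real_))
  })
  res <- dplyr::bind_rows(out)
  class(res) <- c("load_summary", class(res))
  res
}

#' ROH-stratified derived-load ratios per individual
#'
#' Restricts numerator and denominator of the class-to-synonymous
#' derived-allele ratio to sites inside (resp. outside) each
#' individual's own ROH segments. All derived alleles count (1 per
#' het, 2 per hom-derived site); an individual without ROH has `NA`
#' in-ROH ratios and out-ROH counts equal to the totals.
#'
#' @inheritParams load_ratios
#' @param segments ROH segments from [detect_roh()] or truth intervals
#'   (`individual`, `contig`, `start`, `end`).
#' @return A tibble: `individual`, `population`, `species`, `class`,
#'   `derived_in`, `syn_in`, `derived_out`, `syn_out`, `ratio_in`,
#'   `ratio_out`.
#' @export
roh_stratified_ratios <- function(dataset, segments, polarization,
                                  classes = c("tolerated", "deleterious",
                                              "lof"),
                                  synonymous_class = "synonymous") {
  stopifnot(inherits(dataset, "cohort_dataset"))
  dm <- .derived_matrix(dataset, polarization)
  cls <- dm$sites$effect_class
  inds <- dataset$individuals
  segments <- tibble::as_tibble(segments)

  # site-in-ROH indicator per individual
  in_roh <- matrix(FALSE, nrow(dm$sites), nrow(inds))
  if (nrow(segments)) {
    for (i in seq_len(nrow(inds))) {
      si <- segments[segments$individual == inds$id[i], , drop = FALSE]
      if (!nrow(si)) next
      for (cn in unique(si$contig)) {
        rows <- which(dm$sites$contig == cn)
        if (!length(rows)) next
        sc <- si[si$contig == cn, , drop = FALSE]
        sc <- sc[order(sc$start), , drop = FALSE]
        k <- findInterval(dm$sites$pos[rows], sc$start)
        hit <- k >= 1 & dm$sites$pos[rows] <= sc$end[pmax(k, 1L)]
        in_roh[rows[hit], i] <- TRUE
      }
    }
  }

  strat_counts <- function(rows) {
    d <- dm$d[rows, , drop = FALSE]
    alleles <- d
    alleles[is.na(alleles)] <- 0L
    io <- in_roh[rows, , drop = FALSE]
    list(inn = unname(colSums(alleles * io)),
         out = unname(colSums(alleles * !io)))
  }
  syn <- strat_counts(which(cls == synonymous_class))
  out <- lapply(classes, function(cl) {
    cc <- strat_counts(which(cls == cl))
    tibble::tibble(
      individual = inds$id,
      population = inds$population,
      species = inds$species,
      class = cl,
      derived_in = as.integer(cc$inn),
      syn_in = as.integer(syn$inn),
      derived_out = as.integer(cc$out),
      syn_out = as.integer(syn$out),
      ratio_in = ifelse(syn$inn > 0, cc$inn / syn$inn, NA_real_),
      ratio_out = ifelse(syn$out > 0, cc$out / syn$out, NA_real_))
  })
  dplyr::bind_rows(out)
}

#' Welch's t-tests on load summaries between species
#'
#' Compares per-individual ratios between the two species labels with
#' unequal-variance t-tests, per class and stratum. The handful of
#' planned comparisons is reported without multiple-testing
#' correction.
#'
#' @param summary A tibble from [load_ratios()] (columns `ratio_het`,
#'   `ratio_hom`) or [roh_stratified_ratios()] (columns `ratio_in`,
#'   `ratio_out`).
#' @return A tibble: `class`, `stratum`, `mean_1`, `mean_2`,
#'   `t`, `df`, `p`, with species labels in attributes.
#' @export
load_tests <- function(summary) {
  ratio_cols <- intersect(c("ratio_het", "ratio_hom",
                            "ratio_in", "ratio_out"),
                          names(summary))
  sp <- sort(unique(summary$species))
  if (length(sp) != 2) {
    stop("load_tests() needs exactly two species labels", call. = FALSE)
  }
  rows <- list()
  for (cl in unique(summary$class)) {
    for (rc in ratio_cols) {
      x <- summary[[rc]][summary$class == cl & summary$species == sp[1]]
      y <- summary[[rc]][summary$class == cl & summary$species == sp[2]]
      x <- x[is.finite(x)]
      y <- y[is.finite(y)]
      if (length(x) < 2 || length(y) < 2) next
      tt <- stats::t.test(x, y, var.equal = FALSE)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        class = cl, stratum = sub("^ratio_", "", rc),
        mean_1 = mean(x), mean_2 = mean(y),
        t = unname(tt$statistic), df = unname(tt$parameter),
        p = tt$p.value)
    }
  }
  res <- dplyr::bind_rows(rows)
  attr(res, "species") <- sp
  res
}
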