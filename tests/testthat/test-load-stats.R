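# Empirical load pipeline: degeneracy, diversity, heterozygosity, ROH
# detection, polarization, derived counts, burden ratios, LD decay.

make_orf <- function(n_codons, seed) {
  set.seed(seed)
  codons <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  paste(c("ATG", sample(codons, n_codons - 2, replace = TRUE), "TAA"),
        collapse = "")
}

# independent brute-force oracle built on seqinr's translator
oracle_fold <- function(codon, pos) {
  aa <- seqinr::translate(strsplit(codon, "")[[1]])
  nsyn <- sum(vapply(c("A", "C", "G", "T"), function(b) {
    mut <- codon
    substr(mut, pos, pos) <- b
    seqinr::translate(strsplit(mut, "")[[1]]) == aa
  }, logical(1)))
  switch(as.character(nsyn), "1" = "0", "2" = "2", "4" = "4", "other")
}

test_that("degeneracy classification matches the codon-table oracle", {
  skip_if_not_installed("seqinr")
  # exhaustive: all 64 codons x 3 positions, both strands
  codons <- names(Biostrings::GENETIC_CODE)
  body <- paste(codons[Biostrings::GENETIC_CODE[codons] != "*"],
                collapse = "")
  cds_plus <- paste0("ATG", body, "TAA")
  # embed the same CDS on the minus strand elsewhere
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(cds_plus)))
  L <- nchar(cds_plus)
  chrom <- paste0(cds_plus, strrep("A", 50), rc)
  genome <- Biostrings::DNAStringSet(c(chr1 = chrom))
  cds <- tibble::tibble(
    seqid = "chr1",
    start = c(1L, L + 51L),
    end = c(L, 2L * L + 50L),
    strand = c("+", "-"),
    transcript_id = c("fwd", "rev"))
  dm <- classify_degeneracy(genome, cds)
  expect_equal(nrow(dm), 2L * L)
  for (tx in c("fwd", "rev")) {
    sub <- dm[dm$transcript == tx, ]
    expect_true(all(mapply(oracle_fold, sub$codon, sub$codon_pos) ==
                      sub$fold))
  }
  # spot-checks from the genetic code
  ggt <- dm[dm$codon == "GGT" & dm$transcript == "fwd", ]
  expect_true(all(ggt$fold[ggt$codon_pos == 3] == "4"))
  # second positions are 0-fold except in stop codons (TAA/TGA)
  aa <- Biostrings::GENETIC_CODE[dm$codon]
  expect_true(all(dm$fold[dm$codon_pos == 2 & aa != "*"] == "0"))
})

test_that("broken transcripts are skipped with a reason", {
  genome <- Biostrings::DNAStringSet(c(chr1 = make_orf(40, 3)))
  # out-of-frame slice and an internal-stop construct
  cds <- tibble::tibble(seqid = "chr1", start = c(1L, 1L),
                        end = c(119L, 120L), strand = "+",
                        transcript_id = c("bad_frame", "good"))
  dm <- classify_degeneracy(genome, cds)
  expect_named(attr(dm, "skipped"), "bad_frame")
  stopgen <- Biostrings::DNAStringSet(c(chr1 = paste0(
    "ATG", "TAA", "TAA", make_orf(10, 4))))
  dm2 <- classify_degeneracy(
    stopgen, tibble::tibble(seqid = "chr1", start = 1L, end = 9L,
                            strand = "+", transcript_id = "stopper"))
  expect_equal(attr(dm2, "skipped")$stopper, "internal stop codon")
})

test_that("windowed pi matches hand-computed pairwise diversity", {
  # one het individual: two haplotypes differing at one site in 1 kb
  g <- matrix(1L, 1, 1, dimnames = list(NULL, "popA_01"))
  ds <- manual_cohort(g, "synonymous", positions = 500L,
                      contig_length = 1000)
  wp <- windowed_pi(ds, window = 1000, step = 1000)
  expect_equal(wp$pi, 1 / 1000)

  # two individuals 0/0 and 1/1: p = 1/2, n = 4 alleles
  g2 <- matrix(c(0L, 2L), 1, 2,
               dimnames = list(NULL, c("popA_01", "popA_02")))
  ds2 <- manual_cohort(g2, "synonymous", positions = 500L,
                       contig_length = 1000)
  wp2 <- windowed_pi(ds2, window = 1000, step = 1000)
  expect_equal(wp2$pi, 2 * 0.25 * (4 / 3) / 1000)

  # monomorphic window is zero
  g3 <- matrix(0L, 1, 2, dimnames = list(NULL, c("popA_01", "popA_02")))
  ds3 <- manual_cohort(g3, "synonymous", positions = 500L,
                       contig_length = 1000)
  expect_equal(windowed_pi(ds3, 1000, 1000)$pi, 0)

  # defaults follow the 100 kb / 10 kb convention
  expect_equal(formals(windowed_pi)$window, 1e5)
  expect_equal(formals(windowed_pi)$step, 1e4)
})

test_that("individual heterozygosity counts hets per callable bp", {
  g <- matrix(c(0L, 2L, 0L,
                1L, 1L, 1L), 3, 2,
              dimnames = list(NULL, c("popA_01", "popA_02")))
  ds <- manual_cohort(g, rep("synonymous", 3), contig_length = 10000)
  het <- individual_heterozygosity(ds)
  expect_equal(het$heterozygosity, c(0, 3 / 10000))
  expect_equal(het$n_het, c(0L, 3L))
  expect_error(individual_heterozygosity(ds, callable_length = 0),
               "callable")
})

test_that("mean individual heterozygosity tracks population pi under HW", {
  cfg <- tiny_config(n_rare = 10L, n_widespread = 10L)
  cfg$site_budgets <- c(synonymous = 3000L)
  cfg$populations$rare$f_roh_range <- c(0, 0)
  cfg$populations$widespread$f_roh_range <- c(0, 0)
  cfg$missing_rate <- 0
  ds <- generate_cohort(cfg, seed = 6)
  pp <- population_pi(ds)
  het <- individual_heterozygosity(ds)
  for (pn in pp$population) {
    m <- mean(het$heterozygosity[het$population == pn])
    expect_equal(m, pp$pi[pp$population == pn], tolerance = 0.1)
  }
})

test_that("pi0/pi4 reflects selection on 0-fold sites", {
  # identical diversity in both classes -> ratio 1
  g <- matrix(rep(c(0L, 1L, 2L, 1L), 4), 4, 4, byrow = TRUE,
              dimnames = list(NULL, sprintf("popA_%02d", 1:4)))
  ds <- manual_cohort(g, c("synonymous", "deleterious",
                           "synonymous", "deleterious"))
  pr <- pi_ratio_0fold_4fold(ds, effect_class_degmap(ds))
  expect_equal(pr$ratio, 1)

  # the tiny two-cohort scenario: selected 0-fold sites are depleted
  ds2 <- tiny_cohort()
  pr2 <- pi_ratio_0fold_4fold(ds2, effect_class_degmap(ds2))
  expect_true(all(pr2$ratio < 1))
  # the declining, inbred cohort purges harder
  expect_lt(pr2$ratio[pr2$population == "rare"],
            pr2$ratio[pr2$population == "widespread"])
})

test_that("regular heterozygosity never calls ROH", {
  set.seed(7)
  n_sites <- 400L
  g <- matrix(0L, n_sites, 6)
  g[seq(10, n_sites, by = 10), ] <- 1L
  # common alleles at the het sites so non-autozygous emission is high
  colnames(g) <- sprintf("popA_%02d", 1:6)
  ds <- manual_cohort(g, rep("synonymous", n_sites),
                      positions = seq(1000L, by = 1000L,
                                      length.out = n_sites),
                      contig_length = 500000)
  segs <- detect_roh(ds)
  expect_equal(nrow(segs), 0)
})

test_that("implanted tracts are recovered with tight overlap", {
  cfg <- tiny_config(n_rare = 8L, n_widespread = 8L)
  cfg$populations$rare$f_roh_range <- c(0, 0)
  cfg$populations$widespread$f_roh_range <- c(0, 0)
  ds <- generate_cohort(cfg, seed = 13)
  # one 900 kb tract for the first widespread individual (index 9)
  set.seed(14)
  ds <- implant_roh(ds, targets = c(rep(0, 8), 0.9e6 / 4e6, rep(0, 7)),
                    min_length = 8.5e5, mean_length = 9e5,
                    max_length = 9.5e5)
  tr <- ds$truth$roh
  expect_gte(nrow(tr), 1)
  segs <- detect_roh(ds)
  segs1 <- segs[segs$individual == ds$individuals$id[9] &
                  segs$contig == tr$contig[1], ]
  expect_gte(nrow(segs1), 1)
  ov <- sum(pmax(0, pmin(segs1$end, tr$end[1]) -
                   pmax(segs1$start, tr$start[1]) + 1))
  len_t <- tr$end[1] - tr$start[1] + 1
  expect_gt(ov / len_t, 0.9)                       # recall
  expect_gt(ov / sum(segs1$length), 0.9)           # precision
  # retention threshold and the recent-inbreeding subclass
  expect_equal(formals(detect_roh)$min_length, 1e5)
  expect_equal(formals(detect_roh)$long_threshold, 1e6)
})

test_that("f_roh sums segment lengths and guards overlaps", {
  segs <- tibble::tibble(
    individual = c("a", "a", "b"),
    contig = c("c1", "c1", "c1"),
    start = c(1, 2e7, 1),
    end = c(1e7, 2.05e7 + 0.5e6, 2e6),
    length = c(1e7, 5e5 + 1, 2e6),
    long = c(TRUE, FALSE, TRUE))
  fr <- f_roh(segs, genome_length = 1e8)
  expect_equal(fr$f_roh[fr$individual == "a"],
               (1e7 + 1e6 + 1) / 1e8)
  fr_long <- f_roh(segs, 1e8, length_class = "long")
  expect_equal(fr_long$f_roh[fr_long$individual == "a"], 0.1)
  expect_equal(f_roh(segs[0, ], 1e8, individuals = "x")$f_roh, 0)
  bad <- segs
  bad$start[2] <- 5e6L
  expect_error(f_roh(bad, 1e8), "overlap")
})

test_that("outgroup parsimony polarizes and flags sites as documented", {
  g <- matrix(1L, 6, 2, dimnames = list(NULL, c("popA_01", "popA_02")))
  ds <- manual_cohort(
    g, rep("synonymous", 6),
    out1 = c("A", "G", "A", "T", NA, NA),
    out2 = c("A", "G", "G", "T", "A", NA))
  # ref = A, alt = G everywhere
  pol <- polarize_sites(ds, mode = "strict")
  expect_equal(pol$polarized, c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_true(pol$derived_is_alt[1])    # both outgroups = REF
  expect_false(pol$derived_is_alt[2])   # both outgroups = ALT
  expect_equal(pol$flag[3], "outgroup_conflict")
  expect_equal(pol$flag[4], "outgroup_mismatch")
  expect_equal(pol$flag[5], "outgroup_missing")
  expect_equal(pol$flag[6], "outgroup_missing")

  rel <- polarize_sites(ds, mode = "relaxed")
  expect_true(rel$polarized[5])
  expect_equal(rel$flag[5], "single_outgroup")
  expect_false(rel$polarized[3])        # conflicts stay unpolarized
})

test_that("strict-mode misassignment is rare at the default divergence", {
  ds <- tiny_cohort()
  pol <- polarize_sites(ds, mode = "strict")
  expect_gt(mean(pol$polarized), 0.85)
  # truth: ancestral allele is REF at every site
  wrong <- mean(!pol$derived_is_alt[pol$polarized])
  expect_lt(wrong, 0.05)
})

test_that("derived counts follow the 2*hom + het rule", {
  expect_equal(count_derived(c(0L, 1L, 2L, NA), TRUE),
               c(0L, 1L, 2L, NA))
  expect_equal(count_derived(c(0L, 1L, 2L), FALSE), c(2L, 1L, 0L))
  expect_error(count_derived(1L, NA), "unpolarized")
})

test_that("load ratios reproduce a pencil-and-paper fixture", {
  # 3 individuals, 8 sites; ref is ancestral everywhere
  g <- matrix(c(
    # ind1 ind2 ind3
    1L, 2L, 0L,   # syn
    1L, 0L, 1L,   # syn
    2L, 2L, 0L,   # syn
    0L, 1L, NA,   # syn
    1L, 2L, 1L,   # deleterious
    0L, 1L, 1L,   # deleterious
    2L, 0L, 0L,   # lof
    1L, 1L, 2L    # tolerated
  ), nrow = 8, byrow = TRUE,
  dimnames = list(NULL, c("popA_01", "popA_02", "popA_03")))
  cls <- c("synonymous", "synonymous", "synonymous", "synonymous",
           "deleterious", "deleterious", "lof", "tolerated")
  ds <- manual_cohort(g, cls)
  pol <- polarize_sites(ds)
  expect_true(all(pol$polarized))
  lr <- load_ratios(ds, pol)
  # ind1: syn het = 2 (sites 1,2), syn hom sites = 1 (site 3)
  #       del het = 2 (sites 5,6 -> 1,0 het? site5=1, site6=0) -> 1
  ind1 <- lr[lr$individual == "popA_01", ]
  expect_equal(ind1$ratio_het[ind1$class == "deleterious"], 1 / 2)
  expect_equal(ind1$ratio_hom[ind1$class == "deleterious"], 0 / 1)
  expect_equal(ind1$ratio_hom[ind1$class == "lof"], 1 / 1)
  expect_equal(ind1$ratio_het[ind1$class == "tolerated"], 1 / 2)
  # ind3: syn het = 1 (site 2; site 4 missing), syn hom = 0 -> hom NA
  ind3 <- lr[lr$individual == "popA_03", ]
  expect_equal(ind3$ratio_het[ind3$class == "deleterious"], 2 / 1)
  expect_true(is.na(ind3$ratio_hom[ind3$class == "deleterious"]))

  # identical frequency spectra give ratios 1: duplicate the syn rows
  g2 <- rbind(g[1:4, ], g[1:4, ])
  ds2 <- manual_cohort(g2, c(rep("synonymous", 4),
                             rep("deleterious", 4)))
  lr2 <- load_ratios(ds2, polarize_sites(ds2))
  del2 <- lr2[lr2$class == "deleterious", ]
  expect_true(all(del2$ratio_het == 1, na.rm = TRUE))
  expect_true(all(del2$ratio_hom == 1, na.rm = TRUE))
})

test_that("ratio is invariant to hom-ancestral-everywhere sites", {
  ds <- tiny_cohort()
  pol <- polarize_sites(ds)
  lr <- load_ratios(ds, pol)
  # append 50 sites where everyone is hom-ancestral
  pad <- matrix(0L, 50, nrow(ds$individuals),
                dimnames = list(NULL, ds$individuals$id))
  ds2 <- ds
  ds2$sites <- dplyr::bind_rows(
    ds$sites,
    tibble::tibble(site_id = max(ds$sites$site_id) + 1:50,
                   contig = "ctg1",
                   pos = max(ds$sites$pos[ds$sites$contig == "ctg1"]) +
                     seq(1000, by = 1000, length.out = 50),
                   ref = "A", alt = "G",
                   effect_class = "deleterious",
                   anc_truth = "A", out1 = "A", out2 = "A"))
  ds2$genotypes <- rbind(ds$genotypes, pad)
  lr2 <- load_ratios(ds2, polarize_sites(ds2))
  expect_equal(lr$ratio_het, lr2$ratio_het)
  expect_equal(lr$ratio_hom, lr2$ratio_hom)
})

test_that("ROH stratification partitions the derived counts", {
  ds <- tiny_cohort()
  pol <- polarize_sites(ds)
  segs <- detect_roh(ds, eps = 0.001)
  lr <- load_ratios(ds, pol)
  rs <- roh_stratified_ratios(ds, segs, pol)
  merged <- dplyr::inner_join(
    lr, rs, by = c("individual", "population", "species", "class"))
  expect_equal(merged$derived_in + merged$derived_out,
               merged$derived_het + merged$derived_hom)
  expect_equal(merged$syn_in + merged$syn_out,
               merged$syn_het + merged$syn_hom)

  # no segments: everything is outside and totals match
  rs0 <- roh_stratified_ratios(ds, segs[0, ], pol)
  expect_true(all(rs0$derived_in == 0))
  expect_true(all(is.na(rs0$ratio_in)))
  m0 <- dplyr::inner_join(
    lr, rs0, by = c("individual", "population", "species", "class"))
  expect_equal(m0$derived_out, m0$derived_het + m0$derived_hom)
})

test_that("a one-site ROH is stratified exactly", {
  g <- matrix(c(2L, 1L,
                1L, 1L,
                2L, 0L,
                1L, 2L), 4, 2, byrow = TRUE,
              dimnames = list(NULL, c("popA_01", "popA_02")))
  ds <- manual_cohort(g, c("deleterious", "synonymous",
                           "synonymous", "deleterious"),
                      positions = c(1000L, 2000L, 3000L, 4000L))
  segs <- tibble::tibble(individual = "popA_01", contig = "ctg1",
                         start = 2500L, end = 3500L)
  rs <- roh_stratified_ratios(ds, segs, polarize_sites(ds))
  ind1 <- rs[rs$individual == "popA_01" & rs$class == "deleterious", ]
  expect_equal(ind1$syn_in, 2L)        # site 3, hom derived
  expect_equal(ind1$derived_in, 0L)
  expect_equal(ind1$derived_out, 3L)   # sites 1 (2) + 4 (1)
  expect_equal(ind1$syn_out, 1L)       # site 2 het
})

test_that("Welch tests compare the two species labels", {
  ds <- tiny_cohort()
  pol <- polarize_sites(ds)
  lr <- load_ratios(ds, pol)
  tt <- load_tests(lr)
  expect_true(all(c("class", "stratum", "t", "p") %in% names(tt)))
  expect_true(all(tt$p >= 0 & tt$p <= 1))
  expect_setequal(attr(tt, "species"), c("rare", "widespread"))
})

test_that("LD decay is 1 for duplicates and ~1/n for independence", {
  set.seed(8)
  n <- 150
  dup <- rbinom(n, 2, 0.5)
  g <- rbind(dup, dup)
  colnames(g) <- sprintf("popA_%03d", 1:n)
  ds <- manual_cohort(g, rep("synonymous", 2),
                      positions = c(1000L, 1100L))
  ld <- ld_decay(ds, max_dist = 1e4, bin_width = 1e3, max_pairs = 50)
  expect_equal(max(ld$bins$mean_r2), 1, tolerance = 1e-9)

  g2 <- matrix(rbinom(80 * n, 2, 0.4), nrow = 80)
  colnames(g2) <- colnames(g)
  ds2 <- manual_cohort(g2, rep("synonymous", 80),
                       positions = seq(1e4, by = 1e4, length.out = 80))
  ld2 <- ld_decay(ds2, max_dist = 8e5, bin_width = 8e5, max_pairs = 4000)
  r2 <- weighted.mean(ld2$bins$mean_r2, ld2$bins$n_pairs)
  expect_gt(r2, 0.3 / n)
  expect_lt(r2, 3 / n)
  expect_equal(formals(ld_decay)$max_dist, 1e6)
})
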