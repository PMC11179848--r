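# Cohort generator, ROH implantation, VCF round-trip, and the
# record/site filters.

test_that("generation is byte-identical given (config, seed)", {
  cfg <- tiny_config(n_rare = 3L, n_widespread = 3L)
  cfg$site_budgets <- c(synonymous = 600L, deleterious = 300L)
  a <- generate_cohort(cfg, seed = 4)
  b <- generate_cohort(cfg, seed = 4)
  expect_identical(a$sites, b$sites)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$truth$roh, b$truth$roh)
  c <- generate_cohort(cfg, seed = 5)
  expect_false(identical(a$genotypes, c$genotypes))
})

test_that("outgroups equal the ancestral allele at zero divergence", {
  cfg <- tiny_config(n_rare = 3L, n_widespread = 3L)
  cfg$site_budgets <- c(synonymous = 500L)
  cfg$outgroup_divergence <- 0
  ds <- generate_cohort(cfg, seed = 2)
  expect_true(all(ds$sites$out1 == ds$sites$anc_truth))
  expect_true(all(ds$sites$out2 == ds$sites$anc_truth))
})

test_that("the default design is two cohorts of 32 and 51 individuals", {
  cfg <- default_cohort_config()
  expect_equal(cfg$populations$rare$n, 32L)
  expect_equal(cfg$populations$widespread$n, 51L)
  ds <- tiny_cohort()
  expect_equal(as.integer(table(ds$individuals$population)[c(
    "rare", "widespread")]), c(6L, 8L))
  expect_equal(length(unique(ds$individuals$species)), 2)
  validate_cohort(ds)
})

test_that("generated datasets satisfy their structural invariants", {
  ds <- tiny_cohort()
  expect_true(validate_cohort(ds))
  s <- ds$sites
  for (cn in unique(s$contig)) {
    expect_true(!is.unsorted(s$pos[s$contig == cn], strictly = TRUE))
  }
  g <- ds$genotypes
  expect_true(all(g[!is.na(g)] %in% 0:2))
  expect_gt(mean(is.na(g)), 0.005)  # missingness applied
  expect_lt(mean(is.na(g)), 0.05)
})

test_that("ROH implantation reaches its target fraction", {
  cfg <- tiny_config(n_rare = 3L, n_widespread = 3L)
  cfg$site_budgets <- c(synonymous = 2000L)
  cfg$populations$rare$f_roh_range <- c(0, 0)
  cfg$populations$widespread$f_roh_range <- c(0, 0)
  ds <- generate_cohort(cfg, seed = 3)
  expect_equal(nrow(ds$truth$roh), 0)
  expect_true(all(ds$truth$f_roh == 0))

  set.seed(9)
  ds2 <- implant_roh(ds, targets = c(0.22, 0, 0, 0, 0, 0),
                     min_length = 1e5, mean_length = 2.5e5,
                     max_length = 8e5)
  achieved <- ds2$truth$f_roh[[1]]
  expect_lt(abs(achieved - 0.22), 0.01)
  # tract genotypes are homozygous up to the error knob
  tr <- ds2$truth$roh[ds2$truth$roh$individual ==
                        ds2$individuals$id[1], ]
  expect_gt(nrow(tr), 0)
  in_tr <- rep(FALSE, nrow(ds2$sites))
  for (k in seq_len(nrow(tr))) {
    in_tr <- in_tr | (ds2$sites$contig == tr$contig[k] &
                        ds2$sites$pos >= tr$start[k] &
                        ds2$sites$pos <= tr$end[k])
  }
  gg <- ds2$genotypes[in_tr, 1]
  expect_lt(mean(gg == 1, na.rm = TRUE), 0.02)
  expect_error(implant_roh(ds, targets = 0.95), "targets")
})

test_that("VCF write/read round-trips the data model", {
  ds <- tiny_cohort()
  ds100 <- subset_sites(ds, 1:100)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(ds100, f)
  back <- read_vcf(f)
  expect_equal(back$sites$pos, ds100$sites$pos)
  expect_equal(back$sites$ref, ds100$sites$ref)
  expect_equal(back$sites$alt, ds100$sites$alt)
  expect_equal(back$sites$effect_class, ds100$sites$effect_class)
  expect_equal(back$sites$out1, ds100$sites$out1)
  expect_equal(unname(back$genotypes), unname(ds100$genotypes))
  expect_equal(back$contigs$length, ds100$contigs$length)
  expect_equal(back$individuals$population, ds100$individuals$population)
  # missing genotypes survive as ./.
  expect_true(any(is.na(ds100$genotypes)) == any(is.na(back$genotypes)))
  # sidecar truth BED uses 0-based half-open starts
  bed <- read.table(paste0(f, ".roh_truth.bed"), sep = "\t")
  k <- match(paste(bed$V4[1], bed$V1[1]),
             paste(ds$truth$roh$individual, ds$truth$roh$contig))
  expect_true(any(ds$truth$roh$start == bed$V2[1] + 1))
})

test_that("non-biallelic records are rejected with their position", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=ctg1,length=1000000>",
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"x\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", "popA_01"), collapse = "\t"),
    "ctg1\t500\ts1\tA\tG\t.\tPASS\tCLASS=synonymous\tGT\t0/1",
    "ctg1\t777\ts2\tA\tG,T\t.\tPASS\tCLASS=synonymous\tGT\t0/1"
  ), f)
  expect_error(read_vcf(f), "777")
})

test_that("hard filters implement the documented clause semantics", {
  # 10 records, one failing clause each plus two clean ones
  rec <- tibble::tibble(
    id = 1:10,
    QUAL = c(29.9, 30, 100, 100, 100, 100, 100, 100, 100, 100),
    DP = c(10, 10, 4.9, 5, 10, 10, 10, 10, 10, 10),
    QD = c(5, 5, 5, 5, 1.9, 5, 5, 5, 5, 2.0),
    MQ = c(50, 50, 50, 50, 50, 39.9, 50, 50, 50, 40),
    FS = c(0, 0, 0, 0, 0, 0, 60.1, 0, 0, 60),
    SOR = c(1, 1, 1, 1, 1, 1, 1, 3.1, 1, 3),
    MQRankSum = c(0, 0, 0, 0, 0, 0, 0, 0, -12.6, -12.5),
    ReadPosRankSum = c(0, 0, 0, 0, 0, 0, 0, 0, 0, -8.0)
  )
  res <- apply_hard_filters(rec)
  # failures: 1 (QUAL), 3 (DP), 5 (QD), 6 (MQ), 7 (FS), 8 (SOR), 9 (MQRankSum)
  expect_equal(res$kept$id, c(2L, 4L, 10L))
  expect_equal(sum(res$log$n_failed), 7)
  # absent annotation passes the clause and is logged
  rec2 <- tibble::tibble(QUAL = c(100, 20))
  res2 <- apply_hard_filters(rec2)
  expect_equal(nrow(res2$kept), 1)
  expect_equal(res2$log$n_missing[res2$log$clause == "DP"], 2L)
})

test_that("MAF/missingness filters remove boundary cases", {
  # 10 individuals, hand-computed MAF and missingness per site
  g <- rbind(
    rep(0L, 10),                                  # invariant, MAF 0 -> out
    c(1L, rep(0L, 9)),                            # MAF 0.05 -> out (boundary)
    c(1L, 1L, rep(0L, 8)),                        # MAF 0.10 -> kept
    c(rep(2L, 9), 0L),                            # MAF 0.10 -> kept
    c(NA, rep(c(1L, 0L), 4), 1L),                 # missing 0.10 -> out
    c(NA, NA, rep(1L, 8)),                        # missing 0.20 -> out
    c(rep(1L, 5), rep(0L, 5))                     # MAF 0.25 -> kept
  )
  colnames(g) <- sprintf("popA_%02d", 1:10)
  ds <- manual_cohort(g, effect_class = rep("synonymous", nrow(g)))
  out <- site_filters(ds)
  expect_equal(out$sites$site_id, c(3L, 4L, 7L))
  log <- attr(out, "site_filter_log")
  expect_equal(log$n_kept, 3)
})

test_that("LD pruning drops duplicated sites and keeps independent ones", {
  set.seed(12)
  n <- 200
  base <- matrix(rbinom(40 * n, 2, 0.4), nrow = 40)
  g <- rbind(base[1:20, ], base[20, , drop = FALSE], base[21:40, ])
  colnames(g) <- sprintf("popA_%03d", seq_len(n))
  ds <- manual_cohort(g, effect_class = rep("synonymous", nrow(g)))
  kept <- ld_prune(ds)
  # exactly one of the duplicated pair (rows 20, 21) survives
  expect_equal(sum(kept %in% c(20L, 21L)), 1)
  expect_equal(kept[kept %in% c(20L, 21L)], 20L)  # later site removed
  # independent sites at n = 200: expected r^2 ~ 1/200, far below 0.2
  expect_gt(length(kept), 35)
  # documented defaults
  expect_equal(formals(ld_prune)$window, 100L)
  expect_equal(formals(ld_prune)$step, 10L)
  expect_equal(formals(ld_prune)$r2_max, 0.2)
})
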