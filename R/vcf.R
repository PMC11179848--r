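# VCF 4.2 I/O for cohort datasets. Writing is plain-text serialization
# of the package's own data model (GT-only records, effect class and
# ancestral truth in INFO tags); reading goes through vcfR.

#' Write a cohort dataset to VCF 4.2
#'
#' Emits one biallelic SNP record per site with GT genotypes
#' (`0/0`, `0/1`, `1/1`, `./.`), contig header lines, and INFO tags
#' `CLASS` (effect class), `AAtruth` (true ancestral allele), `OG1`,
#' `OG2` (outgroup alleles). Coordinates are 1-based inclusive.
#'
#' @param dataset A `cohort_dataset`.
#' @param path Output file path.
#' @param sidecar If `TRUE` (default), also writes `<path>.classes.tsv`
#'   (site effect classes), `<path>.outgroups.tsv` (outgroup alleles),
#'   and `<path>.roh_truth.bed` (implanted tracts, BED half-open
#'   0-based) next to the VCF.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(dataset, path, sidecar = TRUE) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  s <- dataset$sites
  g <- dataset$genotypes
  gt <- matrix("./.", nrow(g), ncol(g))
  gt[!is.na(g) & g == 0L] <- "0/0"
  gt[!is.na(g) & g == 1L] <- "0/1"
  gt[!is.na(g) & g == 2L] <- "1/1"
  info <- paste0("CLASS=", s$effect_class, ";AAtruth=", s$anc_truth,
                 ";OG1=", s$out1, ";OG2=", s$out2)
  body <- paste(s$contig, s$pos, paste0("site", s$site_id),
                s$ref, s$alt, ".", "PASS", info, "GT",
                apply(gt, 1L, paste, collapse = "\t"),
                sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=genload",
    paste0("##contig=<ID=", dataset$contigs$name,
           ",length=", format(dataset$contigs$length, scientific = FALSE,
                              trim = TRUE), ">"),
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Effect class\">",
    "##INFO=<ID=AAtruth,Number=1,Type=String,Description=\"True ancestral allele\">",
    "##INFO=<ID=OG1,Number=1,Type=String,Description=\"Outgroup 1 allele\">",
    "##INFO=<ID=OG2,Number=1,Type=String,Description=\"Outgroup 2 allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", dataset$individuals$id), collapse = "\t")
  )
  writeLines(c(header, body), path)
  if (sidecar) {
    utils::write.table(
      data.frame(contig = s$contig, pos = s$pos, class = s$effect_class),
      paste0(path, ".classes.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(contig = s$contig, pos = s$pos,
                 out1 = s$out1, out2 = s$out2),
      paste0(path, ".outgroups.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    roh <- dataset$truth$roh
    if (nrow(roh)) {
      utils::write.table(
        data.frame(chrom = roh$contig, start = roh$start - 1L,
                   end = roh$end, name = roh$individual),
        paste0(path, ".roh_truth.bed"),
        sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(path)
}

#' Read a cohort dataset from VCF
#'
#' Parses a VCF (via vcfR), requiring biallelic SNP records; a
#' non-biallelic record raises an error naming its position. Effect
#' classes and outgroup alleles are taken from the INFO tags written by
#' [write_vcf()] or, if absent, from sidecar tables. Populations are
#' inferred from sample-name prefixes (`<population>_<number>`) unless
#' an `individuals` table is given. `read_vcf(write_vcf(x))` is the
#' identity on the data model (minus the simulation truth block).
#'
#' @param path VCF file path.
#' @param class_table Optional data frame `contig, pos, class`.
#' @param outgroup_table Optional data frame `contig, pos, out1, out2`.
#' @param individuals Optional tibble `id, population, species`.
#' @return A `cohort_dataset` (truth block carries only what the file
#'   records).
#' @export
read_vcf <- function(path, class_table = NULL, outgroup_table = NULL,
                     individuals = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  bad <- !grepl("^[ACGT]$", fix$REF) | !grepl("^[ACGT]$", fix$ALT)
  if (any(bad)) {
    k <- which(bad)[1L]
    stop("non-biallelic or non-SNP record at ", fix$CHROM[k], ":",
         fix$POS[k], " (REF=", fix$REF[k], ", ALT=", fix$ALT[k], ")",
         call. = FALSE)
  }
  info_tag <- function(tag) {
    m <- regmatches(fix$INFO,
                    regexpr(paste0("(?:^|;)", tag, "=[^;]+"), fix$INFO))
    has <- grepl(paste0("(?:^|;)", tag, "="), fix$INFO)
    out <- rep(NA_character_, nrow(fix))
    out[has] <- sub(paste0("^;?", tag, "="), "",
                    regmatches(fix$INFO,
                               regexpr(paste0("(?:^|;)", tag, "=[^;]*"),
                                       fix$INFO)))
    out
  }
  eff <- info_tag("CLASS")
  anc <- info_tag("AAtruth")
  og1 <- info_tag("OG1")
  og2 <- info_tag("OG2")

  sites <- tibble::tibble(
    site_id = seq_len(nrow(fix)),
    contig = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    effect_class = eff, anc_truth = anc, out1 = og1, out2 = og2
  )
  key <- paste(sites$contig, sites$pos)
  if (!is.null(class_table)) {
    sites$effect_class <- class_table$class[
      match(key, paste(class_table$contig, class_table$pos))]
  }
  if (!is.null(outgroup_table)) {
    k2 <- match(key, paste(outgroup_table$contig, outgroup_table$pos))
    sites$out1 <- outgroup_table$out1[k2]
    sites$out2 <- outgroup_table$out2[k2]
  }

  gt <- vcfR::extract.gt(v, element = "GT")
  geno <- matrix(NA_integer_, nrow(gt), ncol(gt),
                 dimnames = list(NULL, colnames(gt)))
  geno[gt %in% c("0/0", "0|0")] <- 0L
  geno[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  geno[gt %in% c("1/1", "1|1")] <- 2L

  ids <- colnames(gt)
  if (is.null(individuals)) {
    pop <- sub("_[0-9]+$", "", ids)
    individuals <- tibble::tibble(id = ids, population = pop, species = pop)
  }

  meta <- v@meta
  ctg <- meta[grepl("^##contig=", meta)]
  contigs <- tibble::tibble(
    name = sub(".*ID=([^,>]+).*", "\\1", ctg),
    length = as.numeric(sub(".*length=([0-9]+).*", "\\1", ctg))
  )
  if (nrow(contigs) == 0) {
    stop("VCF is missing ##contig header lines", call. = FALSE)
  }

  classes <- list(
    synonymous = selection_class(0, 0.5),
    tolerated = selection_class(0.001, 0.35),
    deleterious = selection_class(0.1, 0.05),
    lof = selection_class(0.3, 0.02)
  )
  structure(
    list(contigs = contigs, sites = sites, genotypes = geno,
         individuals = individuals,
         truth = list(seed = NA_integer_,
                      config = list(classes = classes),
                      q = list(),
                      roh = tibble::tibble(individual = character(),
                                           contig = character(),
                                           start = integer(),
                                           end = integer()),
                      f_roh = NULL)),
    class = "cohort_dataset")
}
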