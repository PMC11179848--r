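# Shared fixtures: a down-scaled two-cohort config that preserves the
# default scenario's structure (declining inbred cohort vs recovered
# outbred cohort) but runs in seconds, and a per-session cache so
# several test files can reuse the same generated cohort.

tiny_config <- function(n_rare = 6L, n_widespread = 8L) {
  cfg <- default_cohort_config(
    n_rare = n_rare, n_widespread = n_widespread,
    contig_length = 1e6, n_contigs = 4L,
    site_budgets = c(synonymous = 4000L, tolerated = 1500L,
                     deleterious = 1500L, lof = 600L))
  cfg$populations$rare$trajectory <- demographic_trajectory(
    c(200L, 80L, 40L), c(20L, 150L, 50L), name = "rare")
  cfg$populations$widespread$trajectory <- demographic_trajectory(
    c(200L, 150L, 200L), c(20L, 150L, 50L), name = "widespread")
  cfg$roh$mean_length <- 2.5e5
  cfg$roh$max_length <- 8e5
  cfg
}

.cohort_cache <- new.env(parent = emptyenv())

tiny_cohort <- function(seed = 11L) {
  key <- as.character(seed)
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- generate_cohort(tiny_config(), seed = seed)
  }
  .cohort_cache[[key]]
}

# hand-buildable cohort: explicit genotypes / classes / outgroups, for
# pencil-and-paper fixtures
manual_cohort <- function(genotypes, effect_class,
                          out1 = NULL, out2 = NULL,
                          contig_length = 1e6,
                          populations = NULL, species = NULL,
                          positions = NULL) {
  n_sites <- nrow(genotypes)
  n_ind <- ncol(genotypes)
  ids <- colnames(genotypes) %||% sprintf("ind_%02d", seq_len(n_ind))
  populations <- populations %||% rep("popA", n_ind)
  species <- species %||% populations
  positions <- positions %||% seq(1000L, by = 1000L, length.out = n_sites)
  ref <- rep("A", n_sites)
  alt <- rep("G", n_sites)
  classes <- list(
    synonymous = selection_class(0, 0.5),
    tolerated = selection_class(0.001, 0.35),
    deleterious = selection_class(0.1, 0.05),
    lof = selection_class(0.3, 0.02)
  )
  structure(
    list(
      contigs = tibble::tibble(name = "ctg1", length = contig_length),
      sites = tibble::tibble(
        site_id = seq_len(n_sites), contig = "ctg1", pos = positions,
        ref = ref, alt = alt, effect_class = effect_class,
        anc_truth = ref,
        out1 = out1 %||% ref, out2 = out2 %||% ref),
      genotypes = genotypes,
      individuals = tibble::tibble(id = ids, population = populations,
                                   species = species),
      truth = list(seed = NA_integer_,
                   config = list(classes = classes),
                   q = stats::setNames(
                     lapply(unique(populations), function(p) {
                       cols <- which(populations == p)
                       rowMeans(genotypes[, cols, drop = FALSE],
                                na.rm = TRUE) / 2
                     }), unique(populations)),
                   roh = tibble::tibble(individual = character(),
                                        contig = character(),
                                        start = integer(),
                                        end = integer()),
                   f_roh = NULL)),
    class = "cohort_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
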