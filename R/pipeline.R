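# Scenario orchestration: generator -> filters -> polarization -> ROH
# -> load statistics -> burden predictions, with a machine-readable
# summary of all directional checks, plus matrix-vs-simulator engine
# comparison.

#' Run the full two-cohort scenario
#'
#' Executes generate -> polarize -> ROH detection -> diversity,
#' heterozygosity, F_ROH -> zygosity- and ROH-stratified load ratios
#' (and optionally matrix-engine burden predictions for the config's
#' trajectories), then evaluates the directional contrasts expected
#' between a bottlenecked, purging cohort and a large, recovered one:
#' lower diversity, lower heterozygosity, higher F_ROH, lower
#' deleterious/synonymous ratios at het and hom sites, lower
#' deleterious ratios inside than outside ROH, and a negative
#' F_ROH-heterozygosity correlation.
#'
#' @param config Generator config ([default_cohort_config()]).
#' @param seed Integer seed (all randomness flows from it).
#' @param include_predictions Also run [predict_grid()] on the config's
#'   trajectories (slower; default `FALSE`).
#' @param out_dir Optional directory: writes tidy TSV tables and a
#'   `summary.json` (config hash and seed embedded in every output).
#' @param rare,widespread Population names to contrast (defaults to
#'   the two populations of the default config, in declined/recovered
#'   order).
#' @return A list of class `scenario_report`: `tables` (named list of
#'   tibbles: `pi`, `heterozygosity`, `f_roh`, `load`, `roh_load`,
#'   `tests`, optionally `predictions`), `checks` (named logical
#'   vector), `values` (named numeric vector backing the checks),
#'   `seed`, `config_hash`.
#' @export
run_scenario <- function(config = default_cohort_config(), seed = 1L,
                         include_predictions = FALSE, out_dir = NULL,
                         rare = NULL, widespread = NULL) {
  pops <- names(config$populations)
  rare <- rare %||% pops[1L]
  widespread <- widespread %||% pops[2L]
  stage <- "generate"
  res <- tryCatch({
    dataset <- generate_cohort(config, seed)

    stage <- "diversity"
    pi_tab <- population_pi(dataset)
    het_tab <- individual_heterozygosity(dataset)

    stage <- "polarize"
    pol <- polarize_sites(dataset, mode = "strict")

    stage <- "roh"
    segs <- detect_roh(dataset, eps = config$roh$het_error)
    froh_tab <- f_roh(segs, sum(dataset$contigs$length),
                      individuals = dataset$individuals$id)
    froh_tab$population <- dataset$individuals$population[
      match(froh_tab$individual, dataset$individuals$id)]

    stage <- "load"
    load_tab <- load_ratios(dataset, pol)
    roh_load_tab <- roh_stratified_ratios(dataset, segs, pol)
    tests_tab <- load_tests(load_tab)

    stage <- "checks"
    pi_r <- pi_tab$pi[pi_tab$population == rare]
    pi_w <- pi_tab$pi[pi_tab$population == widespread]
    het_r <- mean(het_tab$heterozygosity[het_tab$population == rare])
    het_w <- mean(het_tab$heterozygosity[het_tab$population == widespread])
    froh_r <- mean(froh_tab$f_roh[froh_tab$population == rare])
    froh_w <- mean(froh_tab$f_roh[froh_tab$population == widespread])
    del <- load_tab[load_tab$class == "deleterious", ]
    rhet_r <- mean(del$ratio_het[del$population == rare], na.rm = TRUE)
    rhet_w <- mean(del$ratio_het[del$population == widespread], na.rm = TRUE)
    rhom_r <- mean(del$ratio_hom[del$population == rare], na.rm = TRUE)
    rhom_w <- mean(del$ratio_hom[del$population == widespread], na.rm = TRUE)
    rdel <- roh_load_tab[roh_load_tab$class == "deleterious", ]
    rin <- mean(rdel$ratio_in, na.rm = TRUE)
    rout <- mean(rdel$ratio_out, na.rm = TRUE)
    cor_fh <- stats::cor(froh_tab$f_roh,
                         het_tab$heterozygosity[
                           match(froh_tab$individual, het_tab$individual)])

    checks <- c(
      pi_lower = pi_r < pi_w,
      het_lower = het_r < het_w,
      f_roh_higher = froh_r > froh_w,
      del_het_ratio_lower = rhet_r < rhet_w,
      del_hom_ratio_lower = rhom_r < rhom_w,
      del_in_roh_lower = rin < rout,
      f_roh_het_negative_cor = cor_fh < 0
    )
    values <- c(
      pi_rare = pi_r, pi_widespread = pi_w,
      het_rare = het_r, het_widespread = het_w,
      f_roh_rare = froh_r, f_roh_widespread = froh_w,
      del_ratio_het_rare = rhet_r, del_ratio_het_widespread = rhet_w,
      del_ratio_hom_rare = rhom_r, del_ratio_hom_widespread = rhom_w,
      del_ratio_in_roh = rin, del_ratio_out_roh = rout,
      f_roh_het_cor = cor_fh
    )

    tables <- list(pi = pi_tab, heterozygosity = het_tab,
                   f_roh = froh_tab, load = load_tab,
                   roh_load = roh_load_tab, tests = tests_tab)
    if (include_predictions) {
      stage <- "predict"
      trajs <- lapply(config$populations, `[[`, "trajectory")
      tables$predictions <- predict_grid(trajs)
    }
    list(tables = tables, checks = checks, values = values)
  }, error = function(e) {
    stop("scenario failed at stage '", stage, "' (seed ", seed, "): ",
         conditionMessage(e), call. = FALSE)
  })

  report <- structure(
    list(tables = res$tables, checks = res$checks, values = res$values,
         seed = seed, config_hash = rlang::hash(config)),
    class = "scenario_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(report$tables)) {
      tab <- report$tables[[nm]]
      tab$config_hash <- report$config_hash
      tab$seed <- seed
      utils::write.table(tab, file.path(out_dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(
      list(seed = seed, config_hash = report$config_hash,
           checks = as.list(report$checks),
           values = as.list(report$values)),
      file.path(out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.scenario_report <- function(x, ...) {
  cat("<scenario_report> seed", x$seed, "config", x$config_hash, "\n")
  for (nm in names(x$checks)) {
    cat(sprintf("  %-24s %s\n", nm, if (x$checks[[nm]]) "yes" else "NO"))
  }
  invisible(x)
}

#' Replicate the directional checks over several seeds
#'
#' Runs [run_scenario()] for each seed and tabulates which directional
#' contrasts held.
#'
#' @param seeds Integer vector of seeds.
#' @param config Generator config.
#' @return A tibble with one row per seed and one logical column per
#'   check, plus `all_pass`.
#' @export
directionality_suite <- function(seeds = 1:5,
                                 config = default_cohort_config()) {
  rows <- lapply(seeds, function(sd) {
    rep_i <- run_scenario(config, seed = sd)
    out <- tibble::as_tibble(as.list(rep_i$checks))
    out$seed <- sd
    out$all_pass <- all(rep_i$checks)
    out
  })
  dplyr::bind_rows(rows)
}

#' Compare the matrix engine against the stochastic simulator
#'
#' For every `(s, h)` cell of the default deleterious grid, computes
#' the equilibrium segregating burden with the transition-matrix engine
#' and estimates the same quantity with the forward Wright-Fisher
#' lifetime simulator ([sim_equilibrium_burden()]), reporting the
#' z-score of their difference in Monte-Carlo standard errors. A
#' lambda-linearity row (burden at `lam = 2` over burden at `lam = 1`,
#' exactly 2 by construction) is included as a sanity check.
#'
#' @param N Diploid size at which to compare (`<= 500` keeps the
#'   simulator fast).
#' @param s_values,h_values Parameter grids.
#' @param reps Simulator replicates per cell.
#' @param seed Seed for the simulator stream.
#' @return A tibble: `s`, `h`, `n_seg_matrix`, `n_seg_sim`, `sim_se`,
#'   `z`, `lambda_linearity` (ratio, first row only).
#' @export
compare_engines <- function(N = 200, s_values = c(0.001, 0.01, 0.1),
                            h_values = c(0.05, 0.25, 0.45),
                            reps = 10000, seed = 1L) {
  rows <- list()
  first <- TRUE
  set.seed(seed)
  for (s in s_values) {
    for (h in h_values) {
      sc <- selection_class(s, h)
      eq <- msd_equilibrium(N, sc)
      sim <- sim_equilibrium_burden(N, sc, reps = reps)
      lin <- if (first) {
        msd_equilibrium(N, selection_class(s, h, lam = 2))$n_seg / eq$n_seg
      } else NA_real_
      first <- FALSE
      rows[[length(rows) + 1L]] <- tibble::tibble(
        s = s, h = h,
        n_seg_matrix = eq$n_seg,
        n_seg_sim = sim$n_seg,
        sim_se = sim$n_seg_se,
        z = (sim$n_seg - eq$n_seg) / sim$n_seg_se,
        lambda_linearity = lin)
    }
  }
  dplyr::bind_rows(rows)
}
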