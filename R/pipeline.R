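# Config-driven end-to-end driver: dataset build -> ER/ARD fit + LRT ->
# stochastic maps -> D statistic -> phylogenetic regressions -> occurrence
# thinning -> maxent fit with contributions, response curves and
# difference maps -- with derived per-stage seeds, structured logging and
# a consolidated JSON-serializable report.

#' Assemble a pipeline configuration
#'
#' Inputs may be in-memory objects (tree, trait table, rasters,
#' occurrences) or file paths (Newick / CSV / ESRI ASCII grids), as
#' produced by [synth_world()] or read from disk. A YAML file with the
#' same field names is accepted via `yaml::read_yaml()` when the `yaml`
#' package is installed.
#'
#' @param tree `phylo` or Newick path.
#' @param traits Trait table data frame or CSV path.
#' @param rasters Named list of `raster_grid`s or ASCII grid paths.
#' @param occurrences `occurrence_set` or CSV path (species, lon, lat).
#' @param diversity Optional diversity `raster_grid` or path.
#' @param region,sex_priority Dataset subset selectors.
#' @param clade Optional partition column for the model screen.
#' @param covariate_sets Named list of covariate vectors for
#'   [model_screen()]; `NULL` fits all available covariates once.
#' @param n_maps,n_null,reg,thin_grid_deg,thin_cap Stage parameters.
#' @param run_ventral Fit regressions on ventral subsets too (default
#'   `FALSE`: black ventral skin is too rare for stable regression, so the
#'   subsets are built but the fit is skipped with a logged note).
#' @param seed Master seed; each stochastic stage gets a derived,
#'   logged sub-seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(tree, traits, rasters = NULL,
                            occurrences = NULL, diversity = NULL,
                            region = "head", sex_priority = "male",
                            clade = NULL, covariate_sets = NULL,
                            n_maps = 100, n_null = 1000, reg = 1.0,
                            thin_grid_deg = 2, thin_cap = 50,
                            run_ventral = FALSE, seed = 1L) {
  structure(list(
    tree = tree, traits = traits, rasters = rasters,
    occurrences = occurrences, diversity = diversity,
    region = region, sex_priority = sex_priority, clade = clade,
    covariate_sets = covariate_sets,
    n_maps = n_maps, n_null = n_null, reg = reg,
    thin_grid_deg = thin_grid_deg, thin_cap = thin_cap,
    run_ventral = run_ventral, seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Reads a YAML file whose top-level keys are the arguments of
#' [pipeline_config()]; path-valued entries (tree, traits, rasters,
#' occurrences, diversity) are loaded lazily by [run_pipeline()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read config files", call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

.pipe_load_tree <- function(x) {
  if (inherits(x, "phylo")) return(validate_tree(x))
  suppressMessages(read_newick(x))
}

.pipe_load_traits <- function(x) {
  if (is.data.frame(x)) return(validate_trait_table(x))
  read_trait_table(x)
}

.pipe_log <- function(log_env, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  log_env$lines <- c(log_env$lines, line)
  message(line)
}

#' Per-region descriptive counts of the trait
#'
#' For each body region: species scored, species with the trait (a species
#' counts as black when any of its specimens was scored black), genera and
#' families with at least one black-skinned species, and the percentages
#' over the genera/families represented in the table.
#'
#' @param tab Trait table with `genus` and `family` columns.
#' @return Data frame, one row per region.
#' @export
descriptive_counts <- function(tab) {
  tab <- validate_trait_table(tab)
  miss <- setdiff(c("genus", "family"), names(tab))
  if (length(miss)) stop("trait table missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  out <- lapply(split(tab, tab$region), function(d) {
    by_sp <- vapply(split(d$skin == "black", d$species), any, logical(1))
    sp_black <- names(by_sp)[by_sp]
    gen_black <- unique(d$genus[d$species %in% sp_black])
    fam_black <- unique(d$family[d$species %in% sp_black])
    data.frame(
      region = d$region[1],
      n_species = length(by_sp),
      n_black_species = length(sp_black),
      n_genera_black = length(gen_black),
      n_families_black = length(fam_black),
      pct_genera = 100 * length(gen_black) / length(unique(d$genus)),
      pct_families = 100 * length(fam_black) / length(unique(d$family))
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the full analysis pipeline
#'
#' Executes, in order: analysis-dataset build, ER/ARD Mk fits with the
#' likelihood-ratio test, stochastic mapping with gain/loss summary, the
#' D statistic, phylogenetic logistic regressions (model screen when
#' covariate sets are supplied), occurrence thinning, the maxent fit with
#' variable contributions and response curves, and difference maps against
#' each predictor and relative diversity. Each stochastic stage receives a
#' derived sub-seed; the same config and seed produce an identical report.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Optional directory for `report.json`, `tables/*.csv`,
#'   `maps/*.asc` and `logs/run.log`.
#' @return The report list, invisibly when `out_dir` is given.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log_env <- new.env()
  log_env$lines <- character(0)
  report <- list(config = list(
    region = config$region, sex_priority = config$sex_priority,
    n_maps = config$n_maps, n_null = config$n_null, reg = config$reg,
    thin_grid_deg = config$thin_grid_deg, thin_cap = config$thin_cap,
    seed = config$seed
  ))
  sub_seed <- function(stage, off) {
    s <- config$seed + off
    .pipe_log(log_env, stage, paste("sub-seed", s))
    s
  }
  stage <- function(name, expr) {
    .pipe_log(log_env, name, "start")
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  tree <- stage("load", .pipe_load_tree(config$tree))
  traits <- stage("load", .pipe_load_traits(config$traits))

  ds <- stage("dataset", suppressMessages(build_analysis_dataset(
    traits, region = config$region, sex_priority = config$sex_priority,
    tree = tree)))
  rec <- attr(ds, "reconciliation")
  .pipe_log(log_env, "dataset",
            sprintf("%d species, %d black, %d table names unmatched",
                    nrow(ds), sum(ds$y), length(rec$unmatched_table)))
  report$dataset <- list(subset = attr(ds, "subset"), n_species = nrow(ds),
                         n_black = sum(ds$y),
                         n_unmatched_table = length(rec$unmatched_table),
                         n_dropped_missing = attr(ds, "n_dropped_missing"))
  report$descriptive <- descriptive_counts(traits)

  y <- stats::setNames(ds$y, ds$species)
  tr_sub <- ape::keep.tip(tree, ds$species)

  fit_er <- stage("mk_fit", fit_mk(tr_sub, y, model = "ER"))
  fit_ard <- stage("mk_fit", fit_mk(tr_sub, y, model = "ARD"))
  lrt <- stage("mk_fit", lrt_er_vs_ard(fit_er, fit_ard))
  .pipe_log(log_env, "mk_fit",
            sprintf("ARD q01=%.4g q10=%.4g, LRT p=%.3g",
                    fit_ard$q01, fit_ard$q10, lrt$p))
  report$mk <- list(er = list(q = fit_er$q01, loglik = fit_er$loglik),
                    ard = list(q01 = fit_ard$q01, q10 = fit_ard$q10,
                               loglik = fit_ard$loglik),
                    lrt = lrt,
                    best_model = if (lrt$p < 0.05) "ARD" else "ER")

  maps <- stage("simmap", sample_histories(
    tr_sub, y, fit_ard, n_maps = config$n_maps,
    seed = sub_seed("simmap", 11L)))
  ms <- summarize_maps(maps)
  .pipe_log(log_env, "simmap", sprintf("median gains %g, losses %g",
                                       ms$gains["median"],
                                       ms$losses["median"]))
  report$stochastic_maps <- list(
    n_maps = ms$n_maps,
    gains = as.list(ms$gains), losses = as.list(ms$losses))

  dres <- stage("dstat", d_statistic(tr_sub, y, n_null = config$n_null,
                                     seed = sub_seed("dstat", 23L)))
  report$d_statistic <- dres[c("d_obs", "D", "p_random", "p_brownian",
                               "n_null", "prevalence")]

  # regressions: ventral subsets are built but skipped unless requested
  if (config$region == "venter" && !config$run_ventral) {
    .pipe_log(log_env, "regression",
              "ventral subset built but regression skipped (trait too rare)")
    report$regression <- list(skipped = "ventral")
  } else {
    covs <- setdiff(names(ds)[vapply(ds, is.numeric, logical(1))], "y")
    fit <- stage("regression", fit_phylogistic(ds, tr_sub, covariates = covs))
    null_fit <- fit_phylogistic(ds, tr_sub, covariates = character(0),
                                alpha = fit$alpha)
    report$regression <- list(coefficients = fit$coefficients,
                              alpha = fit$alpha, loglik = fit$loglik,
                              r2 = r2_lik(fit, null_fit), n = fit$n)
    if (!is.null(config$covariate_sets)) {
      report$model_screen <- stage("regression", model_screen(
        ds, tr_sub, config$covariate_sets, clade = config$clade))
    }
  }

  if (!is.null(config$rasters) && !is.null(config$occurrences)) {
    rasters <- lapply(config$rasters, function(r) {
      if (inherits(r, "raster_grid")) r else read_ascii_grid(r)
    })
    occ <- config$occurrences
    if (!inherits(occ, "occurrence_set")) {
      d <- utils::read.csv(occ, stringsAsFactors = FALSE)
      occ <- occurrence_set(d$species, d$lon, d$lat)
    }
    thin <- stage("thin", thin_occurrences(
      occ, grid_deg = config$thin_grid_deg,
      cap_per_species = config$thin_cap, seed = sub_seed("thin", 37L)))
    .pipe_log(log_env, "thin", sprintf("%d -> %d occurrences",
                                       nrow(occ), nrow(thin)))
    mx <- stage("maxent", fit_maxent(thin, rasters, reg = config$reg))
    suit <- predict_suitability(mx, rasters)
    contrib <- variable_contribution(mx)
    curves <- lapply(mx$variables, function(v) response_curve(mx, v))
    names(curves) <- mx$variables
    diffs <- lapply(rasters, function(r) difference_map(suit, r))
    report$maxent <- list(
      lambda = as.list(mx$lambda), gain = mx$gain, entropy = mx$entropy,
      n_presence = mx$n_presence, n_thinned = nrow(thin),
      contribution = contrib,
      difference_map_mean_abs = vapply(diffs, function(d) {
        mean(abs(d$values), na.rm = TRUE)
      }, numeric(1)))
    if (!is.null(config$diversity)) {
      dv <- config$diversity
      if (!inherits(dv, "raster_grid")) dv <- read_ascii_grid(dv)
      rd <- relative_diversity(dv)
      dd <- difference_map(suit, rd)
      report$maxent$diversity_diff_mean_abs <-
        mean(abs(dd$values), na.rm = TRUE)
    }
    if (!is.null(out_dir)) {
      dir.create(file.path(out_dir, "maps"), recursive = TRUE,
                 showWarnings = FALSE)
      write_ascii_grid(suit, file.path(out_dir, "maps", "suitability.asc"))
      for (nm in names(diffs)) {
        write_ascii_grid(diffs[[nm]],
                         file.path(out_dir, "maps",
                                   paste0("diff_", nm, ".asc")))
      }
    }
  }

  report$log <- log_env$lines
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "tables"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(out_dir, "logs"), recursive = TRUE,
               showWarnings = FALSE)
    utils::write.csv(report$descriptive,
                     file.path(out_dir, "tables", "descriptive.csv"),
                     row.names = FALSE)
    if (!is.null(report$regression$coefficients)) {
      utils::write.csv(report$regression$coefficients,
                       file.path(out_dir, "tables", "coefficients.csv"),
                       row.names = FALSE)
    }
    writeLines(log_env$lines, file.path(out_dir, "logs", "run.log"))
    rep_json <- report
    rep_json$log <- NULL                 # timestamps would break identity
    jsonlite::write_json(rep_json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(report))
  }
  report
}
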