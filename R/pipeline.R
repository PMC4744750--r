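#' Assemble and validate a pipeline configuration
#'
#' Collects every knob of the end-to-end analysis in one validated list.
#' Inputs may be data frames or CSV paths (trees: a `phylo`/`multiPhylo`
#' object, list of trees, or a newick path). Defaulted decisions (sufficiency
#' thresholds, thinning, population grid) are logged at run start.
#'
#' @param counts transect counts (data frame or CSV path).
#' @param sites site coordinates (data frame or CSV path).
#' @param temperatures monthly temperatures (data frame or CSV path).
#' @param species optional character vector restricting the species analysed.
#' @param window_config optional per-species generation windows (see
#'   [generation_window()]).
#' @param min_positive_visits,min_span_days sufficiency thresholds.
#' @param cell_size_m temperature grid cell size, metres.
#' @param pop_grid_m population aggregation grid, metres (0 = site-level).
#' @param criterion window-selection criterion, `"t_value"` or
#'   `"coefficient"`.
#' @param n_iter,burn_in,thin Gibbs chain control.
#' @param seed integer RNG seed for the whole run.
#' @param prior a [prior_spec()].
#' @param trees optional phylogenies for the meta-analysis stage.
#' @param traits optional species trait table (`species_id` + trait columns).
#' @param run_meta fit the phylogenetic meta-analysis (requires `trees`).
#' @param out_dir optional output directory for CSVs and the run manifest.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, sites, temperatures, species = NULL,
                            window_config = NULL, min_positive_visits = 3L,
                            min_span_days = 7L, cell_size_m = 5000,
                            pop_grid_m = 50000,
                            criterion = c("t_value", "coefficient"),
                            n_iter = 13000L, burn_in = 3000L, thin = 10L,
                            seed = 1L, prior = prior_spec(), trees = NULL,
                            traits = NULL, run_meta = !is.null(trees),
                            out_dir = NULL) {
  if (is.character(counts)) counts <- read_counts_csv(counts)
  if (is.character(sites)) sites <- read_sites_csv(sites)
  if (is.character(temperatures)) temperatures <- read_temperatures_csv(temperatures)
  if (is.character(trees)) trees <- read_trees_newick(trees)
  if (inherits(trees, "phylo")) trees <- list(trees)
  criterion <- match.arg(criterion)
  stopifnot(min_positive_visits >= 0, min_span_days >= 0, cell_size_m > 0,
            pop_grid_m >= 0, n_iter > burn_in, thin >= 1)
  if (isTRUE(run_meta) && is.null(trees)) {
    stop("run_meta = TRUE requires trees", call. = FALSE)
  }
  structure(list(
    counts = counts, sites = sites, temperatures = temperatures,
    species = species, window_config = window_config,
    min_positive_visits = as.integer(min_positive_visits),
    min_span_days = as.integer(min_span_days), cell_size_m = cell_size_m,
    pop_grid_m = pop_grid_m, criterion = criterion,
    n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
    thin = as.integer(thin), seed = as.integer(seed), prior = prior,
    trees = trees, traits = traits, run_meta = isTRUE(run_meta),
    out_dir = out_dir
  ), class = "pipeline_config")
}

config_hash <- function(config) {
  skel <- config[c("species", "window_config", "min_positive_visits",
                   "min_span_days", "cell_size_m", "pop_grid_m", "criterion",
                   "n_iter", "burn_in", "thin", "seed")]
  skel$prior <- list(V = unclass(config$prior$V), nu = config$prior$nu)
  skel$n_counts <- nrow(config$counts)
  skel$n_sites <- nrow(config$sites)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(skel, auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}

#' Run the full decomposition pipeline
#'
#' Executes, per species: flight-record computation, sufficiency filtering,
#' three-month window selection, population aggregation, the bivariate mixed
#' model, and slope summaries; then optionally the phylogenetic meta-analysis
#' of the within-population slopes and slope differences. Species whose data
#' fail a stage precondition are reported as skipped rather than aborting the
#' run.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return an object of class `pipeline_result`: `summary` (one row per
#'   species with sample sizes, the selected window and mode/HPD columns for
#'   `b_time`, `b_space`, `delta_b` plus the local-adaptation decision),
#'   `selections`, `slopes` (per-species slope posteriors), `skipped`,
#'   `meta` (when run: fits for `b_time` and `delta_b`), and `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  say("run_pipeline: seed %d; sufficiency (%d visits, %d days); pop grid %g m; thin %d",
      config$seed, config$min_positive_visits, config$min_span_days,
      config$pop_grid_m, config$thin)

  windows <- three_month_running_mean(config$temperatures)
  records_all <- flight_records(config$counts, config$window_config)
  records_all <- sufficiency_filter(records_all, config$min_positive_visits,
                                    config$min_span_days, quiet = quiet)
  species <- config$species
  if (is.null(species)) species <- sort(unique(records_all$species_id))

  summary_rows <- list()
  selections <- list()
  slopes <- list()
  skipped <- list()
  for (sp in species) {
    res <- tryCatch({
      rec <- records_all[records_all$species_id == sp, , drop = FALSE]
      if (!nrow(rec)) stop("no sufficient flight records")
      sel <- select_window(rec, windows, config$sites,
                           criterion = config$criterion,
                           cell_size_m = config$cell_size_m)
      obs <- paired_observations(rec, windows, config$sites,
                                 sel$selected_center_month,
                                 pop_grid_m = config$pop_grid_m,
                                 cell_size_m = config$cell_size_m)
      fit <- fit_bivariate_mixed(obs, prior = config$prior,
                                 n_iter = config$n_iter,
                                 burn_in = config$burn_in, thin = config$thin,
                                 seed = config$seed)
      sl <- slopes_from_vcv(fit)
      dec <- test_local_adaptation(sl)
      s <- sl$summary
      list(
        selection = sel, slopes = sl,
        row = data.frame(
          species_id = sp, n_sites = length(unique(obs$site_id)),
          n_site_years = nrow(obs),
          n_populations = length(unique(obs$population_id)),
          window_month = sel$selected_center_month,
          b_time_mode = s$b_time$mode, b_time_lo = s$b_time$hpd[1],
          b_time_hi = s$b_time$hpd[2],
          b_space_mode = s$b_space$mode, b_space_lo = s$b_space$hpd[1],
          b_space_hi = s$b_space$hpd[2],
          delta_b_mode = s$delta_b$mode, delta_b_lo = s$delta_b$hpd[1],
          delta_b_hi = s$delta_b$hpd[2],
          local_adaptation = dec$reject, direction = dec$direction,
          stringsAsFactors = FALSE
        )
      )
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[sp]] <- conditionMessage(res)
      say("species %s skipped: %s", sp, conditionMessage(res))
    } else {
      summary_rows[[sp]] <- res$row
      selections[[sp]] <- res$selection
      slopes[[sp]] <- res$slopes
      say("species %s: window %d, b_time %.2f, b_space %.2f, delta_b %.2f",
          sp, res$row$window_month, res$row$b_time_mode,
          res$row$b_space_mode, res$row$delta_b_mode)
    }
  }
  summary_df <- if (length(summary_rows)) {
    out <- do.call(rbind, summary_rows)
    rownames(out) <- NULL
    out
  } else {
    NULL
  }

  meta <- NULL
  if (config$run_meta && !is.null(summary_df) && nrow(summary_df) >= 3) {
    meta <- list()
    for (what in c("b_time", "delta_b")) {
      est <- data.frame(
        species_id = summary_df$species_id,
        y = summary_df[[paste0(what, "_mode")]],
        m_var = vapply(slopes[summary_df$species_id],
                       function(sl) var(sl[[what]]), numeric(1)),
        stringsAsFactors = FALSE
      )
      meta[[what]] <- tryCatch(
        pool_over_trees(config$trees, est, traits = config$traits,
                        prior = config$prior, total_iter = config$n_iter,
                        thin = config$thin, seed = config$seed),
        error = function(e) {
          say("meta-analysis of %s skipped: %s", what, conditionMessage(e))
          NULL
        }
      )
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("phenodecomp")),
    seed = config$seed, config_hash = config_hash(config),
    n_species_analysed = if (is.null(summary_df)) 0L else nrow(summary_df),
    n_species_skipped = length(skipped),
    defaults = list(min_positive_visits = config$min_positive_visits,
                    min_span_days = config$min_span_days,
                    thin = config$thin, pop_grid_m = config$pop_grid_m,
                    measurement_error = "diagonal M of per-species posterior variances")
  )

  result <- structure(list(
    summary = summary_df, selections = selections, slopes = slopes,
    skipped = skipped, meta = meta, manifest = manifest
  ), class = "pipeline_result")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(summary_df)) {
      write_table_csv(summary_df, file.path(config$out_dir, "species_summary.csv"))
    }
    for (sp in names(selections)) {
      write_table_csv(selections[[sp]]$diagnostics,
                      file.path(config$out_dir,
                                sprintf("window_diagnostics_%s.csv", sp)))
      write_table_csv(
        data.frame(b_time = slopes[[sp]]$b_time, b_space = slopes[[sp]]$b_space,
                   delta_b = slopes[[sp]]$delta_b),
        file.path(config$out_dir, sprintf("slope_draws_%s.csv", sp))
      )
    }
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                                digits = NA),
               file.path(config$out_dir, "manifest.json"))
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  n <- if (is.null(x$summary)) 0L else nrow(x$summary)
  cat(sprintf("Pipeline result: %d species analysed, %d skipped\n",
              n, length(x$skipped)))
  if (n) {
    print(x$summary[, c("species_id", "window_month", "b_time_mode",
                        "b_space_mode", "delta_b_mode", "local_adaptation")],
          digits = 3)
  }
  invisible(x)
}

#' Plot spatial versus temporal slopes
#'
#' Scatter of the among-population (spatial) slope against the
#' within-population (temporal) slope, one point per species, with the line
#' of unity marking the null hypothesis that temperature change over space
#' and time shifts phenology equally. Species below the line (spatial slope
#' shallower, for negative slopes) are flagged.
#'
#' @param summary a species summary data frame from [run_pipeline()] (columns
#'   `species_id`, `b_time_mode`, `b_space_mode`).
#' @param file optional path; when given the figure is written there (device
#'   chosen from the extension by [ggplot2::ggsave()]).
#' @return the ggplot object, invisibly.
#' @export
plot_space_time <- function(summary, file = NULL) {
  if (is.null(summary) || !nrow(summary)) {
    stop("no species summaries to plot", call. = FALSE)
  }
  d <- data.frame(
    species_id = summary$species_id,
    b_time = summary$b_time_mode,
    b_space = summary$b_space_mode
  )
  d$shallower_in_space <- d$b_space > d$b_time  # below unity line in Fig-2 orientation
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$b_space, y = .data$b_time)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$shallower_in_space)) +
    ggplot2::labs(
      x = "Among-population slope (days per °C)",
      y = "Within-population slope (days per °C)",
      colour = "Spatial slope shallower"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(file)) ggplot2::ggsave(file, p, width = 6, height = 5)
  invisible(p)
}
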