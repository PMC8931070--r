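## Run configuration and the end-to-end report: grid -> analysis tables
## -> regressions, written as delimited text with a reproducibility
## manifest binding every output to the network hash, config and seed.

#' Simulation run configuration
#'
#' Collects and validates the tunable settings of the analysis pipeline.
#' Defaults are the reference study conditions: a 30\% production shock,
#' alpha in {0, 0.5, 1}, a relative convergence tolerance of 1e-6, a
#' 95th-percentile reserve level, vulnerability thresholds of 250 and
#' 500 kcal/person/day, a one-million population floor for the reserve
#' table, and 365 days/year for per-capita conversion.
#'
#' @param ... named overrides of the defaults; unknown names are an
#'   error
#' @return an object of class \code{run_config} (a named list)
#' @export
run_config <- function(...) {
  cfg <- list(shock_fraction = 0.3, alphas = c(0, 0.5, 1),
              tolerance = 1e-6, max_steps = 10000, percentile = 0.95,
              thresholds = c(250, 500), pop_min = 1e6, seed = 1,
              days_per_year = 365)
  over <- list(...)
  if (length(over) > 0) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("config overrides must be named")
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown) > 0)
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
  }
  stopifnot(cfg$shock_fraction > 0, cfg$shock_fraction <= 1,
            all(cfg$alphas >= 0), all(cfg$alphas <= 1),
            cfg$tolerance > 0, cfg$max_steps >= 1,
            cfg$percentile > 0, cfg$percentile < 1,
            all(cfg$thresholds >= 0), cfg$pop_min >= 0,
            cfg$days_per_year > 0)
  class(cfg) <- "run_config"
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration:\n")
  for (nm in names(x))
    cat(sprintf("  %-15s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  invisible(x)
}

country_covariates <- function(network, features) {
  co <- network$countries
  f <- features[match(co$id, features$id), ]
  data.frame(id = co$id,
             log_pcgdp = log(co$gdp / co$population),
             in_degree = f$in_degree, out_degree = f$out_degree,
             log_in_strength = log1p(f$in_strength),
             log_out_strength = log1p(f$out_strength),
             c4 = f$c4, clustering = 1000 * f$clustering,
             log_betweenness = log1p(f$betweenness),
             hub = f$hub, pagerank = 1000 * f$pagerank,
             stringsAsFactors = FALSE)
}

country_formula <- function(response) {
  stats::as.formula(paste(
    response, "~ log_pcgdp + in_degree + out_degree + log_in_strength +",
    "log_out_strength + c4 + clustering + log_betweenness + hub +",
    "pagerank + alpha"))
}

write_table <- function(df, dir, name) {
  utils::write.csv(df, file.path(dir, name), row.names = FALSE)
}

fit_to_table <- function(fit) {
  tb <- coef_table(fit)
  data.frame(term = rownames(tb), tb, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Full analysis report on a trade network
#'
#' Chains the whole pipeline: the shock experiment grid, the
#' exposure/hedging/reserves/vulnerability tables, and the three
#' regressions (Tobit on dyadic deficits, negative binomial on
#' exceedance counts at each threshold, OLS on log rank-sums), writing
#' every table as CSV under \code{out_dir} together with a manifest
#' (network hash, configuration, seed, package version).  Timestamps go
#' to the log only, never into data files, so repeated runs with the
#' same configuration are byte-identical.
#'
#' @param network a \code{trade_network}
#' @param config a \code{\link{run_config}}
#' @param out_dir output directory (created if needed); NULL skips
#'   writing
#' @param regressions set FALSE to skip the regression stage (e.g. for
#'   very small fixture networks with fewer rows than covariates)
#' @return invisibly, a list with the grid, feature and topology
#'   objects, all tables and fitted models
#' @export
run_report <- function(network, config = run_config(), out_dir = NULL,
                       regressions = TRUE) {
  stopifnot(inherits(network, "trade_network"),
            inherits(config, "run_config"))
  grid <- run_grid(network, config$shock_fraction, config$alphas,
                   tol = NULL, max_steps = config$max_steps,
                   days_per_year = config$days_per_year)
  features <- node_features(network)
  topo <- topology_summary(network)

  expo <- do.call(rbind, lapply(config$alphas, function(a) {
    e <- exposure(grid, a); e$alpha <- a; e
  }))
  hedg <- do.call(rbind, lapply(config$alphas, function(a) {
    h <- hedging_share(grid, a); h$alpha <- a; h
  }))
  resv <- reserves_p95(grid, pop_min = config$pop_min,
                       percentile = config$percentile)
  cnts <- do.call(rbind, lapply(config$thresholds, function(th) {
    ct <- vulnerability_counts(grid, th); ct$threshold <- th; ct
  }))
  rnks <- vulnerability_rank(grid)

  conservation <- max(grid$runs$residual)
  message(sprintf("conservation check: max |sum(dd) - shock|/shock = %.3g (%s)",
                  conservation, if (conservation < 1e-6) "PASS" else "FAIL"))

  models <- NULL
  if (regressions) {
    dyad <- build_dyadic_table(grid, features, network)
    tob <- tobit_fit(prune_formula(dyadic_formula(), dyad), dyad)
    cov_tab <- country_covariates(network, features)
    nb <- lapply(config$thresholds, function(th) {
      d <- merge(cnts[cnts$threshold == th, ], cov_tab, by = "id")
      d$alpha <- factor(d$alpha)
      negbin_fit(prune_formula(country_formula("count"), d), d)
    })
    names(nb) <- paste0("threshold_", config$thresholds)
    dr <- merge(rnks, cov_tab, by = "id")
    dr$alpha <- factor(dr$alpha)
    ols <- ols_fit(prune_formula(country_formula("log_rank_sum"), dr), dr)
    models <- list(tobit = tob, negbin = nb, ols = ols,
                   tobit_standardized = standardize_coefficients(tob))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table(grid$grid, out_dir, "grid.csv")
    write_table(grid$runs, out_dir, "runs.csv")
    write_table(expo, out_dir, "exposure.csv")
    write_table(hedg, out_dir, "hedging.csv")
    write_table(resv, out_dir, "reserves.csv")
    write_table(cnts, out_dir, "counts.csv")
    write_table(rnks, out_dir, "ranks.csv")
    write_table(features, out_dir, "features.csv")
    if (!is.null(models)) {
      write_table(fit_to_table(models$tobit), out_dir, "tobit.csv")
      for (nm in names(models$negbin))
        write_table(fit_to_table(models$negbin[[nm]]), out_dir,
                    paste0("negbin_", nm, ".csv"))
      write_table(fit_to_table(models$ols), out_dir, "ols.csv")
      write_table(models$tobit_standardized, out_dir,
                  "tobit_standardized.csv")
    }
    manifest <- c(
      paste0("network_hash: ", grid$network_hash),
      paste0("package_version: ",
             as.character(utils::packageVersion("foodcascade"))),
      vapply(names(unclass(config)), function(nm)
        paste0(nm, ": ", paste(format(config[[nm]]), collapse = ",")),
        character(1)))
    writeLines(manifest, file.path(out_dir, "manifest.txt"))
  }
  invisible(list(grid = grid, features = features, topology = topo,
                 exposure = expo, hedging = hedg, reserves = resv,
                 counts = cnts, ranks = rnks, models = models,
                 conservation = conservation, config = config))
}
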