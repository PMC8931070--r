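## Batch shock experiments and the derived country-level statistics:
## exposure (mean deficit over shock origins), hedging (share of a
## domestic shock passed on), emergency-reserve levels (95th percentile
## of pooled deficits), and the two vulnerability measures
## (threshold-exceedance counts and log rank-sums).

#' Run the full shock experiment grid
#'
#' One cascade per (origin country, alpha): every country in turn loses
#' \code{shock_fraction} of its domestic production, for each value of
#' the export/import split alpha.  At the reference settings (172
#' countries, alpha in {0, 0.5, 1}) this yields 3 x 172^2 = 88,752
#' dyadic deficits.
#'
#' @inheritParams run_cascade
#' @param alphas alpha values to sweep
#' @return an object of class \code{shock_grid}: \code{grid} (data.frame
#'   with origin, dest, alpha, dd in kcal/person/day, dd_annual in
#'   kcal/year), \code{shock} (named per-origin kcal/year shock sizes),
#'   \code{runs} (per-cascade convergence log), plus the network hash,
#'   country table and settings used
#' @export
run_grid <- function(network, shock_fraction = 0.3, alphas = c(0, 0.5, 1),
                     tol = NULL, max_steps = 10000, days_per_year = 365) {
  stopifnot(inherits(network, "trade_network"))
  ids <- network$countries$id
  n <- network$n
  shock <- shock_fraction * network$countries$production
  names(shock) <- ids
  cells <- vector("list", length(alphas) * n)
  runs <- vector("list", length(alphas) * n)
  k <- 0L
  for (a in alphas) {
    for (o in ids) {
      res <- withCallingHandlers(
        run_cascade(network, o, shock_fraction, a, tol, max_steps,
                    days_per_year),
        warning = function(w) invokeRestart("muffleWarning"))
      k <- k + 1L
      cells[[k]] <- data.frame(origin = o, dest = ids, alpha = a,
                               dd = unname(res$final_dd_percap),
                               dd_annual = unname(res$final_dd),
                               stringsAsFactors = FALSE)
      runs[[k]] <- data.frame(origin = o, alpha = a, steps = res$steps,
                              converged = res$converged,
                              residual = res$residual,
                              stringsAsFactors = FALSE)
    }
  }
  runs <- do.call(rbind, runs)
  if (any(!runs$converged))
    warning(sum(!runs$converged), " cascade(s) did not converge within ",
            max_steps, " steps")
  structure(list(grid = do.call(rbind, cells), shock = shock, runs = runs,
                 alphas = alphas, shock_fraction = shock_fraction,
                 days_per_year = days_per_year,
                 countries = network$countries,
                 network_hash = network_hash(network)),
            class = "shock_grid")
}

#' @export
print.shock_grid <- function(x, ...) {
  cat(sprintf(
    "Shock experiment grid: %d origins x %d destinations x %d alpha value(s) = %d cells\n",
    length(x$shock), length(x$shock), length(x$alphas), nrow(x$grid)))
  cat(sprintf("  shock fraction %.2f; %d/%d cascades converged\n",
              x$shock_fraction, sum(x$runs$converged), nrow(x$runs)))
  invisible(x)
}

grid_alpha <- function(grid, alpha) {
  stopifnot(inherits(grid, "shock_grid"))
  if (!any(abs(grid$alphas - alpha) < 1e-12))
    stop("alpha ", alpha, " not present in the grid")
  grid$grid[abs(grid$grid$alpha - alpha) < 1e-12, , drop = FALSE]
}

#' Exposure to external shocks
#'
#' A country's exposure is its final demand deficit (kcal/person/day)
#' averaged over the simulations in which each country of the network,
#' one at a time, is the shock origin.  By default the country's own
#' domestic-shock simulation is included in the average;
#' \code{include_domestic = FALSE} averages over foreign origins only.
#'
#' @param grid a \code{shock_grid}
#' @param alpha which alpha slice to average
#' @param include_domestic include the origin = destination simulation
#' @return data.frame with columns id, exposure (kcal/person/day)
#' @export
exposure <- function(grid, alpha = 1, include_domestic = TRUE) {
  g <- grid_alpha(grid, alpha)
  if (!include_domestic) g <- g[g$origin != g$dest, , drop = FALSE]
  agg <- tapply(g$dd, g$dest, mean)
  data.frame(id = names(agg), exposure = unname(agg),
             stringsAsFactors = FALSE)
}

#' Hedging: share of a domestic shock passed on to the network
#'
#' For each origin, 1 minus the fraction of its own shock it retains as
#' final deficit in its own simulation.  1 means the whole domestic
#' shock was shifted onto trade partners, 0 means it was fully absorbed
#' at home.  Countries with a zero shock (no production) get NA.
#'
#' @param grid a \code{shock_grid}
#' @param alpha which alpha slice to use
#' @return data.frame with columns id, hedging in [0, 1] (or NA)
#' @export
hedging_share <- function(grid, alpha = 1) {
  g <- grid_alpha(grid, alpha)
  own <- g[g$origin == g$dest, , drop = FALSE]
  own <- own[match(names(grid$shock), own$origin), ]
  share <- ifelse(grid$shock > 0,
                  1 - own$dd_annual / grid$shock, NA_real_)
  share <- pmin(pmax(share, 0), 1)
  data.frame(id = names(grid$shock), hedging = unname(share),
             stringsAsFactors = FALSE)
}

#' Emergency reserve levels: 95th percentile of pooled deficits
#'
#' For each destination country, pools its final deficits from all
#' simulations across every origin and every alpha in the grid and takes
#' the \code{percentile} quantile (linear interpolation between order
#' statistics).  The result is the reserve stock, in kcal/person/day,
#' that would shield the country from all but the worst
#' (1 - percentile) share of simulated shocks; it is also expressed as a
#' percentage of the country's per-capita daily domestic supply.
#'
#' @param grid a \code{shock_grid}
#' @param pop_min countries below this population are dropped
#' @param percentile quantile level, default 0.95
#' @return data.frame (id, reserve, pct_supply, population), sorted by
#'   descending reserve
#' @export
reserves_p95 <- function(grid, pop_min = 1e6, percentile = 0.95) {
  q <- tapply(grid$grid$dd, grid$grid$dest,
              function(v) stats::quantile(v, percentile, names = FALSE,
                                          type = 7))
  co <- grid$countries
  co <- co[match(names(q), co$id), ]
  supply_pcd <- co$supply / (co$population * grid$days_per_year)
  out <- data.frame(id = names(q), reserve = unname(q),
                    pct_supply = unname(100 * q / supply_pcd),
                    population = co$population, stringsAsFactors = FALSE)
  out <- out[out$population >= pop_min, , drop = FALSE]
  out <- out[order(-out$reserve), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Threshold-exceedance vulnerability counts
#'
#' For each (destination country, alpha), the number of shock origins
#' whose simulation leaves that country with a final deficit at or above
#' the threshold (default thresholds of interest: 250 and 500
#' kcal/person/day, 1/8 and 1/4 of a recommended adult daily intake).
#'
#' @param grid a \code{shock_grid}
#' @param threshold kcal/person/day
#' @return data.frame with columns id, alpha, count
#' @export
vulnerability_counts <- function(grid, threshold = 250) {
  g <- grid$grid
  agg <- stats::aggregate(list(count = as.integer(g$dd >= threshold)),
                          by = list(id = g$dest, alpha = g$alpha), FUN = sum)
  agg <- agg[order(agg$alpha, agg$id), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Rank-based vulnerability score
#'
#' Within each simulation (origin, alpha), destinations are ranked by
#' final deficit, ascending, with the smallest deficit taking rank 1 and
#' ties receiving average ranks.  Per (destination, alpha) the ranks are
#' summed over origins and natural-log transformed; larger values mean
#' the country persistently ends up among the worst-hit.
#'
#' @param grid a \code{shock_grid}
#' @return data.frame with columns id, alpha, rank_sum, log_rank_sum
#' @export
vulnerability_rank <- function(grid) {
  g <- grid$grid
  key <- paste(g$origin, g$alpha, sep = "\r")
  rk <- stats::ave(g$dd, key, FUN = function(v) rank(v, ties.method = "average"))
  agg <- stats::aggregate(list(rank_sum = rk),
                          by = list(id = g$dest, alpha = g$alpha), FUN = sum)
  agg$log_rank_sum <- log(agg$rank_sum)
  agg <- agg[order(agg$alpha, agg$id), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Degree and strength distributions before and after a cascade
#'
#' The data behind before/after comparisons of how a cascade prunes the
#' network: per-country in/out degree and strength at baseline and at
#' cascade termination.
#'
#' @inheritParams run_cascade
#' @return data.frame with columns id, stage ("before"/"after"),
#'   in_degree, out_degree, in_strength, out_strength
#' @export
cascade_distributions <- function(network, origin, shock_fraction = 0.3,
                                  alpha = 1, ...) {
  W0 <- weight_matrix(network)
  res <- run_cascade(network, origin, shock_fraction, alpha, ...)
  W1 <- res$final_weights
  one <- function(W, stage)
    data.frame(id = network$countries$id, stage = stage,
               in_degree = unname(colSums(W > 0)),
               out_degree = unname(rowSums(W > 0)),
               in_strength = unname(colSums(W)),
               out_strength = unname(rowSums(W)),
               stringsAsFactors = FALSE)
  rbind(one(W0, "before"), one(W1, "after"))
}
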