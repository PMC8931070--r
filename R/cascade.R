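## Shock cascade engine.
##
## A shock removes a fraction of one country's domestic production.  The
## origin compensates by cutting exports (a fraction alpha of the shock)
## and/or raising imports (the remaining 1 - alpha, spread across its
## baseline suppliers in proportion to the calories they already supply).
## Every country that thereby acquires a demand deficit tries to shed it
## by cutting its own exports; cuts are allocated across positive
## out-edges in inverse proportion to the partner's GDP, so poor
## importers absorb disproportionate shares.  All deficit holders act
## simultaneously each step, and the cascade stops when no country with
## a positive deficit can cut exports any further.  Calories are only
## transferred, never created or destroyed: the final deficits always
## sum to the initial shock.

new_cascade_state <- function(network, origin) {
  ids <- network$countries$id
  o <- match(origin, ids)
  if (is.na(o)) stop("unknown origin country: ", origin)
  W <- weight_matrix(network)
  prod0 <- network$countries$production
  dem0 <- prod0 + colSums(W) - rowSums(W)
  list(ids = ids, o = o, W = W, W0 = W, prod = prod0, dem0 = dem0,
       gdp = network$countries$gdp, pop = network$countries$population,
       dd = numeric(length(ids)), t = 0L, shock = 0)
}

recompute_dd <- function(state) {
  state$dd <- state$dem0 - state$prod - colSums(state$W) + rowSums(state$W)
  state
}

#' GDP-inverse export reduction shares
#'
#' The fraction of a country's demand deficit that each of its importing
#' partners absorbs when it cuts exports.  With k >= 2 positive
#' out-edges and S the GDP total over those partners, partner j absorbs
#' F_j = ((S - GDP_j) / S) * 1 / (k - 1); with a single out-edge F = 1.
#' Shares sum to one and are inversely related to partner GDP: poorer
#' importers take larger cuts.
#'
#' @param state a cascade state (from \code{apply_initial_shock}) or a
#'   \code{trade_network} (then baseline weights are used)
#' @param country country id whose out-edges are rationed
#' @return named numeric vector of shares over the positive-weight
#'   out-neighbours, summing to 1
#' @export
export_reduction_shares <- function(state, country) {
  if (inherits(state, "trade_network")) {
    W <- weight_matrix(state); gdp <- state$countries$gdp
    ids <- state$countries$id
  } else {
    W <- state$W; gdp <- state$gdp; ids <- state$ids
  }
  i <- match(country, ids)
  if (is.na(i)) stop("unknown country: ", country)
  nbrs <- which(W[i, ] > 0)
  k <- length(nbrs)
  if (k == 0L)
    stop("country ", country, " has no positive out-edges; ",
         "it can only absorb deficit")
  if (k == 1L) {
    f <- 1
  } else {
    S <- sum(gdp[nbrs])
    f <- (S - gdp[nbrs]) / S * (1 / (k - 1))
  }
  names(f) <- ids[nbrs]
  f
}

## allocate an export cut of size `target` across the positive out-edges
## of row i, re-deriving GDP shares each round as edges truncate at zero
reduce_exports <- function(W, gdp, i, target, guard_tol) {
  remaining <- target
  rounds <- sum(W[i, ] > 0) + 1L
  while (remaining > guard_tol && rounds > 0L) {
    nbrs <- which(W[i, ] > 0)
    k <- length(nbrs)
    if (k == 0L) break
    if (k == 1L) {
      f <- 1
    } else {
      S <- sum(gdp[nbrs])
      f <- (S - gdp[nbrs]) / S * (1 / (k - 1))
    }
    cut <- pmin(W[i, nbrs], remaining * f)
    W[i, nbrs] <- W[i, nbrs] - cut
    remaining <- remaining - sum(cut)
    rounds <- rounds - 1L
  }
  W
}

#' Apply the initial production shock
#'
#' Removes \code{shock_fraction} of the origin's production and
#' compensates: a share \code{alpha} of the shock via export cuts
#' (allocated by the GDP-inverse rationing rule, iterated within the
#' call as edges truncate at zero) and \code{1 - alpha} via an import
#' boost spread over baseline suppliers proportionally to the calories
#' they already supply.  If the origin has no baseline imports the
#' import share is rerouted through the export channel (with a warning);
#' whatever can be shed through neither channel stays with the origin as
#' its own deficit.  Demand deficits of all countries are then derived
#' from the changed flows.
#'
#' @param network a \code{trade_network}
#' @param origin country id where the shock originates
#' @param shock_fraction fraction of origin production lost, in (0, 1]
#' @param alpha export/import split in [0, 1]: 1 = all export cuts,
#'   0 = all import increases
#' @return a cascade state (list with weights \code{W}, productions,
#'   baseline demands, deficits \code{dd}, step index \code{t})
#' @export
apply_initial_shock <- function(network, origin, shock_fraction = 0.3,
                                alpha = 1) {
  stopifnot(inherits(network, "trade_network"),
            shock_fraction > 0, shock_fraction <= 1,
            alpha >= 0, alpha <= 1)
  state <- new_cascade_state(network, origin)
  o <- state$o
  shock <- shock_fraction * state$prod[o]
  state$shock <- shock
  if (shock == 0) {
    warning("origin ", origin, " has zero production; zero-shock cascade")
    state$t <- 1L
    return(recompute_dd(state))
  }
  state$prod[o] <- state$prod[o] - shock

  imp0 <- sum(state$W0[, o])
  export_target <- alpha * shock
  import_target <- (1 - alpha) * shock
  if (import_target > 0 && imp0 == 0) {
    warning("origin ", origin, " has no baseline imports; ",
            "import share of the shock rerouted to export cuts")
    export_target <- export_target + import_target
    import_target <- 0
  }
  if (export_target > 0)
    state$W <- reduce_exports(state$W, state$gdp, o, export_target,
                              guard_tol = 1e-12 * shock)
  if (import_target > 0)
    state$W[, o] <- state$W[, o] + import_target * state$W0[, o] / imp0
  state$t <- 1L
  recompute_dd(state)
}

#' Advance the cascade one synchronous step
#'
#' Every country with a deficit above \code{tol} and positive export
#' flow simultaneously cuts each positive out-edge by its deficit times
#' the GDP-inverse share, truncating at zero; the truncated residue
#' remains as deficit and is retried next step over the surviving edges.
#' Deficits are then re-derived for all countries from the updated flows
#' (never accumulated incrementally).
#'
#' @param state a cascade state
#' @param tol deficit tolerance, kcal/year
#' @return the updated state; if no country was eligible to act the
#'   weights are unchanged and only \code{t} advances
#' @export
cascade_step <- function(state, tol = 1e-6 * state$shock) {
  Wt <- state$W
  n <- nrow(Wt)
  A <- Wt > 0
  k <- rowSums(A)
  reducers <- state$dd > tol & k > 0
  r2 <- which(reducers & k >= 2)
  if (length(r2) > 0L) {
    ## row-wise GDP-inverse shares for all multi-edge reducers at once
    G <- matrix(state$gdp, length(r2), n, byrow = TRUE)
    Ar <- A[r2, , drop = FALSE]
    S <- rowSums(Ar * G)
    f <- Ar * ((S - G) / S * (1 / (k[r2] - 1)))
    state$W[r2, ] <- pmax(Wt[r2, , drop = FALSE] - state$dd[r2] * f, 0)
  }
  r1 <- which(reducers & k == 1)
  if (length(r1) > 0L) {
    j <- max.col(A[r1, , drop = FALSE])
    idx <- cbind(r1, j)
    state$W[idx] <- pmax(Wt[idx] - state$dd[r1], 0)
  }
  state$t <- state$t + 1L
  recompute_dd(state)
}

#' Run a shock cascade to termination
#'
#' Applies the initial shock and iterates synchronous steps until no
#' country holds a deficit above tolerance while still having export
#' flow above tolerance to cut, or \code{max_steps} is reached.
#'
#' @inheritParams apply_initial_shock
#' @param tol termination tolerance in kcal/year; defaults to 1e-6
#'   times the shock size
#' @param max_steps step cap; reaching it flags the run not-converged
#' @param days_per_year used for the per-capita daily conversion
#' @return an object of class \code{cascade_result}: final deficits in
#'   kcal/year (\code{final_dd}) and kcal/person/day
#'   (\code{final_dd_percap}), \code{steps}, \code{converged},
#'   conservation \code{residual} |sum(dd) - shock|/shock,
#'   \code{final_weights}, and \code{origin_retained} (origin deficit as
#'   a fraction of the shock)
#' @export
run_cascade <- function(network, origin, shock_fraction = 0.3, alpha = 1,
                        tol = NULL, max_steps = 10000,
                        days_per_year = 365) {
  state <- apply_initial_shock(network, origin, shock_fraction, alpha)
  shock <- state$shock
  if (is.null(tol)) tol <- 1e-6 * max(shock, 1)
  converged <- FALSE
  while (TRUE) {
    active <- state$dd > tol & rowSums(state$W) > tol
    if (!any(active)) { converged <- TRUE; break }
    if (state$t >= max_steps) break
    state <- cascade_step(state, tol)
  }
  dd <- pmax(state$dd, 0)
  names(dd) <- state$ids
  residual <- if (shock > 0) abs(sum(state$dd) - shock) / shock else 0
  structure(list(
    final_dd = dd,
    final_dd_percap = dd / (state$pop * days_per_year),
    steps = state$t, converged = converged, residual = residual,
    final_weights = state$W,
    origin_retained = if (shock > 0) unname(dd[state$o] / shock) else 0,
    origin = state$ids[state$o], alpha = alpha,
    shock_fraction = shock_fraction, shock = shock), class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat(sprintf(
    "Shock cascade: origin %s, %.0f%% production shock (%.4g kcal/yr), alpha = %g\n",
    x$origin, 100 * x$shock_fraction, x$shock, x$alpha))
  cat(sprintf("  steps: %d  converged: %s  conservation residual: %.2e\n",
              x$steps, x$converged, x$residual))
  cat(sprintf("  origin retained %.1f%% of the shock; %d countries with a deficit\n",
              100 * x$origin_retained, sum(x$final_dd > 0)))
  top <- sort(x$final_dd_percap, decreasing = TRUE)
  top <- top[top > 0]
  if (length(top) > 0) {
    cat("  largest final deficits (kcal/person/day):\n")
    print(round(utils::head(top, 5), 3))
  }
  invisible(x)
}
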