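## Seeded synthetic calorie trade networks.
##
## The generator emulates the statistical structure of the observed 2013
## food trade network: ~172 countries, directed density ~0.36, link
## reciprocity ~0.61, heavy-tailed strengths, strong total-degree
## disassortativity, a single weakly connected component, and GDP
## positively associated with export strength.  It does NOT fit any real
## data: it reproduces signs and orders of magnitude, not magnitudes.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

## country codes AAA, AAB, ... in sorted order
country_codes <- function(n) {
  stopifnot(n <= 26^3)
  i <- seq_len(n) - 1L
  paste0(LETTERS[i %/% 676L + 1L],
         LETTERS[(i %/% 26L) %% 26L + 1L],
         LETTERS[i %% 26L + 1L])
}

#' Generate a synthetic calorie trade network
#'
#' Samples a directed weighted trade network whose topology mirrors the
#' observed 2013 international food trade network.  The recipe: each
#' country gets a latent log-normal "size"; unordered country pairs
#' connect with probability proportional to the sum of their scaled
#' sizes (calibrated by bisection so the expected directed density hits
#' the target); a connected pair is mutual with the probability implied
#' by the target reciprocity, otherwise a single edge oriented from the
#' larger country with high probability.  Edge weights are allocated
#' from each importer's calorie import budget (a fixed fraction of its
#' domestic supply, which guarantees non-negative derived production) in
#' proportion to the exporters' sizes.  GDP shares the latent size, so
#' GDP and out-strength are positively rank-correlated, and the
#' size-driven attachment makes total degree strongly disassortative.
#'
#' @param n_countries number of countries (>= 3)
#' @param density target fraction of ordered country pairs linked
#' @param reciprocity target fraction of links whose reverse also exists
#' @param strength_tail sdlog of the latent log-normal country size; the
#'   default gives max/median out-strength well above 50 at n = 172
#' @param supply_percap_range kcal/person/day interval for domestic
#'   supply
#' @param pop_range population interval, sampled log-uniformly
#' @param import_budget_range fraction-of-supply interval for each
#'   country's total calorie imports; the upper end below 1 guarantees
#'   derived production stays positive
#' @param import_only_frac fraction of countries (the smallest by
#'   latent size) that import but do not export, emulating the observed
#'   pattern of many small countries sitting outside the giant strongly
#'   connected trade core; set to 0 for a network where everyone
#'   exports
#' @param seed RNG seed; the same seed always yields the identical
#'   network
#' @param max_tries bounded retries for degenerate draws (e.g. an empty
#'   edge set at very low density) before giving up
#' @return a validated \code{trade_network}
#' @export
generate_network <- function(n_countries = 172, density = 0.358,
                             reciprocity = 0.610, strength_tail = 1.4,
                             supply_percap_range = c(1800, 3600),
                             pop_range = c(1e5, 1e9),
                             import_budget_range = c(0.15, 0.45),
                             import_only_frac = 0.15,
                             seed = 1, max_tries = 20) {
  stopifnot(n_countries >= 3, density > 0, density < 1,
            reciprocity >= 0, reciprocity <= 1,
            strength_tail > 0, max_tries >= 1,
            import_only_frac >= 0, import_only_frac < 1)
  with_seed(seed, generate_network_impl(
    n_countries, density, reciprocity, strength_tail, supply_percap_range,
    pop_range, import_budget_range, import_only_frac, max_tries))
}

generate_network_impl <- function(n, density, reciprocity, strength_tail,
                                  supply_percap_range, pop_range,
                                  import_budget_range, import_only_frac,
                                  max_tries) {
  ids <- country_codes(n)

  ## country attributes
  z <- stats::rlnorm(n, meanlog = 0, sdlog = strength_tail)
  pop <- exp(stats::runif(n, log(pop_range[1]), log(pop_range[2])))
  percap <- stats::runif(n, supply_percap_range[1], supply_percap_range[2])
  supply <- percap * 365 * pop
  size <- z * sqrt(pop / 1e7)
  pc_gdp <- 2000 * z^0.8 * stats::rlnorm(n, 0, 0.4)
  gdp <- pc_gdp * pop

  ## the smallest countries are import-only: in-edges allowed, no
  ## out-edges (their pairs can never be mutual)
  ni <- floor(import_only_frac * n)
  ionly <- rank(size, ties.method = "first") <= ni
  xnodes <- which(!ionly)
  nx <- length(xnodes)
  if (nx < 2) stop("import_only_frac leaves fewer than 2 exporters")

  ## pair-type budget from the density/reciprocity targets.
  ## T = directed edge target, split into mutual pairs (exporter pairs
  ## only) and single edges (exporter pairs + exporter->import-only).
  Tedges <- density * n * (n - 1)
  m2 <- reciprocity * Tedges / 2          # mutual pair count
  singles <- Tedges - 2 * m2
  Nxx <- nx * (nx - 1) / 2
  Nix <- nx * ni
  p_ix0 <- if (ni > 0) min(density * (2 - reciprocity), 1) else 0
  s_ix <- if (ni > 0) min(p_ix0 * Nix, 0.8 * singles) else 0
  s_xx <- singles - s_ix
  P_x <- (m2 + s_xx) / Nxx                # exporter-pair connection prob
  pm_x <- if (P_x > 0) (m2 / Nxx) / P_x else 0
  if (P_x > 1) {
    ## overfull: first push singles onto exporter->import-only pairs,
    ## then absorb the rest by raising the mutual share
    s_ix <- min(singles, Nix)
    s_xx <- singles - s_ix
    P_x <- (m2 + s_xx) / Nxx
    pm_x <- if (P_x > 0) (m2 / Nxx) / P_x else 0
    if (P_x > 1) {
      P_x <- 1
      pm_x <- (Tedges - s_ix) / Nxx - 1
    }
  }
  p_ix <- if (ni > 0) s_ix / Nix else 0
  if (pm_x > 1 + 1e-9 || p_ix > 1 + 1e-9)
    stop("infeasible generator parameters: density ", density,
         " with reciprocity ", reciprocity, " and import_only_frac ",
         ni / n, " cannot be realized")
  pm_x <- min(pm_x, 1); p_ix <- min(p_ix, 1)

  ## size-weighted connection probabilities, bisected to the mean target
  s <- size / max(size)
  scale_to_mean <- function(w, target) {
    if (length(w) == 0) return(numeric(0))
    if (target <= 0) return(rep(0, length(w)))
    if (target >= 1) return(rep(1, length(w)))
    lo <- 0; hi <- 1 / min(w)
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (mean(pmin(1, mid * w)) < target) lo <- mid else hi <- mid
    }
    pmin(1, hi * w)
  }

  utx <- t(utils::combn(xnodes, 2))
  cp_xx <- scale_to_mean(s[utx[, 1]] + s[utx[, 2]], P_x)
  if (ni > 0) {
    ix <- expand.grid(x = xnodes, i = which(ionly))
    cp_ix <- scale_to_mean(s[ix$x], p_ix)
  }

  A <- NULL
  for (try in seq_len(max_tries)) {
    A0 <- matrix(FALSE, n, n)
    conn <- stats::runif(nrow(utx)) < cp_xx
    mut <- conn & (stats::runif(nrow(utx)) < pm_x)
    sng <- conn & !mut
    ## orientation of single links: from the larger country w.p. 0.8
    big_first <- s[utx[, 1]] >= s[utx[, 2]]
    fwd <- stats::runif(nrow(utx)) < ifelse(big_first, 0.8, 0.2)
    A0[utx[mut, , drop = FALSE]] <- TRUE
    A0[utx[mut, c(2, 1), drop = FALSE]] <- TRUE
    A0[utx[sng & fwd, , drop = FALSE]] <- TRUE
    A0[utx[sng & !fwd, c(2, 1), drop = FALSE]] <- TRUE
    if (ni > 0) {
      keep <- stats::runif(nrow(ix)) < cp_ix
      A0[cbind(ix$x[keep], ix$i[keep])] <- TRUE
    }
    if (any(A0)) { A <- A0; break }
  }
  if (is.null(A))
    stop("generation failed: no edges drawn after ", max_tries,
         " tries (density too low?)")

  ## repair weak connectivity: bridge every secondary component to the
  ## component containing the largest country
  comp <- weak_components(A)
  if (max(comp) > 1L) {
    giant <- comp[which.max(size)]
    anchor <- which(comp == giant)[which.max(size[comp == giant])]
    for (k in setdiff(unique(comp), giant)) {
      members <- which(comp == k)
      b <- members[which.max(size[members])]
      A[anchor, b] <- TRUE
    }
  }

  ## weights: importer j splits an import budget (fraction of its
  ## supply) across its in-neighbours in proportion to exporter size
  budget <- stats::runif(n, import_budget_range[1], import_budget_range[2]) *
    supply
  eprop <- size * stats::rlnorm(n, 0, 0.5)
  W <- matrix(0, n, n)
  for (j in seq_len(n)) {
    src <- which(A[, j])
    if (length(src) == 0L) next
    share <- eprop[src] * stats::rlnorm(length(src), 0, 0.35)
    W[src, j] <- budget[j] * share / sum(share)
  }

  idx <- which(W > 0, arr.ind = TRUE)
  edges <- data.frame(origin = ids[idx[, 1]], dest = ids[idx[, 2]],
                      weight = W[idx], stringsAsFactors = FALSE)
  countries <- data.frame(id = ids, name = paste("Country", ids),
                          gdp = gdp, population = pop, supply = supply,
                          stringsAsFactors = FALSE)
  trade_network(countries, edges)
}

## weakly connected component labels of a logical adjacency matrix
weak_components <- function(A) {
  n <- nrow(A)
  U <- A | t(A)
  comp <- integer(n)
  cur <- 0L
  for (v in seq_len(n)) {
    if (comp[v] != 0L) next
    cur <- cur + 1L
    stack <- v
    while (length(stack) > 0L) {
      x <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (comp[x] != 0L) next
      comp[x] <- cur
      stack <- c(stack, which(U[x, ] & comp == 0L))
    }
  }
  comp
}

#' Hand-checkable fixture networks
#'
#' Three tiny networks whose cascade outcomes can be traced by hand.
#'
#' \describe{
#'   \item{chain3}{A -> B (100), B -> C (50).  All GDP 1, population
#'     1000.  Supplies (0, 150, 150) give productions (100, 100, 100),
#'     so a 30\% shock at A is 30 kcal/year.}
#'   \item{star5}{Hub HUB exports 25 kcal/year to each of four leaves
#'     L1..L4 with unequal GDPs (1, 1, 3, 5); hub GDP 10.  L4 also
#'     exports 10 back to the hub, so L4 has a single out-edge (the
#'     F = 1 branch of the GDP-rationing rule).  Populations 1000;
#'     supplies: hub 10, leaves 100 each.}
#'   \item{twoblock8}{Two fully reciprocated 4-country blocks
#'     (A1..A4, B1..B4; within-block weights 10) joined by the single
#'     bridge edge A1 -> B1 (weight 5).  GDPs 1..8, populations 1000,
#'     supplies 100.}
#' }
#'
#' @param name one of \code{"chain3"}, \code{"star5"}, \code{"twoblock8"}
#' @return a validated \code{trade_network}
#' @export
fixture <- function(name = c("chain3", "star5", "twoblock8")) {
  valid <- c("chain3", "star5", "twoblock8")
  if (length(name) != 1L || !name %in% valid)
    stop("unknown fixture; valid names: ", paste(valid, collapse = ", "))
  switch(name,
    chain3 = trade_network(
      data.frame(id = c("A", "B", "C"), name = c("A", "B", "C"),
                 gdp = 1, population = 1000, supply = c(0, 150, 150)),
      data.frame(origin = c("A", "B"), dest = c("B", "C"),
                 weight = c(100, 50))),
    star5 = trade_network(
      data.frame(id = c("HUB", "L1", "L2", "L3", "L4"),
                 name = c("Hub", "Leaf 1", "Leaf 2", "Leaf 3", "Leaf 4"),
                 gdp = c(10, 1, 1, 3, 5), population = 1000,
                 supply = c(10, 100, 100, 100, 100)),
      data.frame(origin = c("HUB", "HUB", "HUB", "HUB", "L4"),
                 dest = c("L1", "L2", "L3", "L4", "HUB"),
                 weight = c(25, 25, 25, 25, 10))),
    twoblock8 = {
      blocks <- list(paste0("A", 1:4), paste0("B", 1:4))
      eo <- character(); ed <- character()
      for (b in blocks) for (i in b) for (j in b) if (i != j) {
        eo <- c(eo, i); ed <- c(ed, j)
      }
      edges <- data.frame(origin = c(eo, "A1"), dest = c(ed, "B1"),
                          weight = c(rep(10, length(eo)), 5))
      ids <- c(blocks[[1]], blocks[[2]])
      trade_network(
        data.frame(id = ids, name = ids, gdp = 1:8, population = 1000,
                   supply = 100),
        edges)
    })
}
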