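## Naive reference cascade, coded separately from the optimized engine.
##
## Everything here is deliberately plain: dense matrices, explicit
## per-country loops, every quantity recomputed from first principles at
## every step.  It exists solely so the optimized engine can be checked
## against an independent implementation on small problems.

#' Brute-force reference cascade
#'
#' A deliberately naive, separately coded cascade implementation used as
#' an independent cross-check of \code{\link{run_cascade}}.  Refuses
#' networks with more than 25 countries.
#'
#' @inheritParams run_cascade
#' @return a list with \code{final_dd} (kcal/year, named),
#'   \code{final_dd_percap}, \code{steps}, \code{converged} and
#'   \code{final_weights}
#' @export
oracle_cascade <- function(network, origin, shock_fraction = 0.3, alpha = 1,
                           tol = NULL, max_steps = 10000,
                           days_per_year = 365) {
  stopifnot(inherits(network, "trade_network"))
  n <- network$n
  if (n > 25) stop("oracle_cascade is limited to networks with <= 25 countries")
  ids <- network$countries$id
  gdp <- network$countries$gdp
  pop <- network$countries$population

  ## dense weights assembled by hand from the edge list
  W <- matrix(0, n, n)
  for (r in seq_len(nrow(network$edges))) {
    W[which(ids == network$edges$origin[r]),
      which(ids == network$edges$dest[r])] <- network$edges$weight[r]
  }
  W0 <- W

  exports_of <- function(W, i) { s <- 0; for (j in 1:n) s <- s + W[i, j]; s }
  imports_of <- function(W, i) { s <- 0; for (j in 1:n) s <- s + W[j, i]; s }

  prod <- numeric(n)
  for (i in 1:n)
    prod[i] <- network$countries$supply[i] + exports_of(W, i) - imports_of(W, i)
  dem0 <- numeric(n)
  for (i in 1:n) dem0[i] <- prod[i] + imports_of(W, i) - exports_of(W, i)

  shares_of <- function(W, i) {
    nbrs <- integer(0)
    for (j in 1:n) if (W[i, j] > 0) nbrs <- c(nbrs, j)
    k <- length(nbrs)
    f <- numeric(k)
    if (k == 1L) f[1] <- 1
    else if (k >= 2L) {
      S <- 0
      for (j in nbrs) S <- S + gdp[j]
      for (m in seq_len(k)) f[m] <- (S - gdp[nbrs[m]]) / S * (1 / (k - 1))
    }
    list(nbrs = nbrs, f = f)
  }

  o <- which(ids == origin)
  if (length(o) != 1L) stop("unknown origin country: ", origin)
  shock <- shock_fraction * prod[o]
  if (is.null(tol)) tol <- 1e-6 * max(shock, 1)
  steps <- 1L
  if (shock > 0) {
    prod[o] <- prod[o] - shock
    imp0 <- imports_of(W0, o)
    etarget <- alpha * shock
    itarget <- (1 - alpha) * shock
    if (itarget > 0 && imp0 == 0) { etarget <- etarget + itarget; itarget <- 0 }
    remaining <- etarget
    guard <- sum(W[o, ] > 0) + 1L
    while (remaining > 1e-12 * shock && guard > 0L) {
      sh <- shares_of(W, o)
      if (length(sh$nbrs) == 0L) break
      done <- 0
      for (m in seq_along(sh$nbrs)) {
        j <- sh$nbrs[m]
        cut <- remaining * sh$f[m]
        if (cut > W[o, j]) cut <- W[o, j]
        W[o, j] <- W[o, j] - cut
        done <- done + cut
      }
      remaining <- remaining - done
      guard <- guard - 1L
    }
    if (itarget > 0)
      for (h in 1:n) W[h, o] <- W[h, o] + itarget * W0[h, o] / imp0
  }

  deficit <- function(W, i)
    dem0[i] - prod[i] - imports_of(W, i) + exports_of(W, i)

  converged <- FALSE
  while (TRUE) {
    dd <- numeric(n)
    for (i in 1:n) dd[i] <- deficit(W, i)
    active <- logical(n)
    for (i in 1:n) active[i] <- dd[i] > tol && exports_of(W, i) > tol
    if (!any(active)) { converged <- TRUE; break }
    if (steps >= max_steps) break
    Wnext <- W
    for (i in 1:n) {
      if (!(dd[i] > tol && exports_of(W, i) > 0)) next
      sh <- shares_of(W, i)
      for (m in seq_along(sh$nbrs)) {
        j <- sh$nbrs[m]
        w <- W[i, j] - dd[i] * sh$f[m]
        if (w < 0) w <- 0
        Wnext[i, j] <- w
      }
    }
    W <- Wnext
    steps <- steps + 1L
  }

  dd <- numeric(n)
  for (i in 1:n) dd[i] <- max(deficit(W, i), 0)
  names(dd) <- ids
  list(final_dd = dd, final_dd_percap = dd / (pop * days_per_year),
       steps = steps, converged = converged, final_weights = W)
}
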