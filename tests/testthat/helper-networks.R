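# Small random trade networks for property and equivalence tests.
# Weights are O(1-100) kcal/year: a convenient scale for tight absolute
# comparisons between independent cascade implementations.
random_small_network <- function(n, seed, density = 0.45) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ids <- sprintf("C%02d", seq_len(n))
  repeat {
    A <- matrix(stats::runif(n * n) < density, n, n)
    diag(A) <- FALSE
    if (any(A)) break
  }
  W <- matrix(0, n, n)
  W[A] <- stats::runif(sum(A), 1, 100)
  imp <- colSums(W); exp_ <- rowSums(W)
  supply <- pmax(0, imp - exp_) + stats::runif(n, 50, 200)
  co <- data.frame(id = ids, name = ids,
                   gdp = exp(stats::runif(n, 0, 4)),
                   population = stats::runif(n, 500, 5000),
                   supply = supply, stringsAsFactors = FALSE)
  idx <- which(W > 0, arr.ind = TRUE)
  trade_network(co, data.frame(origin = ids[idx[, 1]],
                               dest = ids[idx[, 2]], weight = W[idx]))
}

# The default 172-country synthetic network and its full experiment
# grid, computed once and shared across test files.
.default_cache <- new.env(parent = emptyenv())

default_network <- function() {
  if (is.null(.default_cache$net))
    .default_cache$net <- generate_network(seed = 1)
  .default_cache$net
}

default_grid <- function() {
  if (is.null(.default_cache$grid))
    .default_cache$grid <- run_grid(default_network())
  .default_cache$grid
}
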