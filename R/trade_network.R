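#' Construct a calorie trade network
#'
#' A trade network couples a country attribute table with a directed,
#' weighted edge list whose weights are annual calorie flows (kcal/year)
#' from an exporting country to an importing one.  Domestic production is
#' derived from the attribute table and the trade flows as
#' \code{production = supply + exports - imports}: domestic food supply
#' (the food-balance-sheet quantity) adjusted for the country's net trade
#' position.  An immediate consequence is that baseline demand
#' (production + imports - exports) equals supply for every country.
#'
#' Countries are kept in sorted id order throughout, so all derived
#' tables and matrices are deterministic for a given input.
#'
#' @param countries data.frame with columns \code{id} (unique short code),
#'   \code{name}, \code{gdp} (> 0, arbitrary currency units),
#'   \code{population} (> 0, persons), \code{supply} (>= 0, kcal/year).
#' @param edges data.frame with columns \code{origin}, \code{dest},
#'   \code{weight} (kcal/year, > 0).  Zero-weight rows are dropped:
#'   the model treats an absent flow and a zero flow identically.
#' @return An object of class \code{trade_network}: a list with the
#'   validated \code{countries} table (plus a derived \code{production}
#'   column), the \code{edges} table, and \code{n} (country count).
#' @export
trade_network <- function(countries, edges) {
  countries <- as.data.frame(countries, stringsAsFactors = FALSE)
  req <- c("id", "name", "gdp", "population", "supply")
  miss <- setdiff(req, names(countries))
  if (length(miss) > 0L)
    stop("country table is missing columns: ", paste(miss, collapse = ", "))
  countries$id <- as.character(countries$id)
  if (anyDuplicated(countries$id))
    stop("duplicate country ids: ",
         paste(unique(countries$id[duplicated(countries$id)]), collapse = ", "))
  if (any(!is.finite(countries$gdp)) || any(countries$gdp <= 0))
    stop("gdp must be finite and > 0 for every country")
  if (any(!is.finite(countries$population)) || any(countries$population <= 0))
    stop("population must be finite and > 0 for every country")
  if (any(!is.finite(countries$supply)) || any(countries$supply < 0))
    stop("supply must be finite and >= 0 for every country")
  countries <- countries[order(countries$id), req, drop = FALSE]
  rownames(countries) <- NULL

  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    edges <- data.frame(origin = character(), dest = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    reqe <- c("origin", "dest", "weight")
    misse <- setdiff(reqe, names(edges))
    if (length(misse) > 0L)
      stop("edge table is missing columns: ", paste(misse, collapse = ", "))
    edges <- edges[, reqe, drop = FALSE]
    edges$origin <- as.character(edges$origin)
    edges$dest <- as.character(edges$dest)
    unknown <- setdiff(unique(c(edges$origin, edges$dest)), countries$id)
    if (length(unknown) > 0L)
      stop("edge references unknown country id(s): ",
           paste(unknown, collapse = ", "))
    if (any(!is.finite(edges$weight)) || any(edges$weight < 0))
      stop("edge weights must be finite and >= 0")
    edges <- edges[edges$weight > 0, , drop = FALSE]
    if (any(edges$origin == edges$dest))
      stop("self-loop edge(s) for: ",
           paste(unique(edges$origin[edges$origin == edges$dest]),
                 collapse = ", "))
    dup <- duplicated(edges[, c("origin", "dest")])
    if (any(dup))
      stop("duplicate edge(s): ",
           paste(unique(paste0(edges$origin[dup], "->", edges$dest[dup])),
                 collapse = ", "))
    edges <- edges[order(edges$origin, edges$dest), , drop = FALSE]
    rownames(edges) <- NULL
  }

  net <- structure(list(countries = countries, edges = edges,
                        n = nrow(countries)),
                   class = "trade_network")
  net$countries$production <- estimate_production(net)
  neg <- net$countries$production < 0
  if (any(neg))
    stop("derived production < 0 (imports exceed supply + exports) for: ",
         paste(net$countries$id[neg], collapse = ", "))
  net
}

#' Dense weight matrix of a trade network
#'
#' @param network a \code{trade_network}
#' @return n x n numeric matrix, rows = exporting country, columns =
#'   importing country, dimnames the sorted country ids.  Absent flows
#'   are 0.
#' @export
weight_matrix <- function(network) {
  stopifnot(inherits(network, "trade_network"))
  ids <- network$countries$id
  W <- matrix(0, network$n, network$n, dimnames = list(ids, ids))
  if (nrow(network$edges) > 0L)
    W[cbind(match(network$edges$origin, ids),
            match(network$edges$dest, ids))] <- network$edges$weight
  W
}

#' Derive domestic production from supply and trade flows
#'
#' production_i = supply_i + exports_i - imports_i, where exports are the
#' row sums and imports the column sums of the weight matrix.  Idempotent:
#' depends only on the stored supply and edges.
#'
#' @param network a \code{trade_network} (or the pre-validation list used
#'   internally by the constructor)
#' @return named numeric vector of kcal/year, in sorted id order
#' @export
estimate_production <- function(network) {
  W <- weight_matrix(network)
  prod <- network$countries$supply + rowSums(W) - colSums(W)
  names(prod) <- network$countries$id
  prod
}

#' Baseline trade accounts
#'
#' Pre-shock exports (row sums of the weight matrix), imports (column
#' sums) and demand (production + imports - exports) per country, all in
#' kcal/year.  Because production is itself derived as supply plus net
#' exports, baseline demand always equals supply.
#'
#' @param network a \code{trade_network}
#' @return data.frame with columns id, production, exports, imports,
#'   demand, in sorted id order
#' @export
baseline_accounts <- function(network) {
  stopifnot(inherits(network, "trade_network"))
  W <- weight_matrix(network)
  exp_ <- rowSums(W)
  imp_ <- colSums(W)
  data.frame(id = network$countries$id,
             production = network$countries$production,
             exports = unname(exp_), imports = unname(imp_),
             demand = unname(network$countries$production + imp_ - exp_),
             stringsAsFactors = FALSE)
}

#' Read a trade network from its two-file delimited form
#'
#' @param edge_file CSV with header \code{origin_id,dest_id,kcal_per_year}
#' @param attr_file CSV with header \code{id,name,gdp,population,supply}
#' @return a validated \code{trade_network}
#' @export
read_trade_network <- function(edge_file, attr_file) {
  attrs <- utils::read.csv(attr_file, stringsAsFactors = FALSE,
                           colClasses = c(id = "character", name = "character"))
  edges <- utils::read.csv(edge_file, stringsAsFactors = FALSE,
                           colClasses = c(origin_id = "character",
                                          dest_id = "character"))
  rqe <- c("origin_id", "dest_id", "kcal_per_year")
  if (!all(rqe %in% names(edges)))
    stop("edge file must have columns: ", paste(rqe, collapse = ", "))
  names(edges)[match(rqe, names(edges))] <- c("origin", "dest", "weight")
  trade_network(attrs, edges)
}

#' Write a trade network to its two-file delimited form
#'
#' Numeric fields are written with 17 significant digits so a read
#' round-trip reproduces weights bit-exactly.
#'
#' @param network a \code{trade_network}
#' @param edge_file,attr_file output paths
#' @return invisibly, the two paths
#' @export
write_trade_network <- function(network, edge_file, attr_file) {
  stopifnot(inherits(network, "trade_network"))
  co <- network$countries
  at <- data.frame(id = co$id, name = co$name,
                   gdp = sprintf("%.17g", co$gdp),
                   population = sprintf("%.17g", co$population),
                   supply = sprintf("%.17g", co$supply),
                   stringsAsFactors = FALSE)
  utils::write.csv(at, attr_file, row.names = FALSE, quote = TRUE)
  ed <- data.frame(origin_id = network$edges$origin,
                   dest_id = network$edges$dest,
                   kcal_per_year = sprintf("%.17g", network$edges$weight),
                   stringsAsFactors = FALSE)
  utils::write.csv(ed, edge_file, row.names = FALSE, quote = TRUE)
  invisible(c(edge_file, attr_file))
}

#' Convert annual per-country calories to per-capita daily calories
#'
#' @param kcal_year numeric vector, kcal/year, in network country order
#' @param network a \code{trade_network}
#' @param days_per_year days in a year used for the conversion
#' @return kcal/person/day
#' @export
per_capita_daily <- function(kcal_year, network, days_per_year = 365) {
  kcal_year / (network$countries$population * days_per_year)
}

#' Deterministic content hash of a trade network
#'
#' MD5 of the canonical two-file CSV serialization; used to bind grids,
#' feature tables and report manifests to the network they came from.
#'
#' @param network a \code{trade_network}
#' @return a character MD5 digest
#' @export
network_hash <- function(network) {
  ef <- tempfile(fileext = ".csv"); af <- tempfile(fileext = ".csv")
  on.exit(unlink(c(ef, af)), add = TRUE)
  write_trade_network(network, ef, af)
  paste(unname(tools::md5sum(c(af, ef))), collapse = "")
}

#' @export
print.trade_network <- function(x, ...) {
  cat("Calorie trade network:", x$n, "countries,",
      nrow(x$edges), "directed edges\n")
  cat(sprintf("  total trade flow: %.4g kcal/year\n", sum(x$edges$weight)))
  invisible(x)
}

#' @export
summary.trade_network <- function(object, ...) {
  acc <- baseline_accounts(object)
  out <- list(n = object$n, m = nrow(object$edges),
              density = nrow(object$edges) / (object$n * (object$n - 1)),
              total_flow = sum(object$edges$weight), accounts = acc)
  class(out) <- "summary.trade_network"
  out
}

#' @export
print.summary.trade_network <- function(x, ...) {
  cat("Calorie trade network\n")
  cat("  countries:", x$n, "  edges:", x$m,
      sprintf("  density: %.3f\n", x$density))
  cat(sprintf("  total flow: %.4g kcal/year\n", x$total_flow))
  cat("  baseline accounts (kcal/year):\n")
  print(utils::head(x$accounts, 10))
  if (nrow(x$accounts) > 10) cat("  ...\n")
  invisible(x)
}
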