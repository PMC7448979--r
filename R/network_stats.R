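# Topology statistics in the conventions of Cytoscape's NetworkAnalyzer, and
# seed-node module extraction at a shortest-path radius. Statistics for
# multi-component networks are computed per component (finite-distance pairs
# only), which is how a sparse network can report radius 1 alongside a large
# diameter.

#' Topology statistics of a network
#'
#' Conventions: density = 2E / (N(N-1)); avg_neighbors = mean degree;
#' heterogeneity = population sd(degree) / mean(degree); centralization =
#' N/(N-2) * (max_degree/(N-1) - density); shortest paths per connected
#' component; characteristic_path_length = mean distance over all connected
#' ordered pairs; diameter = maximum finite eccentricity; radius = minimum
#' eccentricity over non-isolated nodes; isolated_nodes = degree-0 count.
#'
#' @param net a [tripartite_network()].
#' @return object of class `network_stats` (a named list); for N < 3
#'   centralization is reported as 0 with attribute `centralization_undefined`.
#' @export
compute_stats <- function(net) {
  stopifnot(inherits(net, "tripartite_network"))
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  deg <- igraph::degree(g)

  density <- if (n >= 2L) 2 * e / (n * (n - 1)) else 0
  avg_neighbors <- if (n >= 1L) mean(deg) else 0
  heterogeneity <- if (n >= 1L && mean(deg) > 0) {
    sqrt(mean((deg - mean(deg))^2)) / mean(deg)
  } else 0
  centr_undef <- n < 3L
  centralization <- if (centr_undef) 0 else {
    (n / (n - 2)) * (max(deg) / (n - 1) - density)
  }

  if (n >= 1L) {
    d <- igraph::distances(g)
    diag(d) <- Inf
    finite <- is.finite(d)
    cpl <- if (any(finite)) mean(d[finite]) else 0
    ecc <- apply(d, 1L, function(row) {
      f <- row[is.finite(row)]
      if (length(f)) max(f) else 0
    })
    non_isolated <- deg > 0
    diameter <- if (any(non_isolated)) max(ecc[non_isolated]) else 0
    radius <- if (any(non_isolated)) min(ecc[non_isolated]) else 0
    n_comp <- igraph::components(g)$no
  } else {
    cpl <- 0; diameter <- 0; radius <- 0; n_comp <- 0L
  }

  structure(list(
    nodes = n, edges = e, connected_components = n_comp,
    diameter = diameter, radius = radius, density = density,
    heterogeneity = heterogeneity, centralization = centralization,
    characteristic_path_length = cpl, avg_neighbors = avg_neighbors,
    isolated_nodes = sum(deg == 0)
  ), centralization_undefined = centr_undef, class = "network_stats")
}

#' @export
print.network_stats <- function(x, digits = 3, ...) {
  cat("Network topology statistics\n")
  for (f in names(x)) {
    v <- x[[f]]
    cat(sprintf("  %-28s %s\n", f,
                if (is.numeric(v) && v != round(v)) round(v, digits) else v))
  }
  invisible(x)
}

#' Extract a seed-centered module
#'
#' The module of a seed node at a path length is the induced subnetwork of
#' all nodes within that shortest-path distance of the seed.
#'
#' @param net a [tripartite_network()].
#' @param seed entity id (must exist).
#' @param path_length maximum shortest-path distance (default 2).
#' @return object of class `seed_module`: `seed`, `path_length`, `counts`
#'   (compounds/diseases/targets among the members) and `network` (induced
#'   subnetwork).
#' @export
extract_seed_module <- function(net, seed, path_length = 2L) {
  stopifnot(inherits(net, "tripartite_network"))
  if (!(seed %in% net$entities$id)) stop("unknown seed entity: ", seed)
  g <- as_igraph(net)
  d <- igraph::distances(g, v = seed)[1L, ]
  members <- names(d)[is.finite(d) & d <= path_length]
  sub <- induced_subgraph(net, members)
  kinds <- table(factor(sub$entities$kind, levels = ENTITY_KINDS))
  structure(list(seed = seed, path_length = path_length,
                 counts = c(compounds = unname(kinds[["compound"]]),
                            diseases = unname(kinds[["disease"]]),
                            targets = unname(kinds[["protein"]])),
                 network = sub),
            class = "seed_module")
}

#' @export
print.seed_module <- function(x, ...) {
  cat(sprintf("Seed module of %s at path length %d: %d compounds, %d diseases, %d targets\n",
              x$seed, x$path_length, x$counts[["compounds"]],
              x$counts[["diseases"]], x$counts[["targets"]]))
  invisible(x)
}

#' Side-by-side comparison of two statistic sets
#'
#' @param a,b `network_stats` objects (e.g. original vs expanded network).
#' @param labels column labels.
#' @return data.frame with one row per parameter and a `delta` column
#'   (b - a), writable with [utils::write.table()].
#' @export
compare_stats <- function(a, b, labels = c("a", "b")) {
  stopifnot(inherits(a, "network_stats"), inherits(b, "network_stats"))
  params <- names(unclass(a))
  out <- data.frame(parameter = params,
                    va = unlist(unclass(a))[params],
                    vb = unlist(unclass(b))[params])
  out$delta <- out$vb - out$va
  names(out)[2:3] <- labels
  rownames(out) <- NULL
  out
}
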