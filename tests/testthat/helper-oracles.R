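# Independent oracles and fixture builders shared across the test files.
# Everything here deliberately avoids the package's own code paths: the SIM
# oracle enumerates edge pairs exhaustively, the CCA oracle solves the
# generalized eigenproblem directly, and shortest paths come from a
# Floyd-Warshall implementation.

# exhaustive O(E^2) enumeration of all one-hop inference chains x - m - y;
# rule determined by the kind pattern of (x, m, y)
oracle_sim <- function(net) {
  edges <- net$interactions[net$interactions$provenance == "known", ]
  kind <- setNames(net$entities$kind, net$entities$id)
  canon <- list(CT = c("compound", "protein"), CD = c("compound", "disease"),
                DT = c("disease", "protein"))
  rows <- list()
  n <- nrow(edges)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        e1 <- c(edges$a[i], edges$b[i])
        e2 <- c(edges$a[j], edges$b[j])
        shared <- intersect(e1, e2)
        if (length(shared) != 1L) next
        m <- shared
        x <- setdiff(e1, m)
        y <- setdiff(e2, m)
        if (x == y) next
        km <- kind[[m]]; kx <- kind[[x]]; ky <- kind[[y]]
        ends <- sort(c(kx, ky))
        rule <- NULL
        if (km == "protein") {
          if (identical(ends, c("compound", "disease"))) rule <- "R1_CD"
          else if (identical(ends, c("compound", "protein"))) rule <- "R2_CT"
          else if (identical(ends, c("disease", "protein"))) rule <- "R3_DT"
        } else if (km == "compound") {
          if (identical(ends, c("disease", "protein"))) rule <- "R4_DT"
        } else if (km == "disease") {
          if (identical(ends, c("compound", "protein"))) rule <- "R5_CT"
        }
        if (is.null(rule)) next
        pt <- substr(rule, 4L, 5L)
        want <- canon[[pt]]
        pair <- if (kind[[x]] == want[1L]) c(x, y) else c(y, x)
        rows[[length(rows) + 1L]] <- data.frame(
          pair_type = pt, a = pair[1L], b = pair[2L], rule = rule,
          intermediate = m, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(pair_type = character(), a = character(),
                      b = character(), rule = character(),
                      support = integer(), stringsAsFactors = FALSE))
  }
  df <- unique(do.call(rbind, rows))
  agg <- aggregate(intermediate ~ pair_type + a + b + rule, df,
                   function(v) length(unique(v)))
  names(agg)[names(agg) == "intermediate"] <- "support"
  agg <- agg[order(agg$pair_type, agg$a, agg$b, agg$rule), ]
  rownames(agg) <- NULL
  agg
}

# random typed network with independent edge sampling per admissible pair
random_tripartite <- function(n_c = 10L, n_p = 10L, n_d = 5L, p_edge = 0.2,
                              seed = 1L, with_tt = TRUE) {
  set.seed(seed)
  cs <- paste0("C", seq_len(n_c))
  ts <- paste0("T", seq_len(n_p))
  ds <- paste0("D", seq_len(n_d))
  entities <- data.frame(
    id = c(cs, ts, ds),
    kind = c(rep("compound", n_c), rep("protein", n_p), rep("disease", n_d)),
    stringsAsFactors = FALSE)
  pick <- function(aa, bb, pt) {
    g <- expand.grid(a = aa, b = bb, stringsAsFactors = FALSE)
    if (pt == "TT") g <- g[g$a < g$b, , drop = FALSE]
    g <- g[runif(nrow(g)) < p_edge, , drop = FALSE]
    if (nrow(g)) cbind(g, pair_type = pt) else NULL
  }
  edges <- rbind(pick(cs, ts, "CT"), pick(cs, ds, "CD"), pick(ds, ts, "DT"),
                 if (with_tt) pick(ts, ts, "TT"))
  tripartite_network(entities, edges)
}

# canonical correlations via the generalized eigenproblem on standardized data
oracle_cca_cor <- function(x, y) {
  xs <- scale(x); ys <- scale(y)
  n <- nrow(xs)
  sxx <- crossprod(xs) / (n - 1)
  syy <- crossprod(ys) / (n - 1)
  sxy <- crossprod(xs, ys) / (n - 1)
  m <- solve(sxx) %*% sxy %*% solve(syy) %*% t(sxy)
  ev <- sort(Re(eigen(m)$values), decreasing = TRUE)
  sqrt(pmin(pmax(ev[seq_len(min(ncol(x), ncol(y)))], 0), 1))
}

# all-pairs shortest paths by Floyd-Warshall over the edge list
oracle_distances <- function(ids, edges) {
  n <- length(ids)
  d <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(d) <- 0
  for (i in seq_len(nrow(edges))) {
    d[edges$a[i], edges$b[i]] <- 1
    d[edges$b[i], edges$a[i]] <- 1
  }
  for (k in seq_len(n)) {
    dk <- d[, k]
    for (j in seq_len(n)) {
      cand <- dk + d[k, j]
      upd <- cand < d[, j]
      d[upd, j] <- cand[upd]
    }
  }
  d
}

# small descriptor matrix with named columns
dm <- function(..., ids = NULL) {
  cols <- list(...)
  m <- do.call(cbind, cols)
  colnames(m) <- names(cols)
  rownames(m) <- if (is.null(ids)) paste0("E", seq_len(nrow(m))) else ids
  m
}
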