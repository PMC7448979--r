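# Synthetic test-data generators: the published five-compound evaluation
# network, paired descriptor blocks with an exactly planted canonical
# correlation, and entity-level descriptor matrices with latent-proximity
# interactions that make correlation-space recall a meaningful recovery
# metric.

#' The five-compound / two-target / two-disease evaluation network
#'
#' The known-interaction test set used to evaluate compound/disease-centered
#' inference: 8 compound-disease, 8 compound-target and 2 disease-target
#' interactions among compounds C10, C17, C18, C29, C40, targets T8, T13 and
#' diseases D2, D12. Deterministic.
#'
#' @return a [tripartite_network()] with 9 entities and 18 known edges.
#' @export
table1_network <- function() {
  compounds <- c("C10", "C17", "C18", "C29", "C40")
  entities <- data.frame(
    id = c(compounds, "T8", "T13", "D2", "D12"),
    kind = c(rep("compound", 5L), "protein", "protein", "disease",
             "disease"),
    stringsAsFactors = FALSE)
  cd <- data.frame(a = c(compounds, "C17", "C18", "C29"),
                   b = c(rep("D2", 5L), rep("D12", 3L)),
                   pair_type = "CD", stringsAsFactors = FALSE)
  ct <- data.frame(a = c(compounds, "C17", "C18", "C29"),
                   b = c(rep("T8", 5L), rep("T13", 3L)),
                   pair_type = "CT", stringsAsFactors = FALSE)
  dt <- data.frame(a = c("D2", "D12"), b = c("T8", "T13"),
                   pair_type = "DT", stringsAsFactors = FALSE)
  tripartite_network(entities, rbind(cd, ct, dt))
}

#' Paired descriptor blocks with an exactly planted canonical correlation
#'
#' Generates n paired rows of two blocks sharing latent factors: the first
#' latent pair is correlated at `rho`, a second at `rho2`, and the remaining
#' block columns are independent. Per-column noise with standard deviation
#' `noise_sd` attenuates the observable correlation only marginally (the
#' canonical combination averages the noise over the block), so the fitted
#' first canonical correlation recovers `rho` closely at moderate n.
#'
#' @param n rows (pairs).
#' @param p,q block widths (>= 1; the second planted pair needs >= 2).
#' @param rho planted first canonical correlation in [0, 1).
#' @param rho2 planted second canonical correlation (< rho).
#' @param noise_sd per-column noise standard deviation.
#' @param seed RNG seed.
#' @return list with matrices `X` (n x p) and `Y` (n x q).
#' @export
simulate_paired_descriptors <- function(n = 500L, p = 6L, q = 6L, rho = 0.9,
                                        rho2 = 0.3, noise_sd = 0.1,
                                        seed = 1L) {
  stopifnot(rho >= 0, rho < 1, n >= 3L, p >= 1L, q >= 1L)
  set.seed(seed)
  u1 <- stats::rnorm(n)
  v1 <- rho * u1 + sqrt(1 - rho^2) * stats::rnorm(n)
  x <- matrix(stats::rnorm(n * p), n, p)
  y <- matrix(stats::rnorm(n * q), n, q)
  x[, 1L] <- u1
  y[, 1L] <- v1
  if (p >= 2L && q >= 2L && rho2 > 0) {
    u2 <- stats::rnorm(n)
    x[, 2L] <- u2
    y[, 2L] <- rho2 * u2 + sqrt(1 - rho2^2) * stats::rnorm(n)
  }
  x <- x + noise_sd * matrix(stats::rnorm(n * p), n, p)
  y <- y + noise_sd * matrix(stats::rnorm(n * q), n, q)
  colnames(x) <- paste0("cd", seq_len(p))
  colnames(y) <- paste0("pd", seq_len(q))
  list(X = x, Y = y)
}

#' Default generator configuration
#'
#' Study conditions for the synthetic interaction system: 60 compounds, 20
#' proteins, 8 informative descriptors per side over a 3-dimensional latent
#' space, anchor-pair latent correlation 0.9, descriptor noise sd 0.3,
#' interaction radius 1.6 (grown automatically until every protein has
#' `min_partners` interaction partners). Proteins fall into `n_families`
#' tight families (well-separated centers), mimicking target families whose
#' members are hit by the same analog series of compounds; this is what
#' keeps the realized canonical correlation of the interacting-pair sample
#' near the planted value.
#'
#' @param ... overrides of the default fields.
#' @return list of generator settings.
#' @export
generator_config <- function(...) {
  cfg <- list(n_compounds = 60L, n_proteins = 20L, p = 8L, q = 8L,
              latent_dim = 3L, canonical_rho = 0.9, noise_sd = 0.3,
              interaction_radius = 1.6, min_partners = 4L,
              n_families = 5L, center_scale = 2.2, family_sd = 0.25,
              nuisance = TRUE, seed = 7L)
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown)) {
    stop("unknown generator field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(override)] <- override
  stopifnot(cfg$canonical_rho > 0, cfg$canonical_rho < 1,
            cfg$noise_sd >= 0, cfg$interaction_radius > 0)
  cfg
}

#' Entity-level correlated descriptor matrices
#'
#' Protein latent positions are drawn in families (tight clusters around
#' well-separated centers); each compound is anchored to one protein with a
#' latent offset sized so that the anchor-pair latent correlation equals
#' `canonical_rho`. Observed descriptors are a random linear map of the
#' latents plus independent noise. With `nuisance = TRUE`, contaminant
#' columns (missing values, constant, low relative spread, duplicated,
#' pure noise) are appended to exercise descriptor preprocessing and
#' selection.
#'
#' @param config a [generator_config()].
#' @return list with `compounds` and `proteins` descriptor matrices,
#'   `compound_latents`, `protein_latents`, `anchors` and the `config`.
#' @export
simulate_correlated_descriptors <- function(config = generator_config()) {
  set.seed(config$seed)
  L <- config$latent_dim
  n_c <- config$n_compounds
  n_p <- config$n_proteins

  centers <- config$center_scale * matrix(stats::rnorm(config$n_families * L),
                                          config$n_families, L)
  fam <- sample(rep(seq_len(config$n_families), length.out = n_p))
  zp <- centers[fam, , drop = FALSE] +
    config$family_sd * matrix(stats::rnorm(n_p * L), n_p, L)
  # pair spread giving corr(compound, anchor protein) = canonical_rho per
  # latent coordinate: tau^2 = V (1/rho^2 - 1), V = total latent variance
  v_lat <- config$center_scale^2 + config$family_sd^2
  tau <- sqrt(v_lat * (1 / config$canonical_rho^2 - 1))
  anchors <- sample(rep(seq_len(n_p), length.out = n_c))
  zc <- zp[anchors, , drop = FALSE] +
    tau * matrix(stats::rnorm(n_c * L), n_c, L)

  bx <- matrix(stats::rnorm(L * config$p), L, config$p)
  by <- matrix(stats::rnorm(L * config$q), L, config$q)
  x <- zc %*% bx +
    config$noise_sd * matrix(stats::rnorm(n_c * config$p), n_c, config$p)
  y <- zp %*% by +
    config$noise_sd * matrix(stats::rnorm(n_p * config$q), n_p, config$q)
  rownames(x) <- paste0("C", seq_len(n_c))
  rownames(y) <- paste0("T", seq_len(n_p))
  colnames(x) <- paste0("cd", seq_len(config$p))
  colnames(y) <- paste0("pd", seq_len(config$q))
  if (isTRUE(config$nuisance)) {
    x <- add_nuisance(x, "cd")
    y <- add_nuisance(y, "pd")
  }
  list(compounds = x, proteins = y, compound_latents = zc,
       protein_latents = zp, anchors = anchors, config = config)
}

# contaminant columns: one with missing cells, one constant, one with tiny
# relative spread, one duplicated informative column, two of pure noise
add_nuisance <- function(m, prefix) {
  n <- nrow(m)
  with_na <- stats::rnorm(n)
  with_na[seq_len(max(1L, n %/% 20L))] <- NA
  extra <- cbind(with_na,
                 rep(42, n),
                 100 + 0.1 * stats::rnorm(n),
                 m[, 1L],
                 stats::rnorm(n),
                 stats::rnorm(n))
  colnames(extra) <- paste0(prefix, "_", c("na", "const", "lowrsd", "dup",
                                           "noise1", "noise2"))
  cbind(m, extra)
}

#' Latent-proximity interaction network
#'
#' A compound interacts with a protein when their latent positions are
#' closer than the interaction radius. The radius is grown by 10% steps
#' (up to `max_attempts`) until every protein has at least `min_partners`
#' partners, so cross-validation folds are non-degenerate.
#'
#' @param latents output of [simulate_correlated_descriptors()] (or any list
#'   with `compound_latents` and `protein_latents` carrying row names via
#'   `compounds`/`proteins`).
#' @param config a [generator_config()].
#' @param max_attempts radius growth attempts before giving up.
#' @return a [tripartite_network()] of known CT edges; the radius actually
#'   used is stored in `attr(net, "interaction_radius")`.
#' @export
simulate_interactions <- function(latents, config = latents$config,
                                  max_attempts = 100L) {
  zc <- latents$compound_latents
  zp <- latents$protein_latents
  cid <- rownames(latents$compounds)
  pid <- rownames(latents$proteins)
  n_c <- nrow(zc)
  d <- as.matrix(stats::dist(rbind(zc, zp)))
  d <- d[seq_len(n_c), n_c + seq_len(nrow(zp)), drop = FALSE]
  radius <- config$interaction_radius
  for (attempt in seq_len(max_attempts)) {
    adj <- d < radius
    if (sum(adj) > 0L && all(colSums(adj) >= config$min_partners)) break
    radius <- radius * 1.1
    adj <- NULL
  }
  if (is.null(adj) || sum(adj) == 0L) {
    stop("no interactions after ", max_attempts, " radius increases")
  }
  idx <- which(adj, arr.ind = TRUE)
  entities <- data.frame(id = c(cid, pid),
                         kind = c(rep("compound", length(cid)),
                                  rep("protein", length(pid))),
                         stringsAsFactors = FALSE)
  edges <- data.frame(a = cid[idx[, 1L]], b = pid[idx[, 2L]],
                      pair_type = "CT", stringsAsFactors = FALSE)
  net <- tripartite_network(entities, edges)
  attr(net, "interaction_radius") <- radius
  net
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper: correlated descriptor matrices plus the
#' latent-proximity interaction network, all from one seeded configuration.
#'
#' @param config a [generator_config()].
#' @return list with `network`, `compounds`, `proteins` (descriptor
#'   matrices) and the full generator output under `latents`.
#' @export
simulate_study <- function(config = generator_config()) {
  gen <- simulate_correlated_descriptors(config)
  net <- simulate_interactions(gen, config)
  list(network = net, compounds = gen$compounds, proteins = gen$proteins,
       latents = gen, config = config)
}
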