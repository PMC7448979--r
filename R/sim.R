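# Simple inference model (SIM): one-hop relevance rules over the tripartite
# network. A new edge is inferred from two known edges sharing an intermediate
# node; the support of an inferred pair is its number of distinct
# intermediates. Two rule families:
#
#   target-centered  R1: C-T & T-D => C-D    (intermediate = target)
#                    R2: C-Ta & Ta-Tb => C-Tb (intermediate = target)
#                    R3: Tb-Ta & Ta-D => Tb-D (intermediate = target)
#   entity-centered  R4: C-D & C-T => D-T    (intermediate = compound)
#                    R5: C-D & D-T => C-T    (intermediate = disease)
#
# Inference is a single pass: inferred edges are never reused as premises.
# Routes are recorded in the chain notation "a-intermediate-b".

# join two known-edge sets on a shared endpoint column and assemble inferred
# pairs; returns one row per (pair, intermediate)
join_rule <- function(left, right, by_left, by_right, out_a, out_b,
                      pair_type, rule) {
  if (nrow(left) == 0L || nrow(right) == 0L) {
    return(data.frame(a = character(), b = character(),
                      pair_type = character(), rule = character(),
                      intermediate = character(), stringsAsFactors = FALSE))
  }
  m <- merge(
    data.frame(int = left[[by_left]],
               la = left$a, lb = left$b, stringsAsFactors = FALSE),
    data.frame(int = right[[by_right]],
               ra = right$a, rb = right$b, stringsAsFactors = FALSE),
    by = "int"
  )
  if (nrow(m) == 0L) {
    return(data.frame(a = character(), b = character(),
                      pair_type = character(), rule = character(),
                      intermediate = character(), stringsAsFactors = FALSE))
  }
  pick <- function(df, spec) {
    switch(spec,
           la = df$la, lb = df$lb, ra = df$ra, rb = df$rb, int = df$int)
  }
  out <- data.frame(a = pick(m, out_a), b = pick(m, out_b),
                    pair_type = pair_type, rule = rule,
                    intermediate = m$int, stringsAsFactors = FALSE)
  out[out$a != out$b, , drop = FALSE]
}

# collapse per-intermediate rows into one row per inferred pair with support
# and semicolon-joined routes "a-int-b"
collapse_inferred <- function(rows) {
  if (nrow(rows) == 0L) {
    return(data.frame(pair_type = character(), a = character(),
                      b = character(), rule = character(),
                      support = integer(), routes = character(),
                      stringsAsFactors = FALSE))
  }
  rows <- rows[!duplicated(rows[c("a", "b", "pair_type", "rule",
                                  "intermediate")]), , drop = FALSE]
  key <- paste(rows$pair_type, rows$a, rows$b, rows$rule, sep = "\r")
  split_idx <- split(seq_len(nrow(rows)), key)
  out <- do.call(rbind, lapply(split_idx, function(idx) {
    ints <- sort(unique(rows$intermediate[idx]))
    data.frame(pair_type = rows$pair_type[idx[1L]],
               a = rows$a[idx[1L]], b = rows$b[idx[1L]],
               rule = rows$rule[idx[1L]],
               support = length(ints),
               routes = paste(sprintf("%s-%s-%s", rows$a[idx[1L]], ints,
                                      rows$b[idx[1L]]), collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$pair_type, out$a, out$b, out$rule), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Target-centered inference (rules R1, R2, R3)
#'
#' Emits every interaction that follows from two known edges sharing a
#' target: known C-T and T-D give C-D (R1); known C-Ta and Ta-Tb give C-Tb
#' (R2); known Tb-Ta and Ta-D give Tb-D (R3). Only `known` edges are used as
#' premises, in a single pass.
#'
#' @param net a [tripartite_network()].
#' @return data.frame with columns `pair_type`, `a`, `b`, `rule`, `support`
#'   (number of distinct intermediates) and `routes` (semicolon-joined
#'   `a-intermediate-b` chains).
#' @export
target_centered_inference <- function(net) {
  e <- known_edges(net)
  ct <- e[e$pair_type == "CT", , drop = FALSE]  # a = compound, b = protein
  dt <- e[e$pair_type == "DT", , drop = FALSE]  # a = disease,  b = protein
  tt <- e[e$pair_type == "TT", , drop = FALSE]  # both proteins, a < b
  # TT is undirected: use both orientations when joining on one endpoint
  tt2 <- if (nrow(tt)) {
    rbind(tt, data.frame(a = tt$b, b = tt$a, pair_type = tt$pair_type,
                         provenance = tt$provenance, support = tt$support,
                         stringsAsFactors = FALSE))
  } else tt

  r1 <- join_rule(ct, dt, "b", "b", "la", "ra", "CD", "R1_CD")
  r2 <- join_rule(ct, tt2, "b", "a", "la", "rb", "CT", "R2_CT")
  r3 <- join_rule(tt2, dt, "b", "b", "ra", "la", "DT", "R3_DT")
  collapse_inferred(rbind(r1, r2, r3))
}

#' Compound/disease-centered inference (rules R4, R5)
#'
#' Emits every interaction that follows from two known edges sharing a
#' compound or a disease: known C-D and C-T give D-T with the compound as
#' intermediate (R4); known C-D and D-T give C-T with the disease as
#' intermediate (R5). Support counts distinct intermediates; this family is
#' filtered at support >= 2 in production because it is more prone to false
#' positives than the target-centered family.
#'
#' @inheritParams target_centered_inference
#' @inherit target_centered_inference return
#' @export
entity_centered_inference <- function(net) {
  e <- known_edges(net)
  cd <- e[e$pair_type == "CD", , drop = FALSE]  # a = compound, b = disease
  ct <- e[e$pair_type == "CT", , drop = FALSE]  # a = compound, b = protein
  dt <- e[e$pair_type == "DT", , drop = FALSE]  # a = disease,  b = protein
  r4 <- join_rule(cd, ct, "a", "a", "lb", "rb", "DT", "R4_DT")
  r5 <- join_rule(cd, dt, "b", "a", "la", "rb", "CT", "R5_CT")
  collapse_inferred(rbind(r4, r5))
}

#' Filter inferred interactions by support
#'
#' @param inferred data.frame as returned by the inference functions.
#' @param min_support keep pairs inferred through at least this many distinct
#'   intermediates (>= 1).
#' @return The filtered data.frame, original order preserved.
#' @export
apply_support_filter <- function(inferred, min_support) {
  stopifnot(min_support >= 1L)
  out <- inferred[inferred$support >= min_support, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the simple inference model
#'
#' Runs the requested rule families over the known edges of `net`, applies
#' the per-family support filters, and flags novelty (pair absent from the
#' known edges). In evaluation mode all filtered inferences are returned
#' with known pairs flagged `novel = FALSE`; in production mode
#' (`evaluation_mode = FALSE`) pairs already known are dropped, matching the
#' published workflow's "removal of existing and reduplicative data".
#'
#' @param net a [tripartite_network()].
#' @param min_support_entity_centered support filter for rules R4/R5
#'   (default 2: a pair must be inferred through more than one intermediate).
#' @param min_support_target_centered support filter for rules R1-R3.
#' @param evaluation_mode keep non-novel pairs (flagged) instead of dropping
#'   them.
#' @param families which rule families to run.
#' @return list with `inferred` (all retained inferences, ordered by pair
#'   type then ids) and `novel` (the subset absent from known edges). Both
#'   data.frames carry a logical `novel` column.
#' @export
run_sim <- function(net,
                    min_support_entity_centered = 2L,
                    min_support_target_centered = 1L,
                    evaluation_mode = FALSE,
                    families = c("target_centered", "entity_centered")) {
  families <- match.arg(families, several.ok = TRUE)
  parts <- list()
  if ("target_centered" %in% families) {
    parts$tc <- apply_support_filter(target_centered_inference(net),
                                     min_support_target_centered)
  }
  if ("entity_centered" %in% families) {
    parts$ec <- apply_support_filter(entity_centered_inference(net),
                                     min_support_entity_centered)
  }
  inferred <- do.call(rbind, parts)
  if (is.null(inferred) || nrow(inferred) == 0L) {
    empty <- data.frame(pair_type = character(), a = character(),
                        b = character(), rule = character(),
                        support = integer(), routes = character(),
                        novel = logical(), stringsAsFactors = FALSE)
    return(list(inferred = empty, novel = empty))
  }
  known_keys <- edge_key(known_edges(net))
  inferred$novel <- !(edge_key(inferred) %in% known_keys)
  if (!evaluation_mode) {
    inferred <- inferred[inferred$novel, , drop = FALSE]
  }
  inferred <- inferred[order(inferred$pair_type, inferred$a, inferred$b,
                             inferred$rule), , drop = FALSE]
  rownames(inferred) <- NULL
  novel <- inferred[inferred$novel, , drop = FALSE]
  rownames(novel) <- NULL
  list(inferred = inferred, novel = novel)
}

#' Convert SIM output to interaction edges
#'
#' @param inferred data.frame from [run_sim()] or the inference functions.
#' @return data.frame suitable for [merge_interactions()] with provenance
#'   `sim_inferred`.
#' @export
sim_as_edges <- function(inferred) {
  data.frame(a = inferred$a, b = inferred$b, pair_type = inferred$pair_type,
             provenance = "sim_inferred", support = inferred$support,
             stringsAsFactors = FALSE)
}
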