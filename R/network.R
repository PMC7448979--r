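# Tripartite compound-target-disease interaction network: data model and I/O.

ENTITY_KINDS <- c("compound", "protein", "disease")

# canonical endpoint kinds per pair type; edge (a, b) is stored in this order
PAIR_TYPE_KINDS <- list(
  CT = c("compound", "protein"),
  CD = c("compound", "disease"),
  DT = c("disease", "protein"),
  TT = c("protein", "protein")
)

PROVENANCE_LEVELS <- c("known", "sim_inferred", "ctcs_predicted")

#' Construct a tripartite interaction network
#'
#' A tripartite network holds compounds, proteins and diseases together with
#' undirected interactions of four types: compound-target (CT),
#' compound-disease (CD), disease-target (DT) and protein-protein (TT).
#' Each edge carries a provenance tag (`known`, `sim_inferred` or
#' `ctcs_predicted`) and a support count (number of distinct inference routes;
#' 0 for known or correlation-space predicted edges).
#'
#' Edges are canonicalized so that at most one interaction exists per
#' unordered pair and pair type: CT/CD edges store the compound first, DT
#' edges the disease first, and TT edges order endpoints lexicographically.
#' Self-edges and edges whose endpoint kinds disagree with the pair type are
#' rejected.
#'
#' @param entities data.frame with columns `id` and `kind`
#'   (compound/protein/disease); any further columns are kept as labels.
#' @param interactions data.frame with columns `a`, `b`, `pair_type` and
#'   optionally `provenance` (default "known") and `support` (default 0).
#' @param warn_duplicates warn when duplicate edges are collapsed.
#' @return An object of class `tripartite_network` with elements `entities`
#'   and `interactions`. The number of collapsed duplicate rows is available
#'   as `attr(net, "n_duplicates")`.
#' @export
tripartite_network <- function(entities = NULL, interactions = NULL,
                               warn_duplicates = TRUE) {
  if (is.null(entities)) {
    entities <- data.frame(id = character(), kind = character(),
                           stringsAsFactors = FALSE)
  }
  entities <- as.data.frame(entities, stringsAsFactors = FALSE)
  if (!all(c("id", "kind") %in% names(entities))) {
    stop("entity table needs columns 'id' and 'kind'")
  }
  entities$id <- as.character(entities$id)
  entities$kind <- as.character(entities$kind)
  bad_kind <- setdiff(unique(entities$kind), ENTITY_KINDS)
  if (length(bad_kind)) {
    stop("unknown entity kind(s): ", paste(bad_kind, collapse = ", "))
  }
  if (anyDuplicated(entities$id)) {
    dup <- entities$id[duplicated(entities$id)]
    first <- entities[!duplicated(entities$id), , drop = FALSE]
    conflicting <- vapply(unique(dup), function(id) {
      length(unique(entities$kind[entities$id == id])) > 1L
    }, logical(1))
    if (any(conflicting)) {
      stop("entity id(s) declared with conflicting kinds: ",
           paste(unique(dup)[conflicting], collapse = ", "))
    }
    entities <- first
  }
  rownames(entities) <- NULL

  if (is.null(interactions) || nrow(as.data.frame(interactions)) == 0L) {
    interactions <- empty_interactions()
    n_dup <- 0L
  } else {
    interactions <- as.data.frame(interactions, stringsAsFactors = FALSE)
    if (!all(c("a", "b", "pair_type") %in% names(interactions))) {
      stop("interaction table needs columns 'a', 'b' and 'pair_type'")
    }
    if (is.null(interactions$provenance)) interactions$provenance <- "known"
    if (is.null(interactions$support)) interactions$support <- 0L
    interactions <- interactions[c("a", "b", "pair_type", "provenance",
                                   "support")]
    interactions$a <- as.character(interactions$a)
    interactions$b <- as.character(interactions$b)
    interactions$pair_type <- as.character(interactions$pair_type)
    interactions$provenance <- as.character(interactions$provenance)
    interactions$support <- as.integer(interactions$support)

    bad_pt <- setdiff(unique(interactions$pair_type), names(PAIR_TYPE_KINDS))
    if (length(bad_pt)) {
      stop("unknown pair_type(s): ", paste(bad_pt, collapse = ", "))
    }
    bad_prov <- setdiff(unique(interactions$provenance), PROVENANCE_LEVELS)
    if (length(bad_prov)) {
      stop("unknown provenance value(s): ", paste(bad_prov, collapse = ", "))
    }
    if (any(interactions$a == interactions$b)) {
      i <- which(interactions$a == interactions$b)[1L]
      stop("self-edge not allowed (row ", i, ": ", interactions$a[i], ")")
    }
    kind <- stats::setNames(entities$kind, entities$id)
    missing_ep <- setdiff(c(interactions$a, interactions$b), entities$id)
    if (length(missing_ep)) {
      rows <- which(interactions$a %in% missing_ep |
                      interactions$b %in% missing_ep)
      stop("interaction endpoint(s) absent from entity table: ",
           paste(utils::head(missing_ep, 5L), collapse = ", "),
           " (first offending row ", rows[1L], ")")
    }
    interactions <- canonicalize_edges(interactions, kind)

    key <- edge_key(interactions)
    n_dup <- sum(duplicated(key))
    if (n_dup > 0L) {
      # keep strongest provenance and max support among duplicates
      ord <- order(match(interactions$provenance, PROVENANCE_LEVELS),
                   -interactions$support)
      interactions <- interactions[ord, , drop = FALSE]
      interactions <- interactions[!duplicated(edge_key(interactions)), ,
                                   drop = FALSE]
      if (warn_duplicates) {
        warning(n_dup, " duplicate interaction row(s) collapsed")
      }
    }
    interactions <- interactions[order(interactions$pair_type,
                                       interactions$a, interactions$b), ,
                                 drop = FALSE]
    rownames(interactions) <- NULL
  }

  structure(list(entities = entities, interactions = interactions),
            n_duplicates = n_dup, class = "tripartite_network")
}

empty_interactions <- function() {
  data.frame(a = character(), b = character(), pair_type = character(),
             provenance = character(), support = integer(),
             stringsAsFactors = FALSE)
}

edge_key <- function(edges) {
  paste(edges$a, edges$b, edges$pair_type, sep = "\r")
}

# orient each edge into the canonical endpoint order of its pair type,
# validating endpoint kinds against the pair type
canonicalize_edges <- function(edges, kind) {
  if (nrow(edges) == 0L) return(edges)
  ka <- kind[edges$a]
  kb <- kind[edges$b]
  for (pt in unique(edges$pair_type)) {
    want <- PAIR_TYPE_KINDS[[pt]]
    idx <- which(edges$pair_type == pt)
    ok_fwd <- ka[idx] == want[1L] & kb[idx] == want[2L]
    ok_rev <- ka[idx] == want[2L] & kb[idx] == want[1L]
    bad <- idx[!(ok_fwd | ok_rev)]
    if (length(bad)) {
      stop("pair_type ", pt, " incompatible with endpoint kinds in row ",
           bad[1L], " (", edges$a[bad[1L]], ":", ka[bad[1L]], ", ",
           edges$b[bad[1L]], ":", kb[bad[1L]], ")")
    }
    if (want[1L] == want[2L]) {
      swap <- idx[edges$a[idx] > edges$b[idx]]
    } else {
      swap <- idx[ok_rev & !ok_fwd]
    }
    if (length(swap)) {
      tmp <- edges$a[swap]
      edges$a[swap] <- edges$b[swap]
      edges$b[swap] <- tmp
    }
  }
  edges
}

#' @export
print.tripartite_network <- function(x, ...) {
  kinds <- table(factor(x$entities$kind, levels = ENTITY_KINDS))
  pts <- table(factor(x$interactions$pair_type,
                      levels = names(PAIR_TYPE_KINDS)))
  cat("Tripartite interaction network\n")
  cat(sprintf("  entities:     %d (%d compounds, %d proteins, %d diseases)\n",
              nrow(x$entities), kinds[["compound"]], kinds[["protein"]],
              kinds[["disease"]]))
  cat(sprintf("  interactions: %d (CT %d, CD %d, DT %d, TT %d)\n",
              nrow(x$interactions), pts[["CT"]], pts[["CD"]], pts[["DT"]],
              pts[["TT"]]))
  prov <- table(x$interactions$provenance)
  if (length(prov)) {
    cat("  provenance:  ",
        paste(sprintf("%s %d", names(prov), prov), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.tripartite_network <- function(object, ...) {
  print(object)
  invisible(object)
}

entity_kind_map <- function(net) {
  stats::setNames(net$entities$kind, net$entities$id)
}

known_edges <- function(net) {
  net$interactions[net$interactions$provenance == "known", , drop = FALSE]
}

#' Load a tripartite network from node and edge tables
#'
#' Reads tab- or comma-separated tables (delimiter chosen from the file
#' extension: `.csv` is comma, everything else tab). The node table needs
#' columns `id` and `kind`; extra columns are preserved as labels. The edge
#' table needs columns `a`, `b`, `pair_type`, optionally `provenance` and
#' `support`. Duplicate edges are collapsed with a warning.
#'
#' @param node_file,edge_file paths to the tables.
#' @return A [tripartite_network()].
#' @export
load_network <- function(node_file, edge_file) {
  nodes <- read_table_auto(node_file)
  edges <- read_table_auto(edge_file)
  if (nrow(nodes) == 0L && nrow(edges) > 0L) {
    stop("edge table is non-empty but node table is empty")
  }
  tripartite_network(nodes, if (nrow(edges)) edges else NULL)
}

read_table_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, comment.char = "",
                    check.names = FALSE)
}

#' Merge new interactions into a network
#'
#' Adds a batch of edges (for example SIM-inferred or correlation-space
#' predicted pairs) to an existing network, de-duplicating within the batch
#' and against edges already present. With `dedupe_against_known = TRUE`
#' (the production behaviour) an incoming edge whose pair and pair type
#' already exist keeps the network's edge; the strongest provenance
#' (known > inferred/predicted) and the maximum support are retained either
#' way.
#'
#' @param net a [tripartite_network()].
#' @param new_edges data.frame with columns `a`, `b`, `pair_type` and
#'   optionally `provenance`, `support`.
#' @param dedupe_against_known drop incoming edges whose pair already exists.
#' @param new_entities optional data.frame (`id`, `kind`) declaring endpoints
#'   not yet in the network.
#' @return list with elements `network` (the merged network) and `counts`
#'   (`added`, `dropped_existing`, `dropped_duplicate`), which always sum to
#'   `nrow(new_edges)`.
#' @export
merge_interactions <- function(net, new_edges, dedupe_against_known = TRUE,
                               new_entities = NULL) {
  stopifnot(inherits(net, "tripartite_network"))
  entities <- net$entities
  if (!is.null(new_entities) && nrow(new_entities)) {
    new_entities <- as.data.frame(new_entities, stringsAsFactors = FALSE)
    known_kind <- entity_kind_map(net)
    clash <- new_entities$id %in% names(known_kind) &
      new_entities$kind != known_kind[new_entities$id]
    if (any(clash)) {
      stop("endpoint kind conflict for: ",
           paste(new_entities$id[clash], collapse = ", "))
    }
    add <- !(new_entities$id %in% entities$id)
    if (any(add)) {
      add_df <- new_entities[add, c("id", "kind"), drop = FALSE]
      for (col in setdiff(names(entities), names(add_df))) add_df[[col]] <- NA
      entities <- rbind(entities, add_df[names(entities)])
    }
  }

  new_edges <- as.data.frame(new_edges, stringsAsFactors = FALSE)
  n_in <- nrow(new_edges)
  if (n_in == 0L) {
    return(list(network = net,
                counts = c(added = 0L, dropped_existing = 0L,
                           dropped_duplicate = 0L)))
  }
  if (is.null(new_edges$provenance)) new_edges$provenance <- "sim_inferred"
  if (is.null(new_edges$support)) new_edges$support <- 0L
  new_edges <- new_edges[c("a", "b", "pair_type", "provenance", "support")]
  kind <- stats::setNames(entities$kind, entities$id)
  missing_ep <- setdiff(c(new_edges$a, new_edges$b), entities$id)
  if (length(missing_ep)) {
    stop("new edge endpoint(s) not in network (declare via new_entities): ",
         paste(utils::head(missing_ep, 5L), collapse = ", "))
  }
  new_edges <- canonicalize_edges(new_edges, kind)

  dup_within <- duplicated(edge_key(new_edges))
  dropped_duplicate <- sum(dup_within)
  new_edges <- new_edges[!dup_within, , drop = FALSE]

  existing <- net$interactions
  hit <- edge_key(new_edges) %in% edge_key(existing)
  dropped_existing <- sum(hit)

  if (any(hit)) {
    # upgrade provenance/support of the retained network edge
    incoming <- new_edges[hit, , drop = FALSE]
    idx <- match(edge_key(incoming), edge_key(existing))
    stronger <- match(incoming$provenance, PROVENANCE_LEVELS) <
      match(existing$provenance[idx], PROVENANCE_LEVELS)
    if (!dedupe_against_known || any(stronger)) {
      upgrade <- if (dedupe_against_known) which(stronger) else
        seq_len(nrow(incoming))
      for (j in upgrade) {
        i <- idx[j]
        if (match(incoming$provenance[j], PROVENANCE_LEVELS) <
              match(existing$provenance[i], PROVENANCE_LEVELS)) {
          existing$provenance[i] <- incoming$provenance[j]
        }
        existing$support[i] <- max(existing$support[i], incoming$support[j])
      }
    }
  }
  added_edges <- new_edges[!hit, , drop = FALSE]
  merged <- rbind(existing, added_edges)
  out <- tripartite_network(entities, merged, warn_duplicates = FALSE)
  list(network = out,
       counts = c(added = nrow(added_edges),
                  dropped_existing = dropped_existing,
                  dropped_duplicate = dropped_duplicate))
}

#' Write a network to disk
#'
#' `edge-tsv` writes the interaction table (and, when `node_file` is given,
#' the entity table) so that [load_network()] round-trips the network.
#' `sif` writes the Cytoscape simple-interaction format, one line
#' `a <pair_type> b` per edge, with isolated nodes listed on their own lines.
#'
#' @param net a [tripartite_network()].
#' @param edge_file output path for the edge table / SIF file.
#' @param format `"edge-tsv"` or `"sif"`.
#' @param node_file optional output path for the node table (edge-tsv only).
#' @return `edge_file`, invisibly.
#' @export
write_network <- function(net, edge_file, format = c("edge-tsv", "sif"),
                          node_file = NULL) {
  stopifnot(inherits(net, "tripartite_network"))
  format <- match.arg(format)
  if (format == "edge-tsv") {
    utils::write.table(net$interactions, edge_file, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(node_file)) {
      utils::write.table(net$entities, node_file, sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  } else {
    edges <- net$interactions
    lines <- sprintf("%s %s %s", edges$a, edges$pair_type, edges$b)
    deg <- table(c(edges$a, edges$b))
    isolated <- setdiff(net$entities$id, names(deg))
    writeLines(c(lines, isolated), edge_file)
  }
  invisible(edge_file)
}

#' Induced subgraph on a node set
#'
#' @param net a [tripartite_network()].
#' @param node_ids character vector of entity ids (must all exist).
#' @return A [tripartite_network()] containing exactly the named entities and
#'   the interactions with both endpoints among them.
#' @export
induced_subgraph <- function(net, node_ids) {
  stopifnot(inherits(net, "tripartite_network"))
  node_ids <- as.character(node_ids)
  unknown <- setdiff(node_ids, net$entities$id)
  if (length(unknown)) {
    stop("unknown entity id(s): ", paste(unknown, collapse = ", "))
  }
  ents <- net$entities[net$entities$id %in% node_ids, , drop = FALSE]
  keep <- net$interactions$a %in% node_ids & net$interactions$b %in% node_ids
  tripartite_network(ents, net$interactions[keep, , drop = FALSE],
                     warn_duplicates = FALSE)
}

#' Compare two networks for structural equality
#'
#' Entities (id + kind) and canonicalized interactions (pair, pair type,
#' provenance, support) must match; label columns and row order are ignored.
#'
#' @param a,b networks.
#' @return TRUE or FALSE.
#' @export
networks_equal <- function(a, b) {
  ea <- a$entities[order(a$entities$id), c("id", "kind")]
  eb <- b$entities[order(b$entities$id), c("id", "kind")]
  rownames(ea) <- rownames(eb) <- NULL
  ia <- a$interactions[order(edge_key(a$interactions)), ]
  ib <- b$interactions[order(edge_key(b$interactions)), ]
  rownames(ia) <- rownames(ib) <- NULL
  identical(ea, eb) && identical(ia, ib)
}

# undirected igraph view of the network (used by topology statistics)
as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$interactions[, c("a", "b")],
                                directed = FALSE,
                                vertices = net$entities$id)
}
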