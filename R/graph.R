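#' Metapopulation graphs
#'
#' A metapopulation graph is a set of patches (nodes), each with a fixed
#' number of spaces that agents compete for, connected by weighted directed
#' edges representing dispersal routes.  A migrating agent picks a
#' destination with probability proportional to the weight of the outgoing
#' edge, so only weight ratios matter.
#'
#' @param nodes data frame with columns `id` (character), `capacity`
#'   (positive integer, the number of spaces in the patch) and `role`
#'   (one of `"hub"`, `"leaf"`, `"plain"`).
#' @param edges data frame with columns `src`, `dst` (node ids) and
#'   `weight` (non-negative), or `NULL` for an edgeless graph.
#'
#' @return An object of class `metapop_graph`: a list with elements
#'   `nodes` and `edges`.
#' @examples
#' g <- metapop_graph(
#'   nodes = data.frame(id = c("A", "B"), capacity = 10L, role = "plain"),
#'   edges = data.frame(src = "A", dst = "B", weight = 1)
#' )
#' @export
metapop_graph <- function(nodes, edges = NULL) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (is.null(edges) || NROW(edges) == 0) {
    edges <- data.frame(src = character(), dst = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  }
  need_n <- setdiff(c("id", "capacity", "role"), names(nodes))
  need_e <- setdiff(c("src", "dst", "weight"), names(edges))
  if (length(need_n) || length(need_e)) {
    metamp_abort(
      sprintf("graph document is missing fields: %s",
              paste(c(need_n, need_e), collapse = ", ")),
      "metamp_invalid_graph"
    )
  }
  nodes$id <- as.character(nodes$id)
  nodes$capacity <- suppressWarnings(as.integer(nodes$capacity))
  nodes$role <- as.character(nodes$role)
  edges$src <- as.character(edges$src)
  edges$dst <- as.character(edges$dst)
  edges$weight <- suppressWarnings(as.numeric(edges$weight))
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  g <- structure(
    list(nodes = nodes[, c("id", "capacity", "role")],
         edges = edges[, c("src", "dst", "weight")]),
    class = "metapop_graph"
  )
  validate_metapop_graph(g)
  g
}

#' Validate a metapopulation graph
#'
#' Checks node and edge invariants (unique ids, positive capacities,
#' known roles, existing endpoints, no self-edges, no duplicate ordered
#' edges, non-negative weights) and raises a `metamp_invalid_graph`
#' error listing every offending record.
#'
#' @param graph a [metapop_graph()] object.
#' @return `TRUE`, invisibly, if the graph is valid.
#' @export
validate_metapop_graph <- function(graph) {
  nodes <- graph$nodes
  edges <- graph$edges
  bad <- character()
  if (nrow(nodes) < 1) bad <- c(bad, "graph has no nodes")
  dup <- unique(nodes$id[duplicated(nodes$id)])
  if (length(dup)) bad <- c(bad, sprintf("duplicate node id '%s'", dup))
  nz <- which(is.na(nodes$capacity) | nodes$capacity < 1)
  for (i in nz) bad <- c(bad, sprintf("node '%s' has capacity %s (must be >= 1)",
                                      nodes$id[i], nodes$capacity[i]))
  nr <- which(!nodes$role %in% c("hub", "leaf", "plain"))
  for (i in nr) bad <- c(bad, sprintf("node '%s' has unknown role '%s'",
                                      nodes$id[i], nodes$role[i]))
  if (nrow(edges)) {
    miss <- which(!(edges$src %in% nodes$id) | !(edges$dst %in% nodes$id))
    for (i in miss) bad <- c(bad, sprintf("edge %s->%s references an unknown node",
                                          edges$src[i], edges$dst[i]))
    self <- which(edges$src == edges$dst)
    for (i in self) bad <- c(bad, sprintf("self-edge at node '%s'", edges$src[i]))
    neg <- which(is.na(edges$weight) | edges$weight < 0 | !is.finite(edges$weight))
    for (i in neg) bad <- c(bad, sprintf("edge %s->%s has invalid weight %s",
                                         edges$src[i], edges$dst[i], edges$weight[i]))
    key <- paste(edges$src, edges$dst, sep = "->")
    dupe <- unique(key[duplicated(key)])
    if (length(dupe)) bad <- c(bad, sprintf("duplicate edge %s", dupe))
  }
  if (length(bad)) {
    metamp_abort(paste0("invalid metapopulation graph:\n  - ",
                        paste(bad, collapse = "\n  - ")),
                 "metamp_invalid_graph")
  }
  invisible(TRUE)
}

#' Build a well-mixed (complete) metapopulation
#'
#' Every patch exchanges migrants with every other patch: a complete
#' directed graph with all edge weights equal to 1 and all roles
#' `"plain"`.  This is the standard control topology against which star
#' networks are compared.
#'
#' @param n_nodes number of patches (>= 2).
#' @param capacity spaces per patch (>= 1).
#' @return a [metapop_graph()] with `n_nodes * (n_nodes - 1)` edges.
#' @examples
#' build_well_mixed(4, 1600)
#' @export
build_well_mixed <- function(n_nodes, capacity) {
  if (length(n_nodes) != 1 || is.na(n_nodes) || n_nodes < 2) {
    metamp_abort("a well-mixed graph needs at least 2 nodes",
                 "metamp_invalid_graph")
  }
  if (length(capacity) != 1 || is.na(capacity) || capacity < 1) {
    metamp_abort("capacity must be a positive integer",
                 "metamp_invalid_parameter")
  }
  ids <- paste0("P", seq_len(n_nodes))
  pairs <- expand.grid(src = ids, dst = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$src != pairs$dst, ]
  metapop_graph(
    nodes = data.frame(id = ids, capacity = as.integer(capacity),
                       role = "plain", stringsAsFactors = FALSE),
    edges = data.frame(src = pairs$src, dst = pairs$dst, weight = 1,
                       stringsAsFactors = FALSE)
  )
}

#' Build a star metapopulation
#'
#' One central hub and `n_leaves` peripheral leaves; leaves are connected
#' only through the hub (no leaf-leaf edges).  Dispersal asymmetry is
#' encoded by the two direction weights: `w_leaf_to_hub > w_hub_to_leaf`
#' gives net inward (IN>OUT) migration, the reverse gives net outward
#' (OUT>IN) migration, and equal weights give a balanced (IN=OUT)
#' bidirectional star.  Setting `w_leaf_to_hub = 0` yields the rooted
#' star in which the hub supplies migrants to the leaves but receives
#' none.  Zero-weight directions are omitted from the edge list, so
#' agents in a node with no outgoing edge never migrate.
#'
#' In four-node configurations the hub is the node labelled `"P2"`, with
#' leaves `"P1"`, `"P3"`, `"P4"`; the mutant is conventionally introduced
#' in leaf `"P3"` (see [seed_state()]).
#'
#' @param n_leaves number of leaves (>= 1).
#' @param capacity spaces per patch (>= 1), identical for hub and leaves.
#' @param w_leaf_to_hub weight of each leaf->hub edge (>= 0).
#' @param w_hub_to_leaf weight of each hub->leaf edge (>= 0).
#' @return a [metapop_graph()] with `n_leaves + 1` nodes.
#' @examples
#' build_star(3, 1600)            # balanced bidirectional star
#' build_star(3, 1600, 2, 1)      # inward-weighted (IN>OUT)
#' build_star(3, 1600, 0, 1)      # rooted star (hub->leaf only)
#' @export
build_star <- function(n_leaves, capacity, w_leaf_to_hub = 1, w_hub_to_leaf = 1) {
  if (length(n_leaves) != 1 || is.na(n_leaves) || n_leaves < 1) {
    metamp_abort("a star needs at least one leaf", "metamp_invalid_parameter")
  }
  if (length(capacity) != 1 || is.na(capacity) || capacity < 1) {
    metamp_abort("capacity must be a positive integer", "metamp_invalid_parameter")
  }
  w <- c(w_leaf_to_hub, w_hub_to_leaf)
  if (any(is.na(w)) || any(!is.finite(w)) || any(w < 0)) {
    metamp_abort("edge weights must be finite and non-negative",
                 "metamp_invalid_parameter")
  }
  if (all(w == 0)) {
    metamp_abort("at least one direction must have positive weight",
                 "metamp_invalid_parameter")
  }
  n <- n_leaves + 1
  ids <- paste0("P", seq_len(n))
  hub <- "P2"
  leaves <- setdiff(ids, hub)
  nodes <- data.frame(
    id = ids, capacity = as.integer(capacity),
    role = ifelse(ids == hub, "hub", "leaf"),
    stringsAsFactors = FALSE
  )
  edges <- data.frame(src = character(), dst = character(), weight = numeric(),
                      stringsAsFactors = FALSE)
  if (w_leaf_to_hub > 0) {
    edges <- rbind(edges, data.frame(src = leaves, dst = hub,
                                     weight = w_leaf_to_hub,
                                     stringsAsFactors = FALSE))
  }
  if (w_hub_to_leaf > 0) {
    edges <- rbind(edges, data.frame(src = hub, dst = leaves,
                                     weight = w_hub_to_leaf,
                                     stringsAsFactors = FALSE))
  }
  metapop_graph(nodes = nodes, edges = edges)
}

#' Outgoing dispersal distribution of a node
#'
#' Probability that a migrant leaving `node_id` lands in each neighbour:
#' edge weight divided by the sum of outgoing weights.  Returns an empty
#' vector when the node has no outgoing edge with positive weight;
#' migrants from such a node never move.
#'
#' @param graph a [metapop_graph()].
#' @param node_id a node id present in the graph.
#' @return a named numeric vector of probabilities summing to 1 (or
#'   empty).
#' @export
outgoing_distribution <- function(graph, node_id) {
  if (!node_id %in% graph$nodes$id) {
    metamp_abort(sprintf("node '%s' is not in the graph", node_id),
                 "metamp_invalid_parameter")
  }
  e <- graph$edges[graph$edges$src == node_id & graph$edges$weight > 0, ]
  if (nrow(e) == 0) return(stats::setNames(numeric(0), character(0)))
  stats::setNames(e$weight / sum(e$weight), e$dst)
}

#' Save or load a metapopulation graph as JSON
#'
#' The document is `{"nodes": [{"id","capacity","role"}], "edges":
#' [{"src","dst","weight"}]}`, UTF-8.  `load_graph()` validates the
#' document and raises `metamp_invalid_graph` listing every offending
#' record (duplicate ids, dangling endpoints, negative weights, ...).
#'
#' @param graph a [metapop_graph()].
#' @param path file path.
#' @return `save_graph()` returns `path` invisibly; `load_graph()`
#'   returns a [metapop_graph()].
#' @export
save_graph <- function(graph, path) {
  txt <- jsonlite::toJSON(
    list(nodes = graph$nodes, edges = graph$edges),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname save_graph
#' @export
load_graph <- function(path) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
    error = function(e) metamp_abort(
      sprintf("cannot parse graph document '%s': %s", path, conditionMessage(e)),
      "metamp_invalid_graph")
  )
  if (!is.list(doc) || is.null(doc$nodes)) {
    metamp_abort("graph document has no 'nodes' field", "metamp_invalid_graph")
  }
  edges <- doc$edges
  if (is.null(edges) || NROW(edges) == 0) edges <- NULL
  metapop_graph(nodes = doc$nodes, edges = edges)
}

#' @export
print.metapop_graph <- function(x, ...) {
  roles <- table(x$nodes$role)
  cat(sprintf("<metapop_graph> %d nodes (%s), %d directed edges\n",
              nrow(x$nodes),
              paste(sprintf("%s: %d", names(roles), roles), collapse = ", "),
              nrow(x$edges)))
  cat(sprintf("  capacities: %s\n",
              paste(unique(x$nodes$capacity), collapse = ", ")))
  invisible(x)
}

# Id of the hub node, or NA if none is designated.
hub_node <- function(graph) {
  h <- graph$nodes$id[graph$nodes$role == "hub"]
  if (length(h)) h[1] else NA_character_
}

# Precomputed per-node dispersal tables used by the migration phase.
.graph_runtime <- function(graph) {
  ids <- graph$nodes$id
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    e <- graph$edges[graph$edges$src == ids[i] & graph$edges$weight > 0, ]
    if (nrow(e)) {
      out[[i]] <- list(dst = match(e$dst, ids), prob = e$weight / sum(e$weight))
    }
  }
  list(ids = ids,
       caps = stats::setNames(as.integer(graph$nodes$capacity), ids),
       out = out,
       has_out = which(!vapply(out, is.null, logical(1))))
}
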