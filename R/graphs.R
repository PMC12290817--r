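#' Community graphs over the 15 recurring objects
#'
#' Presentation sequences are quasi-random walks on a graph whose nodes are the
#' 15 recurring objects. Two canonical graphs are used: a *modular* graph with
#' three communities of five objects each (the "structured" condition), and the
#' *complete* graph on 15 nodes (the "unstructured" condition, no sequential
#' dependencies).
#'
#' In the modular graph every node has degree 4. Each community is a complete
#' graph on its five members minus the edge between its two *boundary*
#' ("linking") objects; each boundary object instead carries one edge to the
#' boundary object of a neighbouring community, and the three between-community
#' edges form a ring over the communities. The three other members of each
#' community are *internal* objects.
#'
#' @return An object of class `community_graph`: a list with elements
#'   `node_ids` (integer 1..15), `adjacency` (symmetric logical 15 x 15, zero
#'   diagonal), `community` (integer vector of community labels 1..3),
#'   `role` (character, `"internal"` or `"boundary"`), `boundary_partner`
#'   (integer; for boundary nodes, the community their between-community edge
#'   reaches, `NA` for internal nodes) and `type` (`"modular"` or
#'   `"complete"`).
#' @examples
#' g <- build_modular_graph()
#' all(rowSums(g$adjacency) == 4)
#' @export
build_modular_graph <- function() {
  n <- 15L
  adj <- matrix(FALSE, n, n)
  communities <- list(1:5, 6:10, 11:15)
  # boundary pairs per community; each community is K5 minus the boundary edge
  boundary <- list(c(1L, 5L), c(6L, 10L), c(11L, 15L))
  for (members in communities) {
    adj[members, members] <- TRUE
  }
  diag(adj) <- FALSE
  for (b in boundary) adj[b[1], b[2]] <- adj[b[2], b[1]] <- FALSE
  # between-community edges: ring 1 -> 2 -> 3 -> 1 through boundary nodes
  between <- rbind(c(5L, 6L), c(10L, 11L), c(15L, 1L))
  for (r in seq_len(nrow(between))) {
    adj[between[r, 1], between[r, 2]] <- adj[between[r, 2], between[r, 1]] <- TRUE
  }
  community <- rep(1:3, each = 5L)
  role <- rep("internal", n)
  role[unlist(boundary)] <- "boundary"
  partner <- rep(NA_integer_, n)
  for (r in seq_len(nrow(between))) {
    partner[between[r, 1]] <- community[between[r, 2]]
    partner[between[r, 2]] <- community[between[r, 1]]
  }
  structure(
    list(
      node_ids = seq_len(n), adjacency = adj, community = community,
      role = role, boundary_partner = partner, type = "modular"
    ),
    class = "community_graph"
  )
}

#' @rdname build_modular_graph
#' @details `build_complete_graph()` returns the complete graph on 15 nodes.
#'   It carries the same 5/5/5 partition as the modular graph as a
#'   *counterfactual* community labeling, used only for control analyses: in
#'   the unstructured condition no genuine community structure exists and the
#'   labels should yield null results.
#' @export
build_complete_graph <- function() {
  n <- 15L
  adj <- matrix(TRUE, n, n)
  diag(adj) <- FALSE
  structure(
    list(
      node_ids = seq_len(n), adjacency = adj, community = rep(1:3, each = 5L),
      role = rep("internal", n), boundary_partner = rep(NA_integer_, n),
      type = "complete"
    ),
    class = "community_graph"
  )
}

#' @export
print.community_graph <- function(x, ...) {
  cat(sprintf(
    "community_graph (%s): %d nodes, %d edges, communities of size %s\n",
    x$type, length(x$node_ids), sum(x$adjacency) / 2,
    paste(table(x$community), collapse = "/")
  ))
  invisible(x)
}

stopifnot_graph <- function(graph) {
  if (!inherits(graph, "community_graph")) {
    stop("`graph` must be a community_graph", call. = FALSE)
  }
  adj <- graph$adjacency
  if (!isTRUE(all(adj == t(adj))) || any(diag(adj))) {
    stop("adjacency must be symmetric with zero diagonal", call. = FALSE)
  }
  invisible(graph)
}

#' Classify all object pairs by community membership and adjacency
#'
#' Every unordered pair of distinct objects falls in exactly one of four
#' classes: same community and adjacent (SA), different community and adjacent
#' (DA), same community and non-adjacent (SN), or different community and
#' non-adjacent (DN). On the modular graph the 105 pairs split 27/3/3/72; on
#' the complete graph all pairs are adjacent.
#'
#' @param graph A [community_graph][build_modular_graph].
#' @return A data frame with one row per unordered pair: columns `i`, `j`
#'   (`i < j`) and `type` (factor with levels SA, DA, SN, DN).
#' @examples
#' table(classify_pairs(build_modular_graph())$type)
#' @export
classify_pairs <- function(graph) {
  stopifnot_graph(graph)
  idx <- which(upper.tri(graph$adjacency), arr.ind = TRUE)
  i <- idx[, 1]
  j <- idx[, 2]
  same <- graph$community[i] == graph$community[j]
  adj <- graph$adjacency[idx]
  type <- ifelse(same & adj, "SA",
    ifelse(!same & adj, "DA", ifelse(same & !adj, "SN", "DN"))
  )
  data.frame(
    i = as.integer(i), j = as.integer(j),
    type = factor(type, levels = c("SA", "DA", "SN", "DN"))
  )
}

# (i, j) -> pair-type lookup used by the community statistics; returns a
# 15 x 15 character matrix with NA on the diagonal.
pair_type_matrix <- function(pair_types, n = 15L) {
  m <- matrix(NA_character_, n, n)
  m[cbind(pair_types$i, pair_types$j)] <- as.character(pair_types$type)
  m[cbind(pair_types$j, pair_types$i)] <- as.character(pair_types$type)
  m
}
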