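#' Jaccard similarity between two feature sets
#'
#' `|U intersect V| / |U union V|`, the similarity used for chemical
#' fingerprints (where it is the 2D Tanimoto similarity on MACCS-style
#' on-bit sets), protein-target sets and indication sets. Two empty sets
#' have similarity 0 by convention.
#'
#' @param u,v vectors treated as sets (duplicates ignored).
#' @return a number in \[0, 1\].
#' @export
jaccard <- function(u, v) {
  u <- unique(u)
  v <- unique(v)
  n_union <- length(union(u, v))
  if (n_union == 0L) return(0)
  length(intersect(u, v)) / n_union
}

#' Pairwise Jaccard similarity graph over a feature map
#'
#' Builds a similarity graph whose adjacency entry (u, v) is the Jaccard
#' similarity between the feature sets of entities u and v. The diagonal is
#' zero (no self-edges). Entities with empty feature sets get similarity 0 to
#' everything and trigger a warning.
#'
#' @param features named list mapping each entity to a vector of discrete
#'   feature tokens (target ids, indication terms, fingerprint bit
#'   positions).
#' @param entity_ids ordered entity universe; defaults to `names(features)`.
#'   Entities without an entry are treated as having an empty set.
#' @param name graph label.
#' @return a [similarity_graph()].
#' @export
pairwise_jaccard <- function(features, entity_ids = names(features),
                             name = "jaccard") {
  if (length(entity_ids) < 2L) stop("need at least two entities")
  sets <- lapply(entity_ids, function(e) unique(features[[e]]))
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warning(sum(empty), " entity(ies) with empty feature sets; ",
            "their similarities are 0")
  }
  k <- length(entity_ids)
  a <- matrix(0, k, k)
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      a[i, j] <- a[j, i] <- jaccard(sets[[i]], sets[[j]])
    }
  }
  similarity_graph(entity_ids, adjacency = a, name = name)
}

#' Construct a code hierarchy with entity annotations
#'
#' Represents a coding terminology (ATC-like for drugs, MedDRA-like for side
#' effects) as a child-to-parent edge list plus an annotation map from
#' entities to their leaf codes. A node may have several parents
#' (multi-axial terminologies keep every parent); cycles are rejected.
#' Shortest-path queries treat the edges as undirected.
#'
#' @param parent_edges data frame with columns `child`, `parent` (extra
#'   columns ignored).
#' @param annotations named list mapping each entity to a non-empty character
#'   vector of codes present in the hierarchy.
#' @return an object of class `"gsem_hierarchy"`: list with `nodes`,
#'   `parent_edges`, `annotations`, `levels` (depth per node, roots at 0)
#'   and the internal igraph.
#' @export
hierarchy <- function(parent_edges, annotations) {
  parent_edges <- as.data.frame(parent_edges)
  names(parent_edges)[1:2] <- c("child", "parent")
  child <- as.character(parent_edges$child)
  parent <- as.character(parent_edges$parent)
  nodes <- unique(c(child, parent))
  dg <- igraph::graph_from_edgelist(cbind(child, parent), directed = TRUE)
  if (!igraph::is_dag(dg)) stop("hierarchy contains a cycle")
  ug <- igraph::as_undirected(dg, mode = "collapse")
  roots <- setdiff(nodes, child)
  depth <- igraph::distances(dg, v = igraph::V(dg), to = roots,
                             mode = "out")
  levels <- apply(depth, 1L, min)
  if (is.null(names(annotations)) || !length(annotations)) {
    stop("annotations must be a non-empty named list")
  }
  ann <- lapply(annotations, function(a) unique(as.character(a)))
  bad <- vapply(ann, function(a) length(a) == 0L || !all(a %in% nodes),
                logical(1))
  if (any(bad)) {
    stop("entities with missing or unknown annotation codes: ",
         paste(names(ann)[bad], collapse = ", "))
  }
  structure(list(nodes = nodes,
                 parent_edges = data.frame(child = child, parent = parent,
                                           stringsAsFactors = FALSE),
                 annotations = ann, levels = levels, graph = ug),
            class = "gsem_hierarchy")
}

#' @export
print.gsem_hierarchy <- function(x, ...) {
  cat(sprintf("Code hierarchy: %d nodes, %d edges, depth %d, %d annotated entities\n",
              length(x$nodes), nrow(x$parent_edges), max(x$levels),
              length(x$annotations)))
  invisible(x)
}

#' Shortest path between two annotation sets
#'
#' Minimum over all cross-pairs of codes of the undirected shortest-path
#' edge count in the hierarchy. Sets that share a code are at distance 0.
#' This is the set-to-set distance underlying the taxonomy similarity; with
#' single codes in a 4-level tree the smallest distance between distinct
#' drugs is 2 (siblings) and the largest is 8 (different top-level
#' branches).
#'
#' @param codes_u,codes_v character vectors of codes in the hierarchy.
#' @param h a [hierarchy()].
#' @return a non-negative number of edges (can be `Inf` if disconnected).
#' @export
set_shortest_path <- function(codes_u, codes_v, h) {
  stopifnot(inherits(h, "gsem_hierarchy"))
  codes_u <- unique(as.character(codes_u))
  codes_v <- unique(as.character(codes_v))
  missing <- setdiff(c(codes_u, codes_v), h$nodes)
  if (length(missing)) {
    stop("codes absent from hierarchy: ", paste(missing, collapse = ", "))
  }
  if (length(intersect(codes_u, codes_v))) return(0)
  d <- igraph::distances(h$graph, v = codes_u, to = codes_v)
  min(d)
}

#' Taxonomy similarity graph from a hierarchy
#'
#' For every pair of annotated entities computes the set shortest path SP in
#' the hierarchy and converts it to a similarity
#' `1 - SP(u, v) / max_(i,j) SP(i, j)`, the maximum running over all
#' annotated entity pairs (an empirical normalizer). Values lie in \[0, 1\];
#' a pair sharing a code has similarity 1, the most distant pair similarity
#' 0. The diagonal is zeroed.
#'
#' @param h a [hierarchy()] with at least two annotated entities.
#' @param name graph label.
#' @return a [similarity_graph()] over the annotated entities.
#' @export
taxonomy_similarity <- function(h, name = "taxonomy") {
  stopifnot(inherits(h, "gsem_hierarchy"))
  entities <- names(h$annotations)
  k <- length(entities)
  if (k < 2L) stop("need at least two annotated entities")
  codes <- unique(unlist(h$annotations))
  dmat <- igraph::distances(h$graph, v = codes, to = codes)
  sp <- matrix(0, k, k)
  for (i in seq_len(k - 1L)) {
    ci <- h$annotations[[i]]
    for (j in seq.int(i + 1L, k)) {
      cj <- h$annotations[[j]]
      sp[i, j] <- sp[j, i] <-
        if (length(intersect(ci, cj))) 0 else min(dmat[ci, cj])
    }
  }
  normalizer <- max(sp)
  if (!is.finite(normalizer)) stop("hierarchy is disconnected across entities")
  if (normalizer == 0) {
    stop("degenerate hierarchy: all entities share a code; ",
         "a richer hierarchy is needed to normalize similarities")
  }
  a <- 1 - sp / normalizer
  diag(a) <- 0
  similarity_graph(entities, adjacency = a, name = name)
}
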