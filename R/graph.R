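#' Similarity graphs over one entity set
#'
#' A similarity graph holds a symmetric, non-negative, zero-diagonal
#' adjacency matrix A over a fixed ordered set of entities, together with its
#' degree matrix D (diagonal of row sums) and combinatorial Laplacian
#' L = D - A. The Laplacian drives the smoothness penalty Tr(S L S') that
#' pulls the self-representation coefficients of graph-adjacent entities
#' together.
#'
#' @param entity_ids character vector of unique entity identifiers.
#' @param edges optional data frame (or 3-column matrix) of undirected
#'   weighted edges: columns `from`, `to`, `weight`. When both directions of
#'   a pair are present the larger weight wins. Self-edges are dropped with a
#'   warning (a self-edge contributes nothing to the Laplacian penalty).
#' @param adjacency optional pre-built k x k adjacency matrix (alternative to
#'   `edges`); must be symmetric and non-negative, diagonal is zeroed.
#' @param name short label for the graph (e.g. `"chem"`, `"meddra"`).
#' @return an object of class `"gsem_graph"`: a list with `entity_ids`,
#'   `adjacency`, `degree` (vector of row sums), `laplacian` and `name`.
#' @examples
#' g <- similarity_graph(c("a", "b"), data.frame(from = "a", to = "b",
#'                                               weight = 1))
#' g$laplacian
#' @export
similarity_graph <- function(entity_ids, edges = NULL, adjacency = NULL,
                             name = "graph") {
  entity_ids <- as.character(entity_ids)
  if (anyDuplicated(entity_ids)) stop("duplicate entity identifiers")
  k <- length(entity_ids)
  if (is.null(adjacency)) {
    adjacency <- matrix(0, k, k, dimnames = list(entity_ids, entity_ids))
    if (!is.null(edges) && NROW(edges) > 0L) {
      edges <- as.data.frame(edges)
      names(edges)[1:3] <- c("from", "to", "weight")
      from <- as.character(edges$from)
      to <- as.character(edges$to)
      w <- as.numeric(edges$weight)
      bad <- !(from %in% entity_ids) | !(to %in% entity_ids)
      if (any(bad)) {
        stop("unknown edge endpoint(s): ",
             paste(unique(c(from[bad], to[bad])), collapse = ", "))
      }
      if (any(!is.finite(w)) || any(w < 0)) {
        stop("edge weights must be finite and non-negative")
      }
      self <- from == to
      if (any(self)) {
        warning(sum(self), " self-edge(s) dropped")
        from <- from[!self]; to <- to[!self]; w <- w[!self]
      }
      i <- match(from, entity_ids)
      j <- match(to, entity_ids)
      for (e in seq_along(i)) {
        adjacency[i[e], j[e]] <- max(adjacency[i[e], j[e]], w[e])
      }
      adjacency <- pmax(adjacency, t(adjacency))
    }
  } else {
    adjacency <- as.matrix(adjacency)
    if (nrow(adjacency) != k || ncol(adjacency) != k) {
      stop("adjacency dimension does not match entity_ids")
    }
    if (max(abs(adjacency - t(adjacency))) > 1e-10) {
      stop("adjacency must be symmetric (tolerance 1e-10)")
    }
    if (any(adjacency < 0)) stop("adjacency must be non-negative")
    adjacency <- (adjacency + t(adjacency)) / 2
    diag(adjacency) <- 0
    dimnames(adjacency) <- list(entity_ids, entity_ids)
  }
  degree <- rowSums(adjacency)
  laplacian <- diag(degree, k) - adjacency
  dimnames(laplacian) <- list(entity_ids, entity_ids)
  structure(list(entity_ids = entity_ids, adjacency = adjacency,
                 degree = degree, laplacian = laplacian, name = name),
            class = "gsem_graph")
}

#' @export
print.gsem_graph <- function(x, ...) {
  cat(sprintf("Similarity graph '%s': %d entities, %d edges, total weight %.4g\n",
              x$name, length(x$entity_ids),
              sum(x$adjacency > 0) / 2, sum(x$adjacency) / 2))
  invisible(x)
}

#' Graph-Laplacian smoothness of a coefficient matrix
#'
#' Computes the smoothness penalty of a square coefficient matrix S with
#' respect to a similarity graph: `Tr(S L S')` when the columns of S are the
#' smoothed vectors (used for the side-effect matrix W), `Tr(S' L S)` when
#' the rows are (used for the drug matrix H). Both are half the
#' adjacency-weighted sum of squared differences between the smoothed
#' vectors, hence non-negative for a valid Laplacian.
#'
#' @param s square numeric matrix.
#' @param graph a [similarity_graph()] over the matching entity set.
#' @param mode `"columns"` or `"rows"`: which fibers of `s` are smoothed.
#' @return a single non-negative number.
#' @export
smoothness <- function(s, graph, mode = c("columns", "rows")) {
  mode <- match.arg(mode)
  s <- as.matrix(s)
  k <- length(graph$entity_ids)
  if (nrow(s) != k || ncol(s) != k) {
    stop("coefficient matrix dimension (", nrow(s), "x", ncol(s),
         ") does not match graph dimension ", k)
  }
  l <- graph$laplacian
  val <- if (mode == "columns") sum((s %*% l) * s) else sum((l %*% s) * s)
  # Tr(S L S') = sum((S %*% L) * S); Tr(S' L S) = sum((L %*% S) * S)
  val
}
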