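#' Specification of a synthetic benchmark instance
#'
#' Describes a block-structured (union-of-subspaces) drug/side-effect world:
#' drugs and side effects fall into clusters, a compatibility map decides
#' which drug clusters express which side-effect clusters, and associations
#' appear with probability `density_in` inside compatible blocks and
#' `density_out` elsewhere. Cluster-consistent similarity graphs and a
#' balanced toy hierarchy complete the side information. This is the
#' structure self-expressive models assume, so a correct fit must recover
#' associations masked out of it.
#'
#' @param n_drugs,n_side_effects entity counts (defaults 60 and 50).
#' @param n_drug_clusters,n_se_clusters cluster counts (default 4 each).
#' @param density_in,density_out within-block and background association
#'   probabilities (defaults 0.6 and 0.02; `density_in > density_out`).
#' @param graph_p_in,graph_p_out edge probabilities of the cluster graphs
#'   within and across clusters (defaults 0.8 and 0.05).
#' @param hierarchy_branching,hierarchy_depth toy taxonomy shape (defaults 3
#'   and 4; depth 4 mirrors the 4-level ATC hierarchy).
#' @param seed master seed (default 7).
#' @return a list of class `"gsem_synth_spec"`.
#' @export
synthetic_spec <- function(n_drugs = 60L, n_side_effects = 50L,
                           n_drug_clusters = 4L, n_se_clusters = 4L,
                           density_in = 0.6, density_out = 0.02,
                           graph_p_in = 0.8, graph_p_out = 0.05,
                           hierarchy_branching = 3L, hierarchy_depth = 4L,
                           seed = 7L) {
  stopifnot(n_drugs >= 1, n_side_effects >= 1,
            n_drug_clusters >= 1, n_drug_clusters <= n_drugs,
            n_se_clusters >= 1, n_se_clusters <= n_side_effects,
            density_in >= 0, density_in <= 1,
            density_out >= 0, density_out <= 1,
            density_in > density_out,
            graph_p_in >= 0, graph_p_in <= 1,
            graph_p_out >= 0, graph_p_out <= 1,
            hierarchy_branching >= 2, hierarchy_depth >= 2)
  structure(list(n_drugs = as.integer(n_drugs),
                 n_side_effects = as.integer(n_side_effects),
                 n_drug_clusters = as.integer(n_drug_clusters),
                 n_se_clusters = as.integer(n_se_clusters),
                 density_in = density_in, density_out = density_out,
                 graph_p_in = graph_p_in, graph_p_out = graph_p_out,
                 hierarchy_branching = as.integer(hierarchy_branching),
                 hierarchy_depth = as.integer(hierarchy_depth),
                 seed = as.integer(seed)),
            class = "gsem_synth_spec")
}

#' Generate a block-structured association matrix
#'
#' Assigns drugs and side effects to clusters uniformly, draws a random
#' compatibility map pairing each drug cluster with a side-effect cluster,
#' and samples `x_ij ~ Bernoulli(density_in)` inside compatible blocks,
#' `Bernoulli(density_out)` outside. Every drug is guaranteed at least 5
#' positives by resampling deficient rows (mirroring the study-inclusion
#' rule of keeping only drugs with at least five clinical-trial side
#' effects); rows still deficient after 100 redraws raise an error.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `x` (an [association_matrix()]), `drug_clusters` and
#'   `se_clusters` (integer label vectors named by entity).
#' @export
make_associations <- function(spec) {
  stopifnot(inherits(spec, "gsem_synth_spec"))
  n <- spec$n_drugs
  m <- spec$n_side_effects
  if (m < 5L) stop("cannot guarantee 5 positives per drug with m < 5")
  with_seed(spec$seed, {
    drug_clusters <- sample.int(spec$n_drug_clusters, n, replace = TRUE)
    se_clusters <- sample.int(spec$n_se_clusters, m, replace = TRUE)
    # each drug cluster expresses one randomly chosen side-effect cluster
    compat <- if (spec$n_drug_clusters <= spec$n_se_clusters) {
      sample.int(spec$n_se_clusters, spec$n_drug_clusters)
    } else {
      sample.int(spec$n_se_clusters, spec$n_drug_clusters, replace = TRUE)
    }
    p <- matrix(spec$density_out, n, m)
    in_block <- outer(compat[drug_clusters], se_clusters, "==")
    p[in_block] <- spec$density_in
    x <- matrix(rbinom(n * m, 1L, p), n, m)
    for (i in seq_len(n)) {
      tries <- 0L
      while (sum(x[i, ]) < 5L) {
        tries <- tries + 1L
        if (tries > 100L) {
          stop("row ", i, " cannot reach 5 positives; ",
               "increase densities or side-effect count")
        }
        x[i, ] <- rbinom(m, 1L, p[i, ])
      }
    }
    drug_ids <- sprintf("drug%03d", seq_len(n))
    se_ids <- sprintf("se%03d", seq_len(m))
    list(x = association_matrix(x, drug_ids, se_ids),
         drug_clusters = stats::setNames(drug_clusters, drug_ids),
         se_clusters = stats::setNames(se_clusters, se_ids))
  })
}

#' Cluster-consistent random similarity graph
#'
#' Unit-weight edges appear with probability `p_in` between entities of the
#' same cluster and `p_out` across clusters (a planted-partition graph).
#'
#' @param labels integer cluster labels, named by entity identifier.
#' @param p_in,p_out edge probabilities.
#' @param seed integer seed.
#' @param name graph label.
#' @return a [similarity_graph()].
#' @export
make_cluster_graph <- function(labels, p_in, p_out, seed = 1L,
                               name = "cluster") {
  k <- length(labels)
  if (k < 2L) stop("need at least two entities")
  ids <- names(labels)
  if (is.null(ids)) ids <- paste0("e", seq_len(k))
  with_seed(seed, {
    a <- matrix(0, k, k)
    for (i in seq_len(k - 1L)) {
      for (j in seq.int(i + 1L, k)) {
        pr <- if (labels[i] == labels[j]) p_in else p_out
        a[i, j] <- a[j, i] <- rbinom(1L, 1L, pr)
      }
    }
    similarity_graph(ids, adjacency = a, name = name)
  })
}

#' Balanced toy code hierarchy with random entity annotations
#'
#' Builds a balanced tree of the given branching factor and depth (depth 4
#' emulating the 4-level ATC structure, where leaf-to-leaf distances run
#' from 2 for siblings to `2 * depth` across top-level branches) and
#' annotates each entity with 1 or 2 random leaves.
#'
#' @param branching children per internal node (>= 2).
#' @param depth number of levels below the root (>= 2).
#' @param entities character vector of entity identifiers to annotate.
#' @param seed integer seed.
#' @return a [hierarchy()].
#' @export
make_toy_hierarchy <- function(branching, depth, entities, seed = 1L) {
  stopifnot(branching >= 2, depth >= 2, length(entities) >= 1)
  edges <- list()
  level_nodes <- "root"
  for (lev in seq_len(depth)) {
    children <- unlist(lapply(level_nodes, function(p) {
      paste0(p, ".", seq_len(branching))
    }))
    parents <- rep(level_nodes, each = branching)
    edges[[lev]] <- data.frame(child = children, parent = parents,
                               stringsAsFactors = FALSE)
    level_nodes <- children
  }
  leaves <- level_nodes
  with_seed(seed, {
    ann <- lapply(seq_along(entities), function(i) {
      sample(leaves, sample(1:2, 1L))
    })
    names(ann) <- entities
    hierarchy(do.call(rbind, edges), ann)
  })
}

#' Mask a fraction of known associations for a recovery experiment
#'
#' Flips `floor(fraction * P)` randomly chosen ones of the matrix to zero
#' and returns them as recovery targets. A draw that would strip some row of
#' all its positives is rejected and redrawn (up to 100 times).
#'
#' @param x binary association matrix.
#' @param fraction fraction of positives to mask, in (0, 1).
#' @param seed integer seed.
#' @return list with `x_masked` and `held_out` (two-column index matrix).
#' @export
plant_holdout <- function(x, fraction, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  pos <- which(x == 1)
  n_mask <- floor(fraction * length(pos))
  if (n_mask < 1L) {
    return(list(x_masked = x,
                held_out = matrix(integer(0), 0L, 2L,
                                  dimnames = list(NULL, c("row", "col")))))
  }
  with_seed(seed, {
    for (try in seq_len(100L)) {
      idx <- sample(pos, n_mask)
      x_masked <- x
      x_masked[idx] <- 0
      if (all(rowSums(x_masked) > 0)) {
        held_out <- cbind(row = ((idx - 1L) %% nrow(x)) + 1L,
                          col = ((idx - 1L) %/% nrow(x)) + 1L)
        return(list(x_masked = x_masked, held_out = held_out))
      }
    }
    stop("could not mask ", n_mask,
         " associations without emptying a drug row")
  })
}
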