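# Independent oracles: naive scalar-loop or enumeration implementations used
# only to cross-check the package's vectorized code paths.

# objective by explicit scalar loops; the smoothness term is computed from
# the weighted sum of squared coefficient-vector differences (half of it,
# the trace identity), never via the Laplacian
oracle_objective <- function(x, s, graphs = list(), weights = numeric(0),
                             l2 = 0, l1 = 0, gamma = 0, mode = "W") {
  n <- nrow(x); m <- ncol(x); k <- nrow(s)
  recon <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      pred <- 0
      if (mode == "W") {
        for (v in seq_len(m)) pred <- pred + x[i, v] * s[v, j]
      } else {
        for (u in seq_len(n)) pred <- pred + s[i, u] * x[u, j]
      }
      recon <- recon + (x[i, j] - pred)^2
    }
  }
  val <- recon / 2 + l2 / 2 * sum(s^2) + l1 * sum(abs(s)) +
    gamma * sum(diag(s))
  for (gi in seq_along(graphs)) {
    a <- graphs[[gi]]$adjacency
    sm <- 0
    for (p in seq_len(k)) {
      for (q in seq_len(k)) {
        d2 <- if (mode == "W") sum((s[, p] - s[, q])^2)
              else sum((s[p, ] - s[q, ])^2)
        sm <- sm + a[p, q] * d2
      }
    }
    val <- val + weights[gi] / 2 * (sm / 2)
  }
  val
}

# long-run projected gradient descent on the same convex objective,
# a different algorithm from the multiplicative rule under test
oracle_projected_gradient <- function(x, graphs = list(),
                                      weights = numeric(0), l2 = 0, l1 = 0,
                                      gamma = 0, mode = "W", iters = 3e4,
                                      seed = 1) {
  k <- if (mode == "W") ncol(x) else nrow(x)
  set.seed(seed)
  s <- matrix(runif(k * k, 0, 0.01), k, k)
  cmat <- if (mode == "W") crossprod(x) else tcrossprod(x)
  lip <- norm(cmat, "2") + l2
  for (gi in seq_along(graphs)) {
    lip <- lip + weights[gi] * norm(graphs[[gi]]$laplacian, "2")
  }
  eta <- 1 / lip
  for (it in seq_len(iters)) {
    g <- if (mode == "W") cmat %*% s - cmat else s %*% cmat - cmat
    for (gi in seq_along(graphs)) {
      l <- graphs[[gi]]$laplacian
      g <- g + if (mode == "W") weights[gi] * (s %*% l)
               else weights[gi] * (l %*% s)
    }
    g <- g + l2 * s + l1
    diag(g) <- diag(g) + gamma
    s <- pmax(s - eta * g, 0)
  }
  s
}

# AUROC as the explicit probability over all positive-negative pairs
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# AUPR by stepping through distinct thresholds and counting from scratch
oracle_aupr <- function(scores, labels) {
  thresholds <- sort(unique(scores), decreasing = TRUE)
  p_total <- sum(labels == 1)
  area <- 0
  recall_prev <- 0
  for (t in thresholds) {
    called <- scores >= t
    tp <- sum(labels == 1 & called)
    precision <- tp / sum(called)
    recall <- tp / p_total
    area <- area + (recall - recall_prev) * precision
    recall_prev <- recall
  }
  area
}

# breadth-first shortest path (edge count) on an undirected edge list
oracle_bfs <- function(edges, from, to) {
  if (from == to) return(0)
  adj <- list()
  add <- function(a, b) {
    adj[[a]] <<- c(adj[[a]], b)
  }
  for (r in seq_len(nrow(edges))) {
    add(edges[r, 1], edges[r, 2])
    add(edges[r, 2], edges[r, 1])
  }
  dist <- c(stats::setNames(0, from))
  frontier <- from
  while (length(frontier)) {
    nxt <- character(0)
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1
          if (w == to) return(unname(dist[w]))
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }
  Inf
}

# exact one-tailed rank-sum p-value by enumerating every subset assignment
oracle_ranksum_exact <- function(x, y, alternative) {
  nx <- length(x)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)])
  subsets <- utils::combn(length(r), nx)
  w_all <- apply(subsets, 2, function(idx) sum(r[idx]))
  if (alternative == "greater") {
    mean(w_all >= w_obs - 1e-9)
  } else {
    mean(w_all <= w_obs + 1e-9)
  }
}
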