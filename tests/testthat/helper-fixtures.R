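# fixture builders shared across test files

random_assoc <- function(n, m, density = 0.4, seed = 1) {
  set.seed(seed)
  repeat {
    x <- matrix(rbinom(n * m, 1, density), n, m)
    if (all(rowSums(x) > 0) && all(colSums(x) > 0)) break
  }
  association_matrix(x)
}

random_graph <- function(ids, density = 0.5, seed = 1) {
  set.seed(seed)
  k <- length(ids)
  a <- matrix(0, k, k)
  a[upper.tri(a)] <- rbinom(k * (k - 1) / 2, 1, density) *
    runif(k * (k - 1) / 2, 0.1, 1)
  a <- a + t(a)
  similarity_graph(ids, adjacency = a, name = "rand")
}

# small fitted model used by several prediction/explanation tests
fitted_small_gsem <- function(n = 10, m = 8, seed = 5) {
  x <- random_assoc(n, m, 0.35, seed)
  suppressWarnings(gsem(
    x,
    control_h = gsem_control(l2 = 2, tol = 1e-4, max_iter = 2000,
                             seed = seed + 1),
    control_w = gsem_control(l2 = 2, tol = 1e-4, max_iter = 2000,
                             seed = seed + 2)))
}
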