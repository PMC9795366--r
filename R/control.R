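#' Hyperparameters for one self-representation fit
#'
#' Bundles the tuning constants of a single GSEM objective (either the
#' side-effect fit for W or the drug fit for H) together with the optimizer
#' settings.
#'
#' @param l2 non-negative ridge weight on the squared Frobenius norm (the
#'   elastic-net quadratic part; `a` for the W fit, `c` for the H fit).
#' @param l1 non-negative lasso weight on the entrywise absolute sum
#'   (`b` for W, `d` for H).
#' @param graph_weights named non-negative numeric vector weighing the
#'   Laplacian smoothness penalty of each side-information graph; names must
#'   match the graph names passed to the fit.
#' @param diag_penalty weight of the linear trace penalty that suppresses the
#'   diagonal and rules out the trivial identity solution; the default 1e4 is
#'   large compared with the data term, as intended.
#' @param tol convergence tolerance on the maximum relative change of the
#'   coefficients between iterations (default 1e-2).
#' @param max_iter iteration cap (default 500); hitting it yields a warning,
#'   not an error.
#' @param init_upper coefficients are initialized i.i.d. Uniform(0,
#'   `init_upper`); default 0.01.
#' @param seed integer seed for the random initialization.
#' @return a list of class `"gsem_control"`.
#' @export
gsem_control <- function(l2 = 0, l1 = 0, graph_weights = numeric(0),
                         diag_penalty = 1e4, tol = 1e-2, max_iter = 500L,
                         init_upper = 0.01, seed = 1L) {
  graph_weights <- unlist(graph_weights)
  if (length(graph_weights) && is.null(names(graph_weights))) {
    stop("graph_weights must be named by graph")
  }
  stopifnot(is.finite(l2), l2 >= 0, is.finite(l1), l1 >= 0,
            all(is.finite(graph_weights)), all(graph_weights >= 0),
            is.finite(diag_penalty), diag_penalty >= 0,
            is.finite(tol), tol > 0, tol < 1,
            max_iter >= 1, is.finite(init_upper), init_upper > 0)
  structure(list(l2 = l2, l1 = l1,
                 graph_weights = as.numeric(graph_weights) |>
                   stats::setNames(names(graph_weights)),
                 diag_penalty = diag_penalty, tol = tol,
                 max_iter = as.integer(max_iter),
                 init_upper = init_upper, seed = as.integer(seed)),
            class = "gsem_control")
}

# run code with a temporarily seeded RNG, restoring global state afterwards
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}
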