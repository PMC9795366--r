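#' GSEM objective function
#'
#' Evaluates the convex objective of one self-representation fit. For the
#' side-effect matrix W (`mode = "W"`, S is m x m) it is
#' \deqn{\tfrac12\|X - XS\|_F^2 + \tfrac{\lambda_2}{2}\|S\|_F^2 +
#'   \lambda_1\|S\|_1 + \sum_g \tfrac{w_g}{2}\,\mathrm{Tr}(S L_g S^\top) +
#'   \gamma\,\mathrm{Tr}(S)}
#' and for the drug matrix H (`mode = "H"`, S is n x n) the analogue with
#' reconstruction `X - SX` and row smoothing `Tr(S' L S)`. All terms are
#' convex in S, so the minimum over the non-negative orthant is global.
#'
#' @param x binary association matrix (see [association_matrix()]).
#' @param s square non-negative coefficient matrix (candidate W or H).
#' @param graphs named list of [similarity_graph()] objects over side effects
#'   (`mode = "W"`) or drugs (`mode = "H"`).
#' @param control a [gsem_control()]; every graph in `graphs` needs an entry
#'   in `control$graph_weights`.
#' @param mode `"W"` or `"H"`.
#' @return the objective value, a finite non-negative scalar.
#' @export
gsem_objective <- function(x, s, graphs = list(), control = gsem_control(),
                           mode = c("W", "H")) {
  mode <- match.arg(mode)
  s <- as.matrix(s)
  if (anyNA(s) || any(!is.finite(s))) stop("non-finite values in coefficients")
  check_fit_inputs(x, s, graphs, control, mode)
  recon <- if (mode == "W") x - x %*% s else x - s %*% x
  val <- 0.5 * sum(recon^2) +
    control$l2 / 2 * sum(s^2) +
    control$l1 * sum(abs(s)) +
    control$diag_penalty * sum(diag(s))
  smooth_mode <- if (mode == "W") "columns" else "rows"
  for (nm in names(graphs)) {
    val <- val + control$graph_weights[[nm]] / 2 *
      smoothness(s, graphs[[nm]], smooth_mode)
  }
  val
}

check_fit_inputs <- function(x, s, graphs, control, mode) {
  k <- if (mode == "W") ncol(x) else nrow(x)
  if (nrow(s) != k || ncol(s) != k) {
    stop("coefficient matrix must be ", k, " x ", k, " for mode ", mode)
  }
  if (length(graphs)) {
    if (is.null(names(graphs)) || any(!nzchar(names(graphs)))) {
      stop("graphs must be a named list")
    }
    missing_w <- setdiff(names(graphs), names(control$graph_weights))
    if (length(missing_w)) {
      stop("no graph weight configured for: ",
           paste(missing_w, collapse = ", "))
    }
    for (g in graphs) {
      if (length(g$entity_ids) != k) {
        stop("graph '", g$name, "' dimension ", length(g$entity_ids),
             " does not match ", k)
      }
    }
  }
  invisible(TRUE)
}

# one multiplicative update with precomputed cross-product C
# mode W: C = X'X;  mode H: C = XX'
step_core <- function(s, cmat, graphs, control, mode, eps = 1e-12) {
  num <- cmat
  den <- if (mode == "W") cmat %*% s else s %*% cmat
  for (nm in names(graphs)) {
    w <- control$graph_weights[[nm]]
    if (w == 0) next
    a <- graphs[[nm]]$adjacency
    d <- graphs[[nm]]$degree
    if (mode == "W") {
      num <- num + w * (s %*% a)
      den <- den + w * sweep(s, 2L, d, "*")   # S D, D diagonal
    } else {
      num <- num + w * (a %*% s)
      den <- den + w * d * s                  # D S
    }
  }
  den <- den + control$l2 * s + control$l1
  diag(den) <- diag(den) + control$diag_penalty
  s_new <- s * num / (den + eps)
  if (any(!is.finite(s_new))) stop("non-finite coefficients after update")
  s_new
}

#' One multiplicative update of a self-representation matrix
#'
#' Applies the multiplicative rule once. For `mode = "W"`:
#' `s_ij <- s_ij * (X'X + sum_g w_g S A_g)_ij /
#'   (X'X S + sum_g w_g S D_g + l2 S + l1 + gamma I + eps)_ij`,
#' and the transposed analogue for `mode = "H"`. The rule preserves
#' non-negativity, never increases the objective, and has zeros as absorbing
#' states (an entry at exactly 0 stays 0). A stabilizer `eps = 1e-12` guards
#' the denominator against 0/0.
#'
#' @inheritParams gsem_objective
#' @return the updated coefficient matrix.
#' @export
gsem_step <- function(x, s, graphs = list(), control = gsem_control(),
                      mode = c("W", "H")) {
  mode <- match.arg(mode)
  s <- as.matrix(s)
  check_fit_inputs(x, s, graphs, control, mode)
  cmat <- if (mode == "W") crossprod(x) else tcrossprod(x)
  step_core(s, cmat, graphs, control, mode)
}

#' Fit one self-representation matrix by multiplicative updates
#'
#' Initializes the coefficients i.i.d. Uniform(0, `control$init_upper`) under
#' `control$seed` and iterates [gsem_step()] until the maximum relative
#' entrywise change `max |dS| / (|S| + 1e-12)` drops below `control$tol` or
#' `control$max_iter` is reached. Because the objective is convex and the
#' update satisfies the KKT complementarity conditions at its fixed points,
#' the limit is a global minimizer regardless of the random start.
#'
#' An entity with no associations (an all-zero row or column of X) has an
#' all-zero update numerator; its coefficients decay toward zero, which is
#' reported with a warning.
#'
#' @inheritParams gsem_objective
#' @return a list with components `s` (the fitted matrix, diagonal as
#'   learned), `trace` (class `"gsem_trace"`: `objective` per iteration
#'   including the initial value, `iterations`, `converged`,
#'   `final_relative_change`).
#' @export
fit_selfrep <- function(x, graphs = list(), control = gsem_control(),
                        mode = c("W", "H")) {
  mode <- match.arg(mode)
  k <- if (mode == "W") ncol(x) else nrow(x)
  ids <- if (mode == "W") colnames(x) else rownames(x)
  empties <- if (mode == "W") sum(colSums(x) == 0) else sum(rowSums(x) == 0)
  if (empties > 0) {
    warning(empties, if (mode == "W") " side effect(s)" else " drug(s)",
            " without associations; their coefficients decay to zero")
  }
  s <- with_seed(control$seed,
                 matrix(stats::runif(k * k, 0, control$init_upper), k, k))
  dimnames(s) <- list(ids, ids)
  check_fit_inputs(x, s, graphs, control, mode)
  cmat <- if (mode == "W") crossprod(x) else tcrossprod(x)
  obj <- numeric(control$max_iter + 1L)
  obj[1L] <- gsem_objective(x, s, graphs, control, mode)
  converged <- FALSE
  rel_change <- Inf
  it <- 0L
  while (it < control$max_iter) {
    it <- it + 1L
    s_new <- step_core(s, cmat, graphs, control, mode)
    rel_change <- max(abs(s_new - s) / (abs(s) + 1e-12))
    s <- s_new
    obj[it + 1L] <- gsem_objective(x, s, graphs, control, mode)
    if (rel_change < control$tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("fit did not converge in ", control$max_iter,
            " iterations (last relative change ", signif(rel_change, 3), ")")
  }
  trace <- structure(list(objective = obj[seq_len(it + 1L)],
                          iterations = it, converged = converged,
                          final_relative_change = rel_change),
                     class = "gsem_trace")
  list(s = s, trace = trace)
}

#' KKT complementarity residual
#'
#' Measures first-order optimality of a candidate coefficient matrix for the
#' non-negativity-constrained objective: with analytic gradient G, the
#' residual is `max_ij |min(S_ij, G_ij)|`. It is zero exactly at a KKT point
#' (entries either at the bound with non-negative gradient, or interior with
#' zero gradient); by convexity a KKT point is a global minimizer.
#'
#' @inheritParams gsem_objective
#' @return a non-negative scalar.
#' @export
kkt_residual <- function(x, s, graphs = list(), control = gsem_control(),
                         mode = c("W", "H")) {
  mode <- match.arg(mode)
  s <- as.matrix(s)
  check_fit_inputs(x, s, graphs, control, mode)
  g <- gsem_gradient(x, s, graphs, control, mode)
  max(abs(pmin(s, g)))
}

# analytic gradient of the (smooth surrogate of the) objective on S >= 0;
# the l1 term contributes the constant +l1 valid on the orthant interior
gsem_gradient <- function(x, s, graphs = list(), control = gsem_control(),
                          mode = c("W", "H")) {
  mode <- match.arg(mode)
  cmat <- if (mode == "W") crossprod(x) else tcrossprod(x)
  g <- if (mode == "W") cmat %*% s - cmat else s %*% cmat - cmat
  for (nm in names(graphs)) {
    w <- control$graph_weights[[nm]]
    l <- graphs[[nm]]$laplacian
    g <- g + if (mode == "W") w * (s %*% l) else w * (l %*% s)
  }
  g <- g + control$l2 * s + control$l1
  diag(g) <- diag(g) + control$diag_penalty
  g
}
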