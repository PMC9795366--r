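#' Fit a geometric self-expressive model
#'
#' Learns two non-negative self-representation matrices from a binary
#' drug-by-side-effect association matrix X: a drug similarity matrix H
#' (n x n) such that X is approximated by HX, and a side-effect similarity
#' matrix W (m x m) such that X is approximated by XW. Each is fitted
#' independently by its own convex graph-regularized elastic-net objective
#' (see [gsem_objective()]) using multiplicative updates; side-information
#' graphs over drugs smooth the rows of H, graphs over side effects smooth
#' the columns of W. Predicted scores are `HX + XW` ([predict.gsem()]).
#'
#' After convergence the diagonals of H and W — already driven below 1e-3 by
#' the trace penalty — are hard-zeroed so that no entity can score itself
#' through a residual self-loop.
#'
#' @param x binary association matrix with drug rownames and side-effect
#'   colnames (see [association_matrix()]).
#' @param drug_graphs named list of [similarity_graph()]s over the drugs
#'   (smoothing H). May be empty for the side-information-free model.
#' @param se_graphs named list of [similarity_graph()]s over the side
#'   effects (smoothing W).
#' @param control_h,control_w [gsem_control()] objects for the H and W fits.
#'   The two fits are independent; their seeds should differ.
#' @return an object of class `"gsem"`: a list with `H`, `W`, `trace_h`,
#'   `trace_w`, the training matrix `x`, both controls and the matched call.
#' @examples
#' x <- association_matrix(matrix(rbinom(30, 1, 0.4), 5, 6))
#' fit <- gsem(x, control_h = gsem_control(l2 = 1, seed = 1),
#'             control_w = gsem_control(l2 = 1, seed = 2))
#' round(predict(fit), 2)
#' @export
gsem <- function(x, drug_graphs = list(), se_graphs = list(),
                 control_h = gsem_control(),
                 control_w = gsem_control()) {
  x <- association_matrix(x)
  fit_h <- fit_selfrep(x, drug_graphs, control_h, mode = "H")
  fit_w <- fit_selfrep(x, se_graphs, control_w, mode = "W")
  h <- fit_h$s
  w <- fit_w$s
  diag(h) <- 0
  diag(w) <- 0
  structure(list(H = h, W = w,
                 trace_h = fit_h$trace, trace_w = fit_w$trace,
                 x = x, control_h = control_h, control_w = control_w,
                 call = match.call()),
            class = "gsem")
}

#' @export
print.gsem <- function(x, ...) {
  cat("Geometric self-expressive model\n")
  cat(sprintf("  %d drugs x %d side effects, %d known associations\n",
              nrow(x$x), ncol(x$x), sum(x$x)))
  cat(sprintf("  H fit: %d iterations, %sconverged, objective %.6g\n",
              x$trace_h$iterations, if (x$trace_h$converged) "" else "NOT ",
              tail(x$trace_h$objective, 1L)))
  cat(sprintf("  W fit: %d iterations, %sconverged, objective %.6g\n",
              x$trace_w$iterations, if (x$trace_w$converged) "" else "NOT ",
              tail(x$trace_w$objective, 1L)))
  invisible(x)
}

#' @export
summary.gsem <- function(object, ...) {
  scores <- predict(object)
  out <- list(
    n_drugs = nrow(object$x), n_side_effects = ncol(object$x),
    n_associations = sum(object$x),
    density = mean(object$x),
    h = list(iterations = object$trace_h$iterations,
             converged = object$trace_h$converged,
             objective = tail(object$trace_h$objective, 1L),
             nonzero_frac = mean(object$H > 1e-8),
             max_diag = max(abs(diag(object$H)))),
    w = list(iterations = object$trace_w$iterations,
             converged = object$trace_w$converged,
             objective = tail(object$trace_w$objective, 1L),
             nonzero_frac = mean(object$W > 1e-8),
             max_diag = max(abs(diag(object$W)))),
    score_range = range(scores))
  class(out) <- "summary.gsem"
  out
}

#' @export
print.summary.gsem <- function(x, ...) {
  cat(sprintf("GSEM fit on %d x %d matrix (%d associations, density %.3f)\n",
              x$n_drugs, x$n_side_effects, x$n_associations, x$density))
  for (side in c("h", "w")) {
    s <- x[[side]]
    cat(sprintf(
      "  %s: %d iter, %sconverged, obj %.6g, %.1f%% coefficients > 1e-8\n",
      toupper(side), s$iterations, if (s$converged) "" else "NOT ",
      s$objective, 100 * s$nonzero_frac))
  }
  cat(sprintf("  score range: [%.4g, %.4g]\n",
              x$score_range[1], x$score_range[2]))
  invisible(x)
}

#' Extract the learned self-representation matrices
#'
#' @param object a fitted [gsem()] model.
#' @param which `"both"` (a list), `"H"` or `"W"`.
#' @param ... ignored.
#' @export
coef.gsem <- function(object, which = c("both", "H", "W"), ...) {
  which <- match.arg(which)
  switch(which, both = list(H = object$H, W = object$W),
         H = object$H, W = object$W)
}

#' Predicted association scores
#'
#' Returns the score matrix `HX + XW`: a non-negative real-valued model of
#' the binary training matrix. Entries at training ones are typically large;
#' they are deliberately not masked here (masking known positives is an
#' evaluation concern, not a model one). Scores replacing the zero entries of
#' X are the model's predictions of unknown associations.
#'
#' @param object a fitted [gsem()] model.
#' @param ... ignored.
#' @return an n x m non-negative matrix with the dimnames of the training
#'   matrix.
#' @export
predict.gsem <- function(object, ...) {
  object$H %*% object$x + object$x %*% object$W
}

#' @export
fitted.gsem <- function(object, ...) predict(object)

#' @export
residuals.gsem <- function(object, ...) object$x - predict(object)

#' Plot the optimization traces
#'
#' Draws the objective value of the H and W fits against iteration on a log
#' y-scale; monotone decrease is the visual signature of the multiplicative
#' algorithm's descent guarantee.
#'
#' @param x a fitted [gsem()] model.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.gsem <- function(x, ...) {
  n_it <- max(length(x$trace_h$objective), length(x$trace_w$objective))
  pad <- function(v) c(v, rep(NA_real_, n_it - length(v)))
  graphics::matplot(seq_len(n_it) - 1L,
                    cbind(pad(x$trace_h$objective), pad(x$trace_w$objective)),
                    type = "l", lty = 1, col = c("#1b6ca8", "#c0392b"),
                    log = "y", xlab = "iteration", ylab = "objective", ...)
  graphics::legend("topright", c("H fit", "W fit"), lty = 1,
                   col = c("#1b6ca8", "#c0392b"), bty = "n")
  invisible(x)
}

#' Decompose one predicted score into interpretable terms
#'
#' The score of drug i for side effect j decomposes exactly as
#' `sum_u H[i, u]` over drugs u known to cause j, plus `sum_v W[v, j]` over
#' side effects v known for drug i. Each term is a learned similarity, so the
#' decomposition explains which known associations drive a prediction.
#'
#' @param object a fitted [gsem()] model.
#' @param drug,side_effect identifiers present in the training matrix.
#' @return a list of class `"gsem_explanation"` with `drug_terms` and
#'   `se_terms` (named numeric vectors sorted by decreasing contribution,
#'   ties in identifier order) and `total`, which equals the corresponding
#'   [predict.gsem()] entry.
#' @export
explain_score <- function(object, drug, side_effect) {
  stopifnot(inherits(object, "gsem"))
  x <- object$x
  i <- match(drug, rownames(x))
  j <- match(side_effect, colnames(x))
  if (is.na(i)) stop("unknown drug identifier: ", drug)
  if (is.na(j)) stop("unknown side effect identifier: ", side_effect)
  u <- which(x[, j] == 1)
  v <- which(x[i, ] == 1)
  drug_terms <- stats::setNames(object$H[i, u], rownames(x)[u])
  se_terms <- stats::setNames(object$W[v, j], colnames(x)[v])
  sort_terms <- function(t) {
    if (!length(t)) return(t)
    t[order(-t, seq_along(t))]
  }
  structure(list(drug = drug, side_effect = side_effect,
                 drug_terms = sort_terms(drug_terms),
                 se_terms = sort_terms(se_terms),
                 total = sum(drug_terms) + sum(se_terms)),
            class = "gsem_explanation")
}

#' @export
print.gsem_explanation <- function(x, n = 5L, ...) {
  cat(sprintf("Score for drug '%s' / side effect '%s': %.4g\n",
              x$drug, x$side_effect, x$total))
  show <- function(t, what) {
    cat(sprintf("  %s (%d): %s\n", what, length(t),
                if (length(t)) {
                  paste(sprintf("%s=%.3g", names(head(t, n)), head(t, n)),
                        collapse = ", ")
                } else "none"))
  }
  show(x$drug_terms, "contributions from drugs known to cause the effect")
  show(x$se_terms, "contributions from known side effects of the drug")
  invisible(x)
}

#' Symmetrized self-representation similarity
#'
#' Converts a learned self-representation matrix into a symmetric similarity
#' by averaging with its transpose: `(S + S') / 2`. Applied to H it gives a
#' learned drug-drug similarity, applied to W a side-effect similarity.
#'
#' @param s a square matrix, or a fitted [gsem()] model (then pick `which`).
#' @param which `"H"` or `"W"` when `s` is a model.
#' @return a symmetric non-negative matrix.
#' @export
selfrep_similarity <- function(s, which = c("H", "W")) {
  if (inherits(s, "gsem")) s <- s[[match.arg(which)]]
  s <- as.matrix(s)
  if (nrow(s) != ncol(s)) stop("self-representation must be square")
  (s + t(s)) / 2
}
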