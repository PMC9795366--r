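#' End-to-end recovery experiment on synthetic block data
#'
#' Generates a block-structured instance, masks a fraction of the known
#' associations, fits the model on the masked matrix with the
#' cluster-consistent drug and side-effect graphs, and measures how well the
#' scores rank the held-out positives against sampled negatives (twice as
#' many, drawn from the true zeros). A degree-product baseline — scoring
#' pair (i, j) by row sum times column sum of the training matrix — is
#' evaluated on the same candidates; self-expressive recovery should beat it
#' clearly because the baseline sees popularity but not block structure.
#'
#' @param spec a [synthetic_spec()] describing the instance.
#' @param mask_fraction fraction of positives held out (default 0.1).
#' @param l2 ridge weight of both fits (default 5).
#' @param graph_weight smoothness weight of each cluster graph (default 1).
#' @param seed seed for masking, negative sampling and the fits.
#' @return list with `auroc`, `baseline_auroc`, `n_held_out` and the fitted
#'   model.
#' @export
recovery_experiment <- function(spec = synthetic_spec(),
                                mask_fraction = 0.1, l2 = 5,
                                graph_weight = 1, seed = 11L) {
  sim <- make_associations(spec)
  hold <- plant_holdout(sim$x, mask_fraction, seed = seed)
  x_train <- hold$x_masked
  chem <- make_cluster_graph(sim$drug_clusters, spec$graph_p_in,
                             spec$graph_p_out, seed = seed + 30L,
                             name = "chem")
  meddra <- make_cluster_graph(sim$se_clusters, spec$graph_p_in,
                               spec$graph_p_out, seed = seed + 31L,
                               name = "meddra")
  ctl_h <- gsem_control(l2 = l2, graph_weights = c(chem = graph_weight),
                        tol = 1e-2, max_iter = 2000L, seed = seed + 10L)
  ctl_w <- gsem_control(l2 = l2, graph_weights = c(meddra = graph_weight),
                        tol = 1e-2, max_iter = 2000L, seed = seed + 11L)
  fit <- suppressWarnings(
    gsem(x_train, list(chem = chem), list(meddra = meddra), ctl_h, ctl_w))
  scores <- predict(fit)
  neg <- with_seed(seed + 20L,
                   sample(which(sim$x == 0), 2L * nrow(hold$held_out)))
  labels <- rep(c(1, 0), c(nrow(hold$held_out), length(neg)))
  candidate_scores <- c(scores[hold$held_out], scores[neg])
  baseline <- outer(rowSums(x_train), colSums(x_train))
  list(auroc = auroc(candidate_scores, labels),
       baseline_auroc = auroc(c(baseline[hold$held_out], baseline[neg]),
                              labels),
       n_held_out = nrow(hold$held_out), fit = fit)
}

#' Postmarketing-integration experiment on synthetic data
#'
#' Repeats the single-drug data-integration evaluation
#' ([integration_eval()]) on independently generated synthetic instances.
#' In each repetition a block instance is generated; every drug's positives
#' are split into a clinical part and a postmarket part (a fraction
#' `post_frac` of its associations), so the postmarket labels of a drug's
#' cluster-mates overlap the target's held-out labels. Drug-drug chemical
#' similarities are drawn Uniform(0.2, 0.5) within clusters and
#' Uniform(0, 0.1) across, keeping cluster-mates informative but below the
#' 0.6 leakage threshold. The target drug is the one with the most
#' postmarket positives among drugs with at least 3 on each side. Both
#' strategies are evaluated with identical hyperparameters and seeds.
#'
#' @param n_rep number of repetitions (default 20).
#' @param seed base seed; repetition r uses `seed + r`.
#' @param n_drugs,n_side_effects instance size (default 40 x 40).
#' @param post_frac fraction of each drug's positives labelled postmarket
#'   (default 0.4).
#' @param l2 ridge weight of the fits (default 5).
#' @return data frame with one row per repetition (`rep`, `strategy1`,
#'   `strategy2`) and attribute `medians`.
#' @export
integration_experiment <- function(n_rep = 20L, seed = 100L,
                                   n_drugs = 40L, n_side_effects = 40L,
                                   post_frac = 0.4, l2 = 5) {
  one_rep <- function(rep_seed) {
    spec <- synthetic_spec(n_drugs = n_drugs,
                           n_side_effects = n_side_effects,
                           seed = rep_seed)
    sim <- make_associations(spec)
    x <- sim$x
    n <- nrow(x)
    with_seed(rep_seed + 1000L, {
      x_clin <- x
      x_post <- x * 0
      for (i in seq_len(n)) {
        pos <- which(x[i, ] == 1)
        pm <- sample(pos, max(1L, floor(post_frac * length(pos))))
        x_clin[i, pm] <- 0
        x_post[i, pm] <- 1
      }
      a <- matrix(0, n, n)
      for (i in seq_len(n - 1L)) {
        for (j in seq.int(i + 1L, n)) {
          a[i, j] <- a[j, i] <-
            if (sim$drug_clusters[i] == sim$drug_clusters[j]) {
              stats::runif(1, 0.2, 0.5)
            } else {
              stats::runif(1, 0, 0.1)
            }
        }
      }
      chem <- similarity_graph(rownames(x), adjacency = a, name = "chem")
      ok <- rowSums(x_clin) >= 3 & rowSums(x_post) >= 3
      if (!any(ok)) stop("no eligible target drug in repetition")
      target <- rownames(x)[which(ok)[which.max(rowSums(x_post)[ok])]]
      ctl_h <- gsem_control(l2 = l2, tol = 1e-2, max_iter = 300L,
                            seed = rep_seed + 1L)
      ctl_w <- gsem_control(l2 = l2, tol = 1e-2, max_iter = 300L,
                            seed = rep_seed + 2L)
      c(strategy1 = suppressWarnings(
          integration_eval(target, x_clin, x_post, 1, chem,
                           control_h = ctl_h, control_w = ctl_w)),
        strategy2 = suppressWarnings(
          integration_eval(target, x_clin, x_post, 2, chem,
                           control_h = ctl_h, control_w = ctl_w)))
    })
  }
  res <- t(vapply(seq_len(n_rep), function(r) one_rep(seed + r),
                  numeric(2)))
  out <- data.frame(rep = seq_len(n_rep), strategy1 = res[, 1],
                    strategy2 = res[, 2])
  attr(out, "medians") <- c(strategy1 = stats::median(out$strategy1),
                            strategy2 = stats::median(out$strategy2))
  out
}
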