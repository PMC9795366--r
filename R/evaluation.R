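#' Split known associations into train/validation/test with negative sampling
#'
#' Randomly holds out `floor(test_frac * P)` of the P known associations as
#' the test positives, then `floor(val_frac * (P - |test|))` of the remainder
#' as validation positives; the rest train the model. Each positive set is
#' matched with `neg_ratio` times as many negatives sampled uniformly
#' without replacement from the zero entries of X (never overlapping any
#' positive set; validation and test negatives are disjoint). At a
#' reference scale of 27,610 positives and 10%/10% fractions this yields
#' 2,761 / 2,484 / 22,365 positives.
#'
#' @param x binary association matrix.
#' @param test_frac,val_frac fractions in (0, 1).
#' @param neg_ratio negatives sampled per positive (default 2).
#' @param seed integer; the split is bit-reproducible given the seed.
#' @return an object of class `"gsem_split"`: two-column index matrices
#'   `train_pos`, `val_pos`, `test_pos`, `val_neg`, `test_neg` plus the
#'   `seed`.
#' @export
split_associations <- function(x, test_frac = 0.1, val_frac = 0.1,
                               neg_ratio = 2, seed = 1L) {
  stopifnot(test_frac > 0, test_frac < 1, val_frac > 0, val_frac < 1,
            neg_ratio >= 0)
  pos <- which(x == 1)
  p <- length(pos)
  if (p < 10L) stop("need at least 10 positive associations to split")
  zeros <- which(x == 0)
  with_seed(seed, {
    test_idx <- sample(pos, floor(test_frac * p))
    remainder <- setdiff(pos, test_idx)
    val_idx <- sample(remainder, floor(val_frac * length(remainder)))
    train_idx <- setdiff(remainder, val_idx)
    n_neg <- round(neg_ratio * (length(test_idx) + length(val_idx)))
    if (n_neg > length(zeros)) {
      warning("only ", length(zeros), " zero entries available for ",
              n_neg, " requested negatives; sampling all")
      n_neg <- length(zeros)
    }
    neg_idx <- sample(zeros, n_neg)
    n_test_neg <- min(round(neg_ratio * length(test_idx)), length(neg_idx))
    test_neg <- neg_idx[seq_len(n_test_neg)]
    val_neg <- neg_idx[setdiff(seq_along(neg_idx), seq_len(n_test_neg))]
    as_pairs <- function(idx) {
      cbind(row = ((idx - 1L) %% nrow(x)) + 1L,
            col = ((idx - 1L) %/% nrow(x)) + 1L)
    }
    structure(list(train_pos = as_pairs(train_idx),
                   val_pos = as_pairs(val_idx),
                   test_pos = as_pairs(test_idx),
                   val_neg = as_pairs(val_neg),
                   test_neg = as_pairs(test_neg),
                   seed = as.integer(seed)),
              class = "gsem_split")
  })
}

#' @export
print.gsem_split <- function(x, ...) {
  cat(sprintf(
    "Association split (seed %d): train %d, validation %d (+%d neg), test %d (+%d neg)\n",
    x$seed, nrow(x$train_pos), nrow(x$val_pos), nrow(x$val_neg),
    nrow(x$test_pos), nrow(x$test_neg)))
  invisible(x)
}

#' Mask the validation and test positives out of a matrix
#'
#' Returns the training matrix implied by a split: a copy of `x` with the
#' held-out positives set to zero.
#'
#' @param x the full association matrix the split was drawn from.
#' @param split a [split_associations()] result.
#' @param include_val if `TRUE`, validation positives stay in training (the
#'   re-training step after model selection); default `FALSE`.
#' @export
training_matrix <- function(x, split, include_val = FALSE) {
  x[split$test_pos] <- 0
  if (!include_val) x[split$val_pos] <- 0
  x
}

#' Area under the ROC curve
#'
#' Rank-statistic AUROC with mid-rank tie handling: the probability that a
#' random positive outscores a random negative, ties counting one half.
#' Constant scores therefore give exactly 0.5.
#'
#' @param scores numeric vector.
#' @param labels 0/1 (or logical) vector of the same length with at least
#'   one positive and one negative.
#' @return a number in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUROC undefined: need both positive and negative labels")
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step-wise integral of precision over recall, sweeping the threshold down
#' through the distinct score values with tied scores grouped at a single
#' threshold: `sum_k (recall_k - recall_{k-1}) * precision_k`.
#'
#' @inheritParams auroc
#' @return a number in (0, 1\].
#' @export
aupr <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  p <- sum(labels == 1)
  if (p == 0L || p == length(labels)) {
    stop("AUPR undefined: need both positive and negative labels")
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  grp <- cumsum(!duplicated(s))        # tie groups at equal thresholds
  tp <- tapply(y, grp, sum)
  n_at <- tapply(y, grp, length)
  tp_cum <- cumsum(tp)
  n_cum <- cumsum(n_at)
  precision <- tp_cum / n_cum
  recall <- tp_cum / p
  sum(diff(c(0, recall)) * precision)
}

#' Ratio of reporting frequency per side effect
#'
#' `RRF(j) = (number of drugs associated with side effect j) / Z`, with Z
#' the largest such count over all side effects. The most-reported side
#' effect always has RRF 1; RRF contrasts how broadly a side effect is
#' reported across drugs, e.g. between the clinical-trial and postmarketing
#' eras.
#'
#' @param x binary association matrix (optionally already restricted to one
#'   provenance label).
#' @return an object of class `"gsem_rrf"`: list with `side_effect_ids`,
#'   `rrf` (named, in \[0, 1\]) and the normalizer `z`.
#' @export
rrf <- function(x) {
  counts <- colSums(x)
  z <- max(counts)
  if (z == 0) stop("degenerate input: no associations at all")
  structure(list(side_effect_ids = colnames(x),
                 rrf = counts / z, z = as.integer(z)),
            class = "gsem_rrf")
}

#' @export
print.gsem_rrf <- function(x, ...) {
  cat(sprintf("RRF over %d side effects, normalizer Z = %d\n",
              length(x$rrf), x$z))
  invisible(x)
}

#' Per-drug or per-side-effect ranking performance
#'
#' For each drug (axis `"drug"`) the candidate set is the training-zero
#' entries of its row; its held-out test positives get label 1, every other
#' training zero label 0, and the AUROC of the model scores over those
#' candidates is reported. Entities with fewer than `min_test` test
#' positives are omitted (per-entity AUROC is noisy below that). Axis
#' `"side_effect"` mirrors the procedure over columns.
#'
#' @param scores full n x m score matrix.
#' @param x_train the training association matrix (held-out entries zero).
#' @param test_positives two-column index matrix of held-out positives.
#' @param axis `"drug"` or `"side_effect"`.
#' @param min_test minimum number of test positives (default 10).
#' @return named numeric vector of AUROCs.
#' @export
per_entity_auroc <- function(scores, x_train, test_positives,
                             axis = c("drug", "side_effect"),
                             min_test = 10L) {
  axis <- match.arg(axis)
  stopifnot(all(dim(scores) == dim(x_train)))
  test_mask <- matrix(FALSE, nrow(x_train), ncol(x_train))
  test_mask[test_positives] <- TRUE
  if (axis == "side_effect") {
    scores <- t(scores)
    x_train <- t(x_train)
    test_mask <- t(test_mask)
  }
  out <- numeric(0)
  for (i in seq_len(nrow(x_train))) {
    cand <- which(x_train[i, ] == 0)
    y <- as.numeric(test_mask[i, cand])
    if (sum(y) < min_test || sum(y) == length(y)) next
    out[rownames(x_train)[i]] <- auroc(scores[i, cand], y)
  }
  out
}

#' Summarize per-entity values by group
#'
#' @param values named numeric vector (e.g. per-drug AUROCs or RRFs).
#' @param grouping named character vector mapping entities to group labels;
#'   entities without a mapping fall into `"unclassified"`.
#' @return data frame with columns `group`, `n`, `mean`, `median`, sorted by
#'   group label.
#' @export
group_metrics <- function(values, grouping) {
  g <- grouping[names(values)]
  g[is.na(g)] <- "unclassified"
  agg <- split(unname(values), g)
  data.frame(group = names(agg),
             n = vapply(agg, length, integer(1)),
             mean = vapply(agg, mean, numeric(1)),
             median = vapply(agg, stats::median, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

# one-tailed rank-sum p-value; exact (ties via doubled mid-ranks and a
# subset-sum DP over the permutation distribution) when either side is
# small, normal approximation with tie correction otherwise
ranksum_pvalue <- function(x, y, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  nx <- length(x)
  ny <- length(y)
  if (min(nx, ny) >= 10L) {
    return(stats::wilcox.test(x, y, alternative = alternative,
                              exact = FALSE, correct = FALSE)$p.value)
  }
  r2 <- round(2 * rank(c(x, y)))          # doubled mid-ranks are integers
  w_obs <- sum(r2[seq_len(nx)])
  total <- sum(r2)
  # f[k+1, s+1] = number of size-k subsets of the ranks with doubled sum s
  f <- matrix(0, nx + 1L, total + 1L)
  f[1L, 1L] <- 1
  for (r in r2) {
    kmax <- min(nx, which(rowSums(f) > 0) |> max())
    for (k in seq.int(min(kmax, nx), 1L)) {
      nz <- which(f[k, ] > 0)
      f[k + 1L, nz + r] <- f[k + 1L, nz + r] + f[k, nz]
    }
  }
  dist <- f[nx + 1L, ]
  n_subsets <- sum(dist)
  sums <- seq_along(dist) - 1L
  if (alternative == "greater") {
    sum(dist[sums >= w_obs]) / n_subsets
  } else {
    sum(dist[sums <= w_obs]) / n_subsets
  }
}

#' Group-wise distribution-shift test on RRF values
#'
#' For each group of entities, compares the group's values against all
#' remaining values with a one-tailed Wilcoxon rank-sum test; both tails are
#' evaluated and the more significant is reported with its direction.
#' P-values are Benjamini-Hochberg adjusted across the tested groups, and
#' the effect size is the group median minus the overall median. Groups with
#' fewer than 3 members are skipped with a warning.
#'
#' @param values named numeric vector (typically RRF values per side effect,
#'   or per-drug medians).
#' @param membership named list mapping group labels to entity identifier
#'   vectors.
#' @param alpha significance level for the `significant` flag (default
#'   0.05).
#' @return data frame with columns `group`, `n`, `direction`, `p`,
#'   `p_adjusted`, `effect_size`, `significant`.
#' @export
rrf_shift_test <- function(values, membership, alpha = 0.05) {
  if (length(membership) < 2L) stop("need at least two groups")
  overall_median <- stats::median(values)
  rows <- list()
  for (grp in names(membership)) {
    ids <- intersect(membership[[grp]], names(values))
    if (length(ids) < 3L) {
      warning("group '", grp, "' has fewer than 3 members; skipped")
      next
    }
    x <- values[ids]
    y <- values[setdiff(names(values), ids)]
    if (!length(y)) next
    p_gr <- ranksum_pvalue(x, y, "greater")
    p_le <- ranksum_pvalue(x, y, "less")
    direction <- if (p_gr <= p_le) "greater" else "less"
    rows[[grp]] <- data.frame(
      group = grp, n = length(x), direction = direction,
      p = min(p_gr, p_le),
      effect_size = stats::median(x) - overall_median,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no testable groups (all below 3 members)")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_adjusted < alpha
  out[c("group", "n", "direction", "p", "p_adjusted",
        "effect_size", "significant")]
}

#' Single-drug evaluation with postmarketing data integration
#'
#' Evaluates how well the model recovers a target drug's postmarketing side
#' effects when trained on its clinical-trial associations only, under two
#' strategies for the other drugs: strategy 1 trains them on clinical
#' associations only, strategy 2 on clinical plus postmarketing
#' associations. To prevent leakage through chemical analogs, every other
#' drug whose chemical similarity to the target is at or above
#' `leak_threshold` is removed from the training matrix before fitting.
#'
#' @param target_drug drug identifier (rowname of the matrices).
#' @param x_clinical,x_post binary association matrices on the same
#'   identifier grid: clinical-trial and postmarketing associations.
#' @param strategy 1 or 2.
#' @param chem_graph [similarity_graph()] over the drugs holding pairwise
#'   chemical (Tanimoto) similarities.
#' @param leak_threshold similarity at or above which another drug is
#'   dropped (default 0.6).
#' @param drug_graphs,se_graphs optional side-information graphs passed to
#'   the fit (drug graphs are restricted to the retained drugs).
#' @param control_h,control_w fixed hyperparameters for the fit.
#' @return the AUROC over the target drug's training-zero entries, its
#'   postmarket associations as positives.
#' @export
integration_eval <- function(target_drug, x_clinical, x_post,
                             strategy = c(1, 2), chem_graph,
                             leak_threshold = 0.6,
                             drug_graphs = list(), se_graphs = list(),
                             control_h = gsem_control(),
                             control_w = gsem_control()) {
  strategy <- match.arg(as.character(strategy[1]), c("1", "2"))
  stopifnot(all(dim(x_clinical) == dim(x_post)),
            identical(rownames(x_clinical), rownames(x_post)))
  ti <- match(target_drug, rownames(x_clinical))
  if (is.na(ti)) stop("unknown target drug: ", target_drug)
  if (sum(x_clinical[ti, ]) < 1) stop("target drug has no clinical positives")
  if (sum(x_post[ti, ]) < 1) stop("target drug has no postmarket positives")
  x_train <- x_clinical
  if (strategy == "2") {
    others <- setdiff(seq_len(nrow(x_train)), ti)
    x_train[others, ] <- pmax(x_clinical[others, ], x_post[others, ])
  }
  sim_to_target <- chem_graph$adjacency[
    match(target_drug, chem_graph$entity_ids), ]
  leak <- which(sim_to_target >= leak_threshold &
                  chem_graph$entity_ids != target_drug)
  keep <- setdiff(seq_len(nrow(x_train)), leak)
  if (length(keep) < 2L) {
    stop("degenerate input: leak filter removed every other drug")
  }
  x_train <- x_train[keep, , drop = FALSE]
  keep_se <- colSums(x_train) > 0   # drop side effects with no remaining data
  x_train <- x_train[, keep_se, drop = FALSE]
  kept_graphs <- lapply(drug_graphs, function(g) {
    idx <- match(rownames(x_train), g$entity_ids)
    similarity_graph(rownames(x_train),
                     adjacency = g$adjacency[idx, idx], name = g$name)
  })
  kept_se_graphs <- lapply(se_graphs, function(g) {
    idx <- match(colnames(x_train), g$entity_ids)
    similarity_graph(colnames(x_train),
                     adjacency = g$adjacency[idx, idx], name = g$name)
  })
  fit <- gsem(x_train, kept_graphs, kept_se_graphs, control_h, control_w)
  scores <- predict(fit)
  ti2 <- match(target_drug, rownames(x_train))
  cand <- which(x_train[ti2, ] == 0)
  labels <- as.numeric(x_post[target_drug, colnames(x_train)[cand]] == 1)
  if (sum(labels) == 0L || sum(labels) == length(labels)) {
    stop("target drug has no scorable postmarket candidates")
  }
  auroc(scores[ti2, cand], labels)
}

#' Side-information similarity binned by learned self-representation
#'
#' Interpretability check: pairs of entities are binned by their symmetrized
#' self-representation similarity and the distribution of an independent
#' side-information similarity (chemical, taxonomy, ...) is summarized per
#' bin. If the learned coefficients capture real relationships the bin
#' summaries increase with the self-representation similarity.
#'
#' @param sym_selfrep symmetric matrix from [selfrep_similarity()].
#' @param side_info_graph [similarity_graph()] over the same entities.
#' @param bin_edges increasing break points; intervals are closed on the
#'   left, open on the right, last bin open-ended. Default
#'   `c(0, 0.05, 0.1, 0.2, Inf)`.
#' @return data frame with one row per bin: `bin`, `n`, `mean`, `median`,
#'   `q25`, `q75` of the side-information similarity.
#' @export
selfrep_similarity_bins <- function(sym_selfrep, side_info_graph,
                                    bin_edges = c(0, 0.05, 0.1, 0.2, Inf)) {
  k <- nrow(sym_selfrep)
  stopifnot(k == length(side_info_graph$entity_ids))
  ut <- upper.tri(sym_selfrep)
  s <- sym_selfrep[ut]
  v <- side_info_graph$adjacency[ut]
  bin <- findInterval(s, bin_edges, rightmost.closed = FALSE)
  labels <- paste0("[", head(bin_edges, -1L), ", ",
                   c(tail(head(bin_edges, -1L), -1L), "Inf"), ")")
  out <- lapply(seq_len(length(bin_edges) - 1L), function(b) {
    vb <- v[bin == b]
    if (!length(vb)) {
      data.frame(bin = labels[b], n = 0L, mean = NA_real_,
                 median = NA_real_, q25 = NA_real_, q75 = NA_real_)
    } else {
      q <- stats::quantile(vb, c(0.25, 0.75), names = FALSE)
      data.frame(bin = labels[b], n = length(vb), mean = mean(vb),
                 median = stats::median(vb), q25 = q[1], q75 = q[2])
    }
  })
  do.call(rbind, out)
}
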