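test_that("splits partition the positives and obey the floor arithmetic", {
  x <- random_assoc(20, 15, 0.3, seed = 41)
  sp <- split_associations(x, 0.1, 0.1, neg_ratio = 2, seed = 7)
  p <- sum(x)
  expect_equal(nrow(sp$test_pos), floor(0.1 * p))
  expect_equal(nrow(sp$val_pos), floor(0.1 * (p - nrow(sp$test_pos))))
  expect_equal(nrow(sp$train_pos) + nrow(sp$val_pos) + nrow(sp$test_pos), p)
  # all five sets pairwise disjoint; positives exactly recovered
  key <- function(m) paste(m[, 1], m[, 2])
  all_pos <- c(key(sp$train_pos), key(sp$val_pos), key(sp$test_pos))
  expect_equal(sort(all_pos), sort(key(which(x == 1, arr.ind = TRUE))))
  negs <- c(key(sp$val_neg), key(sp$test_neg))
  expect_equal(anyDuplicated(c(all_pos, negs)), 0L)
  # negatives are zero entries, twice the positives
  expect_true(all(x[sp$val_neg] == 0))
  expect_true(all(x[sp$test_neg] == 0))
  expect_equal(nrow(sp$test_neg), 2 * nrow(sp$test_pos))
  expect_equal(nrow(sp$val_neg), 2 * nrow(sp$val_pos))
  # bit-identical on the same seed
  sp2 <- split_associations(x, 0.1, 0.1, neg_ratio = 2, seed = 7)
  expect_identical(sp, sp2)
})

test_that("a vanishing test fraction still draws the validation set", {
  x <- random_assoc(10, 8, 0.3, seed = 42)
  sp <- split_associations(x, test_frac = 1e-6, val_frac = 0.2, seed = 1)
  expect_equal(nrow(sp$test_pos), 0)
  expect_gt(nrow(sp$val_pos), 0)
})

test_that("negative sampling caps at the available zeros with a warning", {
  x <- association_matrix(rbind(c(1, 1, 1, 0), c(1, 1, 1, 1),
                                c(1, 1, 1, 1)))
  expect_warning(sp <- split_associations(x, 0.3, 0.3, neg_ratio = 5,
                                          seed = 2),
                 "available")
  expect_lte(nrow(sp$test_neg) + nrow(sp$val_neg), 1)
})

test_that("AUROC and AUPR match exhaustive oracles including ties", {
  expect_equal(auroc(c(3, 2, 1), c(1, 1, 0)), 1)
  expect_equal(auroc(rep(1, 6), c(1, 0, 1, 0, 0, 1)), 0.5)
  expect_equal(auroc(c(0.8, 0.6, 0.4), c(1, 0, 1)), 0.5)
  set.seed(43)
  for (rep in 1:50) {
    n <- sample(4:12, 1)
    scores <- sample(seq(0, 1, 0.25), n, replace = TRUE)  # many ties
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))[sample(n)]
    expect_equal(auroc(scores, labels), oracle_auroc(scores, labels),
                 tolerance = 1e-12)
    expect_equal(aupr(scores, labels), oracle_aupr(scores, labels),
                 tolerance = 1e-12)
  }
  expect_error(auroc(1:3, c(1, 1, 1)), "undefined")
  expect_error(aupr(1:3, c(0, 0, 0)), "undefined")
})

test_that("AUROC is invariant under strictly monotone score transforms", {
  set.seed(44)
  scores <- runif(30)
  labels <- rbinom(30, 1, 0.4)
  labels[1:2] <- c(0, 1)
  a0 <- auroc(scores, labels)
  expect_equal(auroc(exp(3 * scores), labels), a0)
  expect_equal(auroc(rank(scores), labels), a0)
})

test_that("RRF normalizes by the busiest side effect", {
  x <- association_matrix(rbind(c(1, 0, 1), c(1, 1, 0), c(1, 0, 1)))
  r <- rrf(x)
  expect_equal(r$z, 3L)
  expect_equal(unname(r$rrf), c(1, 1 / 3, 2 / 3))
  expect_equal(max(r$rrf), 1)
  # column counts are conserved through the normalizer
  expect_equal(unname(r$rrf * r$z), unname(colSums(x)))
  expect_error(rrf(association_matrix(matrix(0, 2, 2))), "degenerate")
})

test_that("per-entity AUROC matches direct pair counting and the floor", {
  set.seed(45)
  x_full <- random_assoc(12, 10, 0.5, seed = 46)
  sp <- split_associations(x_full, 0.3, 0.2, seed = 3)
  x_train <- training_matrix(x_full, sp, include_val = TRUE)
  scores <- matrix(runif(120), 12, 10, dimnames = dimnames(x_full))
  out <- per_entity_auroc(scores, x_train, sp$test_pos, "drug",
                          min_test = 2)
  test_mask <- matrix(FALSE, 12, 10)
  test_mask[sp$test_pos] <- TRUE
  for (d in names(out)) {
    i <- match(d, rownames(x_full))
    cand <- which(x_train[i, ] == 0)
    y <- as.numeric(test_mask[i, cand])
    expect_equal(out[[d]], oracle_auroc(scores[i, cand], y))
  }
  # entities under the test-positive floor are omitted
  per_row_pos <- table(factor(sp$test_pos[, 1], levels = 1:12))
  expect_setequal(names(out),
                  rownames(x_full)[per_row_pos >= 2 &
                                     per_row_pos < rowSums(x_train == 0)])
  out10 <- per_entity_auroc(scores, x_train, sp$test_pos, "drug",
                            min_test = 10)
  expect_length(out10, 0)
})

test_that("a drug whose test positives top its zeros scores AUROC 1", {
  x_train <- association_matrix(rbind(c(1, 0, 0, 0), c(0, 1, 1, 1)))
  test_pos <- cbind(1L, 2L)
  scores <- rbind(c(9, 8, 1, 2), c(1, 1, 1, 1))
  dimnames(scores) <- dimnames(x_train)
  out <- per_entity_auroc(scores, x_train, test_pos, "drug", min_test = 1)
  expect_equal(out[["drug1"]], 1)
})

test_that("group summaries equal a plain loop over groups", {
  vals <- c(a = 0.6, b = 0.8, c = 0.7)
  gm <- group_metrics(vals, c(a = "g1", b = "g1", c = "g2"))
  expect_equal(gm$mean[gm$group == "g1"], 0.7)
  expect_equal(gm$mean[gm$group == "g2"], 0.7)
  # single group reproduces the global summary
  gm1 <- group_metrics(vals, c(a = "g", b = "g", c = "g"))
  expect_equal(gm1$mean, mean(vals))
  expect_equal(gm1$median, median(vals))
  # unmapped entities fall into 'unclassified'; loop oracle on 50 values
  set.seed(47)
  vals <- setNames(runif(50), paste0("e", 1:50))
  grouping <- setNames(sample(c("x", "y", "z"), 40, replace = TRUE),
                       paste0("e", 1:40))
  gm <- group_metrics(vals, grouping)
  for (g in unique(grouping)) {
    members <- names(grouping)[grouping == g]
    expect_equal(gm$mean[gm$group == g], mean(vals[members]))
    expect_equal(gm$n[gm$group == g], length(members))
  }
  expect_equal(gm$n[gm$group == "unclassified"], 10)
})

test_that("rank-sum p-values agree with exact enumeration at small n", {
  set.seed(48)
  for (rep in 1:6) {
    x <- round(runif(8), 2)   # rounding forces occasional ties
    y <- round(runif(sample(6:9, 1)) + 0.2, 2)
    for (alt in c("greater", "less")) {
      expect_equal(gsem:::ranksum_pvalue(x, y, alt),
                   oracle_ranksum_exact(x, y, alt),
                   tolerance = 1e-12)
    }
  }
})

test_that("shift tests detect planted group shifts with BH adjustment", {
  set.seed(49)
  values <- setNames(runif(90), paste0("s", 1:90))
  membership <- list(up = paste0("s", 1:30), mid = paste0("s", 31:60),
                     rest = paste0("s", 61:90))
  values[membership$up] <- values[membership$up] + 2  # clearly shifted up
  res <- rrf_shift_test(values, membership)
  expect_equal(res$direction[res$group == "up"], "greater")
  expect_true(res$significant[res$group == "up"])
  expect_gt(res$effect_size[res$group == "up"], 0)
  # BH step keeps adjusted p monotone in raw p
  ord <- order(res$p)
  expect_true(all(diff(res$p_adjusted[ord]) >= -1e-15))
  expect_true(all(res$p_adjusted >= res$p - 1e-15))
  # two groups drawn from one distribution: no significant shift
  flat <- setNames(runif(80), paste0("f", 1:80))
  res_flat <- rrf_shift_test(flat, list(g1 = paste0("f", 1:40),
                                        g2 = paste0("f", 41:80)))
  expect_true(all(!res_flat$significant))
  expect_lt(max(abs(res_flat$effect_size)), 0.25)
  # undersized groups are skipped with a warning
  expect_warning(
    rrf_shift_test(values, list(tiny = paste0("s", 1:2),
                                rest = paste0("s", 3:90))),
    "fewer than 3")
})

test_that("integration strategies behave at the boundaries", {
  set.seed(50)
  spec <- synthetic_spec(n_drugs = 20L, n_side_effects = 20L,
                         n_se_clusters = 2L, seed = 51)
  sim <- make_associations(spec)
  x <- sim$x
  x_clin <- x
  x_post <- x * 0
  # hold out 40% of drug 1's positives as its postmarket set
  pos1 <- which(x[1, ] == 1)
  pm <- pos1[seq_len(max(2, floor(0.4 * length(pos1))))]
  x_clin[1, pm] <- 0
  x_post[1, pm] <- 1
  n <- nrow(x)
  a <- matrix(0.3, n, n)
  diag(a) <- 0
  chem <- similarity_graph(rownames(x), adjacency = a, name = "chem")
  ctl <- gsem_control(l2 = 2, tol = 1e-2, max_iter = 200, seed = 1)
  # with an empty postmarket set for other drugs, the strategies coincide
  a1 <- suppressWarnings(integration_eval(rownames(x)[1], x_clin, x_post, 1,
                                          chem, control_h = ctl,
                                          control_w = ctl))
  a2 <- suppressWarnings(integration_eval(rownames(x)[1], x_clin, x_post, 2,
                                          chem, control_h = ctl,
                                          control_w = ctl))
  expect_identical(a1, a2)
  # threshold above every similarity removes nobody; zero removes everybody
  a3 <- suppressWarnings(integration_eval(rownames(x)[1], x_clin, x_post, 1,
                                          chem, leak_threshold = 1.01,
                                          control_h = ctl, control_w = ctl))
  expect_identical(a3, a1)
  expect_error(integration_eval(rownames(x)[1], x_clin, x_post, 1, chem,
                                leak_threshold = 0, control_h = ctl,
                                control_w = ctl),
               "degenerate")
})

test_that("similarity bins summarize side information per bin", {
  set.seed(52)
  k <- 12
  ids <- paste0("e", 1:k)
  # planted monotone relation: side-info similarity grows with selfrep
  selfrep <- matrix(runif(k * k, 0, 0.4), k, k)
  selfrep <- (selfrep + t(selfrep)) / 2
  side <- selfrep * 2 + 0.05
  diag(side) <- 0
  g <- similarity_graph(ids, adjacency = pmin(side, 1), name = "side")
  bins <- selfrep_similarity_bins(selfrep, g)
  expect_equal(sum(bins$n), k * (k - 1) / 2)
  filled <- bins[bins$n > 0, ]
  expect_true(all(diff(filled$mean) > 0))
  # constant selfrep similarity puts every pair in the first bin
  const <- matrix(0.03, k, k)
  bins2 <- selfrep_similarity_bins(const, g)
  expect_equal(bins2$n[1], k * (k - 1) / 2)
  expect_equal(sum(bins2$n[-1]), 0)
  # constant side information makes all occupied bin means equal
  g3 <- similarity_graph(ids, adjacency = matrix(0.2, k, k) -
                           diag(0.2, k), name = "flat")
  bins3 <- selfrep_similarity_bins(selfrep, g3)
  expect_true(all(abs(bins3$mean[bins3$n > 0] - 0.2) < 1e-12))
})
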