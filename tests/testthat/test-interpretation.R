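test_that("a constant model attributes nothing; a single stump matches the closed form", {
  set.seed(12)
  n <- 200L
  X <- cbind(a = rbinom(n, 1, 0.4), b = rbinom(n, 1, 0.5),
             c = runif(n))
  rownames(X) <- sprintf("t%d", 1:n)
  # constant target -> no splits -> all attributions zero
  spec0 <- model_spec(eta = 1, max_depth = 1L, nrounds_max = 1L,
                      early_stopping = 1L, n_folds = 2L, seed = 1L,
                      subsample = 1, colsample = 1)
  fit0 <- train_model(X, rep(3, n), spec0)
  ct0 <- compute_attributions(fit0, X)
  expect_true(all(abs(ct0$phi) < 1e-9))
  expect_equal(unique(round(ct0$phi0 + rowSums(ct0$phi), 6)),
               unname(round(predict(fit0, X)[1L], 6)))
  # single depth-1 tree split on 'a': phi_a is two-valued, other
  # features zero, and phi_a(x) = prediction(x) - mean(prediction)
  y <- 2 * X[, "a"] + 0.1
  fit1 <- train_model(X, y, spec0)
  ct1 <- compute_attributions(fit1, X)
  expect_true(all(abs(ct1$phi[, c("b", "c")]) < 1e-9))
  preds <- predict(fit1, X)
  expect_equal(unname(ct1$phi[, "a"]), unname(preds - mean(preds)),
               tolerance = 1e-5)
  expect_lte(length(unique(round(ct1$phi[, "a"], 6))), 2L)
})

test_that("attributions are additive for boosted-tree and ridge fits", {
  set.seed(13)
  n <- 300L
  X <- matrix(runif(n * 6), n, 6,
              dimnames = list(sprintf("t%d", 1:n), paste0("f", 1:6)))
  y <- X[, 1] * 2 - X[, 2] + X[, 3] * X[, 4] + rnorm(n, 0, 0.1)
  spec <- model_spec(eta = 0.2, max_depth = 3L, nrounds_max = 150L,
                     early_stopping = 15L, n_folds = 3L, seed = 2L)
  fit <- train_model(X, y, spec)
  ct <- compute_attributions(fit, X)
  expect_true(check_additivity(ct, tol = 1e-4))
  recon <- ct$phi0 + rowSums(ct$phi)
  expect_equal(recon, ct$predictions, tolerance = 1e-5)
  # ridge attributions reconstruct the linear prediction exactly
  rfit <- train_model(X, y, model_spec(learner = "ridge", seed = 2L))
  rct <- compute_attributions(rfit, X)
  expect_true(check_additivity(rct, tol = 1e-6))
  # random forests have no additive attribution path
  ffit <- train_model(X, y, model_spec(learner = "rf", num_trees = 50L,
                                       n_folds = 2L, seed = 2L))
  expect_error(compute_attributions(ffit, X), "tree-boosting")
})

test_that("factor aggregation sums mean absolute attributions with conservation", {
  phi <- cbind("chip.A.5prime" = c(1, -1, 2), "chip.A.intron" = c(0.5, 0, 0.5),
               "clip.B.intron" = c(-1, 1, -2), "clip.B.3prime" = c(0.5, 0, 0.5),
               "tx.len" = c(0.2, 0.2, 0.2))
  ct <- structure(list(phi = phi, phi0 = rep(0, 3),
                       predictions = rowSums(phi)),
                  class = "contribution_table")
  meta <- parse_feature_name(colnames(phi))
  meta[, kind := ifelse(is.na(assay), "annotation", "binding")]
  agg <- aggregate_by_factor(ct, meta)
  # mirrored attribution profiles give equal factor scores
  expect_equal(agg[factor_name == "A"]$S, agg[factor_name == "B"]$S)
  # double-loop oracle
  or <- sapply(c("A", "B"), function(f) {
    cols <- meta[factor_name %in% f]$name
    tot <- 0
    for (cn in cols) tot <- tot + mean(abs(phi[, cn]))
    tot
  })
  expect_equal(agg[factor_name == "A"]$S, or[["A"]])
  # conservation: sum of factor scores equals sum of column mean |phi|
  expect_equal(sum(agg$S), sum(colMeans(abs(phi))))
  # shares over the factor base sum to one
  expect_equal(sum(agg[factor_name != "annotation"]$share), 1)
  # single factor -> share 1
  one <- aggregate_by_factor(
    structure(list(phi = phi[, 1:2, drop = FALSE], phi0 = rep(0, 3),
                   predictions = rowSums(phi[, 1:2])),
              class = "contribution_table"),
    meta[1:2])
  expect_equal(one$share, 1)
  expect_error(aggregate_by_factor(ct, meta[1:3]), "missing from metadata")
})

test_that("group aggregation covers factor sets (with overlap) and binding modes", {
  scores <- data.table(factor_name = c("A", "B", "C"), S = c(3, 2, 1))
  grouping <- list(S1 = factor_set("S1", c("A", "B")),
                   S2 = factor_set("S2", c("B", "C")),
                   empty = factor_set("empty", "Z"))
  g <- aggregate_by_group(scores, grouping, by = "factor_set")
  expect_equal(g[group == "S1"]$S, 5)
  expect_equal(g[group == "S2"]$S, 3) # B counted in both sets
  expect_equal(g[group == "empty"]$S, 0)
  all_g <- aggregate_by_group(scores,
                              list(all = factor_set("all", c("A", "B", "C"))),
                              by = "factor_set")
  expect_equal(all_g$S, sum(scores$S))
  # binding modes: DNA/RNA x region
  phi <- cbind("chip.A.5prime" = c(1, -1), "clip.B.intron" = c(2, 2),
               "clip.B.intron.Proximal.ncRNA.1" = c(1, 0),
               "tx.len" = c(0.5, 0.5))
  meta <- parse_feature_name(colnames(phi))
  meta[, kind := ifelse(is.na(assay), "annotation", "binding")]
  ct <- structure(list(phi = phi, phi0 = c(0, 0),
                       predictions = rowSums(phi)),
                  class = "contribution_table")
  bm <- aggregate_by_group(by = "binding_mode", ct = ct, meta = meta)
  expect_equal(bm[group == "DNA.5prime"]$S, 1)
  expect_equal(bm[group == "RNA.intron"]$S, 2)
  expect_equal(bm[group == "RNA.intron.proximal.ncRNA"]$S, 0.5)
  expect_equal(bm[group == "annotation"]$S, 0.5)
})

test_that("minimal factor set is the shortest prefix reaching the target share", {
  shares <- data.table(factor_name = c("A", "B", "C", "D"),
                       share = c(0.4, 0.2, 0.2, 0.2))
  sel <- select_minimal_factor_set(shares, 0.5)
  expect_equal(sel$factor_name, c("A", "B"))
  expect_gte(sel$cumulative[nrow(sel)], 0.5)
  # minimality: dropping the last selected factor falls below target
  expect_lt(sel$cumulative[nrow(sel)] - sel$share[nrow(sel)], 0.5)
  expect_equal(select_minimal_factor_set(
    data.table(factor_name = "solo", share = 1), 0.9)$factor_name, "solo")
  expect_error(select_minimal_factor_set(shares, 0), "target_share")
  # exhaustive prefix oracle on random share vectors
  set.seed(14)
  for (rep in 1:50) {
    k <- sample(2:12, 1L)
    s <- runif(k); s <- s / sum(s)
    sh <- data.table(factor_name = sprintf("F%02d", sample(100, k)), share = s)
    tgt <- runif(1, 0.1, 1)
    sel <- select_minimal_factor_set(sh, tgt)
    ord <- sh[order(-share, factor_name)]
    sizes <- which(cumsum(ord$share) >= tgt - 1e-12)
    expect_equal(nrow(sel), min(sizes))
    expect_equal(sel$factor_name, ord$factor_name[seq_len(min(sizes))])
  }
})

test_that("Fisher enrichment gives exact hypergeometric p-values and sample odds ratios", {
  f <- fisher_enrichment(rbind(c(1, 1), c(1, 1)))
  expect_equal(f$odds_ratio, 1)
  expect_equal(f$p_value, oracle_fisher_greater(1, 1, 1, 1))
  f2 <- fisher_enrichment(rbind(c(5, 0), c(0, 5)))
  expect_equal(f2$p_value, 1 / choose(10, 5))
  expect_equal(f2$odds_ratio, Inf)
  # p decreases as the concordant diagonal grows with margins fixed
  p_seq <- sapply(0:5, function(k)
    fisher_enrichment(rbind(c(k, 5 - k), c(5 - k, k)))$p_value)
  expect_true(all(diff(p_seq) < 0))
  expect_error(fisher_enrichment(rbind(c(-1, 1), c(1, 1))), "negative")
  expect_error(fisher_enrichment(rbind(c(1.5, 1), c(1, 1))), "integers")
  # randomized tables match both the enumeration oracle and fisher.test
  set.seed(15)
  for (rep in 1:200) {
    tab <- matrix(rpois(4, 6), 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    got <- fisher_enrichment(tab)
    expect_equal(got$p_value,
                 oracle_fisher_greater(tab[1, 1], tab[1, 2], tab[2, 1],
                                       tab[2, 2]),
                 tolerance = 1e-12)
    expect_equal(got$p_value,
                 stats::fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
})

test_that("set enrichment builds the median-split table and detects planted enrichment", {
  scores <- data.table(factor_name = sprintf("F%02d", 1:20),
                       S = c(rep(2, 8), rep(0.1, 12)))
  fs <- factor_set("hot", sprintf("F%02d", 1:8))
  res <- set_enrichment_test(scores, fs)
  expect_lt(res$p_value, 0.01)
  expect_equal(res$table[1, 1], 8L)
})
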