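# Additive feature attributions (TreeSHAP for boosted trees), factor- and
# group-level aggregation, minimal influential-factor-set selection and
# Fisher enrichment.

#' Per-transcript additive feature attributions
#'
#' For boosted-tree fits, exact tree-path additive attributions
#' (TreeSHAP) are computed: for every transcript the base value plus the
#' per-feature attributions equals the model prediction. Ridge fits get
#' linear attributions `coef_j * (x_ij - mean(x_j))` around the training
#' column means. Random-forest fits are not supported.
#'
#' @param fit a `pause_fit` from [train_model()].
#' @param X feature matrix to explain.
#' @return A list of class `contribution_table`: `phi` (matrix
#'   transcripts x features), `phi0` (per-transcript base value) and
#'   `predictions`.
#' @export
compute_attributions <- function(fit, X) {
  X <- check_columns(fit, X)
  if (fit$learner %in% c("xgb", "gbdt")) {
    ctr <- predict(fit$model, X, predcontrib = TRUE)
    nc <- ncol(ctr)
    phi <- ctr[, -nc, drop = FALSE]
    colnames(phi) <- fit$feature_names
    phi0 <- ctr[, nc]
  } else if (fit$learner == "ridge") {
    b <- as.matrix(coef(fit$model, s = "lambda.min"))
    beta <- b[-1L, 1L][fit$feature_names]
    mu <- fit$train_col_means[fit$feature_names]
    phi <- sweep(X, 2L, mu) * rep(beta, each = nrow(X))
    phi0 <- rep(b[1L, 1L] + sum(beta * mu), nrow(X))
  } else {
    stop("attributions are only defined for tree-boosting and ridge fits")
  }
  rownames(phi) <- rownames(X)
  preds <- predict(fit, X)
  structure(list(phi = phi, phi0 = phi0, predictions = preds),
            class = "contribution_table")
}

#' Check attribution additivity
#'
#' @param ct a `contribution_table`.
#' @param tol relative tolerance (default 1e-4).
#' @return `TRUE` invisibly; violation is an error.
#' @export
check_additivity <- function(ct, tol = 1e-4) {
  recon <- ct$phi0 + rowSums(ct$phi)
  rel <- abs(recon - ct$predictions) / pmax(abs(ct$predictions), 1)
  if (any(rel > tol))
    stop(sprintf("additivity violated: max relative error %.2e", max(rel)))
  invisible(TRUE)
}

#' Aggregate attributions to per-factor contribution scores
#'
#' The contribution score of a factor is the sum, over all of its
#' binding columns (all assays, regions and proximal-ncRNA ranks), of
#' the mean absolute per-transcript attribution of that column.
#' Annotation columns aggregate into the pseudo-factor `"annotation"`.
#' Shares are computed either over binding factors only (default; the
#' annotation block is reported separately) or over all features.
#'
#' @param ct a `contribution_table`.
#' @param meta column metadata (`fm$meta`); unmapped columns are an
#'   error.
#' @param share_base `"factors"` (default) or `"all"`.
#' @param signed use the mean signed attribution instead of mean
#'   absolute (default `FALSE`).
#' @return `data.table(factor_name, S, share)` sorted by decreasing `S`;
#'   shares over the chosen base sum to 1.
#' @export
aggregate_by_factor <- function(ct, meta, share_base = c("factors", "all"),
                                signed = FALSE) {
  share_base <- match.arg(share_base)
  cols <- colnames(ct$phi)
  m <- as.data.table(meta)[match(cols, name)]
  if (any(is.na(m$kind)))
    stop("columns missing from metadata: ",
         paste(head(cols[is.na(m$kind)], 5L), collapse = ", "))
  colscore <- if (signed) colMeans(ct$phi) else colMeans(abs(ct$phi))
  m[, factor_agg := fifelse(kind == "binding", factor_name, "annotation")]
  agg <- m[, .(S = sum(colscore[match(name, cols)])), by = factor_agg]
  setnames(agg, "factor_agg", "factor_name")
  base_total <- if (share_base == "factors") {
    sum(agg[factor_name != "annotation"]$S)
  } else sum(agg$S)
  agg[, share := fifelse(factor_name == "annotation" & share_base == "factors",
                         NA_real_, S / base_total)]
  setorder(agg, -S)
  agg[]
}

#' Aggregate contribution scores by group
#'
#' Groups factor-level scores by functional set, or column-level scores
#' by binding mode (assay x region). Factors belonging to several
#' functional sets are counted in each (sets overlap).
#'
#' @param scores `data.table(factor_name, S)` from
#'   [aggregate_by_factor()], or a `contribution_table` together with
#'   `meta` for `by = "binding_mode"`.
#' @param grouping for `by = "factor_set"`: named list of
#'   [factor_set()]s; ignored for binding modes.
#' @param by `"factor_set"` or `"binding_mode"`.
#' @param ct,meta required for `by = "binding_mode"`.
#' @return `data.table(group, S)`.
#' @export
aggregate_by_group <- function(scores = NULL, grouping = NULL,
                               by = c("factor_set", "binding_mode"),
                               ct = NULL, meta = NULL) {
  by <- match.arg(by)
  if (by == "factor_set") {
    out <- rbindlist(lapply(names(grouping), function(nm) {
      data.table(group = nm,
                 S = sum(scores[factor_name %in% grouping[[nm]]$members]$S))
    }))
    return(out[])
  }
  m <- as.data.table(meta)[match(colnames(ct$phi), name)]
  colscore <- colMeans(abs(ct$phi))
  m[, group := fifelse(kind == "annotation", "annotation",
                       paste(fifelse(assay == "chip", "DNA", "RNA"), region,
                             fifelse(is.na(rank), "", "proximal.ncRNA"),
                             sep = "."))]
  m[, group := sub("\\.$", "", group)]
  m[, .(S = sum(colscore[match(name, colnames(ct$phi))])), by = group][]
}

#' Select the minimal most-influential factor set
#'
#' Sorts factors by decreasing contribution share (ties broken
#' lexicographically) and returns the shortest prefix whose cumulative
#' share reaches the target.
#'
#' @param shares `data.table(factor_name, share)`; the annotation
#'   pseudo-factor (share `NA`) is ignored.
#' @param target_share cumulative share to reach, in (0, 1]; default 0.5.
#' @return `data.table(factor_name, share, cumulative)` of the selected
#'   prefix, in rank order.
#' @export
select_minimal_factor_set <- function(shares, target_share = 0.5) {
  if (!(target_share > 0 && target_share <= 1))
    stop("target_share must be in (0, 1]")
  sh <- as.data.table(shares)[!is.na(share)]
  if (any(sh$share < 0)) stop("negative shares")
  setorder(sh, -share, factor_name)
  sh[, cumulative := cumsum(share)]
  k <- which(sh$cumulative >= target_share)[1L]
  if (is.na(k)) k <- nrow(sh)
  sh[seq_len(k), .(factor_name, share, cumulative)]
}

#' One-sided Fisher's exact test on a 2x2 table
#'
#' Computes the conditional (hypergeometric) exact p-value for the
#' `"greater"` alternative and the sample odds ratio `ad / bc` (0-cell
#' convention: `x/0` is `Inf`, `0/0` is `NaN`).
#'
#' @param table 2x2 non-negative integer matrix
#'   `rbind(c(a, b), c(c, d))`.
#' @param alternative only `"greater"` is offered (enrichment).
#' @return List with `odds_ratio` and `p_value`.
#' @export
fisher_enrichment <- function(table, alternative = "greater") {
  stopifnot(identical(dim(table), c(2L, 2L)) || all(dim(table) == 2))
  if (any(table < 0)) stop("negative counts")
  if (any(table != round(table))) stop("counts must be integers")
  a <- table[1, 1]; b <- table[1, 2]; cc <- table[2, 1]; d <- table[2, 2]
  # P(X >= a) with X ~ Hypergeom(m = a+b, n = c+d, k = a+c)
  p <- phyper(a - 1, a + b, cc + d, a + cc, lower.tail = FALSE)
  or <- (a * d) / (b * cc)
  list(odds_ratio = or, p_value = p)
}

#' Enrichment of a factor set among top contributors
#'
#' Builds the 2x2 table of set membership against above-median group
#' contribution and runs the one-sided Fisher test: are members of the
#' set (e.g. splicing factors) enriched among factors whose score for a
#' binding-mode group (e.g. RNA-intron) exceeds the across-factor
#' median?
#'
#' @param factor_scores `data.table(factor_name, S)` restricted to the
#'   group of interest.
#' @param fs a [factor_set()].
#' @return The [fisher_enrichment()] result plus the table used.
#' @export
set_enrichment_test <- function(factor_scores, fs) {
  sc <- as.data.table(factor_scores)
  top <- sc$S > median(sc$S)
  member <- sc$factor_name %in% fs$members
  tab <- rbind(c(sum(top & member), sum(top & !member)),
               c(sum(!top & member), sum(!top & !member)))
  res <- fisher_enrichment(tab)
  c(res, list(table = tab))
}
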