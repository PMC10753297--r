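## Filtering, normalization, imputation and variance stabilization of
## features x samples abundance tables. Missing values are NA; by
## convention (configurable in the workflows) exact zeros in glycomics
## tables are treated as non-detections, i.e. missing.

.check_groups <- function(m, groups) {
  if (is.null(groups)) stop("group labels required", call. = FALSE)
  if (!is.null(names(groups)) && !is.null(colnames(m))) {
    if (!all(colnames(m) %in% names(groups))) {
      stop("group labels missing for sample(s): ",
           paste(setdiff(colnames(m), names(groups)), collapse = ", "),
           call. = FALSE)
    }
    groups <- groups[colnames(m)]
  }
  if (length(groups) != ncol(m)) {
    stop("group labels must cover all samples", call. = FALSE)
  }
  as.character(groups)
}

#' Remove features that are too sparsely observed
#'
#' Zeros are treated as missing marks for this rule. By default a feature is
#' dropped if it has missing/zero entries in more than half the replicates
#' of any group; if `minSamples` is given, a feature is kept only if at
#' least `minSamples` replicates per group are nonzero.
#'
#' @param x features x samples matrix or [GlycomicsExperiment-class].
#' @param groups per-sample group labels (taken from the experiment's
#'   colData when omitted).
#' @param minSamples optional integer threshold of nonzero replicates
#'   required per group.
#' @return filtered object of the same kind.
#' @export
filterSparseFeatures <- function(x, groups = NULL, minSamples = NULL) {
  m <- .as_matrix(x)
  if (is.null(groups) && is(x, "GlycomicsExperiment")) {
    groups <- sampleGroups(x)
  }
  groups <- .check_groups(m, groups)
  obs <- !is.na(m) & m != 0
  keep <- rep(TRUE, nrow(m))
  for (g in unique(groups)) {
    sel <- groups == g
    n_obs <- rowSums(obs[, sel, drop = FALSE])
    keep <- keep & if (is.null(minSamples)) {
      (sum(sel) - n_obs) <= sum(sel) / 2  # missing in more than half -> drop
    } else {
      n_obs >= minSamples
    }
  }
  if (!any(keep)) {
    stop("no feature passes the sparsity filter; relax minSamples or check ",
         "the missingness structure", call. = FALSE)
  }
  .like_input(x, m[keep, , drop = FALSE])
}

#' Normalize each sample to a total abundance of 100
#'
#' Divides every abundance by the total abundance of its sample (missing
#' values ignored in the total), so each column sums to 100. Idempotent.
#'
#' @param x features x samples matrix or [GlycomicsExperiment-class].
#' @return object of the same kind with column sums of 100.
#' @export
normalizeTotal <- function(x) {
  m <- .as_matrix(x)
  tot <- colSums(m, na.rm = TRUE)
  if (any(tot <= 0)) {
    stop("sample(s) with no positive abundance: ",
         paste(colnames(m)[tot <= 0], collapse = ", "), call. = FALSE)
  }
  .like_input(x, sweep(m, 2, tot, "/") * 100)
}

#' Iterative random-forest imputation of missing values
#'
#' MissForest-style imputation: missing positions are recorded and
#' initialized to their sample's median; then, in each of `iterations`
#' rounds and for each sample with missing values, a random-forest regressor
#' (100 trees, all predictors tried at each split, the usual
#' regression-forest defaults) is trained with the other samples' values as
#' predictors over
#' the features originally observed in that sample, and predicts that
#' sample's missing positions. Negative predictions are clipped at zero and
#' a small constant (1e-6) is finally added everywhere so that no zeros
#' remain; observed values are unchanged except for that constant shift.
#'
#' @param x features x samples matrix or [GlycomicsExperiment-class]
#'   (`NA` = missing); at least 2 samples.
#' @param iterations number of refinement rounds (default 5).
#' @param seed optional integer seed for exact reproducibility.
#' @param num.trees trees per forest (default 100).
#' @return completed object of the same kind, strictly positive.
#' @export
imputeMissForest <- function(x, iterations = 5L, seed = NULL,
                             num.trees = 100L) {
  m <- .as_matrix(x)
  if (ncol(m) < 2L) stop("imputation requires at least 2 samples",
                         call. = FALSE)
  if (any(colSums(!is.na(m)) == 0L)) {
    stop("sample(s) with no observed values cannot be imputed",
         call. = FALSE)
  }
  if (any(rowSums(!is.na(m)) == 0L)) {
    stop("feature(s) missing everywhere; apply filterSparseFeatures first",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  miss <- is.na(m)
  filled <- m
  for (j in seq_len(ncol(m))) {
    if (any(miss[, j])) {
      filled[miss[, j], j] <- stats::median(m[!miss[, j], j])
    }
  }
  if (!any(miss)) return(.like_input(x, filled + 1e-6))
  for (it in seq_len(iterations)) {
    for (j in seq_len(ncol(m))) {
      mj <- miss[, j]
      if (!any(mj)) next
      pred <- as.data.frame(filled[, -j, drop = FALSE])
      colnames(pred) <- paste0("s", seq_len(ncol(pred)))
      fit <- ranger::ranger(
        x = pred[!mj, , drop = FALSE], y = filled[!mj, j],
        num.trees = num.trees, mtry = ncol(pred), min.node.size = 2L,
        num.threads = 1L,
        seed = sample.int(.Machine$integer.max, 1L))
      filled[mj, j] <- stats::predict(
        fit, data = pred[mj, , drop = FALSE],
        num.threads = 1L)$predictions
    }
  }
  filled[filled < 0] <- 0
  .like_input(x, filled + 1e-6)
}

#' Variance-stabilizing normalization
#'
#' Log2-transforms strictly positive abundances, then standardizes each
#' feature. Without `groups`, each feature is centered and scaled by its
#' mean and standard deviation across all samples (rows come out with mean
#' 0, sd 1). With `groups` (the form used before between-group testing),
#' each feature is centered by the grand mean of its group means and scaled
#' by the pooled within-group standard deviation, which equalizes
#' within-group variance while preserving between-group location
#' differences. Features with zero scale are dropped with a warning.
#'
#' @param x features x samples matrix or [GlycomicsExperiment-class], all
#'   values > 0 (impute first).
#' @param groups optional per-sample group labels.
#' @return a plain numeric matrix of transformed values.
#' @export
varianceStabilize <- function(x, groups = NULL) {
  m <- .as_matrix(x)
  if (is.null(groups) && is(x, "GlycomicsExperiment")) {
    groups <- sampleGroups(x)
  }
  if (anyNA(m) || any(m <= 0)) {
    stop("variance stabilization requires strictly positive values; ",
         "run imputeMissForest first", call. = FALSE)
  }
  l <- log2(m)
  if (is.null(groups)) {
    mu <- rowMeans(l)
    sdv <- sqrt(rowSums((l - mu)^2) / (ncol(l) - 1L))
    ctr <- mu
  } else {
    groups <- .check_groups(m, groups)
    gl <- unique(groups)
    gm <- vapply(gl, function(g) {
      rowMeans(l[, groups == g, drop = FALSE])
    }, numeric(nrow(l)))
    gm <- matrix(gm, nrow = nrow(l))
    ctr <- rowMeans(gm)  # grand mean of group means
    ssw <- 0
    for (k in seq_along(gl)) {
      sub <- l[, groups == gl[k], drop = FALSE]
      ssw <- ssw + rowSums((sub - gm[, k])^2)
    }
    sdv <- sqrt(ssw / (ncol(l) - length(gl)))  # pooled within-group sd
  }
  bad <- !is.finite(sdv) | sdv == 0
  if (any(bad)) {
    warning(sum(bad), " constant feature(s) dropped during variance ",
            "stabilization", call. = FALSE)
    l <- l[!bad, , drop = FALSE]
    ctr <- ctr[!bad]
    sdv <- sdv[!bad]
  }
  (l - ctr) / sdv
}

#' Remove features with negligible variance
#'
#' Applied on the relative-abundance (percent) scale before testing; the
#' default cutoff of 0.01 removes essentially constant features only.
#'
#' @param x features x samples matrix or [GlycomicsExperiment-class].
#' @param minVar minimum across-sample variance (default 0.01).
#' @return filtered object of the same kind.
#' @export
filterLowVariance <- function(x, minVar = 0.01) {
  m <- .as_matrix(x)
  v <- apply(m, 1L, stats::var, na.rm = TRUE)
  .like_input(x, m[!is.na(v) & v >= minVar | minVar <= 0, , drop = FALSE])
}
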