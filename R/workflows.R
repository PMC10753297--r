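## End-to-end analysis workflows: two-group differential expression,
## multi-group ANOVA with Tukey HSD post hoc tests, and time-series
## regression. All share the same preprocessing backbone:
## sparse-filter -> total-normalize -> impute -> (motif quantification) ->
## variance-filter -> log2FC -> variance stabilization -> tests -> BH.

# shared preprocessing; returns list(rel = relative-abundance matrix,
# groups = group labels aligned to columns)
.preprocess_pipeline <- function(m, groups, motifs, featureSets,
                                 motifLibrary, minSamples, minVar, impute,
                                 zerosAsMissing, seed) {
  if (is.null(names(groups))) names(groups) <- colnames(m)
  if (zerosAsMissing) m[m == 0] <- NA_real_
  m <- .as_matrix(filterSparseFeatures(m, groups, minSamples))
  m <- .as_matrix(normalizeTotal(m))
  if (impute) {
    # impute within each biological condition so that missing values are
    # never reconstructed from samples of the other group(s)
    for (g in unique(groups)) {
      cols <- colnames(m)[groups[colnames(m)] == g]
      if (anyNA(m[, cols])) {
        m[, cols] <- .as_matrix(imputeMissForest(m[, cols, drop = FALSE],
                                                 seed = seed))
      } else {
        m[, cols] <- m[, cols] + 1e-6
      }
    }
  } else {
    # naive no-imputation arm: non-detections enter as zeros
    m[is.na(m)] <- 0
    m <- m + 1e-6
  }
  if (motifs) {
    parseable <- vapply(rownames(m), function(s) {
      tryCatch({
        suppressWarnings(parseGlycan(s))
        TRUE
      }, error = function(e) FALSE)
    }, logical(1))
    if (!all(parseable)) {
      warning(sum(!parseable), " feature(s) not parseable as glycans; ",
              "excluded from motif quantification", call. = FALSE)
      m <- m[parseable, , drop = FALSE]
    }
    m <- .as_matrix(quantifyMotifs(m, featureSets = featureSets,
                                   motifLibrary = motifLibrary))
  }
  m <- .as_matrix(filterLowVariance(m, minVar))
  m
}

.resolve_two_groups <- function(m, group1, group2) {
  cols <- colnames(m)
  pick <- function(g) {
    if (is.numeric(g)) cols[g] else as.character(g)
  }
  g1 <- pick(group1)
  g2 <- pick(group2)
  unknown <- setdiff(c(g1, g2), cols)
  if (length(unknown)) {
    stop("unknown sample(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (length(intersect(g1, g2))) {
    stop("groups overlap: ", paste(intersect(g1, g2), collapse = ", "),
         call. = FALSE)
  }
  if (length(g1) < 2L || length(g2) < 2L) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  list(g1 = g1, g2 = g2)
}

#' Two-group differential expression analysis
#'
#' Full workflow on a glycan (or motif) abundance table: sparsity filtering,
#' total normalization, random-forest imputation, optional proportional
#' motif quantification, variance filtering, log2 fold changes of group
#' means on the relative scale, group-aware variance stabilization, then
#' per-feature Welch (or paired) t-tests with Cohen's d (or d_z) — or, with
#' `sets = TRUE`, Hotelling's T2 with Mahalanobis effect sizes for each
#' multi-feature correlation set and univariate tests for singletons —
#' plus Levene's test per feature. Benjamini-Hochberg correction is applied
#' separately to the test p values and to the Levene p values.
#'
#' @param x features x samples matrix or [GlycomicsExperiment-class]
#'   (relative abundances; `NA` or, with `zerosAsMissing`, 0 = missing).
#' @param group1,group2 disjoint vectors of sample names (or column
#'   indices); `group2` is the case/treatment — log2 fold changes are
#'   `log2(mean(group2) / mean(group1))`.
#' @param motifs quantify motifs before testing (row names must be glycan
#'   strings).
#' @param featureSets,motifLibrary see [annotateDataset()].
#' @param paired paired design (equal sizes, matched order).
#' @param sets analyze correlation-network sets multivariately.
#' @param minSamples,minVar see [filterSparseFeatures()],
#'   [filterLowVariance()].
#' @param impute random-forest imputation (`FALSE` = treat missing as zero,
#'   the naive practice this workflow is designed to replace).
#' @param zerosAsMissing treat exact zeros as non-detections.
#' @param corThreshold correlation threshold for set construction.
#' @param nBoot bootstrap resamples for the Mahalanobis variance.
#' @param seed optional integer seed (imputation + bootstrap).
#' @return data.frame with one row per feature or set: `feature`, `log2fc`,
#'   `statistic`, `p`, `p_adj`, `effect_size`, `effect_variance`,
#'   `effect_kind`, `levene_p`, `levene_p_adj`, `is_set`, `set_members`
#'   (`;`-separated), ordered by ascending `p_adj` then feature.
#' @examples
#' sim <- simulateGlycomes(nGlycans = 30, nReplicates = 5, nEffects = 3,
#'                         glycans = NA, seed = 7)
#' res <- getDifferentialExpression(
#'   cbind(abundances(sim$control), abundances(sim$test)),
#'   group1 = colnames(abundances(sim$control)),
#'   group2 = colnames(abundances(sim$test)), seed = 7)
#' head(res)
#' @export
getDifferentialExpression <- function(x, group1, group2, motifs = FALSE,
                                      featureSets = c("known", "terminal",
                                                      "exhaustive"),
                                      paired = FALSE, sets = FALSE,
                                      minSamples = NULL, minVar = 0.01,
                                      impute = TRUE, zerosAsMissing = TRUE,
                                      motifLibrary = NULL,
                                      corThreshold = 0.9, nBoot = 1000L,
                                      seed = NULL) {
  m <- .as_matrix(x)
  gg <- .resolve_two_groups(m, group1, group2)
  if (paired && length(gg$g1) != length(gg$g2)) {
    stop("paired design requires equal group sizes", call. = FALSE)
  }
  m <- m[, c(gg$g1, gg$g2), drop = FALSE]
  groups <- stats::setNames(rep(c("group1", "group2"),
                                c(length(gg$g1), length(gg$g2))),
                            colnames(m))
  if (!is.null(seed)) set.seed(seed)
  rel <- .preprocess_pipeline(m, groups, motifs, featureSets, motifLibrary,
                              minSamples, minVar, impute, zerosAsMissing,
                              seed = NULL)
  i1 <- colnames(rel) %in% gg$g1
  i2 <- colnames(rel) %in% gg$g2
  log2fc <- log2(rowMeans(rel[, i2, drop = FALSE]) /
                   rowMeans(rel[, i1, drop = FALSE]))
  vst <- suppressWarnings(varianceStabilize(rel, groups[colnames(rel)]))
  log2fc <- log2fc[rownames(vst)]
  feats <- rownames(vst)
  # per-feature Levene on the variance-stabilized values
  lev <- vapply(feats, function(f) {
    leveneVarianceTest(vst[f, i1], vst[f, i2])$p
  }, numeric(1))
  lev_adj <- benjaminiHochberg(lev)
  run_uni <- function(members) {
    do.call(rbind, lapply(members, function(f) {
      tt <- welchTTest(vst[f, i1], vst[f, i2], paired = paired)
      es <- tryCatch(cohenEffectSize(vst[f, i1], vst[f, i2],
                                     paired = paired),
                     error = function(e) list(value = NA_real_,
                                              variance = NA_real_,
                                              kind = if (paired) "d_z" else
                                                "d"))
      data.frame(feature = f, log2fc = log2fc[f],
                 statistic = tt$statistic, p = tt$p,
                 effect_size = es$value, effect_variance = es$variance,
                 effect_kind = es$kind, levene_p = lev[f],
                 levene_p_adj = lev_adj[f], is_set = FALSE,
                 set_members = f, stringsAsFactors = FALSE)
    }))
  }
  if (sets) {
    comp <- buildCorrelationSets(vst, corThreshold)
    rows <- lapply(comp, function(members) {
      if (length(members) == 1L) return(run_uni(members))
      X <- t(vst[members, i1, drop = FALSE])
      Y <- t(vst[members, i2, drop = FALSE])
      ht <- hotellingT2(X, Y)
      es <- mahalanobisEffect(X, Y, nBoot = nBoot)
      data.frame(
        feature = paste(members, collapse = ";"),
        log2fc = mean(log2fc[members]), statistic = ht$T2, p = ht$p,
        effect_size = es$value, effect_variance = es$variance,
        effect_kind = "mahalanobis",
        levene_p = min(lev[members]),
        levene_p_adj = min(lev_adj[members]), is_set = TRUE,
        set_members = paste(members, collapse = ";"),
        stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, rows)
  } else {
    res <- run_uni(feats)
  }
  res$p_adj <- benjaminiHochberg(res$p)
  res <- res[, c("feature", "log2fc", "statistic", "p", "p_adj",
                 "effect_size", "effect_variance", "effect_kind",
                 "levene_p", "levene_p_adj", "is_set", "set_members")]
  res <- res[order(res$p_adj, res$feature), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Multi-group ANOVA on glycans or motifs
#'
#' Same preprocessing as [getDifferentialExpression()] (variance
#' stabilization uses all groups), then a per-feature one-way ANOVA with
#' Benjamini-Hochberg correction across features; features with adjusted
#' p < `alphaLevel` trigger Tukey HSD tests over all group pairs, whose
#' family-wise adjusted p values below `alphaLevel` mark significant pairs.
#'
#' @inheritParams getDifferentialExpression
#' @param groups per-sample group labels (>= 3 groups, >= 2 replicates
#'   each); taken from the experiment's colData when omitted.
#' @param alphaLevel significance threshold (default 0.05).
#' @return list with `anova` (feature, F, p, p_adj) and `posthoc` (feature,
#'   group1, group2, diff, p_tukey, significant).
#' @export
getGlycanova <- function(x, groups = NULL, motifs = FALSE,
                         featureSets = c("known", "terminal", "exhaustive"),
                         minSamples = NULL, minVar = 0.01, impute = TRUE,
                         zerosAsMissing = TRUE, motifLibrary = NULL,
                         alphaLevel = 0.05, seed = NULL) {
  m <- .as_matrix(x)
  if (is.null(groups) && is(x, "GlycomicsExperiment")) {
    groups <- sampleGroups(x)
  }
  groups <- .check_groups(m, groups)
  tab <- table(groups)
  if (length(tab) < 3L) {
    stop("ANOVA requires at least 3 groups; use ",
         "getDifferentialExpression for two", call. = FALSE)
  }
  if (any(tab < 2L)) stop("every group needs >= 2 replicates",
                          call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  rel <- .preprocess_pipeline(m, groups, motifs, featureSets, motifLibrary,
                              minSamples, minVar, impute, zerosAsMissing,
                              seed = NULL)
  vst <- suppressWarnings(varianceStabilize(rel, groups))
  gf <- factor(groups)
  fits <- lapply(rownames(vst), function(f) {
    stats::aov(vst[f, ] ~ gf)
  })
  an <- do.call(rbind, lapply(seq_along(fits), function(i) {
    a <- stats::anova(fits[[i]])
    data.frame(feature = rownames(vst)[i], F = a[["F value"]][1L],
               p = a[["Pr(>F)"]][1L], stringsAsFactors = FALSE)
  }))
  an$p_adj <- benjaminiHochberg(an$p)
  an <- an[order(an$p_adj, an$feature), , drop = FALSE]
  rownames(an) <- NULL
  sig <- an$feature[!is.na(an$p_adj) & an$p_adj < alphaLevel]
  posthoc <- NULL
  for (f in sig) {
    tk <- stats::TukeyHSD(fits[[match(f, rownames(vst))]])$gf
    cmp <- strsplit(rownames(tk), "-", fixed = TRUE)
    posthoc <- rbind(posthoc, data.frame(
      feature = f,
      group1 = vapply(cmp, `[`, "", 2L),
      group2 = vapply(cmp, `[`, "", 1L),
      diff = tk[, "diff"], p_tukey = tk[, "p adj"],
      significant = tk[, "p adj"] < alphaLevel,
      stringsAsFactors = FALSE))
  }
  if (is.null(posthoc)) {
    posthoc <- data.frame(feature = character(0), group1 = character(0),
                          group2 = character(0), diff = numeric(0),
                          p_tukey = numeric(0), significant = logical(0))
  }
  rownames(posthoc) <- NULL
  list(anova = an, posthoc = posthoc)
}

#' Time-series regression on glycans or motifs
#'
#' Same preprocessing as the other workflows (variance stabilization
#' without groups), then per feature an ordinary least-squares fit of
#' abundance against time. For `degree = 1` the slope is tested with a t
#' test; for `degree > 1` a polynomial of the requested degree is compared
#' with an intercept-only model by an F test. Replicates at a timepoint
#' (e.g. donors) are pooled into one regression. Benjamini-Hochberg
#' correction is applied across features.
#'
#' @inheritParams getDifferentialExpression
#' @param timepoints numeric timepoints, one per sample (>= 3 distinct
#'   values; taken from the experiment's colData when omitted).
#' @param degree polynomial degree (1 = linear; must be below the number of
#'   distinct timepoints).
#' @return data.frame with `feature`, coefficient columns `beta0..betaD`,
#'   `statistic`, `p`, `p_adj`, `degree`, ordered by ascending `p_adj`.
#' @export
getTimeSeries <- function(x, timepoints = NULL, motifs = FALSE,
                          featureSets = c("known", "terminal",
                                          "exhaustive"),
                          degree = 1L, minSamples = NULL, minVar = 0.01,
                          impute = TRUE, zerosAsMissing = TRUE,
                          motifLibrary = NULL, seed = NULL) {
  m <- .as_matrix(x)
  if (is.null(timepoints) && is(x, "GlycomicsExperiment")) {
    timepoints <- timePoints(x)
  }
  if (is.null(timepoints)) stop("timepoints required", call. = FALSE)
  if (!is.null(names(timepoints))) timepoints <- timepoints[colnames(m)]
  stopifnot(length(timepoints) == ncol(m))
  tp <- as.numeric(timepoints)
  n_distinct <- length(unique(tp))
  if (n_distinct < 3L) stop(">= 3 distinct timepoints required",
                            call. = FALSE)
  if (degree >= n_distinct) {
    stop("degree must be below the number of distinct timepoints",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  # sparsity rule applied over all samples as one group
  rel <- .preprocess_pipeline(m, stats::setNames(rep("all", ncol(m)),
                                                 colnames(m)),
                              motifs, featureSets, motifLibrary,
                              minSamples, minVar, impute, zerosAsMissing,
                              seed = NULL)
  vst <- suppressWarnings(varianceStabilize(rel))
  res <- do.call(rbind, lapply(rownames(vst), function(f) {
    y <- vst[f, ]
    fit <- stats::lm(y ~ stats::poly(tp, degree, raw = TRUE))
    cf <- stats::coef(fit)
    if (degree == 1L) {
      sm <- summary(fit)$coefficients
      stat <- sm[2L, "t value"]
      p <- sm[2L, "Pr(>|t|)"]
    } else {
      a <- stats::anova(stats::lm(y ~ 1), fit)
      stat <- a$F[2L]
      p <- a$`Pr(>F)`[2L]
    }
    out <- data.frame(feature = f, stringsAsFactors = FALSE)
    for (d in 0:degree) out[[paste0("beta", d)]] <- unname(cf[d + 1L])
    out$statistic <- stat
    out$p <- p
    out
  }))
  res$p_adj <- benjaminiHochberg(res$p)
  res$degree <- degree
  res <- res[order(res$p_adj, res$feature), , drop = FALSE]
  rownames(res) <- NULL
  res
}
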