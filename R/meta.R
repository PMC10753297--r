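## Fixed-effects and DerSimonian-Laird random-effects meta-analysis of
## per-study effect sizes (Cohen's d with variance), with forest-plot data.

.check_effects <- function(d, varD) {
  stopifnot(length(d) == length(varD), length(d) >= 1L)
  if (any(!is.finite(d)) || any(!is.finite(varD))) {
    stop("effect sizes and variances must be finite", call. = FALSE)
  }
  if (any(varD <= 0)) {
    stop("effect size variances must be positive", call. = FALSE)
  }
  invisible(TRUE)
}

#' Fixed-effects (inverse-variance) meta-analysis
#'
#' Combines per-study effect sizes weighted by the inverse of their
#' variances: `d = sum(w_i d_i) / sum(w_i)` with `w_i = 1/var_i`,
#' `se = sqrt(1/sum(w_i))`, and a two-tailed normal p value for `d/se`.
#'
#' @param d numeric vector of study effect sizes.
#' @param varD numeric vector of their (positive) variances.
#' @return list with `d_combined`, `se_combined`, `p`, `tau2` (0), `k`.
#' @examples
#' fixedEffectsMeta(c(0.5, 1.0), c(0.1, 0.1))$d_combined  # 0.75
#' @export
fixedEffectsMeta <- function(d, varD) {
  .check_effects(d, varD)
  w <- 1 / varD
  dc <- sum(w * d) / sum(w)
  se <- sqrt(1 / sum(w))
  list(d_combined = dc, se_combined = se,
       p = 2 * stats::pnorm(-abs(dc / se)), tau2 = 0, k = length(d))
}

#' Random-effects meta-analysis (DerSimonian-Laird)
#'
#' Estimates the between-study variance as
#' `tau2 = max(0, (Q - (k - 1)) / (sum(w) - sum(w^2)/sum(w)))` with
#' `Q = sum(w_i (d_i - d_FE)^2)`, re-weights each study by
#' `1/(var_i + tau2)` and combines as in the fixed-effects model.
#'
#' @inheritParams fixedEffectsMeta
#' @return list with `d_combined`, `se_combined`, `p`, `tau2`, `k`.
#' @export
randomEffectsMeta <- function(d, varD) {
  .check_effects(d, varD)
  k <- length(d)
  if (k < 2L) stop("random-effects model requires at least 2 studies",
                   call. = FALSE)
  w <- 1 / varD
  d_fe <- sum(w * d) / sum(w)
  Q <- sum(w * (d - d_fe)^2)
  c_dl <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - (k - 1)) / c_dl)
  ws <- 1 / (varD + tau2)
  dc <- sum(ws * d) / sum(ws)
  se <- sqrt(1 / sum(ws))
  list(d_combined = dc, se_combined = se,
       p = 2 * stats::pnorm(-abs(dc / se)), tau2 = tau2, k = k)
}

#' Meta-analysis across per-study differential expression results
#'
#' Collects per-feature effect sizes and variances from several study-level
#' result tables (as returned by [getDifferentialExpression()], or any
#' data.frame with columns `feature`, `effect_size`, `effect_variance`),
#' combines every feature present in at least one study (`k = 1` features
#' are reported under the fixed model; the random-effects model needs two
#' studies and falls back to the single-study estimate with `tau2 = 0`
#' otherwise), and applies Benjamini-Hochberg correction across all
#' combined features. Features are matched across studies by their exact
#' canonical name.
#'
#' @param studies named list of study result data.frames.
#' @param model `"fixed"` or `"random"`.
#' @param forestOutput optional CSV path; per-feature forest-plot data
#'   (per-study d with 95% CI, combined d, adjusted p) are written there.
#' @return data.frame with one row per feature: `feature`, `d_combined`,
#'   `se_combined`, `tau2`, `k`, `p`, `p_adj`.
#' @export
getMetaAnalysis <- function(studies, model = c("fixed", "random"),
                            forestOutput = NULL) {
  model <- match.arg(model)
  stopifnot(is.list(studies), length(studies) >= 1L)
  if (is.null(names(studies)) || any(!nzchar(names(studies)))) {
    names(studies) <- paste0("study", seq_along(studies))
  }
  long <- do.call(rbind, lapply(names(studies), function(s) {
    tab <- as.data.frame(studies[[s]])
    need <- c("feature", "effect_size", "effect_variance")
    if (!all(need %in% colnames(tab))) {
      stop("study '", s, "' lacks columns ",
           paste(setdiff(need, colnames(tab)), collapse = ", "),
           call. = FALSE)
    }
    data.frame(study_id = s, feature = tab$feature, d = tab$effect_size,
               var_d = tab$effect_variance, stringsAsFactors = FALSE)
  }))
  long <- long[is.finite(long$d) & is.finite(long$var_d) & long$var_d > 0, ,
               drop = FALSE]
  if (!nrow(long)) {
    warning("no usable effect sizes across studies", call. = FALSE)
    return(data.frame(feature = character(0), d_combined = numeric(0),
                      se_combined = numeric(0), tau2 = numeric(0),
                      k = integer(0), p = numeric(0), p_adj = numeric(0)))
  }
  feats <- sort(unique(long$feature))
  res <- do.call(rbind, lapply(feats, function(f) {
    sub <- long[long$feature == f, , drop = FALSE]
    fit <- if (model == "random" && nrow(sub) >= 2L) {
      randomEffectsMeta(sub$d, sub$var_d)
    } else {
      fixedEffectsMeta(sub$d, sub$var_d)
    }
    data.frame(feature = f, d_combined = fit$d_combined,
               se_combined = fit$se_combined, tau2 = fit$tau2, k = fit$k,
               p = fit$p, stringsAsFactors = FALSE)
  }))
  res$p_adj <- benjaminiHochberg(res$p)
  res <- res[order(res$p_adj, res$feature), , drop = FALSE]
  rownames(res) <- NULL
  if (!is.null(forestOutput)) {
    ci <- 1.96 * sqrt(long$var_d)
    forest <- data.frame(
      feature = long$feature, study_id = long$study_id, d = long$d,
      ci_low = long$d - ci, ci_high = long$d + ci,
      d_combined = res$d_combined[match(long$feature, res$feature)],
      p_adj = res$p_adj[match(long$feature, res$feature)],
      stringsAsFactors = FALSE)
    forest <- forest[order(forest$feature, forest$study_id), , drop = FALSE]
    utils::write.csv(forest, forestOutput, row.names = FALSE)
  }
  res
}
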