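## Univariate and multivariate tests, effect sizes with variances,
## multiple-testing correction and correlation-network feature sets.

#' Two-tailed Welch or paired t-test
#'
#' Unpaired: Welch's t with Welch-Satterthwaite degrees of freedom. Paired:
#' one-sample t on the differences. Degenerate inputs are handled by
#' convention: identical constant groups give statistic 0 and p = 1; a
#' constant nonzero paired difference gives p = 0 with `degenerate = TRUE`.
#'
#' @param x,y numeric sample vectors (length >= 2 each; equal lengths if
#'   paired). The statistic is oriented as `x` minus `y` (so a negative
#'   statistic means the second group is larger), matching the common
#'   two-sample convention.
#' @param paired logical.
#' @return list with `statistic`, `df`, `p` and `degenerate`.
#' @examples
#' welchTTest(c(1, 2, 3), c(4, 5, 6))
#' @export
welchTTest <- function(x, y, paired = FALSE) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  if (paired && length(x) != length(y)) {
    stop("paired test requires equal group sizes", call. = FALSE)
  }
  if (paired) {
    d <- x - y
    if (stats::sd(d) == 0) {
      if (all(d == 0)) {
        return(list(statistic = 0, df = length(d) - 1L, p = 1,
                    degenerate = TRUE))
      }
      return(list(statistic = sign(mean(d)) * Inf, df = length(d) - 1L,
                  p = 0, degenerate = TRUE))
    }
    tt <- stats::t.test(d)
    return(list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value, degenerate = FALSE))
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(statistic = 0, df = length(x) + length(y) - 2L, p = 1,
                  degenerate = TRUE))
    }
    return(list(statistic = sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2L, p = 0, degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}

#' Cohen's d / d_z with normal-theory variance
#'
#' Unpaired: `d = (mean(y) - mean(x)) / pooled sd` with variance
#' `(n1 + n2)/(n1 n2) + d^2 / (2 (n1 + n2))`. Paired:
#' `d_z = mean(y - x) / sd(y - x)` with variance `1/n + d_z^2 / (2 n)`.
#'
#' @inheritParams welchTTest
#' @return list with `value`, `variance` and `kind` (`"d"` or `"d_z"`).
#' @examples
#' cohenEffectSize(c(1, 2, 3), c(4, 5, 6))
#' @export
cohenEffectSize <- function(x, y, paired = FALSE) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  if (paired) {
    if (length(x) != length(y)) {
      stop("paired effect size requires equal group sizes", call. = FALSE)
    }
    d <- y - x
    n <- length(d)
    s <- stats::sd(d)
    if (s == 0) stop("degenerate paired differences (sd = 0)", call. = FALSE)
    dz <- mean(d) / s
    return(list(value = dz, variance = 1 / n + dz^2 / (2 * n),
                kind = "d_z"))
  }
  n1 <- length(x)
  n2 <- length(y)
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
               (n1 + n2 - 2))
  if (sp == 0) stop("degenerate groups (pooled sd = 0)", call. = FALSE)
  d <- (mean(y) - mean(x)) / sp
  list(value = d,
       variance = (n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)),
       kind = "d")
}

# pooled covariance and mean difference for two sample matrices
# (rows = samples, columns = features)
.pooled_cov <- function(X, Y) {
  n1 <- nrow(X)
  n2 <- nrow(Y)
  S <- ((n1 - 1) * stats::cov(X) + (n2 - 1) * stats::cov(Y)) / (n1 + n2 - 2)
  list(S = S, delta = colMeans(Y) - colMeans(X), n1 = n1, n2 = n2)
}

.quad_form_inv <- function(S, delta) {
  k <- length(delta)
  Si <- tryCatch(solve(S), error = function(e) NULL)
  rank <- k
  if (is.null(Si)) {
    warning("singular pooled covariance; using Moore-Penrose pseudo-inverse",
            call. = FALSE)
    Si <- MASS::ginv(S)
    rank <- qr(S)$rank
  }
  list(q = drop(t(delta) %*% Si %*% delta), rank = rank)
}

#' Hotelling's T-squared test for two multivariate groups
#'
#' `T2 = n1 n2 / (n1 + n2) * delta' S^-1 delta` with pooled covariance `S`;
#' the exact F transform `F = T2 (n - k - 1) / (k (n - 2))` with
#' `n = n1 + n2` is referred to an F(k, n - k - 1) distribution. If `S` is
#' singular (or group sizes are too small for full rank), a Moore-Penrose
#' pseudo-inverse is used with a warning and the effective rank replaces
#' `k`.
#'
#' @param X,Y numeric matrices with samples in rows and the same features in
#'   columns.
#' @return list with `T2`, `F`, `df1`, `df2` and `p`.
#' @examples
#' hotellingT2(cbind(c(1, 2, 3)), cbind(c(4, 5, 6)))
#' @export
hotellingT2 <- function(X, Y) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y)) stop("feature dimensions differ", call. = FALSE)
  if (ncol(X) == 0L) stop("empty feature set", call. = FALSE)
  pc <- .pooled_cov(X, Y)
  n <- pc$n1 + pc$n2
  if (all(pc$delta == 0) && all(pc$S == 0)) {
    return(list(T2 = 0, F = 0, df1 = ncol(X), df2 = max(n - ncol(X) - 1, 1),
                p = 1))
  }
  qf <- .quad_form_inv(pc$S, pc$delta)
  k <- qf$rank
  if (n - 2 < k) {
    warning("sample size small relative to set size; effective rank used",
            call. = FALSE)
    k <- max(min(k, n - 2L), 1L)
  }
  T2 <- pc$n1 * pc$n2 / n * qf$q
  Fstat <- T2 * (n - k - 1) / (k * (n - 2))
  df2 <- n - k - 1
  p <- if (df2 > 0 && is.finite(Fstat)) {
    stats::pf(Fstat, k, df2, lower.tail = FALSE)
  } else NA_real_
  list(T2 = T2, F = Fstat, df1 = k, df2 = df2, p = p)
}

#' Mahalanobis distance effect size with bootstrap variance
#'
#' `value = sqrt(delta' S^-1 delta)` (pooled covariance); its variance is
#' estimated by bootstrapping samples with replacement within each group
#' (default N = 1000) and taking the variance of the recomputed distances.
#' For a single feature the distance reduces to |Cohen's d|.
#'
#' @inheritParams hotellingT2
#' @param nBoot number of bootstrap resamples.
#' @param seed optional integer seed (fixed seed reproduces the variance
#'   exactly).
#' @return list with `value`, `variance` and `kind = "mahalanobis"`.
#' @export
mahalanobisEffect <- function(X, Y, nBoot = 1000L, seed = NULL) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y)) stop("feature dimensions differ", call. = FALSE)
  if (ncol(X) == 0L) stop("empty feature set", call. = FALSE)
  dist_of <- function(A, B) {
    pc <- .pooled_cov(A, B)
    if (all(pc$delta == 0)) return(0)
    q <- suppressWarnings(.quad_form_inv(pc$S, pc$delta)$q)
    sqrt(max(q, 0))
  }
  if (!is.null(seed)) set.seed(seed)
  val <- dist_of(X, Y)
  boots <- vapply(seq_len(nBoot), function(b) {
    dist_of(X[sample.int(nrow(X), replace = TRUE), , drop = FALSE],
            Y[sample.int(nrow(Y), replace = TRUE), , drop = FALSE])
  }, numeric(1))
  list(value = val, variance = stats::var(boots), kind = "mahalanobis")
}

#' Levene's test for equality of variances (Brown-Forsythe variant)
#'
#' One-way ANOVA on the absolute deviations from each group's median.
#'
#' @inheritParams welchTTest
#' @return list with `statistic` (F) and `p`.
#' @export
leveneVarianceTest <- function(x, y) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  z <- c(abs(x - stats::median(x)), abs(y - stats::median(y)))
  g <- factor(rep(c("x", "y"), c(length(x), length(y))))
  if (stats::var(z) == 0) return(list(statistic = 0, p = 1))
  fit <- stats::aov(z ~ g)
  an <- stats::anova(fit)
  list(statistic = an[["F value"]][1L], p = an[["Pr(>F)"]][1L])
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment with monotonicity enforcement;
#' missing entries propagate as missing and do not enter the family size.
#'
#' @param pvals numeric vector of p values in `[0, 1]` (NA allowed).
#' @return adjusted p values in input order.
#' @examples
#' benjaminiHochberg(c(0.01, 0.02, 0.03, 0.04))
#' @export
benjaminiHochberg <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH", n = sum(ok))
}

#' Correlation-network feature sets
#'
#' Builds an adjacency over features with an edge between two features if
#' and only if their Pearson correlation is at least `threshold` but below 1
#' (exact duplicates are deliberately not linked); connected components form
#' the sets, singletons included.
#'
#' @param x features x samples matrix (typically variance-stabilized) or
#'   [GlycomicsExperiment-class]; at least 2 samples.
#' @param threshold correlation threshold (default 0.9).
#' @return list of character vectors of feature names (a partition of the
#'   features).
#' @export
buildCorrelationSets <- function(x, threshold = 0.9) {
  m <- .as_matrix(x)
  stopifnot(ncol(m) >= 2L)
  nm <- rownames(m)
  if (is.null(nm)) nm <- as.character(seq_len(nrow(m)))
  r <- suppressWarnings(stats::cor(t(m)))
  r[is.na(r)] <- 0
  adj <- r >= threshold & r < 1 - 1e-10
  diag(adj) <- FALSE
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(gr)$membership
  unname(split(nm, comp))
}
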