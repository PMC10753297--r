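# Univariate/multivariate tests, effect sizes, BH correction and
# correlation-network sets.

test_that("Welch t-test matches the hand-computed example and conventions", {
  tt <- welchTTest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt$statistic, -3.674235, tolerance = 1e-6)
  expect_equal(tt$df, 4, tolerance = 1e-9)
  expect_equal(tt$p, 0.0213, tolerance = 1e-3)
  x <- c(2, 4, 6, 8)
  same <- welchTTest(x, x)
  expect_identical(c(same$statistic, same$p),
                   c(unname(stats::t.test(x, x)$statistic), 1)[c(1, 2)])
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  # degenerate constant paired differences
  deg <- welchTTest(c(1, 2, 3), c(2, 3, 4), paired = TRUE)
  expect_true(deg$degenerate)
  expect_equal(deg$p, 0)
  expect_error(welchTTest(c(1, 2), c(1, 2, 3), paired = TRUE), "equal")
  # constant identical groups
  cc <- welchTTest(rep(2, 3), rep(2, 4))
  expect_true(cc$degenerate)
  expect_equal(cc$p, 1)
})

test_that("Cohen's d and d_z follow the stated formulas", {
  es <- cohenEffectSize(c(1, 2, 3), c(4, 5, 6))
  expect_equal(es$value, 3)
  expect_equal(es$variance, 6 / 9 + 9 / 12, tolerance = 1e-12)
  expect_identical(es$kind, "d")
  # identical groups: zero effect, variance reduces to (n1+n2)/(n1 n2)
  x <- c(1, 2, 3, 4)
  es0 <- cohenEffectSize(x, x)
  expect_equal(es0$value, 0)
  expect_equal(es0$variance, 8 / 16)
  # antisymmetry
  a <- rnorm(5)
  b <- rnorm(5) + 1
  e1 <- cohenEffectSize(a, b)
  e2 <- cohenEffectSize(b, a)
  expect_equal(e1$value, -e2$value)
  expect_equal(e1$variance, e2$variance)
  # paired
  ez <- cohenEffectSize(c(1, 2, 3), c(3, 5, 7), paired = TRUE)
  d <- c(2, 3, 4)
  expect_equal(ez$value, mean(d) / sd(d))
  expect_equal(ez$variance, 1 / 3 + ez$value^2 / 6)
  expect_identical(ez$kind, "d_z")
  expect_error(cohenEffectSize(rep(1, 3), rep(1, 3)), "degenerate")
})

test_that("Hotelling's T2 reduces to the squared pooled t in 1-D", {
  ht <- hotellingT2(cbind(c(1, 2, 3)), cbind(c(4, 5, 6)))
  expect_equal(ht$T2, 13.5, tolerance = 1e-12)
  set.seed(5)
  for (r in 1:10) {
    x <- rnorm(6)
    y <- rnorm(7, 0.8)
    t_pooled <- unname(stats::t.test(x, y, var.equal = TRUE)$statistic)
    expect_equal(hotellingT2(cbind(x), cbind(y))$T2, t_pooled^2,
                 tolerance = 1e-9)
  }
})

test_that("Hotelling's T2 equals the explicit quadratic form in k = 2", {
  set.seed(8)
  X <- matrix(rnorm(20), 10, 2)
  Y <- matrix(rnorm(20, 0.5), 10, 2)
  ht <- hotellingT2(X, Y)
  S <- (9 * cov(X) + 9 * cov(Y)) / 18
  delta <- colMeans(Y) - colMeans(X)
  T2 <- (10 * 10 / 20) * drop(t(delta) %*% solve(S) %*% delta)
  expect_equal(ht$T2, T2, tolerance = 1e-10)
  Fref <- T2 * (20 - 2 - 1) / (2 * (20 - 2))
  expect_equal(ht$F, Fref, tolerance = 1e-10)
  expect_equal(ht$p, pf(Fref, 2, 17, lower.tail = FALSE), tolerance = 1e-12)
  # identical groups
  same <- hotellingT2(X, X)
  expect_equal(same$T2, 0)
  expect_equal(same$p, 1)
  # singular covariance falls back to the pseudo-inverse with a warning
  Xs <- cbind(X, X[, 1])
  Ys <- cbind(Y, Y[, 1])
  expect_warning(hs <- hotellingT2(Xs, Ys), "pseudo-inverse")
  expect_equal(hs$T2, ht$T2, tolerance = 1e-6)
})

test_that("Mahalanobis effect reduces to |Cohen's d| in 1-D and is
           reproducible under a seed", {
  x <- c(1, 2, 3, 4)
  y <- c(3, 5, 6, 8)
  me <- mahalanobisEffect(cbind(x), cbind(y), nBoot = 50, seed = 7)
  expect_equal(me$value, abs(cohenEffectSize(x, y)$value),
               tolerance = 1e-10)
  me2 <- mahalanobisEffect(cbind(x), cbind(y), nBoot = 50, seed = 7)
  expect_identical(me$variance, me2$variance)
  expect_equal(mahalanobisEffect(cbind(x), cbind(x), nBoot = 10,
                                 seed = 1)$value, 0)
})

test_that("Levene's test matches direct ANOVA on median deviations", {
  x <- c(1, 2, 3, 2, 1)
  y <- c(10, 20, 30, 20, 10)
  lv <- leveneVarianceTest(x, y)
  z <- c(abs(x - median(x)), abs(y - median(y)))
  g <- factor(rep(1:2, each = 5))
  ref <- anova(lm(z ~ g))
  expect_equal(lv$statistic, ref[["F value"]][1], tolerance = 1e-12)
  expect_equal(lv$p, ref[["Pr(>F)"]][1], tolerance = 1e-12)
  if (requireNamespace("car", quietly = TRUE)) {
    cl <- car::leveneTest(c(x, y), g, center = median)
    expect_equal(lv$statistic, cl[["F value"]][1], tolerance = 1e-9)
  }
  expect_equal(leveneVarianceTest(x, x)$statistic, 0)
  # equal dispersion in both groups: clearly not significant
  expect_gt(leveneVarianceTest(c(1, 2, 3, 2, 1), c(5, 6, 7, 6, 5))$p, 0.5)
})

test_that("Benjamini-Hochberg matches the hand-worked example and is a
           proper step-up adjustment", {
  expect_equal(benjaminiHochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjaminiHochberg(0.37), 0.37)
  set.seed(21)
  p <- runif(50)
  adj <- benjaminiHochberg(p)
  expect_true(all(adj >= p) && all(adj <= 1))
  # permutation invariance of the multiset of outputs
  perm <- sample(50)
  expect_equal(sort(benjaminiHochberg(p[perm])), sort(adj))
  # NA propagation without inflating the family
  pna <- c(0.01, NA, 0.02, 0.03, 0.04)
  expect_equal(benjaminiHochberg(pna), c(0.04, NA, 0.04, 0.04, 0.04))
  expect_error(benjaminiHochberg(c(0.5, 1.2)), "0, 1")
})

test_that("correlation sets link features in [threshold, 1) only", {
  set.seed(13)
  base <- rnorm(10)
  m <- rbind(a = base,
             b = base + rnorm(10, 0, 0.12),
             c = base + rnorm(10, 0, 0.12),
             dup1 = 1:10, dup2 = 1:10,
             lone = rnorm(10))
  sets <- buildCorrelationSets(m, threshold = 0.9)
  find_set <- function(f) sets[[which(vapply(sets, function(s) f %in% s,
                                             logical(1)))]]
  expect_setequal(find_set("a"), c("a", "b", "c"))
  # exact duplicates (r = 1) are deliberately not linked
  expect_identical(find_set("dup1"), "dup1")
  expect_identical(find_set("dup2"), "dup2")
  expect_identical(find_set("lone"), "lone")
  # partition property
  expect_setequal(unlist(sets), rownames(m))
  expect_identical(anyDuplicated(unlist(sets)), 0L)
})

test_that("independent features stay singletons at the default threshold", {
  set.seed(77)
  m <- matrix(rnorm(30 * 10), 30, 10,
              dimnames = list(paste0("f", 1:30), NULL))
  sets <- buildCorrelationSets(m)
  expect_gte(mean(lengths(sets) == 1), 0.95)
})
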