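# End-to-end two-group differential expression, ANOVA and time-series
# workflows.

sim_pair <- function(seed, n = 60, reps = 10, scale = 5, miss = 0) {
  sim <- simulateGlycomes(nGlycans = n, nReplicates = reps,
                          nEffects = 5, effectScale = scale,
                          missingFraction = miss, glycans = NA, seed = seed)
  m <- cbind(abundances(sim$control), abundances(sim$test))
  list(m = m, g1 = colnames(abundances(sim$control)),
       g2 = colnames(abundances(sim$test)), truth = sim$truth)
}

test_that("self-vs-self comparison yields no significant features", {
  sp <- sim_pair(31, reps = 5)
  half <- sp$m[, sp$g1]
  dup <- cbind(half, half)
  colnames(dup) <- c(paste0("a", 1:5), paste0("b", 1:5))
  res <- suppressWarnings(getDifferentialExpression(
    dup, paste0("a", 1:5), paste0("b", 1:5)))
  expect_true(all(res$p_adj >= 0.99))
  expect_true(all(abs(res$log2fc) < 1e-9))
})

test_that("injected effects are recovered with controlled error", {
  sp <- sim_pair(32, n = 118, scale = 5)
  res <- getDifferentialExpression(sp$m, sp$g1, sp$g2, seed = 32)
  ev <- evaluateRecovery(res, sp$truth)
  expect_gt(ev$sensitivity, 0.15)
  expect_lte(ev$fpr, 0.05)
  expect_true(is.na(ev$direction_accuracy) || ev$direction_accuracy >= 0.9)
  expect_true(all(res$p_adj >= res$p))
  expect_true(all(is.finite(res$log2fc)))
  # orientation: up-regulated significant features have positive log2fc
  sig_up <- res$feature[res$p_adj < 0.05 &
                          res$feature %in% names(sp$truth)[sp$truth == "up"]]
  expect_true(all(res$log2fc[match(sig_up, res$feature)] > 0))
})

test_that("the group arguments are validated", {
  sp <- sim_pair(33, n = 20, reps = 3)
  expect_error(getDifferentialExpression(sp$m, sp$g1, c(sp$g2[1], sp$g1[1])),
               "overlap")
  expect_error(getDifferentialExpression(sp$m, sp$g1, c(sp$g2, "nope")),
               "unknown sample")
  expect_error(getDifferentialExpression(sp$m, sp$g1[1], sp$g2),
               "at least 2")
  expect_error(getDifferentialExpression(sp$m, sp$g1, sp$g2[1:2],
                                         paired = TRUE), "equal group sizes")
})

test_that("paired analysis uses d_z and the paired t-test", {
  sp <- sim_pair(34, n = 30, reps = 6)
  res <- getDifferentialExpression(sp$m, sp$g1, sp$g2, paired = TRUE,
                                   seed = 34)
  expect_true(all(res$effect_kind == "d_z"))
})

test_that("set analysis partitions features and tests sets multivariately", {
  set.seed(35)
  base <- rgamma(8, 2)
  # three tightly co-regulated features + independent ones
  m <- rbind(
    cor1 = base * rlnorm(8, 0, 0.05),
    cor2 = base * rlnorm(8, 0, 0.05),
    cor3 = base * rlnorm(8, 0, 0.05),
    solo1 = rgamma(8, 2), solo2 = rgamma(8, 2), solo3 = rgamma(8, 2),
    solo4 = rgamma(8, 2))
  colnames(m) <- paste0("s", 1:8)
  res <- suppressWarnings(getDifferentialExpression(
    m, paste0("s", 1:4), paste0("s", 5:8), sets = TRUE, nBoot = 50,
    seed = 35))
  members <- unlist(strsplit(res$set_members, ";", fixed = TRUE))
  expect_setequal(members, rownames(m))
  expect_identical(anyDuplicated(members), 0L)
  if (any(res$is_set)) {
    expect_true(all(res$effect_kind[res$is_set] == "mahalanobis"))
    expect_true(all(res$effect_variance[res$is_set] >= 0))
  }
  expect_true(all(res$effect_kind[!res$is_set] == "d"))
})

test_that("motif-level analysis tests motifs instead of sequences", {
  set.seed(36)
  glycans <- oracle_fixture_glycans(25)
  m <- matrix(rgamma(25 * 8, 2), 25, 8,
              dimnames = list(glycans, paste0("s", 1:8)))
  m <- sweep(m, 2, colSums(m), "/") * 100
  res <- getDifferentialExpression(m, paste0("s", 1:4), paste0("s", 5:8),
                                   motifs = TRUE, featureSets = "terminal",
                                   seed = 36)
  expect_false(any(res$feature %in% glycans))
  expect_true(any(grepl("\\(a2-|\\(b1-|\\(a1-", res$feature)))
})

test_that("ANOVA matches hand-computed sums of squares and triggers Tukey
           only for significant features", {
  # constructed 3-group table analyzed at the vsn level; F checked by hand
  set.seed(37)
  groups <- rep(c("g1", "g2", "g3"), each = 6)
  m <- matrix(rgamma(10 * 18, 3), 10, 18,
              dimnames = list(paste0("f", 1:10), paste0("s", 1:18)))
  m["f1", groups == "g3"] <- m["f1", groups == "g3"] * 8
  m <- sweep(m, 2, colSums(m), "/") * 100
  out <- getGlycanova(m, groups, seed = 37)
  an <- out$anova
  # oracle: recompute F for one feature from the same transformed values
  rel <- m
  rel <- glycodiff::filterLowVariance(glycodiff::normalizeTotal(rel) + 1e-6)
  v <- suppressWarnings(varianceStabilize(rel, groups))
  f <- an$feature[1]
  y <- v[f, ]
  gm <- tapply(y, groups, mean)
  ssb <- sum(6 * (gm - mean(y))^2)
  ssw <- sum((y - gm[groups])^2)
  Fref <- (ssb / 2) / (ssw / 15)
  expect_equal(an$F[an$feature == f], Fref, tolerance = 1e-8)
  # the injected feature is flagged, with Tukey pairs (1,3) and (2,3)
  expect_lt(an$p_adj[an$feature == "f1"], 0.05)
  ph <- out$posthoc[out$posthoc$feature == "f1", ]
  pair <- function(a, b) {
    ph$significant[(ph$group1 == a & ph$group2 == b) |
                     (ph$group1 == b & ph$group2 == a)]
  }
  expect_true(pair("g1", "g3"))
  expect_true(pair("g2", "g3"))
  expect_false(pair("g1", "g2"))
  # only BH-significant features enter the post hoc table
  expect_true(all(out$posthoc$feature %in%
                    an$feature[an$p_adj < 0.05]))
  expect_error(getGlycanova(m, rep(c("a", "b"), each = 9)),
               "at least 3")
})

test_that("three identical groups produce no excess ANOVA discoveries", {
  set.seed(38)
  sim <- simulateGlycomes(nGlycans = 60, nReplicates = 12, nEffects = 0,
                          glycans = NA, seed = 38)
  m <- abundances(sim$control)
  groups <- sample(rep(c("a", "b", "c"), each = 4))
  out <- getGlycanova(m, setNames(groups, colnames(m)), seed = 38)
  expect_lte(mean(out$anova$p_adj < 0.05), 0.05)
})

test_that("time-series regression recovers linear and quadratic trends", {
  set.seed(39)
  tp <- rep(c(0, 1, 2, 3, 4), each = 3)
  ns <- length(tp)
  m <- matrix(rgamma(12 * ns, 3), 12, ns,
              dimnames = list(paste0("f", 1:12), paste0("s", seq_len(ns))))
  m["f1", ] <- 2 * 2^(0.8 * tp) * rlnorm(ns, 0, 0.05)   # rising trend
  m["f2", ] <- 3 * rlnorm(ns, 0, 0.03)                   # flat + noise
  m["f3", ] <- 2^(1.5 * tp - 0.4 * tp^2) * rlnorm(ns, 0, 0.05)  # parabola
  m <- sweep(m, 2, colSums(m), "/") * 100
  res <- getTimeSeries(m, setNames(tp, colnames(m)), seed = 39)
  expect_identical(unique(res$degree), 1L)
  expect_lt(res$p_adj[res$feature == "f1"], 0.05)
  expect_gt(res$beta1[res$feature == "f1"], 0)
  expect_gt(res$p_adj[res$feature == "f2"], 0.05)
  # quadratic trajectory: degree-2 F-test significant, slope test not
  res2 <- getTimeSeries(m, setNames(tp, colnames(m)), degree = 2, seed = 39)
  expect_lt(res2$p_adj[res2$feature == "f3"], 0.05)
  expect_gt(res$p_adj[res$feature == "f3"],
            res2$p_adj[res2$feature == "f3"])
  expect_identical(colnames(res2)[2:4], c("beta0", "beta1", "beta2"))
  expect_error(getTimeSeries(m, setNames(tp, colnames(m)), degree = 5),
               "degree")
  expect_error(getTimeSeries(m[, 1:6], setNames(rep(c(0, 1), 3),
                                                colnames(m)[1:6])),
               "3 distinct")
})

test_that("variance stabilization removes the mean-variance dependence of
           relative abundances", {
  sim <- simulateGlycomes(nGlycans = 118, nEffects = 0, glycans = NA,
                          seed = 71)
  m <- normalizeTotal(cbind(abundances(sim$control),
                            abundances(sim$test))) + 1e-6
  raw_cor <- cor(rowMeans(m), apply(m, 1, sd), method = "spearman")
  v <- varianceStabilize(m)
  vsn_cor <- cor(rowMeans(v), apply(v, 1, sd), method = "spearman")
  expect_gt(raw_cor, 0.8)           # strong heteroscedasticity before
  expect_lt(abs(vsn_cor), 0.2)      # decoupled after
  expect_equal(unname(apply(v, 1, sd)), rep(1, nrow(v)), tolerance = 1e-9)
})

test_that("false-positive rates at a large injected effect stay bounded
           with and without variance stabilization", {
  # vsn arm = standard pipeline; relative arm = Welch on the untransformed
  # relative abundances of the same preprocessed tables
  fpr <- matrix(NA_real_, 6, 2)
  for (r in 1:6) {
    sim <- simulateGlycomes(nGlycans = 118, effectScale = 10, glycans = NA,
                            seed = 600 + r)
    m <- cbind(abundances(sim$control), abundances(sim$test))
    g1 <- colnames(m)[1:10]
    g2 <- colnames(m)[11:20]
    res <- getDifferentialExpression(m, g1, g2, seed = r)
    fpr[r, 1] <- evaluateRecovery(res, sim$truth)$fpr
    rel <- filterLowVariance(normalizeTotal(m) + 1e-6)
    p <- vapply(rownames(rel), function(f) {
      welchTTest(rel[f, g1], rel[f, g2])$p
    }, numeric(1))
    res_rel <- data.frame(feature = rownames(rel),
                          log2fc = log2(rowMeans(rel[, g2]) /
                                          rowMeans(rel[, g1])),
                          p_adj = benjaminiHochberg(p))
    fpr[r, 2] <- evaluateRecovery(res_rel, sim$truth)$fpr
  }
  # under the symmetric concentration scaling, null features acquire a
  # genuine compositional shift at scale 10; both testing scales must keep
  # the resulting false-discovery level moderate
  expect_lte(mean(fpr[, 1]), 0.2)
  expect_lte(mean(fpr[, 2]), 0.2)
})
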