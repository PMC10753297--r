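## Dirichlet simulator of compositional glycomics experiments with known
## ground truth, plus missingness injection and recovery scoring.

# Dirichlet draws via normalized gamma variates; rows = draws
.rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha), nrow = n,
              byrow = TRUE)
  x / rowSums(x)
}

#' Simulate a two-group glycomics experiment
#'
#' Relative glycan abundances are modeled by a Dirichlet distribution whose
#' concentration parameters follow an experimental composition (samples sum
#' to 100). Ground-truth effects are injected by scaling the concentration
#' parameters of the up-regulated features by `effectScale` and dividing
#' those of the down-regulated features by it in the test condition (a
#' symmetric effect on the log scale). Glycan structures are assigned from
#' the packaged fixture list, sialylated structures to up-regulated
#' features and fucosylated (non-sialylated) structures to down-regulated
#' ones.
#'
#' @param nGlycans number of features (default 118; the concentration vector
#'   is resampled to this length when it differs).
#' @param alpha positive concentration parameters (default [defaultAlpha()]).
#' @param nReplicates replicates per group (default 10).
#' @param nEffects number of up- and of down-regulated features (default 10
#'   each) when explicit indices are not given.
#' @param effectIndicesUp,effectIndicesDown optional disjoint feature index
#'   vectors; drawn at random when `NULL`.
#' @param effectScale multiplicative concentration effect (> 0, default 5).
#' @param missingFraction fraction of cells set to missing in each group
#'   table (0 to 0.7; default 0).
#' @param glycans optional character vector of glycan names, one per
#'   feature; `NA` to skip structure assignment (features are then named
#'   `glycan_001`, ...); `NULL` (default) assigns fixture structures.
#' @param seed optional integer seed.
#' @return list with elements `control` and `test`
#'   ([GlycomicsExperiment-class]s, features x replicates, columns summing
#'   to 100 before missingness injection), `truth` (named factor with
#'   levels up/down/null), and `alpha` / `alphaTest` (the concentration
#'   vectors used).
#' @examples
#' sim <- simulateGlycomes(nGlycans = 20, nReplicates = 4, nEffects = 2,
#'                         seed = 1)
#' table(sim$truth)
#' @export
simulateGlycomes <- function(nGlycans = 118L, alpha = defaultAlpha(),
                             nReplicates = 10L, nEffects = 10L,
                             effectIndicesUp = NULL,
                             effectIndicesDown = NULL, effectScale = 5,
                             missingFraction = 0, glycans = NULL,
                             seed = NULL) {
  stopifnot(nGlycans >= 2L, all(alpha > 0), nReplicates >= 2L,
            effectScale > 0)
  if (!is.null(seed)) set.seed(seed)
  if (length(alpha) != nGlycans) {
    alpha <- sample(alpha, nGlycans, replace = length(alpha) < nGlycans)
  }
  idx_ok <- function(i) all(i >= 1L & i <= nGlycans)
  if (!is.null(effectIndicesUp) && !idx_ok(effectIndicesUp) ||
      !is.null(effectIndicesDown) && !idx_ok(effectIndicesDown)) {
    stop("effect index out of range", call. = FALSE)
  }
  assign_structures <- is.null(glycans) ||
    (length(glycans) == 1L && is.na(glycans[1L]))
  feature_names <- NULL
  if (!assign_structures) {
    if (length(glycans) != nGlycans) {
      stop("glycans must have one entry per feature", call. = FALSE)
    }
    feature_names <- glycans
  }
  if (is.null(effectIndicesUp) && is.null(effectIndicesDown)) {
    pick <- sample.int(nGlycans, 2L * nEffects)
    effectIndicesUp <- pick[seq_len(nEffects)]
    effectIndicesDown <- pick[nEffects + seq_len(nEffects)]
  } else {
    effectIndicesUp <- as.integer(effectIndicesUp)
    effectIndicesDown <- as.integer(effectIndicesDown)
  }
  if (length(intersect(effectIndicesUp, effectIndicesDown))) {
    stop("up and down effect sets must be disjoint", call. = FALSE)
  }
  if (is.null(feature_names) && !assign_structures) {
    feature_names <- sprintf("glycan_%03d", seq_len(nGlycans))
  }
  if (assign_structures && is.null(glycans)) {
    pool <- fixtureGlycans("all")
    if (length(pool) < nGlycans) {
      feature_names <- sprintf("glycan_%03d", seq_len(nGlycans))
    } else {
      sial <- pool[grepl("Neu5", pool)]
      fuco <- pool[grepl("Fuc", pool) & !grepl("Neu5", pool)]
      nm <- character(nGlycans)
      up_str <- sample(sial, min(length(sial), length(effectIndicesUp)))
      down_str <- sample(fuco, min(length(fuco),
                                   length(effectIndicesDown)))
      nm[effectIndicesUp[seq_along(up_str)]] <- up_str
      nm[effectIndicesDown[seq_along(down_str)]] <- down_str
      rest <- setdiff(pool, c(up_str, down_str))
      open <- which(nm == "")
      nm[open] <- sample(rest, length(open))
      feature_names <- nm
    }
  }
  if (is.null(feature_names)) {
    feature_names <- sprintf("glycan_%03d", seq_len(nGlycans))
  }
  alpha_test <- alpha
  alpha_test[effectIndicesUp] <- alpha_test[effectIndicesUp] * effectScale
  alpha_test[effectIndicesDown] <- alpha_test[effectIndicesDown] /
    effectScale
  ctrl <- t(.rdirichlet(nReplicates, alpha)) * 100
  test <- t(.rdirichlet(nReplicates, alpha_test)) * 100
  dimnames(ctrl) <- list(feature_names,
                         sprintf("ctrl_%02d", seq_len(nReplicates)))
  dimnames(test) <- list(feature_names,
                         sprintf("test_%02d", seq_len(nReplicates)))
  truth <- rep("null", nGlycans)
  truth[effectIndicesUp] <- "up"
  truth[effectIndicesDown] <- "down"
  truth <- stats::setNames(factor(truth, levels = c("up", "down", "null")),
                           feature_names)
  if (missingFraction > 0) {
    ctrl <- injectMissingness(ctrl, missingFraction)
    test <- injectMissingness(test, missingFraction)
  }
  list(control = GlycomicsExperiment(ctrl,
                                     groups = rep("control", nReplicates)),
       test = GlycomicsExperiment(test, groups = rep("test", nReplicates)),
       truth = truth, alpha = alpha, alphaTest = alpha_test)
}

#' Inject random missingness into an abundance table
#'
#' Sets exactly `round(fraction * cells)` uniformly chosen entries to
#' missing. Masks that blank out an entire feature row are re-drawn (up to
#' 100 times) before being accepted as unavoidable.
#'
#' @param x features x samples matrix or [GlycomicsExperiment-class].
#' @param fraction fraction of cells to blank, in `[0, 0.7]` (the validated
#'   regime).
#' @param seed optional integer seed; a fixed seed reproduces the mask.
#' @return object of the same kind with `NA` at the masked positions.
#' @export
injectMissingness <- function(x, fraction, seed = NULL) {
  m <- .as_matrix(x)
  if (fraction < 0 || fraction > 0.7) {
    stop("missing fraction must lie in [0, 0.7]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  k <- round(fraction * length(m))
  if (k == 0L) return(.like_input(x, m))
  for (try in seq_len(100L)) {
    idx <- sample.int(length(m), k)
    out <- m
    out[idx] <- NA_real_
    if (all(rowSums(!is.na(out)) > 0L)) break
  }
  .like_input(x, out)
}

#' Imputation benchmark on simulated experiments
#'
#' Runs the two-group differential expression workflow over `nExperiments`
#' simulated datasets (by default 128 features, 10 + 10 replicates,
#' 10 up- and 10 down-regulated features at concentration scale 5) in three
#' arms: complete data, `missingFraction` randomly missing cells analyzed
#' with random-forest imputation, and the same incomplete data analyzed
#' naively (missing treated as zero). Returns the mean sensitivity, false
#' positive rate and direction accuracy per arm.
#'
#' @param nExperiments number of simulated experiments (default 50).
#' @param nGlycans,nReplicates,effectScale,missingFraction simulation
#'   conditions (defaults follow the validation set-up: 128 features,
#'   10 replicates per group, scale 5, 30% missing).
#' @param seed integer seed for the whole benchmark.
#' @param arms subset of `c("complete", "imputed", "unimputed")`.
#' @return data.frame with one row per arm: `arm`, `sensitivity`, `fpr`,
#'   `direction_accuracy`.
#' @export
runImputationBenchmark <- function(nExperiments = 50L, nGlycans = 128L,
                                   nReplicates = 10L, effectScale = 5,
                                   missingFraction = 0.3, seed = 1L,
                                   arms = c("complete", "imputed",
                                            "unimputed")) {
  arms <- match.arg(arms, several.ok = TRUE)
  acc <- lapply(stats::setNames(arms, arms), function(a) NULL)
  for (r in seq_len(nExperiments)) {
    sim <- simulateGlycomes(nGlycans = nGlycans, nReplicates = nReplicates,
                            effectScale = effectScale, glycans = NA,
                            seed = seed + r)
    m <- cbind(abundances(sim$control), abundances(sim$test))
    g1 <- colnames(abundances(sim$control))
    g2 <- colnames(abundances(sim$test))
    mm <- if (missingFraction > 0) {
      injectMissingness(m, missingFraction, seed = seed + r)
    } else m
    one <- function(x, impute) {
      res <- getDifferentialExpression(x, g1, g2, impute = impute,
                                       seed = seed + r)
      ev <- evaluateRecovery(res, sim$truth)
      c(sensitivity = ev$sensitivity, fpr = ev$fpr,
        direction_accuracy = ev$direction_accuracy)
    }
    for (a in arms) {
      acc[[a]] <- rbind(acc[[a]], switch(a,
        complete = one(m, TRUE),
        imputed = one(mm, TRUE),
        unimputed = one(mm, FALSE)))
    }
  }
  do.call(rbind, lapply(arms, function(a) {
    data.frame(arm = a,
               sensitivity = mean(acc[[a]][, "sensitivity"]),
               fpr = mean(acc[[a]][, "fpr"]),
               direction_accuracy = mean(acc[[a]][, "direction_accuracy"],
                                         na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
}

#' Motif-level fold-change calibration benchmark
#'
#' Simulates the motif-scaling experiment: a panel of fixture O-glycans in
#' which a fraction `motifShare` of the structures carry a terminal
#' Neu5Ac(a2-6) epitope, Dirichlet abundances with `nReplicates` replicates
#' per condition, and the concentration parameters of all motif-carrying
#' glycans multiplied by `effectScale` in the test condition. Per seeded
#' run it records the realized motif-level log2 fold change of the
#' aggregated terminal Neu5Ac(a2-6) abundance, whether sequence-level
#' differential expression flags any glycan, and whether motif-level
#' analysis flags the Neu5Ac(a2-6) / Neu5Ac(a2-?) terminal motif
#' (BH-adjusted p < 0.05).
#'
#' @param nRuns number of seeded runs (default 20).
#' @param nGlycans panel size (default 80).
#' @param motifShare fraction of panel structures carrying the terminal
#'   Neu5Ac(a2-6) motif (default 0.1).
#' @param nReplicates replicates per condition (default 5).
#' @param effectScale concentration multiplier for motif-carrying glycans
#'   (default 1.25).
#' @param seed integer base seed.
#' @return data.frame with one row per run: `run`, `log2fc`,
#'   `sequence_hits` (count of significant glycans), `motif_hit` (logical).
#' @export
runMotifCalibration <- function(nRuns = 20L, nGlycans = 80L,
                                motifShare = 0.1, nReplicates = 5L,
                                effectScale = 1.25, seed = 1L) {
  pool <- fixtureGlycans("O")
  carries <- vapply(pool, function(s) {
    countMotif(s, "Neu5Ac(a2-6)", constraint = "terminal") > 0
  }, logical(1))
  n_m <- max(1L, round(motifShare * nGlycans))
  out <- NULL
  for (r in seq_len(nRuns)) {
    set.seed(seed + r)
    glycans <- sample(c(sample(pool[carries], n_m),
                        sample(pool[!carries], nGlycans - n_m)))
    alpha <- sample(defaultAlpha(), nGlycans,
                    replace = length(defaultAlpha()) < nGlycans)
    has <- vapply(glycans, function(s) {
      countMotif(s, "Neu5Ac(a2-6)", constraint = "terminal") > 0
    }, logical(1))
    sim <- simulateGlycomes(nGlycans = nGlycans, alpha = alpha,
                            nReplicates = nReplicates,
                            effectIndicesUp = which(has),
                            effectIndicesDown = integer(0),
                            effectScale = effectScale, glycans = glycans,
                            seed = seed + r)
    m <- cbind(abundances(sim$control), abundances(sim$test))
    g1 <- colnames(abundances(sim$control))
    g2 <- colnames(abundances(sim$test))
    q <- quantifyMotifs(m, featureSets = "terminal")
    row <- match("Neu5Ac(a2-6)", rownames(q))
    if (is.na(row)) row <- match("Neu5Ac(a2-?)", rownames(q))
    lfc <- log2(mean(q[row, g2]) / mean(q[row, g1]))
    res_seq <- getDifferentialExpression(m, g1, g2, seed = seed + r)
    res_mot <- getDifferentialExpression(m, g1, g2, motifs = TRUE,
                                         featureSets = "terminal",
                                         seed = seed + r)
    hit <- res_mot$feature %in% c("Neu5Ac(a2-6)", "Neu5Ac(a2-?)") &
      res_mot$p_adj < 0.05
    out <- rbind(out, data.frame(
      run = r, log2fc = lfc,
      sequence_hits = sum(res_seq$p_adj < 0.05, na.rm = TRUE),
      motif_hit = any(hit, na.rm = TRUE)))
  }
  out
}

#' Score recovery of simulated effects
#'
#' Sensitivity is the fraction of true-effect features that are recovered
#' (adjusted p < `alphaLevel` AND matching fold-change sign); features
#' filtered out before testing count as not recovered. The false-positive
#' rate is the fraction of null features reaching significance; specificity
#' is its complement. Direction accuracy is the fraction of significant
#' true-effect features whose sign is correct.
#'
#' @param results data.frame from [getDifferentialExpression()] with columns
#'   `feature`, `log2fc`, `p_adj`.
#' @param truth named factor/character with levels up/down/null (names =
#'   feature names), as returned by [simulateGlycomes()].
#' @param alphaLevel significance cutoff (default 0.05).
#' @return list with `sensitivity`, `specificity`, `fpr`,
#'   `direction_accuracy` (NA when no true effect is significant), and the
#'   underlying counts.
#' @export
evaluateRecovery <- function(results, truth, alphaLevel = 0.05) {
  stopifnot(is.data.frame(results),
            all(c("feature", "log2fc", "p_adj") %in% colnames(results)))
  truth <- stats::setNames(as.character(truth), names(truth))
  if (is.null(names(truth))) {
    stop("truth must be named by feature", call. = FALSE)
  }
  feats <- if ("is_set" %in% colnames(results)) {
    results$feature[!results$is_set]
  } else results$feature
  if (!all(feats %in% names(truth))) {
    stop("result feature(s) absent from truth: ",
         paste(utils::head(setdiff(feats, names(truth))), collapse = ", "),
         call. = FALSE)
  }
  sig <- stats::setNames(rep(FALSE, length(truth)), names(truth))
  sgn <- stats::setNames(rep(NA_real_, length(truth)), names(truth))
  hit <- match(names(truth), results$feature)
  got <- !is.na(hit)
  sig[got] <- results$p_adj[hit[got]] < alphaLevel
  sgn[got] <- sign(results$log2fc[hit[got]])
  is_up <- truth == "up"
  is_down <- truth == "down"
  is_null <- truth == "null"
  correct <- (is_up & sgn %in% 1) | (is_down & sgn %in% -1)
  recovered <- sig & correct
  n_true <- sum(is_up | is_down)
  sens <- if (n_true) sum(recovered[is_up | is_down]) / n_true else NA_real_
  fpr <- if (any(is_null)) mean(sig[is_null]) else NA_real_
  dir_acc <- if (any(sig & (is_up | is_down))) {
    sum(recovered) / sum(sig & (is_up | is_down))
  } else NA_real_
  list(sensitivity = sens, specificity = 1 - fpr, fpr = fpr,
       direction_accuracy = dir_acc,
       n_true = n_true, n_null = sum(is_null),
       n_recovered = sum(recovered[is_up | is_down]))
}
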