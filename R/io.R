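## CSV input/output for abundance tables and result tables.

#' Read a glycan/motif abundance table from CSV or TSV
#'
#' First column = feature name (glycan string or motif), remaining columns =
#' samples; the delimiter (comma or tab) is sniffed from the header. Glycan
#' names are canonicalized; rows that fail to parse keep their original name
#' (with a warning) and are later excluded from motif-level analysis. Empty
#' cells and the sentinels `NA`/`NaN` become missing marks.
#'
#' @param path CSV/TSV file.
#' @param groups,timepoints optional per-sample annotations, passed to
#'   [GlycomicsExperiment()].
#' @return a [GlycomicsExperiment-class].
#' @export
readAbundanceCSV <- function(path, groups = NULL, timepoints = NULL) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("NA", "NaN", ""),
                           comment.char = "")
  if (ncol(tab) < 2L) stop("need a feature column plus >= 1 sample column",
                           call. = FALSE)
  feats <- as.character(tab[[1L]])
  samples <- colnames(tab)[-1L]
  if (anyDuplicated(samples)) {
    stop("duplicate sample ID(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "),
         call. = FALSE)
  }
  canon <- vapply(feats, function(s) {
    tryCatch(suppressWarnings(canonicalizeIUPAC(s)), error = function(e) {
      warning("feature '", s, "' is not a parseable glycan; kept verbatim",
              call. = FALSE)
      s
    })
  }, character(1), USE.NAMES = FALSE)
  if (anyDuplicated(canon)) {
    stop("duplicate feature name(s) after canonicalization: ",
         paste(unique(canon[duplicated(canon)]), collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- canon
  GlycomicsExperiment(m, groups = groups, timepoints = timepoints)
}

#' Write a result table to CSV
#'
#' Deterministic layout: the canonical column order (feature and fold
#' change / coefficients first, then statistic, p, p_adj, effect size and
#' variance, Levene, set membership), rows ordered by ascending adjusted p
#' value with ties broken by feature name, numbers at full precision.
#'
#' @param rows result data.frame from any workflow.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeResultsCSV <- function(rows, path) {
  rows <- as.data.frame(rows)
  lead <- intersect(c("feature", "log2fc",
                      grep("^beta", colnames(rows), value = TRUE),
                      "statistic", "p", "p_adj", "effect_size",
                      "effect_variance", "effect_kind", "levene_p",
                      "levene_p_adj", "is_set", "set_members", "degree"),
                    colnames(rows))
  rows <- rows[, c(lead, setdiff(colnames(rows), lead)), drop = FALSE]
  if (all(c("p_adj", "feature") %in% colnames(rows)) && nrow(rows)) {
    rows <- rows[order(rows$p_adj, rows$feature), , drop = FALSE]
  }
  for (j in seq_along(rows)) {
    if (is.numeric(rows[[j]])) rows[[j]] <- .num17(rows[[j]])
  }
  utils::write.csv(rows, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

# full-precision decimal rendering that round-trips doubles
.num17 <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- NA_character_
  out
}

#' Write an abundance table to CSV
#'
#' Feature names in the first column (`feature`), one column per sample,
#' values at full float precision (the written file reads back bit-equal
#' through [readAbundanceCSV()] for canonical feature names).
#'
#' @param x features x samples matrix or [GlycomicsExperiment-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeAbundanceCSV <- function(x, path) {
  m <- .as_matrix(x)
  out <- data.frame(feature = rownames(m), stringsAsFactors = FALSE,
                    check.names = FALSE)
  for (j in seq_len(ncol(m))) out[[colnames(m)[j]]] <- .num17(m[, j])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
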