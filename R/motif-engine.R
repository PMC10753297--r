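## Motif count matrices, wildcard generalization, feature deduplication and
## proportional motif quantification.

.klass_priority <- c(named = 40, disaccharide = 30, terminal = 20,
                     monosaccharide = 10, generalized = 15)

#' Motif count matrix
#'
#' Glycans x motifs matrix of subtree occurrence counts, together with the
#' motif definitions (one row per column of the count matrix).
#'
#' @slot counts integer matrix, glycans in rows, motifs in columns.
#' @slot motifs data.frame with columns `name`, `pattern`, `constraint`,
#'   `excluded_context`, `klass`, `priority`.
#' @export
setClass("MotifCountMatrix",
  representation(counts = "matrix", motifs = "data.frame"))

setValidity("MotifCountMatrix", function(object) {
  if (ncol(object@counts) != nrow(object@motifs)) {
    return("count columns and motif rows disagree")
  }
  if (any(object@counts < 0)) return("counts must be nonnegative")
  TRUE
})

#' @describeIn MotifCountMatrix the glycans x motifs count matrix
#' @param x,object a `MotifCountMatrix`
#' @export
motifCounts <- function(x) x@counts

#' @describeIn MotifCountMatrix the motif definition table
#' @export
motifInfo <- function(x) x@motifs

setMethod("show", "MotifCountMatrix", function(object) {
  cat(sprintf("MotifCountMatrix: %d glycans x %d motifs (%s)\n",
              nrow(object@counts), ncol(object@counts),
              paste(sprintf("%s: %d", names(table(object@motifs$klass)),
                            table(object@motifs$klass)), collapse = ", ")))
})

#' Load the named motif library
#'
#' Reads the packaged curated library of named glycan epitopes (Lewis and
#' blood-group antigens, O-glycan cores, sialyl-Tn, di-sialyl-T, Sda,
#' LacNAc variants, core fucose, bisecting GlcNAc, ...) and appends any
#' user-supplied additions.
#'
#' @param path optional TSV file with columns `name`, `pattern`,
#'   `constraint`, `excluded_context` (`#` comments allowed); rows are added
#'   to the packaged defaults.
#' @return data.frame with columns `name`, `pattern`, `constraint`,
#'   `excluded_context`, `klass` (= `"named"`).
#' @examples
#' head(loadKnownMotifs())
#' @export
loadKnownMotifs <- function(path = NULL) {
  read_lib <- function(f) {
    lines <- readLines(f, encoding = "UTF-8")
    keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
    lineno <- which(keep)
    lines <- lines[keep]
    if (!length(lines)) stop("empty motif library: ", f, call. = FALSE)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    header <- parts[[1]]
    need <- c("name", "pattern", "constraint")
    if (!all(need %in% header)) {
      stop("motif library ", f, " must have columns name/pattern/constraint",
           call. = FALSE)
    }
    rows <- lapply(seq_along(parts)[-1], function(i) {
      p <- parts[[i]]
      if (length(p) < 3L || !nzchar(p[1]) || !nzchar(p[2]) || !nzchar(p[3])) {
        stop("malformed motif library row at line ", lineno[i], " of ", f,
             call. = FALSE)
      }
      data.frame(name = p[1], pattern = p[2], constraint = p[3],
                 excluded_context = if (length(p) >= 4L && nzchar(p[4])) {
                   p[4]
                 } else NA_character_,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  lib <- read_lib(system.file("extdata", "known_motifs.tsv",
                              package = "glycodiff", mustWork = TRUE))
  if (!is.null(path)) lib <- rbind(lib, read_lib(path))
  if (anyDuplicated(lib$name)) {
    stop("duplicate motif name(s): ",
         paste(unique(lib$name[duplicated(lib$name)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- !lib$constraint %in% c("terminal", "internal", "reducing-end",
                                "flexible")
  if (any(bad)) {
    stop("invalid constraint for motif(s): ",
         paste(lib$name[bad], collapse = ", "), call. = FALSE)
  }
  lib$klass <- "named"
  lib
}

# motif table row -> MotifDefinition
.row_to_motif <- function(r) {
  motifDefinition(r[["name"]], r[["pattern"]], r[["constraint"]],
                  if (is.na(r[["excluded_context"]])) NA_character_ else
                    r[["excluded_context"]],
                  r[["klass"]])
}

# count all motifs (table rows) in all glycan graphs -> glycans x motifs
.count_matrix <- function(graphs, motif_tab) {
  m <- vapply(seq_len(nrow(motif_tab)), function(j) {
    mo <- .row_to_motif(motif_tab[j, ])
    vapply(graphs, function(g) countMotif(g, mo), numeric(1))
  }, numeric(length(graphs)))
  m <- matrix(m, nrow = length(graphs),
              dimnames = list(names(graphs), motif_tab$name))
  m
}

# serialize a pattern graph (+ optional dangling linkage)
.pattern_string <- function(g, dangling = NULL) {
  s <- glycanToString(g)
  if (!is.null(dangling)) {
    s <- paste0(s, "(", dangling[["anomeric"]], dangling[["child"]], "-",
                dangling[["parent"]], ")")
  }
  s
}

# wildcard variants of a pattern: each concrete linkage parent position and
# each concrete substituent position, generalized one field at a time
.generalize_variants <- function(pattern) {
  pat <- .parse_pattern(pattern)
  g <- pat$graph
  out <- character(0)
  for (i in seq_along(g@base)) {
    if (!is.na(g@parentPos[i]) && g@parentPos[i] != "?") {
      g2 <- g
      g2@parentPos[i] <- "?"
      out <- c(out, .pattern_string(g2, pat$dangling))
    }
    s <- g@substituents[[i]]
    for (k in seq_len(nrow(s))) {
      if (s$pos[k] != "?") {
        g2 <- g
        s2 <- s
        s2$pos[k] <- "?"
        g2@substituents[[i]] <- s2
        out <- c(out, .pattern_string(g2, pat$dangling))
      }
    }
  }
  if (!is.null(pat$dangling) && pat$dangling[["parent"]] != "?") {
    d2 <- pat$dangling
    d2[["parent"]] <- "?"
    out <- c(out, .pattern_string(g, d2))
  }
  unique(out)
}

#' Add informative wildcard generalizations to a motif count matrix
#'
#' For every family of terminal/exhaustive motifs that differ in a single
#' linkage parent position or substituent position, a `"?"`-generalized
#' motif (e.g. `Neu5Ac(a2-?)` from `Neu5Ac(a2-3)`) is counted under wildcard
#' matching and retained only if its count vector differs from that of every
#' single specialized family member, i.e. only if it captures non-identical
#' information.
#'
#' @param x a [MotifCountMatrix-class] (typically from terminal and/or
#'   exhaustive annotation).
#' @param graphs optional pre-parsed list of [GlycanGraph-class]s matching
#'   the rows of `x` (parsed from row names otherwise).
#' @return a [MotifCountMatrix-class] with generalized columns appended.
#' @export
generateGeneralizedMotifs <- function(x, graphs = NULL) {
  stopifnot(is(x, "MotifCountMatrix"))
  tab <- x@motifs
  counts <- x@counts
  idx <- which(tab$klass %in% c("terminal", "disaccharide",
                                "monosaccharide"))
  if (!length(idx) || !nrow(counts)) return(x)
  if (is.null(graphs)) {
    graphs <- lapply(rownames(counts), parseGlycan)
    names(graphs) <- rownames(counts)
  }
  # candidate generalized pattern -> family of source motif indices
  fam <- list()
  for (i in idx) {
    for (v in .generalize_variants(tab$pattern[i])) {
      fam[[v]] <- c(fam[[v]], i)
    }
  }
  add_tab <- NULL
  add_cnt <- NULL
  for (v in names(fam)) {
    if (v %in% tab$pattern) next  # already present verbatim
    members <- fam[[v]]
    constraint <- tab$constraint[members[1L]]
    mo <- motifDefinition(v, v, constraint, NA_character_, "generalized")
    cv <- vapply(graphs, function(g) countMotif(g, mo), numeric(1))
    informative <- all(vapply(members, function(i) {
      any(cv != counts[, i])
    }, logical(1)))
    if (!informative) next
    add_tab <- rbind(add_tab, data.frame(
      name = v, pattern = v, constraint = constraint,
      excluded_context = NA_character_, klass = "generalized",
      priority = .klass_priority[[tab$klass[members[1L]]]] - 5,
      stringsAsFactors = FALSE))
    add_cnt <- cbind(add_cnt, cv)
  }
  if (is.null(add_tab)) return(x)
  colnames(add_cnt) <- add_tab$name
  dup <- add_tab$name %in% tab$name
  add_tab <- add_tab[!dup, , drop = FALSE]
  add_cnt <- add_cnt[, !dup, drop = FALSE]
  if (!nrow(add_tab)) return(x)
  new("MotifCountMatrix", counts = cbind(counts, add_cnt),
      motifs = rbind(tab, add_tab))
}

#' Annotate a glycan list with motif counts
#'
#' Builds the glycans x motifs count matrix for any combination of feature
#' sets: `"known"` (curated named epitopes), `"terminal"` (every observed
#' non-reducing residue + linkage combination), and `"exhaustive"` (every
#' observed mono- and disaccharide sub-pattern). Wildcard generalizations
#' that carry non-redundant information are appended for terminal and
#' exhaustive motifs (see [generateGeneralizedMotifs()]).
#'
#' @param glycans character vector of glycan strings (any accepted dialect).
#' @param featureSets non-empty subset of
#'   `c("known", "terminal", "exhaustive")`.
#' @param motifLibrary optional named-motif table from [loadKnownMotifs()].
#' @param deduplicate collapse motif columns with identical count vectors
#'   (see [deduplicateFeatures()]); off by default — deduplication normally
#'   happens on the quantified abundances in [quantifyMotifs()].
#' @return a [MotifCountMatrix-class].
#' @examples
#' annotateDataset("Neu5Ac(a2-3)Gal(b1-3)[Neu5Ac(a2-6)]GalNAc",
#'                 featureSets = "terminal")
#' @export
annotateDataset <- function(glycans,
                            featureSets = c("known", "terminal",
                                            "exhaustive"),
                            motifLibrary = NULL, deduplicate = FALSE) {
  featureSets <- match.arg(featureSets, c("known", "terminal", "exhaustive"),
                           several.ok = TRUE)
  stopifnot(length(glycans) >= 1L)
  canon <- vapply(glycans, function(s) {
    tryCatch(canonicalizeIUPAC(s), error = function(e) {
      stop("unparseable glycan '", s, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }, character(1), USE.NAMES = FALSE)
  graphs <- lapply(canon, parseGlycan)
  names(graphs) <- canon
  tabs <- list()
  if ("known" %in% featureSets) {
    lib <- if (is.null(motifLibrary)) loadKnownMotifs() else motifLibrary
    lib$priority <- .klass_priority[["named"]]
    tabs$known <- lib[, c("name", "pattern", "constraint",
                          "excluded_context", "klass", "priority")]
  }
  if ("terminal" %in% featureSets) {
    term <- unique(do.call(rbind, lapply(graphs, function(g) {
      tr <- terminalResidues(g)
      data.frame(pattern = paste0(tr$residue, "(", tr$linkage, ")"),
                 stringsAsFactors = FALSE)
    })))
    if (nrow(term)) {
      tabs$terminal <- data.frame(
        name = term$pattern, pattern = term$pattern,
        constraint = "terminal", excluded_context = NA_character_,
        klass = "terminal", priority = .klass_priority[["terminal"]],
        stringsAsFactors = FALSE)
    }
  }
  if ("exhaustive" %in% featureSets) {
    mono <- unique(unlist(lapply(graphs, function(g) {
      vapply(seq_along(g@base), function(i) .residue_string(g, i), "")
    })))
    di <- unique(unlist(lapply(graphs, function(g) {
      linked <- which(!is.na(g@parent))
      vapply(linked, function(i) {
        paste0(.residue_string(g, i), "(", g@anomeric[i], g@childPos[i],
               "-", g@parentPos[i], ")", .residue_string(g, g@parent[i]))
      }, "")
    })))
    ex <- data.frame(
      name = c(mono, di), pattern = c(mono, di),
      constraint = "flexible", excluded_context = NA_character_,
      klass = rep(c("monosaccharide", "disaccharide"),
                  c(length(mono), length(di))),
      stringsAsFactors = FALSE)
    ex$priority <- .klass_priority[ex$klass]
    tabs$exhaustive <- ex
  }
  tab <- do.call(rbind, tabs)
  rownames(tab) <- NULL
  tab <- tab[!duplicated(tab$name), , drop = FALSE]
  counts <- .count_matrix(graphs, tab)
  res <- new("MotifCountMatrix", counts = counts, motifs = tab)
  if (any(c("terminal", "exhaustive") %in% featureSets)) {
    res <- generateGeneralizedMotifs(res, graphs)
  }
  if (deduplicate) {
    keep <- .dedup_keep(t(res@counts), res@motifs$priority)
    res <- new("MotifCountMatrix",
               counts = res@counts[, keep, drop = FALSE],
               motifs = res@motifs[keep, , drop = FALSE])
  }
  res
}

# indices of rows to keep after collapsing identical row vectors;
# representative = highest priority, then longest name, then lexicographic
.dedup_keep <- function(x, priority = NULL) {
  if (is.null(priority)) priority <- rep(0, nrow(x))
  key <- vapply(seq_len(nrow(x)), function(i) {
    paste(sprintf("%.15g", x[i, ]), collapse = "\r")
  }, character(1))
  nm <- rownames(x)
  if (is.null(nm)) nm <- as.character(seq_len(nrow(x)))
  keep <- vapply(split(seq_len(nrow(x)), key), function(idx) {
    ord <- order(-priority[idx], -nchar(nm[idx]), nm[idx])
    idx[ord[1L]]
  }, integer(1))
  sort(unname(keep))
}

#' Collapse features with identical value vectors
#'
#' Features (rows) whose value vectors are exactly identical are collapsed
#' to a single representative, prioritized as named motif > disaccharide >
#' terminal > monosaccharide (wildcard-generalized motifs rank just below
#' their concrete class); ties are broken by longer pattern, then
#' lexicographically.
#'
#' @param x features x samples matrix (or [GlycomicsExperiment-class]).
#' @param klass optional character vector of motif classes, one per row.
#' @return object of the same kind with duplicate rows removed.
#' @export
deduplicateFeatures <- function(x, klass = NULL) {
  m <- .as_matrix(x)
  priority <- if (is.null(klass)) NULL else {
    unname(.klass_priority[klass])
  }
  keep <- .dedup_keep(m, priority)
  .like_input(x, m[keep, , drop = FALSE])
}

#' Proportional motif quantification
#'
#' Converts per-sample glycan relative abundances into motif abundances:
#' each glycan's abundance is weighted by its motif occurrence count and
#' summed per motif, so motif density (e.g. several antennae carrying the
#' same epitope) is reflected; each sample column is then rescaled to sum to
#' 100 and redundant motifs are collapsed with [deduplicateFeatures()].
#'
#' @param x glycans x samples abundance matrix (or
#'   [GlycomicsExperiment-class]); rows must correspond 1:1 to `glycans`.
#' @param glycans glycan strings (default: row names of `x`).
#' @param featureSets,motifLibrary see [annotateDataset()].
#' @param deduplicate collapse motifs with identical abundance vectors
#'   (default `TRUE`).
#' @return motifs x samples abundance matrix (columns sum to 100), or a
#'   [GlycomicsExperiment-class] if one was supplied.
#' @examples
#' m <- matrix(c(60, 40), 2, 1, dimnames = list(
#'   c("Neu5Ac(a2-6)GalNAc", "Gal(b1-3)GalNAc"), "s1"))
#' quantifyMotifs(m, featureSets = "terminal")
#' @export
quantifyMotifs <- function(x, glycans = NULL,
                           featureSets = c("known", "terminal",
                                           "exhaustive"),
                           motifLibrary = NULL, deduplicate = TRUE) {
  m <- .as_matrix(x)
  if (is.null(glycans)) glycans <- rownames(m)
  if (is.null(glycans) || length(glycans) != nrow(m)) {
    stop("glycan list and abundance rows do not match", call. = FALSE)
  }
  if (anyNA(m)) {
    stop("motif quantification requires a complete table; impute first",
         call. = FALSE)
  }
  ann <- annotateDataset(glycans, featureSets, motifLibrary,
                         deduplicate = FALSE)
  w <- t(ann@counts) %*% m  # motifs x samples weighted sums
  nonzero <- rowSums(w) > 0
  w <- w[nonzero, , drop = FALSE]
  tab <- ann@motifs[nonzero, , drop = FALSE]
  if (deduplicate) {
    # collapse before rescaling so the output stays compositional
    # (row identity is unaffected by the per-sample scaling)
    keep <- .dedup_keep(w, tab$priority)
    w <- w[keep, , drop = FALSE]
  }
  tot <- colSums(w)
  if (any(tot <= 0)) {
    stop("no motif abundance in sample(s): ",
         paste(colnames(m)[tot <= 0], collapse = ", "), call. = FALSE)
  }
  w <- sweep(w, 2, tot, "/") * 100
  .like_input(x, w)
}
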