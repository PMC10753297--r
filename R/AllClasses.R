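#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- colData
NULL

#' Rooted labeled tree representation of a glycan
#'
#' A glycan in IUPAC-condensed notation is a rooted, directed, labeled tree:
#' the reducing-end residue is the root and every other monosaccharide is
#' linked to exactly one parent through an anomeric configuration and a pair
#' of carbon positions. Substituents (e.g. sulfation) are stored per residue
#' as (position, group) pairs.
#'
#' @slot base character vector of monosaccharide base tokens, one per node.
#' @slot substituents list (one element per node) of data.frames with columns
#'   `pos` (single digit or `"?"`) and `group` (e.g. `"S"` for sulfate).
#' @slot parent integer vector; `parent[i]` is the node index of the parent
#'   of node `i`, `NA` for the root.
#' @slot anomeric,childPos,parentPos character vectors describing the linkage
#'   of each node to its parent (`NA` for the root): anomeric configuration
#'   (`"a"`, `"b"` or `"?"`), child carbon and parent carbon (digit or `"?"`).
#'
#' @seealso [parseGlycan()], [glycanToString()], [countMotif()]
#' @export
setClass("GlycanGraph",
  representation(
    base = "character",
    substituents = "list",
    parent = "integer",
    anomeric = "character",
    childPos = "character",
    parentPos = "character"
  )
)

setValidity("GlycanGraph", function(object) {
  n <- length(object@base)
  if (n < 1L) return("a glycan must contain at least one residue")
  lens <- c(
    length(object@substituents), length(object@parent),
    length(object@anomeric), length(object@childPos),
    length(object@parentPos)
  )
  if (any(lens != n)) return("slot lengths disagree")
  roots <- which(is.na(object@parent))
  if (length(roots) != 1L) return("exactly one root (reducing end) required")
  if (any(stats::na.omit(object@parent) < 1L) ||
      any(stats::na.omit(object@parent) > n)) {
    return("parent index out of range")
  }
  # tree: walking up from every node must reach the root without cycles
  for (i in seq_len(n)) {
    seen <- logical(n)
    j <- i
    while (!is.na(object@parent[j])) {
      if (seen[j]) return("cycle detected; glycan is not a tree")
      seen[j] <- TRUE
      j <- object@parent[j]
    }
  }
  TRUE
})

#' @describeIn GlycanGraph number of residues
#' @param x,object a `GlycanGraph`
#' @export
setMethod("length", "GlycanGraph", function(x) length(x@base))

setMethod("show", "GlycanGraph", function(object) {
  cat("GlycanGraph with", length(object@base), "residue(s):",
      glycanToString(object), "\n")
})

#' Motif definition used for subgraph counting
#'
#' A motif is a connected glycan fragment (pattern) plus a positional
#' constraint that restricts where in a glycan it may match, an optional
#' excluded context (a branch that must NOT hang off the matched root, used
#' e.g. so core 1 structures are not double-counted inside core 2), and a
#' class used to prioritize representatives during deduplication.
#'
#' @slot name unique motif name.
#' @slot pattern IUPAC-condensed fragment; a single residue followed by a
#'   dangling linkage, e.g. `"Neu5Ac(a2-?)"`, denotes a terminal
#'   residue-plus-linkage motif.
#' @slot constraint one of `"terminal"`, `"internal"`, `"reducing-end"`,
#'   `"flexible"`.
#' @slot excludedContext optional pattern with a trailing linkage that must
#'   not be attached to the glycan node matched by the pattern root
#'   (`NA_character_` for none).
#' @slot klass one of `"named"`, `"terminal"`, `"disaccharide"`,
#'   `"monosaccharide"`, `"generalized"`.
#' @export
setClass("MotifDefinition",
  representation(
    name = "character",
    pattern = "character",
    constraint = "character",
    excludedContext = "character",
    klass = "character"
  ),
  prototype(
    constraint = "flexible",
    excludedContext = NA_character_,
    klass = "named"
  )
)

setValidity("MotifDefinition", function(object) {
  if (length(object@name) != 1L || !nzchar(object@name)) {
    return("name must be a single non-empty string")
  }
  if (!object@constraint %in%
      c("terminal", "internal", "reducing-end", "flexible")) {
    return("invalid constraint")
  }
  if (!object@klass %in%
      c("named", "terminal", "disaccharide", "monosaccharide",
        "generalized")) {
    return("invalid klass")
  }
  TRUE
})

#' Construct a MotifDefinition
#'
#' @param name unique motif name.
#' @param pattern IUPAC-condensed fragment (canonical or paper dialect).
#' @param constraint positional constraint, see [MotifDefinition-class].
#' @param excludedContext optional excluded branch pattern, e.g.
#'   `"GlcNAc(b1-6)"`.
#' @param klass motif class used for deduplication priority.
#' @return a [MotifDefinition-class] object.
#' @examples
#' motifDefinition("diSialylT",
#'   "Neu5Ac(a2-3)Gal(b1-3)[Neu5Ac(a2-6)]GalNAc",
#'   constraint = "reducing-end")
#' @export
motifDefinition <- function(name, pattern, constraint = "flexible",
                            excludedContext = NA_character_,
                            klass = "named") {
  new("MotifDefinition", name = as.character(name),
      pattern = as.character(pattern), constraint = constraint,
      excludedContext = as.character(excludedContext), klass = klass)
}

setMethod("show", "MotifDefinition", function(object) {
  cat(sprintf("MotifDefinition '%s' [%s, %s]: %s%s\n",
              object@name, object@klass, object@constraint, object@pattern,
              if (!is.na(object@excludedContext)) {
                paste0(" (excluding ", object@excludedContext, ")")
              } else ""))
})

#' Container for glycan or motif abundance tables
#'
#' Thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' features x samples abundance matrix (assay `"abundance"`; `NA` marks a
#' missing value) plus optional per-sample group labels and timepoints in
#' `colData`.
#'
#' @export
setClass("GlycomicsExperiment", contains = "SummarizedExperiment")

setValidity("GlycomicsExperiment", function(object) {
  if (!"abundance" %in% SummarizedExperiment::assayNames(object)) {
    return("assay 'abundance' required")
  }
  a <- SummarizedExperiment::assay(object, "abundance")
  if (!is.numeric(a)) return("abundance assay must be numeric")
  if (any(a < 0, na.rm = TRUE)) return("abundances must be nonnegative")
  TRUE
})

#' Construct a GlycomicsExperiment
#'
#' @param abundance numeric matrix or data.frame, features x samples, with
#'   row and column names; `NA` marks missing values.
#' @param groups optional character/factor vector of group labels, one per
#'   sample (or named by sample).
#' @param timepoints optional numeric vector of timepoints, one per sample.
#' @return a [GlycomicsExperiment-class].
#' @examples
#' m <- matrix(c(60, 40, 55, 45), 2, dimnames = list(
#'   c("Neu5Ac(a2-6)GalNAc", "Gal(b1-3)GalNAc"), c("s1", "s2")))
#' GlycomicsExperiment(m, groups = c("ctrl", "case"))
#' @export
GlycomicsExperiment <- function(abundance, groups = NULL, timepoints = NULL) {
  abundance <- as.matrix(abundance)
  storage.mode(abundance) <- "double"
  cd <- S4Vectors::DataFrame(row.names = colnames(abundance))
  if (!is.null(groups)) {
    if (!is.null(names(groups))) groups <- groups[colnames(abundance)]
    stopifnot(length(groups) == ncol(abundance))
    cd$group <- as.character(groups)
  }
  if (!is.null(timepoints)) {
    if (!is.null(names(timepoints))) {
      timepoints <- timepoints[colnames(abundance)]
    }
    stopifnot(length(timepoints) == ncol(abundance))
    cd$timepoint <- as.numeric(timepoints)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = abundance), colData = cd)
  new("GlycomicsExperiment", se)
}

#' @describeIn GlycomicsExperiment the abundance matrix
#' @param x a `GlycomicsExperiment`
#' @export
abundances <- function(x) SummarizedExperiment::assay(x, "abundance")

#' @describeIn GlycomicsExperiment per-sample group labels (or `NULL`)
#' @export
sampleGroups <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("group" %in% colnames(cd)) stats::setNames(cd$group, rownames(cd)) else NULL
}

#' @describeIn GlycomicsExperiment per-sample timepoints (or `NULL`)
#' @export
timePoints <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("timepoint" %in% colnames(cd)) {
    stats::setNames(cd$timepoint, rownames(cd))
  } else NULL
}

setMethod("show", "GlycomicsExperiment", function(object) {
  a <- abundances(object)
  cat(sprintf(
    "GlycomicsExperiment: %d features x %d samples (%d missing values)\n",
    nrow(a), ncol(a), sum(is.na(a))))
  g <- sampleGroups(object)
  if (!is.null(g)) {
    cat("groups:", paste(sprintf("%s (n=%d)", names(table(g)), table(g)),
                         collapse = ", "), "\n")
  }
  tp <- timePoints(object)
  if (!is.null(tp)) {
    cat("timepoints:", paste(sort(unique(tp)), collapse = ", "), "\n")
  }
})

# internal: accept a GlycomicsExperiment or a plain matrix
.as_matrix <- function(x) {
  if (is(x, "GlycomicsExperiment")) abundances(x) else {
    m <- as.matrix(x)
    storage.mode(m) <- "double"
    m
  }
}

# internal: return result in the same container class as the input
.like_input <- function(x, m) {
  if (is(x, "GlycomicsExperiment")) {
    GlycomicsExperiment(m,
      groups = {
        g <- sampleGroups(x)
        if (is.null(g)) NULL else g[colnames(m)]
      },
      timepoints = {
        tp <- timePoints(x)
        if (is.null(tp)) NULL else tp[colnames(m)]
      })
  } else m
}
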