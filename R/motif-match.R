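## Wildcard-aware subtree matching of motif patterns inside glycans.
##
## A match is an injective map from motif nodes to glycan nodes preserving
## child -> parent edges. "?" in a motif linkage field or substituent
## position matches any value (including "?"); a concrete motif value
## matches itself or a glycan "?". Matches are counted as distinct node
## subsets, so automorphic duplicates of the same subset count once.

.val_match <- function(mv, gv) mv == "?" | gv == "?" | mv == gv

.residue_match <- function(m, mi, g, gi) {
  if (m@base[mi] != "?" && m@base[mi] != g@base[gi]) return(FALSE)
  ms <- m@substituents[[mi]]
  gs <- g@substituents[[gi]]
  if (nrow(ms) != nrow(gs)) return(FALSE)
  if (!nrow(ms)) return(TRUE)
  # match substituent multisets with position wildcards (greedy injective)
  used <- logical(nrow(gs))
  for (k in seq_len(nrow(ms))) {
    cand <- which(!used & gs$group == ms$group[k] &
                    .val_match(ms$pos[k], gs$pos))
    if (!length(cand)) return(FALSE)
    used[cand[1L]] <- TRUE
  }
  TRUE
}

.link_match <- function(m, mi, g, gi) {
  .val_match(m@anomeric[mi], g@anomeric[gi]) &&
    .val_match(m@childPos[mi], g@childPos[gi]) &&
    .val_match(m@parentPos[mi], g@parentPos[gi])
}

.children_of <- function(g, i) which(!is.na(g@parent) & g@parent == i)

# all injective assignments of motif children (rooted at mi, mapped to gi)
# to glycan children; returns list of named integer maps (motif -> glycan)
.match_down <- function(m, mi, g, gi) {
  if (!.residue_match(m, mi, g, gi)) return(list())
  mkids <- .children_of(m, mi)
  if (!length(mkids)) {
    res <- list(stats::setNames(gi, mi))
    return(res)
  }
  gkids <- .children_of(g, gi)
  if (length(gkids) < length(mkids)) return(list())
  # per motif child, the glycan children it could map to (with sub-maps)
  sub <- lapply(mkids, function(mk) {
    hits <- list()
    for (gk in gkids) {
      if (.link_match(m, mk, g, gk)) {
        for (mm in .match_down(m, mk, g, gk)) {
          hits[[length(hits) + 1L]] <- list(gk = gk, map = mm)
        }
      }
    }
    hits
  })
  out <- list()
  assign_rec <- function(k, usedg, acc) {
    if (k > length(mkids)) {
      out[[length(out) + 1L]] <<- c(stats::setNames(gi, mi), acc)
      return(invisible())
    }
    for (h in sub[[k]]) {
      if (h$gk %in% usedg) next
      assign_rec(k + 1L, c(usedg, h$gk), c(acc, h$map))
    }
  }
  assign_rec(1L, integer(0), integer(0))
  out
}

# parse a motif pattern, splitting off a dangling trailing linkage
# like "Neu5Ac(a2-?)" -> pattern graph "Neu5Ac" + link c(a, 2, ?)
.parse_pattern <- function(pattern, bases = .default_bases()) {
  s <- .normalize_dialect(pattern)
  dangling <- NULL
  if (grepl("\\([ab?][0-9?]-[0-9?]\\)$", s)) {
    lk <- sub("^.*\\(([ab?][0-9?]-[0-9?])\\)$", "\\1", s)
    head <- sub("\\([ab?][0-9?]-[0-9?]\\)$", "", s)
    dangling <- .split_link(lk)
    s <- head
  }
  list(graph = parseGlycan(s, bases), dangling = dangling)
}

.glycan_leaves <- function(g) {
  setdiff(seq_along(g@base), stats::na.omit(g@parent))
}

# does glycan node `anchor` have a child branch matching the excluded
# context (pattern with dangling linkage attached at the anchor)?
.context_attached <- function(ctx, g, anchor) {
  cg <- ctx$graph
  croot <- which(is.na(cg@parent))
  for (gk in .children_of(g, anchor)) {
    if (!is.null(ctx$dangling)) {
      lk_ok <- .val_match(ctx$dangling[["anomeric"]], g@anomeric[gk]) &&
        .val_match(ctx$dangling[["child"]], g@childPos[gk]) &&
        .val_match(ctx$dangling[["parent"]], g@parentPos[gk])
      if (!lk_ok) next
    }
    if (length(.match_down(cg, croot, g, gk))) return(TRUE)
  }
  FALSE
}

#' Count occurrences of a motif within a glycan
#'
#' Counts the distinct node subsets of the glycan whose induced connected
#' subtree matches the motif pattern under wildcard semantics, subject to
#' the motif's positional constraint and optional excluded context.
#' Overlapping matches each count once; automorphic duplicates of one node
#' subset count once.
#'
#' Constraints: `"terminal"` requires every leaf-most pattern residue to map
#' to a non-reducing terminus of the glycan; `"reducing-end"` anchors the
#' pattern root at the glycan root; `"internal"` forbids mapping any pattern
#' node to a non-reducing terminus; `"flexible"` matches anywhere. A pattern
#' consisting of a residue plus a dangling linkage (e.g. `"Neu5Ac(a2-?)"`)
#' additionally requires the linkage to the matched node's parent to agree
#' (single-residue glycans expose the null linkage `"?1-?"`).
#'
#' @param glycan a [GlycanGraph-class] or glycan string.
#' @param motif a [MotifDefinition-class], or a pattern string (combined
#'   with `constraint`/`excludedContext`).
#' @param constraint,excludedContext used when `motif` is a plain pattern
#'   string; see [MotifDefinition-class].
#' @return nonnegative integer count.
#' @examples
#' countMotif("Neu5Ac(a2-3)Gal(b1-3)[Neu5Ac(a2-6)]GalNAc",
#'            "Neu5Ac(a2-?)", constraint = "terminal")
#' @export
countMotif <- function(glycan, motif, constraint = "flexible",
                       excludedContext = NA_character_) {
  if (is.character(glycan)) glycan <- parseGlycan(glycan)
  if (is.character(motif)) {
    motif <- motifDefinition(motif, motif, constraint = constraint,
                             excludedContext = excludedContext)
  }
  stopifnot(is(glycan, "GlycanGraph"), is(motif, "MotifDefinition"))
  pat <- .parse_pattern(motif@pattern)
  m <- pat$graph
  g <- glycan
  ctx <- if (!is.na(motif@excludedContext)) {
    .parse_pattern(motif@excludedContext)
  } else NULL
  mroot <- which(is.na(m@parent))
  mleaves <- .glycan_leaves(m)
  gleaves <- .glycan_leaves(g)
  groot <- which(is.na(g@parent))
  anchors <- if (motif@constraint == "reducing-end") groot else
    seq_along(g@base)
  subsets <- character(0)
  for (a in anchors) {
    if (!is.null(pat$dangling)) {
      # residue-plus-linkage motif: check the anchor's linkage to ITS parent
      an <- if (is.na(g@parent[a])) {
        c(anomeric = "?", child = "1", parent = "?")  # null linkage ?1-?
      } else {
        c(anomeric = g@anomeric[a], child = g@childPos[a],
          parent = g@parentPos[a])
      }
      if (!(.val_match(pat$dangling[["anomeric"]], an[["anomeric"]]) &&
            .val_match(pat$dangling[["child"]], an[["child"]]) &&
            .val_match(pat$dangling[["parent"]], an[["parent"]]))) next
    }
    for (map in .match_down(m, mroot, g, a)) {
      gnodes <- unname(map)
      ok <- switch(motif@constraint,
        "terminal" = all(map[as.character(mleaves)] %in% gleaves),
        "internal" = !any(gnodes %in% gleaves),
        "reducing-end" = ,
        "flexible" = TRUE,
        stop("unknown constraint '", motif@constraint, "'")
      )
      if (!ok) next
      if (!is.null(ctx) && .context_attached(ctx, g, a)) next
      subsets <- c(subsets, paste(sort(gnodes), collapse = ","))
    }
  }
  length(unique(subsets))
}
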