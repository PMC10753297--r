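# Independent oracles used across the test suite. These deliberately use
# different algorithms from the package: motif counts are recomputed by
# enumerating every connected node subset of the glycan tree, and graph
# isomorphism is checked by recursive permutation matching.

# field match with wildcard semantics: "?" matches anything, a concrete
# value matches itself or "?"
.o_val <- function(a, b) a == "?" || b == "?" || a == b

.o_children <- function(g, i) which(!is.na(g@parent) & g@parent == i)

.o_subst_key <- function(g, i) {
  s <- g@substituents[[i]]
  if (!nrow(s)) return(character(0))
  paste(s$pos, s$group, sep = ":")
}

# exact isomorphism of two glycan graphs (no wildcards; used for
# parse/serialize round trips)
iso_glycans <- function(g1, g2) {
  rec <- function(i, j) {
    if (g1@base[i] != g2@base[j]) return(FALSE)
    k1 <- sort(.o_subst_key(g1, i))
    k2 <- sort(.o_subst_key(g2, j))
    if (!identical(k1, k2)) return(FALSE)
    c1 <- .o_children(g1, i)
    c2 <- .o_children(g2, j)
    if (length(c1) != length(c2)) return(FALSE)
    if (!length(c1)) return(TRUE)
    link_eq <- function(a, b) {
      g1@anomeric[a] == g2@anomeric[b] &&
        g1@childPos[a] == g2@childPos[b] &&
        g1@parentPos[a] == g2@parentPos[b]
    }
    perms <- function(v) {
      if (length(v) <= 1L) return(list(v))
      out <- list()
      for (k in seq_along(v)) {
        for (p in perms(v[-k])) out[[length(out) + 1L]] <- c(v[k], p)
      }
      out
    }
    for (p in perms(c2)) {
      ok <- TRUE
      for (t in seq_along(c1)) {
        if (!link_eq(c1[t], p[t]) || !rec(c1[t], p[t])) {
          ok <- FALSE
          break
        }
      }
      if (ok) return(TRUE)
    }
    FALSE
  }
  length(g1@base) == length(g2@base) &&
    rec(which(is.na(g1@parent)), which(is.na(g2@parent)))
}

# all isomorphism mappings (pattern node -> glycan node) of a pattern tree
# onto the subtree induced by `subset` (rooted at the subset's top node),
# with wildcard matching of linkages / substituent positions
.o_mappings <- function(m, g, subset) {
  sub_root <- subset[!(g@parent[subset] %in% subset)]
  if (length(sub_root) != 1L) return(list())
  node_ok <- function(mi, gi) {
    if (m@base[mi] != "?" && m@base[mi] != g@base[gi]) return(FALSE)
    ms <- m@substituents[[mi]]
    gs <- g@substituents[[gi]]
    if (nrow(ms) != nrow(gs)) return(FALSE)
    if (!nrow(ms)) return(TRUE)
    # try all pairings of substituents
    perm_idx <- function(n) {
      if (n == 1L) return(list(1L))
      out <- list()
      for (p in perm_idx(n - 1L)) {
        for (pos in 0:(n - 1L)) {
          out[[length(out) + 1L]] <- append(p, n, after = pos)
        }
      }
      out
    }
    for (p in perm_idx(nrow(ms))) {
      ok <- all(vapply(seq_len(nrow(ms)), function(k) {
        ms$group[k] == gs$group[p[k]] && .o_val(ms$pos[k], gs$pos[p[k]])
      }, logical(1)))
      if (ok) return(TRUE)
    }
    FALSE
  }
  link_ok <- function(mi, gi) {
    .o_val(m@anomeric[mi], g@anomeric[gi]) &&
      .o_val(m@childPos[mi], g@childPos[gi]) &&
      .o_val(m@parentPos[mi], g@parentPos[gi])
  }
  rec <- function(mi, gi) {
    if (!node_ok(mi, gi)) return(list())
    mk <- .o_children(m, mi)
    gk <- intersect(.o_children(g, gi), subset)
    if (length(mk) != length(gk)) return(list())  # induced subtree must match
    if (!length(mk)) return(list(stats::setNames(gi, mi)))
    perms <- function(v) {
      if (length(v) <= 1L) return(list(v))
      out <- list()
      for (k in seq_along(v)) {
        for (p in perms(v[-k])) out[[length(out) + 1L]] <- c(v[k], p)
      }
      out
    }
    maps <- list()
    for (p in perms(gk)) {
      partial <- list(stats::setNames(gi, mi))
      ok <- TRUE
      for (t in seq_along(mk)) {
        if (!link_ok(mk[t], p[t])) {
          ok <- FALSE
          break
        }
        sub_maps <- rec(mk[t], p[t])
        if (!length(sub_maps)) {
          ok <- FALSE
          break
        }
        partial <- unlist(lapply(partial, function(q) {
          lapply(sub_maps, function(sm) c(q, sm))
        }), recursive = FALSE)
      }
      if (ok) maps <- c(maps, partial)
    }
    maps
  }
  rec(which(is.na(m@parent)), sub_root)
}

# brute-force motif count: enumerate every connected node subset and test it
bf_count_motif <- function(glycan, motif) {
  g <- if (is.character(glycan)) parseGlycan(glycan) else glycan
  if (is.character(motif)) motif <- motifDefinition(motif, motif)
  pat <- glycodiff:::.parse_pattern(motif@pattern)
  m <- pat$graph
  n <- length(g@base)
  stopifnot(n <= 14)
  leaves <- setdiff(seq_len(n), stats::na.omit(g@parent))
  groot <- which(is.na(g@parent))
  ctx <- if (!is.na(motif@excludedContext)) {
    glycodiff:::.parse_pattern(motif@excludedContext)
  } else NULL
  total <- 0L
  for (code in seq_len(2^n - 1L)) {
    subset <- which(bitwAnd(code, 2^(seq_len(n) - 1L)) > 0L)
    if (length(subset) != length(m@base)) next
    tops <- subset[!(g@parent[subset] %in% subset)]
    if (length(tops) != 1L) next  # not connected
    maps <- .o_mappings(m, g, subset)
    if (!length(maps)) next
    keep <- FALSE
    for (map in maps) {
      mroot_img <- map[[as.character(which(is.na(m@parent)))]]
      # dangling linkage (residue + linkage motifs)
      if (!is.null(pat$dangling)) {
        a <- mroot_img
        lk <- if (is.na(g@parent[a])) c("?", "1", "?") else {
          c(g@anomeric[a], g@childPos[a], g@parentPos[a])
        }
        if (!(.o_val(pat$dangling[["anomeric"]], lk[1]) &&
              .o_val(pat$dangling[["child"]], lk[2]) &&
              .o_val(pat$dangling[["parent"]], lk[3]))) next
      }
      mleaves <- setdiff(seq_along(m@base), stats::na.omit(m@parent))
      ok <- switch(motif@constraint,
        terminal = all(unlist(map[as.character(mleaves)]) %in% leaves),
        internal = !any(unlist(map) %in% leaves),
        `reducing-end` = mroot_img == groot,
        flexible = TRUE)
      if (!ok) next
      if (!is.null(ctx)) {
        attached <- FALSE
        for (ch in .o_children(g, mroot_img)) {
          if (!is.null(ctx$dangling)) {
            if (!(.o_val(ctx$dangling[["anomeric"]], g@anomeric[ch]) &&
                  .o_val(ctx$dangling[["child"]], g@childPos[ch]) &&
                  .o_val(ctx$dangling[["parent"]], g@parentPos[ch]))) next
          }
          # context pattern matches downward from ch (prefix match: extra
          # glycan children allowed)
          if (length(.o_prefix_map(ctx$graph, g, ch))) {
            attached <- TRUE
            break
          }
        }
        if (attached) next
      }
      keep <- TRUE
      break
    }
    if (keep) total <- total + 1L
  }
  total
}

# prefix mapping (extra glycan children allowed), for excluded contexts
.o_prefix_map <- function(m, g, gi, mi = which(is.na(m@parent))) {
  if (m@base[mi] != "?" && m@base[mi] != g@base[gi]) return(list())
  ms <- m@substituents[[mi]]
  gs <- g@substituents[[gi]]
  if (nrow(ms) != nrow(gs)) return(list())
  if (nrow(ms)) {
    ok <- all(vapply(seq_len(nrow(ms)), function(k) {
      any(ms$group[k] == gs$group & vapply(gs$pos, function(p) {
        .o_val(ms$pos[k], p)
      }, logical(1)))
    }, logical(1)))
    if (!ok) return(list())
  }
  mk <- .o_children(m, mi)
  if (!length(mk)) return(list(gi))
  gk <- .o_children(g, gi)
  assign_rec <- function(t, used) {
    if (t > length(mk)) return(TRUE)
    for (cand in setdiff(gk, used)) {
      lk <- .o_val(m@anomeric[mk[t]], g@anomeric[cand]) &&
        .o_val(m@childPos[mk[t]], g@childPos[cand]) &&
        .o_val(m@parentPos[mk[t]], g@parentPos[cand])
      if (lk && length(.o_prefix_map(m, g, cand, mk[t]))) {
        if (assign_rec(t + 1L, c(used, cand))) return(TRUE)
      }
    }
    FALSE
  }
  if (assign_rec(1L, integer(0))) list(gi) else list()
}

# small pool of fixture glycans used in parameterised tests
oracle_fixture_glycans <- function(n = 50) {
  fx <- fixtureGlycans("all")
  sizes <- vapply(fx, function(s) length(parseGlycan(s)), numeric(1))
  fx <- fx[sizes <= 12]
  fx[seq_len(min(n, length(fx)))]
}
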