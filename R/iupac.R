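## Parsing and canonical serialization of IUPAC-condensed glycan strings.
##
## Accepted input dialects:
##   * Greek (alpha/beta) or latin (a/b) anomeric letters
##   * branches in parentheses (journal style) or square brackets
##   * linkages with or without surrounding parentheses
##   * inline substituents such as "GlcNAc6S" or "GalOS" ("O" = unknown
##     position)
## Canonical output: latin anomeric letters, parenthesized linkages
## "(a2-3)", branches in square brackets, branches at a node ordered by
## parent attachment position (ascending, "?" last; ties by subtree string),
## the first branch written as the unbracketed backbone.

# base monosaccharide alphabet, longest-first so prefix matching is greedy;
# unknown tokens are accepted as opaque labels (with a warning)
.default_bases <- function() {
  b <- c("GlcNAc", "GalNAc", "ManNAc", "Neu5Ac", "Neu5Gc", "HexNAc",
         "GlcA", "IdoA", "GalA", "ManA", "Kdn", "Gal", "Glc", "Man",
         "Fuc", "Xyl", "Rha", "Ara", "Rib", "Fru", "Qui", "All", "Hex",
         "Neu", "Api", "Kdo", "Tal", "Ido", "Alt", "Gul", "Lyx", "Sia")
  b[order(nchar(b), decreasing = TRUE)]
}

.subst_groups <- c("Ac", "Me", "S", "P", "Gc", "N")

.link_rx <- "^[ab?][0-9?]-[0-9?]$"

# transliterate anomeric letters and strip whitespace
.latinize <- function(s) {
  s <- gsub("α", "a", s, fixed = TRUE)
  s <- gsub("β", "b", s, fixed = TRUE)
  gsub("[[:space:]]", "", s)
}

# classify parenthesis groups as linkages (kept) or branches (-> brackets)
.brackets_for_branches <- function(s) {
  chars <- strsplit(s, "")[[1]]
  out <- character(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    if (chars[i] == "(") {
      depth <- 1L
      j <- i
      while (depth > 0L) {
        j <- j + 1L
        if (j > n) stop("unbalanced parentheses in '", s, "'", call. = FALSE)
        if (chars[j] == "(") depth <- depth + 1L
        if (chars[j] == ")") depth <- depth - 1L
      }
      inner <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      inner <- .brackets_for_branches(inner)
      if (grepl(.link_rx, inner)) {
        out <- c(out, "(", inner, ")")
      } else {
        out <- c(out, "[", inner, "]")
      }
      i <- j + 1L
    } else {
      out <- c(out, chars[i])
      i <- i + 1L
    }
  }
  paste(out, collapse = "")
}

# wrap bare linkages like "a2-3" (not already parenthesized)
.wrap_bare_linkages <- function(s) {
  gsub("(?<![(])([ab?])([0-9?])-([0-9?])(?![)])", "(\\1\\2-\\3)", s,
       perl = TRUE)
}

# normalize any accepted dialect into the canonical token layout
# (without reordering branches; ordering happens at serialization)
.normalize_dialect <- function(s) {
  .wrap_bare_linkages(.brackets_for_branches(.latinize(s)))
}

## ---- tokenizer ------------------------------------------------------------

# tokens: residue text / link text / "[" / "]"
.tokenize_glycan <- function(s) {
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  toks <- vector("list", 0L)
  buf <- character(0)
  flush <- function() {
    if (length(buf)) {
      toks[[length(toks) + 1L]] <<- list(type = "residue",
                                         text = paste(buf, collapse = ""))
      buf <<- character(0)
    }
  }
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      flush()
      j <- i
      while (chars[j] != ")") {
        j <- j + 1L
        if (j > n) stop("unbalanced parentheses in '", s, "'", call. = FALSE)
      }
      lk <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      if (!grepl(.link_rx, lk)) {
        stop("unparseable linkage token '(", lk, ")' in '", s, "'",
             call. = FALSE)
      }
      toks[[length(toks) + 1L]] <- list(type = "link", text = lk)
      i <- j + 1L
    } else if (ch == "[" || ch == "]") {
      flush()
      toks[[length(toks) + 1L]] <- list(type = if (ch == "[") "open" else
                                          "close", text = ch)
      i <- i + 1L
    } else if (grepl("^[A-Za-z0-9?]$", ch)) {
      buf <- c(buf, ch)
      i <- i + 1L
    } else {
      stop("unparseable character '", ch, "' in '", s, "'", call. = FALSE)
    }
  }
  flush()
  toks
}

# split a residue token into base + substituents
.parse_residue <- function(txt, bases = .default_bases()) {
  if (txt == "?") {
    return(list(base = "?", subst = data.frame(pos = character(0),
                                               group = character(0))))
  }
  hit <- bases[startsWith(txt, bases)]
  if (length(hit)) {
    base <- hit[1L]
    rest <- substring(txt, nchar(base) + 1L)
    subst <- data.frame(pos = character(0), group = character(0))
    grp_alt <- paste(.subst_groups, collapse = "|")
    rx <- paste0("^([0-9?O])(", grp_alt, ")")
    ok <- TRUE
    while (nzchar(rest)) {
      m <- regmatches(rest, regexec(rx, rest))[[1]]
      if (!length(m)) { ok <- FALSE; break }
      pos <- if (m[2] == "O") "?" else m[2]
      subst <- rbind(subst, data.frame(pos = pos, group = m[3]))
      rest <- substring(rest, nchar(m[1]) + 1L)
    }
    if (ok) return(list(base = base, subst = subst))
  }
  warning("unknown monosaccharide token '", txt,
          "'; kept as opaque label", call. = FALSE)
  list(base = txt, subst = data.frame(pos = character(0),
                                      group = character(0)))
}

.split_link <- function(lk) {
  c(anomeric = substring(lk, 1L, 1L), child = substring(lk, 2L, 2L),
    parent = substring(lk, 4L, 4L))
}

## ---- parser ---------------------------------------------------------------

# mutable accumulator for nodes
.new_builder <- function() {
  e <- new.env(parent = emptyenv())
  e$base <- character(0)
  e$subst <- list()
  e$parent <- integer(0)
  e$an <- character(0)
  e$cp <- character(0)
  e$pp <- character(0)
  e
}

.add_node <- function(b, residue_txt, bases) {
  r <- .parse_residue(residue_txt, bases)
  i <- length(b$base) + 1L
  b$base[i] <- r$base
  b$subst[[i]] <- r$subst
  b$parent[i] <- NA_integer_
  b$an[i] <- NA_character_
  b$cp[i] <- NA_character_
  b$pp[i] <- NA_character_
  i
}

.set_link <- function(b, child, parent, lk) {
  p <- .split_link(lk)
  b$parent[child] <- parent
  b$an[child] <- p[["anomeric"]]
  b$cp[child] <- p[["child"]]
  b$pp[child] <- p[["parent"]]
}

# chain := (child_chain link)? branch* root
.parse_chain <- function(toks, b, bases) {
  n <- length(toks)
  if (n == 0L) stop("empty (sub)chain in glycan string", call. = FALSE)
  last <- toks[[n]]
  if (last$type != "residue") {
    stop("dangling '", last$text, "' where a residue was expected",
         call. = FALSE)
  }
  root <- .add_node(b, last$text, bases)
  i <- n - 1L
  while (i >= 1L && toks[[i]]$type == "close") {
    depth <- 1L
    j <- i
    while (depth > 0L) {
      j <- j - 1L
      if (j < 1L) stop("unbalanced brackets in glycan string", call. = FALSE)
      if (toks[[j]]$type == "close") depth <- depth + 1L
      if (toks[[j]]$type == "open") depth <- depth - 1L
    }
    inner <- toks[(j + 1L):(i - 1L)]
    m <- length(inner)
    if (m < 2L || inner[[m]]$type != "link") {
      stop("branch without a linkage to its parent", call. = FALSE)
    }
    child <- .parse_chain(inner[seq_len(m - 1L)], b, bases)
    .set_link(b, child, root, inner[[m]]$text)
    i <- j - 1L
  }
  if (i >= 1L) {
    if (toks[[i]]$type != "link") {
      stop("expected a linkage before '", last$text, "', found '",
           toks[[i]]$text, "'", call. = FALSE)
    }
    if (i == 1L) stop("dangling linkage '", toks[[i]]$text, "'",
                      call. = FALSE)
    child <- .parse_chain(toks[seq_len(i - 1L)], b, bases)
    .set_link(b, child, root, toks[[i]]$text)
  }
  root
}

#' Parse an IUPAC-condensed glycan string into a GlycanGraph
#'
#' The reducing-end residue (rightmost in the string) becomes the root;
#' every bracketed branch becomes a sibling subtree. Both the canonical
#' dialect and the journal dialect (Greek letters, parenthesized branches,
#' bare linkages) are accepted.
#'
#' @param text a single glycan string.
#' @param bases monosaccharide alphabet (longest match wins); unknown tokens
#'   are kept as opaque labels with a warning.
#' @return a [GlycanGraph-class].
#' @examples
#' g <- parseGlycan("Neu5Ac(a2-3)Gal(b1-3)[Neu5Ac(a2-6)]GalNAc")
#' length(g)
#' @export
parseGlycan <- function(text, bases = .default_bases()) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  s <- .normalize_dialect(text)
  toks <- .tokenize_glycan(s)
  if (sum(vapply(toks, function(t) t$type == "open", TRUE)) !=
      sum(vapply(toks, function(t) t$type == "close", TRUE))) {
    stop("unbalanced brackets in '", text, "'", call. = FALSE)
  }
  b <- .new_builder()
  .parse_chain(toks, b, bases)
  new("GlycanGraph", base = b$base, substituents = b$subst,
      parent = b$parent, anomeric = b$an, childPos = b$cp, parentPos = b$pp)
}

## ---- serializer -----------------------------------------------------------

.residue_string <- function(g, i) {
  s <- g@substituents[[i]]
  if (!nrow(s)) return(g@base[i])
  ord <- order(ifelse(s$pos == "?", "9?", s$pos), s$group)
  paste0(g@base[i], paste0(ifelse(s$pos[ord] == "?", "O", s$pos[ord]),
                           s$group[ord], collapse = ""))
}

.serialize_node <- function(g, i) {
  kids <- which(!is.na(g@parent) & g@parent == i)
  res <- .residue_string(g, i)
  if (!length(kids)) return(res)
  strs <- vapply(kids, function(k) {
    paste0(.serialize_node(g, k),
           "(", g@anomeric[k], g@childPos[k], "-", g@parentPos[k], ")")
  }, character(1))
  ppnum <- suppressWarnings(as.numeric(g@parentPos[kids]))
  ppnum[is.na(ppnum)] <- Inf  # "?" sorts last
  ord <- order(ppnum, strs)
  strs <- strs[ord]
  paste0(strs[1L],
         if (length(strs) > 1L) {
           paste0("[", strs[-1L], "]", collapse = "")
         } else "",
         res)
}

#' Serialize a GlycanGraph to its canonical IUPAC-condensed string
#'
#' Deterministic: branches at every node are ordered by parent attachment
#' position (ascending, `"?"` last, ties broken by subtree string) and the
#' first branch is written as the unbracketed backbone.
#'
#' @param g a [GlycanGraph-class].
#' @return a single character string; `parseGlycan(glycanToString(g))` is
#'   graph-isomorphic to `g`.
#' @examples
#' glycanToString(parseGlycan("Neu5Acα2-3Galβ1-3(Neu5Acα2-6)GalNAc"))
#' @export
glycanToString <- function(g) {
  stopifnot(is(g, "GlycanGraph"))
  .serialize_node(g, which(is.na(g@parent)))
}

#' Canonicalize IUPAC-condensed glycan strings
#'
#' Accepts glycans written in any supported dialect (Greek or latin anomeric
#' letters, parenthesized or bracketed branches, bare or parenthesized
#' linkages, inline substituents) and returns the canonical dialect. The
#' transformation is idempotent and invariant to the input branch order.
#'
#' @param x character vector of glycan strings.
#' @param bases monosaccharide alphabet, see [parseGlycan()].
#' @return character vector of canonical strings.
#' @examples
#' canonicalizeIUPAC("Neu5Acα2-3Galβ1-3(Neu5Acα2-6)GalNAc")
#' @export
canonicalizeIUPAC <- function(x, bases = .default_bases()) {
  vapply(x, function(s) glycanToString(parseGlycan(s, bases)),
         character(1), USE.NAMES = FALSE)
}

#' Terminal residues of a glycan
#'
#' Returns one row per non-reducing terminus (leaf node), carrying the
#' residue (base plus substituents) and its linkage to the parent. A
#' single-residue glycan yields that residue with the null linkage
#' `"?1-?"` so downstream terminal-motif counting still works.
#'
#' @param g a [GlycanGraph-class] or a glycan string.
#' @return data.frame with columns `residue`, `anomeric`, `childPos`,
#'   `parentPos` and `linkage` (e.g. `"a2-3"`).
#' @examples
#' terminalResidues("Neu5Ac(a2-3)Gal(b1-3)[Neu5Ac(a2-6)]GalNAc")
#' @export
terminalResidues <- function(g) {
  if (is.character(g)) g <- parseGlycan(g)
  stopifnot(is(g, "GlycanGraph"))
  n <- length(g@base)
  leaves <- setdiff(seq_len(n), stats::na.omit(g@parent))
  if (n == 1L) {
    return(data.frame(residue = .residue_string(g, 1L), anomeric = "?",
                      childPos = "1", parentPos = "?", linkage = "?1-?",
                      stringsAsFactors = FALSE))
  }
  data.frame(
    residue = vapply(leaves, function(i) .residue_string(g, i), ""),
    anomeric = g@anomeric[leaves],
    childPos = g@childPos[leaves],
    parentPos = g@parentPos[leaves],
    linkage = paste0(g@anomeric[leaves], g@childPos[leaves], "-",
                     g@parentPos[leaves]),
    stringsAsFactors = FALSE
  )
}
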