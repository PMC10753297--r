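## Packaged defaults for the glycome simulator: a Dirichlet concentration
## vector and a curated fixture list of glycan structures.

#' Default Dirichlet concentration parameters
#'
#' A synthetic vector of 118 concentration parameters shaped like a typical
#' glycomics composition (a handful of dominant structures and a long tail
#' of minor ones), scaled so that the parameters sum to 100 as relative
#' abundances do. It stands in for a concentration vector derived from an
#' experimental N-glycome replicate; users reproducing a specific dataset
#' should pass their own measured relative abundances as `alpha`.
#'
#' @return numeric vector of length 118, strictly positive, summing to 100.
#' @examples
#' sum(defaultAlpha())
#' @export
defaultAlpha <- function() {
  c(
    18.5889, 9.4151, 7.1159, 4.7261, 4.3652, 3.8613, 3.5867, 3.2972, 3.2627,
    3.0711, 2.9117, 2.8296, 2.6113, 2.1104, 1.9217, 1.5485, 1.2079, 1.1659,
    1.0737, 0.7380, 0.6711, 0.6682, 0.6204, 0.5826, 0.5793, 0.5793, 0.5788,
    0.5693, 0.5595, 0.5482, 0.5001, 0.4893, 0.4856, 0.4337, 0.4319, 0.4287,
    0.4119, 0.4058, 0.3430, 0.3410, 0.3326, 0.3323, 0.3124, 0.3079, 0.3031,
    0.2996, 0.2995, 0.2889, 0.2818, 0.2744, 0.2701, 0.2692, 0.2674, 0.2532,
    0.2491, 0.2364, 0.2239, 0.2087, 0.2025, 0.1924, 0.1828, 0.1795, 0.1748,
    0.1671, 0.1663, 0.1647, 0.1612, 0.1581, 0.1529, 0.1491, 0.1468, 0.1371,
    0.1346, 0.1327, 0.1266, 0.1097, 0.1092, 0.1082, 0.1080, 0.1071, 0.1067,
    0.1012, 0.0970, 0.0966, 0.0942, 0.0930, 0.0850, 0.0850, 0.0848, 0.0822,
    0.0760, 0.0755, 0.0731, 0.0682, 0.0642, 0.0632, 0.0571, 0.0552, 0.0545,
    0.0484, 0.0481, 0.0476, 0.0476, 0.0456, 0.0449, 0.0354, 0.0328, 0.0308,
    0.0274, 0.0261, 0.0235, 0.0233, 0.0193, 0.0181, 0.0163, 0.0154, 0.0096,
    0.0086
  )
}

#' Curated fixture glycans
#'
#' Returns the packaged list of human O- and/or N-glycan structures used to
#' assign sequences to simulated abundances (canonical IUPAC-condensed).
#'
#' @param type `"O"`, `"N"` or `"all"`.
#' @return character vector of canonical glycan strings.
#' @examples
#' length(fixtureGlycans("O"))
#' @export
fixtureGlycans <- function(type = c("all", "O", "N")) {
  type <- match.arg(type)
  f <- system.file("extdata", "fixture_glycans.tsv", package = "glycodiff",
                   mustWork = TRUE)
  tab <- utils::read.delim(f, comment.char = "#", stringsAsFactors = FALSE)
  if (type != "all") tab <- tab[tab$type == type, , drop = FALSE]
  canonicalizeIUPAC(tab$glycan)
}
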