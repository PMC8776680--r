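# Pairwise protein alignment and percent identity.
#
# All downstream stages (motif checks, greedy clustering) share one scoring
# scheme: BLOSUM62 with affine gaps costing open + length * extend
# (open = 11, extend = 1), the de facto protein default. Two modes:
#   global      - Needleman-Wunsch over the full lengths; terminal gaps count.
#   semi_global - ends-free ("overlap") alignment; terminal gap columns are
#                 excluded from both the numerator and denominator of identity,
#                 so a clean fragment of a longer sequence scores identity 1.

.codh_env <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.codh_env$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .codh_env$BLOSUM62 <- e$BLOSUM62
  }
  .codh_env$BLOSUM62
}

validate_aa <- function(x, arg = "sequence") {
  if (length(x) != 1 || is.na(x) || !nzchar(x)) {
    abort(paste0(arg, " must be a single non-empty amino-acid string"))
  }
  bad <- setdiff(unique(strsplit(x, "")[[1]]), c(AA20, "X"))
  if (length(bad) > 0) {
    abort(paste0(arg, " contains non-amino-acid characters: ",
                 paste(bad, collapse = ", ")))
  }
  invisible(x)
}

aln_type <- function(mode) {
  mode <- match.arg(mode, c("global", "semi_global"))
  if (mode == "global") "global" else "overlap"
}

# identity over alignment columns; 'X' never counts as a match
identity_from_strings <- function(p, s) {
  n <- nchar(p)
  if (n == 0) return(0)
  pc <- strsplit(p, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  sum(pc == sc & pc != "-" & pc != "X") / n
}

#' Align two amino-acid sequences
#'
#' Optimal pairwise alignment under BLOSUM62 with affine gap penalties
#' (open 11, extend 1). In `semi_global` mode terminal gaps are free and the
#' returned aligned strings cover only the overlapping region, so identity is
#' computed without terminal gap columns.
#'
#' @param a,b Amino-acid strings (canonical 20 letters plus `X`).
#' @param mode `"global"` or `"semi_global"`.
#' @return A list with `score`, `identity` (matched identical columns over
#'   alignment columns; `X` counts as mismatch), and the two aligned strings
#'   `aligned_a`, `aligned_b`.
#' @examples
#' align_pair("ACDEFG", "ACDKFG")$identity
#' @export
align_pair <- function(a, b, mode = c("global", "semi_global")) {
  validate_aa(a, "a"); validate_aa(b, "b")
  type <- aln_type(mode)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = blosum62(),
    gapOpening = 11, gapExtension = 1, type = type)
  ap <- as.character(Biostrings::alignedPattern(pa))
  as <- as.character(Biostrings::alignedSubject(pa))
  list(score = Biostrings::score(pa),
       identity = identity_from_strings(ap, as),
       aligned_a = ap, aligned_b = as)
}

#' Percent identity between two sequences
#'
#' @inheritParams align_pair
#' @return Identity fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b, mode = c("global", "semi_global")) {
  align_pair(a, b, mode)$identity
}

# Vectorised identity of one query against many candidate centroids.
# One pairwiseAlignment call; the greedy scan consumes the result in
# centroid-creation order.
identities_to_set <- function(query, centroids, mode = "semi_global") {
  if (length(centroids) == 0) return(numeric(0))
  type <- aln_type(mode)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(centroids), Biostrings::AAString(query),
    substitutionMatrix = blosum62(),
    gapOpening = 11, gapExtension = 1, type = type)
  ap <- as.character(Biostrings::alignedPattern(pa))
  as <- as.character(Biostrings::alignedSubject(pa))
  vapply(seq_along(ap), function(i) identity_from_strings(ap[i], as[i]),
         numeric(1))
}
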