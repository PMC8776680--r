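# Motif profile: an annotated reference sequence defining the residues that a
# valid Ni-CODH must retain. The D-, B- and C-clusters are the metal centres;
# the B-cluster is coordinated by four conserved Cys and the C-cluster carries
# three conserved Cys near the C-terminus. Filtering is deletion-based for all
# motif positions and additionally mutation-based at the seven checked Cys.

#' Construct a motif profile
#'
#' @param reference_sequence Amino-acid string of the annotated reference.
#' @param d_cluster,c_cluster Ordered integer positions (1-based) of the
#'   D-cluster and C-cluster blocks.
#' @param b_cluster_cys Exactly 4 positions holding `C` (the B-cluster Cys).
#' @param c_terminal_cys Exactly 3 positions holding `C`; must be the last
#'   three annotated C-cluster positions.
#' @param catalytic One or more catalytic positions (deletion-checked only).
#' @return An object of class `motif_profile`.
#' @export
motif_profile <- function(reference_sequence, d_cluster, b_cluster_cys,
                          c_cluster, c_terminal_cys, catalytic) {
  validate_aa(reference_sequence, "reference_sequence")
  p <- structure(list(
    reference_sequence = reference_sequence,
    d_cluster = as.integer(d_cluster),
    b_cluster_cys = as.integer(b_cluster_cys),
    c_cluster = as.integer(c_cluster),
    c_terminal_cys = as.integer(c_terminal_cys),
    catalytic = as.integer(catalytic)
  ), class = "motif_profile")
  validate_motif_profile(p)
}

validate_motif_profile <- function(p) {
  n <- nchar(p$reference_sequence)
  pos <- c(p$d_cluster, p$b_cluster_cys, p$c_cluster, p$catalytic)
  if (any(pos < 1L | pos > n)) abort("motif positions outside reference length")
  if (length(p$b_cluster_cys) != 4L) abort("b_cluster_cys must have exactly 4 positions")
  if (length(p$c_terminal_cys) != 3L) abort("c_terminal_cys must have exactly 3 positions")
  if (!all(p$c_terminal_cys %in% p$c_cluster))
    abort("c_terminal_cys must be a subset of c_cluster")
  if (!identical(sort(p$c_terminal_cys), sort(utils::tail(sort(p$c_cluster), 3))))
    abort("c_terminal_cys must be the last three annotated C-cluster positions")
  core <- list(p$d_cluster, p$b_cluster_cys, setdiff(p$c_cluster, p$c_terminal_cys),
               p$c_terminal_cys, p$catalytic)
  if (anyDuplicated(unlist(core)) > 0)
    abort("motif position sets must be pairwise disjoint (terminal Cys within C-cluster excepted)")
  ref <- strsplit(p$reference_sequence, "")[[1]]
  if (!all(ref[p$b_cluster_cys] == "C") || !all(ref[p$c_terminal_cys] == "C"))
    abort("checked Cys positions must hold 'C' in the reference")
  p
}

#' @export
print.motif_profile <- function(x, ...) {
  cat("<motif_profile> reference length", nchar(x$reference_sequence), "aa\n")
  cat("  D-cluster:", paste(x$d_cluster, collapse = ","), "\n")
  cat("  B-cluster Cys:", paste(x$b_cluster_cys, collapse = ","), "\n")
  cat("  C-cluster:", paste(x$c_cluster, collapse = ","),
      "(terminal Cys:", paste(x$c_terminal_cys, collapse = ","), ")\n")
  cat("  catalytic:", paste(x$catalytic, collapse = ","), "\n")
  invisible(x)
}

#' Read / write a motif profile as JSON (1-based positions)
#'
#' @param path File path.
#' @return `read_motif_profile` returns a `motif_profile`.
#' @export
read_motif_profile <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  motif_profile(j$reference_sequence, j$d_cluster, j$b_cluster_cys,
                j$c_cluster, j$c_terminal_cys, j$catalytic)
}

#' @param profile A `motif_profile`.
#' @rdname read_motif_profile
#' @export
write_motif_profile <- function(profile, path) {
  jsonlite::write_json(unclass(profile), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
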