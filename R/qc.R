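# Sequence QC: motif-conservation checks against the reference profile and
# length/priority tier assignment.
#
# A candidate is kept as a representative only if it is full length
# (>= 400 aa by default) and retains every motif position: no deletion in the
# D-, B- or C-cluster or at the catalytic residues, and no mutation of the
# four B-cluster Cys or the three C-terminal C-cluster Cys. MGnify candidates
# failing those criteria but >= 100 aa are kept in a salvage tier that may
# join clusters (to deepen biome tagging) but never found them.

#' Check motif conservation of one candidate against the reference profile
#'
#' Globally aligns the candidate to the profile's reference sequence and maps
#' every annotated motif position onto the candidate. A deletion at any motif
#' position fails; a non-Cys residue (including `X`) at one of the checked Cys
#' positions fails; substitutions elsewhere in the motifs are tolerated
#' (deletion-only criteria).
#'
#' @param sequence Candidate amino-acid string (length >= 100).
#' @param profile A [motif_profile()].
#' @return A list with `verdict` (`"PASS"`/`"FAIL"`), `reasons` (character
#'   vector among `DELETION_D`, `DELETION_B`, `DELETION_C`,
#'   `DELETION_CATALYTIC`, `MUTATION_B_CYS`, `MUTATION_C_TERMINAL_CYS`), and
#'   `mapping`, a tibble of reference motif position to candidate position
#'   (`NA` for gap) and residue.
#' @export
check_motifs <- function(sequence, profile) {
  validate_aa(sequence, "sequence")
  if (nchar(sequence) < 100)
    abort("check_motifs requires candidate length >= 100")
  aln <- align_pair(profile$reference_sequence, sequence, mode = "global")
  pc <- strsplit(aln$aligned_a, "")[[1]]
  sc <- strsplit(aln$aligned_b, "")[[1]]
  # column index of each reference position, then candidate position or NA
  ref_cols <- which(pc != "-")
  cand_pos <- cumsum(sc != "-")
  map_pos <- ifelse(sc[ref_cols] == "-", NA_integer_, cand_pos[ref_cols])
  map_res <- ifelse(sc[ref_cols] == "-", NA_character_, sc[ref_cols])

  motif_pos <- list(
    DELETION_D = profile$d_cluster,
    DELETION_B = profile$b_cluster_cys,
    DELETION_C = profile$c_cluster,
    DELETION_CATALYTIC = profile$catalytic
  )
  reasons <- character(0)
  for (r in names(motif_pos)) {
    if (anyNA(map_pos[motif_pos[[r]]])) reasons <- c(reasons, r)
  }
  bad_b <- map_res[profile$b_cluster_cys]
  if (any(!is.na(bad_b) & bad_b != "C")) reasons <- c(reasons, "MUTATION_B_CYS")
  bad_c <- map_res[profile$c_terminal_cys]
  if (any(!is.na(bad_c) & bad_c != "C")) reasons <- c(reasons, "MUTATION_C_TERMINAL_CYS")

  all_motif <- sort(unique(unlist(motif_pos)))
  list(
    verdict = if (length(reasons) == 0) "PASS" else "FAIL",
    reasons = reasons,
    mapping = tibble(
      ref_pos = all_motif,
      cand_pos = map_pos[all_motif],
      cand_res = map_res[all_motif]
    )
  )
}

#' Assign representative / salvage / rejected tiers
#'
#' Applies the filtering rules to a table of candidate records:
#' * `representative`: length >= `min_rep_length` and motif PASS
#'   (tier `REFSEQ_REP` or `MGNIFY_REP` by source database);
#' * `salvage`: MGnify records of length >= `min_salvage_length` that are not
#'   representatives (too short or motif FAIL); tier `MGNIFY_SALVAGE`;
#' * `rejected`: anything below `min_salvage_length`, and RefSeq/GenBank
#'   records failing the representative criteria.
#'
#' The three buckets partition the input exactly.
#'
#' @param records A data frame with columns `seq_id`, `sequence` and
#'   `source_db` (`"mgnify"` or `"refseq"`).
#' @param profile A [motif_profile()].
#' @param min_rep_length,min_salvage_length Length thresholds (aa).
#' @return The input tibble with added columns `length`, `verdict`, `reasons`
#'   (comma-separated), `tier` and `bucket`.
#' @export
qc_tiers <- function(records, profile, min_rep_length = 400,
                     min_salvage_length = 100) {
  stopifnot(is.data.frame(records))
  need <- c("seq_id", "sequence", "source_db")
  if (!all(need %in% names(records)))
    abort(paste("records must have columns:", paste(need, collapse = ", ")))
  bad_src <- setdiff(unique(records$source_db), c("mgnify", "refseq"))
  if (length(bad_src) > 0)
    abort(paste("unknown source database:", paste(bad_src, collapse = ", ")))

  out <- as_tibble(records)
  out$length <- nchar(out$sequence)
  checks <- map(seq_len(nrow(out)), function(i) {
    if (out$length[i] < min_salvage_length) {
      list(verdict = NA_character_, reasons = character(0))
    } else {
      check_motifs(out$sequence[i], profile)
    }
  })
  out$verdict <- map_chr(checks, function(x) x$verdict %||% NA_character_)
  out$reasons <- map_chr(checks, function(x) paste(x$reasons, collapse = ","))

  is_rep <- out$length >= min_rep_length & !is.na(out$verdict) & out$verdict == "PASS"
  is_salvage <- !is_rep & out$source_db == "mgnify" & out$length >= min_salvage_length
  out$bucket <- dplyr::case_when(is_rep ~ "representative",
                                 is_salvage ~ "salvage",
                                 TRUE ~ "rejected")
  out$tier <- dplyr::case_when(
    is_rep & out$source_db == "refseq" ~ "REFSEQ_REP",
    is_rep & out$source_db == "mgnify" ~ "MGNIFY_REP",
    is_salvage ~ "MGNIFY_SALVAGE",
    TRUE ~ "REJECTED")
  out
}
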