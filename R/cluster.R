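# Tiered greedy centroid clustering at fixed identity (UCLUST-style).
#
# Records are scanned in a strict priority order: RefSeq/GenBank
# representatives, then MGnify representatives, then MGnify salvage, each tier
# sorted by descending length (ties broken by id). Each record joins the FIRST
# existing centroid (in centroid-creation order) with semi-global identity
# >= threshold; otherwise it founds a new cluster if its tier permits
# (representatives only) or, for salvage, is reported unassigned. Clusters are
# never re-centred.

TIER_ORDER <- c(REFSEQ_REP = 1L, MGNIFY_REP = 2L, MGNIFY_SALVAGE = 3L)

#' Order records for greedy clustering
#'
#' @param records A tiered record table (see [qc_tiers()]); rows with tier
#'   `REJECTED` are dropped.
#' @return The records ordered by tier priority (RefSeq representatives,
#'   MGnify representatives, MGnify salvage), then strictly by descending
#'   length, ties broken lexicographically by `seq_id`.
#' @export
sort_for_clustering <- function(records) {
  stopifnot(is.data.frame(records))
  recs <- as_tibble(records) |> filter(.data$tier %in% names(TIER_ORDER))
  if (!"length" %in% names(recs)) recs$length <- nchar(recs$sequence)
  recs |> arrange(TIER_ORDER[.data$tier], dplyr::desc(.data$length), .data$seq_id)
}

check_clustering_order <- function(records) {
  pr <- TIER_ORDER[records$tier]
  if (is.unsorted(pr)) abort("records not ordered by tier priority; run sort_for_clustering()")
  for (t in unique(records$tier)) {
    len <- records$length[records$tier == t]
    if (is.unsorted(-len)) abort("records not in descending length order within tier")
  }
  invisible(TRUE)
}

#' Greedy centroid clustering at a fixed identity threshold
#'
#' @param records Ordered records from [sort_for_clustering()] (columns
#'   `seq_id`, `sequence`, `tier`, `length`; extra columns are carried along).
#' @param threshold Identity threshold in (0, 1]; default 0.90.
#' @param check_order Verify the tier/length ordering before scanning.
#' @return An object of class `codh_clustering` with elements `clusters`
#'   (tibble: `cluster_id`, `centroid_id`, `member_id`, `identity`, `tier`),
#'   `centroids` (tibble incl. each centroid's maximum identity to earlier
#'   centroids at creation time), `unassigned_salvage` (ids) and `threshold`.
#' @export
cluster_greedy <- function(records, threshold = 0.90, check_order = TRUE) {
  stopifnot(is.data.frame(records), threshold > 0, threshold <= 1)
  recs <- as_tibble(records)
  if (!"length" %in% names(recs)) recs$length <- nchar(recs$sequence)
  if (check_order) check_clustering_order(recs)

  n <- nrow(recs)
  cent_seq <- character(0)
  cent_id <- character(0)
  cent_max_ident <- numeric(0)
  assignment <- integer(n)      # 0 = unassigned salvage
  identity <- numeric(n)
  for (i in seq_len(n)) {
    ids <- identities_to_set(recs$sequence[i], cent_seq, mode = "semi_global")
    hit <- which(ids >= threshold)
    if (length(hit) > 0) {
      assignment[i] <- hit[1]
      identity[i] <- ids[hit[1]]
    } else if (recs$tier[i] %in% c("REFSEQ_REP", "MGNIFY_REP")) {
      cent_seq <- c(cent_seq, recs$sequence[i])
      cent_id <- c(cent_id, recs$seq_id[i])
      cent_max_ident <- c(cent_max_ident, if (length(ids)) max(ids) else NA_real_)
      assignment[i] <- length(cent_seq)
      identity[i] <- 1
    } else {
      assignment[i] <- 0L
      identity[i] <- NA_real_
    }
  }

  keep <- assignment > 0L
  clusters <- tibble(
    cluster_id = sprintf("CL%04d", assignment[keep]),
    centroid_id = cent_id[assignment[keep]],
    member_id = recs$seq_id[keep],
    identity = identity[keep],
    tier = recs$tier[keep]
  ) |> arrange(.data$cluster_id, dplyr::desc(.data$member_id == .data$centroid_id),
               .data$member_id)
  centroids <- tibble(
    cluster_id = sprintf("CL%04d", seq_along(cent_id)),
    centroid_id = cent_id,
    sequence = cent_seq,
    max_identity_at_creation = cent_max_ident
  )
  structure(list(clusters = clusters, centroids = centroids,
                 unassigned_salvage = recs$seq_id[!keep],
                 threshold = threshold),
            class = "codh_clustering")
}

#' @export
print.codh_clustering <- function(x, ...) {
  cat("<codh_clustering>", nrow(x$centroids), "clusters,",
      nrow(x$clusters), "members,",
      length(x$unassigned_salvage), "unassigned salvage; threshold",
      x$threshold, "\n")
  invisible(x)
}

#' @describeIn cluster_greedy Tidy membership table (one row per member).
#' @param x A `codh_clustering`.
#' @param ... Unused.
#' @export
tidy.codh_clustering <- function(x, ...) x$clusters

#' @describeIn cluster_greedy One-row summary (cluster/member counts).
#' @export
glance.codh_clustering <- function(x, ...) {
  tibble(n_clusters = nrow(x$centroids),
         n_members = nrow(x$clusters),
         n_unassigned_salvage = length(x$unassigned_salvage),
         threshold = x$threshold)
}

#' Summarise database-source overlap of clusters
#'
#' Counts clusters containing sequences from both source databases, MGnify
#' only, and RefSeq/GenBank only.
#'
#' @param clustering A `codh_clustering`.
#' @param sources A data frame mapping `seq_id` to `source_db`.
#' @return A one-row tibble with `both`, `mgnify_only`, `refseq_only`,
#'   `total` (the three counts sum to `total`).
#' @export
summarize_sources <- function(clustering, sources) {
  stopifnot(inherits(clustering, "codh_clustering"), is.data.frame(sources))
  m <- clustering$clusters |>
    left_join(select(as_tibble(sources), "seq_id", "source_db"),
              by = c(member_id = "seq_id"))
  if (anyNA(m$source_db)) {
    abort(paste("members without a source database mapping:",
                paste(head(m$member_id[is.na(m$source_db)], 5), collapse = ", ")))
  }
  per <- m |> group_by(.data$cluster_id) |>
    summarise(has_mg = any(.data$source_db == "mgnify"),
              has_rs = any(.data$source_db == "refseq"), .groups = "drop")
  tibble(both = sum(per$has_mg & per$has_rs),
         mgnify_only = sum(per$has_mg & !per$has_rs),
         refseq_only = sum(!per$has_mg & per$has_rs),
         total = nrow(per))
}

#' Fraction of clusters taxonomically pure at a rank
#'
#' A cluster counts as pure when all its classified members share a single
#' taxon at the requested rank; clusters with no classified member are
#' excluded from the denominator.
#'
#' @param clustering A `codh_clustering`.
#' @param taxonomy A data frame with `seq_id` and rank columns (e.g. `phylum`,
#'   `genus`, `species`).
#' @param rank Column of `taxonomy` to evaluate.
#' @return Fraction in \[0, 1\] (`NaN` when no cluster has taxonomy).
#' @export
purity_by_rank <- function(clustering, taxonomy, rank = "genus") {
  stopifnot(inherits(clustering, "codh_clustering"), is.data.frame(taxonomy))
  if (!rank %in% names(taxonomy)) abort(paste("unknown rank:", rank))
  m <- clustering$clusters |>
    left_join(select(as_tibble(taxonomy), "seq_id", taxon = dplyr::all_of(rank)),
              by = c(member_id = "seq_id")) |>
    filter(!is.na(.data$taxon))
  per <- m |> group_by(.data$cluster_id) |>
    summarise(pure = dplyr::n_distinct(.data$taxon) == 1L, .groups = "drop")
  mean(per$pure)
}
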