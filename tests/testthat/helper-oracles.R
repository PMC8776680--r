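# Independent oracles used against the package implementations.

AA20_TEST <- c("A","C","D","E","F","G","H","I","K","L",
               "M","N","P","Q","R","S","T","V","W","Y")

blosum62_test <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Plain-R Gotoh affine-gap dynamic programme (gap of length L costs
# open + L * ext). mode "global" or "semi_global" (ends-free, both ends of
# both sequences).
gotoh_score <- function(a, b, open = 11, ext = 1,
                        mode = c("global", "semi_global")) {
  mode <- match.arg(mode)
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  if (mode == "global") {
    M[1, 1] <- 0
    for (i in seq_len(n)) X[i + 1, 1] <- -(open + i * ext)
    for (j in seq_len(m)) Y[1, j + 1] <- -(open + j * ext)
  } else {
    M[, 1] <- 0; M[1, ] <- 0; X[, 1] <- 0; Y[1, ] <- 0
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- blosum62_test[A[i], B[j]]
      M[i + 1, j + 1] <- s + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext,
                             Y[i, j + 1] - open - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext,
                             X[i + 1, j] - open - ext)
    }
  }
  if (mode == "global") {
    max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  } else {
    max(M[n + 1, ], X[n + 1, ], Y[n + 1, ], M[, m + 1], X[, m + 1], Y[, m + 1])
  }
}

random_aa <- function(len) paste(sample(AA20_TEST, len, replace = TRUE),
                                 collapse = "")

# Straight-line re-implementation of the greedy scan contract: compare each
# record to existing centroids in creation order, join the first with
# identity >= threshold, else found a cluster (representatives only).
greedy_oracle <- function(records, threshold = 0.90) {
  cent_seq <- character(0); cent_id <- character(0)
  assign <- character(nrow(records)); unassigned <- character(0)
  for (i in seq_len(nrow(records))) {
    joined <- FALSE
    for (k in seq_along(cent_seq)) {
      if (pairwise_identity(recs_seq <- records$sequence[i], cent_seq[k],
                            mode = "semi_global") >= threshold) {
        assign[i] <- cent_id[k]; joined <- TRUE; break
      }
    }
    if (!joined) {
      if (records$tier[i] %in% c("REFSEQ_REP", "MGNIFY_REP")) {
        cent_seq <- c(cent_seq, records$sequence[i])
        cent_id <- c(cent_id, records$seq_id[i])
        assign[i] <- records$seq_id[i]
      } else {
        assign[i] <- NA_character_
        unassigned <- c(unassigned, records$seq_id[i])
      }
    }
  }
  list(centroid_of = stats::setNames(assign, records$seq_id),
       unassigned = unassigned)
}

# membership of a codh_clustering as a named centroid-per-member vector
membership_of <- function(cl) {
  v <- stats::setNames(cl$clusters$centroid_id, cl$clusters$member_id)
  v[order(names(v))]
}

# Rand index between two label vectors over the same elements
rand_index <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  same_x <- outer(x, x, "==")[upper.tri(diag(n))]
  same_y <- outer(y, y, "==")[upper.tri(diag(n))]
  mean(same_x == same_y)
}

# small intact family with tiers taken from the planted ground truth
sim_tiered <- function(cfg) {
  profile <- sim_reference_profile(cfg)
  fam <- sim_family(profile, cfg)
  recs <- dplyr::left_join(fam$records,
                           dplyr::select(fam$truth, seq_id, true_cluster,
                                         true_clade),
                           by = "seq_id")
  recs$length <- nchar(recs$sequence)
  recs$tier <- ifelse(recs$source_db == "refseq", "REFSEQ_REP", "MGNIFY_REP")
  list(records = recs, profile = profile, truth = fam$truth)
}

# Exhaustive brute-force global affine-gap alignment score: enumerates every
# monotone alignment path recursively (no memoisation), so it is feasible only
# for very short pairs but shares no machinery with the dynamic programmes.
brute_force_score <- function(a, b, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  na <- length(A); nb <- length(B)
  rec <- function(i, j, last) {
    if (i > na && j > nb) return(0)
    best <- -Inf
    if (i <= na && j <= nb)
      best <- max(best, blosum62_test[A[i], B[j]] + rec(i + 1, j + 1, "M"))
    if (i <= na)
      best <- max(best, -(if (last == "X") ext else open + ext) +
                    rec(i + 1, j, "X"))
    if (j <= nb)
      best <- max(best, -(if (last == "Y") ext else open + ext) +
                    rec(i, j + 1, "Y"))
    best
  }
  rec(1, 1, "S")
}
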