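mk_rec <- function(id, seq, tier) {
  tibble::tibble(seq_id = id, sequence = seq, source_db =
                   ifelse(tier == "REFSEQ_REP", "refseq", "mgnify"),
                 length = nchar(seq), tier = tier)
}

test_that("ordering puts RefSeq first, then length, then id", {
  set.seed(20)
  recs <- dplyr::bind_rows(
    mk_rec("mg_long", random_aa(700), "MGNIFY_REP"),
    mk_rec("rs_short", random_aa(500), "REFSEQ_REP"),
    mk_rec("b_tie", random_aa(500), "REFSEQ_REP"),
    mk_rec("a_tie", paste(rep("A", 500), collapse = ""), "REFSEQ_REP"),
    mk_rec("sal", random_aa(200), "MGNIFY_SALVAGE"),
    mk_rec("rej", random_aa(80), "REJECTED"))
  ord <- sort_for_clustering(recs)
  expect_equal(ord$seq_id, c("a_tie", "b_tie", "rs_short", "mg_long", "sal"))
  expect_equal(nrow(sort_for_clustering(recs[0, ])), 0)
})

test_that("identical records share a cluster, unrelated ones do not", {
  set.seed(21)
  s1 <- random_aa(450); s3 <- random_aa(450)
  recs <- dplyr::bind_rows(mk_rec("s1", s1, "REFSEQ_REP"),
                           mk_rec("s2", s1, "REFSEQ_REP"),
                           mk_rec("s3", s3, "REFSEQ_REP"))
  cl <- cluster_greedy(sort_for_clustering(recs))
  expect_equal(nrow(cl$centroids), 2)
  m <- cl$clusters
  expect_equal(m$centroid_id[m$member_id == "s2"], "s1")
  expect_equal(m$identity[m$member_id == "s2"], 1.0)
})

test_that("salvage never founds clusters; unmatched salvage is reported", {
  set.seed(22)
  recs <- dplyr::bind_rows(mk_rec("rep", random_aa(450), "REFSEQ_REP"),
                           mk_rec("sal", random_aa(150), "MGNIFY_SALVAGE"))
  cl <- cluster_greedy(sort_for_clustering(recs))
  expect_equal(nrow(cl$centroids), 1)
  expect_equal(cl$unassigned_salvage, "sal")
})

test_that("unordered input is rejected", {
  set.seed(23)
  recs <- dplyr::bind_rows(mk_rec("mg", random_aa(450), "MGNIFY_REP"),
                           mk_rec("rs", random_aa(450), "REFSEQ_REP"))
  expect_error(cluster_greedy(recs), "not ordered")
})

test_that("greedy partition equals a straight-line oracle on random instances", {
  for (seed in c(31, 32, 33)) {
    cfg <- sim_config(seed = seed, n_clades = sample(1:2, 1),
                      clusters_per_clade = 3, members_per_cluster = 4,
                      seq_length = 450)
    st <- sim_tiered(cfg)
    ord <- sort_for_clustering(st$records)
    cl <- cluster_greedy(ord)
    orc <- greedy_oracle(ord)
    got <- membership_of(cl)
    expect_equal(got, orc$centroid_of[names(got)])
    expect_equal(sort(cl$unassigned_salvage), sort(orc$unassigned))
  }
})

test_that("clustering invariants hold and recover the planted structure", {
  cfg <- sim_config(seed = 34, n_clades = 3, clusters_per_clade = 3,
                    members_per_cluster = 4, within_cluster_divergence = 0.04)
  st <- sim_tiered(cfg)
  cl <- cluster_greedy(sort_for_clustering(st$records), threshold = 0.9)
  expect_true(all(cl$clusters$identity >= 0.9))
  # each centroid was below threshold to all earlier centroids when created
  expect_true(all(cl$centroids$max_identity_at_creation < 0.9, na.rm = TRUE))
  # perfect recovery of planted clusters
  truth <- st$records$true_cluster[match(cl$clusters$member_id, st$records$seq_id)]
  expect_equal(rand_index(cl$clusters$centroid_id, truth), 1.0)
  expect_equal(nrow(cl$centroids), 9)
  # input row order does not matter once re-sorted
  shuffled <- st$records[sample(nrow(st$records)), ]
  cl2 <- cluster_greedy(sort_for_clustering(shuffled), threshold = 0.9)
  expect_identical(membership_of(cl2), membership_of(cl))
})

test_that("source overlap counts sum to the cluster total", {
  cfg <- sim_config(seed = 35, n_clades = 2, clusters_per_clade = 2,
                    members_per_cluster = 4, seq_length = 450)
  st <- sim_tiered(cfg)
  cl <- cluster_greedy(sort_for_clustering(st$records))
  ov <- summarize_sources(cl, st$records)
  expect_equal(ov$both + ov$mgnify_only + ov$refseq_only, ov$total)
  expect_equal(ov$total, nrow(cl$centroids))
  # all-refseq toy case
  set.seed(36)
  recs <- dplyr::bind_rows(mk_rec("r1", random_aa(450), "REFSEQ_REP"),
                           mk_rec("r2", random_aa(450), "REFSEQ_REP"))
  cl2 <- cluster_greedy(sort_for_clustering(recs))
  ov2 <- summarize_sources(cl2, recs)
  expect_equal(ov2$both, 0)
  expect_equal(ov2$refseq_only, ov2$total)
  expect_error(summarize_sources(cl2, recs[1, ]), "without a source")
})

test_that("taxonomic purity counts single-taxon clusters", {
  set.seed(37)
  a <- random_aa(450); b <- random_aa(450)
  recs <- dplyr::bind_rows(mk_rec("a1", a, "REFSEQ_REP"),
                           mk_rec("a2", a, "REFSEQ_REP"),
                           mk_rec("b1", b, "REFSEQ_REP"),
                           mk_rec("b2", b, "REFSEQ_REP"))
  cl <- cluster_greedy(sort_for_clustering(recs))
  tax <- tibble::tibble(seq_id = c("a1", "a2", "b1", "b2"),
                        genus = c("g1", "g1", "g2", "g3"))
  expect_equal(purity_by_rank(cl, tax, "genus"), 0.5)
  tax$genus <- "g1"
  expect_equal(purity_by_rank(cl, tax, "genus"), 1.0)
  expect_error(purity_by_rank(cl, tax, "kingdom"), "unknown rank")
})
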