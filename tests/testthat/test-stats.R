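ann_toy <- tibble::tibble(
  cluster_id = c("c1", "c2", "c3"),
  centroid_id = c("x1", "x2", "x3"),
  clade = c("A", "A", "B"), mini_coos = FALSE, n_members = 2,
  majors = list("host_associated", c("engineered", "environmental_aquatic"),
                character(0)),
  subs = list(character(0), character(0), character(0)),
  phyla = list("p__X", c("p__X", "p__Y"), character(0)),
  genera = list(character(0), character(0), character(0)),
  functions = list(character(0), character(0), character(0)))

test_that("presence matrices mark every label a cluster carries", {
  pres <- build_presence(ann_toy, "major")
  expect_equal(names(pres), c("cluster_id", "engineered",
                              "environmental_aquatic", "host_associated"))
  expect_equal(unlist(pres[pres$cluster_id == "c1", -1], use.names = FALSE),
               c(FALSE, FALSE, TRUE))
  expect_equal(sum(unlist(pres[pres$cluster_id == "c2", -1])), 2)
  expect_equal(nrow(build_presence(ann_toy, "major",
                                   drop_empty_clusters = TRUE)), 2)
  expect_equal(nrow(build_presence(ann_toy[0, ], "major")), 0)
})

test_that("dice matches its set-arithmetic definition", {
  expect_equal(dice(c("a", "b"), c("a", "b")), 1.0)
  expect_equal(dice("a", "b"), 0.0)
  expect_equal(dice(c("a", "b", "c"), c("a", "b", "d", "e")), 4 / 7)
  expect_warning(d0 <- dice(character(0), character(0)), "empty")
  expect_equal(d0, 0)
  set.seed(60)
  for (i in 1:20) {
    a <- sample(letters, sample(0:10, 1))
    b <- sample(letters, sample(1:10, 1))
    expect_equal(dice(a, b), 2 * length(intersect(a, b)) /
                   (length(a) + length(b)))
    expect_equal(dice(a, b), dice(b, a))
  }
})

test_that("pairwise dice agrees with the per-pair oracle", {
  set.seed(61)
  m <- tibble::tibble(cluster_id = sprintf("c%02d", 1:20))
  for (lb in c("w", "x", "y", "z")) m[[lb]] <- sample(c(TRUE, FALSE), 20,
                                                      replace = TRUE)
  pd <- pairwise_dice(m)
  for (i in seq_len(nrow(pd))) {
    a <- m$cluster_id[m[[pd$label_a[i]]]]; b <- m$cluster_id[m[[pd$label_b[i]]]]
    expect_equal(pd$dice[i], suppressWarnings(dice(a, b)))
  }
  # symmetry and unit diagonal
  wide <- tidyr::pivot_wider(pd, names_from = "label_b", values_from = "dice")
  mm <- as.matrix(wide[, -1])
  expect_equal(mm, t(mm), ignore_attr = TRUE)
  expect_true(all(diag(mm)[colSums(as.matrix(m[, -1])) > 0] == 1))
  # orthogonal and duplicated columns
  o <- tibble::tibble(cluster_id = c("c1", "c2"), p = c(TRUE, FALSE),
                      q = c(FALSE, TRUE), r = c(TRUE, FALSE))
  po <- pairwise_dice(o)
  expect_equal(po$dice[po$label_a == "p" & po$label_b == "q"], 0)
  expect_equal(po$dice[po$label_a == "p" & po$label_b == "r"], 1)
})

test_that("shannon diversity matches closed forms", {
  expect_equal(shannon(c(10, 0, 0)), 0)
  expect_equal(shannon(rep(5, 4)), log(4), tolerance = 1e-12)
  expect_equal(shannon(c(75, 25)),
               -0.75 * log(0.75) - 0.25 * log(0.25), tolerance = 1e-12)
  expect_error(shannon(c(0, 0)), "all-zero")
  expect_error(shannon(c(-1, 2)), "non-negative")
  # bounded by ln k and maximised at uniform
  set.seed(62)
  for (i in 1:10) {
    k <- sample(2:8, 1); v <- runif(k)
    expect_lte(shannon(v), log(k) + 1e-12)
  }
})

test_that("composition profiles count clusters per group and label", {
  comp <- clade_composition(ann_toy, group_domain = "major", value = "clade")
  expect_true(all(abs(tapply(comp$fraction, comp$group, sum) - 1) < 1e-12))
  host <- comp[comp$group == "host_associated", ]
  expect_equal(host$label, "A")
  expect_equal(host$fraction, 1.0)
  # counting oracle on random annotations
  set.seed(63)
  n <- 30
  ann <- tibble::tibble(
    cluster_id = sprintf("c%02d", 1:n), centroid_id = sprintf("x%02d", 1:n),
    clade = sample(LETTERS[1:4], n, replace = TRUE), mini_coos = FALSE,
    n_members = 1,
    majors = purrr::map(1:n, ~ sample(c("engineered", "host_associated"),
                                      sample(0:2, 1))),
    subs = list(character(0)), phyla = list(character(0)),
    genera = list(character(0)), functions = list(character(0)))
  comp2 <- clade_composition(ann, group_domain = "major", value = "clade")
  for (i in seq_len(nrow(comp2))) {
    manual <- sum(purrr::map_lgl(seq_len(n), function(j) {
      comp2$group[i] %in% ann$majors[[j]] && ann$clade[j] == comp2$label[i]
    }))
    expect_equal(comp2$n[i], manual)
  }
})

test_that("composition PCA decomposes centred relative abundances", {
  set.seed(64)
  prof <- tidyr::expand_grid(group = sprintf("g%d", 1:5),
                             label = LETTERS[1:4]) |>
    dplyr::mutate(n = rpois(20, 5) + 1) |>
    dplyr::group_by(group) |>
    dplyr::mutate(fraction = n / sum(n)) |>
    dplyr::ungroup()
  p <- composition_pca(prof)
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-9)
  L <- as.matrix(p$loadings[, -1])
  expect_equal(t(L) %*% L, diag(ncol(L)), ignore_attr = TRUE,
               tolerance = 1e-9)
  # full-rank reconstruction of the centred matrix
  S <- as.matrix(p$scores[, -1])
  centred <- scale(as.matrix(tidyr::pivot_wider(
    prof[, c("group", "label", "fraction")], names_from = "label",
    values_from = "fraction")[, -1]), center = TRUE, scale = FALSE)
  expect_equal(S %*% t(L), centred, ignore_attr = TRUE, tolerance = 1e-9)
  # identical groups land on identical scores
  prof2 <- dplyr::bind_rows(prof,
                            dplyr::mutate(prof[prof$group == "g1", ],
                                          group = "g1b"))
  p2 <- composition_pca(prof2)
  expect_equal(p2$scores$PC1[p2$scores$group == "g1"],
               p2$scores$PC1[p2$scores$group == "g1b"])
  expect_s3_class(tidy(p2), "tbl_df")
  expect_equal(sum(glance(p2)$variance_fraction), 1, tolerance = 1e-9)
})

test_that("welch t matches the closed form and its symmetries", {
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  w <- welch_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$t, -3.674234614175, tolerance = 1e-6)
  expect_equal(w$df, 4, tolerance = 1e-6)
  expect_equal(w$p, 0.021311641129, tolerance = 1e-6)
  rev <- welch_t(c(4, 5, 6), c(1, 2, 3))
  expect_equal(rev$t, -w$t)
  expect_equal(rev$p, w$p)
  expect_error(welch_t(1, c(1, 2)), ">= 2")
  expect_error(welch_t(c(1, 1), c(2, 2)), "degenerate")
})

test_that("grubbs flags a planted maximum and respects its preconditions", {
  g <- grubbs_max(c(1, 1.1, 0.9, 5))
  expect_equal(g$g, 1.498752, tolerance = 1e-5)
  expect_equal(g$outlier, 5)
  expect_lt(g$p, 0.05)
  set.seed(65)
  planted <- grubbs_max(c(rnorm(5), 10))
  expect_lt(planted$p, 0.01)
  expect_error(grubbs_max(c(1, 2)), "n >= 3")
  expect_error(grubbs_max(c(2, 2, 2)), "zero standard deviation")
})

test_that("density normalisation scales as count over size", {
  expect_equal(density_per_mbp(4, 2), 2)
  expect_equal(density_per_mbp(0, 3.5), 0)
  expect_equal(density_per_mbp(8, 4), density_per_mbp(4, 2))
  expect_error(density_per_mbp(1, 0), "positive")
})
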