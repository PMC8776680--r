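test_that("configuration invariants are validated", {
  expect_error(sim_config(within_cluster_divergence = 0.3,
                          between_cluster_divergence = 0.2), "ordering")
  expect_error(sim_config(fraction_fragments = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(biome_bias = list(A = c(engineered = 0.5,
                                                  environmental_aquatic = 0.2,
                                                  host_associated = 0.2)),
                          n_clades = 1), "sum to 1")
  expect_error(sim_reference_profile(sim_config(seq_length = 445)),
               "too short")
  expect_error(sim_config(seq_length = 100), ">= 400")
})

test_that("the generated profile annotates Cys where it must", {
  prof <- sim_reference_profile(sim_config(seed = 1))
  ch <- strsplit(prof$reference_sequence, "")[[1]]
  expect_equal(ch[prof$b_cluster_cys], rep("C", 4))
  expect_equal(ch[prof$c_terminal_cys], rep("C", 3))
  expect_identical(prof, sim_reference_profile(sim_config(seed = 1)))
})

test_that("family dimensions and determinism hold", {
  cfg <- sim_config(seed = 2, n_clades = 2, clusters_per_clade = 2,
                    members_per_cluster = 3)
  prof <- sim_reference_profile(cfg)
  fam <- sim_family(prof, cfg)
  expect_equal(nrow(fam$records), 12)
  expect_equal(dplyr::n_distinct(fam$truth$true_cluster), 4)
  expect_identical(fam, sim_family(prof, cfg))
  expect_identical(sim_dataset(cfg), sim_dataset(cfg))
})

test_that("zero within-cluster divergence gives identical members", {
  cfg <- sim_config(seed = 3, n_clades = 1, clusters_per_clade = 2,
                    members_per_cluster = 3, within_cluster_divergence = 0)
  fam <- sim_family(sim_reference_profile(cfg), cfg)
  per <- split(fam$records$sequence, fam$truth$true_cluster)
  for (s in per) expect_equal(length(unique(s)), 1)
})

test_that("empirical identities respect the configured divergence ordering", {
  for (seed in c(4, 11)) {
    cfg <- sim_config(seed = seed, n_clades = 2, clusters_per_clade = 2,
                      members_per_cluster = 2)
    fam <- sim_family(sim_reference_profile(cfg), cfg)
    recs <- dplyr::left_join(fam$records, fam$truth, by = c("seq_id", "source_db"))
    idm <- function(i, j) pairwise_identity(recs$sequence[i], recs$sequence[j],
                                            mode = "semi_global")
    within <- idm(1, 2)                       # same cluster
    between_cl <- idm(1, 3)                   # same clade, other cluster
    between_clade <- idm(1, 5)                # other clade
    expect_gt(within, between_cl)
    expect_gt(between_cl, between_clade)
    expect_gte(within, 1 - 2 * cfg$within_cluster_divergence)
    expect_lte(between_cl, 1 - cfg$between_cluster_divergence + 0.1)
  }
})

test_that("corruption fractions of zero leave every verdict representative", {
  cfg <- sim_config(seed = 5, n_clades = 2, clusters_per_clade = 2,
                    members_per_cluster = 3, fraction_fragments = 0,
                    fraction_too_short = 0, fraction_broken_motif = 0)
  sim <- sim_dataset(cfg)
  expect_true(all(sim$truth$verdict == "representative"))
})

test_that("corruptions plant the intended classes and lengths", {
  cfg <- sim_config(seed = 6, n_clades = 2, clusters_per_clade = 3,
                    members_per_cluster = 5, fraction_fragments = 0.2,
                    fraction_too_short = 0.1, fraction_broken_motif = 0.2)
  sim <- sim_dataset(cfg)
  len <- nchar(sim$records$sequence)
  frag <- sim$truth$qc_class == "fragment"
  expect_true(any(frag))
  expect_true(all(len[frag] >= 100 & len[frag] <= 399))
  expect_true(all(len[sim$truth$qc_class == "too_short"] < 100))
  broken <- sim$truth$qc_class == "motif_broken"
  expect_true(any(broken))
  expect_true(all(len[broken] >= 400))
  expect_equal(sim$truth$verdict[frag & sim$truth$source_db == "mgnify"][1],
               "salvage")
})

test_that("metadata respects biome bias, function pools and shared genus", {
  bias <- list(
    A = c(engineered = 1, environmental_aquatic = 0, host_associated = 0),
    B = c(engineered = 0, environmental_aquatic = 0, host_associated = 1))
  cfg <- sim_config(seed = 7, n_clades = 2, clusters_per_clade = 2,
                    members_per_cluster = 4, biome_bias = bias,
                    clade_functions = list(A = "WLP", B = "WLP"),
                    fraction_fragments = 0, fraction_too_short = 0,
                    fraction_broken_motif = 0)
  sim <- sim_dataset(cfg)
  seq_biome <- dplyr::inner_join(sim$meta, sim$biome, by = "sample_id") |>
    collapse_biome() |>
    dplyr::inner_join(sim$truth, by = "seq_id")
  expect_true(all(seq_biome$major[seq_biome$true_clade == "B"] == "host_associated"))
  expect_true(all(seq_biome$major[seq_biome$true_clade == "A"] == "engineered"))
  # every focal context carries the planted WLP COG
  ctx <- extract_contexts(sim$features, sim$focal)
  fun <- ctx |> dplyr::group_by(genome_id) |>
    dplyr::group_modify(~ tibble::tibble(f = list(annotate_context(.x)))) |>
    dplyr::ungroup()
  expect_true(all(purrr::map_lgl(fun$f, ~ "WLP" %in% .x)))
  # one genus per true cluster
  gen <- dplyr::inner_join(sim$meta, sim$taxonomy, by = "genome_id") |>
    dplyr::inner_join(sim$truth, by = "seq_id")
  per <- tapply(gen$genus, gen$true_cluster, dplyr::n_distinct)
  expect_true(all(per == 1))
})

test_that("written datasets are byte-identical across reruns", {
  cfg <- sim_config(seed = 8, n_clades = 1, clusters_per_clade = 2,
                    members_per_cluster = 2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_sim_dataset(sim_dataset(cfg), d1)
  p2 <- write_sim_dataset(sim_dataset(cfg), d2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]), info = k)
  }
})
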