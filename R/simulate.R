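# Synthetic Ni-CODH family simulator with planted ground truth.
#
# Sequences are generated on a three-level hierarchy (clade ancestor ->
# cluster ancestor -> member) by uniform random substitution at non-motif
# sites, so pairwise identities are controlled directly by the configured
# divergence fractions (within < between-cluster < between-clade). Motif
# positions are never touched except by deliberate corruptions, which plant
# known filter verdicts. Metadata emulates MGnify biome lineages (biased per
# clade), GTDB-style taxonomy (one genus per true cluster), and COG-annotated
# gene neighbourhoods drawn from per-clade function pools.

#' Simulation configuration
#'
#' @param seed Integer RNG seed; every `sim_*` function derives its stream
#'   from it, so identical configs reproduce outputs byte for byte.
#' @param n_clades,clusters_per_clade,members_per_cluster Family dimensions.
#' @param seq_length Full-length sequence length in residues (>= 400).
#' @param within_cluster_divergence Per-member substitution fraction from the
#'   cluster ancestor; pairwise within-cluster divergence is at most twice
#'   this.
#' @param between_cluster_divergence,between_clade_divergence Target pairwise
#'   divergence between clusters of one clade and between clades (each
#'   ancestor mutates at half the stated rate from the common ancestor).
#' @param fraction_fragments Fraction of records truncated to 100-399 aa.
#' @param fraction_too_short Fraction truncated below 100 aa.
#' @param fraction_broken_motif Fraction of full-length records given a
#'   motif-breaking corruption (B-cluster Cys substitution or a deletion
#'   across the D-cluster).
#' @param fraction_refseq Probability that a non-founding member carries a
#'   RefSeq/GenBank source (the first member of every cluster always does, so
#'   each cluster has genome-linked metadata).
#' @param biome_bias Named list: clade label -> probability vector over
#'   `c("engineered", "environmental_aquatic", "host_associated")`. The
#'   default plants clades B, C and E almost exclusively in host-associated
#'   samples (with a small engineered share and none environmental), and the
#'   remaining clades mostly in environmental/engineered samples.
#' @param clade_phylum Named character: clade -> phylum; default puts B, C
#'   and E in one phylum (Firmicutes_A) and spreads the rest.
#' @param clade_functions Named list: clade -> function names whose defining
#'   COGs are planted in the gene neighbourhoods of that clade's RefSeq
#'   members.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_clades = 8,
                       clusters_per_clade = 5,
                       members_per_cluster = 5,
                       seq_length = 630,
                       within_cluster_divergence = 0.05,
                       between_cluster_divergence = 0.20,
                       between_clade_divergence = 0.40,
                       fraction_fragments = 0.15,
                       fraction_too_short = 0.02,
                       fraction_broken_motif = 0.05,
                       fraction_refseq = 0.3,
                       biome_bias = NULL,
                       clade_phylum = NULL,
                       clade_functions = NULL) {
  clades <- LETTERS[seq_len(n_clades)]
  host_clades <- intersect(clades, c("B", "C", "E"))
  if (is.null(biome_bias)) {
    biome_bias <- lapply(setNames(clades, clades), function(cl) {
      if (cl %in% host_clades) {
        c(engineered = 0.10, environmental_aquatic = 0.00, host_associated = 0.90)
      } else {
        c(engineered = 0.40, environmental_aquatic = 0.55, host_associated = 0.05)
      }
    })
  }
  if (is.null(clade_phylum)) {
    pool <- c(A = "p__Desulfobacterota", B = "p__Firmicutes_A",
              C = "p__Firmicutes_A", D = "p__Halobacteriota",
              E = "p__Firmicutes_A", F = "p__Chloroflexota",
              G = "p__Thermoproteota", H = "p__Firmicutes_B")
    clade_phylum <- setNames(rep_len(unname(pool), n_clades), clades)
    clade_phylum[intersect(clades, names(pool))] <-
      pool[intersect(clades, names(pool))]
  }
  if (is.null(clade_functions)) {
    pool <- list(A = c("WLP", "CooF"), B = c("WLP", "CooF"), C = "FNOR",
                 D = "ECH", E = "CooF", F = "ABC_transporter",
                 G = "metallochaperone", H = character(0))
    clade_functions <- lapply(setNames(clades, clades), function(cl) {
      pool[[cl]] %||% character(0)
    })
  }
  cfg <- structure(list(
    seed = as.integer(seed), n_clades = n_clades, clades = clades,
    clusters_per_clade = clusters_per_clade,
    members_per_cluster = members_per_cluster,
    seq_length = seq_length,
    within_cluster_divergence = within_cluster_divergence,
    between_cluster_divergence = between_cluster_divergence,
    between_clade_divergence = between_clade_divergence,
    fraction_fragments = fraction_fragments,
    fraction_too_short = fraction_too_short,
    fraction_broken_motif = fraction_broken_motif,
    fraction_refseq = fraction_refseq,
    biome_bias = biome_bias,
    clade_phylum = clade_phylum,
    clade_functions = clade_functions
  ), class = "sim_config")
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  fr <- c(cfg$within_cluster_divergence, cfg$between_cluster_divergence,
          cfg$between_clade_divergence, cfg$fraction_fragments,
          cfg$fraction_too_short, cfg$fraction_broken_motif,
          cfg$fraction_refseq)
  if (any(fr < 0 | fr > 1)) abort("all fractions must lie in [0, 1]")
  if (!(cfg$within_cluster_divergence < cfg$between_cluster_divergence &&
        cfg$between_cluster_divergence < cfg$between_clade_divergence))
    abort("divergence ordering violated: need within < between-cluster < between-clade")
  if (cfg$seq_length < 400) abort("seq_length must be >= 400 for full-length records")
  for (cl in cfg$clades) {
    p <- cfg$biome_bias[[cl]]
    if (is.null(p) || abs(sum(p) - 1) > 1e-8)
      abort(paste0("biome_bias for clade ", cl, " must sum to 1"))
  }
  cfg
}

#' Generate an annotated reference motif profile
#'
#' Places disjoint motif annotations on a random sequence: a 6-residue
#' D-cluster block, four B-cluster Cys, a C-cluster block whose last three
#' annotated residues are Cys near the C-terminus, and two catalytic
#' positions.
#'
#' @param config A [sim_config()]; `seq_length` must be >= 450 so all motifs
#'   fit.
#' @return A [motif_profile()].
#' @export
sim_reference_profile <- function(config) {
  L <- config$seq_length
  if (L < 450) abort("seq_length too short to place motifs (need >= 450)")
  withr::local_seed(config$seed)
  s <- sample(AA20, L, replace = TRUE)
  d <- 41:46
  b <- c(60L, 67L, 73L, 80L)
  cat_pos <- c(100L, 261L)
  c_block <- c((L - 40):(L - 36), L - 12L, L - 9L, L - 6L)
  c_term <- c(L - 12L, L - 9L, L - 6L)
  s[c(b, c_term)] <- "C"
  motif_profile(paste(s, collapse = ""), d, b, c_block, c_term, cat_pos)
}

motif_positions <- function(profile) {
  sort(unique(c(profile$d_cluster, profile$b_cluster_cys,
                profile$c_cluster, profile$catalytic)))
}

# substitute exactly round(rate * |free|) free positions, each to one of the
# 19 non-identical canonical residues
mutate_seq <- function(chars, free, rate) {
  k <- round(rate * length(free))
  if (k == 0) return(chars)
  at <- sample(free, k)
  chars[at] <- vapply(chars[at], function(a) sample(setdiff(AA20, a), 1), "")
  chars
}

#' Simulate a clustered protein family with planted ground truth
#'
#' @param profile A [motif_profile()] from [sim_reference_profile()].
#' @param config A [sim_config()].
#' @return A list with `records` (tibble `seq_id`, `sequence`, `source_db`)
#'   and `truth` (tibble adding `true_cluster`, `true_clade`, `qc_class`
#'   (`"intact"`), `verdict` (`"representative"`)).
#' @export
sim_family <- function(profile, config) {
  validate_sim_config(config)
  withr::local_seed(config$seed + 1L)
  ref <- strsplit(profile$reference_sequence, "")[[1]]
  free <- setdiff(seq_along(ref), motif_positions(profile))

  rows <- list()
  for (ci in seq_len(config$n_clades)) {
    clade <- config$clades[ci]
    clade_anc <- mutate_seq(ref, free, config$between_clade_divergence / 2)
    for (k in seq_len(config$clusters_per_clade)) {
      clus_anc <- mutate_seq(clade_anc, free, config$between_cluster_divergence / 2)
      clus_id <- sprintf("%s_c%02d", clade, k)
      for (m in seq_len(config$members_per_cluster)) {
        mem <- mutate_seq(clus_anc, free, config$within_cluster_divergence)
        src <- if (m == 1 || runif(1) < config$fraction_refseq) "refseq" else "mgnify"
        rows[[length(rows) + 1]] <- tibble(
          seq_id = sprintf("%s_m%02d", clus_id, m),
          sequence = paste(mem, collapse = ""),
          source_db = src, true_cluster = clus_id, true_clade = clade)
      }
    }
  }
  recs <- purrr::list_rbind(rows)
  truth <- recs |> select(-"sequence") |>
    mutate(qc_class = "intact", verdict = "representative")
  list(records = select(recs, "seq_id", "sequence", "source_db"),
       truth = truth)
}

expected_verdict <- function(qc_class, source_db) {
  dplyr::case_when(
    qc_class == "intact" ~ "representative",
    qc_class == "too_short" ~ "rejected",
    source_db == "mgnify" ~ "salvage",
    TRUE ~ "rejected")
}

#' Corrupt simulated records to plant filter verdicts
#'
#' Disjoint random subsets of records are truncated to 100-399 aa (window kept
#' overlapping the B-cluster so salvage fragments remain clusterable),
#' truncated below 100 aa, or given a motif-breaking corruption (one
#' B-cluster Cys substituted to Ala, or four residues deleted across the
#' D-cluster). Ground-truth verdicts are updated per the filtering rules.
#'
#' @param family Output of [sim_family()].
#' @param profile The [motif_profile()] used to generate the family.
#' @param config A [sim_config()].
#' @return A list like `family` with corrupted `records` and updated `truth`
#'   (`qc_class` in `intact`/`fragment`/`too_short`/`motif_broken`; `verdict`
#'   in `representative`/`salvage`/`rejected`).
#' @export
sim_corrupt <- function(family, profile, config) {
  withr::local_seed(config$seed + 2L)
  recs <- family$records
  truth <- family$truth
  n <- nrow(recs)
  n_frag <- round(config$fraction_fragments * n)
  n_short <- round(config$fraction_too_short * n)
  n_broken <- round(config$fraction_broken_motif * n)
  pick <- sample(n, min(n, n_frag + n_short + n_broken))
  idx_frag <- pick[seq_len(n_frag)]
  idx_short <- pick[n_frag + seq_len(n_short)]
  idx_broken <- pick[n_frag + n_short + seq_len(n_broken)]

  bmin <- min(profile$b_cluster_cys); bmax <- max(profile$b_cluster_cys)
  for (i in idx_frag) {
    L <- nchar(recs$sequence[i])
    len <- sample(100:399, 1)
    lo <- max(1L, bmax - len + 1L)
    hi <- min(bmin, L - len + 1L)
    start <- if (lo <= hi) sample(lo:hi, 1) else 1L
    recs$sequence[i] <- substr(recs$sequence[i], start, start + len - 1L)
    truth$qc_class[i] <- "fragment"
  }
  for (i in idx_short) {
    L <- nchar(recs$sequence[i])
    len <- sample(30:99, 1)
    start <- sample(seq_len(L - len + 1L), 1)
    recs$sequence[i] <- substr(recs$sequence[i], start, start + len - 1L)
    truth$qc_class[i] <- "too_short"
  }
  for (i in idx_broken) {
    ch <- strsplit(recs$sequence[i], "")[[1]]
    if (runif(1) < 0.5) {
      ch[sample(profile$b_cluster_cys, 1)] <- "A"
    } else {
      ch <- ch[-(profile$d_cluster[2:5])]
    }
    recs$sequence[i] <- paste(ch, collapse = "")
    truth$qc_class[i] <- "motif_broken"
  }
  truth$verdict <- expected_verdict(truth$qc_class, truth$source_db)
  list(records = recs, truth = truth)
}

lineage_pools <- function() {
  list(
    engineered = c("root:Engineered:Biogas plant", "root:Engineered:Bioreactor",
                   "root:Engineered:Bioremediation", "root:Engineered:Food production",
                   "root:Engineered:Solid waste", "root:Engineered:Wastewater"),
    environmental_aquatic = c("root:Environmental:Aquatic:Aquaculture",
                              "root:Environmental:Aquatic:Estuary",
                              "root:Environmental:Aquatic:Freshwater",
                              "root:Environmental:Aquatic:Marine",
                              "root:Environmental:Aquatic:Thermal springs"),
    host_associated = c("root:Host-associated:Human:Digestive system:Large intestine",
                        "root:Host-associated:Mammals:Digestive system",
                        "root:Host-associated:Mammals:Respiratory system")
  )
}

#' Simulate biome, taxonomy and gene-context metadata
#'
#' MGnify-sourced records get a sample id, an MGnify-style biome lineage
#' drawn from their clade's `biome_bias`, and an assembly size (for per-Mbp
#' density). RefSeq-sourced records get a genome, a locus tag, GTDB-style
#' taxonomy (one genus per true cluster; phylum per clade), and a +/-15-CDS
#' gene neighbourhood carrying the clade's function-defining COGs plus random
#' background COGs.
#'
#' @param family Output of [sim_family()] or [sim_corrupt()].
#' @param config A [sim_config()].
#' @return A list of tibbles: `meta` (per-sequence links: `seq_id`,
#'   `sample_id`, `genome_id`, `locus_tag`), `biome` (`sample_id`, `lineage`,
#'   `assembly_mbp`), `taxonomy` (`genome_id`, `phylum`, `genus`, `species`,
#'   `gtdb_taxonomy`), `features` (CDS table with COG ids), `focal`
#'   (`genome_id`, `locus_tag` of the Ni-CODH loci).
#' @export
sim_metadata <- function(family, config) {
  validate_sim_config(config)
  withr::local_seed(config$seed + 3L)
  truth <- family$truth
  pools <- lineage_pools()
  rule_cogs <- cog_function_rules()
  majors <- c("engineered", "environmental_aquatic", "host_associated")

  meta <- tibble(seq_id = truth$seq_id,
                 sample_id = NA_character_, genome_id = NA_character_,
                 locus_tag = NA_character_)
  biome_rows <- list(); tax_rows <- list(); feat_rows <- list(); focal_rows <- list()
  for (i in seq_len(nrow(truth))) {
    cl <- truth$true_clade[i]
    if (truth$source_db[i] == "mgnify") {
      sample_id <- sprintf("S%04d", i)
      major <- sample(majors, 1, prob = config$biome_bias[[cl]])
      meta$sample_id[i] <- sample_id
      biome_rows[[length(biome_rows) + 1]] <- tibble(
        sample_id = sample_id,
        lineage = sample(pools[[major]], 1),
        assembly_mbp = round(runif(1, 0.5, 10), 3))
    } else {
      genome_id <- paste0("G_", truth$seq_id[i])
      contig <- paste0(genome_id, "_ctg1")
      focal_tag <- sprintf("%s_%03d", genome_id, 16L)
      meta$genome_id[i] <- genome_id
      meta$locus_tag[i] <- focal_tag
      tax_rows[[length(tax_rows) + 1]] <- tibble(
        genome_id = genome_id,
        phylum = config$clade_phylum[[cl]],
        genus = paste0("g__", truth$true_cluster[i]),
        species = paste0("s__", truth$true_cluster[i], "_sp"),
        gtdb_taxonomy = paste0("d__Bacteria;", config$clade_phylum[[cl]],
                               ";c__;o__;f__;g__", truth$true_cluster[i],
                               ";s__", truth$true_cluster[i], "_sp"))
      # 31 CDS: focal at index 16, 15 neighbours each side
      cogs <- rep(NA_character_, 31)
      need <- unlist(lapply(config$clade_functions[[cl]], function(f) {
        unlist(rule_cogs$cogs[rule_cogs$func == f])
      }))
      if (length(need) > 0) {
        slots <- sample(setdiff(1:31, 16), length(need))
        cogs[slots] <- need
      }
      bg <- setdiff(which(is.na(cogs)), 16)
      bg <- bg[runif(length(bg)) < 0.3]
      cogs[bg] <- sprintf("COG9%03d", sample(0:999, length(bg), replace = TRUE))
      feat_rows[[length(feat_rows) + 1]] <- tibble(
        genome_id = genome_id, contig_id = contig,
        locus_tag = sprintf("%s_%03d", genome_id, 1:31),
        start = (0:30) * 1000L + 1L, end = (0:30) * 1000L + 900L,
        strand = sample(c("+", "-"), 31, replace = TRUE),
        cog_ids = ifelse(is.na(cogs), "", cogs))
      focal_rows[[length(focal_rows) + 1]] <- tibble(
        genome_id = genome_id, locus_tag = focal_tag)
    }
  }
  list(meta = meta,
       biome = purrr::list_rbind(biome_rows),
       taxonomy = purrr::list_rbind(tax_rows),
       features = purrr::list_rbind(feat_rows),
       focal = purrr::list_rbind(focal_rows))
}

#' Emit a ground-truth phylogeny over cluster centroids
#'
#' Builds a Newick tree in which every clade is a perfectly monophyletic
#' group containing its centroid leaves plus two labelled reference leaves
#' (`REF_<clade>_1`, `REF_<clade>_2`); internal nodes carry support 0.99.
#'
#' @param centroid_clades A data frame with `leaf_id` and `clade` for each
#'   centroid to place.
#' @param config A [sim_config()] (seed only).
#' @return A list with `tree` (`phylo`) and `references` (tibble `leaf_id`,
#'   `clade`, `is_mini_coos`).
#' @export
sim_tree <- function(centroid_clades, config) {
  stopifnot(is.data.frame(centroid_clades))
  clades <- sort(unique(centroid_clades$clade))
  cat_node <- function(leaves) {
    sub <- paste0(leaves[1], ":0.05")
    for (l in leaves[-1]) sub <- paste0("(", sub, ",", l, ":0.05)0.99:0.05")
    sub
  }
  subs <- map_chr(clades, function(cl) {
    ids <- sort(centroid_clades$leaf_id[centroid_clades$clade == cl])
    cat_node(c(paste0("REF_", cl, "_1"), paste0("REF_", cl, "_2"), ids))
  })
  nwk <- paste0("(", paste(subs, collapse = ","), ");")
  refs <- tibble(
    leaf_id = c(paste0("REF_", rep(clades, each = 2), "_", 1:2)),
    clade = rep(clades, each = 2),
    is_mini_coos = FALSE)
  list(tree = parse_newick(nwk), references = refs)
}

#' Simulate a complete analysis-ready dataset
#'
#' Convenience wrapper: reference profile, family, corruptions and metadata
#' from one config.
#'
#' @param config A [sim_config()].
#' @return A list with `profile`, `records`, `truth`, `meta`, `biome`,
#'   `taxonomy`, `features`, `focal`.
#' @export
sim_dataset <- function(config = sim_config()) {
  profile <- sim_reference_profile(config)
  fam <- sim_family(profile, config)
  fam <- sim_corrupt(fam, profile, config)
  md <- sim_metadata(fam, config)
  c(list(profile = profile, records = fam$records, truth = fam$truth), md)
}

#' Write a simulated dataset to disk
#'
#' Sequences as FASTA; metadata tables as tab-separated UTF-8 with header
#' row; the motif profile and ground truth as JSON.
#'
#' @param sim Output of [sim_dataset()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named vector of file paths.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    fasta = file.path(dir, "sequences.fasta"),
    profile = file.path(dir, "profile.json"),
    meta = file.path(dir, "sequence_metadata.tsv"),
    biome = file.path(dir, "biomes.tsv"),
    taxonomy = file.path(dir, "taxonomy.tsv"),
    features = file.path(dir, "features.tsv"),
    focal = file.path(dir, "focal_loci.tsv"),
    truth = file.path(dir, "ground_truth.json"))
  aa <- Biostrings::AAStringSet(setNames(sim$records$sequence, sim$records$seq_id))
  Biostrings::writeXStringSet(aa, paths[["fasta"]])
  write_motif_profile(sim$profile, paths[["profile"]])
  readr::write_tsv(left_join(sim$meta,
                             select(sim$records, "seq_id", "source_db"),
                             by = "seq_id"),
                   paths[["meta"]])
  readr::write_tsv(sim$biome, paths[["biome"]])
  readr::write_tsv(sim$taxonomy, paths[["taxonomy"]])
  readr::write_tsv(sim$features, paths[["features"]])
  readr::write_tsv(sim$focal, paths[["focal"]])
  jsonlite::write_json(sim$truth, paths[["truth"]], dataframe = "columns")
  invisible(paths)
}
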