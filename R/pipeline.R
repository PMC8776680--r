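# End-to-end orchestration: qc -> cluster -> classify -> annotate -> stats,
# file in / file out, with fail-fast input validation and a machine-readable
# run manifest. Identical config + inputs give identical outputs.

#' Pipeline configuration
#'
#' @param fasta Candidate sequences (FASTA; required).
#' @param profile Motif profile JSON (required; see [write_motif_profile()]).
#' @param meta Per-sequence metadata TSV: `seq_id`, `sample_id`, `genome_id`,
#'   `locus_tag`, `source_db` (required).
#' @param biome Sample biome TSV (`sample_id`, `lineage`, optional
#'   `assembly_mbp`), or `NULL` to skip biome annotation.
#' @param taxonomy Genome taxonomy TSV (`genome_id`, `phylum`, `genus`,
#'   `species`), or `NULL`.
#' @param features,focal CDS feature table and focal locus TSVs, or `NULL`.
#' @param tree Newick tree over cluster centroids with labelled reference
#'   leaves, or `NULL` to skip clade assignment.
#' @param clade_references Reference label TSV (`leaf_id`, `clade`,
#'   `is_mini_coos`); required when `tree` is given.
#' @param outdir Output directory.
#' @param identity Clustering identity threshold (default 0.90).
#' @param min_rep_length,min_salvage_length QC length thresholds (400 / 100).
#' @param window Gene-neighbourhood half-width in CDS (default 15).
#' @param support_min Clade-assignment support gate (default 0.95).
#' @param min_subcategory_n Minimum sequences per biome subcategory
#'   (default 2).
#' @param biome_mapping Biome mapping TSV, or `NULL` for the packaged default.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(fasta, profile, meta, outdir,
                            biome = NULL, taxonomy = NULL, features = NULL,
                            focal = NULL, tree = NULL, clade_references = NULL,
                            identity = 0.90, min_rep_length = 400,
                            min_salvage_length = 100, window = 15,
                            support_min = 0.95, min_subcategory_n = 2,
                            biome_mapping = NULL, seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

read_tsv_q <- function(path) readr::read_tsv(path, show_col_types = FALSE,
                                             progress = FALSE)

validate_pipeline_config <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$identity <= 0 || config$identity > 1)
    abort("identity threshold must be in (0, 1]")
  paths <- purrr::compact(config[c("fasta", "profile", "meta", "biome",
                                   "taxonomy", "features", "focal", "tree",
                                   "clade_references", "biome_mapping")])
  missing <- names(paths)[!file.exists(unlist(paths))]
  if (length(missing) > 0)
    abort(paste("input files not found:", paste(missing, collapse = ", ")))
  if (!is.null(config$tree) && is.null(config$clade_references))
    abort("clade_references is required when a tree is given")
  if (xor(is.null(config$features), is.null(config$focal)))
    abort("features and focal must be given together")
  invisible(config)
}

#' Run the full analysis pipeline
#'
#' Executes qc, clustering, clade classification, annotation and statistics
#' in order, writing TSV/JSON outputs and a run manifest to
#' `config$outdir`. All inputs are validated before the first stage runs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results (`qc`,
#'   `clustering`, `clades`, `annotated`, `stats`) and the `manifest`.
#' @export
run_pipeline <- function(config) {
  validate_pipeline_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  t_stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- expr
    dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    message(sprintf("[%s] done in %.1fs", name, dt))
    stages[[name]] <<- list(status = "completed", seconds = round(dt, 2))
    res
  }

  # ---- qc
  qc <- t_stage("qc", {
    aa <- Biostrings::readAAStringSet(config$fasta)
    meta <- read_tsv_q(config$meta)
    records <- tibble(seq_id = names(aa), sequence = as.character(aa)) |>
      left_join(meta, by = "seq_id")
    if (anyNA(records$source_db))
      abort("sequences missing from the metadata table")
    profile <- read_motif_profile(config$profile)
    out <- qc_tiers(records, profile, config$min_rep_length,
                    config$min_salvage_length)
    readr::write_tsv(select(out, -"sequence"), file.path(config$outdir, "qc_tiers.tsv"))
    out
  })
  stages$qc$n <- nrow(qc)

  # ---- cluster
  clustering <- t_stage("cluster", {
    ordered <- sort_for_clustering(qc)
    res <- cluster_greedy(ordered, threshold = config$identity)
    uc <- bind_rows(
      res$clusters |>
        transmute(record_type = ifelse(.data$member_id == .data$centroid_id, "S", "H"),
                  .data$cluster_id, .data$identity,
                  query_id = .data$member_id, .data$centroid_id),
      tibble(record_type = "N", cluster_id = NA_character_, identity = NA_real_,
             query_id = res$unassigned_salvage, centroid_id = NA_character_))
    readr::write_tsv(uc, file.path(config$outdir, "clusters_uc.tsv"))
    cents <- Biostrings::AAStringSet(setNames(res$centroids$sequence,
                                              res$centroids$centroid_id))
    Biostrings::writeXStringSet(cents, file.path(config$outdir, "centroids.fasta"))
    res
  })
  stages$cluster$n <- nrow(clustering$centroids)

  # ---- classify
  clade_map <- NULL
  if (!is.null(config$tree)) {
    clade_map <- t_stage("classify", {
      tr <- parse_newick(paste(readLines(config$tree, warn = FALSE), collapse = ""))
      refs <- read_tsv_q(config$clade_references)
      cm <- assign_clades(tr, refs, support_min = config$support_min)
      readr::write_tsv(cm, file.path(config$outdir, "clades.tsv"))
      cm
    })
    stages$classify$n <- nrow(clade_map)
  } else {
    stages$classify <- list(status = "skipped", n = 0L)
  }

  # ---- annotate
  annotated <- t_stage("annotate", {
    meta <- read_tsv_q(config$meta)
    biome_seq <- NULL
    if (!is.null(config$biome)) {
      mapping <- if (is.null(config$biome_mapping)) default_biome_mapping()
                 else read_tsv_q(config$biome_mapping)
      biome_seq <- meta |> filter(!is.na(.data$sample_id)) |>
        inner_join(read_tsv_q(config$biome), by = "sample_id") |>
        collapse_biome(mapping = mapping) |>
        filter_rare_subcategories(min_sequences = config$min_subcategory_n) |>
        select("seq_id", "major", "sub") |>
        semi_join(clustering$clusters, by = c(seq_id = "member_id"))
    }
    tax_seq <- NULL
    if (!is.null(config$taxonomy)) {
      tax_seq <- meta |> filter(!is.na(.data$genome_id)) |>
        inner_join(read_tsv_q(config$taxonomy), by = "genome_id") |>
        select("seq_id", "phylum", "genus", "species") |>
        semi_join(clustering$clusters, by = c(seq_id = "member_id"))
    }
    fun_seq <- NULL
    if (!is.null(config$features)) {
      ctx <- extract_contexts(read_tsv_q(config$features),
                              read_tsv_q(config$focal), window = config$window)
      funs <- ctx |> group_by(.data$genome_id, .data$focal_locus) |>
        group_modify(function(d, g) tibble(func = annotate_context(
          d, window = config$window))) |>
        ungroup()
      fun_seq <- meta |> filter(!is.na(.data$locus_tag)) |>
        inner_join(funs, by = c(genome_id = "genome_id",
                                locus_tag = "focal_locus")) |>
        select("seq_id", "func") |>
        semi_join(clustering$clusters, by = c(seq_id = "member_id"))
    }
    ann <- join_annotations(clustering, biome = biome_seq, taxonomy = tax_seq,
                            functions = fun_seq, clade_map = clade_map)
    flat <- ann |> mutate(across(where(is.list),
                                 ~ map_chr(.x, paste, collapse = ",")))
    readr::write_tsv(flat, file.path(config$outdir, "annotated_clusters.tsv"))
    ann
  })
  stages$annotate$n <- nrow(annotated)

  # ---- stats
  stats_out <- t_stage("stats", {
    out <- list()
    meta <- read_tsv_q(config$meta)
    out$source_overlap <- summarize_sources(
      clustering, select(qc, "seq_id", "source_db"))
    if (!is.null(config$taxonomy)) {
      tax_seq <- meta |> filter(!is.na(.data$genome_id)) |>
        inner_join(read_tsv_q(config$taxonomy), by = "genome_id")
      out$genus_purity <- purity_by_rank(clustering, tax_seq, "genus")
    }
    if (!is.null(config$biome)) {
      pres <- build_presence(annotated, "major")
      if (ncol(pres) >= 3) {
        dmaj <- pairwise_dice(pres)
        readr::write_tsv(dmaj, file.path(config$outdir, "dice_major.tsv"))
        out$dice_major <- dmaj
      }
      comp <- clade_composition(annotated, group_domain = "major", value = "clade")
      readr::write_tsv(comp, file.path(config$outdir, "composition_clade_by_major.tsv"))
      out$composition <- comp
      if (!is.null(config$taxonomy)) {
        phy <- clade_composition(annotated, group_domain = "major", value = "phyla")
        sh <- phy |> group_by(.data$group) |>
          summarise(shannon = shannon(.data$n), n_phyla = dplyr::n(),
                    .groups = "drop")
        readr::write_tsv(sh, file.path(config$outdir, "shannon_phylum_by_major.tsv"))
        out$shannon_phylum <- sh
      }
    }
    jsonlite::write_json(
      list(source_overlap = out$source_overlap,
           genus_purity = out$genus_purity,
           n_clusters = nrow(clustering$centroids)),
      file.path(config$outdir, "cluster_summary.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "columns")
    out
  })
  stages$stats$n <- length(stats_out)

  manifest <- list(
    package_version = as.character(utils::packageVersion("codhbiome")),
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "outdir")]),
    thresholds = config[c("identity", "min_rep_length", "min_salvage_length",
                          "window", "support_min", "min_subcategory_n")],
    stages = stages)
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(qc = qc, clustering = clustering, clades = clade_map,
                 annotated = annotated, stats = stats_out,
                 manifest = manifest))
}
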