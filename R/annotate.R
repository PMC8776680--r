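# Biome, taxonomy and gene-neighbourhood annotation.
#
# Biome lineages are MGnify-style colon-delimited strings collapsed by
# longest-prefix rules to three major categories (engineered, environmental
# (aquatic), host-associated) and fifteen subcategories. Gene neighbourhoods
# (15 coding sequences up- and downstream of each focal locus) are summarised
# into functional flags via fixed COG rules.

#' Default biome lineage mapping
#'
#' Longest-prefix rules over colon-delimited lineages covering the three major
#' biome categories and their fifteen subcategories. Shipped editable as
#' `inst/extdata/biome_mapping.tsv` (lineage spellings drift between database
#' releases).
#'
#' @return A tibble with `lineage_prefix`, `major`, `sub`.
#' @export
default_biome_mapping <- function() {
  tribble(
    ~lineage_prefix, ~major, ~sub,
    "root:Engineered", "engineered", "OTHER",
    "root:Engineered:Biogas plant", "engineered", "biogas plant",
    "root:Engineered:Bioreactor", "engineered", "bioreactor",
    "root:Engineered:Bioremediation", "engineered", "bioremediation",
    "root:Engineered:Food production", "engineered", "food production",
    "root:Engineered:Solid waste", "engineered", "solid waste",
    "root:Engineered:Wastewater", "engineered", "waste water",
    "root:Environmental:Aquatic", "environmental_aquatic", "OTHER",
    "root:Environmental:Aquatic:Aquaculture", "environmental_aquatic", "aquaculture",
    "root:Environmental:Aquatic:Estuary", "environmental_aquatic", "estuary",
    "root:Environmental:Aquatic:Freshwater", "environmental_aquatic", "freshwater",
    "root:Environmental:Aquatic:Marine", "environmental_aquatic", "marine",
    "root:Environmental:Aquatic:Thermal springs", "environmental_aquatic", "thermal springs",
    "root:Host-associated", "host_associated", "OTHER",
    "root:Host-associated:Human:Digestive system", "host_associated", "human digestive system",
    "root:Host-associated:Human:Skin", "host_associated", "human skin",
    "root:Host-associated:Mammals:Digestive system", "host_associated", "mammals digestive system",
    "root:Host-associated:Mammals:Respiratory system", "host_associated", "mammals respiratory systems"
  )
}

match_lineage <- function(lineage, mapping) {
  hits <- mapping$lineage_prefix == lineage |
    startsWith(lineage, paste0(mapping$lineage_prefix, ":"))
  if (!any(hits)) return(c(major = "OTHER", sub = "OTHER"))
  best <- which(hits)[which.max(nchar(mapping$lineage_prefix[hits]))]
  c(major = mapping$major[best], sub = mapping$sub[best])
}

#' Collapse biome lineages to major/sub categories
#'
#' Deterministic longest-prefix match of each lineage against the mapping
#' rules; lineages matching no rule collapse to `OTHER`/`OTHER`.
#'
#' @param data A data frame with a lineage column.
#' @param mapping A rule table (see [default_biome_mapping()]).
#' @param lineage Name of the lineage column.
#' @return `data` with `major` and `sub` columns added.
#' @export
collapse_biome <- function(data, mapping = default_biome_mapping(),
                           lineage = "lineage") {
  stopifnot(is.data.frame(data), lineage %in% names(data))
  lin <- data[[lineage]]
  if (any(is.na(lin) | !nzchar(lin))) abort("empty biome lineage")
  res <- t(vapply(lin, match_lineage, character(2), mapping = mapping))
  out <- as_tibble(data)
  out$major <- unname(res[, "major"])
  out$sub <- unname(res[, "sub"])
  out
}

#' Drop rare biome subcategories
#'
#' Subcategories represented by fewer than `min_sequences` rows are removed
#' from subcategory-level analyses. With `keep_major = TRUE` (default) the
#' rows are retained for major-level analyses with `sub` set to `NA`;
#' otherwise the rows are dropped entirely.
#'
#' @param assignments Output of [collapse_biome()].
#' @param min_sequences Minimum rows per subcategory (default 2).
#' @param keep_major Retain rare-subcategory rows at major level.
#' @return The filtered assignments tibble.
#' @export
filter_rare_subcategories <- function(assignments, min_sequences = 2,
                                      keep_major = TRUE) {
  stopifnot(min_sequences >= 1)
  counts <- assignments |> count(.data$sub)
  rare <- counts$sub[counts$n < min_sequences]
  out <- as_tibble(assignments)
  if (keep_major) {
    out$sub[out$sub %in% rare] <- NA_character_
    out
  } else {
    filter(out, !(.data$sub %in% rare))
  }
}

#' COG rules for neighbouring gene-associated functions
#'
#' `any` rules fire when one listed COG is present in the window; `all` rules
#' require every listed COG (possibly on different neighbours).
#'
#' @return A tibble with `func`, `cogs` (list), `mode` (`"any"`/`"all"`).
#' @export
cog_function_rules <- function() {
  tribble(
    ~func, ~cogs, ~mode,
    "WLP", list("COG1614"), "any",
    "CooF", list("COG0437", "COG1142"), "any",
    "FNOR", list("COG1251"), "any",
    "ECH", list("COG3260", "COG3261"), "all",
    "ABC_transporter", list("COG0600", "COG1116", "COG0715"), "all",
    "metallochaperone", list("COG3640", "COG1532"), "any"
  )
}

#' Extract gene-neighbourhood contexts
#'
#' Builds the window of coding sequences around each focal locus, by gene
#' order on the contig (strand recorded upstream but not used).
#'
#' @param features Feature table: `genome_id`, `contig_id`, `locus_tag`,
#'   `start`, `end`, `strand`, `cog_ids` (comma-separated, may be empty).
#' @param focal A data frame with `genome_id`, `locus_tag` of the focal genes.
#' @param window Number of coding sequences on each side (default 15).
#' @return A tibble `genome_id`, `focal_locus`, `offset` (nonzero, within
#'   the window), `locus_tag`, `cog_ids`.
#' @export
extract_contexts <- function(features, focal, window = 15) {
  stopifnot(is.data.frame(features), is.data.frame(focal))
  feats <- as_tibble(features) |>
    group_by(.data$genome_id, .data$contig_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(gene_index = dplyr::row_number()) |>
    ungroup()
  foc <- as_tibble(focal) |>
    left_join(select(feats, "genome_id", "contig_id", "locus_tag", "gene_index"),
              by = c("genome_id", "locus_tag"))
  if (anyNA(foc$gene_index))
    abort("focal loci absent from the feature table")
  purrr::pmap(foc, function(genome_id, locus_tag, contig_id, gene_index, ...) {
    feats |>
      filter(.data$genome_id == !!genome_id, .data$contig_id == !!contig_id) |>
      mutate(offset = .data$gene_index - !!gene_index) |>
      filter(.data$offset != 0, abs(.data$offset) <= window) |>
      transmute(.data$genome_id, focal_locus = !!locus_tag, .data$offset,
                .data$locus_tag, .data$cog_ids)
  }) |> purrr::list_rbind()
}

#' Categorise a genomic context into functional flags
#'
#' @param context Context rows for one focal gene (columns `offset`,
#'   `cog_ids`); offsets beyond the window are ignored.
#' @param rules Rule table from [cog_function_rules()].
#' @param window Window half-width (default 15).
#' @return Character vector of function names (possibly empty), in rule order.
#' @export
annotate_context <- function(context, rules = cog_function_rules(), window = 15) {
  stopifnot(is.data.frame(context))
  ctx <- filter(as_tibble(context), abs(.data$offset) <= window,
                .data$offset != 0)
  cogs <- unlist(strsplit(ctx$cog_ids[!is.na(ctx$cog_ids)], ","))
  cogs <- unique(trimws(cogs[nzchar(cogs)]))
  if (length(cogs) > 0 && any(!grepl("^COG\\d+$", cogs)))
    abort(paste("malformed COG id:",
                paste(cogs[!grepl("^COG\\d+$", cogs)], collapse = ", ")))
  hit <- map_lgl(seq_len(nrow(rules)), function(i) {
    need <- unlist(rules$cogs[[i]])
    if (rules$mode[i] == "all") all(need %in% cogs) else any(need %in% cogs)
  })
  rules$func[hit]
}

#' Join clusters with clade, biome, taxonomy and function annotations
#'
#' @param clustering A `codh_clustering`.
#' @param biome Per-sequence biome assignments (`seq_id`, `major`, `sub`).
#' @param taxonomy Per-sequence taxonomy (`seq_id`, `phylum`, `genus`,
#'   `species`); genome-derived, so typically RefSeq members only.
#' @param functions Per-sequence functional flags (`seq_id`, `func`), long
#'   format; typically RefSeq members only.
#' @param clade_map Clade assignment of centroids ([assign_clades()] output).
#' @return A tibble with one row per cluster: `cluster_id`, `centroid_id`,
#'   `clade`, `mini_coos`, `n_members`, and list-columns `majors`, `subs`,
#'   `phyla`, `genera`, `functions` (empty character vectors when a metadata
#'   type is absent, never `NULL`).
#' @export
join_annotations <- function(clustering, biome = NULL, taxonomy = NULL,
                             functions = NULL, clade_map = NULL) {
  stopifnot(inherits(clustering, "codh_clustering"))
  members <- clustering$clusters
  known <- members$member_id
  check_ids <- function(tbl, what) {
    if (is.null(tbl)) return(invisible())
    bad <- setdiff(tbl$seq_id, known)
    if (length(bad) > 0)
      abort(paste0(what, " references unknown sequence ids: ",
                   paste(head(bad, 5), collapse = ", ")))
  }
  check_ids(biome, "biome table")
  check_ids(taxonomy, "taxonomy table")
  check_ids(functions, "function table")

  collect <- function(tbl, col) {
    if (is.null(tbl)) return(function(ids) character(0))
    lut <- split(tbl[[col]], tbl$seq_id)
    function(ids) {
      v <- unlist(lut[ids], use.names = FALSE)
      as.character(sort(unique(v[!is.na(v)])))
    }
  }
  g_major <- collect(biome, "major"); g_sub <- collect(biome, "sub")
  g_phy <- collect(taxonomy, "phylum"); g_gen <- collect(taxonomy, "genus")
  g_fun <- collect(functions, "func")

  out <- members |>
    group_by(.data$cluster_id, .data$centroid_id) |>
    summarise(n_members = dplyr::n(),
              majors = list(g_major(.data$member_id)),
              subs = list(g_sub(.data$member_id)),
              phyla = list(g_phy(.data$member_id)),
              genera = list(g_gen(.data$member_id)),
              functions = list(g_fun(.data$member_id)),
              .groups = "drop")
  if (!is.null(clade_map)) {
    out <- out |>
      left_join(select(as_tibble(clade_map), "leaf_id", "clade", "mini_coos"),
                by = c(centroid_id = "leaf_id")) |>
      mutate(clade = dplyr::coalesce(.data$clade, "UNASSIGNED"),
             mini_coos = dplyr::coalesce(.data$mini_coos, FALSE))
  } else {
    out$clade <- "UNASSIGNED"; out$mini_coos <- FALSE
  }
  relocate(out, "clade", "mini_coos", .after = "centroid_id")
}
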