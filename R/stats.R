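# Cluster co-occurrence and composition statistics.
#
# Clusters x labels presence/absence structures feed Dice co-occurrence,
# clade/taxon composition profiles, Shannon diversity, PCA, Welch's t test,
# a one-sided Grubbs maximum-outlier test, and per-Mbp density normalisation.

#' Build a cluster-by-label presence matrix
#'
#' A cell is `TRUE` when the cluster has at least one member carrying the
#' label, so a cluster may be present under several labels at once. Labels
#' that occur in no cluster are dropped; all-absent clusters are retained
#' unless `drop_empty_clusters`.
#'
#' @param annotated Output of [join_annotations()].
#' @param domain One of `"major"`, `"sub"`, `"phylum"`, `"genus"`,
#'   `"function"`, `"clade"`.
#' @param drop_empty_clusters Drop rows with no label in the domain.
#' @return A tibble: `cluster_id` plus one logical column per label.
#' @export
build_presence <- function(annotated,
                           domain = c("major", "sub", "phylum", "genus",
                                      "function", "clade"),
                           drop_empty_clusters = FALSE) {
  domain <- match.arg(domain)
  col <- switch(domain, major = "majors", sub = "subs", phylum = "phyla",
                genus = "genera", `function` = "functions", clade = "clade")
  vals <- if (domain == "clade") as.list(annotated$clade) else annotated[[col]]
  labels <- sort(unique(unlist(vals)))
  out <- tibble(cluster_id = annotated$cluster_id)
  for (lb in labels) out[[lb]] <- map_lgl(vals, function(v) lb %in% v)
  if (drop_empty_clusters && length(labels) > 0) {
    keep <- rowSums(as.matrix(out[, labels, drop = FALSE])) > 0
    out <- out[keep, , drop = FALSE]
  }
  out
}

#' Dice similarity of two cluster-id sets
#'
#' `2|A intersect B| / (|A| + |B|)`; defined as 0 (with a warning) when both
#' sets are empty.
#'
#' @param a,b Vectors of cluster ids.
#' @return Similarity fraction in \[0, 1\].
#' @export
dice <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) + length(b) == 0) {
    warn("Dice of two empty sets; returning 0")
    return(0)
  }
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Pairwise Dice coefficients between presence-matrix labels
#'
#' @param presence Output of [build_presence()].
#' @return A long tibble `label_a`, `label_b`, `dice`, symmetric with unit
#'   diagonal for non-empty labels.
#' @export
pairwise_dice <- function(presence) {
  labels <- setdiff(names(presence), "cluster_id")
  if (length(labels) < 2) abort("pairwise_dice needs at least 2 labels")
  sets <- lapply(labels, function(lb) presence$cluster_id[presence[[lb]]])
  names(sets) <- labels
  grid <- tidyr::expand_grid(label_a = labels, label_b = labels)
  grid$dice <- map_dbl(seq_len(nrow(grid)), function(i) {
    suppressWarnings(dice(sets[[grid$label_a[i]]], sets[[grid$label_b[i]]]))
  })
  grid
}

#' Shannon diversity index (natural log)
#'
#' @param counts Non-negative counts per category; total must be positive.
#' @return `H = -sum p_i ln p_i` over categories with `p_i > 0`.
#' @export
shannon <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || anyNA(counts)) abort("counts must be non-negative")
  if (sum(counts) <= 0) abort("all-zero counts")
  unname(vegan::diversity(counts, index = "shannon"))
}

#' Composition profile of clusters by clade (or another label) per group
#'
#' Counts clusters per clade within each group defined by a presence domain
#' (e.g. per major biome, counting a cluster under every biome it occurs in),
#' and derives relative abundances.
#'
#' @param annotated Output of [join_annotations()].
#' @param group_domain Presence domain defining the groups (see
#'   [build_presence()]), or `"source"` is not supported here — pass a
#'   precomputed grouping via `groups`.
#' @param value Column of `annotated` tallied within groups: `"clade"`
#'   (default) or a list-column name such as `"phyla"` or `"functions"`.
#' @param groups Optional tibble `cluster_id`, `group` overriding
#'   `group_domain`.
#' @return A tibble `group`, `label`, `n`, `fraction`; fractions sum to 1
#'   within each non-empty group.
#' @export
clade_composition <- function(annotated, group_domain = "major",
                              value = "clade", groups = NULL) {
  if (is.null(groups)) {
    pres <- build_presence(annotated, domain = group_domain)
    groups <- tidyr::pivot_longer(pres, -"cluster_id", names_to = "group",
                                  values_to = "present") |>
      filter(.data$present) |> select("cluster_id", "group")
  }
  vals <- annotated |>
    select("cluster_id", val = dplyr::all_of(value)) |>
    (\(d) if (is.list(d$val)) tidyr::unnest_longer(d, "val") else d)() |>
    filter(!is.na(.data$val))
  groups |>
    inner_join(vals, by = "cluster_id", relationship = "many-to-many") |>
    count(.data$group, label = .data$val) |>
    group_by(.data$group) |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    ungroup()
}

#' Principal component analysis of composition profiles
#'
#' Rows are groups (e.g. biomes), columns relative abundances per label;
#' the matrix is column-centred (not variance-scaled) and decomposed by SVD.
#' Groups with zero total are dropped with a warning.
#'
#' @param profiles Output of [clade_composition()].
#' @return An object of class `codh_pca` with `scores`, `loadings`,
#'   `variance_fraction`, and the underlying [stats::prcomp()] fit.
#' @export
composition_pca <- function(profiles) {
  wide <- profiles |>
    select("group", "label", "fraction") |>
    tidyr::pivot_wider(names_from = "label", values_from = "fraction",
                       values_fill = 0)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$group
  if (nrow(m) < 2 || ncol(m) < 2)
    abort("composition_pca needs at least 2 groups and 2 labels")
  fit <- prcomp(m, center = TRUE, scale. = FALSE)
  vf <- fit$sdev^2 / sum(fit$sdev^2)
  structure(list(
    scores = as_tibble(fit$x, rownames = "group"),
    loadings = as_tibble(fit$rotation, rownames = "label"),
    variance_fraction = vf,
    fit = fit
  ), class = "codh_pca")
}

#' @export
print.codh_pca <- function(x, ...) {
  cat("<codh_pca>", nrow(x$scores), "groups,", nrow(x$loadings), "labels\n")
  cat("  variance fractions:",
      paste(sprintf("%.3f", head(x$variance_fraction, 4)), collapse = " "), "\n")
  invisible(x)
}

#' @describeIn composition_pca Tidy scores table.
#' @param x A `codh_pca`.
#' @param ... Unused.
#' @export
tidy.codh_pca <- function(x, ...) {
  tidyr::pivot_longer(x$scores, -"group", names_to = "PC",
                      values_to = "score")
}

#' @describeIn composition_pca Per-component variance summary.
#' @export
glance.codh_pca <- function(x, ...) {
  tibble(PC = paste0("PC", seq_along(x$variance_fraction)),
         variance_fraction = x$variance_fraction,
         cumulative = cumsum(x$variance_fraction))
}

#' Welch's two-sample t test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' (wraps [stats::t.test()]).
#'
#' @param x,y Numeric samples of size >= 2; at least one with nonzero
#'   variance.
#' @param sides `"two.sided"` (default), `"less"` or `"greater"`.
#' @return A one-row tibble `t`, `df`, `p`, `mean_x`, `mean_y`.
#' @export
welch_t <- function(x, y, sides = c("two.sided", "less", "greater")) {
  sides <- match.arg(sides)
  if (length(x) < 2 || length(y) < 2) abort("both samples need >= 2 values")
  if (sd(x) == 0 && sd(y) == 0) abort("both samples degenerate (zero variance)")
  ht <- t.test(x, y, var.equal = FALSE, alternative = sides)
  tibble(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value, mean_x = mean(x), mean_y = mean(y))
}

#' Grubbs test for a single maximum outlier
#'
#' One-sided test of the largest value: `G = (max - mean) / sd`. The p value
#' uses the standard t-distribution transform
#' `p = n * P(T_{n-2} > sqrt(n (n-2) G^2 / ((n-1)^2 - n G^2)))`, capped at 1.
#' A two-sided variant (largest absolute deviation) is available.
#'
#' @param values Numeric sample, n >= 3, nonzero standard deviation.
#' @param two_sided Test the largest absolute deviation instead.
#' @return A one-row tibble `g`, `p`, `outlier`, `n`.
#' @export
grubbs_max <- function(values, two_sided = FALSE) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3) abort("Grubbs test needs n >= 3")
  s <- sd(values)
  if (s == 0) abort("zero standard deviation")
  dev <- if (two_sided) abs(values - mean(values)) else values - mean(values)
  i <- which.max(dev)
  g <- dev[i] / s
  denom <- (n - 1)^2 - n * g^2
  p <- if (denom <= 0) 0 else {
    tstat <- sqrt(n * (n - 2) * g^2 / denom)
    n * pt(tstat, df = n - 2, lower.tail = FALSE)
  }
  if (two_sided) p <- 2 * p
  tibble(g = g, p = min(1, p), outlier = values[i], n = n)
}

#' Sequence density per megabase
#'
#' @param count Sequence count (>= 0).
#' @param size_mbp Assembly size in Mbp (> 0).
#' @return `count / size_mbp`.
#' @export
density_per_mbp <- function(count, size_mbp) {
  if (any(size_mbp <= 0)) abort("assembly size must be positive")
  count / size_mbp
}
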