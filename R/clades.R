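# Reference-guided clade assignment on a phylogeny of cluster centroids.
#
# Clades (A-H, plus the mini-CooS sublabel inside clade G) are defined by
# labelled reference leaves. Each query leaf is assigned from the smallest
# edge-bipartition side that contains it together with at least one reference:
# if all references in that side carry one clade label (and the bipartition is
# adequately supported) the query inherits it; otherwise the side is expanded
# to the next-smallest candidate, with UNASSIGNED on unresolvable conflict.
# Because bipartitions ignore rooting, assignment is invariant under
# re-rooting; paraphyletic clades (e.g. clade F split into several reference
# groups) are handled naturally since each group supports its own side.

#' Parse a Newick string into a phylogeny
#'
#' Thin validated wrapper around [ape::read.tree()]: rejects malformed input
#' and duplicated leaf labels. Topology, branch lengths and internal node
#' support labels round-trip through [ape::write.tree()].
#'
#' @param text A Newick string.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  tr <- tryCatch(suppressWarnings(ape::read.tree(text = text)),
                 error = function(e) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    abort("malformed Newick string")
  if (anyDuplicated(tr$tip.label) > 0)
    abort("duplicate leaf labels in tree")
  tr
}

# numeric supports on the [0,1] scale; values > 1 treated as percentages
parse_supports <- function(labels) {
  s <- suppressWarnings(as.numeric(labels))
  if (any(!is.na(s) & s > 1)) s <- s / 100
  s
}

#' Assign clades to tree leaves from labelled references
#'
#' @param tree A `phylo` object whose leaves are cluster centroids plus
#'   reference sequences; internal node labels, when present, are read as
#'   bootstrap supports (auto-scaled: values > 1 are percentages).
#' @param references A data frame with columns `leaf_id`, `clade` and
#'   optionally `is_mini_coos` (logical); every clade must have at least two
#'   reference leaves present in the tree.
#' @param support_min Minimum support for a bipartition to be used as
#'   assignment evidence (default 0.95); bipartitions without a support value
#'   always qualify. Set `use_support = FALSE` to disable the gate.
#' @param use_support Apply the support gate.
#' @return A tibble with `leaf_id`, `clade` (`"UNASSIGNED"` when no clean
#'   reference bipartition exists), `is_reference`, `mini_coos` (all
#'   supporting references flagged mini-CooS), and `support` of the assigning
#'   bipartition (`NA` for references and unassigned leaves).
#' @export
assign_clades <- function(tree, references, support_min = 0.95,
                          use_support = TRUE) {
  stopifnot(inherits(tree, "phylo"), is.data.frame(references))
  refs <- as_tibble(references)
  if (!"is_mini_coos" %in% names(refs)) refs$is_mini_coos <- FALSE
  missing_ref <- setdiff(refs$leaf_id, tree$tip.label)
  if (length(missing_ref) > 0)
    abort(paste("reference leaves absent from tree:",
                paste(missing_ref, collapse = ", ")))
  per_clade <- table(refs$clade)
  if (any(per_clade < 2))
    abort(paste("clades with fewer than 2 reference leaves:",
                paste(names(per_clade)[per_clade < 2], collapse = ", ")))

  ntip <- length(tree$tip.label)
  parts <- ape::prop.part(tree)                     # tip sets per internal node
  supports <- if (!is.null(tree$node.label)) parse_supports(tree$node.label)
              else rep(NA_real_, tree$Nnode)

  all_tips <- seq_len(ntip)
  # Collect bipartition sides, deduplicated: with a binary root the two child
  # subtrees are complements describing one unrooted edge, possibly labelled
  # twice; merge duplicate sides keeping the best support.
  side_env <- new.env(parent = emptyenv())
  add_side <- function(s, supp) {
    key <- paste(s, collapse = ",")
    old <- side_env[[key]]
    if (is.null(old)) {
      side_env[[key]] <- list(s = s, supp = supp)
    } else if (!is.na(supp) && (is.na(old$supp) || supp > old$supp)) {
      side_env[[key]]$supp <- supp
    }
  }
  for (k in seq_along(parts)) {
    s <- sort(parts[[k]])
    if (length(s) >= ntip) next                     # trivial (added separately)
    add_side(s, supports[k])
    add_side(sort(setdiff(all_tips, s)), supports[k])
  }
  add_side(all_tips, NA_real_)                      # last-resort whole tree
  merged <- as.list(side_env)
  sides <- map(merged, "s")
  side_support <- map_dbl(merged, "supp")

  ref_tip <- match(refs$leaf_id, tree$tip.label)
  ref_clade <- setNames(refs$clade, ref_tip)
  ref_mini <- setNames(refs$is_mini_coos, ref_tip)
  has_ref <- map_lgl(sides, function(s) any(s %in% ref_tip))
  ord <- order(lengths(sides))

  assign_one <- function(q) {
    for (k in ord) {
      s <- sides[[k]]
      if (!(q %in% s) || !has_ref[k]) next
      if (use_support && !is.na(side_support[k]) && side_support[k] < support_min)
        next
      in_refs <- as.character(intersect(s, ref_tip))
      clades <- unique(ref_clade[in_refs])
      if (length(clades) == 1) {
        return(list(clade = unname(clades),
                    mini = all(ref_mini[in_refs]),
                    support = side_support[k]))
      }
      # conflicting references: expand to the next-smallest side
    }
    list(clade = "UNASSIGNED", mini = FALSE, support = NA_real_)
  }

  out <- map(all_tips, function(q) {
    if (q %in% ref_tip) {
      i <- match(q, ref_tip)
      list(clade = refs$clade[i], mini = refs$is_mini_coos[i],
           support = NA_real_, is_ref = TRUE)
    } else {
      c(assign_one(q), list(is_ref = FALSE))
    }
  })
  tibble(
    leaf_id = tree$tip.label,
    clade = map_chr(out, "clade"),
    is_reference = map_lgl(out, "is_ref"),
    mini_coos = map_lgl(out, "mini"),
    support = map_dbl(out, "support")
  )
}
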