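#' Clade labeling of query leaves via reference anchors
#'
#' A tree containing both query sequences and reference sequences of known
#' clade membership ("anchors") can be used to label the queries. Two
#' readings of "the clade an anchor defines" are implemented:
#'
#' * `nearest-anchor` (default): each query leaf takes the group of the
#'   anchor at minimal patristic distance (sum of branch lengths). Ties are
#'   broken by the smaller patristic distance from the query to its MRCA
#'   with the anchor, then by lexicographically smallest group; tie events
#'   are recorded in the `ties` attribute.
#' * `smallest-anchored-clade`: each query takes the group of the smallest
#'   clade that contains it together with at least one anchor, provided all
#'   anchors inside that clade agree on one group; otherwise the query is
#'   left unlabeled.
#'
#' Both methods are invariant under leaf reordering and ladderization, and
#' `nearest-anchor` is invariant under uniform scaling of branch lengths.
#'
#' @param tree rooted `phylo` tree (with branch lengths for
#'   `nearest-anchor`). Unrooted trees raise an error unless
#'   `midpoint_root = TRUE`, in which case they are midpoint-rooted first
#'   (root placement affects [root_order()], hence the explicit flag).
#' @param anchors named character vector: anchor leaf label -> group label.
#' @param method `"nearest-anchor"` or `"smallest-anchored-clade"`.
#' @param midpoint_root midpoint-root an unrooted input tree.
#' @return named character vector over all non-anchor leaves (group label
#'   or `NA`), with attribute `ties` listing tie-broken queries.
#' @export
assign_groups <- function(tree, anchors,
                          method = c("nearest-anchor",
                                     "smallest-anchored-clade"),
                          midpoint_root = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) {
    if (!midpoint_root) {
      stop("tree is unrooted; re-root it or set midpoint_root = TRUE ",
           "(midpoint rooting)")
    }
    if (!requireNamespace("phangorn", quietly = TRUE)) {
      stop("midpoint rooting requires the 'phangorn' package")
    }
    tree <- phangorn::midpoint(tree)
  }
  missing_anchor <- setdiff(names(anchors), tree$tip.label)
  if (length(missing_anchor)) {
    stop("anchor leaf/leaves not in tree: ",
         paste(missing_anchor, collapse = ", "))
  }
  queries <- setdiff(tree$tip.label, names(anchors))
  out <- stats::setNames(rep(NA_character_, length(queries)), queries)
  ties <- character()
  if (!length(anchors) || !length(queries)) {
    attr(out, "ties") <- ties
    return(out)
  }
  if (method == "nearest-anchor") {
    if (is.null(tree$edge.length)) {
      stop("nearest-anchor assignment needs branch lengths")
    }
    dn <- ape::dist.nodes(tree)
    tip_idx <- stats::setNames(seq_along(tree$tip.label), tree$tip.label)
    for (q in queries) {
      d <- dn[tip_idx[[q]], tip_idx[names(anchors)]]
      best <- which(d <= min(d) + 1e-12 * max(min(d), 1))
      if (length(best) > 1L) {
        cand <- names(anchors)[best]
        dm <- vapply(cand, function(a) {
          m <- ape::getMRCA(tree, c(q, a))
          dn[tip_idx[[q]], m]
        }, 0)
        grp <- unname(anchors[cand])
        o <- order(dm, grp)
        if (length(unique(grp)) > 1L) ties <- c(ties, q)
        out[[q]] <- grp[o[1L]]
      } else {
        out[[q]] <- unname(anchors[best])
      }
    }
  } else {
    tips_below <- clade_tip_sets(tree)
    anchor_set <- names(anchors)
    for (q in queries) {
      anc <- node_ancestry(tree, which(tree$tip.label == q))
      for (node in anc) {  # nearest ancestor first => smallest clade first
        leaves <- tips_below[[as.character(node)]]
        in_clade <- intersect(leaves, anchor_set)
        if (length(in_clade)) {
          grps <- unique(unname(anchors[in_clade]))
          if (length(grps) == 1L) out[[q]] <- grps
          break
        }
      }
    }
  }
  attr(out, "ties") <- ties
  out
}

# tip labels below each internal node
clade_tip_sets <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  n_tip <- length(tree$tip.label)
  out <- lapply(pp, function(ix) labs[ix])
  names(out) <- as.character(n_tip + seq_along(pp))
  out
}

# internal-node ancestors of a node, nearest first, ending at the root
node_ancestry <- function(tree, node) {
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  anc <- integer()
  cur <- node
  while (parent[cur] != 0L) {
    cur <- parent[cur]
    anc <- c(anc, cur)
  }
  anc
}

#' Census of group membership by species
#'
#' Counts labeled leaves per (group, species) and flags, per group, whether
#' its leaves form a monophyletic clade (polyphyletic groups are how
#' discordant family organisations show up between species).
#'
#' @param tree a rooted `phylo` tree.
#' @param groups named character vector: leaf -> group (anchors and/or
#'   assigned queries); leaves absent from the map count as unlabeled.
#' @param species named character vector: leaf -> species label.
#' @return list with `census` (data frame `group`, `species`, `n`),
#'   `monophyletic` (named logical per group) and `unlabeled` (count).
#' @export
group_census <- function(tree, groups, species) {
  stopifnot(inherits(tree, "phylo"))
  groups <- groups[!is.na(groups)]
  leaves <- intersect(names(groups), tree$tip.label)
  groups <- groups[leaves]
  sp <- unname(species[leaves])
  census <- as.data.frame(table(group = unname(groups), species = sp),
                          stringsAsFactors = FALSE)
  names(census)[3L] <- "n"
  census$n <- as.integer(census$n)
  census <- census[census$n > 0L, , drop = FALSE]
  rownames(census) <- NULL
  mono <- vapply(sort(unique(unname(groups))), function(g) {
    tips <- names(groups)[groups == g]
    length(tips) == 1L || ape::is.monophyletic(tree, tips)
  }, TRUE)
  list(census = census, monophyletic = mono,
       unlabeled = length(setdiff(tree$tip.label, names(groups))))
}

#' Order groups by distance of their MRCA from the root
#'
#' For cross-study comparison of family organisation, groups are ordered
#' from closest to furthest from the root, measured by the edge-count depth
#' of each group's MRCA (branch-length depth as tie-break). Groups whose
#' MRCAs tie on both measures share a rank and are reported as tied.
#'
#' @inheritParams group_census
#' @return data frame `group`, `edge_depth`, `bl_depth`, `rank` (ties share
#'   a rank), ordered root-outward.
#' @export
root_order <- function(tree, groups) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("root_order() needs a rooted tree")
  groups <- groups[!is.na(groups)]
  gs <- sort(unique(unname(groups)))
  if (!length(gs)) {
    return(data.frame(group = character(), edge_depth = integer(),
                      bl_depth = numeric(), rank = integer()))
  }
  root <- length(tree$tip.label) + 1L
  # edge-count and branch-length depth of every node from the root
  n_node <- max(tree$edge)
  edepth <- rep(NA_integer_, n_node); edepth[root] <- 0L
  bdepth <- rep(NA_real_, n_node); bdepth[root] <- 0
  tree <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  el <- tree$edge.length %||% rep(0, nrow(tree$edge))
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]; ch <- tree$edge[i, 2L]
    edepth[ch] <- edepth[p] + 1L
    bdepth[ch] <- bdepth[p] + el[i]
  }
  mrca_of <- function(tips) {
    if (length(tips) == 1L) which(tree$tip.label == tips) else ape::getMRCA(tree, tips)
  }
  d <- do.call(rbind, lapply(gs, function(g) {
    node <- mrca_of(names(groups)[groups == g])
    data.frame(group = g, edge_depth = edepth[node], bl_depth = bdepth[node],
               stringsAsFactors = FALSE)
  }))
  d <- d[order(d$edge_depth, d$bl_depth, d$group), , drop = FALSE]
  key <- paste(d$edge_depth, signif(d$bl_depth, 12))
  d$rank <- match(key, unique(key))
  rownames(d) <- NULL
  d
}

#' Read anchor / species maps
#'
#' Two-column TSV (`leaf`, `value`) used for anchor->group and
#' leaf->species maps alongside a newick tree.
#'
#' @param path file path.
#' @return named character vector.
#' @export
read_leaf_map <- function(path) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                         col.names = c("leaf", "value"))
  stats::setNames(d$value, d$leaf)
}
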