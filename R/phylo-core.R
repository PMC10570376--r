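#' Read a Newick tree
#'
#' Thin wrapper around \code{ape::read.tree} that enforces the package's tree
#' contract: unique tip labels and non-negative branch lengths. Polytomies
#' are allowed and preserved.
#'
#' @param text A Newick string, or \code{NULL} when \code{file} is given.
#' @param file Path to a Newick file.
#' @return A rooted \code{phylo} object with branch lengths.
#' @examples
#' tr <- parseNewick("((A:1,B:1):1,(C:1,D:1):1);")
#' @export
parseNewick <- function(text = NULL, file = NULL) {
  tr <- suppressWarnings(
    if (!is.null(file)) ape::read.tree(file = file)
    else ape::read.tree(text = text))
  if (is.null(tr)) stop("malformed Newick string", call. = FALSE)
  assertThat(!anyDuplicated(tr$tip.label),
             "duplicate tip names in tree: %s",
             paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
                   collapse = ", "))
  assertThat(!is.null(tr$edge.length), "tree has no branch lengths")
  assertThat(all(tr$edge.length >= 0), "negative branch lengths in tree")
  tr
}

#' Write a tree as Newick
#'
#' @param tree A \code{phylo} object.
#' @param file Optional path; when omitted the Newick string is returned.
#' @return The Newick string (invisibly when writing to file).
#' @export
writeNewick <- function(tree, file = NULL) {
  if (is.null(file)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = file)
  invisible(ape::write.tree(tree))
}

# Depth of every node below the root, in branch-length units.
nodeDepths <- function(tree) ape::node.depth.edgelength(tree)

# Attach a new tip as an extra child of an existing internal node.
# Exact edge surgery: no other branch length is touched.
bindTipAtNode <- function(tree, label, node, pendant) {
  n <- length(tree$tip.label)
  edge <- tree$edge
  edge[edge > n] <- edge[edge > n] + 1L
  tree$edge <- rbind(edge, c(node + 1L, n + 1L))
  tree$edge.length <- c(tree$edge.length, pendant)
  tree$tip.label <- c(tree$tip.label, label)
  attr(tree, "order") <- NULL
  stats::reorder(tree, "cladewise")
}

# Split the edge above `child` at `position` above it and hang a new tip
# (with its own pendant length) from the split point.
bindTipOnEdge <- function(tree, label, child, position, pendant) {
  n <- length(tree$tip.label)
  edge <- tree$edge
  len <- tree$edge.length
  edge[edge > n] <- edge[edge > n] + 1L
  childAdj <- if (child > n) child + 1L else child
  k <- which(edge[, 2] == childAdj)
  assertThat(length(k) == 1, "child %d has no parent edge", child)
  assertThat(len[k] >= position - 1e-12,
             "split position exceeds the edge length")
  newTip <- n + 1L
  newNode <- n + 1L + tree$Nnode + 1L
  edge[k, 2] <- newNode
  lenTop <- max(len[k] - position, 0)
  len[k] <- lenTop
  tree$edge <- rbind(edge, c(newNode, childAdj), c(newNode, newTip))
  tree$edge.length <- c(len, position, pendant)
  tree$tip.label <- c(tree$tip.label, label)
  tree$Nnode <- tree$Nnode + 1L
  attr(tree, "order") <- NULL
  stats::reorder(tree, "cladewise")
}

# Height of the tree = maximum root-to-tip depth.
treeHeight <- function(tree) max(nodeDepths(tree)[seq_along(tree$tip.label)])

#' Check ultrametricity of root-to-tip depths
#'
#' @param tree A \code{phylo}.
#' @param tol Relative tolerance on depth spread.
#' @return Logical.
#' @export
isUltrametric <- function(tree, tol = 1e-8) {
  d <- nodeDepths(tree)[seq_along(tree$tip.label)]
  (max(d) - min(d)) <= tol * max(max(d), .Machine$double.eps)
}

#' Graft missing species onto a backbone tree
#'
#' Each target species is attached as a new pendant tip at the crown node
#' (MRCA of the tips already present) of its genus or, when the genus has no
#' tips, of its family. The pendant edge length equals the height of the
#' attachment node above the tip level, so an ultrametric backbone stays
#' ultrametric. When a genus (or family) is represented by a single tip the
#' crown node does not exist; by default the pendant edge of that tip is split
#' at half its length and the target attached there
#' (\code{monotypic = "split"}); \code{monotypic = "parent"} attaches at the
#' tip's parent node instead.
#'
#' @param tree Ultrametric \code{phylo} backbone.
#' @param tax A \linkS4class{TaxonomyMap} covering backbone tips and targets.
#' @param targets Character vector of species to add (absent from the tree).
#' @param monotypic Placement rule for single-tip genera/families.
#' @return The enlarged tree, with attribute \code{"graft_report"}: a list
#'   with counts \code{added_at_genus} and \code{added_at_family}.
#' @seealso \code{\link{graftReport}}
#' @export
graftMissingSpecies <- function(tree, tax, targets,
                                monotypic = c("split", "parent")) {
  monotypic <- match.arg(monotypic)
  assertThat(!any(targets %in% tree$tip.label),
             "targets already present in tree: %s",
             paste(intersect(targets, tree$tip.label), collapse = ", "))
  assertThat(all(targets %in% tax@species),
             "targets missing from taxonomy: %s",
             paste(setdiff(targets, tax@species), collapse = ", "))

  # resolve placements up front so unplaceable species error as a batch
  tipGenus <- genusOf(tax, tree$tip.label)
  tipFamily <- familyOf(tax, tree$tip.label)
  level <- character(length(targets))
  for (i in seq_along(targets)) {
    g <- genusOf(tax, targets[i]); f <- familyOf(tax, targets[i])
    level[i] <- if (any(tipGenus == g, na.rm = TRUE)) "genus"
                else if (any(tipFamily == f, na.rm = TRUE)) "family"
                else "none"
  }
  if (any(level == "none"))
    stop("species with no congeneric or confamilial tips in tree: ",
         paste(targets[level == "none"], collapse = ", "), call. = FALSE)

  # freeze the backbone height: per-graft rounding must not compound
  H <- treeHeight(tree)
  for (i in seq_along(targets)) {
    sp <- targets[i]
    members <- if (level[i] == "genus") {
      tree$tip.label[genusOf(tax, tree$tip.label) == genusOf(tax, sp)]
    } else {
      tree$tip.label[familyOf(tax, tree$tip.label) == familyOf(tax, sp)]
    }
    members <- members[!is.na(members)]
    depths <- nodeDepths(tree)
    if (length(members) >= 2) {
      node <- ape::getMRCA(tree, members)
      tree <- bindTipAtNode(tree, sp, node, H - depths[node])
    } else {
      tipIdx <- match(members, tree$tip.label)
      pend <- tree$edge.length[tree$edge[, 2] == tipIdx]
      if (monotypic == "split") {
        tree <- bindTipOnEdge(tree, sp, tipIdx, pend / 2, pend / 2)
      } else {
        parent <- tree$edge[tree$edge[, 2] == tipIdx, 1]
        tree <- bindTipAtNode(tree, sp, parent, pend)
      }
    }
  }
  attr(tree, "graft_report") <- list(added_at_genus = sum(level == "genus"),
                                     added_at_family = sum(level == "family"))
  tree
}

#' Retrieve the graft report of a grafted tree
#'
#' @param tree A tree returned by \code{\link{graftMissingSpecies}}.
#' @return List with \code{added_at_genus} and \code{added_at_family} counts.
#' @export
graftReport <- function(tree) attr(tree, "graft_report")

#' Collapse a tree to genus or family resolution
#'
#' Every species becomes a pendant tip attached at the crown node (MRCA) of
#' its genus (or family); structure within the rank is discarded while
#' ultrametricity and between-rank structure are preserved. Ranks represented
#' by a single tip are left untouched. Ranks must be monophyletic on the
#' input tree.
#'
#' @param tree Ultrametric \code{phylo} with all tips mapped in \code{tax}.
#' @param tax A \linkS4class{TaxonomyMap}.
#' @param rank \code{"genus"} or \code{"family"}.
#' @return The collapsed tree.
#' @export
collapseToRank <- function(tree, tax, rank = c("genus", "family")) {
  rank <- match.arg(rank)
  assertThat(all(tree$tip.label %in% tax@species),
             "tips not mapped in taxonomy: %s",
             paste(setdiff(tree$tip.label, tax@species), collapse = ", "))
  lab <- if (rank == "genus") genusOf(tax, tree$tip.label)
         else familyOf(tax, tree$tip.label)
  groups <- split(tree$tip.label, lab)
  depths <- nodeDepths(tree)
  H <- max(depths[seq_along(tree$tip.label)])

  crown <- vapply(groups, function(tips) {
    if (length(tips) < 2) return(NA_real_)
    node <- ape::getMRCA(tree, tips)
    below <- ape::extract.clade(tree, node)$tip.label
    assertThat(setequal(below, tips),
               "rank '%s' is not monophyletic on the tree",
               lab[match(tips[1], tree$tip.label)])
    H - depths[node]
  }, numeric(1))

  multi <- names(groups)[lengths(groups) >= 2]
  if (length(multi) == length(groups) && length(groups) == 1) {
    # whole tree is one rank: star tree at the root
    tips <- groups[[1]]
    star <- ape::read.tree(text = paste0("(", paste0(tips, ":", H,
                                                     collapse = ","), ");"))
    return(star)
  }
  reps <- vapply(groups, `[`, character(1), 1)
  out <- ape::keep.tip(tree, reps)
  tol <- 1e-9 * max(H, 1)
  for (g in multi) {
    tips <- groups[[g]]
    h <- crown[g]
    rep <- reps[g]
    repIdx <- match(rep, out$tip.label)
    pend <- out$edge.length[out$edge[, 2] == repIdx]
    others <- setdiff(tips, rep)
    if (pend - h > tol) {
      # split the representative's pendant edge at the crown height
      out <- bindTipOnEdge(out, others[1], repIdx, h, h)
    } else {
      # crown node survived pruning (non-exclusive rank above): attach there
      parent <- out$edge[out$edge[, 2] == repIdx, 1]
      out <- bindTipAtNode(out, others[1], parent, h)
    }
    for (sp in others[-1]) {
      repIdx <- match(rep, out$tip.label)
      parent <- out$edge[out$edge[, 2] == repIdx, 1]
      out <- bindTipAtNode(out, sp, parent, h)
    }
  }
  out
}

# Validate one side of a cross-group tip set against a tree.
checkTipSet <- function(tree, set, what) {
  assertThat(length(set) > 0, "%s set is empty", what)
  bad <- setdiff(set, tree$tip.label)
  assertThat(length(bad) == 0, "%s set contains non-tips: %s", what,
             paste(head(bad, 5), collapse = ", "))
}

#' Cross-group mean pairwise phylogenetic distance
#'
#' The average patristic distance between every alien-native species pair:
#' \deqn{MPD = \frac{1}{|A||B|} \sum_{a \in A}\sum_{b \in B} d(a, b).}
#' Computed in a single postorder pass by edge contribution: each edge
#' contributes its length times the number of alien-native pairs whose path
#' crosses it. Identical to the brute-force mean over the patristic matrix,
#' but linear in tree size.
#'
#' @param tree A \code{phylo} with branch lengths.
#' @param aliens,natives Disjoint, non-empty character vectors of tip names.
#' @return The MPD, in branch-length units.
#' @examples
#' tr <- parseNewick("((A:1,B:1):1,(C:1,D:1):1);")
#' crossgroupMPD(tr, "A", c("C", "D"))  # 4
#' @export
crossgroupMPD <- function(tree, aliens, natives) {
  checkTipSet(tree, aliens, "alien")
  checkTipSet(tree, natives, "native")
  assertThat(length(intersect(aliens, natives)) == 0,
             "alien and native sets overlap: %s",
             paste(head(intersect(aliens, natives), 5), collapse = ", "))
  po <- stats::reorder(tree, "postorder")
  ntip <- length(po$tip.label)
  nnode <- po$Nnode
  nA <- numeric(ntip + nnode); nB <- numeric(ntip + nnode)
  nA[match(aliens, po$tip.label)] <- 1
  nB[match(natives, po$tip.label)] <- 1
  NA_ <- length(aliens); NB_ <- length(natives)
  e1 <- po$edge[, 1]; e2 <- po$edge[, 2]; len <- po$edge.length
  total <- 0
  for (k in seq_along(len)) {
    a <- nA[e2[k]]; b <- nB[e2[k]]
    total <- total + len[k] * (a * (NB_ - b) + b * (NA_ - a))
    nA[e1[k]] <- nA[e1[k]] + a
    nB[e1[k]] <- nB[e1[k]] + b
  }
  total / (NA_ * NB_)
}

#' Summed patristic distance from every tip to a tip set
#'
#' Two-pass (postorder + preorder) algorithm returning, for every tip t of
#' the tree, \eqn{\sum_{b \in set} d(t, b)} in O(edges) time. This is the
#' engine behind the null-model randomizations: the cross-group MPD of any
#' alien draw A against a fixed native set B is \code{mean(S[A]) / |B|} by
#' linearity.
#'
#' @param tree A \code{phylo} with branch lengths.
#' @param set Character vector of tip names (the fixed group).
#' @return Named numeric vector over all tips; members of \code{set} include
#'   their zero self-distance.
#' @export
distancesToSet <- function(tree, set) {
  checkTipSet(tree, set, "target")
  po <- stats::reorder(tree, "postorder")
  ntip <- length(po$tip.label)
  nn <- ntip + po$Nnode
  cnt <- numeric(nn); down <- numeric(nn); up <- numeric(nn)
  cnt[match(set, po$tip.label)] <- 1
  K <- length(set)
  e1 <- po$edge[, 1]; e2 <- po$edge[, 2]; len <- po$edge.length
  for (k in seq_along(len)) {
    p <- e1[k]; ch <- e2[k]
    down[p] <- down[p] + down[ch] + cnt[ch] * len[k]
    cnt[p] <- cnt[p] + cnt[ch]
  }
  for (k in rev(seq_along(len))) {
    p <- e1[k]; ch <- e2[k]
    up[ch] <- up[p] + down[p] - down[ch] - cnt[ch] * len[k] +
      (K - cnt[ch]) * len[k]
  }
  out <- down[seq_len(ntip)] + up[seq_len(ntip)]
  names(out) <- po$tip.label
  out[tree$tip.label]
}

#' Cross-group mean nearest taxon distance
#'
#' Mean over the alien species of the patristic distance to the closest
#' native. Provided as a utility alongside \code{\link{crossgroupMPD}}; the
#' headline analyses use MPD because tip-level resolution of megaphylogenies
#' is poor.
#'
#' @inheritParams crossgroupMPD
#' @return The MNTD, in branch-length units.
#' @export
crossgroupMNTD <- function(tree, aliens, natives) {
  checkTipSet(tree, aliens, "alien")
  checkTipSet(tree, natives, "native")
  assertThat(length(intersect(aliens, natives)) == 0,
             "alien and native sets overlap")
  sub <- ape::keep.tip(tree, union(aliens, natives))
  D <- stats::cophenetic(sub)
  mean(apply(D[aliens, natives, drop = FALSE], 1, min))
}
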