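# Real-valued evolutionary trace. A column's importance combines its
# overall variability (Shannon entropy over amino-acid frequencies, gaps
# excluded) with WHERE in the phylogeny the variation falls: the tree is
# cut into n = 1 .. N-1 groups by removing internal nodes root-first in
# order of height, within-group entropies are averaged at each depth, and
# the depth-weighted sum (plus 1) is the rvET score. Lower = more
# evolutionarily important; an invariant column scores exactly 1.

#' Read a protein multiple sequence alignment from FASTA
#'
#' @param path FASTA file with aligned sequences (gap character `-`).
#' @return Character matrix, rows = sequences (rownames = ids), columns =
#'   alignment positions, uppercase.
#' @export
read_alignment <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = FALSE,
                             set.attributes = FALSE)
  lens <- lengths(seqs)
  if (length(unique(lens)) != 1) {
    stop("sequences have unequal aligned lengths", call. = FALSE)
  }
  m <- do.call(rbind, lapply(seqs, toupper))
  rownames(m) <- names(seqs)
  m
}

.as_aln_matrix <- function(aln) {
  if (is.matrix(aln)) return(aln)
  if (is.list(aln) || is.character(aln)) {
    m <- do.call(rbind, strsplit(toupper(unlist(aln)), ""))
    rownames(m) <- names(aln)
    return(m)
  }
  stop("alignment must be a character matrix or named character vector",
       call. = FALSE)
}

#' Shannon entropy of one alignment column
#'
#' Entropy in nats over the 20 amino-acid frequencies; gaps (and any
#' non-standard letters) are excluded from the counts. An all-gap column
#' has no defined frequency distribution and returns `NA`.
#'
#' @param aln Alignment matrix (see [read_alignment()]) or named character
#'   vector of aligned sequences.
#' @param i Column index (1-based).
#' @return Entropy s_i in nats, in `[0, log(20)]`, or `NA`.
#' @export
position_entropy <- function(aln, i) {
  m <- .as_aln_matrix(aln)
  stopifnot(i >= 1, i <= ncol(m))
  .column_entropy(m[, i])
}

.column_entropy <- function(col) {
  col <- col[col %in% .aa1]
  if (length(col) == 0) return(NA_real_)
  f <- table(col) / length(col)
  -sum(f * log(f))
}

# successive partitions of the leaves of a rooted tree: ordering internal
# nodes by height above the root (root first; ties by node number) and
# activating them one at a time splits the leaf set into successively
# finer groups. Returns a list: element k = list(n_groups, membership)
# after activating the first k-1 internal nodes (k = 1 is the root-only,
# single-group partition). Partitions with n_groups >= N(leaves) are
# dropped (the sum in the score runs to N-1 groups).
.tree_partitions <- function(tree) {
  nt <- ape::Ntip(tree)
  root <- nt + 1L
  depths <- ape::node.depth.edgelength(tree)
  internals <- seq.int(nt + 1L, nt + tree$Nnode)
  internals <- internals[order(depths[internals], internals)]
  parent_of <- integer(nt + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  anc_path <- function(tip) {
    p <- tip
    path <- integer(0)
    while (p != root) {
      p <- parent_of[p]
      path <- c(path, p)
    }
    path   # ancestors from nearest to root
  }
  paths <- lapply(seq_len(nt), anc_path)
  out <- list()
  for (k in seq_along(internals)) {
    active <- internals[seq_len(k - 1L)]
    # a tip's group is its nearest ancestor whose own ancestors are all
    # active but which is not itself "split"; equivalently the child-side
    # subtree root under the deepest active ancestor
    membership <- vapply(seq_len(nt), function(tip) {
      path <- paths[[tip]]           # nearest ancestor ... root
      grp <- tip
      for (a in path) {
        if (a %in% active) break
        grp <- a
      }
      grp
    }, 0L)
    ng <- length(unique(membership))
    if (ng >= nt) break
    out[[length(out) + 1L]] <- list(n_groups = ng,
                                    membership = membership)
  }
  # deduplicate partitions that did not refine (can happen with ties)
  keep <- !duplicated(vapply(out, function(p)
    paste(p$membership, collapse = ","), ""))
  out[keep]
}

#' Real-valued evolutionary-trace scores
#'
#' For every alignment column: at each tree partition into n groups
#' (n = 1 .. N-1, obtained by activating internal nodes root-first by
#' height), the within-group column entropies (gaps excluded; an all-gap
#' group contributes 0) are combined as
#' `sum_n w_node(n) * sum_g w_group(n) * s_ig`, and the score is 1 plus
#' that sum. Default weights `w_node = w_group = 1/n` average the group
#' entropies at each depth and down-weight deep partitions; both are
#' pluggable.
#'
#' @param aln Alignment matrix or named character vector.
#' @param tree A rooted `phylo` tree whose tip labels equal the alignment
#'   ids (a mismatch errors, listing the orphans). When `NULL`, a
#'   neighbor-joining tree from p-distances is built with [nj_tree()] as a
#'   convenience.
#' @param w_node,w_group Functions of the group count n giving the node
#'   and group weights (defaults `1/n`).
#' @return Data frame of class `rvet_profile`: `column`, `entropy` (nats),
#'   `rvET` (>= 1; exactly 1 for an invariant gap-free column), `rank`
#'   (1 = most important; ties broken by column index).
#' @export
rvet_scores <- function(aln, tree = NULL,
                        w_node = function(n) 1 / n,
                        w_group = function(n) 1 / n) {
  m <- .as_aln_matrix(aln)
  if (nrow(m) < 2) stop("need at least 2 sequences", call. = FALSE)
  if (is.null(tree)) tree <- nj_tree(m)
  orphans <- c(setdiff(tree$tip.label, rownames(m)),
               setdiff(rownames(m), tree$tip.label))
  if (length(orphans) > 0) {
    stop("tree/alignment mismatch; orphan ids: ",
         paste(unique(orphans), collapse = ", "), call. = FALSE)
  }
  m <- m[tree$tip.label, , drop = FALSE]   # rows in tip order
  parts <- .tree_partitions(tree)
  nc <- ncol(m)
  scores <- numeric(nc)
  entropy <- vapply(seq_len(nc), function(i) .column_entropy(m[, i]), 0)
  for (p in parts) {
    n <- p$n_groups
    idx_by_group <- split(seq_len(nrow(m)), p$membership)
    wn <- w_node(n)
    wg <- w_group(n)
    for (i in seq_len(nc)) {
      s_g <- vapply(idx_by_group, function(idx) {
        s <- .column_entropy(m[idx, i])
        if (is.na(s)) 0 else s   # all-gap group contributes 0
      }, 0)
      scores[i] <- scores[i] + wn * wg * sum(s_g)
    }
  }
  rvet <- 1 + scores
  ord <- order(rvet, seq_len(nc))
  rank <- integer(nc)
  rank[ord] <- seq_len(nc)
  out <- data.frame(column = seq_len(nc), entropy = entropy, rvET = rvet,
                    rank = rank)
  class(out) <- c("rvet_profile", class(out))
  out
}

#' Neighbor-joining tree from alignment p-distances
#'
#' Convenience constructor for when no tree is supplied: pairwise
#' p-distances (fraction of differing non-gap positions) -> NJ -> midpoint
#' rooting. Not a substitute for a curated phylogeny.
#'
#' @param aln Alignment matrix or named character vector.
#' @return A rooted `phylo` object.
#' @export
nj_tree <- function(aln) {
  m <- .as_aln_matrix(aln)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      ok <- m[i, ] %in% .aa1 & m[j, ] %in% .aa1
      d[i, j] <- d[j, i] <- if (any(ok)) mean(m[i, ok] != m[j, ok]) else 0
    }
  }
  tr <- ape::nj(stats::as.dist(d))
  tr <- phangorn::midpoint(tr)
  # NJ can produce tiny negative branch lengths; clamp for height ordering
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Top-ranked fraction of alignment positions
#'
#' @param profile An `rvet_profile`.
#' @param fraction Fraction in (0, 1]; `floor(fraction * ncols)` positions
#'   with the lowest (best) rvET scores are returned, ties broken by lower
#'   column index.
#' @return Integer vector of column indices, best first.
#' @export
rank_top_fraction <- function(profile, fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]", call. = FALSE)
  }
  if (nrow(profile) == 0) stop("empty profile", call. = FALSE)
  k <- floor(fraction * nrow(profile))
  ord <- order(profile$rvET, profile$column)
  profile$column[ord][seq_len(k)]
}

#' Branch-point substitutions of one alignment column
#'
#' Infers ancestral states by Fitch small parsimony with deterministic tie
#' resolution: an ambiguous node takes its parent's assigned state when
#' that state is in the node's set, otherwise the set member supported by
#' the most child subtrees, with remaining ties broken alphabetically.
#' Every tree edge across which the inferred state changes is returned.
#' Gaps are treated as a 21st state.
#'
#' @param aln Alignment matrix or named character vector.
#' @param tree Rooted `phylo` tree, tips matching the alignment ids.
#' @param column Column index.
#' @return Data frame: `parent_node`, `child_node`, `parent_state`,
#'   `child_state`, `child_is_tip`, `child_label` (tip label or "").
#'   Empty for an invariant column.
#' @export
branch_substitutions <- function(aln, tree, column) {
  m <- .as_aln_matrix(aln)
  stopifnot(column >= 1, column <= ncol(m))
  orphans <- c(setdiff(tree$tip.label, rownames(m)),
               setdiff(rownames(m), tree$tip.label))
  if (length(orphans) > 0) {
    stop("tree/alignment mismatch; orphan ids: ",
         paste(unique(orphans), collapse = ", "), call. = FALSE)
  }
  nt <- ape::Ntip(tree)
  nn <- nt + tree$Nnode
  root <- nt + 1L
  states <- m[tree$tip.label, column]
  # children lists
  kids <- vector("list", nn)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; c_ <- tree$edge[e, 2]
    kids[[p]] <- c(kids[[p]], c_)
  }
  # Fitch downpass (post-order over internal nodes)
  sets <- vector("list", nn)
  for (tip in seq_len(nt)) sets[[tip]] <- states[tip]
  postorder <- rev(unique(tree$edge[order(tree$edge[, 1]), 1]))
  # ensure children before parents: process internal nodes by decreasing
  # height, which in ape's numbering needs an explicit traversal
  depth_order <- order(ape::node.depth.edgelength(tree)[seq.int(nt + 1L, nn)],
                       decreasing = TRUE)
  postorder <- (seq.int(nt + 1L, nn))[depth_order]
  for (v in postorder) {
    child_sets <- lapply(kids[[v]], function(k) sets[[k]])
    inter <- Reduce(intersect, child_sets)
    sets[[v]] <- if (length(inter) > 0) inter else
      sort(unique(unlist(child_sets)))
  }
  # uppass assignment with deterministic ties: prefer the parent's state,
  # then the set member supported by most child subtrees, then alphabet
  pick <- function(v, parent_state = NULL) {
    s <- sort(sets[[v]])
    if (!is.null(parent_state) && parent_state %in% s) return(parent_state)
    if (length(s) == 1 || is.null(kids[[v]])) return(s[1])
    support <- vapply(s, function(st)
      sum(vapply(kids[[v]], function(k) st %in% sets[[k]], TRUE)), 0L)
    s[which.max(support)]   # which.max takes the first (alphabetical) tie
  }
  assign_state <- character(nn)
  preorder <- rev(postorder)
  assign_state[root] <- pick(root)
  for (v in preorder) {
    if (v != root) {
      p <- .parent_of(tree, v)
      assign_state[v] <- pick(v, assign_state[p])
    }
    for (k in kids[[v]]) {
      if (k <= nt) {
        assign_state[k] <- sets[[k]]
      }
    }
  }
  rows <- list()
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; c_ <- tree$edge[e, 2]
    if (c_ > nt && assign_state[c_] == "") {
      # child internal node not yet assigned (multifurcation orderings)
      assign_state[c_] <- pick(c_, assign_state[p])
    }
    if (assign_state[p] != assign_state[c_]) {
      rows[[length(rows) + 1L]] <- data.frame(
        parent_node = p, child_node = c_,
        parent_state = assign_state[p], child_state = assign_state[c_],
        child_is_tip = c_ <= nt,
        child_label = if (c_ <= nt) tree$tip.label[c_] else "",
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(parent_node = integer(), child_node = integer(),
               parent_state = character(), child_state = character(),
               child_is_tip = logical(), child_label = character())
}

.parent_of <- function(tree, v) {
  tree$edge[tree$edge[, 2] == v, 1]
}
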