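#' Newick parsing and writing
#'
#' Thin wrappers over \pkg{ape} with enough digits for lossless round trips.
#'
#' @param text Newick string.
#' @return \code{parse_newick}: an \code{ape::phylo}; \code{write_newick}: a
#'   newick string.
#' @export
parse_newick <- function(text) {
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("malformed newick: ", conditionMessage(e)))
  if (is.null(tr)) stop("malformed newick string")
  tr
}

#' @rdname parse_newick
#' @param tree \code{ape::phylo}.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree, digits = 15)
}

# Stable display name per node: node label when present, else "N<id>".
node_name <- function(tree, nodes = seq_len(ape::Ntip(tree) + tree$Nnode)) {
  ntip <- ape::Ntip(tree)
  nm <- character(length(nodes))
  for (i in seq_along(nodes)) {
    v <- nodes[i]
    if (v <= ntip) {
      nm[i] <- tree$tip.label[v]
    } else if (!is.null(tree$node.label) &&
               nzchar(tree$node.label[v - ntip])) {
      nm[i] <- tree$node.label[v - ntip]
    } else {
      nm[i] <- paste0("N", v)
    }
  }
  nm
}

# Sorted tip labels below each internal node, collapsed with "|": a rooting-
# independent key used to match nodes across re-rooted copies of a tree.
clade_signature <- function(tree) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  sig <- character(nn)
  sig[seq_len(ntip)] <- tree$tip.label
  for (v in (ntip + 1L):nn) {
    tips <- ape::extract.clade(tree, v)$tip.label
    sig[v] <- paste(sort(tips, method = "radix"), collapse = "|")
  }
  sig
}

# Adjacency list of an (un)rooted phylo: for node v, matrix of (neighbor,
# length) pairs. Used by the re-rooting machinery.
tree_adjacency <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  adj <- vector("list", n)
  for (k in seq_len(nrow(tree$edge))) {
    a <- tree$edge[k, 1L]; b <- tree$edge[k, 2L]; len <- tree$edge.length[k]
    adj[[a]] <- rbind(adj[[a]], c(b, len))
    adj[[b]] <- rbind(adj[[b]], c(a, len))
  }
  adj
}

# Root an unrooted tree at a point along edge `edge_row` (row index into
# tree$edge), at distance `pos` from the edge's first endpoint. Rebuilds the
# topology by traversal and re-reads it, preserving all tip-to-tip distances
# and internal labels.
root_at_edge <- function(tree, edge_row, pos) {
  stopifnot(edge_row >= 1, edge_row <= nrow(tree$edge))
  a <- tree$edge[edge_row, 1L]; b <- tree$edge[edge_row, 2L]
  len <- tree$edge.length[edge_row]
  stopifnot(pos >= -1e-12, pos <= len + 1e-12)
  pos <- min(max(pos, 0), len)
  adj <- tree_adjacency(tree)
  ntip <- ape::Ntip(tree)
  lab <- function(v) {
    if (v <= ntip) tree$tip.label[v]
    else if (!is.null(tree$node.label)) tree$node.label[v - ntip] else ""
  }
  fmt <- function(x) sprintf("%.15g", x)
  sub_nwk <- function(v, parent, blen) {
    nbrs <- adj[[v]]
    kids <- nbrs[nbrs[, 1L] != parent, , drop = FALSE]
    if (nrow(kids) == 0L) {
      paste0(lab(v), ":", fmt(blen))
    } else {
      inner <- vapply(seq_len(nrow(kids)), function(i)
        sub_nwk(kids[i, 1L], v, kids[i, 2L]), character(1))
      paste0("(", paste(inner, collapse = ","), ")", lab(v), ":", fmt(blen))
    }
  }
  nwk <- paste0("(", sub_nwk(a, b, pos), ",", sub_nwk(b, a, len - pos), ");")
  parse_newick(nwk)
}

#' Root a tree by minimal ancestral deviation (MAD)
#'
#' For each candidate root position rho on each branch, every tip pair (b, c)
#' contributes a relative deviation |2 d(a, b)/d(b, c) - 1| where a is the
#' pair's ancestor induced by the root position; the position's score is the
#' root mean square of all pair deviations. Pairs straddling the candidate
#' branch depend on rho (their induced ancestor is the root point itself) and
#' the per-branch minimum is found in closed form (the score is quadratic in
#' rho); same-side pairs contribute a rho-free term. The global root is the
#' branch/position with the minimal score, ties broken by smallest (branch
#' index, rho).
#'
#' @param tree \code{ape::phylo}, rooted or unrooted; >= 3 tips. A rooted
#'   input is unrooted first (the score is a function of the unrooted metric).
#' @return List with \code{tree} (the rooted tree), \code{edge} (endpoint node
#'   pair of the chosen branch in the unrooted tree), \code{rho} (relative
#'   position from the first endpoint), \code{mad_score}, and
#'   \code{branch_scores} (data.frame u, v, rho, score: the per-branch
#'   minima, in the unrooted tree's edge order).
#' @export
mad_root <- function(tree) {
  un <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  ntip <- ape::Ntip(un)
  if (ntip < 3L) stop("mad_root needs >= 3 tips")
  D <- ape::dist.nodes(un)
  tipD <- D[seq_len(ntip), seq_len(ntip)]
  if (any(tipD[upper.tri(tipD)] <= 0)) {
    stop("mad_root: zero tip-to-tip path length (zero-length pendant branches)")
  }
  npairs <- choose(ntip, 2L)
  adj <- tree_adjacency(un)
  # tips on the `v` side when edge (u,v) is removed
  side_tips <- function(v, u) {
    seen <- logical(ape::Ntip(un) + un$Nnode)
    stack <- v; seen[u] <- TRUE; out <- integer(0)
    while (length(stack)) {
      x <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (seen[x]) next
      seen[x] <- TRUE
      if (x <= ntip) out <- c(out, x)
      nb <- adj[[x]][, 1L]
      stack <- c(stack, nb[!seen[nb]])
    }
    out
  }
  same_side_ss <- function(tips, anchor) {
    # sum of r^2 over pairs within `tips`, ancestors taken toward `anchor`
    if (length(tips) < 2L) return(0)
    da <- D[anchor, tips]
    num <- outer(da, da, "-")
    den <- tipD[tips, tips]
    r2 <- (num / den)^2
    sum(r2[upper.tri(r2)])
  }
  best <- NULL
  branch_scores <- data.frame(u = un$edge[, 1L], v = un$edge[, 2L],
                              rho = NA_real_, score = NA_real_)
  for (k in seq_len(nrow(un$edge))) {
    u <- un$edge[k, 1L]; v <- un$edge[k, 2L]; len <- un$edge.length[k]
    tv <- side_tips(v, u)
    tu <- setdiff(seq_len(ntip), tv)
    dub <- D[u, tu]                       # u-side tip distances to u
    dvc <- D[v, tv]
    dbc <- outer(dub, rep(1, length(tv))) + len +
      outer(rep(1, length(tu)), dvc)      # straddling pair path lengths
    A <- 2 * len / dbc
    B <- 2 * outer(dub, rep(1, length(tv))) / dbc - 1
    sA2 <- sum(A * A)
    rho <- if (len > 0 && sA2 > 0) min(max(-sum(A * B) / sA2, 0), 1) else 0
    ss <- sum((A * rho + B)^2) + same_side_ss(tu, u) + same_side_ss(tv, v)
    score <- sqrt(ss / npairs)
    branch_scores$rho[k] <- rho
    branch_scores$score[k] <- score
    if (is.null(best) || score < best$score - 1e-15) {
      best <- list(score = score, k = k, rho = rho, u = u, v = v, len = len)
    }
  }
  rooted <- root_at_edge(un, best$k, best$rho * best$len)
  list(tree = rooted, edge = c(best$u, best$v), rho = best$rho,
       mad_score = best$score, branch_scores = branch_scores)
}

#' Root a tree on a specified outgroup
#'
#' The outgroup tips must form one side of a branch of the unrooted tree; the
#' root is placed at the midpoint of that branch.
#'
#' @param tree \code{ape::phylo}.
#' @param outgroup_tips Character vector of tip labels.
#' @return Rooted \code{ape::phylo}.
#' @export
root_on_outgroup <- function(tree, outgroup_tips) {
  un <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  ntip <- ape::Ntip(un)
  unknown <- setdiff(outgroup_tips, un$tip.label)
  if (length(unknown)) {
    stop("unknown outgroup tips: ", paste(unknown, collapse = ", "))
  }
  og <- sort(match(outgroup_tips, un$tip.label))
  if (length(og) == 0L || length(og) == ntip) {
    stop("outgroup must be a proper nonempty subset of the tips")
  }
  adj <- tree_adjacency(un)
  for (k in seq_len(nrow(un$edge))) {
    u <- un$edge[k, 1L]; v <- un$edge[k, 2L]
    seen <- logical(ntip + un$Nnode); seen[u] <- TRUE
    stack <- v; tips_v <- integer(0)
    while (length(stack)) {
      x <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (seen[x]) next
      seen[x] <- TRUE
      if (x <= ntip) tips_v <- c(tips_v, x)
      nb <- adj[[x]][, 1L]
      stack <- c(stack, nb[!seen[nb]])
    }
    tips_v <- sort(tips_v)
    if (identical(tips_v, og) ||
        identical(sort(setdiff(seq_len(ntip), tips_v)), og)) {
      return(root_at_edge(un, k, un$edge.length[k] / 2))
    }
  }
  stop(sprintf(
    "outgroup {%s} does not form one side of any branch (not an unrooted split)",
    paste(outgroup_tips, collapse = ",")))
}

#' Resolve named ancestors on a rooted tree
#'
#' Each named clade definition (a set of tip labels) is resolved to the most
#' recent common ancestor of those tips, with a flag stating whether the
#' MRCA's full clade equals the given set (monophyly).
#'
#' @param tree Rooted \code{ape::phylo}.
#' @param clade_defs Named list: ancestor name -> character vector of tips.
#' @return data.frame: name, node (ape node id), node_name, monophyletic.
#' @export
resolve_ancestors <- function(tree, clade_defs) {
  stopifnot(ape::is.rooted(tree), length(clade_defs) > 0)
  ntip <- ape::Ntip(tree)
  rows <- lapply(names(clade_defs), function(nm) {
    tips <- clade_defs[[nm]]
    unknown <- setdiff(tips, tree$tip.label)
    if (length(unknown)) {
      stop(sprintf("ancestor '%s': unknown tips %s", nm,
                   paste(unknown, collapse = ", ")))
    }
    if (length(tips) == 1L) {
      v <- match(tips, tree$tip.label)
      mono <- TRUE
    } else {
      v <- ape::getMRCA(tree, tips)
      clade <- ape::extract.clade(tree, v)$tip.label
      mono <- setequal(clade, tips)
    }
    data.frame(name = nm, node = v, node_name = node_name(tree, v),
               monophyletic = mono, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Resolve polytomies into zero-length dichotomies, deterministically given the
# input representation; warns when anything was changed.
ensure_binary <- function(tree) {
  if (ape::is.binary(tree)) return(tree)
  warning("tree contains polytomies; resolving deterministically with zero-length branches")
  tr <- ape::multi2di(tree, random = FALSE)
  tr$edge.length[is.na(tr$edge.length)] <- 0
  tr
}
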