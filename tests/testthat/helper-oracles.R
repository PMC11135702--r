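# Independent oracles used across the suite. They deliberately avoid the
# package's pruning / closed-form code paths.

# ER transition probability, written out independently of er_pstay
oracle_ptrans <- function(from, to, q, t) {
  if (from == to) (1 + exp(-2 * q * t)) / 2 else (1 - exp(-2 * q * t)) / 2
}

# Brute-force enumeration over all joint internal-state assignments:
# likelihood and marginal posteriors for a binary character under ER Mk with
# prior (1/2, 1/2).
oracle_enum_er <- function(tree, states, q) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  internal <- (ntip + 1L):nn
  m <- length(internal)
  full <- integer(nn)
  full[seq_len(ntip)] <- states[tree$tip.label]
  lik <- 0
  marg <- numeric(nn)
  for (code in 0:(2^m - 1)) {
    assign <- as.integer(intToBits(code))[seq_len(m)]
    full[internal] <- assign
    p <- 0.5  # root prior
    for (k in seq_len(nrow(tree$edge))) {
      p <- p * oracle_ptrans(full[tree$edge[k, 1L]], full[tree$edge[k, 2L]],
                             q, tree$edge.length[k])
    }
    lik <- lik + p
    marg <- marg + p * full
  }
  list(lik = lik, loglik = log(lik), post = marg / lik)
}

# Dense-grid MAD scan: for a candidate root at relative position rho on each
# branch, score = RMS over all tip pairs of |2 d(a,b)/d(b,c) - 1| with a the
# point of path(b,c) closest to the root. Direct evaluation, no closed form.
oracle_mad_grid <- function(tree, npos = 1e4) {
  un <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  ntip <- ape::Ntip(un)
  D <- ape::dist.nodes(un)
  pairs <- t(utils::combn(ntip, 2L))
  # tips on the v side of each edge
  adj <- orgatlas:::tree_adjacency(un)
  side <- function(v, u) {
    seen <- logical(nrow(D)); seen[u] <- TRUE; stack <- v; out <- integer(0)
    while (length(stack)) {
      x <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (seen[x]) next
      seen[x] <- TRUE
      if (x <= ntip) out <- c(out, x)
      nb <- adj[[x]][, 1L]; stack <- c(stack, nb[!seen[nb]])
    }
    out
  }
  rho <- seq(0, 1, length.out = npos)
  out <- data.frame(u = un$edge[, 1L], v = un$edge[, 2L],
                    rho = NA_real_, score = NA_real_)
  for (k in seq_len(nrow(un$edge))) {
    u <- un$edge[k, 1L]; v <- un$edge[k, 2L]; len <- un$edge.length[k]
    on_v <- seq_len(ntip) %in% side(v, u)
    # distance from the candidate root to each tip, per grid position
    dxb <- outer(ifelse(on_v, D[v, seq_len(ntip)], D[u, seq_len(ntip)]),
                 rep(1, npos))
    add <- outer(on_v, rho, function(s, r) ifelse(s, (1 - r) * len, r * len))
    dxb <- dxb + add
    ss <- numeric(npos)
    for (pi in seq_len(nrow(pairs))) {
      b <- pairs[pi, 1L]; c_ <- pairs[pi, 2L]
      dbc <- D[b, c_]
      dab <- pmax((dbc + dxb[b, ] - dxb[c_, ]) / 2, 0)
      dab <- pmin(dab, dbc)
      ss <- ss + (2 * dab / dbc - 1)^2
    }
    sc <- sqrt(ss / nrow(pairs))
    i <- which.min(sc)
    out$rho[k] <- rho[i]
    out$score[k] <- sc[i]
  }
  out
}

# Random binary rooted tree with uniform branch lengths (oracle fuzz cases)
random_tree <- function(ntip, min_len = 0.05, max_len = 2) {
  tr <- ape::rtree(ntip, rooted = TRUE)
  tr$edge.length <- stats::runif(nrow(tr$edge), min_len, max_len)
  tr
}

random_states <- function(tree) {
  repeat {
    st <- stats::setNames(sample(0:1, ape::Ntip(tree), replace = TRUE),
                          tree$tip.label)
    if (length(unique(st)) > 1L) return(st)
  }
}
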