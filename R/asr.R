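# Equal-rates binary Mk transition probabilities over a branch of length t:
# P(stay) = (1 + exp(-2qt))/2, P(flip) = (1 - exp(-2qt))/2.
er_pstay <- function(q, t) 0.5 * (1 + exp(-2 * q * t))

# Down-pass (pruning) partial likelihoods with per-node rescaling.
# Returns list(D = n x 2 matrix of scaled partials [P(data below v | state)],
# logscale = per-node accumulated log scale, order = postorder internal nodes).
er_downpass <- function(tree, states, q) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  tr <- ape::reorder.phylo(tree, "postorder")
  D <- matrix(0, nn, 2L)
  logscale <- numeric(nn)
  D[cbind(seq_len(ntip), states[tree$tip.label] + 1L)] <- 1
  # M[k, ] = message of edge k to its parent: M[s_parent] = sum_s P(s_p,s) D[child, s]
  M <- matrix(0, nrow(tr$edge), 2L)
  parents <- tr$edge[, 1L]
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1L]; ch <- tr$edge[k, 2L]; t <- tr$edge.length[k]
    ps <- er_pstay(q, t); pf <- 1 - ps
    M[k, ] <- c(ps * D[ch, 1L] + pf * D[ch, 2L],
                pf * D[ch, 1L] + ps * D[ch, 2L])
    if (D[p, 1L] == 0 && D[p, 2L] == 0) D[p, ] <- 1  # first child seen
    D[p, ] <- D[p, ] * M[k, ]
    logscale[p] <- logscale[p] + logscale[ch]
    # rescale once all children of p are absorbed (safe to do every time)
    s <- sum(D[p, ])
    if (s > 0 && (s < 1e-100 || s > 1e100)) {
      D[p, ] <- D[p, ] / s
      logscale[p] <- logscale[p] + log(s)
    }
  }
  root <- setdiff(tr$edge[, 1L], tr$edge[, 2L])[1L]
  list(D = D, logscale = logscale, M = M, tr = tr, root = root,
       parents = parents)
}

#' Log-likelihood of a binary presence/absence character under the ER Mk model
#'
#' Felsenstein pruning with a stationary root prior of (1/2, 1/2) and one
#' gain/loss rate \code{q} per unit branch length.
#'
#' @param tree Rooted \code{ape::phylo} with branch lengths.
#' @param states Named integer vector (0 = absent, 1 = present) covering every
#'   tip label.
#' @param q Positive rate.
#' @return Log-likelihood (finite scalar).
#' @export
er_loglik <- function(tree, states, q) {
  if (q <= 0) stop("rate q must be > 0")
  missing <- setdiff(tree$tip.label, names(states))
  if (length(missing)) stop("states missing for tips: ",
                            paste(missing, collapse = ", "))
  dp <- er_downpass(tree, states, q)
  log(sum(0.5 * dp$D[dp$root, ])) + dp$logscale[dp$root]
}

#' Maximum-likelihood ER rate for one character
#'
#' One-dimensional optimization of \code{\link{er_loglik}} over log-rate
#' within \code{bounds}. Constant characters have a degenerate ML rate
#' (q -> 0) and are rejected; callers handle them explicitly.
#'
#' @inheritParams er_loglik
#' @param bounds Positive search interval \code{c(q_min, q_max)}.
#' @return List with \code{q} (the ML rate) and \code{loglik}.
#' @export
er_fit_rate <- function(tree, states, bounds = c(1e-6, 100)) {
  st <- states[tree$tip.label]
  if (length(unique(st)) < 2L) {
    stop("constant character: ML rate is degenerate (q -> 0)")
  }
  f <- function(lq) -er_loglik(tree, states, exp(lq))
  opt <- stats::optimize(f, interval = log(bounds), tol = 1e-9)
  list(q = exp(opt$minimum), loglik = -opt$objective)
}

#' Marginal posterior probability of presence at every node
#'
#' Combines the pruning (down-pass) partials with an outside (up-pass)
#' recursion; the result at each node equals what re-rooting the tree at that
#' node and normalizing prior times conditional likelihood would give. Tip
#' posteriors equal the observed states.
#'
#' @inheritParams er_loglik
#' @return Numeric vector of P(present), one per node (tips first, ape node
#'   numbering), named via node labels / \code{N<id>}.
#' @export
er_marginal_posteriors <- function(tree, states, q) {
  if (q <= 0) stop("rate q must be > 0")
  dp <- er_downpass(tree, states, q)
  tr <- dp$tr
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  U <- matrix(0, nn, 2L)
  U[dp$root, ] <- c(0.5, 0.5)
  # preorder = reverse postorder edge sweep
  for (k in rev(seq_len(nrow(tr$edge)))) {
    p <- tr$edge[k, 1L]; ch <- tr$edge[k, 2L]; t <- tr$edge.length[k]
    ps <- er_pstay(q, t); pf <- 1 - ps
    # outside message at p excluding child ch: U[p,] * prod of sibling messages
    sib <- which(tr$edge[, 1L] == p & tr$edge[, 2L] != ch)
    out_p <- U[p, ]
    for (s in sib) out_p <- out_p * dp$M[s, ]
    U[ch, ] <- c(ps * out_p[1L] + pf * out_p[2L],
                 pf * out_p[1L] + ps * out_p[2L])
    s <- sum(U[ch, ])
    if (s > 0) U[ch, ] <- U[ch, ] / s
  }
  post <- dp$D * U
  norm <- rowSums(post)
  p1 <- post[, 2L] / norm
  names(p1) <- node_name(tree)
  p1
}

#' Ancestral state reconstruction for every orthogroup in a presence matrix
#'
#' Fits a per-orthogroup ML rate (or one shared rate) and computes marginal
#' posteriors of presence at every internal node. Constant characters are
#' handled by convention: posteriors equal the observed constant state, the
#' rate is recorded as 0 with a degeneracy flag. Matrix species missing from
#' the tree are dropped with a warning; tree tips missing from the matrix are
#' scored absent.
#'
#' @param presence Binary matrix og x species.
#' @param tree Rooted binary \code{ape::phylo}.
#' @param params \code{\link{atlas_params}} (rate bounds).
#' @param rate_mode \code{"per_og"} (default) or \code{"global"} (one rate
#'   maximizing the summed log-likelihood of non-constant characters).
#' @return Object of class \code{ancestral_state_table}: list with
#'   \code{posteriors} (og x internal-node matrix of P(present)),
#'   \code{rates} (data.frame og_id, q_hat, loglik, degenerate),
#'   \code{tree}, \code{tip_posteriors}, \code{rate_mode}, \code{prior}.
#' @export
asr_all <- function(presence, tree, params = atlas_params(),
                    rate_mode = c("per_og", "global")) {
  rate_mode <- match.arg(rate_mode)
  tree <- ensure_binary(tree)
  extra <- setdiff(colnames(presence), tree$tip.label)
  if (length(extra)) {
    warning("species in matrix but not in tree, dropped: ",
            paste(extra, collapse = ", "))
    presence <- presence[, setdiff(colnames(presence), extra), drop = FALSE]
  }
  tips <- tree$tip.label
  ntip <- ape::Ntip(tree)
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  inames <- node_name(tree, internal)
  ogs <- rownames(presence)
  post <- matrix(NA_real_, length(ogs), length(internal),
                 dimnames = list(ogs, inames))
  tpost <- matrix(NA_real_, length(ogs), ntip, dimnames = list(ogs, tips))
  qhat <- numeric(length(ogs)); ll <- numeric(length(ogs))
  degen <- logical(length(ogs))
  state_of <- function(og) {
    st <- stats::setNames(integer(ntip), tips)
    have <- intersect(tips, colnames(presence))
    st[have] <- as.integer(presence[og, have] > 0)
    st
  }
  qglobal <- NA_real_
  if (rate_mode == "global") {
    nonconst <- ogs[vapply(ogs, function(og) {
      st <- state_of(og); length(unique(st)) > 1L
    }, logical(1))]
    if (length(nonconst)) {
      f <- function(lq) -sum(vapply(nonconst, function(og)
        er_loglik(tree, state_of(og), exp(lq)), numeric(1)))
      qglobal <- exp(stats::optimize(
        f, interval = log(params$rate_bounds), tol = 1e-9)$minimum)
    }
  }
  for (i in seq_along(ogs)) {
    st <- state_of(ogs[i])
    if (length(unique(st)) < 2L) {
      const <- st[[1L]]
      post[i, ] <- const
      tpost[i, ] <- st
      qhat[i] <- 0; ll[i] <- 0; degen[i] <- TRUE
      next
    }
    q <- if (rate_mode == "global") qglobal else
      er_fit_rate(tree, st, params$rate_bounds)$q
    p1 <- er_marginal_posteriors(tree, st, q)
    post[i, ] <- p1[internal]
    tpost[i, ] <- p1[seq_len(ntip)]
    qhat[i] <- q
    ll[i] <- er_loglik(tree, st, q)
  }
  structure(list(
    posteriors = post,
    tip_posteriors = tpost,
    rates = data.frame(og_id = ogs, q_hat = qhat, loglik = ll,
                       degenerate = degen, stringsAsFactors = FALSE),
    tree = tree, rate_mode = rate_mode, prior = c(0.5, 0.5)),
    class = "ancestral_state_table")
}

#' Call orthogroup gains at named ancestors
#'
#' An orthogroup is newly recruited at ancestor A when its posterior of
#' presence at A is strictly greater than \code{tau} and it is absent in the
#' preceding ancestor (A's parent). "Absent" defaults to confident absence,
#' parent posterior < 1 - tau; the lax reading (parent posterior < tau) is
#' selectable. The root has no preceding ancestor: orthogroups confidently
#' present there are reported separately as present-at-root, never as gains.
#'
#' @param ast \code{\link{asr_all}} result.
#' @param ancestors data.frame from \code{\link{resolve_ancestors}} (columns
#'   name, node) or a named integer vector of ape node ids.
#' @param tau Posterior threshold (strict).
#' @param parent_rule \code{"confident"} or \code{"lax"}.
#' @param root_rule \code{"error"} (default: a root ancestor is refused) or
#'   \code{"present_at_root"}.
#' @return Object of class \code{gain_event_table}: list with \code{gains}
#'   (named list ancestor -> sorted og ids), \code{present_at_root},
#'   \code{tau}, \code{parent_rule}.
#' @export
call_gains <- function(ast, ancestors, tau = 0.75,
                       parent_rule = c("confident", "lax"),
                       root_rule = c("error", "present_at_root")) {
  parent_rule <- match.arg(parent_rule)
  root_rule <- match.arg(root_rule)
  stopifnot(tau > 0, tau < 1)
  tree <- ast$tree
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  if (is.data.frame(ancestors)) {
    nodes <- stats::setNames(ancestors$node, ancestors$name)
  } else {
    nodes <- ancestors
  }
  all_names <- node_name(tree)
  gains <- list()
  present_at_root <- NULL
  for (nm in names(nodes)) {
    v <- nodes[[nm]]
    if (v == root) {
      if (root_rule == "error") {
        stop(sprintf("ancestor '%s' is the root: no preceding ancestor; %s",
                     nm, "use root_rule = 'present_at_root'"))
      }
      pv <- ast$posteriors[, all_names[v]]
      present_at_root <- sort(rownames(ast$posteriors)[pv > tau],
                              method = "radix")
      next
    }
    parent <- tree$edge[tree$edge[, 2L] == v, 1L]
    pv <- ast$posteriors[, all_names[v]]
    pp_col <- all_names[parent]
    pp <- if (parent <= ntip) stop("ancestor parent is a tip?") else
      ast$posteriors[, pp_col]
    absent <- if (parent_rule == "confident") pp < 1 - tau else pp < tau
    gains[[nm]] <- sort(rownames(ast$posteriors)[pv > tau & absent],
                        method = "radix")
  }
  structure(list(gains = gains, present_at_root = present_at_root,
                 tau = tau, parent_rule = parent_rule),
            class = "gain_event_table")
}

#' Per-node posterior trace for a single orthogroup
#'
#' Control-style report: the tree annotated with per-node posteriors of
#' presence (as internal node labels in a newick string) plus a tidy table.
#'
#' @param og_id Orthogroup id present in \code{ast}.
#' @param ast \code{\link{asr_all}} result.
#' @return List with \code{newick} (node-labeled tree) and \code{table}
#'   (data.frame node, node_name, is_tip, p_present).
#' @export
single_character_report <- function(og_id, ast) {
  if (!og_id %in% rownames(ast$posteriors)) {
    stop(sprintf("unknown orthogroup '%s'", og_id))
  }
  tree <- ast$tree
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  p <- c(ast$tip_posteriors[og_id, tree$tip.label],
         ast$posteriors[og_id, node_name(tree, (ntip + 1L):nn)])
  out_tree <- tree
  out_tree$node.label <- sprintf("%.6f", p[(ntip + 1L):nn])
  df <- data.frame(node = seq_len(nn), node_name = node_name(tree),
                   is_tip = seq_len(nn) <= ntip, p_present = unname(p),
                   stringsAsFactors = FALSE)
  list(newick = write_newick(out_tree), table = df)
}
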