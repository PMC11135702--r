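make_ast <- function(tree, posteriors, tip_posteriors = NULL) {
  structure(list(posteriors = posteriors, tip_posteriors = tip_posteriors,
                 tree = tree, prior = c(0.5, 0.5)),
            class = "ancestral_state_table")
}

test_that("cherry likelihood matches the closed form and the q -> 0 limit", {
  tr <- parse_newick("(A:0.7,B:0.7);")
  st <- c(A = 1L, B = 1L)
  for (q in c(0.05, 0.3, 1.5)) {
    ps <- (1 + exp(-2 * q * 0.7)) / 2
    pf <- 1 - ps
    expect_equal(er_loglik(tr, st, q), log(0.5 * (ps^2 + pf^2)),
                 tolerance = 1e-12)
  }
  expect_equal(er_loglik(tr, st, 1e-9), log(0.5), tolerance = 1e-6)
  # constant-present character on a bigger tree: likelihood -> 1/2 as q -> 0
  tr2 <- random_tree(6)
  st2 <- stats::setNames(rep(1L, 6), tr2$tip.label)
  expect_equal(er_loglik(tr2, st2, 1e-9), log(0.5), tolerance = 1e-6)
  expect_error(er_loglik(tr, st, 0), "q must be > 0")
})

test_that("pruning equals enumeration on randomized small trees", {
  set.seed(202)
  for (i in 1:40) {
    tr <- random_tree(sample(3:6, 1))
    st <- random_states(tr)
    q <- runif(1, 0.05, 2)
    oracle <- oracle_enum_er(tr, st, q)
    expect_equal(er_loglik(tr, st, q), oracle$loglik, tolerance = 1e-10)
    post <- er_marginal_posteriors(tr, st, q)
    expect_equal(unname(post), unname(oracle$post), tolerance = 1e-10)
  }
})

test_that("posterior normalization and tip posteriors equal observed states", {
  set.seed(210)
  tr <- random_tree(10)
  st <- random_states(tr)
  post <- er_marginal_posteriors(tr, st, 0.4)
  expect_true(all(post >= 0 & post <= 1))
  expect_equal(unname(post[seq_len(10)]), unname(st[tr$tip.label]))
})

test_that("ER symmetry: flipping 0/1 maps posteriors to their complement", {
  set.seed(230)
  for (i in 1:10) {
    tr <- random_tree(sample(4:12, 1))
    st <- random_states(tr)
    q <- runif(1, 0.05, 1.5)
    p <- er_marginal_posteriors(tr, st, q)
    pf <- er_marginal_posteriors(tr, stats::setNames(1L - st, names(st)), q)
    expect_equal(unname(pf), unname(1 - p), tolerance = 1e-12)
    # and the ML rate is unchanged
    expect_equal(er_fit_rate(tr, st)$q,
                 er_fit_rate(tr, stats::setNames(1L - st, names(st)))$q,
                 tolerance = 1e-9)
  }
})

test_that("fitted rate beats a 100-point log-grid; constant characters refused", {
  set.seed(240)
  bounds <- c(1e-6, 100)
  for (i in 1:5) {
    tr <- random_tree(8)
    st <- random_states(tr)
    fit <- er_fit_rate(tr, st, bounds)
    grid <- exp(seq(log(bounds[1]), log(bounds[2]), length.out = 100))
    gl <- vapply(grid, function(q) er_loglik(tr, st, q), numeric(1))
    expect_gte(fit$loglik, max(gl) - 1e-6)
  }
  stc <- stats::setNames(rep(1L, 8), random_tree(8)$tip.label)
  expect_error(er_fit_rate(random_tree(8), stc), "constant character")
})

test_that("symmetric cherry with states (1,0) has root posterior exactly 1/2", {
  tr <- parse_newick("(A:1,B:1);")
  post <- er_marginal_posteriors(tr, c(A = 1L, B = 0L), 0.3)
  expect_equal(unname(post["N3"]), 0.5, tolerance = 1e-12)
})

test_that("all-present character: internal posteriors -> 1 as q -> 0", {
  tr <- random_tree(6)
  st <- stats::setNames(rep(1L, 6), tr$tip.label)
  post <- er_marginal_posteriors(tr, st, 1e-8)
  expect_true(all(post > 1 - 1e-6))
})

test_that("asr_all: constant conventions, row permutation, missing tips", {
  set.seed(260)
  tr <- random_tree(8)
  m <- rbind(const1 = rep(1L, 8), const0 = rep(0L, 8),
             var1 = c(rep(1L, 4), rep(0L, 4)))
  colnames(m) <- tr$tip.label
  ast <- asr_all(m, tr)
  expect_true(all(ast$posteriors["const1", ] == 1))
  expect_true(all(ast$posteriors["const0", ] == 0))
  expect_true(all(ast$rates$degenerate == c(TRUE, TRUE, FALSE)))
  expect_equal(ast$rates$q_hat[1:2], c(0, 0))
  # row permutation changes nothing but order
  ast2 <- asr_all(m[c(3, 1, 2), ], tr)
  expect_equal(ast2$posteriors[rownames(ast$posteriors), ], ast$posteriors)
  # tree tips absent from the matrix are scored absent
  m3 <- m[, 1:6]
  expect_warning(ast3 <- asr_all(cbind(m3, ghost_species = c(1L, 1L, 0L)), tr),
                 "ghost_species")
  ast4 <- asr_all(m3, tr)
  expect_equal(ast3$posteriors, ast4$posteriors)
})

test_that("gain calling: thresholds, parent rules, root handling", {
  tr <- parse_newick("((A:1,B:1):1,C:1);")   # root N4, inner N5
  post <- rbind(og_gain = c(N4 = 0.10, N5 = 0.90),
                og_parent_mid = c(N4 = 0.50, N5 = 0.90),
                og_exact = c(N4 = 0.10, N5 = 0.75),
                og_rootpres = c(N4 = 0.90, N5 = 0.95))
  ast <- make_ast(tr, post)
  anc <- c(inner = 5L)
  g <- call_gains(ast, anc, tau = 0.75, parent_rule = "confident")
  expect_identical(g$gains$inner, "og_gain")  # og_rootpres parent is 0.90
  expect_false("og_exact" %in% g$gains$inner)      # P = tau is not "> tau"
  g_lax <- call_gains(ast, anc, tau = 0.75, parent_rule = "lax")
  expect_true("og_parent_mid" %in% g_lax$gains$inner)
  expect_false("og_parent_mid" %in% g$gains$inner)
  expect_error(call_gains(ast, c(root = 4L), tau = 0.75), "root")
  g_root <- call_gains(ast, c(root = 4L), tau = 0.75,
                       root_rule = "present_at_root")
  expect_identical(g_root$present_at_root, "og_rootpres")
  expect_length(g_root$gains, 0L)
})

test_that("gain sets are nested across the threshold sweep", {
  set.seed(300)
  tr <- parse_newick("(((A:1,B:1):1,C:2):1,D:3);")
  for (rep in 1:10) {
    post <- matrix(runif(20 * 3), 20, 3,
                   dimnames = list(sprintf("OG%02d", 1:20),
                                   c("N5", "N6", "N7")))
    ast <- make_ast(tr, post)
    anc <- c(a = 6L, b = 7L)
    gs <- lapply(c(0.65, 0.75, 0.85), function(tau)
      call_gains(ast, anc, tau = tau))
    for (nm in names(anc)) {
      expect_true(all(gs[[3]]$gains[[nm]] %in% gs[[2]]$gains[[nm]]))
      expect_true(all(gs[[2]]$gains[[nm]] %in% gs[[1]]$gains[[nm]]))
    }
  }
})

test_that("single_character_report: constant trace, newick round trip, errors", {
  tr <- random_tree(6)
  m <- rbind(allpres = rep(1L, 6))
  colnames(m) <- tr$tip.label
  ast <- asr_all(m, tr)
  rep1 <- single_character_report("allpres", ast)
  expect_true(all(rep1$table$p_present == 1))
  back <- parse_newick(rep1$newick)
  expect_equal(sort(back$tip.label), sort(tr$tip.label))
  expect_equal(ape::cophenetic.phylo(back)[tr$tip.label, tr$tip.label],
               ape::cophenetic.phylo(tr)[tr$tip.label, tr$tip.label],
               tolerance = 1e-9)
  expect_error(single_character_report("nope", ast), "unknown orthogroup")
})

test_that("an rbcS-like green-only character is called gained at the green crown", {
  sim <- get_fixture()$sim
  lm <- sim$lineages
  green <- lm$species_id[lm$is_green]
  tr <- sim$tree
  states <- stats::setNames(as.integer(tr$tip.label %in% green),
                            tr$tip.label)
  m <- matrix(states, 1, dimnames = list("rbcS_like", names(states)))
  ast <- asr_all(m, tr)
  anc <- resolve_ancestors(tr, list(green_crown = green))
  g <- call_gains(ast, anc, tau = 0.75)
  expect_identical(g$gains$green_crown, "rbcS_like")
})
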