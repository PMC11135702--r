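test_that("simulate_tree is deterministic and clocklike", {
  cfg <- small_sim_config(seed = 5L)
  set.seed(5); t1 <- simulate_tree(cfg)
  set.seed(5); t2 <- simulate_tree(cfg)
  expect_identical(write_newick(t1), write_newick(t2))
  d <- ape::node.depth.edgelength(t1)[seq_len(ape::Ntip(t1))]
  expect_lt(max(d) - min(d), 1e-9)
  expect_true(ape::is.binary(t1))
  expect_true(ape::is.rooted(t1))
})

test_that("two-species lineage-free tree is a cherry with equal branches", {
  cfg <- sim_config(lineages = data.frame(label = "x", n_species = 2L),
                    seed = 1L)
  set.seed(1)
  tr <- simulate_tree(cfg)
  expect_equal(ape::Ntip(tr), 2L)
  expect_equal(tr$edge.length[1], tr$edge.length[2], tolerance = 1e-12)
})

test_that("absorbing limits of the gain/loss process", {
  set.seed(3)
  tr <- simulate_tree(small_sim_config(seed = 3L))
  st1 <- simulate_og_states(tr, alpha = 0.5, beta = 0, root_p = 1, n_ogs = 20)
  expect_true(all(st1$states == 1L))
  st0 <- simulate_og_states(tr, alpha = 0, beta = 0.5, root_p = 0, n_ogs = 20)
  expect_true(all(st0$states == 0L))
  expect_warning(simulate_og_states(tr, 0, 0, 0.5, 5), "alpha = beta = 0")
})

test_that("deep-tree tip states approach the stationary distribution", {
  set.seed(9)
  tr <- simulate_tree(small_sim_config(seed = 9L))
  tr$edge.length <- tr$edge.length * 50  # 2(alpha+beta)t >> 1 everywhere
  st <- simulate_og_states(tr, alpha = 0.1, beta = 0.1, root_p = 0,
                           n_ogs = 10000)
  expect_equal(mean(st$presence), 0.5, tolerance = 0.02)
})

test_that("events are consistent with state changes; presence conserved", {
  set.seed(13)
  tr <- simulate_tree(small_sim_config(seed = 13L))
  st <- simulate_og_states(tr, 0.3, 0.3, 0.5, 50)
  nms <- colnames(st$states)
  for (i in seq_len(nrow(st$events))) {
    ev <- st$events[i, ]
    from <- st$states[ev$og_id, ev$parent]
    to <- st$states[ev$og_id, ev$child]
    expect_true(from != to)
    expect_equal(unname(to), if (ev$type == "gain") 1L else 0L)
  }
  expect_equal(sum(st$presence), sum(st$states[, seq_len(ape::Ntip(tr))]))
})

test_that("doubling branch lengths with halved rates reproduces the process", {
  set.seed(17)
  tr <- simulate_tree(small_sim_config(seed = 17L))
  tr2 <- tr; tr2$edge.length <- tr2$edge.length * 2
  set.seed(99); a <- simulate_og_states(tr, 0.4, 0.2, 0.5, 200)
  set.seed(99); b <- simulate_og_states(tr2, 0.2, 0.1, 0.5, 200)
  expect_identical(a$states, b$states)  # matched seed: exact invariance
})

test_that("simulate_dataset is byte-identical under identical config", {
  cfg <- small_sim_config(seed = 31L)
  d1 <- file.path(tempdir(), "simdet1"); d2 <- file.path(tempdir(), "simdet2")
  unlink(c(d1, d2), recursive = TRUE)
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  files <- list.files(d1, recursive = TRUE)
  expect_identical(files, list.files(d2, recursive = TRUE))
  for (f in files) {
    expect_identical(readBin(file.path(d1, f), "raw", 2e6),
                     readBin(file.path(d2, f), "raw", 2e6))
  }
})

test_that("fixture files are parseable and match in-memory ground truth", {
  fx <- get_fixture()
  sim <- fx$sim; dir <- fx$dir
  ogs <- read_orthogroups_tsv(file.path(dir, "orthogroups.tsv"))
  expect_identical(ogs, sim$ogs)
  pm <- build_presence_matrix(ogs, colnames(sim$presence))
  populated <- intersect(rownames(sim$presence), rownames(pm))
  expect_identical(pm[populated, ], sim$presence[populated, ])
  states <- read_matrix_tsv(file.path(dir, "ground_truth", "states.tsv"),
                            integer_mode = TRUE)
  expect_identical(states, sim$states)
  tr <- parse_newick(readLines(file.path(dir, "tree.nwk")))
  expect_identical(sort(tr$tip.label), sort(sim$tree$tip.label))
})

test_that("designated organelle sets are recovered exactly by the classifier", {
  fx <- get_fixture()
  sim <- fx$sim
  sets <- read_experimental_sets(file.path(fx$dir, "experimental.tsv"))
  org <- select_organelle_ogs(sim$ogs, sets)
  expect_identical(org$pog_ids, sim$pogs)
  expect_identical(org$mog_ids, sim$mogs)
  expect_identical(sort(intersect(org$pog_ids, org$mog_ids)), sim$dual)
  expect_length(org$unmatched, 0L)
})

test_that("planted N-terminal charge classes are recovered by the screen", {
  sim <- get_fixture()$sim
  ch <- vapply(sim$proteins$sequence, nterm_charge, integer(1))
  expected <- ifelse(sim$charge_class[sim$proteins$og_id] == "charge2", 2L, 0L)
  expect_identical(unname(ch), unname(expected))
})

test_that("inconsistent config errors", {
  cfg <- small_sim_config(seed = 7L)
  cfg$n_pog <- 500L  # more designated POGs than orthogroups exist
  expect_error(simulate_dataset(cfg, tempfile()), "inconsistent config")
})
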