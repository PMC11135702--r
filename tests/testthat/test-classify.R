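test_that("GOG rule boundaries: >=3 green, <3 non-green, both strict as stated", {
  cases <- data.frame(og = c("in_3_0", "out_2_0", "out_5_3", "in_5_2"),
                      green = c(3L, 2L, 5L, 5L), nongreen = c(0L, 0L, 3L, 2L))
  m <- boundary_matrix(cases)
  expect_identical(select_gogs(m, boundary_lineages()),
                   c("in_3_0", "in_5_2"))
})

test_that("core-GOG rule: strictly more than 90% of green species", {
  cases <- data.frame(og = c("core_144", "not_143", "not_90pct"),
                      green = c(144L, 143L, 9L), nongreen = 0L)
  # 144/159 = 0.9057 in, 143/159 = 0.8994 out; 9/10 = 0.90 exactly out
  m1 <- boundary_matrix(cases[1:2, ], n_green = 159L, n_nongreen = 2L)
  lm1 <- boundary_lineages(159L, 2L)
  gogs <- select_gogs(m1, lm1)
  expect_identical(select_core_gogs(gogs, m1, lm1), "core_144")
  m2 <- boundary_matrix(cases[3, ], n_green = 10L, n_nongreen = 2L)
  lm2 <- boundary_lineages(10L, 2L)
  expect_identical(select_core_gogs(select_gogs(m2, lm2), m2, lm2),
                   character(0))
})

test_that("core-GOG selection errors with zero green species", {
  m <- matrix(1L, 1, 2, dimnames = list("OG1", c("n001", "n002")))
  expect_error(select_core_gogs("OG1", m, boundary_lineages(0L, 2L)),
               "no green species")
})

test_that("GOG rule is monotone in the stated directions", {
  set.seed(41)
  lm <- boundary_lineages(8L, 8L)
  for (rep in 1:20) {
    m <- matrix(rbinom(16L, 1L, 0.4), 1, 16,
                dimnames = list("OG", lm$species_id))
    was_gog <- length(select_gogs(m, lm)) == 1L
    zg <- which(m[1, 1:8] == 0L)
    if (length(zg)) {
      m2 <- m; m2[1, zg[1]] <- 1L  # add a green presence
      if (was_gog) expect_length(select_gogs(m2, lm), 1L)
    }
    zn <- which(m[1, 9:16] == 0L)
    if (length(zn) && !was_gog) {
      m3 <- m; m3[1, 8L + zn[1]] <- 1L  # add a non-green presence
      expect_length(select_gogs(m3, lm), 0L)
    }
  }
})

test_that("species counted once regardless of copy number", {
  tab <- orthogroup_table(rep("OG1", 5),
                          c("a1", "a2", "a3", "a4", "b1"),
                          c(rep("g001", 4), "g002"))
  lm <- boundary_lineages(3L, 1L)
  m <- build_presence_matrix(tab, lm$species_id)
  expect_length(select_gogs(m, lm), 0L)  # 2 green species, 40 paralogs or not
})

test_that("organelle classification: trigger, overlap, provenance, shuffle invariance", {
  tab <- orthogroup_table(c("OG1", "OG1", "OG2", "OG3"),
                          c("at1", "x1", "at2", "y1"),
                          c("ref1", "spX", "ref1", "spY"))
  sets <- list(experimental_set("plastid", "ref1", c("at1", "at2", "zz9")),
               experimental_set("mitochondrion", "ref1", "at2"))
  org <- select_organelle_ogs(tab, sets)
  expect_identical(org$pog_ids, c("OG1", "OG2"))
  expect_identical(org$mog_ids, "OG2")          # OG2 is both POG and MOG
  expect_identical(org$unmatched, "zz9")
  expect_identical(org$provenance$protein_id[org$provenance$og_id == "OG1"],
                   "at1")
  # member order invariance
  perm <- tab[sample(nrow(tab)), ]
  org2 <- select_organelle_ogs(
    orthogroup_table(perm$og_id, perm$protein_id, perm$species_id), sets)
  expect_identical(org2[c("pog_ids", "mog_ids")], org[c("pog_ids", "mog_ids")])
})

test_that("species_summary: PN/ON/P-per-O and conservation", {
  tab <- orthogroup_table(c("OG1", "OG1", "OG2"), c("p1", "p2", "p3"),
                          c("A", "A", "B"))
  species <- c("A", "B", "C")
  pm <- build_presence_matrix(tab, species)
  cn <- build_copy_number_matrix(tab, species)
  sm <- species_summary(c("OG1", "OG2"), pm, cn)
  expect_equal(sm$PN, c(2L, 1L, 0L))
  expect_equal(sm$ON, c(1L, 1L, 0L))
  expect_equal(sm$P_per_O, c(2, 1, 0))
  # conservation on the simulated fixture
  sim <- get_fixture()$sim
  pm2 <- build_presence_matrix(sim$ogs)
  cn2 <- build_copy_number_matrix(sim$ogs)
  all_ogs <- rownames(pm2)
  expect_equal(sum(species_summary(all_ogs, pm2, cn2)$PN), nrow(sim$ogs))
})

test_that("build matrices: empty table, unknown species error, display clamp", {
  empty <- orthogroup_table(character(0), character(0), character(0))
  m <- build_presence_matrix(empty, c("A", "B"))
  expect_equal(dim(m), c(0L, 2L))
  tab <- orthogroup_table("OG1", "p1", "A")
  expect_error(build_presence_matrix(tab, "B"), "A")
  cn <- matrix(c(3L, 80L), 1, 2, dimnames = list("OG1", c("A", "B")))
  expect_equal(unname(display_clamp(cn, 50L)[1, ]), c(3L, 50L))
})
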