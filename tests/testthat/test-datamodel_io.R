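write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

test_that("orthogroups.tsv dialect: membership, empty cells, species from header", {
  f <- write_lines_tmp(c("OG\tSpA\tSpB",
                         "OG1\tp1, p2\tp3",
                         "OG2\tp4\t"))
  tab <- read_orthogroups_tsv(f)
  expect_s3_class(tab, "orthogroup_table")
  og1 <- tab[tab$og_id == "OG1", ]
  expect_setequal(paste(og1$protein_id, og1$species_id),
                  c("p1 SpA", "p2 SpA", "p3 SpB"))
  og2 <- tab[tab$og_id == "OG2", ]
  expect_equal(og2$species_id, "SpA")
  expect_equal(nrow(tab), 4L)
})

test_that("orthogroups.tsv errors: duplicate OG id, protein under two species", {
  f <- write_lines_tmp(c("OG\tSpA\tSpB", "OG1\tp1\t", "OG1\tp2\t"))
  expect_error(read_orthogroups_tsv(f), "duplicate orthogroup id 'OG1'")
  f2 <- write_lines_tmp(c("OG\tSpA\tSpB", "OG1\tp1\tp1"))
  expect_error(read_orthogroups_tsv(f2), "p1")
})

test_that("orthogroup parsing is row-order insensitive", {
  rows <- c("OG1\tp1, p2\tp3", "OG2\tp4\tp5", "OG3\t\tp6")
  f1 <- write_lines_tmp(c("OG\tSpA\tSpB", rows))
  f2 <- write_lines_tmp(c("OG\tSpA\tSpB", rev(rows)))
  expect_identical(read_orthogroups_tsv(f1), read_orthogroups_tsv(f2))
})

test_that("orthogroups writer round-trips through the reader", {
  sim <- get_fixture()$sim
  f <- tempfile(fileext = ".tsv")
  write_orthogroups_tsv(sim$ogs, f)
  expect_identical(read_orthogroups_tsv(f), sim$ogs)
})

test_that("fasta reader: id token, uppercasing, stop stripping, errors", {
  f <- tempfile(fileext = ".faa")
  writeLines(c(">p1 some description", "mkra", ">p2", "MKRA*"), f)
  rec <- read_fasta(f, species_id = "SpA")
  expect_equal(rec$protein_id, c("p1", "p2"))
  expect_equal(rec$sequence, c("MKRA", "MKRA"))
  expect_equal(rec$species_id, c("SpA", "SpA"))

  writeLines(c(">p1", "MK", ">p1", "RA"), f)
  expect_error(read_fasta(f), "duplicate protein id 'p1'")
  writeLines(c(">p1", "*"), f)
  expect_error(read_fasta(f), "empty sequence")
})

test_that("tblout parser: field-5 accession, version stripping, filtering, dedup", {
  f <- write_lines_tmp(c(
    "# comment line",
    "p1 - PPR - PF01535.20 1e-10 50.0 0.0",
    "p1 - PPR - PF01535.20 1e-10 50.0 0.0",
    "p2 - decoy - PF99999 1e-3 8.0 0.0",
    "p3 - mTERF - PF02536 1e-12 60.0 0.0"))
  hits <- read_domain_tblout(f, ppr_mterf_accessions())
  expect_equal(hits$protein_id, c("p1", "p3"))
  expect_equal(hits$accession, c("PF01535", "PF02536"))

  f2 <- write_lines_tmp(c("p1 - short", "x"))
  expect_error(read_domain_tblout(f2), "line 1")
})

test_that("matrix TSV round trips: integer exact, empty, probabilities", {
  m <- matrix(c(1L, 0L, 3L, 50L), 2, 2,
              dimnames = list(c("OG1", "OG2"), c("A", "B")))
  f <- tempfile()
  write_matrix_tsv(m, f)
  expect_identical(read_matrix_tsv(f, integer_mode = TRUE), m)

  empty <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("A", "B")))
  write_matrix_tsv(empty, f)
  back <- read_matrix_tsv(f, integer_mode = TRUE)
  expect_equal(dim(back), c(0L, 2L))
  expect_equal(colnames(back), c("A", "B"))

  p <- matrix(c(1 / 3, 2 / 7), 1, 2, dimnames = list("OG1", c("N4", "N5")))
  write_matrix_tsv(p, f)
  expect_equal(read_matrix_tsv(f), p, tolerance = 1e-12)
})

test_that("copy-number matrix binarized equals presence matrix (invariant)", {
  sim <- get_fixture()$sim
  cn <- build_copy_number_matrix(sim$ogs)
  pm <- build_presence_matrix(sim$ogs)
  expect_identical((cn > 0L) * 1L, pm * 1L)
  # matches simulated tip states; orthogroups lost everywhere have no members
  # and therefore no matrix row
  populated <- intersect(rownames(sim$presence), rownames(pm))
  expect_identical(pm[populated, colnames(sim$presence)],
                   sim$presence[populated, ])
  empty <- setdiff(rownames(sim$presence), rownames(pm))
  expect_true(all(rowSums(sim$presence[empty, , drop = FALSE]) == 0))
})

test_that("map readers: ko map drops empty cells, experimental sets split", {
  f <- write_lines_tmp(c("protein_id\tkoid", "p1\tK00001", "p2\t"))
  ko <- read_ko_map(f)
  expect_identical(ko, c(p1 = "K00001"))

  f2 <- write_lines_tmp(c("protein_id\torganelle\treference_species",
                          "p1\tplastid\tref1", "p2\tplastid\tref1",
                          "p3\tmitochondrion\tref2"))
  sets <- read_experimental_sets(f2)
  expect_length(sets, 2L)
  orgs <- vapply(sets, function(s) s$organelle, character(1))
  expect_setequal(orgs, c("plastid", "mitochondrion"))
  expect_equal(sets[[which(orgs == "plastid")]]$protein_ids, c("p1", "p2"))
})
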