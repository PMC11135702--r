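#' Configuration for the synthetic-data generator
#'
#' Describes a complete synthetic world: a clocklike species tree over labeled
#' lineages, orthogroup presence/absence evolved under a two-state gain/loss
#' Markov process with known ancestral states, per-species copy numbers,
#' protein sequences with controlled N-terminal charge classes, KO labels with
#' a missing fraction, domain hits for designated RNA-metabolism families, and
#' experimental organelle proteome lists sampled from designated plastid and
#' mitochondrial families.
#'
#' @param lineages data.frame with columns \code{label} (deepest lineage
#'   first) and \code{n_species}.
#' @param seed Integer RNG seed, recorded in the output manifest.
#' @param tree_depth Root-to-tip depth of the clock tree (time units).
#' @param birth_rate Yule birth rate used inside each lineage subtree.
#' @param alpha,beta Per-orthogroup gain (0 to 1) and loss (1 to 0) rates per
#'   unit branch length.
#' @param root_p Probability an orthogroup is present at the root.
#' @param n_ogs Number of orthogroups.
#' @param copy_geom_p Geometric parameter for copy numbers given presence
#'   (copies = 1 + Geom(p), support >= 1).
#' @param ko_annotated_og_fraction Fraction of orthogroups with a planted KO.
#' @param koid_missing_fraction Per-protein probability that the KO label is
#'   missing.
#' @param ko_noise Per-protein probability of a decoy KO replacing the
#'   planted one.
#' @param n_pog,n_mog Numbers of designated plastid / mitochondrial
#'   orthogroups (drawn among orthogroups present in a reference species).
#' @param n_dual Size of the planted POG/MOG overlap.
#' @param n_rna_ogs Designated RNA-metabolism orthogroups (subset of
#'   organelle orthogroups) receiving PPR/mTERF domain hits.
#' @param domain_positive_fraction Per-member probability of a domain hit in
#'   an RNA-metabolism orthogroup.
#' @param seq_len_range Protein length range (uniform).
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(lineages = data.frame(
                         label = c("outgroup_eukaryote", "rhodophyte",
                                   "glaucophyte", "chlorophyte",
                                   "zygnematophyceae", "embryophyte"),
                         n_species = c(4L, 3L, 2L, 6L, 4L, 8L),
                         stringsAsFactors = FALSE),
                       seed = 1L,
                       tree_depth = 1,
                       birth_rate = 1,
                       alpha = 0.2, beta = 0.2,
                       root_p = 0.5,
                       n_ogs = 300L,
                       copy_geom_p = 0.5,
                       ko_annotated_og_fraction = 0.6,
                       koid_missing_fraction = 0.3,
                       ko_noise = 0.1,
                       n_pog = 40L, n_mog = 25L, n_dual = 5L,
                       n_rna_ogs = 12L,
                       domain_positive_fraction = 0.9,
                       seq_len_range = c(80L, 160L)) {
  stopifnot(nrow(lineages) >= 1, all(lineages$n_species >= 1),
            alpha >= 0, beta >= 0, root_p >= 0, root_p <= 1,
            n_ogs >= 1, copy_geom_p > 0, copy_geom_p < 1,
            koid_missing_fraction >= 0, koid_missing_fraction <= 1,
            ko_noise >= 0, ko_noise <= 1,
            n_dual <= n_pog, n_dual <= n_mog,
            domain_positive_fraction >= 0, domain_positive_fraction <= 1)
  structure(as.list(environment()), class = "sim_config")
}

# Yule (pure-birth) clock subtree with n tips rescaled to a given crown depth;
# returns a newick fragment without the trailing ";" and without a root edge.
yule_subtree_newick <- function(label, n, crown, birth) {
  tips <- sprintf("%s_%02d", label, seq_len(n))
  if (n == 1L) return(tips)
  tr <- ape::rphylo(n, birth = birth, death = 0)
  depths <- ape::node.depth.edgelength(tr)
  tr$edge.length <- tr$edge.length * crown / max(depths[seq_len(n)])
  tr$tip.label <- tips
  sub("\\);$", ")", sub("^", "", ape::write.tree(tr, digits = 15)))
}

#' Simulate a rooted ultrametric species tree over labeled lineages
#'
#' Lineages branch off a pectinate backbone (deepest lineage first, splits at
#' evenly spaced depths); within each lineage a seeded Yule clock subtree is
#' grown with crown depth half its stem attachment depth. The result is
#' binary, rooted and clocklike. Uses the current RNG state; seed via
#' \code{set.seed} or \code{\link{simulate_dataset}}.
#'
#' @param config \code{\link{sim_config}}.
#' @return Rooted ultrametric \code{ape::phylo} with lineage-tagged tips.
#' @export
simulate_tree <- function(config) {
  ln <- config$lineages
  k <- nrow(ln)
  depth <- config$tree_depth
  if (k == 1L) {
    nwk <- paste0(yule_subtree_newick(ln$label[1], ln$n_species[1],
                                      depth, config$birth_rate), ";")
    return(parse_newick(nwk))
  }
  h <- depth * (k - seq_len(k - 1L)) / (k - 1L)  # split heights, h[1] = depth
  attach_h <- c(h, h[k - 1L])                    # per-lineage stem attachment
  crown <- ifelse(ln$n_species > 1L, attach_h / 2, 0)
  subs <- vapply(seq_len(k), function(j)
    yule_subtree_newick(ln$label[j], ln$n_species[j], crown[j],
                        config$birth_rate), character(1))
  fmt <- function(x) sprintf("%.15g", x)
  cur <- paste0("(", subs[k - 1L], ":", fmt(attach_h[k - 1L] - crown[k - 1L]),
                ",", subs[k], ":", fmt(attach_h[k] - crown[k]), ")")
  if (k > 2L) {
    for (j in (k - 2L):1L) {
      cur <- paste0("(", subs[j], ":", fmt(h[j] - crown[j]), ",",
                    cur, ":", fmt(h[j] - h[j + 1L]), ")")
    }
  }
  parse_newick(paste0(cur, ";"))
}

#' Evolve binary orthogroup presence/absence along a tree
#'
#' Root states are Bernoulli(\code{root_p}); along each branch of length t the
#' state flips with the exact two-state Markov probabilities
#' P(0 to 1) = a/(a+b) (1 - exp(-(a+b) t)) and
#' P(1 to 0) = b/(a+b) (1 - exp(-(a+b) t)). All node states and per-branch
#' events are recorded. Uses the current RNG state.
#'
#' @param tree Rooted \code{ape::phylo} with branch lengths.
#' @param alpha,beta Gain and loss rates (>= 0).
#' @param root_p Root presence probability.
#' @param n_ogs Number of independent characters.
#' @param og_ids Optional character ids (default \code{OG0000001} ...).
#' @return List: \code{states} (og x node matrix over all nodes, columns
#'   named), \code{presence} (og x tip submatrix), \code{events} (data.frame
#'   og_id, parent, child, type in gain/loss), \code{tree}.
#' @export
simulate_og_states <- function(tree, alpha, beta, root_p, n_ogs,
                               og_ids = sprintf("OG%07d", seq_len(n_ogs))) {
  stopifnot(ape::is.rooted(tree), alpha >= 0, beta >= 0)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  nms <- node_name(tree)
  S <- matrix(NA_integer_, n_ogs, nn, dimnames = list(og_ids, nms))
  root <- ntip + 1L
  S[, root] <- stats::rbinom(n_ogs, 1L, root_p)
  r <- alpha + beta
  if (r == 0) {
    warning("alpha = beta = 0: states copied from the root everywhere")
  }
  tr <- ape::reorder.phylo(tree, "cladewise")
  ev_og <- character(0); ev_par <- character(0); ev_ch <- character(0)
  ev_ty <- character(0)
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1L]; ch <- tr$edge[k, 2L]; t <- tr$edge.length[k]
    sp <- S[, p]
    if (r == 0) {
      S[, ch] <- sp
    } else {
      p01 <- alpha / r * (1 - exp(-r * t))
      p10 <- beta / r * (1 - exp(-r * t))
      u <- stats::runif(n_ogs)
      S[, ch] <- ifelse(sp == 0L, as.integer(u < p01), as.integer(u >= p10))
    }
    chg <- which(S[, ch] != sp)
    if (length(chg)) {
      ev_og <- c(ev_og, og_ids[chg])
      ev_par <- c(ev_par, rep(nms[p], length(chg)))
      ev_ch <- c(ev_ch, rep(nms[ch], length(chg)))
      ev_ty <- c(ev_ty, ifelse(S[chg, ch] == 1L, "gain", "loss"))
    }
  }
  list(states = S,
       presence = S[, seq_len(ntip), drop = FALSE],
       events = data.frame(og_id = ev_og, parent = ev_par, child = ev_ch,
                           type = ev_ty, stringsAsFactors = FALSE),
       tree = tree)
}

# amino-acid alphabets for sequence generation; the "neutral" set carries no
# charge under the K/R vs D/E convention (H excluded too).
aa_all <- function() strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
aa_neutral <- function() strsplit("ACFGILMNPQSTVWY", "")[[1]]

random_sequence <- function(len, charge_class = c("charge0", "charge2"),
                            prefix_len = 20L) {
  charge_class <- match.arg(charge_class)
  prefix <- c("M", sample(aa_neutral(), prefix_len - 1L, replace = TRUE))
  if (charge_class == "charge2") prefix[c(2L, 3L)] <- "K"
  body_len <- max(len - prefix_len, 0L)
  body <- sample(aa_all(), body_len, replace = TRUE)
  paste(c(prefix, body), collapse = "")
}

#' Generate a complete on-disk synthetic dataset with ground truth
#'
#' Runs the whole generative model of \code{\link{sim_config}} under the
#' config seed and writes every input the pipeline consumes (per-species
#' FASTA, Orthogroups.tsv, lineage map, KO and BRITE maps, domain tblout,
#' experimental proteome lists, newick tree) plus a \code{ground_truth/}
#' directory and a \code{manifest.json} recording config and seed. Identical
#' configs produce byte-identical fixtures.
#'
#' @param config \code{\link{sim_config}}.
#' @param out_dir Output directory (created).
#' @return (invisibly) a list with the in-memory objects: tree, states,
#'   presence, copy numbers, orthogroup table, proteins, lineage map, ko map,
#'   experimental sets and the designation tables.
#' @export
simulate_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "proteomes"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "ground_truth"), showWarnings = FALSE)

  tree <- simulate_tree(config)
  st <- simulate_og_states(tree, config$alpha, config$beta, config$root_p,
                           config$n_ogs)
  species <- sort(tree$tip.label, method = "radix")
  presence <- st$presence[, species, drop = FALSE]
  ogids <- rownames(presence)

  # copy numbers: 1 + geometric, only where present
  copy <- presence
  npos <- sum(presence > 0)
  copy[presence > 0] <- 1L + stats::rgeom(npos, config$copy_geom_p)

  lineages <- lineage_map(species, sub("_[0-9]+$", "", species))

  # reference species: two embryophytes (or the last lineage when absent)
  ref_pool <- lineages$species_id[lineages$lineage ==
                                    utils::tail(config$lineages$label, 1L)]
  reference_species <- utils::head(sort(ref_pool, method = "radix"), 2L)
  if (length(reference_species) < 1L) {
    stop("inconsistent config: no species available as reference proteome")
  }

  # designations among OGs present in >= 1 reference species
  candidates <- ogids[rowSums(presence[, reference_species, drop = FALSE]) > 0]
  if (length(candidates) < config$n_pog + config$n_mog - config$n_dual) {
    stop(sprintf(
      "inconsistent config: only %d orthogroups present in reference species, need %d",
      length(candidates), config$n_pog + config$n_mog - config$n_dual))
  }
  pogs <- sort(sample(candidates, config$n_pog), method = "radix")
  dual <- sort(sample(pogs, config$n_dual), method = "radix")
  mog_rest <- sort(sample(setdiff(candidates, pogs),
                          config$n_mog - config$n_dual), method = "radix")
  mogs <- sort(c(dual, mog_rest), method = "radix")
  organelle_ogs <- sort(unique(c(pogs, mogs)), method = "radix")
  rna <- sort(sample(organelle_ogs, min(config$n_rna_ogs,
                                        length(organelle_ogs))),
              method = "radix")
  charge_class <- stats::setNames(rep("charge0", length(ogids)), ogids)
  charge_class[unique(c(dual, rna))] <- "charge2"

  # proteins
  prot_og <- character(0); prot_sp <- character(0); prot_id <- character(0)
  for (og in ogids) {
    for (sp in species[copy[og, ] > 0]) {
      n <- copy[og, sp]
      prot_og <- c(prot_og, rep(og, n))
      prot_sp <- c(prot_sp, rep(sp, n))
      prot_id <- c(prot_id, sprintf("%s.%s.p%02d", sp, og, seq_len(n)))
    }
  }
  lens <- sample(seq(config$seq_len_range[1], config$seq_len_range[2]),
                 length(prot_id), replace = TRUE)
  seqs <- vapply(seq_along(prot_id), function(i)
    random_sequence(lens[i], charge_class[[prot_og[i]]]), character(1))
  proteins <- data.frame(protein_id = prot_id, species_id = prot_sp,
                         og_id = prot_og, sequence = seqs,
                         stringsAsFactors = FALSE)
  ogs <- orthogroup_table(prot_og, prot_id, prot_sp)

  # KO labels and BRITE categories
  n_ann <- round(config$ko_annotated_og_fraction * length(ogids))
  annotated_ogs <- sort(sample(ogids, n_ann), method = "radix")
  og_ko <- stats::setNames(rep(NA_character_, length(ogids)), ogids)
  og_ko[annotated_ogs] <- sprintf("K%05d", seq_len(n_ann))
  decoys <- sprintf("K9%04d", seq_len(50))
  categories <- c("Photosynthesis", "Carbon metabolism", "Lipid metabolism",
                  "Protein synthesis and folding", "Membrane trafficking",
                  "Mitochondrial biogenesis", "RNA metabolism", "Enzymes")
  all_kos <- c(og_ko[annotated_ogs], decoys)
  brite_map <- stats::setNames(
    rep(categories, length.out = length(all_kos)), all_kos)
  ko_prot <- character(0); ko_val <- character(0)
  for (i in seq_len(nrow(proteins))) {
    planted <- og_ko[[proteins$og_id[i]]]
    if (is.na(planted)) next
    if (stats::runif(1) < config$koid_missing_fraction) next
    ko <- if (stats::runif(1) < config$ko_noise) sample(decoys, 1L) else planted
    ko_prot <- c(ko_prot, proteins$protein_id[i])
    ko_val <- c(ko_val, ko)
  }
  ko_map <- stats::setNames(ko_val, ko_prot)

  # domain hits: RNA-metabolism members positive with configured probability,
  # plus out-of-screen decoy hits on a few background proteins
  accs <- ppr_mterf_accessions()
  hit_prot <- character(0); hit_acc <- character(0)
  for (og in rna) {
    members <- proteins$protein_id[proteins$og_id == og]
    pos <- members[stats::runif(length(members)) <
                     config$domain_positive_fraction]
    if (length(pos)) {
      hit_prot <- c(hit_prot, pos)
      hit_acc <- c(hit_acc, sample(accs, length(pos), replace = TRUE))
    }
  }
  bg <- proteins$protein_id[!proteins$og_id %in% rna]
  decoy_prot <- sample(bg, min(10L, length(bg)))
  tbl_lines <- c(
    "#                                                               --- full sequence ---",
    "# target name        accession  query name           accession    E-value  score  bias",
    "#------------------- ---------- -------------------- ---------- --------- ------ -----",
    sprintf("%s - %s - %s.17 1e-20 55.0 0.1", hit_prot,
            ifelse(hit_acc == "PF02536", "mTERF", "PPR"), hit_acc),
    sprintf("%s - decoy - PF99999.1 1e-5 12.0 0.0", decoy_prot))
  domain_truth <- unique(data.frame(protein_id = hit_prot, accession = hit_acc,
                                    stringsAsFactors = FALSE))

  # experimental proteome lists: every designated POG/MOG contributes >= 1
  # protein from a reference species where it is present
  sample_one <- function(og) {
    for (ref in reference_species) {
      cand <- proteins$protein_id[proteins$og_id == og &
                                    proteins$species_id == ref]
      if (length(cand)) {
        return(data.frame(protein_id = cand[sample.int(length(cand), 1L)],
                          reference_species = ref, stringsAsFactors = FALSE))
      }
    }
    stop(sprintf("designated organelle orthogroup %s absent from reference species", og))
  }
  exp_rows <- list()
  for (og in pogs) {
    r <- sample_one(og); r$organelle <- "plastid"; exp_rows[[length(exp_rows) + 1L]] <- r
  }
  for (og in mogs) {
    r <- sample_one(og); r$organelle <- "mitochondrion"; exp_rows[[length(exp_rows) + 1L]] <- r
  }
  experimental_df <- do.call(rbind, exp_rows)
  experimental_df <- experimental_df[
    order(experimental_df$organelle, experimental_df$reference_species,
          experimental_df$protein_id, method = "radix"),
    c("protein_id", "organelle", "reference_species")]

  # ---- write everything ------------------------------------------------
  write_orthogroups_tsv(ogs, file.path(out_dir, "orthogroups.tsv"), species)
  for (sp in species) {
    write_fasta(proteins[proteins$species_id == sp, , drop = FALSE],
                file.path(out_dir, "proteomes", paste0(sp, ".faa")))
  }
  write_tsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_tsv(data.frame(species_id = lineages$species_id,
                       lineage = lineages$lineage),
            file.path(out_dir, "lineages.tsv"))
  write_tsv(data.frame(protein_id = names(ko_map), koid = unname(ko_map)),
            file.path(out_dir, "ko_map.tsv"))
  write_tsv(data.frame(koid = names(brite_map), category = unname(brite_map)),
            file.path(out_dir, "brite_map.tsv"))
  ov <- default_overrides()
  write_tsv(data.frame(raw = names(ov), final = unname(ov)),
            file.path(out_dir, "overrides.tsv"))
  writeLines(tbl_lines, file.path(out_dir, "domains.tblout"), useBytes = TRUE)
  write_tsv(experimental_df, file.path(out_dir, "experimental.tsv"))
  writeLines(write_newick(tree), file.path(out_dir, "tree.nwk"),
             useBytes = TRUE)

  gt_dir <- file.path(out_dir, "ground_truth")
  write_matrix_tsv(st$states, file.path(gt_dir, "states.tsv"))
  write_tsv(data.frame(node_name = node_name(tree),
                       tip_signature = clade_signature(tree)),
            file.path(gt_dir, "nodes.tsv"))
  write_tsv(st$events, file.path(gt_dir, "events.tsv"))
  write_tsv(data.frame(og_id = ogids,
                       is_pog = ogids %in% pogs,
                       is_mog = ogids %in% mogs,
                       is_rna = ogids %in% rna,
                       koid = unname(og_ko),
                       charge_class = unname(charge_class[ogids])),
            file.path(gt_dir, "og_truth.tsv"))
  manifest <- list(
    generator = "orgatlas::simulate_dataset",
    seed = config$seed,
    config = config[setdiff(names(config), "lineages")],
    lineages = config$lineages,
    reference_species = reference_species)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(tree = tree, states = st$states, events = st$events,
                 presence = presence, copy = copy, ogs = ogs,
                 proteins = proteins, lineages = lineages, ko_map = ko_map,
                 brite_map = brite_map, og_ko = og_ko,
                 domain_hits = domain_truth,
                 experimental = experimental_df,
                 pogs = pogs, mogs = mogs, dual = dual, rna = rna,
                 charge_class = charge_class,
                 reference_species = reference_species))
}
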