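#' Derive default named-ancestor clade definitions from a lineage map
#'
#' One crown ancestor per lineage with at least two species, plus composite
#' ancestors when their lineages are sampled: the green crown
#' (Chloroplastida), the zygnematophyceae + embryophyte split (ZE) and the
#' Archaeplastida (green + rhodophyte + glaucophyte).
#'
#' @param lineages \code{\link{lineage_map}}.
#' @return Named list: ancestor name -> tip set.
#' @export
default_clade_defs <- function(lineages) {
  defs <- list()
  for (lab in unique(lineages$lineage)) {
    sp <- lineages$species_id[lineages$lineage == lab]
    if (length(sp) >= 2L) defs[[paste0(lab, "_crown")]] <- sp
  }
  green <- lineages$species_id[lineages$is_green]
  if (length(green) >= 2L) defs[["Chloroplastida"]] <- green
  ze <- lineages$species_id[lineages$lineage %in%
                              c("zygnematophyceae", "embryophyte")]
  if (length(unique(lineages$lineage[lineages$species_id %in% ze])) == 2L) {
    defs[["ZE"]] <- ze
  }
  arch <- lineages$species_id[lineages$is_green |
                                lineages$lineage %in%
                                c("rhodophyte", "glaucophyte")]
  if (length(arch) >= 2L && length(arch) > length(green)) {
    defs[["Archaeplastida"]] <- arch
  }
  defs
}

#' Run the whole atlas pipeline on a set of input files
#'
#' Classification (GOG/core GOG/POG/MOG), majority-rule annotation, tree
#' rooting, ancestral presence/absence reconstruction of the organelle
#' orthogroups, gain calling across the threshold sweep, domain and charge
#' screens, and a plain-text report. All outputs are TSV/newick/JSON with
#' deterministic ordering; re-running with identical inputs and parameters
#' yields byte-identical files.
#'
#' @param inputs Named list of paths: \code{orthogroups}, \code{proteome_dir},
#'   \code{lineages}, \code{ko_map}, \code{brite_map}, \code{overrides},
#'   \code{domains}, \code{experimental}, \code{tree}.
#' @param out_dir Output directory (created).
#' @param params \code{\link{atlas_params}}.
#' @param rooting \code{"mad"} (default), \code{"outgroup"} or \code{"asis"}
#'   (tree already rooted).
#' @param outgroup_tips Tips for \code{rooting = "outgroup"}.
#' @param clade_defs Named list of ancestor tip sets; default derived from the
#'   lineage map via \code{\link{default_clade_defs}}.
#' @param rate_mode Passed to \code{\link{asr_all}}.
#' @return (invisibly) list of in-memory results.
#' @export
run_atlas <- function(inputs, out_dir, params = atlas_params(),
                      rooting = c("mad", "outgroup", "asis"),
                      outgroup_tips = NULL, clade_defs = NULL,
                      rate_mode = "per_og") {
  rooting <- match.arg(rooting)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  ogs <- read_orthogroups_tsv(inputs$orthogroups)
  lineages <- read_lineage_map(inputs$lineages)
  species <- lineages$species_id
  faa <- list.files(inputs$proteome_dir, pattern = "\\.faa$",
                    full.names = TRUE)
  faa <- faa[order(basename(faa), method = "radix")]
  proteins <- do.call(rbind, lapply(faa, function(f)
    read_fasta(f, species_id = sub("\\.faa$", "", basename(f)))))
  ko_map <- read_ko_map(inputs$ko_map)
  brite_map <- read_map_tsv(inputs$brite_map)
  overrides <- read_map_tsv(inputs$overrides)
  hits <- read_domain_tblout(inputs$domains, ppr_mterf_accessions())
  experimental <- read_experimental_sets(inputs$experimental)
  tree_in <- parse_newick(readLines(inputs$tree, warn = FALSE))

  presence <- build_presence_matrix(ogs, species)
  copy <- build_copy_number_matrix(ogs, species)
  gogs <- select_gogs(presence, lineages, params)
  core <- select_core_gogs(gogs, presence, lineages, params)
  org <- select_organelle_ogs(ogs, experimental)
  organelle_ogs <- sort(unique(c(org$pog_ids, org$mog_ids)), method = "radix")
  annotations <- annotate_orthogroups(ogs, ko_map, brite_map, overrides)

  rooted <- switch(rooting,
    mad = mad_root(tree_in)$tree,
    outgroup = root_on_outgroup(tree_in, outgroup_tips),
    asis = {
      if (!ape::is.rooted(tree_in)) stop("rooting = 'asis' needs a rooted tree")
      tree_in
    })
  if (is.null(clade_defs)) clade_defs <- default_clade_defs(lineages)
  ancestors <- resolve_ancestors(rooted, clade_defs)

  org_presence <- presence[organelle_ogs, , drop = FALSE]
  ast <- asr_all(org_presence, rooted, params, rate_mode = rate_mode)
  gains <- lapply(params$tau_sweep, function(tau)
    call_gains(ast, ancestors, tau = tau,
               parent_rule = params$gain_parent_rule,
               root_rule = "present_at_root"))
  names(gains) <- sprintf("%.2f", params$tau_sweep)

  screen <- domain_screen(ogs[ogs$og_id %in% organelle_ogs, , drop = FALSE],
                          hits, ppr_mterf_accessions(),
                          threshold = params$domain_fraction_threshold,
                          comparator = params$domain_comparator)
  flagged <- screen$og_id[screen$flagged]
  dommat <- domain_presence_matrix(flagged, ogs, hits, species)
  dual <- dual_targeting_report(org$pog_ids, org$mog_ids, ogs, proteins,
                                window = params$nterm_window)

  # ---- outputs ---------------------------------------------------------
  write_tsv(data.frame(og_id = gogs), "gogs.tsv")
  write_tsv(data.frame(og_id = core), "core_gogs.tsv")
  write_tsv(data.frame(og_id = org$pog_ids), "pogs.tsv")
  write_tsv(data.frame(og_id = org$mog_ids), "mogs.tsv")
  write_tsv(org$provenance, "organelle_provenance.tsv")
  write_tsv(species_summary(organelle_ogs, presence, copy),
            "summary_per_species.tsv")
  write_tsv(as.data.frame(annotations), "annotations.tsv")
  writeLines(write_newick(rooted), file.path(out_dir, "rooted_tree.nwk"),
             useBytes = TRUE)
  anc_out <- ancestors
  anc_out$tip_signature <- clade_signature(rooted)[ancestors$node]
  write_tsv(anc_out, "ancestors.tsv")
  write_matrix_tsv(ast$posteriors, file.path(out_dir, "posteriors.tsv"))
  write_tsv(ast$rates, "rates.tsv")
  for (nm in names(gains)) {
    g <- gains[[nm]]
    rows <- do.call(rbind, c(list(
      data.frame(ancestor = character(0), og_id = character(0))),
      lapply(names(g$gains), function(a)
        if (length(g$gains[[a]]))
          data.frame(ancestor = a, og_id = g$gains[[a]],
                     stringsAsFactors = FALSE))))
    write_tsv(rows, sprintf("gains_tau%s.tsv", nm))
    if (!is.null(g$present_at_root)) {
      write_tsv(data.frame(og_id = g$present_at_root),
                sprintf("present_at_root_tau%s.tsv", nm))
    }
  }
  write_tsv(as.data.frame(screen), "screen_domains.tsv")
  write_matrix_tsv(dommat * 1L, file.path(out_dir, "domain_presence.tsv"))
  write_tsv(dual, "dual_targeting.tsv")

  manifest <- list(
    tool = "orgatlas::run_atlas",
    version = as.character(utils::packageVersion("orgatlas")),
    params = unclass(params),
    rooting = rooting,
    rate_mode = rate_mode,
    inputs = lapply(inputs, basename))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  res <- list(presence = presence, copy = copy, gogs = gogs, core_gogs = core,
              pog_ids = org$pog_ids, mog_ids = org$mog_ids,
              annotations = annotations, tree = rooted,
              ancestors = ancestors, ast = ast, gains = gains,
              screen = screen, domain_presence = dommat, dual = dual,
              params = params)
  atlas_report(out_dir)
  invisible(res)
}

#' Seeded end-to-end demo: simulate a dataset and run the full pipeline
#'
#' @param seed Integer seed (drives the whole synthetic world).
#' @param out_dir Output directory; fixture under \code{fixture/}, results
#'   under \code{results/}.
#' @param config Optional \code{\link{sim_config}} (its seed is overridden).
#' @param params \code{\link{atlas_params}}.
#' @return (invisibly) the \code{\link{run_atlas}} result.
#' @export
run_demo <- function(seed = 42L, out_dir, config = NULL,
                     params = atlas_params()) {
  if (is.null(config)) config <- sim_config(seed = as.integer(seed))
  else config$seed <- as.integer(seed)
  fixture <- file.path(out_dir, "fixture")
  simulate_dataset(config, fixture)
  inputs <- list(
    orthogroups = file.path(fixture, "orthogroups.tsv"),
    proteome_dir = file.path(fixture, "proteomes"),
    lineages = file.path(fixture, "lineages.tsv"),
    ko_map = file.path(fixture, "ko_map.tsv"),
    brite_map = file.path(fixture, "brite_map.tsv"),
    overrides = file.path(fixture, "overrides.tsv"),
    domains = file.path(fixture, "domains.tblout"),
    experimental = file.path(fixture, "experimental.tsv"),
    tree = file.path(fixture, "tree.nwk"))
  invisible(run_atlas(inputs, file.path(out_dir, "results"), params = params))
}

#' Plain-text summary report of a pipeline output directory
#'
#' Every number is read back from the stage TSVs, so the report is traceable
#' to the on-disk results cell by cell.
#'
#' @param out_dir A \code{\link{run_atlas}} output directory.
#' @return Character vector of report lines (also written to
#'   \code{report.txt}).
#' @export
atlas_report <- function(out_dir) {
  rd <- function(name) utils::read.delim(file.path(out_dir, name), sep = "\t",
                                         colClasses = "character", quote = "")
  lines <- c("orgatlas run summary", "====================")
  counts <- vapply(c("gogs.tsv", "core_gogs.tsv", "pogs.tsv", "mogs.tsv"),
                   function(f) nrow(rd(f)), integer(1))
  lines <- c(lines, sprintf("%-10s %d", c("GOGs:", "core GOGs:", "POGs:",
                                          "MOGs:"), counts))
  ann <- rd("annotations.tsv")
  n_ann <- sum(ann$category != "unannotated")
  lines <- c(lines, sprintf("annotated orthogroups: %d / %d", n_ann,
                            nrow(ann)))
  gain_files <- sort(list.files(out_dir, pattern = "^gains_tau.*\\.tsv$"))
  for (f in gain_files) {
    g <- rd(f)
    lines <- c(lines, sprintf("-- %s --", f))
    if (nrow(g) == 0L) {
      lines <- c(lines, "  (no gains called)")
    } else {
      tab <- table(g$ancestor)
      lines <- c(lines, sprintf("  %-28s %d", names(tab), as.integer(tab)))
    }
  }
  scr <- rd("screen_domains.tsv")
  lines <- c(lines, sprintf("RNA-metabolism flagged orthogroups: %d",
                            sum(scr$flagged == "TRUE")))
  dual <- rd("dual_targeting.tsv")
  lines <- c(lines, sprintf("POG/MOG dual orthogroups: %d", nrow(dual)))
  sm <- rd("summary_per_species.tsv")
  lines <- c(lines, "per-species organelle summary (PN/ON/P_per_O):",
             sprintf("  %-24s %4s %4s %6s", sm$species_id, sm$PN, sm$ON,
                     sm$P_per_O))
  writeLines(lines, file.path(out_dir, "report.txt"), useBytes = TRUE)
  invisible(lines)
}
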