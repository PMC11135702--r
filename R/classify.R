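#' Presence and copy-number matrices from an orthogroup table
#'
#' Rows are orthogroups (sorted), columns the supplied species order. A
#' presence cell is 1 iff the orthogroup has at least one member protein in
#' that species; a copy-number cell counts the member proteins. Binarizing the
#' copy-number matrix reproduces the presence matrix exactly.
#'
#' @param ogs An \code{\link{orthogroup_table}}.
#' @param species Ordered, duplicate-free species vector; must cover every
#'   species occurring in \code{ogs}.
#' @return Integer matrix og x species.
#' @export
build_copy_number_matrix <- function(ogs, species = og_species(ogs)) {
  species <- as.character(species)
  if (anyDuplicated(species)) stop("species list contains duplicates")
  missing <- setdiff(unique(ogs$species_id), species)
  if (length(missing)) {
    stop(sprintf("species in table but not in species list: %s",
                 paste(missing, collapse = ", ")))
  }
  ids <- og_ids(ogs)
  m <- matrix(0L, nrow = length(ids), ncol = length(species),
              dimnames = list(ids, species))
  if (nrow(ogs)) {
    tab <- table(factor(ogs$og_id, levels = ids),
                 factor(ogs$species_id, levels = species))
    m[] <- as.integer(tab)
  }
  m
}

#' @rdname build_copy_number_matrix
#' @export
build_presence_matrix <- function(ogs, species = og_species(ogs)) {
  m <- build_copy_number_matrix(ogs, species)
  m[] <- as.integer(m > 0L)
  m
}

# Count, per orthogroup row, the distinct green and non-green species with
# presence. Species count once regardless of copy number.
green_counts <- function(presence, lineages) {
  sp <- colnames(presence)
  unknown <- setdiff(sp, lineages$species_id)
  if (length(unknown)) {
    stop(sprintf("species without lineage label: %s",
                 paste(unknown, collapse = ", ")))
  }
  isg <- lineages$is_green[match(sp, lineages$species_id)]
  pres <- presence > 0L
  list(green = as.integer(pres %*% isg),
       nongreen = as.integer(pres %*% !isg),
       n_green_species = sum(isg))
}

#' Select green orthogroups (GOGs)
#'
#' An orthogroup is a GOG when it occurs in at least
#' \code{params$min_green_species} distinct Chloroplastida species and in
#' strictly fewer than \code{params$max_nongreen_species} species outside the
#' Chloroplastida.
#'
#' @param presence Presence matrix (og x species).
#' @param lineages A \code{\link{lineage_map}} covering all matrix species.
#' @param params \code{\link{atlas_params}}.
#' @return Character vector of selected og ids (sorted).
#' @export
select_gogs <- function(presence, lineages, params = atlas_params()) {
  cnt <- green_counts(presence, lineages)
  sel <- cnt$green >= params$min_green_species &
    cnt$nongreen < params$max_nongreen_species
  sort(rownames(presence)[sel])
}

#' Select core GOGs
#'
#' A GOG is core when it occurs in strictly more than
#' \code{params$core_fraction} of the green species present in the analyzed
#' matrix (denominator: green species among the matrix columns).
#'
#' @param gogs Character vector of GOG ids (subset of matrix rows).
#' @inheritParams select_gogs
#' @return Character vector of core GOG ids (sorted).
#' @export
select_core_gogs <- function(gogs, presence, lineages,
                             params = atlas_params()) {
  cnt <- green_counts(presence, lineages)
  if (cnt$n_green_species == 0L) {
    stop("no green species in the presence matrix; core-GOG fraction undefined")
  }
  frac <- cnt$green / cnt$n_green_species
  names(frac) <- rownames(presence)
  sort(intersect(gogs, rownames(presence)[frac > params$core_fraction]))
}

#' Select plastid and mitochondrial orthogroups (POGs/MOGs)
#'
#' An orthogroup is a POG when it contains at least one protein from any
#' experimentally verified plastid proteome, and a MOG analogously for
#' mitochondrial proteomes. The two sets may overlap. Experimental protein ids
#' with no orthogroup membership are collected, not fatal.
#'
#' @param ogs An \code{\link{orthogroup_table}}.
#' @param experimental List of \code{\link{experimental_set}} objects.
#' @return List with \code{pog_ids}, \code{mog_ids} (sorted character
#'   vectors), \code{provenance} (data.frame og_id, protein_id,
#'   reference_species, organelle: which protein triggered membership) and
#'   \code{unmatched} (experimental ids absent from the table).
#' @export
select_organelle_ogs <- function(ogs, experimental) {
  prov <- data.frame(og_id = character(0), protein_id = character(0),
                     reference_species = character(0),
                     organelle = character(0), stringsAsFactors = FALSE)
  unmatched <- character(0)
  for (xs in experimental) {
    stopifnot(inherits(xs, "experimental_set"))
    hit <- ogs[ogs$protein_id %in% xs$protein_ids, , drop = FALSE]
    unmatched <- c(unmatched, setdiff(xs$protein_ids, hit$protein_id))
    if (nrow(hit)) {
      prov <- rbind(prov, data.frame(
        og_id = hit$og_id, protein_id = hit$protein_id,
        reference_species = xs$reference_species, organelle = xs$organelle,
        stringsAsFactors = FALSE))
    }
  }
  prov <- prov[order(prov$og_id, prov$organelle, prov$protein_id), ,
               drop = FALSE]
  rownames(prov) <- NULL
  list(pog_ids = sort(unique(prov$og_id[prov$organelle == "plastid"])),
       mog_ids = sort(unique(prov$og_id[prov$organelle == "mitochondrion"])),
       provenance = prov,
       unmatched = sort(unique(unmatched)))
}

#' Per-species summary of an orthogroup set
#'
#' For each species: PN, the total protein count across the set's orthogroups;
#' ON, the number of the set's orthogroups present; and P/O = PN/ON (0 when
#' ON = 0).
#'
#' @param ogset Character vector of og ids (subset of matrix rows).
#' @param presence Presence matrix.
#' @param copy Copy-number matrix with identical dimnames.
#' @return data.frame species_id, PN, ON, P_per_O, ordered as the matrix
#'   columns.
#' @export
species_summary <- function(ogset, presence, copy) {
  stopifnot(identical(dimnames(presence), dimnames(copy)),
            all(ogset %in% rownames(presence)))
  p <- presence[ogset, , drop = FALSE]
  cc <- copy[ogset, , drop = FALSE]
  PN <- colSums(cc)
  ON <- colSums(p)
  data.frame(species_id = colnames(presence), PN = as.integer(PN),
             ON = as.integer(ON),
             P_per_O = ifelse(ON == 0, 0, PN / ON),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Clamp a copy-number matrix for heat-map display
#'
#' Display-only transform: values above the cap are shown as the cap (the
#' darkest shade); underlying data are never modified.
#' @param copy Copy-number matrix.
#' @param cap Display cap (default 50).
#' @return Matrix with values clamped at \code{cap}.
#' @export
display_clamp <- function(copy, cap = 50L) pmin(copy, cap)
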