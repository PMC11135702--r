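#' Orthogroup membership table
#'
#' The raw substrate of the atlas: a long-format table mapping orthogroup ids
#' to member proteins and their species of origin. Each protein belongs to at
#' most one orthogroup and one species.
#'
#' @param og_id,protein_id,species_id Character vectors of equal length.
#' @return A data.frame of class \code{orthogroup_table} with columns
#'   \code{og_id}, \code{protein_id}, \code{species_id}, sorted by
#'   (og_id, species_id, protein_id).
#' @export
orthogroup_table <- function(og_id, protein_id, species_id) {
  og_id <- as.character(og_id)
  protein_id <- as.character(protein_id)
  species_id <- as.character(species_id)
  stopifnot(length(og_id) == length(protein_id),
            length(og_id) == length(species_id))
  if (any(!nzchar(protein_id)) || any(!nzchar(species_id)) ||
      any(!nzchar(og_id))) {
    stop("orthogroup_table: empty og/protein/species ids are not allowed")
  }
  dup <- duplicated(protein_id)
  if (any(dup)) {
    offender <- protein_id[dup][1]
    other <- species_id[protein_id == offender]
    if (length(unique(other)) > 1L) {
      stop(sprintf("protein '%s' is listed under more than one species (%s)",
                   offender, paste(unique(other), collapse = ", ")))
    }
    stop(sprintf("protein '%s' is listed more than once", offender))
  }
  df <- data.frame(og_id = og_id, protein_id = protein_id,
                   species_id = species_id, stringsAsFactors = FALSE)
  df <- df[order(df$og_id, df$species_id, df$protein_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("orthogroup_table", "data.frame")
  df
}

#' Species-to-lineage map
#'
#' Assigns every species a lineage label from a controlled vocabulary and a
#' derived flag marking membership in the Chloroplastida (green lineage).
#'
#' @param species_id Character vector of species ids.
#' @param lineage Character vector of lineage labels.
#' @param green_labels Labels counted as Chloroplastida.
#' @return data.frame of class \code{lineage_map} with columns
#'   \code{species_id}, \code{lineage}, \code{is_green}.
#' @export
lineage_map <- function(species_id, lineage,
                        green_labels = c("chlorophyte", "prasinodermophyte",
                                         "streptophyte_alga",
                                         "zygnematophyceae", "embryophyte")) {
  species_id <- as.character(species_id)
  lineage <- as.character(lineage)
  stopifnot(length(species_id) == length(lineage), !anyDuplicated(species_id))
  df <- data.frame(species_id = species_id, lineage = lineage,
                   is_green = lineage %in% green_labels,
                   stringsAsFactors = FALSE)
  df <- df[order(df$species_id), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "green_labels") <- green_labels
  class(df) <- c("lineage_map", "data.frame")
  df
}

#' Experimentally verified organelle proteome
#'
#' A set of protein ids from one reference species whose localization to one
#' organelle has experimental support; used to seed plastid/mitochondrial
#' orthogroup classification.
#'
#' @param organelle \code{"plastid"} or \code{"mitochondrion"}.
#' @param reference_species Species id the proteins belong to.
#' @param protein_ids Character vector (deduplicated).
#' @return list of class \code{experimental_set}.
#' @export
experimental_set <- function(organelle = c("plastid", "mitochondrion"),
                             reference_species, protein_ids) {
  organelle <- match.arg(organelle)
  stopifnot(nzchar(reference_species))
  structure(list(organelle = organelle,
                 reference_species = as.character(reference_species),
                 protein_ids = sort(unique(as.character(protein_ids)))),
            class = "experimental_set")
}

# Distinct species ids occurring in an orthogroup table, sorted.
og_species <- function(ogs) sort(unique(ogs$species_id))

# Distinct orthogroup ids, sorted.
og_ids <- function(ogs) sort(unique(ogs$og_id))
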