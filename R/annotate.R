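#' Majority-rule KO assignment for one orthogroup
#'
#' Member proteins vote with their KO identifiers; missing annotations
#' (\code{NA}) are excluded from the vote. The plurality winner is assigned;
#' ties are broken deterministically by the lexicographically smallest KO id.
#' If no member carries a KO id the orthogroup stays unassigned.
#'
#' @param koids Character vector of member KO ids, \code{NA} for missing.
#' @return List with \code{koid} (character or \code{NA}) and \code{counts}
#'   (named integer vector of votes, decreasing then lexicographic).
#' @export
majority_koid <- function(koids) {
  koids <- koids[!is.na(koids) & nzchar(koids)]
  if (!length(koids)) {
    return(list(koid = NA_character_, counts = integer(0)))
  }
  tab <- table(koids)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  ord <- order(-counts, names(counts))
  counts <- counts[ord]
  list(koid = names(counts)[1L], counts = counts)
}

#' Map a KO id to a functional category
#'
#' Applies the BRITE category map, then an optional curation override table
#' remapping uninformative raw categories (such as "Enzymes") to final ones.
#' Unmapped KO ids (or missing ids) yield \code{"unannotated"}.
#'
#' @param koid KO id or \code{NA}.
#' @param brite_map Named character vector koid -> raw category.
#' @param overrides Named character vector raw category -> final category.
#' @return Single category string.
#' @export
categorize <- function(koid, brite_map, overrides = default_overrides()) {
  if (is.na(koid) || !koid %in% names(brite_map)) return("unannotated")
  raw <- unname(brite_map[[koid]])
  if (raw %in% names(overrides)) unname(overrides[[raw]]) else raw
}

#' Default BRITE-category curation overrides
#'
#' Minimal shipped table remapping generic BRITE labels that would otherwise
#' dominate compositions; editable/replaceable by the user.
#' @return Named character vector raw -> final.
#' @export
default_overrides <- function() {
  c("Enzymes" = "unannotated-generic",
    "Exosome" = "Protein synthesis and folding",
    "Exosomes" = "Protein synthesis and folding")
}

#' Annotate a whole orthogroup table
#'
#' @param ogs An \code{\link{orthogroup_table}}.
#' @param ko_map Named character vector protein_id -> koid (missing proteins
#'   simply absent).
#' @param brite_map Named character vector koid -> raw category.
#' @param overrides Named character vector raw -> final category.
#' @return data.frame of class \code{annotation_result}: og_id, koid,
#'   n_votes, n_members, category.
#' @export
annotate_orthogroups <- function(ogs, ko_map, brite_map,
                                 overrides = default_overrides()) {
  ids <- og_ids(ogs)
  res <- lapply(ids, function(og) {
    members <- ogs$protein_id[ogs$og_id == og]
    kos <- unname(ko_map[members])           # NA where not annotated
    mk <- majority_koid(kos)
    data.frame(og_id = og, koid = mk$koid,
               n_votes = if (length(mk$counts)) mk$counts[[1L]] else 0L,
               n_members = length(members),
               category = categorize(mk$koid, brite_map, overrides),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(og_id = character(0), koid = character(0),
                      n_votes = integer(0), n_members = integer(0),
                      category = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("annotation_result", "data.frame")
  out
}

#' Functional category composition of an orthogroup set
#'
#' Counts and proportions of final categories among the annotated members of
#' the set (proportions normalize over annotated orthogroups and sum to 1),
#' plus the annotated fraction of the whole set.
#'
#' @param ids Character vector of og ids (nonempty).
#' @param annotations An \code{annotation_result}.
#' @return List with \code{composition} (data.frame category, count,
#'   proportion) and \code{annotated_fraction}.
#' @export
category_composition <- function(ids, annotations) {
  if (!length(ids)) stop("category_composition: empty orthogroup set")
  ann <- annotations[annotations$og_id %in% ids, , drop = FALSE]
  annotated <- ann[!is.na(ann$koid) & ann$category != "unannotated", ,
                   drop = FALSE]
  frac <- nrow(annotated) / length(ids)
  if (!nrow(annotated)) {
    comp <- data.frame(category = character(0), count = integer(0),
                       proportion = numeric(0), stringsAsFactors = FALSE)
  } else {
    tab <- sort(table(annotated$category), decreasing = TRUE)
    comp <- data.frame(category = names(tab), count = as.integer(tab),
                       proportion = as.integer(tab) / nrow(annotated),
                       stringsAsFactors = FALSE)
  }
  list(composition = comp, annotated_fraction = frac)
}
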