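#' Domain-fraction screen for one orthogroup set
#'
#' A member protein counts as domain-positive when it has at least one hit to
#' any screen accession; an orthogroup is flagged as an RNA-metabolism
#' orthogroup when the fraction of domain-positive members exceeds the
#' threshold (strictly by default; ">=" selectable, both phrasings occur in
#' the source workflow).
#'
#' @param ogs An \code{\link{orthogroup_table}} restricted (or not) to the
#'   orthogroups of interest.
#' @param hits A \code{domain_hit_table} (see
#'   \code{\link{read_domain_tblout}}).
#' @param screen_accessions Accessions defining the screen (unversioned).
#' @param threshold Fraction threshold (default 0.60).
#' @param comparator \code{"gt"} (strict) or \code{"ge"}.
#' @return data.frame of class \code{domain_screen_result}: og_id, n_members,
#'   n_with_domain, fraction, flagged.
#' @export
domain_screen <- function(ogs, hits,
                          screen_accessions = ppr_mterf_accessions(),
                          threshold = 0.60, comparator = c("gt", "ge")) {
  comparator <- match.arg(comparator)
  if (!nrow(ogs)) stop("domain_screen: empty orthogroup table")
  acc <- sub("\\.\\d+$", "", screen_accessions)
  pos <- unique(hits$protein_id[hits$accession %in% acc])
  ids <- og_ids(ogs)
  rows <- lapply(ids, function(og) {
    members <- ogs$protein_id[ogs$og_id == og]
    nw <- sum(members %in% pos)
    fr <- nw / length(members)
    data.frame(og_id = og, n_members = length(members), n_with_domain = nw,
               fraction = fr,
               flagged = if (comparator == "gt") fr > threshold
                         else fr >= threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("domain_screen_result", "data.frame")
  out
}

#' Screen accessions for PPR and mTERF domains
#' @return Character vector of Pfam accessions.
#' @export
ppr_mterf_accessions <- function() {
  c("PF01535", "PF12854", "PF13041", "PF13812", "PF02536")
}

#' Per-species domain presence across flagged orthogroups
#'
#' A cell (species, og) is TRUE iff at least one member of the orthogroup in
#' that species carries a screen-domain hit. This deliberately differs from
#' orthogroup presence: a species may harbor the family while none of its
#' members carries the domain.
#'
#' @param flagged_ogs Character vector of og ids.
#' @param ogs \code{\link{orthogroup_table}}.
#' @param hits \code{domain_hit_table}.
#' @param species Ordered species vector for the rows.
#' @param screen_accessions Accessions defining the screen.
#' @return Logical matrix species x og.
#' @export
domain_presence_matrix <- function(flagged_ogs, ogs, hits,
                                   species = og_species(ogs),
                                   screen_accessions = ppr_mterf_accessions()) {
  acc <- sub("\\.\\d+$", "", screen_accessions)
  pos <- unique(hits$protein_id[hits$accession %in% acc])
  m <- matrix(FALSE, length(species), length(flagged_ogs),
              dimnames = list(species, flagged_ogs))
  sub <- ogs[ogs$og_id %in% flagged_ogs & ogs$protein_id %in% pos, ,
             drop = FALSE]
  if (nrow(sub)) {
    m[cbind(match(sub$species_id, species), match(sub$og_id, flagged_ogs))] <- TRUE
  }
  m
}

#' Net charge of a protein N-terminus
#'
#' Counts K and R as +1 and D and E as -1 over the first \code{window}
#' residues (the whole sequence when shorter); histidine is neutral and
#' terminus charges are ignored. The initiator methionine is included.
#'
#' @param sequence Amino-acid string (nonempty).
#' @param window Number of N-terminal residues (default 20).
#' @return Integer net charge.
#' @export
nterm_charge <- function(sequence, window = 20L) {
  stopifnot(nzchar(sequence))
  prefix <- substr(sequence, 1L, min(window, nchar(sequence)))
  aa <- strsplit(prefix, "", fixed = TRUE)[[1L]]
  sum(aa %in% c("K", "R")) - sum(aa %in% c("D", "E"))
}

#' Candidate dually targeted orthogroups
#'
#' Orthogroups classified as both plastid and mitochondrial, with the range of
#' member N-terminal charges as a dual-targeting-compatible signal.
#'
#' @param pog_ids,mog_ids Character vectors of classified og ids.
#' @param ogs \code{\link{orthogroup_table}}.
#' @param proteins data.frame with \code{protein_id}, \code{sequence}.
#' @param window N-terminal window for \code{\link{nterm_charge}}.
#' @return data.frame: og_id, n_members, charge_min, charge_max.
#' @export
dual_targeting_report <- function(pog_ids, mog_ids, ogs, proteins,
                                  window = 20L) {
  both <- sort(intersect(pog_ids, mog_ids), method = "radix")
  rows <- lapply(both, function(og) {
    members <- ogs$protein_id[ogs$og_id == og]
    seqs <- proteins$sequence[match(members, proteins$protein_id)]
    seqs <- seqs[!is.na(seqs)]
    ch <- vapply(seqs, nterm_charge, integer(1), window = window)
    data.frame(og_id = og, n_members = length(members),
               charge_min = if (length(ch)) min(ch) else NA_integer_,
               charge_max = if (length(ch)) max(ch) else NA_integer_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(og_id = character(0), n_members = integer(0),
                      charge_min = integer(0), charge_max = integer(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
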