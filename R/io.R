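#' Read an OrthoFinder-style Orthogroups.tsv
#'
#' First column is the orthogroup id; each remaining column is one species,
#' named in the header, holding a comma-separated list of member proteins.
#' Species identity is taken from the column header (headers are
#' authoritative); empty cells mean no members in that species.
#'
#' @param path Path to a tab-separated file.
#' @return An \code{\link{orthogroup_table}}.
#' @export
read_orthogroups_tsv <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", na.strings = NULL)
  if (ncol(raw) < 2L) stop("orthogroups file needs an OG column plus >=1 species column")
  ogid <- raw[[1L]]
  if (anyDuplicated(ogid)) {
    stop(sprintf("duplicate orthogroup id '%s' in %s",
                 ogid[duplicated(ogid)][1], path))
  }
  species <- colnames(raw)[-1L]
  out_og <- character(0); out_p <- character(0); out_s <- character(0)
  for (j in seq_along(species)) {
    cells <- raw[[j + 1L]]
    nonempty <- which(nzchar(trimws(cells)))
    for (i in nonempty) {
      prots <- trimws(strsplit(cells[i], ",", fixed = TRUE)[[1L]])
      prots <- prots[nzchar(prots)]
      out_og <- c(out_og, rep(ogid[i], length(prots)))
      out_p <- c(out_p, prots)
      out_s <- c(out_s, rep(species[j], length(prots)))
    }
  }
  orthogroup_table(out_og, out_p, out_s)
}

#' Write an orthogroup table in OrthoFinder dialect
#'
#' @param ogs An \code{\link{orthogroup_table}}.
#' @param path Output path.
#' @param species Optional ordered species vector for the columns; defaults to
#'   the sorted species present.
#' @export
write_orthogroups_tsv <- function(ogs, path, species = og_species(ogs)) {
  ids <- og_ids(ogs)
  header <- paste(c("Orthogroup", species), collapse = "\t")
  rows <- vapply(ids, function(og) {
    sub <- ogs[ogs$og_id == og, , drop = FALSE]
    cells <- vapply(species, function(s)
      paste(sort(sub$protein_id[sub$species_id == s]), collapse = ", "),
      character(1))
    paste(c(og, cells), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path, useBytes = TRUE)
}

#' Read protein sequences from FASTA
#'
#' The id token before the first whitespace becomes the protein id; sequences
#' are uppercased and a trailing stop character \code{*} is stripped.
#'
#' @param path FASTA file.
#' @param species_id Optional species id attached to every record.
#' @return data.frame with columns \code{protein_id}, \code{species_id},
#'   \code{sequence}.
#' @export
read_fasta <- function(path, species_id = NA_character_) {
  aa <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate protein id '%s' in %s", ids[duplicated(ids)][1], path))
  }
  seqs <- toupper(as.character(aa))
  seqs <- sub("\\*+$", "", seqs)
  if (any(!nzchar(seqs))) {
    stop(sprintf("empty sequence for '%s' in %s", ids[!nzchar(seqs)][1], path))
  }
  data.frame(protein_id = ids, species_id = species_id, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write protein sequences to FASTA
#' @param proteins data.frame with \code{protein_id} and \code{sequence}.
#' @param path Output path.
#' @export
write_fasta <- function(proteins, path) {
  x <- Biostrings::BStringSet(proteins$sequence)
  names(x) <- proteins$protein_id
  Biostrings::writeXStringSet(x, path)
}

#' Read a HMMER3 per-target table (\code{--tblout}) of domain hits
#'
#' Comment lines starting with \code{#} are skipped; fields are
#' whitespace-delimited with the target name in field 1 and the query
#' accession in field 5. Accession version suffixes (\code{PF01535.20}) are
#' stripped, hits outside \code{accepted_accessions} are dropped and duplicate
#' (protein, accession) pairs are collapsed.
#'
#' @param path tblout file.
#' @param accepted_accessions Character vector of unversioned accessions to
#'   keep; \code{NULL} keeps all.
#' @return data.frame of class \code{domain_hit_table} with columns
#'   \code{protein_id}, \code{accession}.
#' @export
read_domain_tblout <- function(path, accepted_accessions = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  prot <- character(0); acc <- character(0)
  for (i in which(keep)) {
    fields <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(fields) < 5L) {
      stop(sprintf("unparseable tblout line %d in %s: fewer than 5 fields", i, path))
    }
    prot <- c(prot, fields[1L])
    acc <- c(acc, sub("\\.\\d+$", "", fields[5L]))
  }
  df <- data.frame(protein_id = prot, accession = acc, stringsAsFactors = FALSE)
  if (!is.null(accepted_accessions)) {
    df <- df[df$accession %in% sub("\\.\\d+$", "", accepted_accessions), ,
             drop = FALSE]
  }
  df <- unique(df)
  df <- df[order(df$protein_id, df$accession), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("domain_hit_table", "data.frame")
  df
}

#' Write/read labeled numeric matrices as TSV
#'
#' Row labels go in the first column (header \code{id}); rows and columns are
#' written in the matrix's own order. Integer matrices round-trip bit-exactly;
#' probabilities are serialized with 15 significant digits.
#'
#' @param m Numeric matrix with dimnames.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(m, path) {
  if (any(grepl("\t", c(rownames(m), colnames(m))))) {
    stop("matrix labels must not contain tab characters")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  header <- paste(c("id", colnames(m)), collapse = "\t")
  writeLines(header, con, useBytes = TRUE)
  if (nrow(m) > 0L) {
    body <- apply(m, 1L, function(r)
      paste(format(r, digits = 15, scientific = FALSE, trim = TRUE),
            collapse = "\t"))
    writeLines(paste(rownames(m), body, sep = "\t"), con, useBytes = TRUE)
  }
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @param integer_mode Read cells as integers (exact) rather than doubles.
#' @export
read_matrix_tsv <- function(path, integer_mode = FALSE) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "")
  cn <- colnames(df)[-1L]
  m <- matrix(if (integer_mode) integer(0) else numeric(0),
              nrow = nrow(df), ncol = length(cn),
              dimnames = list(df[[1L]], cn))
  if (nrow(df) > 0L) {
    vals <- as.matrix(df[, -1L, drop = FALSE])
    m[] <- if (integer_mode) as.integer(vals) else as.numeric(vals)
  }
  m
}

#' Read a species-to-lineage TSV (columns \code{species_id}, \code{lineage})
#' @param path TSV path.
#' @param green_labels Passed to \code{\link{lineage_map}}.
#' @return A \code{\link{lineage_map}}.
#' @export
read_lineage_map <- function(path,
                             green_labels = formals(lineage_map)$green_labels) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  lineage_map(df$species_id, df$lineage, green_labels = eval(green_labels))
}

#' Read a protein-to-KO map (columns \code{protein_id}, \code{koid})
#'
#' Proteins with no KO annotation are simply absent from the file (or have an
#' empty \code{koid} cell); missingness is represented as absence, never as a
#' sentinel string.
#' @param path TSV path.
#' @return Named character vector protein_id -> koid.
#' @export
read_ko_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  df <- df[nzchar(df$koid), , drop = FALSE]
  stats::setNames(df$koid, df$protein_id)
}

#' Read a two-column TSV into a named character vector (first -> second)
#' @param path TSV path with a header.
#' @return Named character vector.
#' @export
read_map_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  stats::setNames(df[[2L]], df[[1L]])
}

#' Read an experimental organelle proteome list
#'
#' TSV with columns \code{protein_id}, \code{organelle},
#' \code{reference_species}; one file may mix organelles.
#' @param path TSV path.
#' @return List of \code{\link{experimental_set}} objects, one per
#'   (organelle, reference_species) combination present.
#' @export
read_experimental_sets <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  keys <- unique(df[, c("organelle", "reference_species")])
  lapply(seq_len(nrow(keys)), function(i) {
    sel <- df$organelle == keys$organelle[i] &
      df$reference_species == keys$reference_species[i]
    experimental_set(keys$organelle[i], keys$reference_species[i],
                     df$protein_id[sel])
  })
}
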