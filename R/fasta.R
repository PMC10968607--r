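#' Construct a set of protein records
#'
#' A `lox_records` object is a data frame with one row per candidate LOX
#' sequence and columns `id`, `organism`, `residues` and `source`.
#'
#' @param id character vector of unique accession-like identifiers.
#' @param residues character vector of amino-acid sequences (20 standard
#'   one-letter codes plus `X`); lowercase is accepted and uppercased, gap
#'   (`-`, `.`) and stop (`*`) characters are stripped.
#' @param organism free-text description, recycled if scalar.
#' @param source provenance flag, `"user"` or `"fixture"`.
#' @return A data frame of class `lox_records`.
#' @export
protein_records <- function(id, residues, organism = "", source = "user") {
  id <- as.character(id)
  if (anyDuplicated(id)) {
    stop("duplicate record id: ", id[duplicated(id)][1L])
  }
  residues <- toupper(gsub("[-.*]", "", as.character(residues)))
  if (any(!nzchar(residues))) {
    stop("empty sequence for id: ", id[!nzchar(residues)][1L])
  }
  bad <- grepl(paste0("[^", paste(c(AA20, "X"), collapse = ""), "]"), residues)
  if (any(bad)) {
    stop("invalid residue letters in id: ", id[bad][1L])
  }
  source <- match.arg(source, c("user", "fixture"))
  out <- data.frame(
    id = id,
    organism = rep_len(as.character(organism), length(id)),
    residues = residues,
    source = source,
    stringsAsFactors = FALSE
  )
  class(out) <- c("lox_records", "data.frame")
  out
}

#' Read protein records from a FASTA file
#'
#' The header token before the first whitespace becomes the record id, the
#' remainder the organism field. Sequences are uppercased and gap/stop
#' characters removed.
#'
#' @param path path to a FASTA file.
#' @param source provenance flag stored on the records.
#' @return A `lox_records` data frame, entries in file order.
#' @export
read_fasta <- function(path, source = "user") {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  organism <- ifelse(grepl("\\s", headers),
                     sub("^\\S+\\s+", "", headers), "")
  protein_records(id, as.character(set), organism = organism, source = source)
}

#' Write protein records to a FASTA file
#'
#' @param records a `lox_records` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(inherits(records, "lox_records"))
  set <- Biostrings::AAStringSet(records$residues)
  names(set) <- ifelse(nzchar(records$organism),
                       paste(records$id, records$organism),
                       records$id)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
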