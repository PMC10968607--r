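#' Curation thresholds for candidate LOX sequences
#'
#' @param min_sites minimum number of located iron-coordination sites
#'   (out of five) a sequence must preserve. The default 3 keeps sequences
#'   preserving at least three of the five cofactor coordination residues.
#' @param min_length minimum sequence length in residues; shorter sequences
#'   are treated as fragments. The threshold is a package convention (a
#'   complete LOX domain is several hundred residues).
#' @param require_terminal_hydrophobic if `TRUE`, additionally require the
#'   fifth (hydrophobic, Ile/Leu/Val) site to be among the located sites.
#' @return A list of class `curation_config`.
#' @export
curation_config <- function(min_sites = 3L, min_length = 200L,
                            require_terminal_hydrophobic = FALSE) {
  min_sites <- as.integer(min_sites)
  min_length <- as.integer(min_length)
  stopifnot(min_sites >= 0L, min_sites <= 5L, min_length > 0L)
  structure(
    list(min_sites = min_sites, min_length = min_length,
         require_terminal_hydrophobic = require_terminal_hydrophobic),
    class = "curation_config"
  )
}

#' Filter candidate sequences by length and coordination-site completeness
#'
#' A record is kept iff its length is at least `min_length` and its
#' coordination pattern preserves at least `min_sites` of the five sites.
#' Removal reasons are assigned in the order fragment, then no detectable
#' coordination site at all (completeness 0, the operational proxy for "no
#' putative LOX domain"), then too few sites.
#'
#' @param records a `lox_records` data frame.
#' @param patterns a list of `coord_pattern` objects aligned 1:1 with
#'   `records` (same ids, e.g. from [scan_all()]).
#' @param config a [curation_config()].
#' @return A data frame of class `curation_report` with columns `id`,
#'   `decision` (`kept`, `removed_fragment`, `removed_no_domain`,
#'   `removed_few_sites`), `length` and `completeness`, plus a `counts`
#'   attribute tabulating decisions.
#' @export
filter_candidates <- function(records, patterns, config = curation_config()) {
  stopifnot(inherits(records, "lox_records"), inherits(config, "curation_config"))
  pat_ids <- vapply(patterns, function(p) p$id, character(1))
  if (!identical(sort(pat_ids), sort(records$id))) {
    stop("pattern ids do not match record ids")
  }
  patterns <- patterns[match(records$id, pat_ids)]
  len <- nchar(records$residues)
  completeness <- vapply(patterns, function(p) p$completeness, integer(1))
  t5_found <- vapply(patterns, function(p) p$sites$found[p$sites$role == "T5"],
                     logical(1))

  decision <- rep("kept", nrow(records))
  decision[completeness < config$min_sites] <- "removed_few_sites"
  if (config$require_terminal_hydrophobic) {
    decision[!t5_found] <- "removed_few_sites"
  }
  decision[completeness == 0L] <- "removed_no_domain"
  decision[len < config$min_length] <- "removed_fragment"

  out <- data.frame(
    id = records$id, decision = decision,
    length = len, completeness = completeness,
    stringsAsFactors = FALSE
  )
  counts <- table(factor(decision, levels = c(
    "kept", "removed_fragment", "removed_no_domain", "removed_few_sites"
  )))
  attr(out, "counts") <- counts
  class(out) <- c("curation_report", "data.frame")
  out
}

#' Subset records kept by a curation report
#'
#' @param records a `lox_records` data frame.
#' @param report the matching `curation_report`.
#' @return The kept subset of `records`.
#' @export
kept_records <- function(records, report) {
  keep <- report$id[report$decision == "kept"]
  out <- records[records$id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("lox_records", "data.frame")
  out
}

#' Write a curation report as TSV
#'
#' @param report a `curation_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_curation_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
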