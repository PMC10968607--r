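#' Reference annotation set for coordination-site scanning
#'
#' Anchors pair reference sequences with the 1-based positions of their five
#' iron-coordination sites (roles `H1`, `H2`, `H3`, `X4`, `T5`). Queries are
#' aligned to the best-identity reference and the annotated positions are
#' projected onto the query.
#'
#' @param records a `lox_records` data frame of reference sequences.
#' @param sites a data frame with columns `id`, `H1`, `H2`, `H3`, `X4`, `T5`
#'   (1-based positions into the corresponding reference sequence).
#' @return A list of class `lox_anchors`.
#' @export
coordination_anchors <- function(records, sites) {
  stopifnot(inherits(records, "lox_records"),
            all(c("id", SITE_ROLES) %in% names(sites)))
  if (!all(records$id %in% sites$id)) stop("missing site annotation for some ids")
  entries <- lapply(seq_len(nrow(records)), function(i) {
    row <- sites[sites$id == records$id[i], , drop = FALSE]
    pos <- as.integer(row[1, SITE_ROLES])
    names(pos) <- SITE_ROLES
    seq <- records$residues[i]
    if (any(pos < 1L | pos > nchar(seq))) {
      stop("site position out of range for reference ", records$id[i])
    }
    list(id = records$id[i], residues = seq, sites = pos)
  })
  structure(entries, class = "lox_anchors")
}

#' Read / write a site-annotation sidecar (TSV, 0-based positions)
#'
#' The on-disk sidecar stores 0-based positions (columns `id`, `H1` .. `T5`);
#' in-memory anchors use 1-based positions.
#'
#' @param records reference `lox_records` matching the sidecar ids.
#' @param path sidecar path.
#' @return [read_anchor_sites()] returns a `lox_anchors` object;
#'   [write_anchor_sites()] returns `path` invisibly.
#' @export
read_anchor_sites <- function(records, path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  tab[SITE_ROLES] <- tab[SITE_ROLES] + 1L
  coordination_anchors(records, tab)
}

#' @rdname read_anchor_sites
#' @param anchors a `lox_anchors` object.
#' @export
write_anchor_sites <- function(anchors, path) {
  tab <- do.call(rbind, lapply(anchors, function(a) {
    data.frame(id = a$id, as.list(a$sites - 1L), stringsAsFactors = FALSE)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# map each position of ref onto query coordinates through a global alignment;
# positions falling in query gaps get the nearest preceding query position
project_positions <- function(query, ref) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(ref), Biostrings::AAString(query),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 4,
    type = "global"
  )
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  map <- integer(nchar(ref))
  ri <- 0L; qi <- 0L
  for (k in seq_along(p)) {
    if (s[k] != "-") qi <- qi + 1L
    if (p[k] != "-") {
      ri <- ri + 1L
      map[ri] <- max(qi, 1L)
    }
  }
  list(map = map, identity = Biostrings::pid(aln))
}

#' Locate the five iron-coordination sites in a sequence
#'
#' The query is globally aligned to the best-identity reference in `anchors`;
#' the reference's annotated site positions are projected onto the query and
#' verified locally: the projected position, or a window of +/- `window`
#' residues around it, must contain the residue class expected at that role
#' (His for the three His sites; Asn/His/Gln/Ser for the fourth site;
#' Ile/Leu/Val for the terminal hydrophobic site). Sites failing verification
#' are marked not found.
#'
#' @param record a single-row `lox_records` data frame (or an id-named list
#'   with a `residues` element).
#' @param anchors a [coordination_anchors()] reference set.
#' @param window verification half-window in residues (default 2).
#' @return A list of class `coord_pattern` with elements `id`, `sites` (data
#'   frame role/residue/position/found, positions 1-based), `s1` (residues
#'   strictly between H1 and H2; canonical 4), `s2` (between H3 and X4;
#'   canonical 3), `tandem_his_at_H3` (His immediately after H3),
#'   `completeness` (0-5), `reference` and `identity`.
#' @export
scan_coordination <- function(record, anchors, window = 2L) {
  if (!inherits(anchors, "lox_anchors") || length(anchors) == 0L) {
    stop("a non-empty reference annotation set is required")
  }
  id <- record$id[1]
  seq <- record$residues[1]
  letters <- strsplit(seq, "")[[1]]

  proj <- lapply(anchors, function(a) project_positions(seq, a$residues))
  best <- which.max(vapply(proj, `[[`, numeric(1), "identity"))
  pr <- proj[[best]]
  ref <- anchors[[best]]

  sites <- data.frame(role = SITE_ROLES, residue = NA_character_,
                      position = NA_integer_, found = FALSE,
                      stringsAsFactors = FALSE)
  if (pr$identity >= 10) {
    for (i in seq_along(SITE_ROLES)) {
      role <- SITE_ROLES[i]
      p0 <- pr$map[ref$sites[[role]]]
      cand <- seq(max(1L, p0 - window), min(length(letters), p0 + window))
      hit <- cand[letters[cand] %in% SITE_CLASSES[[role]]]
      if (length(hit)) {
        pos <- hit[which.min(abs(hit - p0))]
        sites$position[i] <- pos
        sites$residue[i] <- letters[pos]
        sites$found[i] <- TRUE
      }
    }
    # enforce strictly increasing positions in role order
    last <- 0L
    for (i in seq_len(nrow(sites))) {
      if (sites$found[i]) {
        if (sites$position[i] <= last) {
          sites$found[i] <- FALSE
          sites$position[i] <- NA_integer_
          sites$residue[i] <- NA_character_
        } else {
          last <- sites$position[i]
        }
      }
    }
  }

  pos <- stats::setNames(sites$position, sites$role)
  s1 <- if (sites$found[1] && sites$found[2]) pos[["H2"]] - pos[["H1"]] - 1L else NA_integer_
  s2 <- if (sites$found[3] && sites$found[4]) pos[["X4"]] - pos[["H3"]] - 1L else NA_integer_
  tandem <- isTRUE(sites$found[3]) && pos[["H3"]] < length(letters) &&
    letters[pos[["H3"]] + 1L] == "H"

  structure(
    list(id = id, sites = sites, s1 = s1, s2 = s2,
         tandem_his_at_H3 = tandem,
         completeness = sum(sites$found),
         reference = ref$id, identity = pr$identity),
    class = "coord_pattern"
  )
}

#' Scan every record in a set
#'
#' @inheritParams scan_coordination
#' @param records a `lox_records` data frame.
#' @return A list of `coord_pattern` objects, one per record, in input order.
#' @export
scan_all <- function(records, anchors, window = 2L) {
  lapply(seq_len(nrow(records)), function(i) {
    scan_coordination(records[i, , drop = FALSE], anchors, window = window)
  })
}

#' Group-discriminating motif configuration
#'
#' Groups 1 and 2 share the canonical coordination pattern and are told apart
#' by a motif present in one group and absent in the other. Motifs use a
#' small PROSITE-like dialect: `-`-separated tokens that are literal residues
#' (`WRF`), a character class (`[ST]`), or a bounded gap (`x`, `x(2)`,
#' `x(2,4)`).
#'
#' @param group1 motif present in group-1 sequences, or `NULL`.
#' @param group2 motif present in group-2 sequences, or `NULL`.
#' @return A list of class `motif_config`.
#' @export
motif_config <- function(group1 = NULL, group2 = NULL) {
  structure(
    list(
      group1 = group1, group2 = group2,
      group1_regex = if (!is.null(group1)) motif_regex(group1),
      group2_regex = if (!is.null(group2)) motif_regex(group2)
    ),
    class = "motif_config"
  )
}

#' Convert a PROSITE-like motif to a regular expression
#'
#' @param motif motif string in the dialect documented at [motif_config()].
#' @return A regular expression string.
#' @export
motif_regex <- function(motif) {
  tokens <- strsplit(motif, "-", fixed = TRUE)[[1]]
  out <- vapply(tokens, function(tk) {
    if (grepl("^[A-Z]+$", tk)) return(tk)
    if (grepl("^\\[[A-Z]+\\]$", tk)) return(tk)
    if (tk == "x") return(".")
    m <- regmatches(tk, regexec("^x\\((\\d+)(,(\\d+))?\\)$", tk))[[1]]
    if (length(m)) {
      if (nzchar(m[4])) return(sprintf(".{%s,%s}", m[2], m[4]))
      return(sprintf(".{%s}", m[2]))
    }
    stop("invalid motif token: ", tk)
  }, character(1))
  paste(out, collapse = "")
}

#' Classify a coordination pattern into a sequence group
#'
#' Applies the group decision table to the measured spacings and fourth-site
#' identity. With the canonical His-His spacing and one extra residue before
#' the fourth site (`s2 == 4`, an insertion), the fourth-site identity maps
#' to groups 4a (Asn), 4b (Gln), 5a (Ser) and 5b (His). With the canonical
#' `s2 == 3`: a shortened His-His spacing with a His fourth site is group 3;
#' a His immediately following the third His (tandem) with Asn is group 6;
#' otherwise Asn patterns are group 1 or 2 by discriminating motif, or
#' `UNRESOLVED_12` when no motif decides. Anything else is `UNCLASSIFIED`.
#'
#' @param pattern a `coord_pattern` with completeness >= 3.
#' @param motifs a [motif_config()]; motifs are only consulted for the
#'   group-1/group-2 decision.
#' @param sequence the record's residue string (needed for motif matching);
#'   may be omitted, in which case canonical patterns fall to
#'   `UNRESOLVED_12`.
#' @return A single label among `G1`, `G2`, `G3`, `G4a`, `G4b`, `G5a`,
#'   `G5b`, `G6`, `UNRESOLVED_12`, `UNCLASSIFIED`.
#' @export
classify_pattern <- function(pattern, motifs = motif_config(), sequence = NULL) {
  stopifnot(inherits(pattern, "coord_pattern"))
  if (pattern$completeness < 3L) {
    stop("classify_pattern requires completeness >= 3 (got ",
         pattern$completeness, ")")
  }
  s1 <- pattern$s1
  s2 <- pattern$s2
  x4 <- pattern$sites$residue[pattern$sites$role == "X4"]
  tandem <- isTRUE(pattern$tandem_his_at_H3)
  if (is.na(s2) || is.na(x4)) return("UNCLASSIFIED")

  if (s2 == 4L) {
    return(switch(x4, N = "G4a", Q = "G4b", S = "G5a", H = "G5b",
                  "UNCLASSIFIED"))
  }
  if (s2 == 3L) {
    if (!is.na(s1) && s1 < 4L && x4 == "H") return("G3")
    if (x4 == "N") {
      if (tandem) return("G6")
      if (!is.null(sequence)) {
        if (!is.null(motifs$group2_regex) && grepl(motifs$group2_regex, sequence)) {
          return("G2")
        }
        if (!is.null(motifs$group1_regex) && grepl(motifs$group1_regex, sequence)) {
          return("G1")
        }
      }
      return("UNRESOLVED_12")
    }
  }
  "UNCLASSIFIED"
}

#' Classify all scanned patterns
#'
#' @param patterns list of `coord_pattern` objects.
#' @param records the matching `lox_records` (sequences used for motif
#'   matching).
#' @param motifs a [motif_config()].
#' @return Named character vector of group labels; patterns with
#'   completeness < 3 get `NA`.
#' @export
classify_all <- function(patterns, records, motifs = motif_config()) {
  labs <- vapply(patterns, function(p) {
    if (p$completeness < 3L) return(NA_character_)
    seq <- records$residues[match(p$id, records$id)]
    classify_pattern(p, motifs, seq)
  }, character(1))
  stats::setNames(labs, vapply(patterns, `[[`, character(1), "id"))
}

#' Write a pattern report as TSV
#'
#' One row per record: site positions (1-based) and identities, spacings,
#' tandem flag, completeness and group label.
#'
#' @param patterns list of `coord_pattern` objects.
#' @param labels named group labels (e.g. from [classify_all()]), optional.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pattern_report <- function(patterns, path, labels = NULL) {
  rows <- lapply(patterns, function(p) {
    pos <- stats::setNames(p$sites$position, paste0("pos_", p$sites$role))
    res <- stats::setNames(p$sites$residue, paste0("res_", p$sites$role))
    data.frame(id = p$id, t(pos), t(res), s1 = p$s1, s2 = p$s2,
               tandem = p$tandem_his_at_H3, completeness = p$completeness,
               group = if (is.null(labels)) NA_character_ else unname(labels[p$id]),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
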