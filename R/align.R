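aa_codes <- function(seq) {
  match(strsplit(seq, "")[[1]], c(AA20, "X"), nomatch = 21L)
}

# 22x22 scoring matrix over codes 0 (gap), 1..20 (amino acids), 21 (X),
# stored 1-based: row/col 1 is the gap state
profile_submat <- function(gap_mismatch = -4) {
  b62 <- get_blosum62()
  k <- 22L
  sub <- matrix(0, k, k)
  sub[1, ] <- gap_mismatch
  sub[, 1] <- gap_mismatch
  sub[1, 1] <- 0
  sub[2:21, 2:21] <- b62[AA20, AA20]
  sub[22, ] <- 0
  sub[, 22] <- 0
  sub
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

merge_profiles <- function(A, B, sub, gap) {
  path <- nw_profile(A, B, sub, gap)
  n <- length(path$a)
  out <- matrix(0L, nrow(A) + nrow(B), n)
  rownames(out) <- c(rownames(A), rownames(B))
  ia <- path$a > 0L
  ib <- path$b > 0L
  out[seq_len(nrow(A)), ia] <- A[, path$a[ia], drop = FALSE]
  out[nrow(A) + seq_len(nrow(B)), ib] <- B[, path$b[ib], drop = FALSE]
  out
}

#' Progressive multiple alignment of protein records
#'
#' A simple progressive aligner intended to provide alignment columns for
#' distance estimation and column bootstrapping, not publication-grade
#' alignments: pairwise Poisson-corrected distances give a neighbor-joining
#' guide tree, and profiles are merged bottom-up with a Needleman-Wunsch
#' profile aligner (BLOSUM62 column scores, linear gap penalty).
#'
#' @param records a `lox_records` data frame (>= 2 records).
#' @param d optional precomputed [distance_matrix()]; computed if missing.
#' @param gap linear gap penalty per column (negative).
#' @return A character matrix of class `lox_msa`, rows named by record id in
#'   input order, entries one-letter residues or `"-"`.
#' @export
progressive_alignment <- function(records, d = NULL, gap = -8) {
  stopifnot(inherits(records, "lox_records"), nrow(records) >= 2L)
  sub <- profile_submat()
  profiles <- lapply(seq_len(nrow(records)), function(i) {
    m <- matrix(aa_codes(records$residues[i]), nrow = 1L)
    rownames(m) <- records$id[i]
    m
  })
  names(profiles) <- records$id

  if (nrow(records) == 2L) {
    merged <- merge_profiles(profiles[[1]], profiles[[2]], sub, gap)
  } else {
    if (is.null(d)) d <- distance_matrix(records)
    guide <- ape::nj(d)
    merged <- local({
      ntip <- length(guide$tip.label)
      node_profiles <- vector("list", ntip + guide$Nnode)
      node_profiles[seq_len(ntip)] <- profiles[guide$tip.label]
      edge <- ape::reorder.phylo(guide, "postorder")$edge
      for (k in seq_len(nrow(edge))) {
        parent <- edge[k, 1]; child <- edge[k, 2]
        if (is.null(node_profiles[[parent]])) {
          node_profiles[[parent]] <- node_profiles[[child]]
        } else {
          node_profiles[[parent]] <- merge_profiles(
            node_profiles[[parent]], node_profiles[[child]], sub, gap)
        }
      }
      node_profiles[[ntip + 1L]]
    })
  }

  merged <- merged[match(records$id, rownames(merged)), , drop = FALSE]
  chars <- c("-", AA20, "X")
  out <- matrix(chars[merged + 1L], nrow = nrow(merged),
                dimnames = list(rownames(merged), NULL))
  class(out) <- c("lox_msa", class(out))
  out
}

# Poisson-corrected distance from a proportion of differing sites; p is
# clamped at 0.95 so saturated pairs get the documented maximum -ln(0.05)
poisson_distance <- function(p, p_max = 0.95) {
  -log(1 - pmin(p, p_max))
}

#' Pairwise distances from alignment columns
#'
#' p-distance over columns where both rows are ungapped, Poisson-corrected
#' (`d = -ln(1 - p)`, `p` clamped at 0.95). Pairs with no comparable columns
#' get the clamped maximum.
#'
#' @param msa a `lox_msa` character matrix.
#' @return A symmetric distance matrix with row/col names.
#' @export
msa_distances <- function(msa) {
  n <- nrow(msa)
  d <- matrix(0, n, n, dimnames = list(rownames(msa), rownames(msa)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      ok <- msa[i, ] != "-" & msa[j, ] != "-"
      p <- if (any(ok)) mean(msa[i, ok] != msa[j, ok]) else 1
      d[i, j] <- d[j, i] <- poisson_distance(p)
    }
  }
  d
}
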