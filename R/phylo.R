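#' Pairwise Poisson-corrected distances between protein records
#'
#' Each pair is globally aligned (BLOSUM62, affine gaps); the p-distance is
#' the proportion of differing residues over aligned columns where neither
#' sequence is gapped, then Poisson-corrected as `d = -ln(1 - p)` with `p`
#' clamped at 0.95 (so the maximum distance is `-ln(0.05)`, about 3.0
#' substitutions/site).
#'
#' @param records a `lox_records` data frame with at least 3 records.
#' @return A symmetric numeric matrix with ids as dimnames.
#' @export
distance_matrix <- function(records) {
  stopifnot(inherits(records, "lox_records"))
  if (nrow(records) < 3L) stop("at least 3 records are required")
  if (any(!nzchar(records$residues))) stop("zero-length sequence")
  n <- nrow(records)
  seqs <- lapply(records$residues, Biostrings::AAString)
  d <- matrix(0, n, n, dimnames = list(records$id, records$id))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      aln <- Biostrings::pairwiseAlignment(
        seqs[[i]], seqs[[j]], substitutionMatrix = "BLOSUM62",
        gapOpening = 10, gapExtension = 4, type = "global"
      )
      a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
      b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
      ok <- a != "-" & b != "-"
      p <- if (any(ok)) mean(a[ok] != b[ok]) else 1
      d[i, j] <- d[j, i] <- poisson_distance(p)
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining; deterministic given the matrix.
#'
#' @param d symmetric distance matrix with ids as dimnames (>= 3 taxa).
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("at least 3 taxa are required")
  if (any(!is.finite(d))) stop("non-finite distance entries")
  if (is.null(rownames(d))) stop("distance matrix must carry ids as dimnames")
  ape::nj(d)
}

#' Neighbor-joining tree with bootstrap clade support
#'
#' Builds a progressive alignment over the records, a neighbor-joining tree
#' from its Poisson-corrected column distances, and `B` bootstrap
#' pseudo-replicates by resampling alignment columns with replacement; the
#' support of an internal edge is the number of replicates whose tree
#' contains the same bipartition.
#'
#' @param records a `lox_records` data frame (>= 3 records).
#' @param B number of bootstrap replicates (default 100).
#' @param seed integer seed; results are reproducible given the seed.
#' @param msa optional precomputed [progressive_alignment()] of `records`.
#' @return A `phylo` tree whose `node.label` holds integer supports in
#'   `[0, B]` (`NA` on the root node); attribute `B` records the replicate
#'   count.
#' @export
bootstrap_supports <- function(records, B = 100L, seed = 1L, msa = NULL) {
  B <- as.integer(B)
  if (B < 1L) stop("B must be >= 1")
  if (is.null(msa)) msa <- progressive_alignment(records)
  tree <- nj_tree(msa_distances(msa))
  set.seed(seed)
  supports <- ape::boot.phylo(
    tree, msa, function(m) nj_tree(msa_distances(structure(m, class = class(msa)))),
    B = B, rooted = FALSE, quiet = TRUE
  )
  supports[1L] <- NA_integer_
  tree$node.label <- supports
  attr(tree, "B") <- B
  tree
}

# tip-index sets below every internal node of a phylo tree, indexed node - Ntip
clade_tipsets <- function(tree) {
  pp <- ape::prop.part(tree)
  lapply(pp, function(x) sort(x))
}

#' Partition tree leaves into supported groups
#'
#' Grouping is bipartition-based: every internal edge with bootstrap
#' support above `threshold` defines a supported split, represented by its
#' smaller tip side (so that a group is a coherent clade rather than
#' "everything else"); on a tree these sides form a nested family, and the
#' maximal supported sides are the groups. Leaves in no supported side form
#' a residual group. A group whose members carry two or more distinct
#' fourth-site (X4) identities is recursively split into lettered subgroups
#' along supported internal edges (full support in practice) until each
#' subgroup is X4-homogeneous or no supported split remains. When
#' classification `labels` are supplied, `UNRESOLVED_12` members are
#' resolved to `G1`/`G2` by majority among motif-resolved members of the
#' same terminal group.
#'
#' @param tree a supported tree from [bootstrap_supports()] (node labels =
#'   integer supports).
#' @param patterns list of `coord_pattern` objects covering every leaf.
#' @param threshold support threshold (default 95; groups require support
#'   strictly greater).
#' @param labels optional named group labels from [classify_all()].
#' @return A list of class `lox_groups`: `membership` (data frame `id`,
#'   `group`, `terminal`, and `label` when `labels` given) and `groups`
#'   (data frame `group`, `n`, `support`, `x4`).
#' @export
extract_groups <- function(tree, patterns, threshold = 95L, labels = NULL) {
  ids <- tree$tip.label
  pat_ids <- vapply(patterns, `[[`, character(1), "id")
  if (!all(ids %in% pat_ids)) {
    stop("leaf without a coordination pattern: ",
         paste(setdiff(ids, pat_ids), collapse = ", "))
  }
  x4 <- vapply(patterns, function(p) {
    r <- p$sites$residue[p$sites$role == "X4"]
    if (is.na(r)) NA_character_ else r
  }, character(1))
  names(x4) <- pat_ids

  ntip <- length(tree$tip.label)
  ref_tip <- which.min(rank(tree$tip.label))
  raw_sets <- clade_tipsets(tree)
  support <- suppressWarnings(as.numeric(tree$node.label))
  # canonical side of each bipartition: the smaller side (ties broken
  # against the side holding the reference tip); these sides are nested
  tipsets <- lapply(raw_sets, function(s) {
    if (length(s) > ntip / 2 ||
        (length(s) == ntip / 2 && ref_tip %in% s)) {
      setdiff(seq_len(ntip), s)
    } else s
  })

  is_supported <- !is.na(support) & support > threshold
  # maximal supported sides: not contained in another supported side
  maximal <- which(is_supported)
  maximal <- maximal[vapply(maximal, function(k) {
    !any(vapply(setdiff(which(is_supported), k), function(m) {
      all(tipsets[[k]] %in% tipsets[[m]]) && length(tipsets[[m]]) > length(tipsets[[k]])
    }, logical(1)))
  }, logical(1))]

  # deterministic group order: by first tip label (alphabetical)
  first_tip <- vapply(maximal, function(k) min(tree$tip.label[tipsets[[k]]]),
                      character(1))
  maximal <- maximal[order(first_tip)]

  group_of <- rep(NA_integer_, ntip)
  names(group_of) <- tree$tip.label
  for (g in seq_along(maximal)) {
    group_of[tipsets[[maximal[g]]]] <- g
  }
  residual <- which(is.na(group_of))
  groups_support <- support[maximal]
  group_nodes <- maximal
  if (length(residual)) {
    group_of[residual] <- length(maximal) + 1L
    group_nodes <- c(group_nodes, NA_integer_)
    groups_support <- c(groups_support, NA_real_)
  }

  # split heterogeneous groups at supported internal edges
  split_clade <- function(node_idx, members) {
    vals <- unique(stats::na.omit(x4[tree$tip.label[members]]))
    if (length(vals) <= 1L) return(list(members))
    children <- which(vapply(seq_along(tipsets), function(k) {
      k != node_idx && is_supported[k] &&
        all(tipsets[[k]] %in% members) && length(tipsets[[k]]) < length(members)
    }, logical(1)))
    if (!length(children)) return(list(members))
    # maximal supported children within the clade
    children <- children[vapply(children, function(k) {
      !any(vapply(setdiff(children, k), function(m) {
        all(tipsets[[k]] %in% tipsets[[m]]) && length(tipsets[[m]]) > length(tipsets[[k]])
      }, logical(1)))
    }, logical(1))]
    parts <- list()
    covered <- integer(0)
    for (k in children) {
      parts <- c(parts, split_clade(k, tipsets[[k]]))
      covered <- c(covered, tipsets[[k]])
    }
    rest <- setdiff(members, covered)
    if (length(rest)) parts <- c(parts, list(rest))
    parts
  }

  terminal <- character(ntip)
  names(terminal) <- tree$tip.label
  for (g in seq_len(max(group_of))) {
    members <- which(group_of == g)
    node_idx <- if (g <= length(maximal)) maximal[g] else NA_integer_
    parts <- if (!is.na(node_idx)) split_clade(node_idx, members) else list(members)
    parts <- parts[order(vapply(parts, function(m) min(tree$tip.label[m]),
                                character(1)))]
    if (length(parts) == 1L) {
      terminal[members] <- as.character(g)
    } else {
      for (p in seq_along(parts)) {
        terminal[parts[[p]]] <- paste0(g, letters[p])
      }
    }
  }

  membership <- data.frame(
    id = tree$tip.label,
    group = unname(group_of),
    terminal = unname(terminal),
    stringsAsFactors = FALSE
  )
  membership <- membership[match(ids, membership$id), , drop = FALSE]
  rownames(membership) <- NULL

  if (!is.null(labels)) {
    lab <- unname(labels[membership$id])
    for (tg in unique(membership$terminal)) {
      sel <- membership$terminal == tg
      unres <- sel & !is.na(lab) & lab == "UNRESOLVED_12"
      if (any(unres)) {
        resolved <- lab[sel & lab %in% c("G1", "G2")]
        if (length(resolved)) {
          lab[unres] <- names(sort(table(resolved), decreasing = TRUE))[1]
        }
      }
    }
    membership$label <- lab
  }

  groups <- do.call(rbind, lapply(seq_len(max(group_of)), function(g) {
    members <- membership$id[membership$group == g]
    data.frame(
      group = g, n = length(members),
      support = groups_support[g],
      x4 = paste(sort(unique(stats::na.omit(x4[members]))), collapse = ","),
      stringsAsFactors = FALSE
    )
  }))

  structure(list(membership = membership, groups = groups),
            class = "lox_groups")
}

#' Write a supported tree as Newick
#'
#' Bootstrap supports are written as internal node labels.
#'
#' @param tree a `phylo` from [bootstrap_supports()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_support_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a group partition as TSV
#'
#' @param partition a `lox_groups` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  utils::write.table(partition$membership, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
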