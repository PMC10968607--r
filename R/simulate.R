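# skeleton of each terminal coordination pattern: spacing between the His
# pair (s1, canonical 4), spacing before the fourth site (s2, canonical 3,
# 4 = insertion), fourth-site identity, tandem His after H3, and which
# discriminating motif (if any) the group carries
GROUP_SKELETONS <- data.frame(
  group = c("G1", "G2", "G3", "G4a", "G4b", "G5a", "G5b", "G6"),
  s1 = c(4L, 4L, 3L, 4L, 4L, 4L, 4L, 4L),
  s2 = c(3L, 3L, 3L, 4L, 4L, 4L, 4L, 3L),
  x4 = c("N", "N", "H", "N", "Q", "S", "H", "N"),
  tandem = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
  motif = c("group1", "group2", NA, NA, NA, NA, NA, NA),
  stringsAsFactors = FALSE
)

#' Default group-1/group-2 discriminating motifs used by the generators
#'
#' Two literal 8-residue motifs, one implanted in each of the two canonical
#' groups by [make_group_sequences()]; real analyses supply their own
#' motifs via [motif_config()].
#'
#' @return A [motif_config()].
#' @export
default_motifs <- function() {
  motif_config(group1 = "YWRPDGFE", group2 = "FHKNWSTQ")
}

random_background <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

mutate_background <- function(letters, rate, protected) {
  free <- setdiff(seq_along(letters), protected)
  n_mut <- stats::rbinom(1L, length(free), rate)
  if (n_mut == 0L) return(letters)
  pos <- sample(free, n_mut)
  letters[pos] <- vapply(letters[pos], function(a) {
    sample(setdiff(AA20, a), 1L)
  }, character(1))
  letters
}

#' Generate synthetic LOX sequence families with truth annotations
#'
#' For each of the eight terminal coordination patterns (groups 1-6 with
#' subgroups 4a/4b and 5a/5b) a family of random-background sequences is
#' generated with the group's coordination motif implanted at randomized but
#' recorded positions: the His pair in the first half of the sequence, the
#' second His/fourth-site couple in the second half, and the hydrophobic
#' fifth site near the end. Groups 1 and 2 additionally carry the
#' discriminating motifs. The first family member is the unmutated
#' prototype; further members carry point mutations (at `mutation_rate`)
#' outside the implanted positions, providing within-group diversity for
#' tree building. The family backgrounds radiate star-like from a single
#' ancestral background: each major group diverges independently from the
#' ancestor (at `major_divergence`), so no pair of major groups shares
#' derived signal and deep inter-group edges stay unsupported, while each
#' subgroup pair (4a/4b, 5a/5b) diverges a further `pair_divergence` from a
#' shared group background so the pair forms one supported top-level clade.
#' Saturating the backgrounds instead (independent random sequences) makes
#' all inter-family distances collapse onto a common ceiling, and identical
#' tie-broken joins then earn spurious bootstrap support.
#'
#' @param seed integer seed; output is byte-identical for a given seed and
#'   parameter set.
#' @param per_group family size (>= 1).
#' @param length_range background length range in residues.
#' @param mutation_rate per-residue mutation rate within families (<= 2%
#'   by default).
#' @param major_divergence per-residue divergence of each major-group
#'   background from the common ancestral background.
#' @param pair_divergence extra divergence between the backgrounds of a
#'   subgroup pair.
#' @param motifs a [motif_config()] providing the two implanted motifs.
#' @return A list: `records` (`lox_records`, ids `<group>_<k>`), `truth`
#'   (data frame with implanted 1-based site positions, spacings, fourth-
#'   site identity, tandem flag and group label per record), `anchors`
#'   (a [coordination_anchors()] set built from the prototypes), `motifs`.
#' @export
make_group_sequences <- function(seed, per_group = 4L,
                                 length_range = c(600L, 750L),
                                 mutation_rate = 0.02,
                                 major_divergence = 0.55,
                                 pair_divergence = 0.12,
                                 motifs = default_motifs()) {
  stopifnot(per_group >= 1L)
  set.seed(seed)

  # star-like radiation from one ancestral background; subgroup pairs
  # share a group background with some extra divergence
  L <- sample(seq(length_range[1], length_range[2]), 1L)
  ancestor <- strsplit(random_background(L), "")[[1]]
  bg <- list()
  for (g in c("G1", "G2", "G3", "G6")) {
    bg[[g]] <- mutate_background(ancestor, major_divergence, integer(0))
  }
  for (pair in list(c("G4a", "G4b"), c("G5a", "G5b"))) {
    base <- mutate_background(ancestor, major_divergence, integer(0))
    bg[[pair[1]]] <- base
    bg[[pair[2]]] <- mutate_background(base, pair_divergence, integer(0))
  }

  records <- list()
  truth <- list()
  proto_rows <- list()
  for (gi in seq_len(nrow(GROUP_SKELETONS))) {
    sk <- GROUP_SKELETONS[gi, ]
    letters <- bg[[sk$group]]
    L <- length(letters)

    h1 <- sample(seq(floor(0.15 * L), floor(0.35 * L)), 1L)
    h2 <- h1 + sk$s1 + 1L
    h3 <- sample(seq(floor(0.55 * L), floor(0.75 * L)), 1L)
    x4 <- h3 + sk$s2 + 1L
    t5 <- sample(seq(L - 20L, L - 5L), 1L)
    sites <- c(H1 = h1, H2 = h2, H3 = h3, X4 = x4, T5 = t5)

    letters[h1] <- "H"; letters[h2] <- "H"; letters[h3] <- "H"
    letters[x4] <- sk$x4; letters[t5] <- "I"
    protected <- c(sites, h3 + 1L)
    if (sk$tandem) {
      letters[h3 + 1L] <- "H"
    } else if (letters[h3 + 1L] == "H") {
      letters[h3 + 1L] <- "A"
    }
    if (!is.na(sk$motif)) {
      m <- strsplit(motifs[[sk$motif]], "")[[1]]
      m_start <- floor(0.45 * L)
      letters[m_start + seq_along(m) - 1L] <- m
      protected <- c(protected, m_start + seq_along(m) - 1L)
    }

    for (k in seq_len(per_group)) {
      mem <- if (k == 1L) letters else
        mutate_background(letters, mutation_rate, protected)
      id <- paste0(sk$group, "_", k)
      records[[id]] <- paste(mem, collapse = "")
      truth[[id]] <- data.frame(
        id = id, group = sk$group, t(sites),
        s1 = sk$s1, s2 = sk$s2, x4 = sk$x4, tandem = sk$tandem,
        stringsAsFactors = FALSE
      )
    }
    proto_rows[[sk$group]] <- data.frame(id = paste0(sk$group, "_1"),
                                         t(sites), stringsAsFactors = FALSE)
  }

  recs <- protein_records(names(records), unlist(records), source = "fixture")
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  protos <- recs[match(paste0(GROUP_SKELETONS$group, "_1"), recs$id), ,
                 drop = FALSE]
  class(protos) <- c("lox_records", "data.frame")
  anchors <- coordination_anchors(protos, do.call(rbind, proto_rows))
  list(records = recs, truth = truth, anchors = anchors, motifs = motifs)
}

#' Canned reference set: one idealized sequence per coordination pattern
#'
#' A deterministic set of eight prototype sequences, one per terminal group
#' pattern, with its anchors and truth table; used as the reference panel
#' for scanning and for group-taxonomy checks.
#'
#' @return Same structure as [make_group_sequences()].
#' @export
reference_group_set <- function() {
  make_group_sequences(seed = 193L, per_group = 1L, mutation_rate = 0)
}

#' Generate an idealized pocket structure as a PDB fixture
#'
#' Builds a pseudo-pocket along the z axis: the gate residue's CA marks the
#' channel mouth at the origin, two pocket-bottom marker residues sit 15
#' Angstrom deeper, and the iron lies midway. The fatty-acid carbon chain
#' runs along the axis at bond-length steps (1.52 Angstrom single, 1.33
#' double) with small lateral kinks, positioned so that the requested carbon
#' is uniquely nearest the iron (margin >= 0.4 Angstrom) and the carboxyl
#' head (C1, carrying two oxygens) matches the requested orientation.
#' Double bonds are placed every third bond starting at C5, the
#' cis-methylene pattern of polyunsaturated fatty acids.
#'
#' @param n_carbons chain length (>= 4).
#' @param nearest_index carbon index that must end up nearest the iron.
#' @param orientation `"HEAD_EXTERNAL"` or `"HEAD_INTERNAL"`.
#' @param gate_residue `"GLY"` (open channel) or `"ALA"` (closed).
#' @param seed integer seed controlling the lateral kink phase.
#' @param path output PDB path (default a tempfile).
#' @return A list: `path`, `truth` (requested facts plus gate selector
#'   `"A:427"`, bottom selectors, expected gate state, double-bond indices).
#' @export
make_pocket_fixture <- function(n_carbons, nearest_index, orientation,
                                gate_residue = "GLY", seed = 1L,
                                path = tempfile(fileext = ".pdb")) {
  stopifnot(n_carbons >= 4L)
  if (nearest_index < 1L || nearest_index > n_carbons) {
    stop("nearest_index outside the chain")
  }
  orientation <- normalize_orientation(orientation)
  gate_residue <- toupper(gate_residue)
  set.seed(seed)
  # kink phase anchored so the requested carbon sits at the lateral minimum,
  # keeping its nearest-to-iron margin robust to the seeded jitter
  phase <- 3 * pi / 2 - 0.8 * nearest_index + stats::runif(1L, -0.15, 0.15)

  dir <- if (orientation == "HEAD_EXTERNAL") -1 else 1
  db <- if (n_carbons >= 6L) seq(5L, n_carbons - 1L, by = 3L) else integer(0)
  ang <- 0.8 * seq_len(n_carbons) + phase
  lat <- cbind(2.0 + 0.20 * sin(ang), 0.20 * cos(ang))
  z <- numeric(n_carbons)
  for (i in seq_len(n_carbons - 1L)) {
    b <- if (i %in% db) 1.33 else 1.52
    dxy2 <- sum((lat[i + 1L, ] - lat[i, ])^2)
    z[i + 1L] <- z[i] + dir * sqrt(b^2 - dxy2)
  }
  z <- z - z[nearest_index] - 7.5
  carbons <- cbind(lat, z)

  fe <- c(0, 0, -7.5)
  dfe <- sqrt(rowSums((carbons - matrix(fe, n_carbons, 3, byrow = TRUE))^2))
  if (which.min(dfe) != nearest_index ||
      sort(dfe)[2] - min(dfe) < 0.4) {
    stop("inconsistent request: nearest-carbon margin cannot be achieved")
  }

  ox_dir <- c(0.65, 0.95, -dir * 0.45)
  o1 <- carbons[1L, ] + 1.25 * ox_dir / sqrt(sum(ox_dir^2))
  ox_dir2 <- c(0.65, -0.95, -dir * 0.45)
  o2 <- carbons[1L, ] + 1.25 * ox_dir2 / sqrt(sum(ox_dir2^2))

  gate_atoms <- rbind(N = c(-1.25, 0.40, 0.30), CA = c(0, 0, 0),
                      C = c(1.30, 0.55, 0.25), O = c(1.85, 1.45, 0.60))
  bottom1 <- rbind(N = c(-1.75, 0.35, -14.8), CA = c(-0.60, 0, -15.0),
                   C = c(0.45, 0.80, -15.4), CB = c(-0.75, -0.65, -16.2))
  bottom2 <- rbind(N = c(1.90, -0.30, -14.7), CA = c(0.60, 0, -15.0),
                   C = c(-0.40, -0.85, -15.3), CB = c(0.80, 0.70, -16.1))

  xyz <- rbind(gate_atoms, bottom1, bottom2, FE = fe, carbons, O1 = o1, O2 = o2)
  n_at <- nrow(xyz)
  atom_names <- c(rownames(gate_atoms), rownames(bottom1), rownames(bottom2),
                  "FE", paste0("C", seq_len(n_carbons)), "O1", "O2")
  resname <- c(rep(gate_residue, 4L), rep("ALA", 8L), "FE",
               rep("LIG", n_carbons + 2L))
  resno <- c(rep(427L, 4L), rep(589L, 4L), rep(620L, 4L), 901L,
             rep(902L, n_carbons + 2L))
  type <- c(rep("ATOM", 12L), rep("HETATM", n_at - 12L))
  elesy <- c(substr(c(rownames(gate_atoms), rownames(bottom1),
                      rownames(bottom2)), 1L, 1L),
             "FE", rep("C", n_carbons), "O", "O")

  bio3d::write.pdb(file = path, xyz = as.vector(t(xyz)), type = type,
                   resno = resno, resid = resname,
                   eleno = seq_len(n_at), elety = atom_names,
                   chain = rep("A", n_at), elesy = elesy)

  list(
    path = path,
    truth = list(
      n_carbons = n_carbons, nearest_index = nearest_index,
      orientation = orientation, gate_residue = gate_residue,
      gate = "A:427", bottom = c("A:589", "A:620"),
      gate_state = if (gate_residue == "GLY") "OPEN" else "CLOSED",
      double_bonds = db
    )
  )
}
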