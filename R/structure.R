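#' Load atoms from a PDB file
#'
#' Parses ATOM/HETATM records (fixed-column PDB dialect) into a data frame.
#' Elements come from columns 77-78 when present, with a fallback to the
#' leading letters of the atom name. Residue numbering and insertion codes
#' are kept as in the file.
#'
#' @param path path to a PDB file.
#' @return A data frame of class `lox_atoms` with columns `type`, `name`,
#'   `element`, `resname`, `resno`, `ins`, `chain`, `x`, `y`, `z`.
#' @export
load_structure <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("unparsable PDB file ", path, ": ",
                                           conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stop("no atoms in ", path)
  element <- toupper(trimws(at$elesy))
  fallback <- !nzchar(element) | is.na(element)
  if (any(fallback)) {
    element[fallback] <- sub("[0-9'].*$", "", toupper(trimws(at$elety[fallback])))
  }
  out <- data.frame(
    type = at$type, name = trimws(at$elety), element = element,
    resname = trimws(at$resid), resno = at$resno,
    ins = ifelse(is.na(at$insert) | at$insert == "", "", at$insert),
    chain = ifelse(is.na(at$chain), "", at$chain),
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(as.matrix(out[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in ", path)
  }
  class(out) <- c("lox_atoms", "data.frame")
  out
}

atom_xyz <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z")])
}

#' Locate the catalytic iron
#'
#' @param atoms a `lox_atoms` data frame.
#' @return Numeric xyz of the unique Fe atom.
#' @export
find_iron <- function(atoms) {
  fe <- atoms[atoms$element == "FE", , drop = FALSE]
  if (nrow(fe) == 0L) stop("no cofactor: no Fe atom found")
  if (nrow(fe) > 1L) {
    stop("multiple Fe atoms: ",
         paste(sprintf("%s %s%d", fe$resname, fe$chain, fe$resno), collapse = "; "))
  }
  c(fe$x, fe$y, fe$z)
}

#' Residues coordinating the iron
#'
#' Returns residues owning a candidate ligating atom - a side-chain N, O or
#' S, or a backbone carbonyl O (the route used by the hydrophobic fifth
#' site) - within `cutoff` of the iron (inclusive), sorted by distance.
#'
#' @param atoms a `lox_atoms` data frame.
#' @param fe_xyz iron position from [find_iron()].
#' @param cutoff distance cutoff in Angstrom (default 3.0).
#' @return Data frame `resname`, `resno`, `chain`, `dist`.
#' @export
coordination_shell <- function(atoms, fe_xyz, cutoff = 3.0) {
  cand <- atoms$element %in% c("N", "O", "S") &
    !(atoms$name %in% c("N", "CA", "C")) | atoms$name == "O"
  cand <- cand & atoms$element != "FE"
  sel <- atoms[cand, , drop = FALSE]
  if (nrow(sel) == 0L) return(data.frame(resname = character(0),
                                         resno = integer(0),
                                         chain = character(0),
                                         dist = numeric(0)))
  d <- sqrt(colSums((t(atom_xyz(sel)) - fe_xyz)^2))
  sel <- sel[d <= cutoff, , drop = FALSE]
  d <- d[d <= cutoff]
  if (nrow(sel) == 0L) return(data.frame(resname = character(0),
                                         resno = integer(0),
                                         chain = character(0),
                                         dist = numeric(0)))
  key <- paste(sel$chain, sel$resno, sel$ins, sel$resname)
  best <- tapply(d, key, min)
  first <- !duplicated(key)
  out <- data.frame(resname = sel$resname[first], resno = sel$resno[first],
                    chain = sel$chain[first],
                    dist = as.numeric(best[key[first]]),
                    stringsAsFactors = FALSE)
  out[order(out$dist), , drop = FALSE]
}

#' Extract the ordered fatty-acid carbon chain of a ligand
#'
#' The carboxyl carbon (C1) is the carbon bonded (<= 1.6 Angstrom) to two
#' oxygens; the chain is ordered by a connectivity walk over carbon-carbon
#' bonds (<= 1.9 Angstrom) starting at C1. Bonds of 1.40 Angstrom or less
#' are recorded as double bonds. Branched carbon graphs are rejected.
#'
#' @param atoms a `lox_atoms` data frame.
#' @param ligand_resname residue name of the ligand (e.g. `"LIG"`, `"EPA"`).
#' @return A list of class `ligand_chain`: `carbons` (n x 3 matrix, rows
#'   `C1..Cn` in chemistry numbering from the acid head), `n`,
#'   `double_bonds` (indices `i` meaning a double bond Ci-Ci+1), `oxygens`
#'   (carboxyl oxygen coordinates).
#' @export
ligand_chain <- function(atoms, ligand_resname) {
  lig <- atoms[atoms$resname == ligand_resname, , drop = FALSE]
  if (nrow(lig) == 0L) stop("no ligand residue named ", ligand_resname)
  carb <- lig[lig$element == "C", , drop = FALSE]
  oxy <- lig[lig$element == "O", , drop = FALSE]
  if (nrow(carb) == 0L) stop("ligand has no carbon atoms")
  cxyz <- atom_xyz(carb)
  oxyz <- atom_xyz(oxy)

  n_ox <- if (nrow(oxy)) {
    apply(cxyz, 1L, function(p) sum(sqrt(colSums((t(oxyz) - p)^2)) <= 1.6))
  } else rep(0L, nrow(carb))
  start <- which(n_ox >= 2L)
  if (length(start) == 0L) stop("no carboxyl carbon (carbon bonded to two oxygens)")
  if (length(start) > 1L) stop("ambiguous carboxyl carbon")

  dmat <- as.matrix(stats::dist(cxyz))
  adj <- dmat <= 1.9 & dmat > 0
  deg <- rowSums(adj)
  if (any(deg > 2L)) stop("branched carbon graph")

  order_idx <- integer(nrow(carb))
  order_idx[1L] <- start
  prev <- 0L
  cur <- start
  for (k in seq_len(nrow(carb) - 1L)) {
    nxt <- setdiff(which(adj[cur, ]), prev)
    if (length(nxt) != 1L) stop("broken carbon chain at position ", k)
    prev <- cur
    cur <- nxt
    order_idx[k + 1L] <- cur
  }
  carbons <- cxyz[order_idx, , drop = FALSE]
  rownames(carbons) <- paste0("C", seq_len(nrow(carbons)))
  bond_len <- sqrt(rowSums((carbons[-1L, , drop = FALSE] -
                              carbons[-nrow(carbons), , drop = FALSE])^2))
  structure(
    list(carbons = carbons, n = nrow(carbons),
         double_bonds = unname(which(bond_len <= 1.40)),
         oxygens = oxyz),
    class = "ligand_chain"
  )
}

#' Carbon nearest to the iron
#'
#' @param chain a [ligand_chain()].
#' @param fe_xyz iron position.
#' @param tie_tol two carbons within this margin of the minimum flag a tie
#'   (default 0.05 Angstrom); on a tie the lower index is reported.
#' @return List `index`, `distance`, `tie`, `tied` (all indices within the
#'   tie margin).
#' @export
nearest_carbon <- function(chain, fe_xyz, tie_tol = 0.05) {
  stopifnot(inherits(chain, "ligand_chain"), chain$n >= 1L)
  d <- sqrt(colSums((t(chain$carbons) - fe_xyz)^2))
  tied <- which(d <= min(d) + tie_tol)
  list(index = min(tied), distance = unname(d[min(tied)]),
       tie = length(tied) > 1L, tied = tied)
}

#' Oxygen-channel gate state of a residue
#'
#' A glycine at the gate position leaves the upper mouth of the oxygen
#' channel open; any other residue (alanine in the structures motivating the
#' rule) occludes it, driving O2 deeper into the cavity.
#'
#' @param atoms a `lox_atoms` data frame.
#' @param gate residue selector `"<chain>:<resno>"` (e.g. `"A:427"`).
#' @return List `state` (`"OPEN"`/`"CLOSED"`), `resname`, `resno`, `chain`.
#' @export
gate_state <- function(atoms, gate) {
  res <- select_residue(atoms, gate)
  state <- if (res$resname[1] == "GLY") "OPEN" else "CLOSED"
  list(state = state, resname = res$resname[1],
       resno = res$resno[1], chain = res$chain[1])
}

select_residue <- function(atoms, selector) {
  parts <- strsplit(selector, ":", fixed = TRUE)[[1]]
  if (length(parts) == 2L) {
    sel <- atoms$chain == parts[1] & atoms$resno == as.integer(parts[2])
  } else {
    sel <- atoms$resno == as.integer(parts[1])
  }
  res <- atoms[sel, , drop = FALSE]
  if (nrow(res) == 0L) stop("no residue matching ", selector)
  res
}

residue_ca <- function(atoms, selector) {
  res <- select_residue(atoms, selector)
  ca <- res[res$name == "CA", , drop = FALSE]
  if (nrow(ca) == 0L) stop("residue ", selector, " has no CA atom")
  c(ca$x[1], ca$y[1], ca$z[1])
}

#' Geometric frame of the catalytic pocket
#'
#' The frame is defined per structure by configuration: the gate residue's
#' CA marks the channel mouth, the centroid of the pocket-bottom residues'
#' CA atoms marks the deep end, and the mouth-to-bottom unit vector is the
#' pocket axis along which depth is measured.
#'
#' @param atoms a `lox_atoms` data frame.
#' @param gate gate residue selector `"A:427"`.
#' @param bottom character vector of pocket-bottom residue selectors
#'   (e.g. `c("A:589", "A:620")`).
#' @return A list of class `pocket_frame`: `fe_xyz`, `mouth_xyz`,
#'   `bottom_xyz`, `axis` (unit vector).
#' @export
pocket_frame <- function(atoms, gate, bottom) {
  fe <- find_iron(atoms)
  mouth <- residue_ca(atoms, gate)
  bxyz <- colMeans(do.call(rbind, lapply(bottom, residue_ca, atoms = atoms)))
  v <- bxyz - mouth
  len <- sqrt(sum(v^2))
  if (len < 1e-6) stop("degenerate pocket axis: mouth coincides with bottom")
  structure(list(fe_xyz = fe, mouth_xyz = mouth, bottom_xyz = bxyz,
                 axis = v / len),
            class = "pocket_frame")
}

pocket_depth <- function(xyz, frame) {
  sum((xyz - frame$mouth_xyz) * frame$axis)
}

#' Orientation of the fatty-acid head in the pocket
#'
#' Depth is the projection onto the pocket axis; the substrate is
#' `HEAD_INTERNAL` when its carboxyl carbon (C1) lies deeper than its tail
#' carbon (Cn), else `HEAD_EXTERNAL`.
#'
#' @param chain a [ligand_chain()].
#' @param frame a [pocket_frame()].
#' @return `"HEAD_INTERNAL"` or `"HEAD_EXTERNAL"`.
#' @export
head_orientation <- function(chain, frame) {
  stopifnot(inherits(frame, "pocket_frame"))
  d1 <- pocket_depth(chain$carbons[1L, ], frame)
  dn <- pocket_depth(chain$carbons[chain$n, ], frame)
  if (d1 > dn) "HEAD_INTERNAL" else "HEAD_EXTERNAL"
}

#' Protein residues contacting the ligand
#'
#' @param atoms a `lox_atoms` data frame.
#' @param chain a [ligand_chain()] (its carbon and oxygen atoms are used).
#' @param ligand_resname ligand residue name (excluded from the protein
#'   side).
#' @param cutoff contact cutoff in Angstrom (default 4.0).
#' @return Data frame of unique contacting residues in sequence order.
#' @export
contacts <- function(atoms, chain, ligand_resname, cutoff = 4.0) {
  lig_xyz <- rbind(chain$carbons, chain$oxygens)
  prot <- atoms[atoms$resname != ligand_resname & atoms$element != "FE", ,
                drop = FALSE]
  if (nrow(prot) == 0L) return(data.frame(resname = character(0),
                                          resno = integer(0),
                                          chain = character(0)))
  pxyz <- atom_xyz(prot)
  mind <- apply(pxyz, 1L, function(p) min(sqrt(colSums((t(lig_xyz) - p)^2))))
  hit <- prot[mind <= cutoff, , drop = FALSE]
  key <- paste(hit$chain, hit$resno, hit$ins)
  hit <- hit[!duplicated(key), c("resname", "resno", "chain"), drop = FALSE]
  hit <- hit[order(hit$chain, hit$resno), , drop = FALSE]
  rownames(hit) <- NULL
  hit
}

#' Hydrogen-bond candidates between ligand oxygens and the protein
#'
#' Donor/acceptor geometry is not evaluated; pairs are ligand O to protein
#' N/O within `d_max`.
#'
#' @param atoms a `lox_atoms` data frame.
#' @param chain a [ligand_chain()].
#' @param ligand_resname ligand residue name.
#' @param d_max distance ceiling in Angstrom (default 3.5).
#' @return Data frame with the protein atom, residue and distance per pair.
#' @export
hbonds <- function(atoms, chain, ligand_resname, d_max = 3.5) {
  if (nrow(chain$oxygens) == 0L) {
    return(data.frame(ligand_atom = character(0), atom = character(0),
                      resname = character(0), resno = integer(0),
                      chain = character(0), dist = numeric(0)))
  }
  prot <- atoms[atoms$resname != ligand_resname &
                  atoms$element %in% c("N", "O"), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(chain$oxygens))) {
    if (nrow(prot) == 0L) break
    d <- sqrt(colSums((t(atom_xyz(prot)) - chain$oxygens[i, ])^2))
    sel <- which(d <= d_max)
    if (length(sel)) {
      out[[length(out) + 1L]] <- data.frame(
        ligand_atom = paste0("O", i), atom = prot$name[sel],
        resname = prot$resname[sel], resno = prot$resno[sel],
        chain = prot$chain[sel], dist = d[sel],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(ligand_atom = character(0), atom = character(0),
                      resname = character(0), resno = integer(0),
                      chain = character(0), dist = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
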