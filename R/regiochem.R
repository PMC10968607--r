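normalize_orientation <- function(orientation) {
  o <- toupper(gsub("-", "_", as.character(orientation)[1]))
  if (!o %in% c("HEAD_EXTERNAL", "HEAD_INTERNAL")) {
    stop("orientation must be HEAD_EXTERNAL or HEAD_INTERNAL")
  }
  o
}

normalize_gate <- function(gate) {
  if (is.list(gate)) gate <- gate$state
  g <- toupper(as.character(gate)[1])
  if (!g %in% c("OPEN", "CLOSED")) stop("gate must be OPEN or CLOSED")
  g
}

new_lox_call <- function(nearest, candidates, oxidation, gate, orientation,
                         flags, rationale = NULL) {
  structure(
    list(nearest = nearest, candidates = candidates, oxidation = oxidation,
         lox_type = paste0("LOX", oxidation), gate = gate,
         orientation = orientation, flags = flags, rationale = rationale),
    class = "lox_call"
  )
}

#' @export
print.lox_call <- function(x, ...) {
  cat(sprintf("%s: nearest carbon C%d -> oxidation at C%d (gate %s, %s)\n",
              x$lox_type, x$nearest, x$oxidation, x$gate, x$orientation))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Call the LOX type from categorical pose facts
#'
#' The iron abstracts a hydrogen from the substrate carbon nearest to it
#' (index `n`, numbered from the carboxyl carbon C1); molecular oxygen then
#' adds two carbons away, at `n - 2` or `n + 2`. Which side is chosen is set
#' by the oxygen channel: the two candidates are labelled by pocket side -
#' with the head external, `n - 2` lies toward the pocket entrance and
#' `n + 2` toward the bottom; with the head internal the sides swap. An open
#' gate (glycine) lets O2 attack the entrance-side candidate; a closed gate
#' (alanine or bulkier) drives O2 deeper, selecting the bottom-side
#' candidate. A candidate falling off the chain ends falls back to the other
#' one, flagged `single_candidate`.
#'
#' @param n index of the carbon nearest the iron (1-based from the carboxyl
#'   carbon).
#' @param chain_length number of carbons in the substrate chain.
#' @param orientation `"HEAD_EXTERNAL"` or `"HEAD_INTERNAL"` (see
#'   [head_orientation()]).
#' @param gate `"OPEN"` or `"CLOSED"`, or a [gate_state()] result.
#' @return A `lox_call` list: `nearest`, `candidates`, `oxidation`,
#'   `lox_type` (`"LOX<k>"`), `gate`, `orientation`, `flags`.
#' @export
call_lox_type_categorical <- function(n, chain_length, orientation, gate) {
  n <- as.integer(n)
  chain_length <- as.integer(chain_length)
  if (n < 1L || n > chain_length) {
    stop("nearest carbon index ", n, " outside chain of length ", chain_length)
  }
  orientation <- normalize_orientation(orientation)
  gate <- normalize_gate(gate)

  if (orientation == "HEAD_EXTERNAL") {
    external_side <- n - 2L
    deep_side <- n + 2L
  } else {
    external_side <- n + 2L
    deep_side <- n - 2L
  }
  selected <- if (gate == "OPEN") external_side else deep_side
  other <- if (gate == "OPEN") deep_side else external_side

  in_range <- function(k) k >= 1L && k <= chain_length
  flags <- character(0)
  if (!in_range(selected)) {
    if (!in_range(other)) {
      stop("both oxidation candidates fall outside the chain")
    }
    selected <- other
    flags <- "single_candidate"
  } else if (!in_range(other)) {
    flags <- "single_candidate"
  }
  candidates <- sort(c(n - 2L, n + 2L))
  candidates <- candidates[candidates >= 1L & candidates <= chain_length]
  new_lox_call(n, candidates, selected, gate, orientation, flags)
}

#' Call the LOX type from pose geometry
#'
#' Geometric counterpart of [call_lox_type_categorical()]: the nearest
#' carbon comes from iron-carbon distances; the O2 delivery point is the
#' channel mouth when the gate is open and the pocket bottom when closed;
#' among the in-range candidates `n - 2` / `n + 2`, the carbon closest to
#' the delivery point is oxidized. Flags record iron-distance ties
#' (`tie_at_iron`), a chosen carbon that is not an endpoint of any recorded
#' double bond (`candidate_not_at_double_bond`), and single-candidate
#' boundary cases.
#'
#' @param chain a [ligand_chain()].
#' @param frame a [pocket_frame()].
#' @param gate `"OPEN"`/`"CLOSED"` or a [gate_state()] result.
#' @param fe_xyz iron position; defaults to the frame's.
#' @return A `lox_call`; `rationale` holds the candidate-to-delivery-point
#'   distances.
#' @export
call_lox_type_geometric <- function(chain, frame, gate, fe_xyz = frame$fe_xyz) {
  stopifnot(inherits(chain, "ligand_chain"), inherits(frame, "pocket_frame"))
  gate <- normalize_gate(gate)
  nc <- nearest_carbon(chain, fe_xyz)
  n <- nc$index
  candidates <- c(n - 2L, n + 2L)
  candidates <- candidates[candidates >= 1L & candidates <= chain$n]
  if (length(candidates) == 0L) {
    stop("both oxidation candidates fall outside the chain")
  }
  delivery <- if (gate == "OPEN") frame$mouth_xyz else frame$bottom_xyz
  dcand <- vapply(candidates, function(k) {
    sqrt(sum((chain$carbons[k, ] - delivery)^2))
  }, numeric(1))
  k <- candidates[which.min(dcand)]

  flags <- character(0)
  if (nc$tie) flags <- c(flags, "tie_at_iron")
  if (length(candidates) == 1L) flags <- c(flags, "single_candidate")
  at_double <- k %in% chain$double_bonds | (k - 1L) %in% chain$double_bonds
  if (!at_double) flags <- c(flags, "candidate_not_at_double_bond")

  new_lox_call(n, candidates, k, gate, head_orientation(chain, frame), flags,
               rationale = list(candidates = candidates,
                                delivery_distances = dcand,
                                tied_at_iron = nc$tied,
                                iron_distance = nc$distance))
}

#' Full pose report for one structure
#'
#' Wires the pocket-geometry operations together: parse, locate the iron,
#' extract the ligand chain, build the pocket frame, and emit the geometric
#' regiochemistry call plus contacts and hydrogen-bond candidates.
#'
#' @param path PDB file path.
#' @param ligand ligand residue name.
#' @param gate gate residue selector `"A:427"`.
#' @param bottom pocket-bottom residue selectors.
#' @param json optional path; when given, the report is also written as JSON.
#' @return A list of class `pose_report` with the pose facts and the
#'   `lox_call`.
#' @export
pose_report <- function(path, ligand, gate, bottom, json = NULL) {
  atoms <- load_structure(path)
  fe <- find_iron(atoms)
  chain <- ligand_chain(atoms, ligand)
  frame <- pocket_frame(atoms, gate, bottom)
  gs <- gate_state(atoms, gate)
  nc <- nearest_carbon(chain, fe)
  call <- call_lox_type_geometric(chain, frame, gs, fe)
  rep <- structure(
    list(
      path = path, ligand = ligand,
      nearest_carbon = nc$index, nearest_distance = nc$distance,
      tie_at_iron = nc$tie,
      gate = gs, orientation = head_orientation(chain, frame),
      oxidation = call$oxidation, lox_type = call$lox_type,
      flags = call$flags,
      contacts = contacts(atoms, chain, ligand),
      hbonds = hbonds(atoms, chain, ligand),
      shell = coordination_shell(atoms, fe)
    ),
    class = "pose_report"
  )
  if (!is.null(json)) {
    jsonlite::write_json(unclass(rep), json, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  rep
}
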