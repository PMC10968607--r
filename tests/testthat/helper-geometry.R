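# random rigid motions for invariance tests

random_rotation <- function() {
  m <- matrix(stats::rnorm(9), 3L, 3L)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

# apply a rotation + translation to every atom of a lox_atoms data frame
rigid_transform <- function(atoms, rot, shift) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(rot)
  atoms$x <- xyz[, 1L] + shift[1L]
  atoms$y <- xyz[, 2L] + shift[2L]
  atoms$z <- xyz[, 3L] + shift[3L]
  atoms
}

# pose facts derived from an atom set with the standard fixture selectors
pose_facts <- function(atoms) {
  fe <- find_iron(atoms)
  chain <- ligand_chain(atoms, "LIG")
  frame <- pocket_frame(atoms, "A:427", c("A:589", "A:620"))
  gs <- gate_state(atoms, "A:427")
  nc <- nearest_carbon(chain, fe)
  call <- call_lox_type_geometric(chain, frame, gs, fe)
  list(nearest = nc$index, tie = nc$tie, gate = gs$state,
       orientation = head_orientation(chain, frame),
       oxidation = call$oxidation, chain = chain, frame = frame)
}
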