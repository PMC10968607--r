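# most structure tests run on one generated idealized pocket
fx <- make_pocket_fixture(20, 10, "HEAD_EXTERNAL", "GLY", seed = 7)
atoms <- load_structure(fx$path)

test_that("PDB parsing returns every atom with elements and exact anchors", {
  expect_s3_class(atoms, "lox_atoms")
  expect_equal(nrow(atoms), 12L + 1L + 22L)  # 3 residues, Fe, C20 + 2 O
  fe_row <- atoms[atoms$element == "FE", ]
  expect_equal(fe_row$type, "HETATM")
  # fixture anchor coordinates survive the write/read round trip
  expect_equal(unname(find_iron(atoms)), c(0, 0, -7.5), tolerance = 1e-3)
  ca <- atoms[atoms$name == "CA" & atoms$resno == 427, ]
  expect_equal(c(ca$x, ca$y, ca$z), c(0, 0, 0), tolerance = 1e-3)
  expect_error(load_structure(tempfile("nothere")), "no such file")
})

test_that("iron lookup demands exactly one cofactor", {
  no_fe <- atoms[atoms$element != "FE", ]
  class(no_fe) <- class(atoms)
  expect_error(find_iron(no_fe), "no cofactor")
  two_fe <- rbind(atoms, atoms[atoms$element == "FE", ])
  class(two_fe) <- class(atoms)
  expect_error(find_iron(two_fe), "multiple Fe")
})

test_that("the coordination shell honors its inclusive cutoff", {
  mk <- function(name, element, resname, resno, d) {
    data.frame(type = "ATOM", name = name, element = element,
               resname = resname, resno = resno, ins = "", chain = "A",
               x = d, y = 0, z = 0, stringsAsFactors = FALSE)
  }
  shell_atoms <- rbind(
    mk("NE2", "N", "HIS", 1, 2.2), mk("NE2", "N", "HIS", 2, 2.2),
    mk("NE2", "N", "HIS", 3, 2.2), mk("OD1", "O", "ASN", 4, 2.3),
    mk("O", "O", "ILE", 5, 2.5),      # backbone carbonyl route
    mk("CB", "C", "LEU", 6, 2.0),     # carbon: never a ligator
    mk("OG", "O", "SER", 7, 3.0),     # exactly at cutoff: included
    mk("OG", "O", "THR", 8, 3.2))     # beyond cutoff
  class(shell_atoms) <- c("lox_atoms", "data.frame")
  shell <- coordination_shell(shell_atoms, c(0, 0, 0), cutoff = 3.0)
  expect_equal(nrow(shell), 6L)
  expect_true(all(diff(shell$dist) >= 0))
  expect_false(8 %in% shell$resno)
  expect_equal(nrow(coordination_shell(shell_atoms, c(0, 0, 0), cutoff = 1.0)), 0L)
})

test_that("the ligand chain walks from the carboxyl head, in any atom order", {
  chain <- ligand_chain(atoms, "LIG")
  expect_equal(chain$n, 20L)
  expect_equal(rownames(chain$carbons)[1], "C1")
  expect_equal(chain$double_bonds, fx$truth$double_bonds)
  expect_equal(nrow(chain$oxygens), 2L)
  # permutation invariance of the connectivity walk
  set.seed(2)
  shuffled <- atoms[sample(nrow(atoms)), ]
  class(shuffled) <- class(atoms)
  chain2 <- ligand_chain(shuffled, "LIG")
  expect_equal(chain2$carbons, chain$carbons)
  expect_equal(chain2$double_bonds, chain$double_bonds)
  # stripping the oxygens removes the carboxyl anchor
  no_ox <- atoms[!(atoms$resname == "LIG" & atoms$element == "O"), ]
  class(no_ox) <- class(atoms)
  expect_error(ligand_chain(no_ox, "LIG"), "carboxyl")
  expect_error(ligand_chain(atoms, "XYZ"), "no ligand")
})

test_that("branched carbon graphs are rejected", {
  lig <- atoms[atoms$resname == "LIG", ]
  branch <- lig[lig$name == "C5", ]
  branch$name <- "C99"
  branch$x <- branch$x + 1.4
  branched <- rbind(atoms, branch)
  class(branched) <- class(atoms)
  expect_error(ligand_chain(branched, "LIG"), "branched")
})

test_that("nearest carbon matches brute force and reports ties low-first", {
  chain <- ligand_chain(atoms, "LIG")
  fe <- find_iron(atoms)
  nc <- nearest_carbon(chain, fe)
  brute <- which.min(sqrt(colSums((t(chain$carbons) - fe)^2)))
  expect_equal(nc$index, unname(brute))
  expect_equal(nc$index, 10L)
  expect_false(nc$tie)
  # engineered tie: two carbons equidistant from the iron
  tied <- structure(list(
    carbons = matrix(c(0, 0, 2, 0, 0, -2, 0, 0, 6), 3, 3, byrow = TRUE,
                     dimnames = list(c("C1", "C2", "C3"), NULL)),
    n = 3L, double_bonds = integer(0), oxygens = matrix(numeric(0), 0, 3)),
    class = "ligand_chain")
  tc <- nearest_carbon(tied, c(0, 0, 0))
  expect_true(tc$tie)
  expect_equal(tc$index, 1L)
  expect_equal(sort(unname(tc$tied)), c(1L, 2L))
})

test_that("head orientation flips under reflection through the iron plane", {
  chain <- ligand_chain(atoms, "LIG")
  frame <- pocket_frame(atoms, "A:427", c("A:589", "A:620"))
  expect_equal(head_orientation(chain, frame), "HEAD_EXTERNAL")
  flipped <- chain
  flipped$carbons[, 3] <- -15 - flipped$carbons[, 3]
  expect_equal(head_orientation(flipped, frame), "HEAD_INTERNAL")
})

test_that("gate state is open for glycine and closed otherwise", {
  expect_equal(gate_state(atoms, "A:427")$state, "OPEN")
  fx_ala <- make_pocket_fixture(16, 8, "HEAD_INTERNAL", "ALA", seed = 7)
  atoms_ala <- load_structure(fx_ala$path)
  expect_equal(gate_state(atoms_ala, "A:427")$state, "CLOSED")
  expect_error(gate_state(atoms, "A:999"), "no residue")
})

test_that("contact and hydrogen-bond cutoffs behave at their boundaries", {
  base <- data.frame(
    type = "ATOM",
    name = c("CB", "CB", "OG"), element = c("C", "C", "O"),
    resname = c("LEU", "VAL", "SER"), resno = c(10L, 11L, 12L),
    ins = "", chain = "A",
    x = c(3.8, 4.2, 2.9), y = 0, z = 0, stringsAsFactors = FALSE)
  chain <- structure(list(
    carbons = matrix(c(0, 0, 0), 1, 3,
                     dimnames = list("C1", NULL)),
    n = 1L, double_bonds = integer(0),
    oxygens = matrix(c(0, 0, 0), 1, 3)), class = "ligand_chain")
  class(base) <- c("lox_atoms", "data.frame")
  cts <- contacts(base, chain, "LIG", cutoff = 4.0)
  expect_equal(cts$resno, c(10L, 12L))  # 4.2 excluded
  hb <- hbonds(base, chain, "LIG", d_max = 3.5)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$resname, "SER")
  expect_equal(hb$dist, 2.9, tolerance = 1e-9)
})

test_that("geometry calls are invariant under rigid motion", {
  set.seed(12)
  before <- pose_facts(atoms)
  for (k in 1:3) {
    moved <- rigid_transform(atoms, random_rotation(),
                             stats::rnorm(3, sd = 20))
    after <- pose_facts(moved)
    expect_equal(after$nearest, before$nearest)
    expect_equal(after$gate, before$gate)
    expect_equal(after$orientation, before$orientation)
    expect_equal(after$oxidation, before$oxidation)
  }
})
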