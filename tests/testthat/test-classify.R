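test_that("the decision table is total and matches the group definitions", {
  grid <- expand.grid(s1 = 0:6, s2 = 2:5, x4 = c("N", "H", "Q", "S"),
                      tandem = c(TRUE, FALSE), stringsAsFactors = FALSE)
  expected <- function(s1, s2, x4, tandem) {
    if (s2 == 4) {
      return(switch(x4, N = "G4a", Q = "G4b", S = "G5a", H = "G5b"))
    }
    if (s2 == 3) {
      if (s1 < 4 && x4 == "H") return("G3")
      if (x4 == "N" && tandem) return("G6")
      if (x4 == "N") return("UNRESOLVED_12")
    }
    "UNCLASSIFIED"
  }
  labels <- c("G1", "G2", "G3", "G4a", "G4b", "G5a", "G5b", "G6",
              "UNRESOLVED_12", "UNCLASSIFIED")
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    got <- classify_pattern(spaced_pattern(g$s1, g$s2, g$x4, g$tandem))
    expect_length(got, 1L)
    expect_true(got %in% labels)
    expect_equal(got, expected(g$s1, g$s2, g$x4, g$tandem),
                 info = paste(g, collapse = "/"))
  }
})

test_that("discriminating motifs separate the two canonical groups", {
  motifs <- motif_config(group1 = "YWRPDGFE", group2 = "FHKNWSTQ")
  p <- spaced_pattern(4, 3, "N")
  base <- strrep("A", 200)
  expect_equal(classify_pattern(p, motifs, paste0(base, "YWRPDGFE", base)), "G1")
  expect_equal(classify_pattern(p, motifs, paste0(base, "FHKNWSTQ", base)), "G2")
  expect_equal(classify_pattern(p, motifs, paste0(base, base)), "UNRESOLVED_12")
  # without motifs the canonical pattern stays unresolved
  expect_equal(classify_pattern(p, motif_config(), paste0(base, "YWRPDGFE")),
               "UNRESOLVED_12")
})

test_that("patterns below the completeness floor are refused", {
  expect_error(classify_pattern(fake_pattern("x", 2L)), "completeness")
})

test_that("the motif dialect converts to anchored residue patterns", {
  expect_equal(motif_regex("W-x(2)-[DE]-F"), "W.{2}[DE]F")
  expect_equal(motif_regex("WRF-x(1,3)-G"), "WRF.{1,3}G")
  expect_equal(motif_regex("x-H"), ".H")
  expect_error(motif_regex("W-?"), "invalid motif token")
})

test_that("classification ignores residues outside the coordination sites", {
  sim <- make_group_sequences(seed = 71, per_group = 1L)
  pats <- scan_all(sim$records, sim$anchors)
  labs <- classify_all(pats, sim$records, sim$motifs)
  set.seed(8)
  for (gid in c("G3_1", "G4a_1", "G5b_1", "G6_1")) {
    rec <- sim$records[sim$records$id == gid, , drop = FALSE]
    tr <- sim$truth[sim$truth$id == gid, ]
    letters <- strsplit(rec$residues, "")[[1]]
    sites <- unlist(tr[c("H1", "H2", "H3", "X4", "T5")])
    shield <- unique(as.vector(outer(sites, -3:3, `+`)))
    free <- setdiff(seq_along(letters), shield)
    pos <- sample(free, 25)
    letters[pos] <- sample(strsplit("ACDEFGIKMPQRSTVWY", "")[[1]],
                           25, replace = TRUE)
    mutant <- protein_records(gid, paste(letters, collapse = ""))
    p2 <- scan_coordination(mutant, sim$anchors)
    expect_equal(classify_pattern(p2, sim$motifs, mutant$residues),
                 unname(labs[gid]), info = gid)
  }
})
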