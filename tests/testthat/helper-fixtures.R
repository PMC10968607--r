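# shared builders for small synthetic inputs used across test files

# minimal coordination pattern with a given completeness (sites are filled
# in role order); enough structure for curation and grouping tests
fake_pattern <- function(id, completeness = 5L, x4 = "N") {
  found <- seq_len(5L) <= completeness
  pos <- ifelse(found, c(100L, 105L, 400L, 404L, 590L), NA_integer_)
  res <- ifelse(found, c("H", "H", "H", x4, "I"), NA_character_)
  structure(
    list(id = id,
         sites = data.frame(role = c("H1", "H2", "H3", "X4", "T5"),
                            residue = res, position = pos, found = found,
                            stringsAsFactors = FALSE),
         s1 = if (completeness >= 2L) 4L else NA_integer_,
         s2 = if (completeness >= 4L) 3L else NA_integer_,
         tandem_his_at_H3 = FALSE,
         completeness = sum(found), reference = "ref", identity = 99),
    class = "coord_pattern"
  )
}

# synthetic coordination pattern with explicit spacings, for decision-table
# walks (positions are consistent with the requested spacings)
spaced_pattern <- function(s1, s2, x4, tandem = FALSE) {
  h1 <- 100L
  h2 <- h1 + s1 + 1L
  h3 <- 400L
  p4 <- h3 + s2 + 1L
  structure(
    list(id = "synthetic",
         sites = data.frame(role = c("H1", "H2", "H3", "X4", "T5"),
                            residue = c("H", "H", "H", x4, "I"),
                            position = c(h1, h2, h3, p4, 600L),
                            found = TRUE, stringsAsFactors = FALSE),
         s1 = as.integer(s1), s2 = as.integer(s2),
         tandem_his_at_H3 = tandem,
         completeness = 5L, reference = "ref", identity = 99),
    class = "coord_pattern"
  )
}

# two diverged sequence blocks (independent backgrounds, ~3% within-block
# mutations): the block split must dominate any tree built over them
make_two_block_records <- function(seed, n_per = 4L, len = 250L,
                                   within = 0.03) {
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  mk_block <- function(prefix) {
    proto <- sample(aa, len, replace = TRUE)
    vapply(seq_len(n_per), function(k) {
      s <- proto
      if (k > 1L) {
        pos <- which(stats::runif(len) < within)
        s[pos] <- vapply(s[pos], function(a) sample(setdiff(aa, a), 1L),
                         character(1))
      }
      paste(s, collapse = "")
    }, character(1))
  }
  protein_records(
    id = c(paste0("blkA_", seq_len(n_per)), paste0("blkB_", seq_len(n_per))),
    residues = c(mk_block("A"), mk_block("B")),
    source = "fixture"
  )
}

# bootstrap support of the bipartition separating `ids` from the rest,
# read off a supported tree (NA when no internal edge induces that split)
support_of_split <- function(tree, ids) {
  ntip <- length(tree$tip.label)
  want <- sort(match(ids, tree$tip.label))
  pp <- ape::prop.part(tree)
  supp <- suppressWarnings(as.numeric(tree$node.label))
  for (k in seq_along(pp)) {
    side <- sort(pp[[k]])
    comp <- sort(setdiff(seq_len(ntip), side))
    if (identical(side, want) || identical(comp, want)) return(supp[k])
  }
  NA_real_
}
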