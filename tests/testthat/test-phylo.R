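test_that("pairwise distances follow the Poisson-corrected p-distance", {
  set.seed(5)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  base <- sample(aa, 100, replace = TRUE)
  # exactly 10 of 100 aligned columns differ, no gaps
  mut <- base
  pos <- sample(100, 10)
  mut[pos] <- vapply(base[pos], function(a) sample(setdiff(aa, a), 1),
                     character(1))
  recs <- protein_records(c("a", "b", "c"),
                          c(paste(base, collapse = ""),
                            paste(mut, collapse = ""),
                            paste(base, collapse = "")))
  d <- distance_matrix(recs)
  expect_equal(unname(d["a", "c"]), 0)            # identical pair
  expect_equal(unname(d["a", "b"]), -log(0.90), tolerance = 1e-12)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
})

test_that("saturated pairs are clamped at the documented maximum", {
  set.seed(9)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  recs <- protein_records(paste0("r", 1:3), vapply(1:3, function(i) {
    paste(sample(aa, 300, replace = TRUE), collapse = "")
  }, character(1)))
  d <- distance_matrix(recs)
  expect_true(all(d[upper.tri(d)] <= -log(0.05) + 1e-9))
})

test_that("neighbor joining resolves four taxa by the four-point condition", {
  # additive distances generated on ((A,B),(C,D)) with internal edge 1.0
  d <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  d["A", "B"] <- d["B", "A"] <- 0.3
  d["C", "D"] <- d["D", "C"] <- 0.4
  for (i in c("A", "B")) for (j in c("C", "D")) {
    d[i, j] <- d[j, i] <- 0.15 + 1.0 + 0.2
  }
  # enumeration oracle: the pairing with the smallest sum of cross terms
  sums <- c(AB_CD = d["A", "B"] + d["C", "D"],
            AC_BD = d["A", "C"] + d["B", "D"],
            AD_BC = d["A", "D"] + d["B", "C"])
  expect_equal(names(which.min(sums)), "AB_CD")
  tree <- nj_tree(d)
  pp <- ape::prop.part(tree)
  sides <- lapply(pp, function(s) sort(tree$tip.label[s]))
  expect_true(any(vapply(sides, identical, logical(1), c("A", "B"))) ||
                any(vapply(sides, identical, logical(1), c("C", "D"))))
})

test_that("three taxa get exact closed-form branch lengths", {
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree <- nj_tree(d)
  lens <- sort(tree$edge.length)
  expect_equal(lens, sort(c(0.5, 1.5, 2.5)))
})

test_that("neighbor joining recovers random additive topologies", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    gen <- ape::rtree(n, br = function(k) stats::runif(k, 0.1, 1))
    gen <- ape::unroot(gen)
    d <- ape::cophenetic.phylo(gen)
    est <- nj_tree(d)
    expect_equal(ape::dist.topo(ape::unroot(est), gen), 0,
                 ignore_attr = TRUE)
  }
})

test_that("degenerate matrices are rejected", {
  d <- matrix(c(0, Inf, Inf, 0), 2, 2)
  expect_error(nj_tree(d), "3 taxa")
  d3 <- matrix(Inf, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(d3), "non-finite")
})

test_that("bootstrap supports stay within [0, B] and B = 1 is binary", {
  recs <- make_two_block_records(seed = 3, n_per = 3L, len = 150L)
  msa <- progressive_alignment(recs)
  t1 <- bootstrap_supports(recs, B = 1L, seed = 2, msa = msa)
  supp <- suppressWarnings(as.numeric(t1$node.label))
  expect_true(all(supp[!is.na(supp)] %in% c(0, 1)))
  t25 <- bootstrap_supports(recs, B = 25L, seed = 2, msa = msa)
  supp25 <- suppressWarnings(as.numeric(t25$node.label))
  expect_true(all(supp25[!is.na(supp25)] >= 0 & supp25[!is.na(supp25)] <= 25))
  expect_error(bootstrap_supports(recs, B = 0L), "B must be")
})

test_that("the block split keeps its support when record order is permuted", {
  recs <- make_two_block_records(seed = 11, n_per = 4L, len = 200L)
  blockA <- recs$id[1:4]
  perm <- recs[c(5, 2, 7, 4, 1, 8, 3, 6), , drop = FALSE]
  class(perm) <- c("lox_records", "data.frame")
  for (r in list(recs, perm)) {
    tree <- bootstrap_supports(r, B = 25L, seed = 6)
    expect_gte(support_of_split(tree, blockA), 20)
  }
})

test_that("supported trees round-trip through Newick with node labels", {
  recs <- make_two_block_records(seed = 4, n_per = 3L, len = 120L)
  tree <- bootstrap_supports(recs, B = 10L, seed = 1)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_support_tree(tree, f)
  back <- ape::read.tree(f)
  expect_setequal(back$tip.label, recs$id)
  expect_true(any(!is.na(suppressWarnings(as.numeric(back$node.label)))))
})
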