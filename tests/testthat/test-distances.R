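# K2P distances, patristic distances, neighbor joining, midpoint rooting.

test_that("pair counts follow pairwise deletion over unambiguous bases", {
  pc <- pair_counts("ACGTACGTAC", "ACGTACGTAC")
  expect_equal(pc[c("P", "Q", "n_sites")],
               list(P = 0, Q = 0, n_sites = 10L))

  pc <- pair_counts("ACGTACGTAC", "GCGTACGTAC")   # one A<->G transition
  expect_equal(pc$P, 0.1)
  expect_equal(pc$Q, 0)

  pc <- pair_counts("AC-TACGTAC", "ACGTACGTAN")   # gap + N columns dropped
  expect_equal(pc$n_sites, 8L)

  expect_error(pair_counts("ACG", "ACGT"), "differ in length")
  expect_error(pair_counts("NNNN", "ACGT"), "no overlap")
})

test_that("K2P matches the closed form and flags saturation", {
  expect_equal(k2p_distance(0, 0), 0)
  expect_equal(k2p_distance(0.1, 0), -0.5 * log(0.8), tolerance = 1e-12)
  expect_equal(round(k2p_distance(0.1, 0), 6), 0.111572)
  expect_identical(k2p_distance(0.45, 0.10), Inf)   # 1-2P-Q = 0
  expect_identical(k2p_distance(0.0, 0.55), Inf)    # 1-2Q < 0
})

test_that("K2P matrices are symmetric and agree with ape::dist.dna", {
  aln <- toy_alignment(c(a = "ACGTACGTAC", b = "ACGTACGTAC",
                         c = "GCGTACGTAC"))
  m <- k2p_matrix(aln)
  expect_equal(diag(m), c(a = 0, b = 0, c = 0))
  expect_equal(m, t(m), ignore_attr = TRUE)
  expect_equal(m["a", "b"], 0)
  expect_equal(round(m["a", "c"], 4), 0.1116)

  set.seed(3)
  for (i in 1:5) {
    tp <- simulate_tree(simulation_config(n_species = 4,
                                          tips_per_species = 2,
                                          seed = 100 + i))
    aln <- simulate_sequences(tp$tree, 400, kappa = 3, seed = NULL)
    m <- k2p_matrix(aln)
    bin <- ape::as.DNAbin(lapply(apply(aln$mat, 1, paste, collapse = ""),
                                 function(s) strsplit(tolower(s), "")[[1]]))
    ref <- as.matrix(ape::dist.dna(bin, model = "K80",
                                   pairwise.deletion = TRUE))
    expect_equal(m[rownames(ref), colnames(ref)], ref,
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("column duplication leaves K2P unchanged; d >= p-distance", {
  aln <- toy_alignment(c(a = "ACGTACGTAC", b = "GCGTACCTAC"))
  dup <- toy_alignment(c(a = strrep("ACGTACGTAC", 2),
                         b = strrep("GCGTACCTAC", 2)))
  expect_equal(k2p_matrix(aln)["a", "b"], k2p_matrix(dup)["a", "b"])

  pc <- pair_counts("ACGTACGTAC", "GCGTACCTAC")
  p_dist <- pc$P + pc$Q
  expect_gte(k2p_distance(pc), p_dist)
})

test_that("patristic distances are path sums and additive", {
  expect_equal(patristic_matrix(read_newick("(A:0.1,B:0.2);"))["A", "B"],
               0.3)
  m <- patristic_matrix(read_newick("((A:1,B:1):1,(C:1,D:1):1);"))
  expect_equal(m["A", "C"], 4)
  expect_equal(m["A", "B"], 2)

  set.seed(11)
  tr <- ape::rtree(10)
  m <- patristic_matrix(tr)
  expect_equal(m, patristic_oracle(tr)[rownames(m), colnames(m)],
               tolerance = 1e-9, ignore_attr = TRUE)
  # four-point condition on every quartet
  labs <- rownames(m)
  for (q in combn(10, 4, simplify = FALSE)) {
    ij <- labs[q]
    s <- sort(c(m[ij[1], ij[2]] + m[ij[3], ij[4]],
                m[ij[1], ij[3]] + m[ij[2], ij[4]],
                m[ij[1], ij[4]] + m[ij[2], ij[3]]))
    expect_lt(s[3] - s[2], 1e-9)
  }

  tr$edge.length <- NULL
  expect_error(patristic_matrix(tr), "missing branch lengths")
})

test_that("neighbor joining inverts patristic_matrix on additive input", {
  true <- read_newick("((A:1,B:2):0.5,(C:0.7,D:1.3):0.9);")
  m <- patristic_matrix(true)
  nj <- neighbor_joining(m)
  expect_equal(patristic_matrix(nj)[rownames(m), colnames(m)], m,
               tolerance = 1e-9, ignore_attr = TRUE)

  set.seed(5)
  for (i in 1:10) {
    tr <- ape::rtree(sample(4:12, 1))
    m <- patristic_matrix(tr)
    nj <- neighbor_joining(m)
    expect_equal(patristic_matrix(nj)[rownames(m), colnames(m)], m,
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("neighbor joining handles degenerate and saturated input", {
  # three taxa: closed-form branch lengths
  m3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  nj3 <- neighbor_joining(m3)
  p <- patristic_matrix(nj3)
  expect_equal(p["A", "B"], 3, tolerance = 1e-9)
  expect_equal(p["A", "C"], 4, tolerance = 1e-9)
  expect_equal(p["B", "C"], 5, tolerance = 1e-9)

  z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  njz <- neighbor_joining(z)
  expect_true(all(njz$edge.length == 0))
  expect_true(all(patristic_matrix(njz) == 0))

  zi <- z; zi["a", "b"] <- zi["b", "a"] <- Inf
  expect_error(neighbor_joining(zi), "saturated")
})

test_that("midpoint rooting preserves patristic distances", {
  tr <- midpoint_root(read_newick("(A:1,B:3);"))
  depth <- ape::node.depth.edgelength(tr)
  expect_equal(depth[1:2], c(2, 2))   # root placed 2.0 from each tip
  expect_equal(patristic_matrix(tr)["A", "B"], 4)

  set.seed(13)
  for (i in 1:10) {
    tr <- ape::rtree(sample(4:15, 1), rooted = FALSE)
    m0 <- patristic_matrix(tr)
    m1 <- patristic_matrix(midpoint_root(tr))
    expect_equal(m1[rownames(m0), colnames(m0)], m0,
                 tolerance = 1e-9, ignore_attr = TRUE)
  }

  flat <- read_newick("((A:0,B:0):0,C:0);")
  expect_warning(midpoint_root(ape::unroot(flat)), "all branch lengths zero")
})

test_that("distance matrices round-trip through square CSV and PHYLIP", {
  m <- patristic_matrix(read_newick("((A:1,B:2):0.5,C:1.5);"))
  f <- tempfile(fileext = ".csv")
  write_distmat(m, f)
  expect_equal(read_distmat(f), m, tolerance = 1e-12, ignore_attr = TRUE)

  fp <- tempfile(fileext = ".phy")
  writeLines(c("3",
               paste("A", paste(m["A", ], collapse = " ")),
               paste("B", paste(m["B", ], collapse = " ")),
               paste("C", paste(m["C", ], collapse = " "))), fp)
  expect_equal(read_distmat(fp), m, tolerance = 1e-12, ignore_attr = TRUE)
})
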