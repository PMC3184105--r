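test_that("Poisson distance follows the -ln(1-p) closed form with the gap rule", {
  aln <- c(t1 = "ACDEFGHI", t2 = "ACDEFGHI")
  d <- poissonDist(aln)
  expect_equal(d$d["t1", "t2"], 0)

  # half of comparable sites differ -> d = ln 2
  aln2 <- c(t1 = "AAAA", t2 = "AACC")
  d2 <- poissonDist(aln2)
  expect_equal(d2$p["t1", "t2"], 0.5)
  expect_equal(d2$d["t1", "t2"], log(2))

  # gap column excluded: 3 comparable sites, all equal
  aln3 <- c(t1 = "AC-A", t2 = "ACGA")
  d3 <- poissonDist(aln3)
  expect_equal(d3$n_sites["t1", "t2"], 3)
  expect_equal(d3$d["t1", "t2"], 0)
  # X treated as unknown too
  expect_equal(poissonDist(c(a = "AXAA", b = "ACAA"))$n_sites["a", "b"], 3)

  expect_error(poissonDist(c(a = "AAAA", b = "CCCC")), "saturated")
  expect_error(poissonDist(c(a = "--AA", b = "CC--")), "no comparable sites")
})

test_that("pairwise vs complete deletion differ exactly as defined", {
  aln <- c(a = "ACDE-GHI", b = "ACDEFGHI", c = "AC-EFGHI")
  dp <- poissonDist(aln, deletion = "pairwise")
  dc <- poissonDist(aln, deletion = "complete")
  expect_equal(dp$n_sites["a", "b"], 7)
  expect_equal(dc$n_sites["a", "b"], 6)   # both gap columns dropped globally
})

test_that("Poisson distances are permutation-equivariant in taxa", {
  set.seed(47)
  rows <- stats::setNames(vapply(1:5, function(i) random_protein(200), ""),
                          paste0("t", 1:5))
  # introduce shared differences
  rows[2] <- paste0(substr(rows[1], 1, 150), substr(rows[2], 151, 200))
  d <- poissonDist(rows)$d
  perm <- c(3, 1, 5, 2, 4)
  d_perm <- poissonDist(rows[perm])$d
  expect_equal(d_perm[names(rows), names(rows)], d)
})

test_that("three-taxon NJ matches the closed form and rejects bad input", {
  d <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- njTree(d)
  lens <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(lens[c("a", "b", "c")]), c(0.05, 0.15, 0.25))
  expect_error(njTree(d[1:2, 1:2]), "three taxa")
  d_bad <- d; d_bad[1, 2] <- 0.5
  expect_error(njTree(d_bad), "symmetric")
  d_neg <- d; d_neg[1, 2] <- d_neg[2, 1] <- -0.1
  expect_error(njTree(d_neg), "negative")
})

test_that("NJ reproduces generating trees exactly on additive matrices", {
  set.seed(53)
  for (n in c(4, 5, 6, 8)) {
    for (rep in 1:5) {
      true_tree <- ape::rtree(n, rooted = FALSE,
                              br = function(k) runif(k, 0.05, 0.5))
      dmat <- ape::cophenetic.phylo(true_tree)
      est <- njTree(dmat[true_tree$tip.label, true_tree$tip.label])
      # identical topology
      expect_equal(ape::dist.topo(ape::unroot(true_tree), est), 0,
                   ignore_attr = TRUE)
      # and identical path lengths (branch lengths recovered)
      expect_equal(ape::cophenetic.phylo(est)[true_tree$tip.label,
                                              true_tree$tip.label],
                   dmat, tolerance = 1e-8)
    }
  }
})

test_that("NJ agrees with an independent implementation on noisy matrices", {
  set.seed(59)
  for (rep in 1:5) {
    n <- 6
    base <- ape::cophenetic.phylo(ape::rtree(n, rooted = FALSE))
    noise <- matrix(runif(n * n, 0, 0.02), n); noise <- noise + t(noise)
    diag(noise) <- 0
    dmat <- base + noise
    est <- njTree(dmat)
    ref <- ape::nj(as.dist(dmat))
    expect_equal(ape::dist.topo(est, ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("all-equal distances still give a valid deterministic tree", {
  d <- matrix(0.4, 5, 5, dimnames = list(paste0("t", 1:5), paste0("t", 1:5)))
  diag(d) <- 0
  t1 <- njTree(d)
  t2 <- njTree(d)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_identical(sort(t1$tip.label), paste0("t", 1:5))
  expect_true(all(t1$edge.length >= 0))
})

test_that("tree shape is invariant to taxon input order", {
  set.seed(61)
  rows <- stats::setNames(vapply(1:6, function(i) random_protein(150), ""),
                          paste0("t", 1:6))
  d <- poissonDist(rows)
  t1 <- njTree(d)
  perm <- sample(6)
  t2 <- njTree(d$d[perm, perm])
  expect_equal(ape::dist.topo(t1, t2), 0, ignore_attr = TRUE)
  expect_equal(sum(t1$edge.length), sum(t2$edge.length), tolerance = 1e-10)
})

test_that("negative NJ branch estimates are clamped to zero", {
  # strongly non-additive random matrices exercise the clamp-and-transfer
  # rule; ape::nj on the same inputs is allowed to return negatives
  set.seed(79)
  saw_negative_in_reference <- FALSE
  for (rep in 1:10) {
    n <- 5
    d <- matrix(0, n, n, dimnames = list(paste0("t", 1:n), paste0("t", 1:n)))
    d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.05, 1)
    d <- d + t(d)
    tr <- njTree(d)
    expect_true(all(tr$edge.length >= 0))
    expect_equal(tr$Nnode, n - 2)
    if (any(ape::nj(as.dist(d))$edge.length < 0))
      saw_negative_in_reference <- TRUE
  }
  expect_true(saw_negative_in_reference)
})

test_that("bootstrap supports are seed-reproducible and saturate on forced splits", {
  # two identical pairs, strongly different between pairs: central split 100
  set.seed(67)
  block1 <- random_protein(120)
  ch <- strsplit(block1, "")[[1]]
  flip <- sample(120, 70)                 # strong but unsaturated divergence
  for (i in flip) ch[i] <- sample(setdiff(
    strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], ch[i]), 1)
  block2 <- paste(ch, collapse = "")
  aln <- c(A = block1, B = block1, C = block2, D = block2)
  tr <- bootstrapSupport(aln, n_reps = 50, seed = 5)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(100 %in% sup)

  tr2 <- bootstrapSupport(aln, n_reps = 50, seed = 5)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
  tr3 <- bootstrapSupport(aln, n_reps = 50, seed = 6)
  expect_identical(sort(tr3$tip.label), sort(tr$tip.label))
})

test_that("true splits earn more bootstrap support than false splits", {
  set.seed(71)
  # simulate an alignment down a fixed 6-taxon tree by per-branch mutation
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  mut <- function(s, p) {
    ch <- strsplit(s, "")[[1]]
    hit <- runif(length(ch)) < p
    for (i in which(hit)) ch[i] <- sample(setdiff(aa, ch[i]), 1)
    paste(ch, collapse = "")
  }
  n_sites <- 500
  root <- random_protein(n_sites)
  # topology ((A,B),(C,D),(E,F)) with internal branches
  nAB <- mut(root, 0.15); nCD <- mut(root, 0.15); nEF <- mut(root, 0.15)
  aln <- c(A = mut(nAB, 0.05), B = mut(nAB, 0.05),
           C = mut(nCD, 0.05), D = mut(nCD, 0.05),
           E = mut(nEF, 0.05), F = mut(nEF, 0.05))
  tr <- bootstrapSupport(aln, n_reps = 100, seed = 11)
  nwk <- withr::local_tempfile(fileext = ".nwk")
  writeNewick(tr, nwk)
  expect_true(file.exists(nwk))
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_gte(min(sup, na.rm = TRUE), 90)  # all true splits strongly supported
})

test_that("aligned FASTA round-trips into the distance pipeline", {
  set.seed(73)
  rows <- stats::setNames(vapply(1:4, function(i) random_protein(100), ""),
                          paste0("tax", 1:4))
  afa <- withr::local_tempfile(fileext = ".afa")
  writeFasta(rows, afa)
  aln <- readProteinAlignment(afa)
  expect_identical(aln, rows)
  expect_s3_class(njTree(poissonDist(aln)), "phylo")
})
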