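test_that("pairwise alignment statistics behave on identity, divergence and junk", {
  set.seed(41)
  s <- random_protein(120)
  self <- alignProteins(s, s)
  expect_equal(self$identity_percent, 100)
  expect_equal(self$coverage_percent, 100)

  # gapless pair differing at exactly 60 of 100 positions -> identity 40
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  a <- sample(aa, 100, replace = TRUE)
  b <- a
  flip <- sample(100, 60)
  for (i in flip) b[i] <- sample(setdiff(aa, a[i]), 1)
  hit <- alignProteins(paste(a, collapse = ""), paste(b, collapse = ""))
  # local alignment may trim a few non-matching end columns; the column-count
  # identity of the full-length comparison is the floor
  expect_gte(hit$identity_percent, 40.0 - 1e-9)
  expect_lte(hit$identity_percent, 55)

  junk <- alignProteins("MKV", paste(rep("A", 40), collapse = ""))
  expect_lt(junk$coverage_percent, 80)
  expect_error(alignProteins("", "MKV"), "empty")
})

test_that("identical proteomes pair completely; unrelated ones not at all", {
  set.seed(13)
  x <- vapply(1:8, function(i) random_protein(150), "")
  names(x) <- sprintf("L%02d", 1:8)
  pa <- proteome_from_vec(x, "A")
  pb <- proteome_from_vec(stats::setNames(x, sprintf("M%02d", 1:8)), "B")
  tab <- reciprocalOrthologs(pa, pb)
  expect_identical(nrow(orthologPairs(tab)), 8L)
  expect_identical(orthologPairs(tab)$locus_a[order(orthologPairs(tab)$locus_a)],
                   sprintf("L%02d", 1:8))
  expect_true(all(orthologPairs(tab)$identity_ab == 100))

  y <- vapply(1:6, function(i) random_protein(150), "")
  names(y) <- sprintf("N%02d", 1:6)
  expect_identical(nrow(orthologPairs(
    reciprocalOrthologs(pa, proteome_from_vec(y, "C")))), 0L)
})

test_that("reciprocal orthology is symmetric and order-invariant", {
  tri <- simulateTriad(10, c(2, 2, 0), divergence = 0.25, mean_len = 150,
                       seed = 17)
  pa <- tri$proteomes$A; pb <- tri$proteomes$B
  t_ab <- reciprocalOrthologs(pa, pb)
  t_ba <- reciprocalOrthologs(pb, pa)
  key_ab <- sort(paste(orthologPairs(t_ab)$locus_a, orthologPairs(t_ab)$locus_b))
  key_ba <- sort(paste(orthologPairs(t_ba)$locus_b, orthologPairs(t_ba)$locus_a))
  expect_identical(key_ab, key_ba)

  # permuting protein input order changes nothing
  perm <- sample(length(pa))
  pa_perm <- new("Proteome", genome_id = "A", proteins = proteins(pa)[perm])
  t_perm <- reciprocalOrthologs(pa_perm, pb)
  expect_identical(
    sort(paste(orthologPairs(t_perm)$locus_a, orthologPairs(t_perm)$locus_b)),
    key_ab)
})

test_that("orthology recovers planted triad truth perfectly across seeds", {
  for (seed in 1:20) {
    div <- sample(c(0.1, 0.2, 0.3), 1)
    tri <- simulateTriad(8, c(2, 1, 0), divergence = div, mean_len = 120,
                         seed = seed)
    tab <- reciprocalOrthologs(tri$proteomes$A, tri$proteomes$B)
    got <- paste(orthologPairs(tab)$locus_a, orthologPairs(tab)$locus_b)
    want <- paste(tri$truth$families$A, tri$truth$families$B)
    expect_identical(sort(got), sort(want), info = sprintf("seed %d", seed))
  }
})

test_that("triad partitioning separates conserved, shared and unique loci", {
  # three identical proteomes
  set.seed(19)
  x <- stats::setNames(vapply(1:6, function(i) random_protein(130), ""),
                       sprintf("g%d", 1:6))
  ps <- lapply(c("A", "B", "C"), function(id) {
    nm <- paste0(id, "_", names(x))
    proteome_from_vec(stats::setNames(x, nm), id)
  })
  part <- partitionTriad(ps[[1]], ps[[2]], ps[[3]])
  cnt <- partitionCounts(part)
  expect_identical(cnt$conserved_all, 6L)
  expect_identical(unname(cnt$unique), c(0L, 0L, 0L))

  tri <- simulateTriad(25, c(4, 3, 2), divergence = 0.25, mean_len = 150,
                       seed = 11)
  part2 <- partitionTriad(tri$proteomes$A, tri$proteomes$B, tri$proteomes$C)
  cnt2 <- partitionCounts(part2)
  expect_identical(cnt2$conserved_all, 25L)
  expect_identical(unname(cnt2$unique), c(4L, 3L, 2L))
  expect_identical(sum(vapply(part2@shared_two, length, integer(1))), 0L)
  # planted triples are exactly the conserved triples
  got <- do.call(paste, part2@conserved)
  want <- paste(tri$truth$families$A, tri$truth$families$B,
                tri$truth$families$C)
  expect_identical(sort(got), sort(want))
})

test_that("core-gene audit flags present and absent genes correctly", {
  set.seed(23)
  core <- stats::setNames(vapply(1:10, function(i) random_protein(200), ""),
                          sprintf("gp%02d", 1:10))
  p_self <- proteome_from_vec(stats::setNames(core, paste0("loc", 1:10)), "G")
  audit <- coreGeneAudit(p_self, Biostrings::AAStringSet(core))
  expect_true(all(audit$status == "present"))

  # an all-X decoy can never be present
  core_decoy <- c(core, decoy = strrep("X", 150))
  audit2 <- coreGeneAudit(p_self, Biostrings::AAStringSet(core_decoy))
  expect_identical(audit2$status[audit2$core_gene == "decoy"], "absent")

  # proteome built from 9 of 10 core genes at 30% divergence -> one absent
  mut <- vapply(core[1:9], function(s) {
    ch <- strsplit(s, "")[[1]]
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    hit <- runif(length(ch)) < 0.3
    for (i in which(hit)) ch[i] <- sample(setdiff(aa, ch[i]), 1)
    paste(ch, collapse = "")
  }, "")
  p_partial <- proteome_from_vec(
    stats::setNames(mut, paste0("loc", 1:9)), "H")
  audit3 <- coreGeneAudit(p_partial, Biostrings::AAStringSet(core))
  expect_identical(sum(audit3$status == "absent"), 1L)
  expect_identical(audit3$core_gene[audit3$status == "absent"], "gp10")
})

test_that("region identity equals the per-column oracle and handles both modes", {
  set.seed(29)
  a <- random_protein(300)
  expect_equal(regionIdentity(a, c(50, 120), a, c(50, 120))$identity_percent,
               100)
  expect_error(regionIdentity(a, c(1, 10), a, c(1, 11), mode = "gapless"),
               "equal-length")
  for (i in 1:10) {
    x <- random_protein(109); y <- random_protein(109)
    cx <- strsplit(x, "")[[1]]; cy <- strsplit(y, "")[[1]]
    want <- 100 * sum(cx == cy) / 109
    got <- regionIdentity(x, c(1, 109), y, c(1, 109))$identity_percent
    expect_equal(got, want)
  }
  # global mode on identical regions embedded in different contexts
  b <- paste0(random_protein(55), substr(a, 103, 211), random_protein(36))
  rm_g <- regionIdentity(a, c(103, 211), b, c(56, 164), mode = "global")
  expect_equal(rm_g$identity_percent, 100)
})

test_that("the planted spike-like region pair shows the expected identity", {
  sp <- spike_region_pair()
  rm <- regionIdentity(sp$a, c(103, 211), sp$b, c(156, 264), mode = "gapless")
  expect_equal(rm$identity_percent, sp$expected_identity)
  expect_equal(round(rm$identity_percent), 45)
})

test_that("shared homolog counting is monotone in relatedness", {
  tri <- simulateTriad(12, c(3, 2, 0), divergence = 0.2, mean_len = 150,
                       seed = 31)
  n <- sharedHomologCount(tri$proteomes$A, tri$proteomes$B)
  expect_identical(n, 12L)
  expect_identical(
    sharedHomologCount(tri$proteomes$A, tri$proteomes$A), 15L)
  set.seed(32)
  unrelated <- proteome_from_vec(
    stats::setNames(vapply(1:10, function(i) random_protein(150), ""),
                    paste0("u", 1:10)), "U")
  expect_identical(sharedHomologCount(tri$proteomes$A, unrelated), 0L)
})

test_that("synteny blocks reflect gene-order conservation", {
  set.seed(37)
  x <- stats::setNames(vapply(1:10, function(i) random_protein(140), ""),
                       sprintf("a%02d", 1:10))
  pa <- proteome_from_vec(x, "A")
  mk_pb <- function(ord) {
    proteome_from_vec(stats::setNames(x[ord], sprintf("b%02d", ord)), "B")
  }
  # identical order -> one block covering everything
  pb <- mk_pb(1:10)
  syn <- syntenyBlocks(reciprocalOrthologs(pa, pb), pa, pb)
  expect_identical(syn$n_blocks, 1L)
  expect_equal(syn$synteny_fraction, 1.0)

  # single-gene transposition -> two multi-anchor blocks
  pb2 <- mk_pb(c(1:4, 6:10, 5))
  syn2 <- syntenyBlocks(reciprocalOrthologs(pa, pb2), pa, pb2)
  expect_identical(syn2$n_blocks, 2L)

  # inversion is a block with '-' orientation
  pb3 <- mk_pb(c(1:3, 7:4, 8:10))
  syn3 <- syntenyBlocks(reciprocalOrthologs(pa, pb3), pa, pb3)
  expect_true("-" %in% syn3$blocks$orientation)
  expect_equal(syn3$synteny_fraction, 1.0)

  # random permutations destroy most synteny
  set.seed(38)
  fr <- replicate(5, {
    pbr <- mk_pb(sample(10))
    syntenyBlocks(reciprocalOrthologs(pa, pbr), pa, pbr)$synteny_fraction
  })
  expect_lt(mean(fr), 0.5)

  # circular permutation: one wrap allowed
  pb4 <- mk_pb(c(6:10, 1:5))
  syn4 <- syntenyBlocks(reciprocalOrthologs(pa, pb4), pa, pb4,
                        circular = TRUE)
  expect_identical(syn4$n_blocks, 1L)
  expect_equal(syn4$synteny_fraction, 1.0)
})

test_that("ortholog tables export cleanly as TSV", {
  tri <- simulateTriad(5, c(1, 0, 0), divergence = 0.1, mean_len = 100,
                       seed = 39)
  tab <- reciprocalOrthologs(tri$proteomes$A, tri$proteomes$B)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeOrthologTable(tab, tsv)
  back <- read.delim(tsv)
  expect_identical(nrow(back), 5L)
  expect_true(all(c("locus_a", "locus_b", "identity_ab") %in% names(back)))
})
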