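test_that("SD scoring matches the consensus-sliding definition", {
  expect_identical(scoreSD("AAAGGAGGTAAAAA")$sd_score, 6L)
  expect_identical(scoreSD("GGAGGT")$sd_score, 6L)
  # one mismatch at consensus position 3
  expect_identical(scoreSD(paste0("GGTGGT", strrep("A", 9)))$sd_score, 5L)
  # chance hexamers in a poly-C window never reach the default threshold
  expect_lte(scoreSD(strrep("C", 15))$sd_score, 2L)
  expect_error(scoreSD("GGAGG"), "shorter than 6")
  # ties broken toward the placement closest to the start codon
  res <- scoreSD("GGAGGTAAAGGAGGT")
  expect_identical(res$sd_score, 6L)
  expect_identical(res$sd_offset, 0L)
  # enumeration oracle on random windows
  set.seed(5)
  for (i in 1:25) {
    w <- random_dna(15)
    expect_identical(scoreSD(w)$sd_score, oracle_sd_best(w))
  }
})

test_that("a planted ORF is called exactly once with exact structure", {
  g <- as_genome(planted_orf_seq(30))
  calls <- callOrfs(g)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$strand, "+")
  expect_identical(calls$start_codon, "ATG")
  expect_identical(calls$n_codons, 31L)
  expect_identical(calls$end - calls$start + 1L, 3L * 32L)
  expect_gte(calls$sd_score, 4L)

  # boundary: only 29 extra codons -> no call
  expect_identical(nrow(callOrfs(as_genome(planted_orf_seq(29)))), 0L)
  # without the SD requirement the short ORF is still length-filtered out
  p_nosd <- annotateParams(require_sd = FALSE)
  expect_identical(nrow(callOrfs(as_genome(planted_orf_seq(29)), p_nosd)), 0L)
})

test_that("ORF calling equals the brute-force six-frame oracle on random genomes", {
  set.seed(101)
  for (rep in 1:4) {
    s <- random_dna(3000, gc = 0.45)
    calls <- callOrfs(as_genome(s))
    ref <- oracle_orfs(s)
    expect_identical(orf_key(calls), orf_key(ref))
    expect_identical(calls$n_codons, ref$n_codons)
    # without the SD screen as well
    calls2 <- callOrfs(as_genome(s), annotateParams(require_sd = FALSE))
    ref2 <- oracle_orfs(s, require_sd = FALSE)
    expect_identical(orf_key(calls2), orf_key(ref2))
  }
})

test_that("every ORF call re-verifies against the genome sequence", {
  set.seed(77)
  s <- random_dna(5000, gc = 0.5)
  g <- as_genome(s)
  calls <- callOrfs(g, annotateParams(require_sd = FALSE))
  expect_gt(nrow(calls), 0)
  for (i in seq_len(nrow(calls))) {
    nt <- substr(s, calls$start[i], calls$end[i])
    if (calls$strand[i] == "-") nt <- oracle_revcomp(nt)
    expect_identical(substr(nt, 1, 3), calls$start_codon[i])
    # translates cleanly: no internal stop, length = n_codons
    aa <- translateCds(as_genome(nt), GenomicRanges::GRanges(
      "t", IRanges::IRanges(1, nchar(nt)), strand = "+"))
    expect_identical(nchar(aa), calls$n_codons[i])
  }
})

test_that("planted-gene recall is 100% with exact coordinates across seeds", {
  for (seed in 1:20) {
    sim <- simulateGenome(6000, gc = 44.5, n_genes = 8, n_promoters = 2,
                          seed = seed)
    calls <- callOrfs(sim$genome)
    expect_true(all(orf_key(sim$truth$genes) %in% orf_key(calls)),
                info = sprintf("seed %d", seed))
  }
})

test_that("background false positives match the oracle on a gene-free genome", {
  sim <- simulateGenome(4000, gc = 44.5, n_genes = 0, n_promoters = 0,
                        seed = 9)
  s <- as.character(genomeSeq(sim$genome))
  expect_identical(orf_key(callOrfs(sim$genome)), orf_key(oracle_orfs(s)))
})

test_that("circular ORF calls are invariant under genome rotation", {
  sim <- simulateGenome(5000, gc = 44.5, n_genes = 6, n_promoters = 0,
                        seed = 21, gene_codons = c(31, 40))
  s <- as.character(genomeSeq(sim$genome))
  L <- nchar(s)
  # wrap window large enough to span any rotated gene or background ORF
  p <- annotateParams(wrap_bp = 1000)
  base <- callOrfs(as_genome(s, topology = "circular"), p)
  norm <- function(calls, shift) {
    st <- ((calls$start - 1 + shift) %% L) + 1
    sort(paste(st, calls$strand, calls$n_codons))
  }
  for (shift in c(137, 2513)) {
    rot <- paste0(substr(s, shift + 1, L), substr(s, 1, shift))
    calls_rot <- callOrfs(as_genome(rot, topology = "circular"), p)
    expect_identical(norm(calls_rot, shift), norm(base, 0),
                     info = sprintf("shift %d", shift))
  }
})

test_that("promoter scanning finds planted consensus and obeys the spacer bounds", {
  mk <- function(spacer) {
    paste0(strrep("C", 40), "TTGACA", random_dna(spacer), "TATAAT",
           strrep("C", 40))
  }
  set.seed(8)
  hits <- scanPromoters(as_genome(mk(17)))
  fwd <- hits[hits$strand == "+", ]
  expect_identical(nrow(fwd), 1L)
  expect_identical(fwd$pos_minus35, 41L)
  expect_identical(fwd$spacer, 17L)
  expect_identical(fwd$mm35 + fwd$mm10, 0L)
  # 14 nt spacer is outside [15, 18]
  expect_identical(nrow(scanPromoters(as_genome(mk(14)))), 0L)
  expect_identical(nrow(scanPromoters(as_genome(mk(19)))), 0L)
})

test_that("promoter scanning equals the sliding-window oracle, with and without mismatches", {
  set.seed(303)
  for (rep in 1:3) {
    s <- random_dna(4000, gc = 0.45)
    for (mm in c(0L, 1L)) {
      p <- annotateParams(promoter_max_mismatches = mm)
      got <- scanPromoters(as_genome(s), p)
      ref <- oracle_promoters(s, max_mm = mm)
      expect_identical(prom_key(got), prom_key(ref),
                       info = sprintf("rep %d mm %d", rep, mm))
    }
  }
})

test_that("eight planted promoters are all recovered alongside oracle-matched background", {
  sim <- simulateGenome(12000, gc = 44.5, n_genes = 0, n_promoters = 8,
                        seed = 7)
  hits <- scanPromoters(sim$genome)
  expect_true(all(prom_key(sim$truth$promoters) %in% prom_key(hits)))
  ref <- oracle_promoters(as.character(genomeSeq(sim$genome)))
  expect_identical(prom_key(hits), prom_key(ref))
})

test_that("CDS translation follows the bacterial code with start/stop handling", {
  tr <- function(nt, strand = "+") {
    g <- as_genome(if (strand == "-") oracle_revcomp(nt) else nt)
    translateCds(g, GenomicRanges::GRanges(
      "t", IRanges::IRanges(1, nchar(nt)), strand = strand))
  }
  expect_identical(tr("ATGAAATAA"), "MK")
  expect_identical(tr("TTGAAATAA"), "MK")   # alternative start -> M
  expect_identical(tr("GTGAAATAA"), "MK")
  expect_error(tr("ATGTAAAAATAA"), "internal stop codon at codon position 2")
  expect_error(tr("ATGAAAT"), "not divisible by 3")
  # reverse-strand feature equals translation of the reverse complement
  set.seed(12)
  for (i in 1:5) {
    nt <- paste0("ATG", paste(sample(setdiff(
      as.vector(outer(outer(c("A","C","G","T"), c("A","C","G","T"), paste0),
                      c("A","C","G","T"), paste0)),
      c("TAA", "TAG", "TGA")), 20, replace = TRUE), collapse = ""), "TAA")
    g <- as_genome(oracle_revcomp(nt))
    got <- translateCds(g, GenomicRanges::GRanges(
      "t", IRanges::IRanges(1, nchar(nt)), strand = "-"))
    expect_identical(got, tr(nt))
  }
})

test_that("GFF output writes one row per call with valid coordinates", {
  sim <- simulateGenome(4000, n_genes = 4, n_promoters = 2, seed = 2)
  orfs <- callOrfs(sim$genome)
  proms <- scanPromoters(sim$genome)
  gff <- withr::local_tempfile(fileext = ".gff")
  writeAnnotationGff(sim$genome, orfs, proms, gff)
  lines <- readLines(gff)
  expect_identical(lines[1], "##gff-version 3")
  expect_identical(length(lines) - 1L, nrow(orfs) + nrow(proms))
})
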