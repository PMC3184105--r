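.DNA <- c("A", "C", "G", "T")
.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.SENSE_CODONS <- {
  all_cod <- as.vector(outer(outer(.DNA, .DNA, paste0), .DNA, paste0))
  setdiff(all_cod, c("TAA", "TAG", "TGA"))
}

.randomDna <- function(n, gc_frac) {
  p <- c((1 - gc_frac) / 2, gc_frac / 2, gc_frac / 2, (1 - gc_frac) / 2)
  paste(sample(.DNA, n, replace = TRUE, prob = p), collapse = "")
}

# Sense codons drawn to roughly honour the background GC fraction.
.randomSenseCodons <- function(n, gc_frac) {
  gcw <- vapply(strsplit(.SENSE_CODONS, ""), function(ch)
    sum(ch %in% c("G", "C")), numeric(1))
  w <- (gc_frac^gcw) * ((1 - gc_frac)^(3 - gcw))
  sample(.SENSE_CODONS, n, replace = TRUE, prob = w)
}

.sdHexamer <- function(n_matches) {
  cons <- strsplit("GGAGGT", "")[[1]]
  out <- cons
  if (n_matches < 6L) {
    flip <- sample.int(6L, 6L - n_matches)
    for (i in flip) out[i] <- sample(setdiff(.DNA, cons[i]), 1L)
  }
  paste(out, collapse = "")
}

#' Simulate a phage-like genome with planted genes and promoters
#'
#' The background is drawn at the requested GC. Each planted gene cassette
#' carries an upstream Shine-Dalgarno hexamer with `sd_matches` of 6
#' positions matching GGAGGT (3' end 7 bp before the start codon), an
#' in-frame stop immediately upstream of the start codon (so the planted
#' start is the upstream-most start of its frame segment and [callOrfs()]
#' recovers the exact coordinates), a valid start codon, a stop-free body and
#' a terminating TAA. Promoters are planted at exact sigma-70 consensus with
#' a random 15-18 nt spacer. Elements are placed non-overlapping on random
#' strands.
#'
#' @param length_bp Genome length.
#' @param gc Target GC, percent (default 44.5). `gc = 0` yields an all-AT
#'   background (documented degenerate case).
#' @param n_genes,n_promoters Numbers of planted elements.
#' @param sd_matches Matches to GGAGGT in planted SD sites, 0-6 (default 6).
#' @param seed Integer seed; same seed, same output (byte-identical).
#' @param gene_codons Length-2 range for `n_codons` of planted genes
#'   (including the start codon; default 31-80).
#' @return A list with `genome` (a [PhageGenome], planted genes as CDS
#'   features) and `truth` (lists `genes` and `promoters` plus the request).
#' @export
simulateGenome <- function(length_bp, gc = 44.5, n_genes = 10L,
                           n_promoters = 3L, sd_matches = 6L, seed = 1L,
                           gene_codons = c(31L, 80L)) {
  stopifnot(.isCount(length_bp), length_bp >= 100, gc >= 0, gc <= 100,
            .isCount(n_genes), .isCount(n_promoters),
            .isCount(sd_matches), sd_matches <= 6,
            length(gene_codons) == 2L, gene_codons[1] >= 31L)
  gc_frac <- gc / 100
  .withSeed(.substreamSeed(seed, "genome"), {
    n_cod <- if (n_genes > 0)
      sample(seq(gene_codons[1], gene_codons[2]), n_genes, replace = TRUE)
      else integer()
    gene_len <- 13L + 3L * (n_cod + 1L)        # SD6 + N4 + TAA3 + ORF
    spacers <- if (n_promoters > 0)
      sample(15:18, n_promoters, replace = TRUE) else integer()
    prom_len <- 12L + spacers
    lens <- c(gene_len, prom_len)
    k <- length(lens)
    free <- length_bp - sum(lens)
    if (free < 0)
      stop("infeasible packing: planted elements exceed the genome length")
    ord <- if (k > 0) sample.int(k) else integer()
    gaps <- if (k > 0) as.vector(stats::rmultinom(1, free, rep(1, k + 1L)))
            else free

    kind <- c(rep("gene", n_genes), rep("prom", n_promoters))[ord]
    elem_idx <- c(seq_len(n_genes), seq_len(n_promoters))[ord]
    strands <- sample(c("+", "-"), max(k, 1L), replace = TRUE)

    pieces <- character(0)
    pos <- 0L
    genes <- list(); proms <- list()
    for (e in seq_len(k)) {
      bg <- .randomDna(gaps[e], gc_frac)
      pieces <- c(pieces, bg); pos <- pos + gaps[e]
      st <- strands[e]
      if (kind[e] == "gene") {
        i <- elem_idx[e]
        cassette <- paste0(
          .sdHexamer(sd_matches), .randomDna(4L, gc_frac), "TAA",
          sample(c("ATG", "GTG", "TTG", "CTG"), 1L,
                 prob = c(0.7, 0.15, 0.1, 0.05)),
          paste(.randomSenseCodons(n_cod[i] - 1L, gc_frac), collapse = ""),
          "TAA")
        if (st == "-") {
          genes[[i]] <- data.frame(
            locus_id = sprintf("g%03d", i),
            start = pos + 1L, end = pos + 3L * (n_cod[i] + 1L),
            strand = "-", n_codons = n_cod[i], sd_offset = 7L,
            stringsAsFactors = FALSE)
          cassette <- .revcomp(cassette)
        } else {
          genes[[i]] <- data.frame(
            locus_id = sprintf("g%03d", i),
            start = pos + 14L, end = pos + nchar(cassette),
            strand = "+", n_codons = n_cod[i], sd_offset = 7L,
            stringsAsFactors = FALSE)
        }
      } else {
        i <- elem_idx[e]
        cassette <- paste0("TTGACA", .randomDna(spacers[i], gc_frac), "TATAAT")
        if (st == "-") cassette <- .revcomp(cassette)
        # truth records the leftmost forward coordinate of the -35 hexamer,
        # matching the scanPromoters convention (on '-' it sits at the right
        # end of the cassette)
        proms[[i]] <- data.frame(
          pos_minus35 = if (st == "+") pos + 1L else pos + spacers[i] + 7L,
          spacer = spacers[i], strand = st, stringsAsFactors = FALSE)
      }
      pieces <- c(pieces, cassette); pos <- pos + nchar(cassette)
    }
    pieces <- c(pieces, .randomDna(if (k > 0) gaps[k + 1L] else length_bp,
                                   gc_frac))
    seq_chr <- paste(pieces, collapse = "")
    stopifnot(nchar(seq_chr) == length_bp)

    genes_df <- if (length(genes)) do.call(rbind, genes) else
      data.frame(locus_id = character(), start = integer(), end = integer(),
                 strand = character(), n_codons = integer(),
                 sd_offset = integer(), stringsAsFactors = FALSE)
    proms_df <- if (length(proms)) do.call(rbind, proms) else
      data.frame(pos_minus35 = integer(), spacer = integer(),
                 strand = character(), stringsAsFactors = FALSE)

    gr <- if (nrow(genes_df)) GenomicRanges::GRanges(
      "sim", IRanges::IRanges(genes_df$start, genes_df$end),
      strand = genes_df$strand) else GenomicRanges::GRanges()
    mcols(gr)$locus_id <- genes_df$locus_id
    mcols(gr)$kind <- rep("CDS", nrow(genes_df))
    mcols(gr)$translation <- rep(NA_character_, nrow(genes_df))
    g <- new("PhageGenome",
             id = sprintf("simgenome_seed%d", as.integer(seed)),
             description = "synthetic phage-like genome with planted elements",
             sequence = Biostrings::DNAString(seq_chr), topology = "linear",
             features = gr)
    list(genome = g,
         truth = list(genes = genes_df, promoters = proms_df,
                      gc_percent = gc, sd_matches = sd_matches, seed = seed))
  })
}

.mutateProtein <- function(s, divergence, indel_rate = 0) {
  ch <- strsplit(s, "")[[1]]
  hit <- stats::runif(length(ch)) < divergence
  for (i in which(hit)) ch[i] <- sample(setdiff(.AA20, ch[i]), 1L)
  if (indel_rate > 0) ch <- ch[stats::runif(length(ch)) >= indel_rate]
  paste(ch, collapse = "")
}

#' Simulate a triad of proteomes with planted orthology
#'
#' Shared families descend from a common random ancestor protein, mutated
#' independently in each genome at per-site probability `divergence`
#' (uniform substitution over the 19 alternatives; deletions only with
#' `indel_rate > 0`). Unique genes are drawn independently per genome. Gene
#' orders are shuffled with recorded permutations so synteny statistics can
#' be tested against truth.
#'
#' @param n_shared Number of three-way ortholog families (e.g. 147).
#' @param n_unique Integer triple of per-genome unique gene counts.
#' @param divergence Per-site substitution probability in `[0, 0.5)`; values
#'   at or beyond 0.5 are rejected (saturation guard).
#' @param mean_len Mean ancestor length, aa (Poisson, min 50; default 300).
#' @param seed Integer seed.
#' @param genome_ids Identifiers (default `c("A","B","C")`).
#' @param indel_rate Optional per-site deletion probability (default 0).
#' @return A list with `proteomes` (list of three [Proteome]s) and `truth`
#'   (`families` data.frame, `unique` list, `order` permutations).
#' @export
simulateTriad <- function(n_shared, n_unique = c(0L, 0L, 0L),
                          divergence = 0.2, mean_len = 300L, seed = 1L,
                          genome_ids = c("A", "B", "C"), indel_rate = 0) {
  stopifnot(.isCount(n_shared), length(n_unique) == 3L,
            all(vapply(n_unique, .isCount, logical(1))),
            length(genome_ids) == 3L, !anyDuplicated(genome_ids))
  if (divergence < 0 || divergence >= 0.5)
    stop("divergence must lie in [0, 0.5): beyond that pairs approach saturation")
  .withSeed(.substreamSeed(seed, "triad"), {
    fam_len <- pmax(50L, stats::rpois(n_shared, mean_len))
    ancestors <- vapply(fam_len, function(n)
      paste(sample(.AA20, n, replace = TRUE), collapse = ""), "")
    prot <- list()
    fam_locus <- matrix("", n_shared, 3,
                        dimnames = list(NULL, genome_ids))
    uniq <- stats::setNames(vector("list", 3), genome_ids)
    for (k in 1:3) {
      gid <- genome_ids[k]
      shared_seqs <- vapply(ancestors, .mutateProtein, "",
                            divergence = divergence, indel_rate = indel_rate,
                            USE.NAMES = FALSE)
      uniq_seqs <- vapply(pmax(50L, stats::rpois(n_unique[k], mean_len)),
                          function(n) paste(sample(.AA20, n, replace = TRUE),
                                            collapse = ""), "")
      seqs <- c(shared_seqs, uniq_seqs)
      ids <- sprintf("%s_g%03d", gid, seq_along(seqs))
      fam_locus[, k] <- ids[seq_len(n_shared)]
      uniq[[gid]] <- ids[seq_len(n_unique[k]) + n_shared]
      perm <- sample.int(length(seqs))
      aa <- Biostrings::AAStringSet(seqs[perm])
      names(aa) <- ids[perm]
      prot[[gid]] <- list(
        proteome = new("Proteome", genome_id = gid, proteins = aa),
        order = perm)
    }
    families <- data.frame(family = sprintf("fam%03d", seq_len(n_shared)),
                           stringsAsFactors = FALSE)
    for (k in 1:3) families[[genome_ids[k]]] <- fam_locus[, k]
    list(
      proteomes = stats::setNames(lapply(prot, `[[`, "proteome"), genome_ids),
      truth = list(families = families, unique = uniq,
                   order = lapply(prot, `[[`, "order"),
                   divergence = divergence, seed = seed))
  })
}

#' Simulate a one-step growth curve
#'
#' Total phage stay at the infective-center baseline until `eclipse`, then
#' rise log-linearly to `burst` times baseline by `latent + rise_tail`
#' minutes and plateau; the first post-eclipse sample already sits ~4x above
#' baseline (intracellular phage accumulate fast relative to the sampling
#' interval). Infective centers rise analogously starting at `latent`.
#' Multiplicative lognormal noise with coefficient of variation `cv` is
#' applied to titers. With `lysis_inhibited = TRUE` the OD column rises
#' (roughly tripling) until `lysis_onset` and then falls (high-MOI profile);
#' otherwise it peaks early (~25 min) and collapses.
#'
#' @param eclipse,latent Eclipse and latent periods, minutes.
#' @param burst Burst size, phage per infected cell.
#' @param baseline_ic Baseline of infective centers, PFU/mL.
#' @param cv Coefficient of variation of the multiplicative titer noise.
#' @param n_points,t_max Sampling grid: `n_points` equally spaced samples on
#'   `[0, t_max]` (defaults 25 points over 120 min = 5-min intervals).
#' @param lysis_inhibited Generate the high-MOI, lysis-inhibited OD profile.
#' @param seed Integer seed.
#' @param rise_tail Minutes after `latent` at which the rise completes
#'   (default 10).
#' @param lysis_onset Onset of lysis for the inhibited OD profile
#'   (default 90 min).
#' @return A data.frame (`time`, `total_pfu`, `infective_centers`, `od600`)
#'   with attributes `moi` and `truth`.
#' @export
simulateGrowth <- function(eclipse = 20, latent = 40, burst = 440,
                           baseline_ic = 1e6, cv = 0.1, n_points = 25L,
                           t_max = 120, lysis_inhibited = FALSE, seed = 1L,
                           rise_tail = 10, lysis_onset = 90) {
  if (cv < 0) stop("cv must be non-negative")
  stopifnot(eclipse <= latent, latent < t_max, burst >= 1, baseline_ic > 0,
            .isCount(n_points), n_points >= 5)
  .withSeed(.substreamSeed(seed, "growth"), {
    tt <- seq(0, t_max, length.out = n_points)
    rise_end <- min(latent + rise_tail, t_max)
    jump <- 4
    riser <- function(t, t0) {
      ifelse(t < t0, 1,
             pmin(burst, jump * burst^((t - t0) / max(rise_end - eclipse, 1e-9))))
    }
    total <- baseline_ic * riser(tt, eclipse)
    ic <- baseline_ic * riser(tt, latent)
    if (cv > 0) {
      sdlog <- sqrt(log(1 + cv^2))
      total <- total * exp(stats::rnorm(n_points, 0, sdlog))
      ic <- ic * exp(stats::rnorm(n_points, 0, sdlog))
    }
    od0 <- 0.3
    if (lysis_inhibited) {
      od <- ifelse(tt <= lysis_onset, od0 * 3^(tt / lysis_onset),
                   pmax(0.05, 3 * od0 - (tt - lysis_onset) *
                          (3 * od0 - 0.05) / max(t_max - lysis_onset, 1e-9)))
      moi <- 10
    } else {
      peak <- 25
      od <- ifelse(tt <= peak, od0 * 1.3^(tt / peak),
                   pmax(0.03, od0 * 1.3 - (tt - peak) * 0.02))
      moi <- 0.1
    }
    if (cv > 0) od <- od * exp(stats::rnorm(n_points, 0, sqrt(log(1 + (cv / 2)^2))))
    out <- data.frame(time = tt, total_pfu = total, infective_centers = ic,
                      od600 = od)
    attr(out, "moi") <- moi
    attr(out, "truth") <- list(eclipse = eclipse, latent = latent,
                               burst = burst, baseline_ic = baseline_ic,
                               cv = cv, lysis_inhibited = lysis_inhibited,
                               seed = seed)
    out
  })
}

#' Simulate isotope-labelling series
#'
#' Linear acid-precipitable-count trajectories with Gaussian noise for an
#' infected culture and an uninfected control.
#'
#' @param slope Infected-culture slope, cpm/min (0 for the
#'   no-incorporation pattern).
#' @param background_slope Control slope, cpm/min.
#' @param n_points Number of samples (>= 4).
#' @param noise_sd Gaussian noise SD on cpm.
#' @param seed Integer seed.
#' @param t_max Last sampling time, minutes (default 30).
#' @param intercept Baseline cpm (default 100).
#' @return A list with `infected` and `control` data.frames (`time`, `cpm`)
#'   and `truth`.
#' @export
simulateLabel <- function(slope = 0, background_slope = 50, n_points = 8L,
                          noise_sd = 5, seed = 1L, t_max = 30,
                          intercept = 100) {
  if (n_points < 4L) stop("at least 4 points are required")
  stopifnot(noise_sd >= 0)
  .withSeed(.substreamSeed(seed, "label"), {
    tt <- seq(0, t_max, length.out = n_points)
    infected <- data.frame(
      time = tt,
      cpm = pmax(0, intercept + slope * tt +
                   stats::rnorm(n_points, 0, noise_sd)))
    control <- data.frame(
      time = tt,
      cpm = pmax(0, intercept + background_slope * tt +
                   stats::rnorm(n_points, 0, noise_sd)))
    list(infected = infected, control = control,
         truth = list(slope = slope, background_slope = background_slope,
                      noise_sd = noise_sd, seed = seed))
  })
}

#' Write a simulated genome and its truth sidecars
#'
#' @param sim Result of [simulateGenome()].
#' @param prefix Output path prefix; writes `<prefix>.fasta`,
#'   `<prefix>.genes.tsv`, `<prefix>.promoters.tsv`.
#' @return The FASTA path, invisibly.
#' @export
writeSimulatedGenome <- function(sim, prefix) {
  writeFasta(sim$genome, paste0(prefix, ".fasta"))
  utils::write.table(sim$truth$genes, paste0(prefix, ".genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$promoters, paste0(prefix, ".promoters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paste0(prefix, ".fasta"))
}
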