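#' Annotation parameters
#'
#' Thresholds for gene calling and promoter scanning. A gene call requires an
#' ATG/GTG/CTG/TTG start codon, at least `min_extra_codons` further codons
#' before an in-frame stop, and (when `require_sd`) an upstream hexamer
#' matching the Shine-Dalgarno consensus GGAGGT at `sd_min_matches` or more
#' of its six positions within `sd_window_bp` of the start codon. The
#' promoter scan requires the sigma-70 consensus TTGACA (N15-18) TATAAT with
#' at most `promoter_max_mismatches` mismatches summed over both hexamers.
#'
#' @param min_extra_codons Minimum codons after the start codon (default 30).
#' @param sd_window_bp Width of the upstream window searched for the SD
#'   hexamer, in bp (default 15).
#' @param sd_min_matches Minimum matches to GGAGGT, 0-6 (default 4).
#' @param promoter_max_mismatches Combined -35/-10 mismatch budget (default 0,
#'   exact consensus).
#' @param require_sd Require the SD screen for a gene call (default TRUE).
#' @param wrap_bp Bases of the sequence start logically appended when
#'   scanning a circular genome across its origin. Default
#'   `3 * (min_extra_codons + 2)`; raise it if origin-spanning genes longer
#'   than that are expected.
#' @return A list of class `annotate_params`.
#' @export
annotateParams <- function(min_extra_codons = 30L, sd_window_bp = 15L,
                           sd_min_matches = 4L, promoter_max_mismatches = 0L,
                           require_sd = TRUE, wrap_bp = NULL) {
  stopifnot(.isCount(min_extra_codons), .isCount(sd_window_bp),
            .isCount(sd_min_matches), sd_min_matches <= 6,
            .isCount(promoter_max_mismatches), is.logical(require_sd))
  if (is.null(wrap_bp)) wrap_bp <- 3L * (min_extra_codons + 2L)
  stopifnot(.isCount(wrap_bp))
  structure(list(min_extra_codons = as.integer(min_extra_codons),
                 sd_window_bp = as.integer(sd_window_bp),
                 sd_min_matches = as.integer(sd_min_matches),
                 promoter_max_mismatches = as.integer(promoter_max_mismatches),
                 require_sd = isTRUE(require_sd),
                 wrap_bp = as.integer(wrap_bp)),
            class = "annotate_params")
}

#' Score a Shine-Dalgarno window against the GGAGGT consensus
#'
#' Slides the GGAGGT hexamer over every ungapped placement inside the window
#' (the bases immediately upstream of a start codon, coding strand) and
#' returns the best match count; ties are broken toward the placement closest
#' to the start codon.
#'
#' @param upstream Character string of upstream bases, 3' end abutting the
#'   start codon.
#' @param window_bp Width of the window actually searched (the trailing
#'   `window_bp` bases of `upstream`); default the whole string.
#' @return A list with `sd_score` (0-6 matches) and `sd_offset` (bp between
#'   the hexamer's 3' end and the start codon).
#' @examples
#' scoreSD("AAAGGAGGTAAAAA")$sd_score  # 6
#' @export
scoreSD <- function(upstream, window_bp = nchar(upstream)) {
  stopifnot(is.character(upstream), length(upstream) == 1L)
  upstream <- toupper(upstream)
  w <- substr(upstream, max(1L, nchar(upstream) - window_bp + 1L),
              nchar(upstream))
  W <- nchar(w)
  if (W < 6L) stop("SD window shorter than 6 bp")
  cons <- strsplit("GGAGGT", "")[[1]]
  chars <- strsplit(w, "")[[1]]
  best_score <- -1L; best_off <- NA_integer_
  for (i in seq_len(W - 5L)) {          # ascending i = descending offset
    sc <- sum(chars[i:(i + 5L)] == cons)
    off <- W - (i + 5L)
    if (sc >= best_score) { best_score <- sc; best_off <- off }
  }
  list(sd_score = as.integer(best_score), sd_offset = as.integer(best_off))
}

# Window of up to window_bp bases upstream of scan-string position b.
# For circular molecules, positions before base 1 wrap to the end of the
# circle (length circle_len); for linear ones the window is truncated.
.sdWindow <- function(scan_chars, b, window_bp, circular, circle_len) {
  lo <- b - window_bp
  if (lo >= 1L) return(paste(scan_chars[lo:(b - 1L)], collapse = ""))
  if (!circular) {
    if (b == 1L) return("")
    return(paste(scan_chars[1L:(b - 1L)], collapse = ""))
  }
  idx <- lo:(b - 1L)
  idx <- ifelse(idx >= 1L, idx, idx + circle_len)
  paste(scan_chars[idx], collapse = "")
}

.scanOrfStrand <- function(scan_s, circle_len, circular, p) {
  starts_set <- c("ATG", "GTG", "CTG", "TTG")
  stops_set <- c("TAA", "TAG", "TGA")
  min_ncod <- p$min_extra_codons + 1L
  scan_chars <- strsplit(scan_s, "")[[1]]
  nc <- nchar(scan_s)
  out <- list()
  for (f in 0:2) {
    n_cod <- (nc - f) %/% 3L
    if (n_cod < min_ncod + 1L) next
    pos0 <- f + 1L + 3L * (seq_len(n_cod) - 1L)
    cods <- substring(scan_s, pos0, pos0 + 2L)
    is_stop <- cods %in% stops_set
    is_start <- cods %in% starts_set
    prev <- 0L
    for (k in which(is_stop)) {
      hi <- k - min_ncod
      if (hi >= prev + 1L) {
        for (j in (prev + 1L):hi) {
          if (!is_start[j]) next
          b <- pos0[j]
          if (b > circle_len) break      # duplicate of an unwrapped call
          sd <- list(sd_score = NA_integer_, sd_offset = NA_integer_)
          win <- .sdWindow(scan_chars, b, p$sd_window_bp, circular, circle_len)
          if (nchar(win) >= 6L) sd <- scoreSD(win)
          else sd$sd_score <- 0L
          if (p$require_sd &&
              (is.na(sd$sd_score) || sd$sd_score < p$sd_min_matches)) next
          out[[length(out) + 1L]] <- list(
            pos = b, n_codons = k - j, start_codon = cods[j],
            sd_score = sd$sd_score, sd_offset = sd$sd_offset)
          break                          # upstream-most qualifying start
        }
      }
      prev <- k
    }
  }
  out
}

#' Call open reading frames with the Shine-Dalgarno screen
#'
#' Scans all six reading frames. Within each stop-codon-bounded frame
#' segment the upstream-most start codon that satisfies the length and SD
#' criteria is reported (the longest qualifying ORF), so overlapping ORFs on
#' the same or opposite strands are all returned without greedy resolution.
#' Circular genomes are scanned across the origin by logically appending the
#' first `wrap_bp` bases; calls whose start lies past the origin copy are
#' de-duplicated. Reported `end` coordinates include the stop codon and may
#' exceed the genome length for origin-spanning calls on circular genomes
#' (position `p > length` wraps to `p - length`).
#'
#' @param g A [PhageGenome].
#' @param params An [annotateParams()] list.
#' @return A data.frame with columns `start`, `end`, `strand`, `start_codon`,
#'   `n_codons` (including the start codon, excluding the stop), `sd_score`,
#'   `sd_offset`, ordered by `start`.
#' @export
callOrfs <- function(g, params = annotateParams()) {
  stopifnot(is(g, "PhageGenome"), inherits(params, "annotate_params"))
  s <- as.character(g@sequence)
  .checkAlphabet(s)
  L <- nchar(s)
  circular <- g@topology == "circular"
  wrap <- if (circular) min(params$wrap_bp, L) else 0L

  fwd <- paste0(s, substr(s, 1L, wrap))
  rc <- .revcomp(s)
  rcx <- paste0(rc, substr(rc, 1L, wrap))

  rows <- list()
  for (st in c("+", "-")) {
    scan_s <- if (st == "+") fwd else rcx
    hits <- .scanOrfStrand(scan_s, L, circular, params)
    for (h in hits) {
      len <- 3L * (h$n_codons + 1L)
      if (st == "+") {
        start <- h$pos
      } else {
        e_rc <- h$pos + len - 1L
        start <- L - e_rc + 1L
        if (start < 1L) start <- start + L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        start = start, end = start + len - 1L, strand = st,
        start_codon = h$start_codon, n_codons = h$n_codons,
        sd_score = h$sd_score, sd_offset = h$sd_offset,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(), end = integer(), strand = character(),
               start_codon = character(), n_codons = integer(),
               sd_score = integer(), sd_offset = integer(),
               stringsAsFactors = FALSE)
  if (circular && nrow(out) > 1L) {
    # calls sharing one stop codon describe the same gene: the scan of a
    # rotated circle can expose an origin-truncated segment whose true
    # upstream-most start lies across the origin; keep the longest call.
    stop_pos <- ifelse(out$strand == "+", out$end, out$start)
    key <- paste(out$strand, ((stop_pos - 1L) %% L) + 1L)
    keep <- unlist(lapply(split(seq_len(nrow(out)), key), function(ix)
      ix[which.max(out$n_codons[ix])]))
    out <- out[sort(keep), , drop = FALSE]
  }
  out <- out[order(out$start, out$strand, out$end), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("orf_calls", "data.frame")
  out
}

#' Scan for sigma-70 promoter consensus placements
#'
#' Reports every placement, on both strands, of TTGACA and TATAAT separated
#' by a 15-18 nt spacer with at most `promoter_max_mismatches` mismatches
#' summed over the two hexamers. Overlapping placements with different
#' spacers are all reported. `pos_minus35` is the leftmost forward-strand
#' coordinate of the -35 hexamer on either strand. Circular genomes are
#' scanned across the origin.
#'
#' @inheritParams callOrfs
#' @return A data.frame with columns `pos_minus35`, `spacer`, `mm35`, `mm10`,
#'   `strand`.
#' @export
scanPromoters <- function(g, params = annotateParams()) {
  stopifnot(is(g, "PhageGenome"), inherits(params, "annotate_params"))
  s <- as.character(g@sequence)
  .checkAlphabet(s)
  L <- nchar(s)
  circular <- g@topology == "circular"
  wrap <- if (circular) min(29L, L) else 0L    # 6 + 18 + 6 - 1
  max_mm <- params$promoter_max_mismatches
  p35 <- Biostrings::DNAString("TTGACA")
  p10 <- Biostrings::DNAString("TATAAT")

  scanOne <- function(seq_chr) {
    subj <- Biostrings::DNAString(seq_chr)
    n <- length(subj)
    c35 <- Biostrings::start(Biostrings::matchPattern(
      p35, subj, max.mismatch = max_mm, fixed = TRUE))
    c35 <- c35[c35 >= 1L & c35 <= L]            # de-duplicate wrapped copies
    res <- list()
    for (a in c35) {
      mm35 <- Biostrings::neditStartingAt(p35, subj, starting.at = a,
                                          fixed = TRUE)
      if (mm35 > max_mm) next
      for (sp in 15:18) {
        b <- a + 6L + sp
        if (b + 5L > n) next
        mm10 <- Biostrings::neditStartingAt(p10, subj, starting.at = b,
                                            fixed = TRUE)
        if (mm35 + mm10 <= max_mm)
          res[[length(res) + 1L]] <- c(pos = a, spacer = sp,
                                       mm35 = mm35, mm10 = mm10)
      }
    }
    res
  }

  rows <- list()
  fwd_hits <- scanOne(paste0(s, substr(s, 1L, wrap)))
  for (h in fwd_hits)
    rows[[length(rows) + 1L]] <- data.frame(
      pos_minus35 = unname(h["pos"]), spacer = unname(h["spacer"]),
      mm35 = unname(h["mm35"]), mm10 = unname(h["mm10"]), strand = "+",
      stringsAsFactors = FALSE)
  rc <- .revcomp(s)
  rev_hits <- scanOne(paste0(rc, substr(rc, 1L, wrap)))
  for (h in rev_hits) {
    pos <- L - unname(h["pos"]) - 4L             # leftmost forward coordinate
    if (pos < 1L) pos <- pos + L
    rows[[length(rows) + 1L]] <- data.frame(
      pos_minus35 = pos, spacer = unname(h["spacer"]),
      mm35 = unname(h["mm35"]), mm10 = unname(h["mm10"]), strand = "-",
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pos_minus35 = integer(), spacer = integer(), mm35 = integer(),
               mm10 = integer(), strand = character(), stringsAsFactors = FALSE)
  out <- out[order(out$pos_minus35, out$strand, out$spacer), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("promoter_hits", "data.frame")
  out
}

#' Translate a CDS feature with the bacterial genetic code
#'
#' Translation table 11; GTG/CTG/TTG initiator codons are rendered as M and
#' the trailing stop is removed. An internal stop is an error naming the
#' offending codon position.
#'
#' @param g A [PhageGenome].
#' @param f A length-one [GenomicRanges::GRanges] (see [featureAt()]), or any
#'   object with `start`, `end` and `strand` accessors.
#' @return The protein sequence as a character string.
#' @export
translateCds <- function(g, f) {
  stopifnot(is(g, "PhageGenome"))
  st <- GenomicRanges::start(f)[1]
  en <- GenomicRanges::end(f)[1]
  strand_f <- as.character(GenomicRanges::strand(f))[1]
  s <- as.character(Biostrings::subseq(g@sequence, st, en))
  if (strand_f == "-") s <- .revcomp(s)
  if (nchar(s) %% 3L != 0L)
    stop(sprintf("CDS length %d is not divisible by 3", nchar(s)))
  code <- Biostrings::getGeneticCode("11")
  pos0 <- seq(1L, nchar(s), by = 3L)
  cods <- substring(s, pos0, pos0 + 2L)
  aa <- unname(code[cods])
  aa[is.na(aa)] <- "X"                       # codons containing N
  n <- length(aa)
  if (aa[n] == "*") { aa <- aa[-n]; n <- n - 1L }
  internal <- which(aa == "*")
  if (length(internal))
    stop(sprintf("internal stop codon at codon position %d", internal[[1]]))
  if (cods[[1]] %in% c("ATG", "GTG", "CTG", "TTG")) aa[1] <- "M"
  paste(aa, collapse = "")
}

#' Proteins of a set of ORF calls
#'
#' @param g A [PhageGenome].
#' @param orfs A data.frame from [callOrfs()].
#' @return A named [Biostrings::AAStringSet] (ids `orf_<n>`).
#' @export
orfProteins <- function(g, orfs) {
  s <- as.character(g@sequence)
  L <- nchar(s)
  getSeq <- function(st, en) {
    if (en <= L) return(substr(s, st, en))
    paste0(substr(s, st, L), substr(s, 1L, en - L))   # origin-spanning call
  }
  out <- character(nrow(orfs))
  for (i in seq_len(nrow(orfs))) {
    nt <- getSeq(orfs$start[i], orfs$end[i])
    if (orfs$strand[i] == "-") nt <- .revcomp(nt)
    tmp <- new("PhageGenome", id = "tmp", description = "",
               sequence = Biostrings::DNAString(nt), topology = "linear",
               features = GenomicRanges::GRanges())
    out[i] <- translateCds(tmp, GenomicRanges::GRanges(
      "tmp", IRanges::IRanges(1L, nchar(nt)), strand = "+"))
  }
  aa <- Biostrings::AAStringSet(out)
  names(aa) <- sprintf("orf_%d", seq_len(nrow(orfs)))
  aa
}

#' Write ORF and promoter calls as a GFF3-style table
#'
#' @param g A [PhageGenome].
#' @param orfs Result of [callOrfs()] (optional).
#' @param promoters Result of [scanPromoters()] (optional).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeAnnotationGff <- function(g, orfs = NULL, promoters = NULL, path) {
  rows <- character()
  if (!is.null(orfs) && nrow(orfs))
    rows <- c(rows, sprintf(
      "%s\tPhageCompare\tCDS\t%d\t%d\t%d\t%s\t.\tID=orf_%d;sd_offset=%s",
      g@id, orfs$start, orfs$end, orfs$sd_score, orfs$strand,
      seq_len(nrow(orfs)), orfs$sd_offset))
  if (!is.null(promoters) && nrow(promoters))
    rows <- c(rows, sprintf(
      "%s\tPhageCompare\tpromoter\t%d\t%d\t%d\t%s\t.\tspacer=%d",
      g@id, promoters$pos_minus35, promoters$pos_minus35 + 11L +
        promoters$spacer, promoters$mm35 + promoters$mm10,
      promoters$strand, promoters$spacer))
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}
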