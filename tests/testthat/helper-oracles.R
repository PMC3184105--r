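# Independent brute-force oracles, deliberately written with naive loops and
# a different control flow than the package implementation.

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

oracle_gc <- function(s) {
  ch <- strsplit(toupper(s), "")[[1]]
  round(100 * sum(ch %in% c("G", "C")) / sum(ch %in% c("A", "C", "G", "T")), 1)
}

# Best SD match count in the window (chars immediately upstream of a start).
oracle_sd_best <- function(window) {
  cons <- strsplit("GGAGGT", "")[[1]]
  ch <- strsplit(window, "")[[1]]
  W <- length(ch)
  if (W < 6) return(0L)
  best <- 0L
  for (i in 1:(W - 5)) best <- max(best, sum(ch[i:(i + 5)] == cons))
  best
}

# Six-frame brute-force ORF scanner (linear sequences only). For every start
# codon, extend codon-by-codon to the first in-frame stop; keep calls with
# n_codons >= 31 and a passing SD window; then, among calls sharing one stop
# (same frame & strand), keep only the upstream-most.
oracle_orfs <- function(seq_chr, min_extra = 30, sd_min = 4, window = 15,
                        require_sd = TRUE) {
  starts <- c("ATG", "GTG", "CTG", "TTG")
  stops <- c("TAA", "TAG", "TGA")
  L <- nchar(seq_chr)
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq_chr else oracle_revcomp(seq_chr)
    for (b in 1:max(L - 2, 1)) {
      cod <- substr(s, b, b + 2)
      if (!cod %in% starts) next
      # extend to first in-frame stop
      k <- b + 3; n_codons <- 1L; stop_at <- NA
      while (k + 2 <= L) {
        ck <- substr(s, k, k + 2)
        if (ck %in% stops) { stop_at <- k; break }
        n_codons <- n_codons + 1L
        k <- k + 3
      }
      if (is.na(stop_at) || n_codons < min_extra + 1) next
      if (require_sd) {
        win <- substr(s, max(1, b - window), b - 1)
        if (nchar(win) < 6 || oracle_sd_best(win) < sd_min) next
      }
      e <- stop_at + 2
      if (strand == "+") {
        res[[length(res) + 1]] <- data.frame(
          start = b, end = e, strand = strand, n_codons = n_codons,
          stop_key = paste(strand, stop_at), stringsAsFactors = FALSE)
      } else {
        res[[length(res) + 1]] <- data.frame(
          start = L - e + 1, end = L - b + 1, strand = strand,
          n_codons = n_codons, stop_key = paste(strand, stop_at),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res))
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), n_codons = integer()))
  df <- do.call(rbind, res)
  # upstream-most qualifying call per stop codon = largest n_codons
  keep <- unlist(lapply(split(seq_len(nrow(df)), df$stop_key), function(ix) {
    ix[which.max(df$n_codons[ix])]
  }))
  df <- df[keep, c("start", "end", "strand", "n_codons")]
  df[order(df$start, df$strand), , drop = FALSE]
}

# Naive sliding-window promoter oracle (linear sequences, both strands).
oracle_promoters <- function(seq_chr, max_mm = 0) {
  L <- nchar(seq_chr)
  hexmm <- function(s, pos, pat) {
    sub <- substr(s, pos, pos + 5)
    if (nchar(sub) < 6) return(Inf)
    sum(strsplit(sub, "")[[1]] != strsplit(pat, "")[[1]])
  }
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq_chr else oracle_revcomp(seq_chr)
    for (a in 1:max(L - 5, 1)) {
      m35 <- hexmm(s, a, "TTGACA")
      if (m35 > max_mm) next
      for (sp in 15:18) {
        b <- a + 6 + sp
        m10 <- hexmm(s, b, "TATAAT")
        if (m35 + m10 <= max_mm) {
          pos <- if (strand == "+") a else L - a - 4
          out[[length(out) + 1]] <- data.frame(
            pos_minus35 = pos, spacer = sp, strand = strand,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(pos_minus35 = integer(), spacer = integer(),
                      strand = character()))
  df <- do.call(rbind, out)
  df[order(df$pos_minus35, df$strand, df$spacer), , drop = FALSE]
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

as_genome <- function(seq_chr, id = "test", topology = "linear") {
  new("PhageGenome", id = id, description = "",
      sequence = Biostrings::DNAString(seq_chr), topology = topology,
      features = GenomicRanges::GRanges())
}

proteome_from_vec <- function(x, id) {
  aa <- Biostrings::AAStringSet(x)
  new("Proteome", genome_id = id, proteins = aa)
}

orf_key <- function(df) paste(df$start, df$end, df$strand)
prom_key <- function(df) paste(df$pos_minus35, df$spacer, df$strand)
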