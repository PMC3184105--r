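.blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

.asAA <- function(x) {
  if (is(x, "AAString")) return(x)
  if (is(x, "AAStringSet")) return(x[[1]])
  Biostrings::AAString(toupper(as.character(x)))
}

#' Align two proteins locally
#'
#' Smith-Waterman local alignment under BLOSUM62 with affine gaps
#' (open 11, extend 1). Identity is identical columns over aligned columns,
#' gap columns included in the denominator; coverage is the aligned span on
#' the shorter protein divided by the shorter length (`coverage_mode` selects
#' alternatives).
#'
#' @param a,b Protein sequences (character or [Biostrings::AAString]).
#' @param gap_open,gap_extend Affine gap penalties (defaults 11, 1).
#' @param coverage_mode `"shorter"` (default), `"query"` (span on `a` over
#'   length of `a`) or `"both"` (minimum of the two per-sequence coverages).
#' @return A list of class `pairwise_hit` with `score`, `identity_percent`,
#'   `coverage_percent`, `q_range`, `s_range`, `alignment_length`.
#' @export
alignProteins <- function(a, b, gap_open = 11, gap_extend = 1,
                          coverage_mode = c("shorter", "query", "both")) {
  coverage_mode <- match.arg(coverage_mode)
  a <- .asAA(a); b <- .asAA(b)
  if (length(a) == 0L || length(b) == 0L)
    stop("cannot align an empty protein sequence")
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "local", substitutionMatrix = .blosum62(),
    gapOpening = gap_open, gapExtension = gap_extend)
  qr <- c(Biostrings::start(Biostrings::pattern(aln)),
          Biostrings::end(Biostrings::pattern(aln)))
  sr <- c(Biostrings::start(Biostrings::subject(aln)),
          Biostrings::end(Biostrings::subject(aln)))
  cov_a <- 100 * (qr[2] - qr[1] + 1L) / length(a)
  cov_b <- 100 * (sr[2] - sr[1] + 1L) / length(b)
  cov <- switch(coverage_mode,
    shorter = if (length(a) <= length(b)) cov_a else cov_b,
    query = cov_a,
    both = min(cov_a, cov_b))
  structure(list(
    score = Biostrings::score(aln),
    identity_percent = Biostrings::pid(aln, type = "PID1"),
    coverage_percent = cov,
    q_range = qr, s_range = sr,
    alignment_length = nchar(as.character(Biostrings::pattern(aln)))),
    class = "pairwise_hit")
}

#' @export
print.pairwise_hit <- function(x, ...) {
  cat(sprintf(
    "pairwise hit: score %.0f, identity %.1f%%, coverage %.1f%%, q %d-%d, s %d-%d\n",
    x$score, x$identity_percent, x$coverage_percent,
    x$q_range[1], x$q_range[2], x$s_range[1], x$s_range[2]))
  invisible(x)
}

# All-against-all alignment statistics between two proteomes. Local alignment
# scores under a symmetric matrix are direction-symmetric, so one direction
# suffices. Returns nA x nB matrices: score, identity, cov_a, cov_b.
.allPairStats <- function(pa, pb, gap_open = 11, gap_extend = 1) {
  A <- proteins(pa); B <- proteins(pb)
  nA <- length(A); nB <- length(B)
  mat <- .blosum62()
  score <- identity <- cov_a <- cov_b <-
    matrix(NA_real_, nA, nB, dimnames = list(names(A), names(B)))
  wA <- Biostrings::width(A); wB <- Biostrings::width(B)
  for (j in seq_len(nB)) {
    aln <- Biostrings::pairwiseAlignment(
      A, B[[j]], type = "local", substitutionMatrix = mat,
      gapOpening = gap_open, gapExtension = gap_extend)
    score[, j] <- Biostrings::score(aln)
    identity[, j] <- Biostrings::pid(aln, type = "PID1")
    spanA <- Biostrings::end(Biostrings::pattern(aln)) -
      Biostrings::start(Biostrings::pattern(aln)) + 1L
    spanB <- Biostrings::end(Biostrings::subject(aln)) -
      Biostrings::start(Biostrings::subject(aln)) + 1L
    cov_a[, j] <- 100 * spanA / wA
    cov_b[, j] <- 100 * spanB / wB[j]
  }
  list(score = score, identity = identity, cov_a = cov_a, cov_b = cov_b,
       wA = wA, wB = wB)
}

# Coverage matrix under the chosen length-anchoring rule. "shorter" picks,
# per cell, the coverage of whichever protein is shorter.
.coverageMatrix <- function(st, coverage_mode) {
  switch(coverage_mode,
    shorter = {
      WA <- matrix(st$wA, length(st$wA), length(st$wB))
      WB <- matrix(st$wB, length(st$wA), length(st$wB), byrow = TRUE)
      ifelse(WA <= WB, st$cov_a, st$cov_b)
    },
    query = st$cov_a,
    both = pmin(st$cov_a, st$cov_b))
}

# Qualifying-hit matrix under the identity/coverage thresholds.
.qualifies <- function(st, min_identity, min_coverage, coverage_mode) {
  st$identity >= min_identity &
    .coverageMatrix(st, coverage_mode) >= min_coverage
}

#' Reciprocal-best-hit orthologs between two proteomes
#'
#' Locus `x` of proteome `a` pairs with `y` of proteome `b` when each is the
#' other's best-scoring hit and both directions satisfy the identity and
#' coverage thresholds (the classic 40%/80% reciprocal rule by default).
#' Score ties are broken by higher identity, then lexicographic locus id.
#'
#' @param pa,pb [Proteome] objects.
#' @param min_identity Minimum percent identity (default 40).
#' @param min_coverage Minimum percent coverage (default 80).
#' @param coverage_mode Which length anchors the coverage rule: `"shorter"`
#'   (default), `"query"` or `"both"`.
#' @param pairing `"rbh"` (default): mutual best-scoring hits, then threshold
#'   filtered. `"best_qualifying"`: mutual best hits among threshold-passing
#'   hits only.
#' @param gap_open,gap_extend Affine gap penalties.
#' @return An [OrthologTable].
#' @export
reciprocalOrthologs <- function(pa, pb, min_identity = 40, min_coverage = 80,
                                coverage_mode = c("shorter", "query", "both"),
                                pairing = c("rbh", "best_qualifying"),
                                gap_open = 11, gap_extend = 1) {
  coverage_mode <- match.arg(coverage_mode)
  pairing <- match.arg(pairing)
  stopifnot(is(pa, "Proteome"), is(pb, "Proteome"),
            length(pa) > 0L, length(pb) > 0L)
  st <- .allPairStats(pa, pb, gap_open, gap_extend)
  .orthologTableFromStats(pa, pb, st, min_identity, min_coverage,
                          coverage_mode, pairing)
}

.bestHit <- function(score_row, ident_row, ids) {
  best <- which(score_row == max(score_row))
  if (length(best) > 1L) {
    best <- best[ident_row[best] == max(ident_row[best])]
    if (length(best) > 1L) best <- best[order(ids[best])][1]
  }
  best[[1]]
}

.orthologTableFromStats <- function(pa, pb, st, min_identity, min_coverage,
                                    coverage_mode, pairing = "rbh") {
  qual <- .qualifies(st, min_identity, min_coverage, coverage_mode)
  idsA <- rownames(st$score); idsB <- colnames(st$score)
  score <- st$score
  if (pairing == "best_qualifying") score[!qual] <- -Inf
  nA <- length(idsA); nB <- length(idsB)
  bestB <- integer(nA)    # best subject for each query
  for (i in seq_len(nA))
    bestB[i] <- if (all(!is.finite(score[i, ]))) NA_integer_ else
      .bestHit(score[i, ], st$identity[i, ], idsB)
  bestA <- integer(nB)
  for (j in seq_len(nB))
    bestA[j] <- if (all(!is.finite(score[, j]))) NA_integer_ else
      .bestHit(score[, j], st$identity[, j], idsA)
  rows <- list()
  for (i in seq_len(nA)) {
    j <- bestB[i]
    if (is.na(j) || is.na(bestA[j]) || bestA[j] != i) next
    if (!qual[i, j]) next
    # threshold check in both directions (identity/score symmetric; query
    # coverage differs by direction)
    if (coverage_mode == "query" &&
        !(st$cov_a[i, j] >= min_coverage && st$cov_b[i, j] >= min_coverage))
      next
    rows[[length(rows) + 1L]] <- data.frame(
      locus_a = idsA[i], locus_b = idsB[j], score = st$score[i, j],
      identity_ab = st$identity[i, j], coverage_ab = st$cov_a[i, j],
      identity_ba = st$identity[i, j], coverage_ba = st$cov_b[i, j],
      stringsAsFactors = FALSE)
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus_a = character(), locus_b = character(),
               score = numeric(), identity_ab = numeric(),
               coverage_ab = numeric(), identity_ba = numeric(),
               coverage_ba = numeric(), stringsAsFactors = FALSE)
  new("OrthologTable", genome_a = genomeId(pa), genome_b = genomeId(pb),
      pairs = pairs,
      params = list(min_identity = min_identity, min_coverage = min_coverage,
                    coverage_mode = coverage_mode, pairing = pairing))
}

#' Conserved/unique partition of three proteomes
#'
#' Computes the three pairwise ortholog tables, then: `conserved` = triples
#' mutually linked by all three tables; `unique` = loci of one genome with no
#' threshold-qualifying hit in either other genome; `shared_two` = the
#' remainder (qualifying hit somewhere, but no three-way triple).
#'
#' @inheritParams reciprocalOrthologs
#' @param pc The third [Proteome].
#' @return A [TriadPartition].
#' @export
partitionTriad <- function(pa, pb, pc, min_identity = 40, min_coverage = 80,
                           coverage_mode = c("shorter", "query", "both"),
                           pairing = c("rbh", "best_qualifying"),
                           gap_open = 11, gap_extend = 1) {
  coverage_mode <- match.arg(coverage_mode)
  pairing <- match.arg(pairing)
  prots <- list(pa, pb, pc)
  ids <- vapply(prots, genomeId, character(1))
  if (anyDuplicated(ids)) stop("the three proteomes must have distinct ids")
  st_ab <- .allPairStats(pa, pb, gap_open, gap_extend)
  st_ac <- .allPairStats(pa, pc, gap_open, gap_extend)
  st_bc <- .allPairStats(pb, pc, gap_open, gap_extend)
  t_ab <- .orthologTableFromStats(pa, pb, st_ab, min_identity, min_coverage,
                                  coverage_mode, pairing)
  t_ac <- .orthologTableFromStats(pa, pc, st_ac, min_identity, min_coverage,
                                  coverage_mode, pairing)
  t_bc <- .orthologTableFromStats(pb, pc, st_bc, min_identity, min_coverage,
                                  coverage_mode, pairing)

  map_ab <- stats::setNames(t_ab@pairs$locus_b, t_ab@pairs$locus_a)
  map_ac <- stats::setNames(t_ac@pairs$locus_b, t_ac@pairs$locus_a)
  map_bc <- stats::setNames(t_bc@pairs$locus_b, t_bc@pairs$locus_a)
  triples <- list()
  for (x in names(map_ab)) {
    y <- map_ab[[x]]
    if (!x %in% names(map_ac)) next
    z <- map_ac[[x]]
    if (!y %in% names(map_bc) || map_bc[[y]] != z) next
    triples[[length(triples) + 1L]] <- data.frame(
      a = x, b = y, c = z, stringsAsFactors = FALSE)
  }
  conserved <- if (length(triples)) do.call(rbind, triples) else
    data.frame(a = character(), b = character(), c = character(),
               stringsAsFactors = FALSE)
  names(conserved) <- ids

  qual_ab <- .qualifies(st_ab, min_identity, min_coverage, coverage_mode)
  qual_ac <- .qualifies(st_ac, min_identity, min_coverage, coverage_mode)
  qual_bc <- .qualifies(st_bc, min_identity, min_coverage, coverage_mode)
  has_hit <- list()
  has_hit[[ids[1]]] <- rowSums(qual_ab) > 0 | rowSums(qual_ac) > 0
  has_hit[[ids[2]]] <- colSums(qual_ab) > 0 | rowSums(qual_bc) > 0
  has_hit[[ids[3]]] <- colSums(qual_ac) > 0 | colSums(qual_bc) > 0

  unique_loci <- shared_two <- stats::setNames(vector("list", 3), ids)
  all_names <- list(names(proteins(pa)), names(proteins(pb)),
                    names(proteins(pc)))
  for (k in 1:3) {
    g <- ids[k]
    in_triple <- conserved[[g]]
    hh <- has_hit[[g]]
    unique_loci[[g]] <- all_names[[k]][!hh[all_names[[k]]]]
    shared_two[[g]] <- setdiff(all_names[[k]][hh[all_names[[k]]]], in_triple)
  }

  new("TriadPartition", genomes = ids,
      n_genes = stats::setNames(vapply(prots, length, integer(1)), ids),
      conserved = conserved, shared_two = shared_two,
      unique_loci = unique_loci,
      tables = list(ab = t_ab, ac = t_ac, bc = t_bc))
}

#' Audit a proteome against a named core-gene set
#'
#' Each core gene (T4 nomenclature, e.g. gp34) is marked present when any
#' proteome member passes the thresholds against it. Defaults are laxer than
#' the orthology rule because core genes are expected to be distant homologs.
#'
#' @param p A [Proteome].
#' @param core Named [Biostrings::AAStringSet] of core reference proteins.
#' @param min_identity,min_coverage Thresholds (defaults 30, 50).
#' @param coverage_mode See [reciprocalOrthologs()].
#' @return A data.frame (class `core_audit`) with one row per core gene:
#'   `core_gene`, `status`, `best_locus`, `identity`, `coverage`, `score`.
#' @export
coreGeneAudit <- function(p, core, min_identity = 30, min_coverage = 50,
                          coverage_mode = c("shorter", "query", "both")) {
  coverage_mode <- match.arg(coverage_mode)
  stopifnot(is(p, "Proteome"), length(core) > 0L)
  if (is(core, "Proteome")) core <- proteins(core)
  core_p <- new("Proteome", genome_id = "__core__",
                proteins = Biostrings::AAStringSet(core))
  st <- .allPairStats(core_p, p)
  qual <- .qualifies(st, min_identity, min_coverage, coverage_mode)
  cov <- .coverageMatrix(st, coverage_mode)
  out <- data.frame(core_gene = names(core), status = "absent",
                    best_locus = NA_character_, identity = NA_real_,
                    coverage = NA_real_, score = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(core)) {
    if (!any(qual[i, ])) next
    j <- which(qual[i, ])[which.max(st$score[i, qual[i, ]])]
    out$status[i] <- "present"
    out$best_locus[i] <- colnames(st$score)[j]
    out$identity[i] <- st$identity[i, j]
    out$coverage[i] <- cov[i, j]
    out$score[i] <- st$score[i, j]
  }
  class(out) <- c("core_audit", "data.frame")
  out
}

#' Identity between two specified protein regions
#'
#' In `gapless` mode the two (equal-length) excised regions are compared
#' column by column; in `global` mode they are aligned end to end with affine
#' gaps and identity is reported over aligned columns (gap columns in the
#' denominator). The significance estimate is a Karlin-Altschul-style
#' approximation and is flagged approximate.
#'
#' @param prot_a,prot_b Protein sequences.
#' @param a_range,b_range Length-2 integer vectors, 1-based inclusive
#'   amino-acid ranges.
#' @param mode `"gapless"` (default) or `"global"`.
#' @return A list of class `region_match`: `identity_percent`,
#'   `alignment_length`, `score`, `e_value_like` (approximate), ranges.
#' @export
regionIdentity <- function(prot_a, a_range, prot_b, b_range,
                           mode = c("gapless", "global")) {
  mode <- match.arg(mode)
  a <- toupper(as.character(prot_a)); b <- toupper(as.character(prot_b))
  stopifnot(length(a_range) == 2L, length(b_range) == 2L,
            a_range[1] >= 1L, a_range[2] <= nchar(a),
            b_range[1] >= 1L, b_range[2] <= nchar(b),
            a_range[1] <= a_range[2], b_range[1] <= b_range[2])
  ra <- substr(a, a_range[1], a_range[2])
  rb <- substr(b, b_range[1], b_range[2])
  mat <- .blosum62()
  if (mode == "gapless") {
    if (nchar(ra) != nchar(rb))
      stop("gapless mode requires equal-length ranges")
    ca <- strsplit(ra, "")[[1]]; cb <- strsplit(rb, "")[[1]]
    n_id <- sum(ca == cb & ca != "X")
    len <- nchar(ra)
    score <- sum(mat[cbind(ca, cb)])
    ident <- 100 * n_id / len
  } else {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(ra), Biostrings::AAString(rb), type = "global",
      substitutionMatrix = mat, gapOpening = 11, gapExtension = 1)
    ident <- Biostrings::pid(aln, type = "PID1")
    len <- nchar(as.character(Biostrings::pattern(aln)))
    score <- Biostrings::score(aln)
  }
  # gapped BLOSUM62 Karlin-Altschul parameters (lambda 0.267, K 0.041)
  evalue <- 0.041 * nchar(ra) * nchar(rb) * exp(-0.267 * max(score, 0))
  structure(list(a_range = a_range, b_range = b_range,
                 identity_percent = ident, alignment_length = len,
                 score = score, e_value_like = evalue,
                 e_value_note = "Karlin-Altschul-style approximation"),
            class = "region_match")
}

#' @export
print.region_match <- function(x, ...) {
  cat(sprintf(
    "region match: a[%d-%d] vs b[%d-%d], identity %.1f%% over %d columns (E ~ %.2g)\n",
    x$a_range[1], x$a_range[2], x$b_range[1], x$b_range[2],
    x$identity_percent, x$alignment_length, x$e_value_like))
  invisible(x)
}

#' Count loci with at least one qualifying (non-reciprocal) hit
#'
#' The count is threshold-sensitive and intended as a descriptive statistic,
#' not a calibrated quantity.
#'
#' @inheritParams reciprocalOrthologs
#' @return Integer: number of `pa` loci with at least one hit in `pb` passing
#'   the thresholds.
#' @export
sharedHomologCount <- function(pa, pb, min_identity = 40, min_coverage = 80,
                               coverage_mode = c("shorter", "query", "both")) {
  coverage_mode <- match.arg(coverage_mode)
  st <- .allPairStats(pa, pb)
  qual <- .qualifies(st, min_identity, min_coverage, coverage_mode)
  sum(rowSums(qual) > 0)
}

#' Synteny blocks from ortholog anchors
#'
#' Anchors (ortholog pairs) sorted by gene position in the first proteome are
#' chained into maximal runs whose positions in the second proteome advance
#' by exactly +1 (or -1 throughout, for inversions). For circularly permuted
#' genomes (`circular = TRUE`) the first and last run may be merged across
#' the origin. `synteny_fraction` is the proportion of anchors lying in runs
#' of length >= 2.
#'
#' @param tab An [OrthologTable] computed from `pa` and `pb`.
#' @param pa,pb The same [Proteome]s the table was computed from.
#' @param circular Allow one wrap at the origin (default FALSE).
#' @return A list of class `synteny_result`: `blocks` (data.frame with
#'   `a_from`, `a_to`, `b_from`, `b_to`, `n_anchors`, `orientation`),
#'   `n_blocks` (runs of length >= 2), `n_singletons`, `synteny_fraction`,
#'   `n_anchors`.
#' @export
syntenyBlocks <- function(tab, pa, pb, circular = FALSE) {
  stopifnot(is(tab, "OrthologTable"))
  prs <- tab@pairs
  if (!nrow(prs))
    return(structure(list(blocks = data.frame(), n_blocks = 0L,
                          n_singletons = 0L, synteny_fraction = NA_real_,
                          n_anchors = 0L), class = "synteny_result"))
  pos_a <- match(prs$locus_a, names(proteins(pa)))
  pos_b <- match(prs$locus_b, names(proteins(pb)))
  if (anyNA(pos_a) || anyNA(pos_b))
    stop("ortholog table does not match the supplied proteomes")
  o <- order(pos_a)
  pos_a <- pos_a[o]; pos_b <- pos_b[o]
  n <- length(pos_a)
  run_id <- integer(n); run_dir <- integer(n)
  run_id[1] <- 1L; cur_dir <- 0L
  for (i in seq_len(n - 1L)) {
    d <- pos_b[i + 1L] - pos_b[i]
    if ((d == 1L || d == -1L) && (cur_dir == 0L || d == cur_dir)) {
      run_id[i + 1L] <- run_id[i]; cur_dir <- d
    } else if (d == 1L || d == -1L) {
      run_id[i + 1L] <- run_id[i] + 1L; cur_dir <- d
    } else {
      run_id[i + 1L] <- run_id[i] + 1L; cur_dir <- 0L
    }
    run_dir[run_id[i + 1L]] <- cur_dir
  }
  blocks <- do.call(rbind, lapply(split(seq_len(n), run_id), function(ix) {
    data.frame(a_from = pos_a[ix[1]], a_to = pos_a[ix[length(ix)]],
               b_from = pos_b[ix[1]], b_to = pos_b[ix[length(ix)]],
               n_anchors = length(ix),
               orientation = if (length(ix) == 1L) "." else
                 if (pos_b[ix[2]] > pos_b[ix[1]]) "+" else "-",
               stringsAsFactors = FALSE)
  }))
  rownames(blocks) <- NULL
  merged_across_origin <- FALSE
  if (circular && nrow(blocks) > 1L) {
    nb_a <- length(proteins(pa)); nb_b <- length(proteins(pb))
    first <- blocks[1, ]; last <- blocks[nrow(blocks), ]
    joins <- function(dirs, to, from, nmax)
      (to %% nmax) + 1L == from
    same_dir <- first$orientation %in% c(".", last$orientation) ||
      last$orientation == "."
    if (same_dir && joins(NULL, last$a_to, first$a_from, nb_a) &&
        joins(NULL, last$b_to, first$b_from, nb_b)) {
      blocks$n_anchors[1] <- blocks$n_anchors[1] + last$n_anchors
      blocks$a_from[1] <- last$a_from; blocks$b_from[1] <- last$b_from
      blocks <- blocks[-nrow(blocks), , drop = FALSE]
      merged_across_origin <- TRUE
    }
  }
  big <- blocks$n_anchors >= 2L
  structure(list(blocks = blocks,
                 n_blocks = sum(big),
                 n_singletons = sum(!big),
                 synteny_fraction = sum(blocks$n_anchors[big]) / n,
                 n_anchors = n,
                 merged_across_origin = merged_across_origin),
            class = "synteny_result")
}

#' @export
print.synteny_result <- function(x, ...) {
  cat(sprintf(
    "synteny: %d anchors in %d block(s) (+%d singleton(s)), fraction %.3f\n",
    x$n_anchors, x$n_blocks, x$n_singletons, x$synteny_fraction))
  invisible(x)
}

#' Write an ortholog table as TSV
#'
#' @param tab An [OrthologTable].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeOrthologTable <- function(tab, path) {
  utils::write.table(tab@pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
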