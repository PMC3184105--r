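#' Three-genome comparison report
#'
#' End-to-end driver: reads (or accepts) three genomes, derives their
#' proteomes (stored CDS translations when annotated, otherwise de novo gene
#' calls via [callOrfs()]), computes per-genome statistics, the three
#' pairwise ortholog tables, the conserved/unique triad partition and
#' ortholog-anchor synteny, and assembles a genome-properties summary table
#' (size, GC, gene count, conserved and unique counts).
#'
#' @param genomes List or vector of three [PhageGenome] objects or file
#'   paths (FASTA/GenBank).
#' @param params [annotateParams()] used when de novo calling is needed.
#' @param min_identity,min_coverage,coverage_mode,pairing Orthology
#'   thresholds, see [reciprocalOrthologs()].
#' @param out_dir Optional output directory; when given, summary, ortholog,
#'   partition and synteny tables are written as TSV along with the resolved
#'   configuration (`config.tsv`) for provenance.
#' @return A list of class `triad_report`: `summary` (data.frame),
#'   `partition` ([TriadPartition]), `synteny` (per-pair results), `stats`,
#'   `proteomes`, `config`.
#' @export
runTriadReport <- function(genomes, params = annotateParams(),
                           min_identity = 40, min_coverage = 80,
                           coverage_mode = c("shorter", "query", "both"),
                           pairing = c("rbh", "best_qualifying"),
                           out_dir = NULL) {
  coverage_mode <- match.arg(coverage_mode)
  pairing <- match.arg(pairing)
  if (length(genomes) != 3L) stop("exactly three genomes are required")
  gs <- lapply(genomes, function(g) {
    if (is(g, "PhageGenome")) g else readGenome(g)
  })
  ids <- vapply(gs, genomeId, character(1))
  if (anyDuplicated(ids)) stop("genomes must have distinct ids")

  stats_list <- lapply(gs, function(g) {
    tryCatch(genomeStats(g),
             error = function(e) stop(sprintf("stats stage failed for '%s': %s",
                                              genomeId(g), conditionMessage(e)),
                                      call. = FALSE))
  })
  proteomes <- lapply(gs, function(g) {
    has_cds <- length(g@features) && any(mcols(g@features)$kind == "CDS")
    tryCatch({
      if (has_cds) proteomeFromGenome(g)
      else {
        orfs <- callOrfs(g, params)
        if (!nrow(orfs))
          stop("no genes called; cannot build a proteome")
        aa <- orfProteins(g, orfs)
        names(aa) <- sprintf("%s_%s", genomeId(g), names(aa))
        new("Proteome", genome_id = genomeId(g), proteins = aa)
      }
    }, error = function(e) stop(sprintf("annotation stage failed for '%s': %s",
                                        genomeId(g), conditionMessage(e)),
                                call. = FALSE))
  })

  part <- tryCatch(
    partitionTriad(proteomes[[1]], proteomes[[2]], proteomes[[3]],
                   min_identity = min_identity, min_coverage = min_coverage,
                   coverage_mode = coverage_mode, pairing = pairing),
    error = function(e) stop(sprintf("orthology stage failed: %s",
                                     conditionMessage(e)), call. = FALSE))
  cnt <- partitionCounts(part)

  circular <- vapply(gs, function(g) topology(g) == "circular", logical(1))
  syn <- list(
    ab = syntenyBlocks(part@tables$ab, proteomes[[1]], proteomes[[2]],
                       circular = circular[1] || circular[2]),
    ac = syntenyBlocks(part@tables$ac, proteomes[[1]], proteomes[[3]],
                       circular = circular[1] || circular[3]),
    bc = syntenyBlocks(part@tables$bc, proteomes[[2]], proteomes[[3]],
                       circular = circular[2] || circular[3]))

  summary_df <- data.frame(
    genome = ids,
    genome_size_bp = vapply(stats_list, `[[`, numeric(1), "length_bp"),
    gc_percent = vapply(stats_list, `[[`, numeric(1), "gc_percent"),
    predicted_genes = vapply(proteomes, length, integer(1)),
    conserved_all = rep(cnt$conserved_all, 3),
    unique = unname(cnt$unique[ids]),
    stringsAsFactors = FALSE)

  config <- list(min_identity = min_identity, min_coverage = min_coverage,
                 coverage_mode = coverage_mode, pairing = pairing,
                 min_extra_codons = params$min_extra_codons,
                 sd_window_bp = params$sd_window_bp,
                 sd_min_matches = params$sd_min_matches,
                 require_sd = params$require_sd)

  out <- structure(list(summary = summary_df, partition = part,
                        synteny = syn, stats = stats_list,
                        proteomes = proteomes, config = config),
                   class = "triad_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(summary_df, file.path(out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (nm in names(part@tables))
      writeOrthologTable(part@tables[[nm]],
                         file.path(out_dir, sprintf("orthologs_%s.tsv", nm)))
    utils::write.table(part@conserved, file.path(out_dir, "conserved.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    uq <- data.frame(
      genome = rep(ids, vapply(part@unique_loci[ids], length, integer(1))),
      locus = unlist(part@unique_loci[ids], use.names = FALSE),
      stringsAsFactors = FALSE)
    utils::write.table(uq, file.path(out_dir, "unique.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cfg <- data.frame(key = names(config),
                      value = vapply(config, as.character, character(1)),
                      stringsAsFactors = FALSE)
    utils::write.table(cfg, file.path(out_dir, "config.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' @export
print.triad_report <- function(x, ...) {
  cat("Triad comparison report\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
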