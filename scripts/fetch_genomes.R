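#!/usr/bin/env Rscript
# Convenience helper for users WITH network access: downloads the three
# deposited ViI-like phage genome records (CBA120, ViI, AG3) from NCBI as
# GenBank flat files, ready for runTriadReport(). No test or analysis in
# this package requires these downloads.
#
#   Rscript scripts/fetch_genomes.R [outdir]

args <- commandArgs(trailingOnly = TRUE)
outdir <- if (length(args)) args[[1]] else "genomes"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

accessions <- c(CBA120 = "JN593240", ViI = "FQ312032", AG3 = "FJ373894")
base <- "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi"

for (nm in names(accessions)) {
  acc <- accessions[[nm]]
  dest <- file.path(outdir, paste0(acc, ".gbk"))
  url <- sprintf("%s?db=nuccore&id=%s&rettype=gbwithparts&retmode=text",
                 base, acc)
  message("fetching ", nm, " (", acc, ") -> ", dest)
  utils::download.file(url, dest, quiet = TRUE, mode = "wb")
  Sys.sleep(1)   # NCBI rate courtesy
}
message("done. Example:\n  R> runTriadReport(list(",
        paste(sprintf("'%s/%s.gbk'", outdir, accessions), collapse = ", "),
        "))")
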