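# Minimal GenBank flat-file parser: LOCUS, DEFINITION, ACCESSION/VERSION,
# the FEATURES table (CDS/tRNA and friends with locus_tag/gene/product/
# translation qualifiers) and the ORIGIN sequence block. Joined locations are
# collapsed to their outer span (rare in phage records; a message is emitted).

.gbParseLocation <- function(loc, line_no) {
  loc <- gsub("[<>[:space:]]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  joined <- FALSE
  if (grepl("^(join|order)\\(", loc)) {
    joined <- TRUE
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  }
  if (grepl("complement", loc)) {  # complement nested inside join
    strand <- "-"
    loc <- gsub("complement\\(|\\)", "", loc)
  }
  parts <- strsplit(loc, ",")[[1]]
  nums <- suppressWarnings(lapply(strsplit(parts, "\\.\\."), as.integer))
  flat <- unlist(nums)
  if (!length(flat) || anyNA(flat))
    stop(sprintf("GenBank format error at line %d: cannot parse location '%s'",
                 line_no, loc), call. = FALSE)
  if (joined && length(parts) > 1L)
    message(sprintf("joined location collapsed to outer span at line %d", line_no))
  list(start = min(flat), end = max(flat), strand = strand)
}

.gbParseFeatures <- function(lines, offset) {
  feats <- list()
  cur <- NULL
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    key <- trimws(substr(ln, 1, 20))
    body <- trimws(substr(ln, 21, nchar(ln)))
    if (nzchar(key)) {                       # new feature
      if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
      cur <- list(key = key, loc = body, quals = character(), line = offset + i)
    } else if (!is.null(cur)) {
      if (startsWith(body, "/")) {
        cur$quals <- c(cur$quals, body)
      } else if (length(cur$quals)) {        # continuation of a qualifier value
        n <- length(cur$quals)
        sep <- if (grepl("/translation=", cur$quals[n], fixed = TRUE) ||
                   !grepl("\"$", body)) "" else " "
        cur$quals[n] <- paste0(cur$quals[n], sep, body)
      } else {                               # continuation of the location
        cur$loc <- paste0(cur$loc, body)
      }
    }
  }
  if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
  feats
}

.gbQual <- function(quals, name) {
  hit <- grep(paste0("^/", name, "="), quals, value = TRUE)
  if (!length(hit)) return(NA_character_)
  v <- sub(paste0("^/", name, "="), "", hit[[1]])
  gsub("^\"|\"$", "", v)
}

.readGenBank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (!length(locus_i))
    stop(sprintf("GenBank format error at line 1 of '%s': no LOCUS line", path),
         call. = FALSE)
  locus_i <- locus_i[[1]]
  locus_fields <- strsplit(trimws(lines[[locus_i]]), "[[:space:]]+")[[1]]
  topo <- if (any(tolower(locus_fields) == "circular")) "circular" else "linear"

  id <- NA_character_
  for (key in c("^VERSION", "^ACCESSION")) {       # versioned id preferred
    ki <- grep(key, lines)
    if (length(ki)) {
      f <- strsplit(trimws(lines[[ki[[1]]]]), "[[:space:]]+")[[1]]
      if (length(f) >= 2) { id <- f[[2]]; break }
    }
  }
  if (is.na(id)) id <- locus_fields[[2]]

  defn <- ""
  def_i <- grep("^DEFINITION", lines)
  if (length(def_i)) {
    j <- def_i[[1]]
    defn <- sub("^DEFINITION[[:space:]]*", "", lines[[j]])
    while (j + 1 <= length(lines) && grepl("^[[:space:]]", lines[[j + 1]])) {
      j <- j + 1
      defn <- paste(defn, trimws(lines[[j]]))
    }
  }

  origin_i <- grep("^ORIGIN", lines)
  if (!length(origin_i))
    stop(sprintf("GenBank format error in '%s': no ORIGIN block", path),
         call. = FALSE)
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[end_i > origin_i[[1]]][1] else length(lines) + 1L
  seq_chr <- toupper(gsub("[^A-Za-z]", "",
                          paste(lines[(origin_i[[1]] + 1L):(end_i - 1L)],
                                collapse = "")))
  if (!nzchar(seq_chr))
    stop(sprintf("empty-input error: '%s' has no sequence", path), call. = FALSE)
  .checkAlphabet(seq_chr, where = sprintf("'%s'", path))

  feat_i <- grep("^FEATURES", lines)
  raw_feats <- list()
  if (length(feat_i)) {
    f0 <- feat_i[[1]] + 1L
    f1 <- origin_i[[1]] - 1L
    base_i <- grep("^(BASE COUNT|CONTIG)", lines)
    if (length(base_i) && any(base_i > f0 & base_i < f1))
      f1 <- min(base_i[base_i > f0]) - 1L
    raw_feats <- .gbParseFeatures(lines[f0:f1], offset = f0 - 1L)
  }

  keep <- vapply(raw_feats, function(f) !f$key %in% c("source", "gene"),
                 logical(1))
  raw_feats <- raw_feats[keep]
  n <- length(raw_feats)
  start <- end <- integer(n); strand <- locus_id <- kind <- trans <- character(n)
  for (k in seq_len(n)) {
    f <- raw_feats[[k]]
    loc <- .gbParseLocation(f$loc, f$line)
    start[k] <- loc$start; end[k] <- loc$end; strand[k] <- loc$strand
    kind[k] <- if (f$key %in% c("CDS", "tRNA")) f$key else "other"
    lt <- .gbQual(f$quals, "locus_tag")
    if (is.na(lt)) lt <- .gbQual(f$quals, "gene")
    if (is.na(lt)) lt <- sprintf("%s_%03d", f$key, k)
    locus_id[k] <- lt
    tr <- .gbQual(f$quals, "translation")
    trans[k] <- if (is.na(tr)) NA_character_ else gsub("[[:space:]]", "", tr)
  }

  gr <- GenomicRanges::GRanges(
    seqnames = id,
    ranges = IRanges::IRanges(start = if (n) start else integer(),
                              end = if (n) end else integer()),
    strand = if (n) strand else character()
  )
  mcols(gr)$locus_id <- if (n) locus_id else character()
  mcols(gr)$kind <- if (n) kind else character()
  mcols(gr)$translation <- if (n) trans else character()

  g <- new("PhageGenome", id = id, description = defn,
           sequence = Biostrings::DNAString(seq_chr),
           topology = topo, features = gr)

  # fill in missing CDS translations with the bacterial code (table 11)
  miss <- which(mcols(gr)$kind == "CDS" & is.na(mcols(gr)$translation))
  for (k in miss) {
    tr <- tryCatch(
      translateCds(g, featureAt(g, k)),
      error = function(e) {
        warning(sprintf("could not translate CDS '%s': %s",
                        mcols(gr)$locus_id[k], conditionMessage(e)),
                call. = FALSE)
        NA_character_
      })
    mcols(g@features)$translation[k] <- tr
  }
  validObject(g)
  g
}
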