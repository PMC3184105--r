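# Alignment inputs are accepted as a named character vector, a character
# matrix (rows = taxa), or an AAStringSet/AAMultipleAlignment; internally a
# taxa x sites character matrix.
.alnMatrix <- function(aln) {
  if (is(aln, "AAMultipleAlignment")) aln <- methods::as(aln, "AAStringSet")
  if (is(aln, "AAStringSet") || is(aln, "BStringSet")) {
    x <- stats::setNames(as.character(aln), names(aln))
  } else if (is.matrix(aln)) {
    return(aln)
  } else if (is.character(aln)) {
    x <- aln
  } else stop("unsupported alignment representation")
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("alignment rows must be named by taxon")
  if (length(unique(nchar(x))) != 1L)
    stop("alignment rows must all have equal length")
  do.call(rbind, lapply(stats::setNames(toupper(x), names(x)),
                        function(s) strsplit(s, "")[[1]]))
}

#' Read an aligned protein FASTA
#'
#' @param path Aligned FASTA path.
#' @return A named character vector of equal-length aligned rows.
#' @export
readProteinAlignment <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(unique(Biostrings::width(aa))) != 1L)
    stop(sprintf("'%s' is not an alignment: unequal row lengths", path))
  stats::setNames(as.character(aa), sub("[[:space:]].*$", "", names(aa)))
}

#' Poisson-corrected distances from a protein alignment
#'
#' For each pair of rows, the mismatch proportion `p` is computed over
#' comparable sites and corrected for multiple substitutions as
#' `d = -ln(1 - p)`. Sites containing a gap (`-`) or unknown (`X`, `?`, `.`,
#' `*`) are treated as unknown states: with `deletion = "pairwise"` (default)
#' they are excluded per pair; with `"complete"` any column containing one is
#' dropped for all pairs.
#'
#' @param aln Alignment (named character vector, matrix, or
#'   [Biostrings::AAStringSet]).
#' @param deletion `"pairwise"` (default) or `"complete"`.
#' @return A list of class `poisson_dist`: `d` (distance matrix), `p`
#'   (mismatch proportions), `n_sites` (comparable sites per pair), `taxa`.
#' @examples
#' aln <- c(t1 = "ACDE", t2 = "ACDE", t3 = "AADD")
#' poissonDist(aln)$d["t1", "t2"]  # 0
#' @export
poissonDist <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  m <- .alnMatrix(aln)
  if (nrow(m) < 2L) stop("at least two taxa are required")
  unknown <- m %in% c("-", "X", "?", ".", "*")
  dim(unknown) <- dim(m)
  if (deletion == "complete") {
    keep <- colSums(unknown) == 0L
    m <- m[, keep, drop = FALSE]
    unknown <- unknown[, keep, drop = FALSE]
  }
  n <- nrow(m)
  taxa <- rownames(m)
  d <- p <- matrix(0, n, n, dimnames = list(taxa, taxa))
  ns <- matrix(ncol(m), n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !unknown[i, ] & !unknown[j, ]
    n_ok <- sum(ok)
    if (n_ok == 0L)
      stop(sprintf("no comparable sites between '%s' and '%s'",
                   taxa[i], taxa[j]))
    pij <- sum(m[i, ok] != m[j, ok]) / n_ok
    if (pij >= 1)
      stop(sprintf("saturated pair '%s'/'%s': all comparable sites differ",
                   taxa[i], taxa[j]))
    p[i, j] <- p[j, i] <- pij
    d[i, j] <- d[j, i] <- -log(1 - pij)
    ns[i, j] <- ns[j, i] <- n_ok
  }
  structure(list(d = d, p = p, n_sites = ns, taxa = taxa),
            class = "poisson_dist")
}

.asDistMatrix <- function(d) {
  if (inherits(d, "poisson_dist")) d <- d$d
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("distances must be a square matrix, 'dist' or poisson_dist")
  if (is.null(rownames(d)))
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  if (any(d < 0)) stop("negative distances are not allowed")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration on the Q-criterion. Ties are broken
#' deterministically by taxon order. Negative branch lengths are clamped to
#' zero with the deficit transferred to the sibling branch, so all branch
#' lengths of the returned tree are non-negative.
#'
#' @param d A distance matrix, [stats::dist], or the result of
#'   [poissonDist()].
#' @return An unrooted [ape::phylo] tree with branch lengths.
#' @examples
#' d <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3,
#'             dimnames = list(c("a","b","c"), c("a","b","c")))
#' njTree(d)$edge.length  # 0.05 0.15 0.25
#' @export
njTree <- function(d) {
  d <- .asDistMatrix(d)
  n0 <- nrow(d)
  if (n0 < 3L) stop("at least three taxa are required")
  taxa <- rownames(d)

  # node bookkeeping: tips 1..n0, internal nodes numbered from n0+1 (ape
  # convention: root of the final unrooted tree is node n0+1)
  n_internal <- n0 - 2L
  next_internal <- n0 + n_internal      # allocate downward; relabel later
  active <- seq_len(n0)                 # node ids of active clusters
  D <- d
  edges <- list()

  clamp <- function(len1, len2) {
    # clamp-and-transfer: negative branch zeroed, deficit moved to sibling
    if (len1 < 0) { len2 <- max(len2 + len1, 0); len1 <- 0 }
    if (len2 < 0) { len1 <- max(len1 + len2, 0); len2 <- 0 }
    c(len1, len2)
  }

  node_ids <- active
  while (length(active) > 3L) {
    n <- length(active)
    rs <- rowSums(D)
    Q <- (n - 2) * D - outer(rs, rs, "+")
    diag(Q) <- Inf
    ij <- which(Q == min(Q), arr.ind = TRUE)
    ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE][1, ]   # deterministic
    i <- min(ij); j <- max(ij)
    li <- 0.5 * D[i, j] + (rs[i] - rs[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    ll <- clamp(li, lj)
    new_node <- next_internal; next_internal <- next_internal - 1L
    edges[[length(edges) + 1L]] <- c(new_node, node_ids[i], ll[1])
    edges[[length(edges) + 1L]] <- c(new_node, node_ids[j], ll[2])
    du <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    D <- D2
    node_ids <- c(node_ids[keep], new_node)
    active <- c(active[keep], new_node)
  }
  # final three clusters joined at one internal node
  dd <- D
  x <- 0.5 * (dd[1, 2] + dd[1, 3] - dd[2, 3])
  y <- 0.5 * (dd[1, 2] + dd[2, 3] - dd[1, 3])
  z <- 0.5 * (dd[1, 3] + dd[2, 3] - dd[1, 2])
  lens <- c(x, y, z)
  # clamp any negative terminal branch, transferring within the triple
  for (k in which(lens < 0)) {
    deficit <- lens[k]; lens[k] <- 0
    sib <- which.max(lens)
    lens[sib] <- max(lens[sib] + deficit, 0)
  }
  centre <- next_internal
  for (k in 1:3)
    edges[[length(edges) + 1L]] <- c(centre, node_ids[k], lens[k])
  stopifnot(centre == n0 + 1L)

  em <- do.call(rbind, edges)
  tree <- list(edge = cbind(as.integer(em[, 1]), as.integer(em[, 2])),
               edge.length = em[, 3],
               tip.label = taxa,
               Nnode = n_internal)
  class(tree) <- "phylo"
  tree <- ape::reorder.phylo(tree, "cladewise")
  tree
}

# Canonical representation of the non-trivial splits of an unrooted tree:
# for each internal edge, the sorted tip set on the side away from tip 1.
.treeSplits <- function(tree) {
  n_tip <- length(tree$tip.label)
  desc <- vector("list", n_tip + tree$Nnode)
  post <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(post$edge))) {
    par <- post$edge[k, 1]; ch <- post$edge[k, 2]
    desc[[par]] <- c(desc[[par]],
                     if (ch <= n_tip) ch else desc[[ch]])
  }
  splits <- character()
  for (k in seq_len(nrow(post$edge))) {
    ch <- post$edge[k, 2]
    if (ch <= n_tip) next
    side <- desc[[ch]]
    if (1L %in% side) side <- setdiff(seq_len(n_tip), side)
    if (length(side) < 2L || length(side) > n_tip - 2L) next
    splits <- c(splits,
                paste(sort(tree$tip.label[side]), collapse = "|"))
  }
  unique(splits)
}

#' Bootstrap supports for the neighbor-joining tree
#'
#' Resamples alignment columns with replacement `n_reps` times; each
#' pseudoreplicate is run through [poissonDist()] and [njTree()], and the
#' support of each internal split of the full-data tree is the percentage of
#' replicate trees containing that split. Replicates in which a pair
#' saturates (all comparable sites differ) are skipped with a warning and the
#' denominator adjusted.
#'
#' @inheritParams poissonDist
#' @param n_reps Number of pseudoreplicates (default 100).
#' @param seed Integer seed; results are reproducible given the seed.
#' @return The full-data [ape::phylo] tree with integer percent supports as
#'   `node.label` (NA for the root/basal node) and attributes
#'   `n_effective_reps` and `n_skipped`.
#' @export
bootstrapSupport <- function(aln, n_reps = 100L, seed = 1L,
                             deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  m <- .alnMatrix(aln)
  if (nrow(m) < 4L)
    warning("supports are only meaningful for four or more taxa")
  full <- njTree(poissonDist(m, deletion = deletion))
  target <- .treeSplits(full)
  counts <- stats::setNames(numeric(length(target)), target)
  n_ok <- 0L; n_skip <- 0L
  .withSeed(seed, {
    for (r in seq_len(n_reps)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      rep_tree <- tryCatch(
        njTree(poissonDist(m[, cols, drop = FALSE], deletion = deletion)),
        error = function(e) e)
      if (inherits(rep_tree, "error")) { n_skip <- n_skip + 1L; next }
      n_ok <- n_ok + 1L
      hit <- .treeSplits(rep_tree)
      counts[target %in% hit] <- counts[target %in% hit] + 1
    }
  })
  if (n_skip > 0L)
    warning(sprintf("%d of %d pseudoreplicates skipped (saturation); supports based on %d",
                    n_skip, n_reps, n_ok))
  support <- if (n_ok > 0L) round(100 * counts / n_ok) else
    stats::setNames(rep(NA_real_, length(target)), target)

  # attach supports as internal node labels of the full tree
  n_tip <- length(full$tip.label)
  node_lab <- rep(NA_character_, full$Nnode)
  post <- ape::reorder.phylo(full, "postorder")
  desc <- vector("list", n_tip + full$Nnode)
  for (k in seq_len(nrow(post$edge))) {
    par <- post$edge[k, 1]; ch <- post$edge[k, 2]
    desc[[par]] <- c(desc[[par]], if (ch <= n_tip) ch else desc[[ch]])
  }
  for (nd in (n_tip + 1L):(n_tip + full$Nnode)) {
    side <- desc[[nd]]
    if (is.null(side)) next
    if (1L %in% side) side <- setdiff(seq_len(n_tip), side)
    if (length(side) < 2L || length(side) > n_tip - 2L) next
    key <- paste(sort(full$tip.label[side]), collapse = "|")
    if (key %in% names(support))
      node_lab[nd - n_tip] <- as.character(support[[key]])
  }
  full$node.label <- node_lab
  attr(full, "n_effective_reps") <- n_ok
  attr(full, "n_skipped") <- n_skip
  full
}

#' Write a tree in Newick format
#'
#' Branch lengths and any integer supports (internal node labels) are kept.
#'
#' @param tree An [ape::phylo] tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
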