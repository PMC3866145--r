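## Distance-matrix neighbor-joining and monophyly checks; a light surface
## for the reciprocal-monophyly property of F and M clades.

validate_distance_matrix <- function(d) {
  d <- as.matrix(d)
  if (is.null(rownames(d))) rownames(d) <- colnames(d)
  if (is.null(rownames(d))) rownames(d) <- paste0("t", seq_len(nrow(d)))
  colnames(d) <- rownames(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (any(d < 0)) stop("negative distances")
  if (any(abs(d - t(d)) > 1e-8)) stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("diagonal must be zero")
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with deterministic tie-breaking (the
#' lowest-index pair, row-major, on equal Q). Negative branch lengths are
#' clamped to zero with a message. The result is an unrooted `ape::phylo`
#' tree.
#'
#' @param d Symmetric non-negative distance matrix with zero diagonal and
#'   at least 3 labelled taxa.
#' @return An `ape` `phylo` object.
#' @export
nj_tree <- function(d) {
  d <- validate_distance_matrix(d)
  n0 <- nrow(d)
  if (n0 < 3L) stop("need at least 3 taxa")
  clamped <- FALSE
  bl <- function(x) {
    if (x < 0) clamped <<- TRUE
    format(max(x, 0), digits = 12)
  }
  nodes <- rownames(d)              # newick fragment per active cluster
  while (nrow(d) > 3L) {
    m <- nrow(d)
    r <- rowSums(d)
    Q <- (m - 2) * d - outer(r, r, "+")
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[order(pmin(idx[, 1L], idx[, 2L]),
                     pmax(idx[, 1L], idx[, 2L])), , drop = FALSE]
    i <- min(idx[1L, ]); j <- max(idx[1L, ])
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    new_lab <- paste0("(", nodes[i], ":", bl(li), ",",
                      nodes[j], ":", bl(lj), ")")
    dn <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dn[keep]),
                c(dn[keep], 0))
    nodes <- c(nodes[keep], new_lab)
    rownames(d2) <- colnames(d2) <- c(rownames(d)[keep], new_lab)
    d <- d2
  }
  ## final three clusters joined at an unresolved root (unrooted tree)
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- paste0("(", nodes[1L], ":", bl(la), ",", nodes[2L], ":", bl(lb),
                ",", nodes[3L], ":", bl(lc), ");")
  if (clamped) message("negative branch length(s) clamped to 0")
  ape::read.tree(text = nwk)
}

#' Is a taxon subset monophyletic on an unrooted tree?
#'
#' True iff some edge of the tree bipartitions the leaves into the subset
#' versus its complement (single leaves and complements of single leaves
#' are trivially monophyletic).
#'
#' @param tree An `ape` `phylo` object.
#' @param taxa Character vector: non-empty proper subset of the tip labels.
#' @return Logical flag.
#' @export
is_monophyletic <- function(tree, taxa) {
  tips <- tree$tip.label
  unknown <- setdiff(taxa, tips)
  if (length(unknown)) stop("unknown taxa: ", paste(unknown, collapse = ", "))
  if (!length(taxa) || length(taxa) >= length(tips)) {
    stop("taxa must be a non-empty proper subset of the leaves")
  }
  if (length(taxa) == 1L || length(taxa) == length(tips) - 1L) return(TRUE)
  target <- sort(match(taxa, tips))
  pp <- ape::prop.part(tree)
  for (cl in pp) {
    s <- sort(cl)
    if (identical(s, target) ||
        identical(s, sort(setdiff(seq_along(tips), target)))) {
      return(TRUE)
    }
  }
  FALSE
}

#' Write / read a PHYLIP-style square distance matrix as TSV
#'
#' @param d Distance matrix.
#' @param path File path.
#' @return `read_distance_tsv` returns the matrix; the writer returns
#'   `path` invisibly.
#' @export
write_distance_tsv <- function(d, path) {
  d <- validate_distance_matrix(d)
  write.table(data.frame(taxon = rownames(d), d, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_tsv
#' @export
read_distance_tsv <- function(path) {
  tab <- read.delim(path, check.names = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab[[1L]]
  validate_distance_matrix(m)
}
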