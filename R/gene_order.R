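## Signed circular gene orders: extraction, adjacency sets, breakpoint
## distance, clade-diagnostic (synapomorphic) adjacencies.

#' Construct a signed circular gene order
#'
#' @param labels Character vector of gene labels around the circle.
#' @param signs Integer vector of +1/-1 strand signs.
#' @param id Genome identifier.
#' @param scope `"pcg-rrna"` or `"all"`.
#' @return Object of class `gene_order`.
#' @export
gene_order <- function(labels, signs = rep(1L, length(labels)), id = "order",
                       scope = "all") {
  stopifnot(length(labels) == length(signs))
  if (anyDuplicated(labels)) stop("gene labels must be unique")
  structure(list(id = id, labels = labels, signs = as.integer(signs),
                 scope = scope),
            class = "gene_order")
}

#' @export
print.gene_order <- function(x, ...) {
  cat(sprintf("<gene_order> %s (%s): %s\n", x$id, x$scope,
              order_string(x)))
  invisible(x)
}

#' Serialize a gene order as a signed label string
#'
#' @param order A `gene_order`.
#' @return Hyphen-joined string, `-` prefix marking heavy-strand genes.
#' @export
order_string <- function(order) {
  paste(ifelse(order$signs < 0L, paste0("-", order$labels), order$labels),
        collapse = "-")
}

## rotate so the anchor gene comes first
canonicalize_order <- function(labels, signs, anchor = "cox1") {
  i <- match(anchor, labels)
  if (is.na(i)) {
    i <- order(labels)[1L]
    message("anchor '", anchor, "' missing; canonicalizing at '",
            labels[i], "'")
  }
  idx <- ((i - 1L + seq_along(labels) - 1L) %% length(labels)) + 1L
  list(labels = labels[idx], signs = signs[idx])
}

#' Extract the signed circular gene order of a genome
#'
#' Genes are sorted by start position around the circle and the order is
#' canonicalized to start at `cox1` (falling back to the lexicographically
#' smallest label if absent). Scope `"pcg-rrna"` keeps the 13 typical
#' protein-coding genes plus the two rRNAs; `"all"` keeps every gene
#' feature (control region excluded).
#'
#' @param genome A `mito_genome`.
#' @param scope `"pcg-rrna"` (default) or `"all"`.
#' @return A [gene_order()].
#' @export
extract_order <- function(genome, scope = c("pcg-rrna", "all")) {
  scope <- match.arg(scope)
  f <- genome$features
  keep <- if (scope == "pcg-rrna") {
    f$label %in% c(TYPICAL_PCGS, "rrnS", "rrnL")
  } else {
    f$kind %in% c("PCG", "ORF", "rRNA", "tRNA")
  }
  f <- f[keep, , drop = FALSE]
  if (!nrow(f)) stop("no genes in scope '", scope, "' for ", genome$id)
  f <- f[order(f$start), , drop = FALSE]
  cn <- canonicalize_order(f$label, f$strand)
  gene_order(cn$labels, cn$signs, id = genome$id, scope = scope)
}

## canonical encoding of one signed circular adjacency: (a,sa) -> (b,sb) is
## the same adjacency as (b,-sb) -> (a,-sa); keep the lexicographically
## smaller encoding
encode_adjacency <- function(la, sa, lb, sb) {
  fwd <- paste0(ifelse(sa < 0, "-", "+"), la, "|",
                ifelse(sb < 0, "-", "+"), lb)
  rev <- paste0(ifelse(sb < 0, "+", "-"), lb, "|",
                ifelse(sa < 0, "+", "-"), la)
  ifelse(fwd <= rev, fwd, rev)
}

#' Signed adjacency set of a circular gene order
#'
#' @param order A [gene_order()].
#' @return Character vector of canonical adjacency encodings; its length
#'   equals the number of genes (circular order).
#' @export
adjacency_set <- function(order) {
  n <- length(order$labels)
  nxt <- c(2:n, 1L)
  encode_adjacency(order$labels, order$signs,
                   order$labels[nxt], order$signs[nxt])
}

#' Breakpoint distance between two gene orders
#'
#' Number of signed circular adjacencies of one order absent from the
#' other (symmetric for equal label sets).
#'
#' @param a,b [gene_order()] objects over the same label set.
#' @return Non-negative integer.
#' @export
breakpoint_distance <- function(a, b) {
  if (!setequal(a$labels, b$labels)) {
    only_a <- setdiff(a$labels, b$labels)
    only_b <- setdiff(b$labels, a$labels)
    stop("label sets differ; only in a: ",
         paste(only_a, collapse = ","), "; only in b: ",
         paste(only_b, collapse = ","))
  }
  length(setdiff(adjacency_set(a), adjacency_set(b)))
}

#' Clade-diagnostic (synapomorphic) adjacencies
#'
#' Adjacencies present in every gene order of the group and absent from
#' every order outside it.
#'
#' @param orders Named list of [gene_order()] objects.
#' @param group Character vector of identifiers (names of `orders`) forming
#'   the candidate clade.
#' @return Character vector of canonical adjacency encodings.
#' @export
synapomorphic_adjacencies <- function(orders, group) {
  nm <- names(orders)
  if (is.null(nm)) stop("orders must be a named list")
  if (!all(group %in% nm)) {
    stop("unknown group members: ",
         paste(setdiff(group, nm), collapse = ", "))
  }
  outside <- setdiff(nm, group)
  if (!length(group) || !length(outside)) {
    stop("group and its complement must both be non-empty")
  }
  in_sets <- lapply(orders[group], adjacency_set)
  out_sets <- lapply(orders[outside], adjacency_set)
  shared <- Reduce(intersect, in_sets)
  setdiff(shared, unique(unlist(out_sets)))
}

#' Apply a rearrangement to a gene order
#'
#' `inversion` reverses the segment `[from, to]` and flips its signs;
#' `transposition` moves the segment intact so that it follows position
#' `dest` (an index in the order *after* segment removal; 0 = front).
#'
#' @param order A [gene_order()].
#' @param op `"inversion"` or `"transposition"`.
#' @param from,to 1-based segment bounds (inclusive).
#' @param dest Destination index for transposition.
#' @return A [gene_order()].
#' @export
apply_rearrangement <- function(order, op = c("inversion", "transposition"),
                                from, to, dest = NULL) {
  op <- match.arg(op)
  n <- length(order$labels)
  if (from < 1L || to > n || from > to) stop("invalid segment [", from,
                                             ", ", to, "]")
  idx <- from:to
  if (op == "inversion") {
    labels <- order$labels; signs <- order$signs
    labels[idx] <- rev(labels[idx])
    signs[idx] <- -rev(signs[idx])
    return(gene_order(labels, signs, id = order$id, scope = order$scope))
  }
  if (is.null(dest)) stop("transposition needs dest")
  seg_l <- order$labels[idx]; seg_s <- order$signs[idx]
  rem_l <- order$labels[-idx]; rem_s <- order$signs[-idx]
  if (dest < 0L || dest > length(rem_l)) stop("dest out of range")
  labels <- append(rem_l, seg_l, after = dest)
  signs <- append(rem_s, seg_s, after = dest)
  gene_order(labels, signs, id = order$id, scope = order$scope)
}
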