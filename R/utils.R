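#' @importFrom stats sd setNames rnorm runif
#' @importFrom utils read.delim write.table head tail
NULL

DNA_ALPHABET <- c("A", "C", "G", "T")

## cache for genetic-code lookups (Biostrings tables, keyed by id)
.code_cache <- new.env(parent = emptyenv())

#' Genetic-code table
#'
#' Returns a named character vector mapping codons to one-letter amino acids
#' (stop = `"*"`). Defaults to the invertebrate mitochondrial code
#' (translation table 5), the code used throughout the package.
#'
#' @param code Genetic-code identifier understood by
#'   [Biostrings::getGeneticCode()] (e.g. `"5"`, `"1"`).
#' @return Named character vector of length 64.
#' @export
genetic_code <- function(code = "5") {
  key <- as.character(code)
  if (is.null(.code_cache[[key]])) {
    .code_cache[[key]] <- Biostrings::getGeneticCode(key)
  }
  .code_cache[[key]]
}

stop_codons <- function(code = "5") {
  gc <- genetic_code(code)
  names(gc)[gc == "*"]
}

#' Reverse complement of a nucleotide string
#'
#' @param x Single character string over the DNA alphabet (ambiguity codes
#'   allowed).
#' @return Reverse-complemented character string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

seq_chars <- function(x) strsplit(toupper(x), "", fixed = TRUE)[[1L]]

chars_to_codons <- function(ch) {
  n <- length(ch)
  if (n %% 3L != 0L) stop("sequence length not a multiple of 3")
  if (n == 0L) return(character(0))
  paste0(ch[seq(1L, n, 3L)], ch[seq(2L, n, 3L)], ch[seq(3L, n, 3L)])
}

split_codons <- function(x) chars_to_codons(seq_chars(x))

#' Translate an in-frame coding sequence
#'
#' The first codon is translated as methionine regardless of identity
#' (mitochondrial alternative initiation); internal stop codons raise an
#' error; a terminal stop is dropped when `drop_stop = TRUE`.
#'
#' @param cds In-frame nucleotide string (length a multiple of 3).
#' @param code Genetic-code id (default `"5"`).
#' @param drop_stop Drop a terminal stop codon from the peptide (default
#'   `TRUE`).
#' @return Single amino-acid string.
#' @export
translate_cds <- function(cds, code = "5", drop_stop = TRUE) {
  codons <- split_codons(cds)
  if (length(codons) == 0L) stop("empty CDS")
  gc <- genetic_code(code)
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  aa[1L] <- "M"
  n <- length(aa)
  if (drop_stop && aa[n] == "*") {
    aa <- aa[-n]
    n <- n - 1L
  }
  if (any(aa == "*")) {
    stop("internal stop codon at codon ", which(aa == "*")[1L])
  }
  paste(aa, collapse = "")
}

## deterministic integer sub-seed derivation, kept below 2^31
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 1013 * k) %% 2147483647)
}

## run expr with a local RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
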