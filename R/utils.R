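#' @import data.table
#' @importFrom stats median rnorm runif setNames
#' @importFrom utils head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Random DNA sequence
#'
#' @param n Length in base pairs.
#' @return A single character string of `n` uniformly drawn bases.
#' @keywords internal
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Extract a (possibly wrapping) substring from a circular sequence
#'
#' Coordinates are 0-based half-open; `start` is reduced modulo the sequence
#' length and the extracted window may wrap past the origin.
#'
#' @param seq Character scalar.
#' @param start 0-based start.
#' @param len Window length (must be <= nchar(seq) for circular extraction).
#' @param circular Wrap around the origin when TRUE.
#' @return Character scalar of length `len`.
#' @keywords internal
circ_substr <- function(seq, start, len, circular = TRUE) {
  L <- nchar(seq)
  stopifnot(len <= L)
  start <- ((start %% L) + L) %% L
  if (start + len <= L) {
    substr(seq, start + 1L, start + len)
  } else if (circular) {
    paste0(substr(seq, start + 1L, L), substr(seq, 1L, start + len - L))
  } else {
    stop("window [", start, ", ", start + len, ") exceeds a linear sequence of length ", L)
  }
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA path.
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  # keep only the id token, as aligners do
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Locate the minimap2 executable
#'
#' @return Path to minimap2.
#' @keywords internal
minimap2_path <- function() {
  p <- Sys.which("minimap2")
  if (!nzchar(p)) stop("minimap2 executable not found on PATH")
  unname(p)
}

# Oriented-coordinate helpers -------------------------------------------------
# All alignment coordinates are stored on each read's forward strand (PAF
# convention). These helpers flip an interval into the coordinate system of
# the reverse-complemented read.

flip_interval_start <- function(start, end, len) len - end
flip_interval_end <- function(start, end, len) len - start

# Oriented node naming for the layout graph: "<read_id>+" / "<read_id>-".
# Loop resolution may duplicate a node; duplicates carry a ".<k>" suffix on
# the read id part ("read_0001.2+"), which onode_read() strips.
onode <- function(read_id, orient) paste0(read_id, orient)
onode_read <- function(node) {
  sub("\\.[0-9]+$", "", substr(node, 1L, nchar(node) - 1L))
}
onode_orient <- function(node) substr(node, nchar(node), nchar(node))
onode_rc <- function(node) {
  o <- onode_orient(node)
  # keep any instance suffix: rc("x.2+") is "x.2-"
  paste0(substr(node, 1L, nchar(node) - 1L), ifelse(o == "+", "-", "+"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
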