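#' Read a FASTA file into a named character vector
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()]: any line wrapping is
#' accepted, sequences are uppercased, and names are truncated at the first
#' whitespace (the usual FASTA identifier convention).
#'
#' @param path FASTA file path
#' @return named character vector of uppercase sequences
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs named character vector
#' @param path output path
#' @param width line width
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' @keywords internal
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Round half-up to a fixed number of decimals
#'
#' Report percentages use commercial rounding (0.05 -> 0.1), not the IEEE
#' round-half-even of [round()].
#'
#' @param x numeric
#' @param digits decimals to keep
#' @return numeric
#' @export
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores (or removes) the global `.Random.seed` afterwards, so seeded
#' generators do not disturb the caller's RNG stream.
#'
#' @param seed integer seed, or NULL to leave the RNG alone
#' @param expr expression to evaluate
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
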