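#' Motif classes for microsatellite scanning
#'
#' SSR motifs are grouped by unit length into the six conventional classes.
#' `motif_class_names()` returns the class name for each unit length 1..6;
#' `default_thresholds()` returns the minimum repeat counts used for mining
#' high-repeat-number microsatellites (Mono 20, Di 8, Tri 8, Tetra 8,
#' Penta 6, Hexa 6).
#'
#' @return `motif_class_names()`: character vector of length 6.
#'   `default_thresholds()`: named integer vector (names are class names).
#' @export
motif_class_names <- function() {
  c("Mono", "Di", "Tri", "Tetra", "Penta", "Hexa")
}

#' @rdname motif_class_names
#' @export
default_thresholds <- function() {
  c(Mono = 20L, Di = 8L, Tri = 8L, Tetra = 8L, Penta = 6L, Hexa = 6L)
}

#' Unit length of a motif class
#' @param class_name one of Mono, Di, Tri, Tetra, Penta, Hexa
#' @return integer unit length 1..6
#' @export
class_unit_length <- function(class_name) {
  m <- match(class_name, motif_class_names())
  if (anyNA(m)) {
    stop("unknown motif class: ", paste(class_name[is.na(m)], collapse = ", "))
  }
  m
}

.check_alphabet <- function(motif, allow_n = FALSE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]+$"
  bad <- !grepl(pat, motif)
  if (any(bad)) {
    stop("invalid alphabet: expected uppercase ",
         if (allow_n) "ACGTN" else "ACGT",
         ", got ", paste(unique(motif[bad]), collapse = ", "))
  }
  invisible(motif)
}

#' Test whether a motif is primitive
#'
#' A motif is primitive when it is not itself a repetition of a shorter unit
#' (so "ATAT" is not a valid tetranucleotide motif: it is two copies of "AT").
#'
#' @param motif uppercase ACGT string
#' @return logical
#' @export
is_primitive_motif <- function(motif) {
  vapply(motif, function(m) {
    n <- nchar(m)
    if (n <= 1L) return(TRUE)
    for (d in seq_len(n - 1L)) {
      if (n %% d == 0L &&
          m == strrep(substr(m, 1L, d), n %/% d)) {
        return(FALSE)
      }
    }
    TRUE
  }, logical(1), USE.NAMES = FALSE)
}

.rotations <- function(motif) {
  n <- nchar(motif)
  vapply(seq_len(n), function(i) {
    paste0(substr(motif, i, n), substr(motif, 1L, i - 1L))
  }, character(1))
}

#' Canonical motif family
#'
#' Maps a repeat unit to its family: the lexicographically smallest cyclic
#' rotation of the motif on the same strand. Cyclic rotations such as AG and
#' GA are one family; reverse complements are *not* merged, so AG/GA and
#' CT/TC remain distinct families (families are strand-specific).
#'
#' @param motif character vector of uppercase ACGT motifs; each must be
#'   primitive (see [is_primitive_motif()]).
#' @return character vector of family strings.
#' @examples
#' canonical_family("GA")   # "AG"
#' canonical_family("TAA")  # "AAT"
#' @export
canonical_family <- function(motif) {
  if (length(motif) == 0L) return(character(0))
  .check_alphabet(motif)
  if (!all(is_primitive_motif(motif))) {
    stop("invalid motif: not primitive (a repetition of a shorter unit): ",
         paste(unique(motif[!is_primitive_motif(motif)]), collapse = ", "))
  }
  vapply(motif, function(m) min(.rotations(m)), character(1),
         USE.NAMES = FALSE)
}
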