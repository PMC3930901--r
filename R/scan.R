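#' Scanner configuration
#'
#' Holds the per-class minimum repeat counts, optional per-sequence
#' overrides, and the flanking length used when extracting fragments.
#' The default thresholds target high-repeat-number microsatellites
#' (Mono 20, Di 8, Tri 8, Tetra 8, Penta 6, Hexa 6). Overrides exist to
#' express exceptions such as a relaxed dinucleotide threshold on a single
#' chromosome, e.g. `overrides = list(Chr6 = c(Di = 5))`.
#'
#' @param thresholds named integer vector over the six motif classes
#' @param overrides named list: sequence id -> named vector class -> min
#'   repeats
#' @param flank_length bases of flank to keep on each side of a tract
#' @return an object of class `scan_config`
#' @export
scan_config <- function(thresholds = default_thresholds(),
                        overrides = list(),
                        flank_length = 200L) {
  full <- default_thresholds()
  if (!is.null(names(thresholds))) {
    bad <- setdiff(names(thresholds), names(full))
    if (length(bad)) stop("unknown motif class in thresholds: ",
                          paste(bad, collapse = ", "))
    full[names(thresholds)] <- thresholds
  } else if (length(thresholds) == 6L) {
    full[] <- thresholds
  } else {
    stop("thresholds must be named by motif class or have length 6")
  }
  if (any(full < 2L)) stop("all thresholds must be >= 2")
  for (ov in overrides) {
    if (is.null(names(ov)) || !all(names(ov) %in% names(full))) {
      stop("overrides must be named vectors class -> min_repeats")
    }
    if (any(ov < 2L)) stop("all thresholds must be >= 2")
  }
  if (flank_length < 0L) stop("flank_length must be >= 0")
  structure(list(thresholds = as.integer(full),
                 overrides = overrides,
                 flank_length = as.integer(flank_length)),
            class = "scan_config")
}

.effective_thresholds <- function(config, seq_id) {
  thr <- config$thresholds
  names(thr) <- motif_class_names()
  ov <- config$overrides[[seq_id]]
  if (!is.null(ov)) thr[names(ov)] <- as.integer(ov)
  thr
}

.empty_loci <- function() {
  data.frame(locus_id = character(0), seq_id = character(0),
             start = integer(0), end = integer(0),
             motif = character(0), family = character(0),
             class = character(0), repeat_count = integer(0),
             tract_length = integer(0), stringsAsFactors = FALSE)
}

#' Scan one sequence for perfect microsatellite tracts
#'
#' Finds all maximal perfect tandem runs of unit length 1-6 whose repeat
#' count meets the class threshold (after any per-sequence override). Runs
#' are assigned to the smallest unit length that generates them (a poly-A
#' run is Mono, never Di "AA"), reported on the forward strand with 1-based
#' inclusive coordinates, and never span an N. Where a maximal periodic
#' region admits several phases (e.g. ...ATATAT... read as AT or TA), the
#' leftmost phase defines the motif and the reported tract.
#'
#' @param seq_id sequence identifier
#' @param sequence uppercase ACGTN string (lowercase is accepted and
#'   uppercased)
#' @param config a [scan_config()]
#' @return data.frame with columns locus_id, seq_id, start, end, motif,
#'   family, class, repeat_count, tract_length, sorted by start.
#' @export
scan_sequence <- function(seq_id, sequence, config = scan_config()) {
  sequence <- toupper(sequence)
  if (!grepl("^[ACGTN]*$", sequence)) {
    stop("invalid alphabet in sequence '", seq_id, "': expected ACGTN")
  }
  n <- nchar(sequence)
  if (n == 0L) return(.empty_loci())
  x <- strsplit(sequence, "", fixed = TRUE)[[1]]
  ok <- x != "N"
  thr <- .effective_thresholds(config, seq_id)

  starts <- integer(0); units <- integer(0); counts <- integer(0)
  for (u in 1:6) {
    min_rep <- thr[[u]]
    if (n < u * 2L) next
    eq <- x[(u + 1L):n] == x[1:(n - u)] & ok[(u + 1L):n] & ok[1:(n - u)]
    r <- rle(eq)
    if (!any(r$values)) next
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    keep <- r$values & r$lengths >= u * (min_rep - 1L)
    for (i in which(keep)) {
      a <- run_start[i]; b <- run_end[i]
      len <- b - a + 1L + u          # length of the periodic region
      cnt <- len %/% u
      if (cnt < min_rep) next
      starts <- c(starts, a); units <- c(units, u); counts <- c(counts, cnt)
    }
  }
  if (!length(starts)) return(.empty_loci())

  motif <- substring(sequence, starts, starts + units - 1L)
  prim <- units == 1L | is_primitive_motif(motif)
  starts <- starts[prim]; units <- units[prim]
  counts <- counts[prim]; motif <- motif[prim]
  if (!length(starts)) return(.empty_loci())

  o <- order(starts, units)
  starts <- starts[o]; units <- units[o]; counts <- counts[o]; motif <- motif[o]
  tract_len <- units * counts
  df <- data.frame(
    locus_id = sprintf("%s_SSR%04d", seq_id, seq_along(starts)),
    seq_id = seq_id,
    start = starts,
    end = starts + tract_len - 1L,
    motif = motif,
    family = canonical_family(motif),
    class = motif_class_names()[units],
    repeat_count = counts,
    tract_length = tract_len,
    stringsAsFactors = FALSE
  )
  rownames(df) <- NULL
  df
}

#' Scan every sequence of a genome
#'
#' @param genome named character vector of sequences (see [read_fasta()])
#' @param config a [scan_config()]
#' @return data.frame of loci over all sequences (see [scan_sequence()])
#' @export
scan_genome <- function(genome, config = scan_config()) {
  if (is.null(names(genome)) || anyNA(names(genome))) {
    stop("genome sequences must be named")
  }
  out <- lapply(names(genome), function(sid) {
    scan_sequence(sid, genome[[sid]], config)
  })
  do.call(rbind, c(list(.empty_loci()), out))
}

#' Extract a tract with its flanking sequence
#'
#' Returns the fragment `[max(1, start - flank) .. min(len, end + flank)]`
#' together with absolute coordinates and how much each side was clipped at
#' a sequence boundary.
#'
#' @param locus one-row loci data.frame (or list) with seq_id, start, end
#' @param genome named character vector of sequences
#' @param flank_length bases on each side
#' @return list with seq_id, frag_start, frag_end, left_clip, right_clip,
#'   sequence, and the tract's 1-based position inside the fragment
#'   (tract_start, tract_end)
#' @export
extract_flanks <- function(locus, genome, flank_length = 200L) {
  sid <- locus$seq_id
  if (!sid %in% names(genome)) stop("missing sequence: ", sid)
  seq <- genome[[sid]]
  len <- nchar(seq)
  if (locus$start < 1L || locus$end > len) {
    stop("locus coordinates outside sequence ", sid)
  }
  fs <- max(1L, locus$start - flank_length)
  fe <- min(len, locus$end + flank_length)
  list(seq_id = sid, frag_start = fs, frag_end = fe,
       left_clip = flank_length - (locus$start - fs),
       right_clip = flank_length - (fe - locus$end),
       sequence = substr(seq, fs, fe),
       tract_start = locus$start - fs + 1L,
       tract_end = locus$end - fs + 1L)
}

#' Classify loci as coding or non-coding
#'
#' A locus is `coding` iff its tract overlaps any coding interval by at
#' least one base; with no intervals every locus is `non-coding`.
#'
#' @param loci loci data.frame
#' @param coding_intervals data.frame with seq_id, start, end (1-based
#'   inclusive), or NULL
#' @return the loci data.frame with an added `context` column
#' @export
classify_genomic_context <- function(loci, coding_intervals = NULL) {
  context <- rep("non-coding", nrow(loci))
  if (!is.null(coding_intervals) && nrow(coding_intervals) > 0L) {
    for (sid in unique(loci$seq_id)) {
      li <- which(loci$seq_id == sid)
      ci <- coding_intervals[coding_intervals$seq_id == sid, , drop = FALSE]
      if (!nrow(ci)) next
      q <- IRanges::IRanges(loci$start[li], loci$end[li])
      s <- IRanges::IRanges(ci$start, ci$end)
      hit <- IRanges::overlapsAny(q, s)
      context[li[hit]] <- "coding"
    }
  }
  loci$context <- context
  loci
}

#' Count loci by sequence and motif class
#'
#' @param loci loci data.frame
#' @return data.frame with one row per seq_id (sorted), one column per
#'   motif class, a Total column, and a final Total row
#' @export
summarize_by_class_and_chrom <- function(loci) {
  cls <- motif_class_names()
  sids <- sort(unique(loci$seq_id))
  tab <- matrix(0L, nrow = length(sids), ncol = length(cls),
                dimnames = list(sids, cls))
  if (nrow(loci)) {
    t0 <- table(factor(loci$seq_id, levels = sids),
                factor(loci$class, levels = cls))
    tab[] <- as.integer(t0)
  }
  df <- data.frame(seq_id = sids, tab, stringsAsFactors = FALSE,
                   row.names = NULL, check.names = FALSE)
  df$Total <- as.integer(rowSums(tab))
  total_row <- data.frame(seq_id = "Total",
                          as.list(colSums(df[cls])),
                          Total = sum(df$Total),
                          stringsAsFactors = FALSE, check.names = FALSE)
  rbind(df, total_row)
}

#' Write / read loci tables
#'
#' Tab-separated with header
#' `locus_id seq_id start end motif family class repeat_count tract_length`.
#'
#' @param loci loci data.frame
#' @param path file path
#' @export
write_loci <- function(loci, path) {
  cols <- c("locus_id", "seq_id", "start", "end", "motif", "family",
            "class", "repeat_count", "tract_length")
  .write_tsv(loci[, cols], path)
}

#' @rdname write_loci
#' @export
read_loci <- function(path) {
  df <- .read_tsv(path, colClasses = c(
    locus_id = "character", seq_id = "character", start = "integer",
    end = "integer", motif = "character", family = "character",
    class = "character", repeat_count = "integer",
    tract_length = "integer"))
  df
}

#' Write loci as GFF3
#'
#' Emits `microsatellite` features, 1-based inclusive, forward strand.
#'
#' @param loci loci data.frame
#' @param path file path
#' @export
write_loci_gff3 <- function(loci, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(loci)) {
    attrs <- sprintf("ID=%s;motif=%s;family=%s;repeat_count=%d",
                     loci$locus_id, loci$motif, loci$family,
                     loci$repeat_count)
    writeLines(paste(loci$seq_id, "ssrforge", "microsatellite",
                     loci$start, loci$end, ".", "+", ".", attrs,
                     sep = "\t"), con)
  }
  invisible(path)
}
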