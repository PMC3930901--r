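#' Anchor a locus's flanks in an alternate assembly
#'
#' Locates the `anchor_length` bases immediately left and right of the SSR
#' tract in an alternate assembly: exact match first, then the best match
#' with at most `max_mismatches` mismatches. Both anchors must be unique in
#' the assembly, land on the same sequence, and be in consistent order on
#' the forward strand; the interval between them is returned so the tract
#' can be re-measured. Ambiguous (multi-hit) or absent anchors give
#' `NULL` (the locus is unresolved).
#'
#' @param left,right flank sequences (the bases adjacent to the tract);
#'   each must be at least `anchor_length` long
#' @param alt named character vector of assembly sequences
#' @param max_mismatches mismatch budget for approximate matching
#' @param anchor_length bases of each flank used as anchor
#' @return NULL, or list(seq_id, start, end, sequence) for the inter-anchor
#'   interval (start > end means a zero-length interval: tract deleted)
#' @export
anchor_flanks <- function(left, right, alt, max_mismatches = 2L,
                          anchor_length = 50L) {
  if (nchar(left) < anchor_length || nchar(right) < anchor_length) {
    return(NULL)
  }
  la <- substr(left, nchar(left) - anchor_length + 1L, nchar(left))
  ra <- substr(right, 1L, anchor_length)
  lh <- .locate_unique(la, alt, max_mismatches)
  if (is.null(lh)) return(NULL)
  rh <- .locate_unique(ra, alt, max_mismatches)
  if (is.null(rh)) return(NULL)
  if (lh$seq_id != rh$seq_id || rh$start <= lh$end) return(NULL)
  list(seq_id = lh$seq_id, start = lh$end + 1L, end = rh$start - 1L,
       sequence = if (rh$start - 1L >= lh$end + 1L)
         substr(alt[[lh$seq_id]], lh$end + 1L, rh$start - 1L) else "")
}

# Unique best occurrence of `pattern` across all sequences of `store`:
# exact matches first; if none, matches at the smallest mismatch count
# <= max_mismatches. More than one occurrence at the chosen level -> NULL.
.locate_unique <- function(pattern, store, max_mismatches) {
  pat <- Biostrings::DNAString(pattern)
  found <- list()
  for (mm in 0:max_mismatches) {
    for (sid in names(store)) {
      m <- Biostrings::matchPattern(pat, Biostrings::DNAString(store[[sid]]),
                                    max.mismatch = mm, min.mismatch = mm)
      if (length(m)) {
        for (i in seq_along(m)) {
          found[[length(found) + 1L]] <- list(
            seq_id = sid, start = IRanges::start(m)[i],
            end = IRanges::end(m)[i])
        }
      }
    }
    if (length(found) == 1L) return(found[[1]])
    if (length(found) > 1L) return(NULL)   # ambiguous at best level
  }
  NULL
}

#' Measure the tract length of a family within an interval
#'
#' Returns the length in bases (unit length x repeat count) of the longest
#' maximal perfect run inside `interval_seq` whose unit belongs to
#' `family` (cyclic rotations on the same strand); 0 when no unit of the
#' family occurs.
#'
#' @param interval_seq sequence between the two anchors
#' @param family canonical family string (see [canonical_family()])
#' @return integer number of bases
#' @export
measure_alt_tract <- function(interval_seq, family) {
  interval_seq <- toupper(interval_seq)
  u <- nchar(family)
  n <- nchar(interval_seq)
  if (n < u) return(0L)
  rot <- .rotations(family)
  best <- 0L
  # maximal period-u regions, leftmost phase (same convention as the scan)
  x <- strsplit(interval_seq, "", fixed = TRUE)[[1]]
  ok <- x != "N"
  if (n >= 2L * u) {
    eq <- x[(u + 1L):n] == x[1:(n - u)] & ok[(u + 1L):n] & ok[1:(n - u)]
    r <- rle(eq)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    for (i in which(r$values)) {
      a <- run_start[i]
      len <- r$lengths[i] + u
      cnt <- len %/% u
      motif <- substr(interval_seq, a, a + u - 1L)
      if (motif %in% rot) best <- max(best, u * cnt)
    }
  }
  if (best == 0L) {
    # single unit occurrences (no periodic extension)
    for (m in rot) {
      if (grepl(m, interval_seq, fixed = TRUE)) return(u)
    }
  }
  as.integer(best)
}

#' Call the polymorphism status of one locus
#'
#' @param ref_len reference tract length in bases (> 0)
#' @param alt_lens named numeric vector/list of anchored alternate tract
#'   lengths (assemblies that failed to anchor are absent)
#' @param min_diff minimum absolute length difference, in bases, to call a
#'   polymorphism
#' @return list(status, deltas): status one of "polymorphic",
#'   "monomorphic", "unresolved"; deltas = named signed differences
#'   (alt - ref)
#' @export
call_polymorphism <- function(ref_len, alt_lens, min_diff = 1L) {
  stopifnot(ref_len > 0)
  alt_lens <- unlist(alt_lens)
  if (!length(alt_lens)) {
    return(list(status = "unresolved", deltas = numeric(0)))
  }
  deltas <- alt_lens - ref_len
  status <- if (any(abs(deltas) >= min_diff)) "polymorphic" else "monomorphic"
  list(status = status, deltas = deltas)
}

#' Compare loci between the reference and alternate assemblies
#'
#' For every locus, both flanks are anchored in each alternate assembly
#' ([anchor_flanks()]), the tract is re-measured in the inter-anchor
#' interval ([measure_alt_tract()]) and the status is called
#' ([call_polymorphism()]).
#'
#' @param loci loci data.frame (from [scan_genome()])
#' @param ref named character vector: reference genome
#' @param alts named list of named character vectors: alternate assemblies
#' @param flank_length flank taken around each tract
#' @param anchor_length,max_mismatches see [anchor_flanks()]
#' @param min_diff see [call_polymorphism()]
#' @return data.frame: locus_id, seq_id, family, class, ref_len, one
#'   `<name>_len` and `<name>_delta` column per assembly (NA when not
#'   anchored), status
#' @export
compare_loci <- function(loci, ref, alts, flank_length = 200L,
                         anchor_length = 50L, max_mismatches = 2L,
                         min_diff = 1L) {
  stopifnot(is.list(alts), !is.null(names(alts)))
  n <- nrow(loci)
  res <- data.frame(locus_id = loci$locus_id, seq_id = loci$seq_id,
                    family = loci$family, class = loci$class,
                    ref_len = loci$tract_length, stringsAsFactors = FALSE)
  lens <- matrix(NA_integer_, n, length(alts),
                 dimnames = list(NULL, names(alts)))
  for (i in seq_len(n)) {
    frag <- extract_flanks(loci[i, ], ref, flank_length)
    left <- substr(frag$sequence, 1L, frag$tract_start - 1L)
    right <- substr(frag$sequence, frag$tract_end + 1L,
                    nchar(frag$sequence))
    for (a in names(alts)) {
      iv <- anchor_flanks(left, right, alts[[a]], max_mismatches,
                          anchor_length)
      if (!is.null(iv)) {
        lens[i, a] <- measure_alt_tract(iv$sequence, loci$family[i])
      }
    }
  }
  status <- character(n)
  for (i in seq_len(n)) {
    cl <- call_polymorphism(res$ref_len[i],
                            lens[i, !is.na(lens[i, ]), drop = TRUE],
                            min_diff)
    status[i] <- cl$status
  }
  for (a in names(alts)) {
    res[[paste0(a, "_len")]] <- lens[, a]
    res[[paste0(a, "_delta")]] <- lens[, a] - res$ref_len
  }
  res$status <- status
  res
}

#' Summarize polymorphism rates
#'
#' Counts polymorphic loci per group (chromosome/sequence or motif class)
#' and per assembly, with percentages recomputed from the integer counts
#' in the same row and rounded half-up to one decimal. A 0-of-0 percentage
#' is emitted as NA (blank on write).
#'
#' @param comparisons data.frame from [compare_loci()]
#' @param group_by "seq_id" or "class"
#' @param min_diff minimum |delta| counted as polymorphic (match the value
#'   used in [compare_loci()])
#' @return data.frame with columns group, n_total, then per assembly
#'   `<name>_polymorphic` and `<name>_pct`; final Total row
#' @export
summarize_rates <- function(comparisons, group_by = c("seq_id", "class"),
                            min_diff = 1L) {
  group_by <- match.arg(group_by)
  if (!nrow(comparisons)) return(data.frame())
  assemblies <- sub("_len$", "",
                    grep("_len$", names(comparisons), value = TRUE))
  assemblies <- setdiff(assemblies, "ref")
  groups <- sort(unique(comparisons[[group_by]]))
  out <- data.frame(group = c(groups, "Total"), stringsAsFactors = FALSE)
  idx <- c(lapply(groups, function(g) comparisons[[group_by]] == g),
           list(rep(TRUE, nrow(comparisons))))
  out$n_total <- vapply(idx, sum, integer(1))
  for (a in assemblies) {
    delta <- comparisons[[paste0(a, "_delta")]]
    poly <- !is.na(delta) & abs(delta) >= min_diff
    np <- vapply(idx, function(ii) sum(poly & ii), integer(1))
    out[[paste0(a, "_polymorphic")]] <- np
    out[[paste0(a, "_pct")]] <- ifelse(
      out$n_total > 0, round_half_up(100 * np / out$n_total, 1), NA_real_)
  }
  out
}
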