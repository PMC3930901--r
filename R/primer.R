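#' Wallace-rule melting temperature
#'
#' Tm = 2 x (A + T) + 4 x (G + C) degrees Celsius. Chosen over
#' nearest-neighbor thermodynamics because it is exactly reproducible with
#' no parameter tables (a documented deviation from typical primer-design
#' software).
#'
#' @param seq character vector of ACGT sequences ("" gives 0)
#' @return numeric vector of temperatures
#' @export
wallace_tm <- function(seq) {
  bad <- !grepl("^[ACGT]*$", seq)
  if (any(bad)) stop("invalid base in primer sequence")
  at <- nchar(gsub("[GC]", "", seq))
  gc <- nchar(seq) - at
  2 * at + 4 * gc
}

#' GC fraction of a sequence
#' @param seq character vector of ACGT sequences
#' @return numeric in 0..1 (NaN for "")
#' @export
gc_fraction <- function(seq) {
  (nchar(seq) - nchar(gsub("[GC]", "", seq))) / nchar(seq)
}

.max_homopolymer <- function(seq) {
  vapply(strsplit(seq, "", fixed = TRUE), function(x) {
    if (!length(x)) return(0L)
    max(rle(x)$lengths)
  }, integer(1))
}

#' Primer-design constraints
#'
#' Defaults: primer length 18-24 nt, Wallace Tm 55-62 deg C, GC fraction
#' 0.40-0.60, Tm difference between the two primers at most 3 deg C,
#' product size 100-300 bp, homopolymer runs at most 4 nt. Only the
#' product range is dictated by the marker-genotyping platform (gel
#' resolution); the rest follow common primer-design practice.
#'
#' @param primer_len integer c(min, max)
#' @param tm_range numeric c(min, max) deg C
#' @param gc_range numeric c(min, max) fraction
#' @param max_tm_diff deg C
#' @param product_range integer c(min, max) bp
#' @param max_homopolymer nt
#' @return object of class `primer_constraints`
#' @export
primer_constraints <- function(primer_len = c(18L, 24L),
                               tm_range = c(55, 62),
                               gc_range = c(0.40, 0.60),
                               max_tm_diff = 3,
                               product_range = c(100L, 300L),
                               max_homopolymer = 4L) {
  for (r in list(primer_len, tm_range, gc_range, product_range)) {
    if (length(r) != 2L || r[1] > r[2]) stop("constraint range must be c(min, max)")
  }
  structure(list(primer_len = as.integer(primer_len), tm_range = tm_range,
                 gc_range = gc_range, max_tm_diff = max_tm_diff,
                 product_range = as.integer(product_range),
                 max_homopolymer = as.integer(max_homopolymer)),
            class = "primer_constraints")
}

# All single-primer candidates in [lo, hi] of fragment passing the
# per-primer constraints. Returns start, end, seq, tm.
.primer_candidates <- function(fragment, lo, hi, cons) {
  if (hi - lo + 1L < cons$primer_len[1]) {
    return(data.frame(start = integer(0), end = integer(0),
                      seq = character(0), tm = numeric(0)))
  }
  lens <- cons$primer_len[1]:cons$primer_len[2]
  grid <- expand.grid(start = lo:hi, len = lens)
  grid <- grid[grid$start + grid$len - 1L <= hi, , drop = FALSE]
  if (!nrow(grid)) {
    return(data.frame(start = integer(0), end = integer(0),
                      seq = character(0), tm = numeric(0)))
  }
  s <- substring(fragment, grid$start, grid$start + grid$len - 1L)
  tm <- wallace_tm(s)
  gc <- gc_fraction(s)
  keep <- tm >= cons$tm_range[1] & tm <= cons$tm_range[2] &
    gc >= cons$gc_range[1] & gc <= cons$gc_range[2] &
    .max_homopolymer(s) <= cons$max_homopolymer
  data.frame(start = grid$start[keep],
             end = grid$start[keep] + grid$len[keep] - 1L,
             seq = s[keep], tm = tm[keep], stringsAsFactors = FALSE)
}

#' Design the best primer pair for an SSR-containing fragment
#'
#' Enumerates every candidate (forward, reverse) primer window flanking the
#' tract that satisfies all constraints, scores each pair with
#' `penalty = |tm_f - 60| + |tm_r - 60| + |tm_f - tm_r| +
#' 0.01 x |product_size - 200|`, and returns the minimum-penalty pair.
#' Ties are broken by smaller forward start, then smaller product size, so
#' the result is deterministic. The reverse primer is reported 5'->3' on
#' the minus strand. Neither primer overlaps the tract and the product
#' always contains the full tract.
#'
#' @param fragment sequence containing the tract
#' @param tract_start,tract_end 1-based tract position within `fragment`
#' @param constraints a [primer_constraints()]
#' @return list of class `primer_pair` (forward, reverse, fwd_start,
#'   fwd_end, rev_start, rev_end, tm_f, tm_r, gc_f, gc_r, product_size,
#'   penalty), or an object of class `primer_fail` whose `$reason` names
#'   the failing constraint (test with [primer_failed()])
#' @export
design_pair <- function(fragment, tract_start, tract_end,
                        constraints = primer_constraints()) {
  cons <- constraints
  fragment <- toupper(fragment)
  n <- nchar(fragment)
  fail <- function(reason) structure(list(reason = reason),
                                     class = "primer_fail")
  if (n < cons$product_range[1]) return(fail("product-range"))
  if (tract_start - 1L < cons$primer_len[1] ||
      n - tract_end < cons$primer_len[1]) {
    return(fail("flank-too-short"))
  }
  fwd <- .primer_candidates(fragment, 1L, tract_start - 1L, cons)
  if (!nrow(fwd)) return(fail("no-forward-primer"))
  rev <- .primer_candidates(fragment, tract_end + 1L, n, cons)
  if (!nrow(rev)) return(fail("no-reverse-primer"))

  prod <- outer(fwd$start, rev$end, function(f, r) r - f + 1L)
  tmd <- abs(outer(fwd$tm, rev$tm, `-`))
  ok <- prod >= cons$product_range[1] & prod <= cons$product_range[2] &
    tmd <= cons$max_tm_diff
  if (!any(ok)) return(fail("no-compatible-pair"))
  pen <- abs(outer(fwd$tm - 60, rep(0, nrow(rev)), `+`)) +
    abs(outer(rep(0, nrow(fwd)), rev$tm - 60, `+`)) +
    tmd + 0.01 * abs(prod - 200)
  pen[!ok] <- Inf
  # minimum penalty; ties -> smaller forward start, then smaller product
  cand <- which(pen <= min(pen) + 1e-12, arr.ind = TRUE)
  fi <- cand[, 1]; ri <- cand[, 2]
  o <- order(fwd$start[fi], prod[cand], ri)
  fi <- fi[o[1]]; ri <- ri[o[1]]
  structure(class = "primer_pair", list(forward = fwd$seq[fi],
       reverse = revcomp(substr(fragment, rev$start[ri], rev$end[ri])),
       fwd_start = fwd$start[fi], fwd_end = fwd$end[fi],
       rev_start = rev$start[ri], rev_end = rev$end[ri],
       tm_f = fwd$tm[fi], tm_r = rev$tm[ri],
       gc_f = gc_fraction(fwd$seq[fi]), gc_r = gc_fraction(rev$seq[ri]),
       product_size = rev$end[ri] - fwd$start[fi] + 1L,
       penalty = pen[fi, ri]))
}

#' Did primer design fail?
#'
#' @param x result of [design_pair()]
#' @return TRUE when `x` is a `primer_fail` (its `$reason` says why)
#' @export
primer_failed <- function(x) inherits(x, "primer_fail")

#' Exact in-silico PCR on a fragment
#'
#' Finds every product produced by exact matches of the forward primer and
#' of the reverse complement of the reverse primer, with the forward match
#' upstream.
#'
#' @param fragment template sequence
#' @param forward,reverse primer sequences (reverse 5'->3' on minus strand)
#' @return data.frame of products: start, end, size
#' @export
in_silico_pcr <- function(fragment, forward, reverse) {
  fragment <- toupper(fragment)
  f_sites <- .all_occurrences(fragment, toupper(forward))
  r_seq <- revcomp(toupper(reverse))
  r_sites <- .all_occurrences(fragment, r_seq)
  out <- data.frame(start = integer(0), end = integer(0), size = integer(0))
  for (f in f_sites) {
    for (r in r_sites) {
      r_end <- r + nchar(r_seq) - 1L
      if (r >= f + nchar(forward)) {
        out <- rbind(out, data.frame(start = f, end = r_end,
                                     size = r_end - f + 1L))
      }
    }
  }
  out
}

.all_occurrences <- function(text, pattern) {
  res <- integer(0)
  from <- 1L
  repeat {
    p <- regexpr(pattern, substr(text, from, nchar(text)), fixed = TRUE)
    if (p < 0) break
    res <- c(res, from + p - 1L)
    from <- from + p
  }
  res
}

#' Design primers for a set of loci
#'
#' Runs [design_pair()] on the fragment of every locus and tallies designs
#' per sequence.
#'
#' @param loci loci data.frame
#' @param genome named character vector (reference)
#' @param constraints a [primer_constraints()]
#' @param flank_length flank taken around each tract
#' @return list with `primers` (data.frame locus_id, seq_id, fwd_seq,
#'   rev_seq, fwd_start, rev_start (fragment coordinates), tm_f, tm_r,
#'   product_size, penalty), `failed` (locus_id, reason), and `counts`
#'   (per-sequence designed counts with Total row)
#' @export
batch_design <- function(loci, genome, constraints = primer_constraints(),
                         flank_length = 200L) {
  rows <- list(); failed <- list()
  for (i in seq_len(nrow(loci))) {
    frag <- extract_flanks(loci[i, ], genome, flank_length)
    pp <- design_pair(frag$sequence, frag$tract_start, frag$tract_end,
                      constraints)
    if (primer_failed(pp)) {
      failed[[length(failed) + 1L]] <- data.frame(
        locus_id = loci$locus_id[i], reason = pp$reason,
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        locus_id = loci$locus_id[i], seq_id = loci$seq_id[i],
        fwd_seq = pp$forward, rev_seq = pp$reverse,
        fwd_start = pp$fwd_start, rev_start = pp$rev_start,
        tm_f = pp$tm_f, tm_r = pp$tm_r,
        product_size = pp$product_size, penalty = pp$penalty,
        stringsAsFactors = FALSE)
    }
  }
  primers <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus_id = character(0), seq_id = character(0),
               fwd_seq = character(0), rev_seq = character(0),
               fwd_start = integer(0), rev_start = integer(0),
               tm_f = numeric(0), tm_r = numeric(0),
               product_size = integer(0), penalty = numeric(0))
  counts <- if (nrow(primers)) {
    stats::aggregate(list(designed = primers$locus_id),
                     by = list(seq_id = primers$seq_id), FUN = length)
  } else {
    data.frame(seq_id = character(0), designed = integer(0))
  }
  counts <- rbind(counts, data.frame(seq_id = "Total",
                                     designed = nrow(primers)))
  list(primers = primers,
       failed = if (length(failed)) do.call(rbind, failed) else
         data.frame(locus_id = character(0), reason = character(0)),
       counts = counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
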