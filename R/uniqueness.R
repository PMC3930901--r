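#' Read a 12-column tabular alignment hit file
#'
#' Accepts the standard tab-separated hit table (query, subject, %identity,
#' length, mismatches, gapopens, qstart, qend, sstart, send, evalue,
#' bitscore). The bitscore column is taken as the alignment score and
#' %identity is converted to a fraction. Hits are grouped by query and each
#' group sorted by descending score, ties broken by subject id then subject
#' start.
#'
#' @param path file path
#' @return data.frame with columns query_id, subject_id, subject_start,
#'   subject_end, score, identity, ordered as described (class `hit_table`)
#' @export
read_hit_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(structure(data.frame(query_id = character(0),
                                subject_id = character(0),
                                subject_start = integer(0),
                                subject_end = integer(0),
                                score = numeric(0),
                                identity = numeric(0),
                                stringsAsFactors = FALSE),
                     class = c("hit_table", "data.frame")))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield < 12L)) {
    stop("parse error in hit table at line ",
         which(nfield < 12L)[1], ": expected >= 12 tab-separated columns")
  }
  m <- do.call(rbind, lapply(parts, `[`, 1:12))
  df <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    subject_start = as.integer(m[, 9]), subject_end = as.integer(m[, 10]),
    score = as.numeric(m[, 12]), identity = as.numeric(m[, 3]) / 100,
    stringsAsFactors = FALSE)
  if (anyNA(df$score) || anyNA(df$subject_start)) {
    bad <- which(is.na(df$score) | is.na(df$subject_start))[1]
    stop("parse error in hit table at line ", bad, ": non-numeric field")
  }
  df <- df[order(df$query_id, -df$score, df$subject_id, df$subject_start), ]
  rownames(df) <- NULL
  structure(df, class = c("hit_table", "data.frame"))
}

#' Desk-scale seed-and-extend search of a fragment against a genome
#'
#' A deliberately simple stand-in for a genome-wide aligner, used when no
#' external hit table is supplied: exact k-mer seeds, ungapped extension on
#' each seed diagonal, scoring match +1 / mismatch -1. For each diagonal
#' carrying at least one seed, the maximal-scoring ungapped interval is
#' reported when its score reaches `min_score`. A fragment copied verbatim
#' from the genome always produces its self-hit with score equal to the
#' fragment length.
#'
#' @param fragment query sequence (uppercase ACGT; length >= k)
#' @param genome named character vector of sequences
#' @param k seed length
#' @param min_score minimum reported score
#' @return data.frame of hits: subject_id, subject_start, subject_end,
#'   score, identity, sorted by descending score (ties: subject_id, start)
#' @export
naive_search <- function(fragment, genome, k = 15L, min_score = 30L) {
  fragment <- toupper(fragment)
  m <- nchar(fragment)
  if (m < k) stop("fragment too short: length ", m, " < k = ", k)
  fx <- strsplit(fragment, "", fixed = TRUE)[[1]]
  kmer_starts <- 1:(m - k + 1L)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(
    substring(fragment, kmer_starts, kmer_starts + k - 1L)))
  hits <- list()
  for (sid in names(genome)) {
    subj <- toupper(genome[[sid]])
    n <- nchar(subj)
    if (n < k) next
    mt <- Biostrings::matchPDict(pd, Biostrings::DNAString(subj))
    st <- IRanges::start(mt)      # list: per k-mer, genome start positions
    qpos <- rep(kmer_starts, lengths(st))
    spos <- unlist(st, use.names = FALSE)
    if (!length(spos)) next
    diags <- unique(spos - qpos)
    sx <- strsplit(subj, "", fixed = TRUE)[[1]]
    for (d in sort(diags)) {
      # overlap of fragment positions i with genome positions i + d
      i0 <- max(1L, 1L - d); i1 <- min(m, n - d)
      sc <- ifelse(fx[i0:i1] == sx[(i0 + d):(i1 + d)], 1L, -1L)
      best <- .max_subarray(sc)
      if (best$sum >= min_score) {
        a <- i0 + best$from - 1L; b <- i0 + best$to - 1L
        hits[[length(hits) + 1L]] <- data.frame(
          subject_id = sid, subject_start = a + d, subject_end = b + d,
          score = best$sum,
          identity = sum(sc[best$from:best$to] == 1L) / (best$to - best$from + 1L),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(subject_id = character(0), subject_start = integer(0),
                      subject_end = integer(0), score = numeric(0),
                      identity = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- unique(out)
  out <- out[order(-out$score, out$subject_id, out$subject_start), ]
  rownames(out) <- NULL
  out
}

# Kadane's maximum-scoring subarray; leftmost-longest on ties.
.max_subarray <- function(v) {
  best <- -Inf; best_from <- 1L; best_to <- 1L
  cur <- 0; cur_from <- 1L
  for (i in seq_along(v)) {
    if (cur <= 0) { cur <- 0; cur_from <- i }
    cur <- cur + v[i]
    if (cur > best) { best <- cur; best_from <- cur_from; best_to <- i }
  }
  list(sum = best, from = best_from, to = best_to)
}

#' Five-fold single-copy test
#'
#' A query is single copy when its top alignment score is at least
#' `fold` times its second-best score ("at least five fold higher"; the
#' boundary is inclusive). A single hit is single copy by definition.
#'
#' @param scores numeric vector sorted descending
#' @param fold ratio threshold (> 1)
#' @return logical
#' @export
single_copy_test <- function(scores, fold = 5) {
  if (!length(scores)) stop("no hits: single-copy status undefined")
  if (is.unsorted(rev(scores))) stop("scores must be sorted descending")
  if (fold <= 1) stop("fold must be > 1")
  if (length(scores) == 1L) return(TRUE)
  scores[1] >= fold * scores[2]
}

#' Retain single-copy loci
#'
#' Applies [single_copy_test()] per locus using either a pre-computed hit
#' table (query ids = locus ids) or the built-in [naive_search()] against a
#' genome. Loci with zero hits cannot be confirmed single-copy and are
#' removed (logged as `no-hit`).
#'
#' @param loci loci data.frame
#' @param hits a `hit_table` (from [read_hit_table()]), or NULL to search
#' @param genome named character vector (required when `hits` is NULL)
#' @param fold ratio threshold
#' @param flank_length flank used to build query fragments for the
#'   built-in search
#' @param ... further arguments to [naive_search()]
#' @return list with `retained` (loci subset) and `log` (data.frame
#'   locus_id, top_score, second_score, verdict)
#' @export
filter_single_copy <- function(loci, hits = NULL, genome = NULL, fold = 5,
                               flank_length = 200L, ...) {
  get_scores <- function(locus) {
    if (!is.null(hits)) {
      hits$score[hits$query_id == locus$locus_id]
    } else {
      frag <- extract_flanks(locus, genome, flank_length)
      naive_search(frag$sequence, genome, ...)$score
    }
  }
  n <- nrow(loci)
  top <- second <- rep(NA_real_, n)
  verdict <- character(n)
  for (i in seq_len(n)) {
    sc <- sort(get_scores(loci[i, ]), decreasing = TRUE)
    if (!length(sc)) {
      verdict[i] <- "no-hit"
    } else {
      top[i] <- sc[1]
      if (length(sc) > 1L) second[i] <- sc[2]
      verdict[i] <- if (single_copy_test(sc, fold)) "single-copy" else "multi-copy"
    }
  }
  list(retained = loci[verdict == "single-copy", , drop = FALSE],
       log = data.frame(locus_id = loci$locus_id, top_score = top,
                        second_score = second, verdict = verdict,
                        stringsAsFactors = FALSE))
}
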