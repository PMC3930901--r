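# Independent oracles and small fixture generators.
# These deliberately re-derive results by brute force, not via the package
# code paths they are used to check.

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# Brute-force SSR scan: tests every unit length at every position, extends
# the perfect run char by char, keeps leftmost-phase maximal runs meeting
# the thresholds with a primitive motif.
oracle_scan <- function(sequence, thresholds = c(20L, 8L, 8L, 8L, 6L, 6L)) {
  x <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  n <- length(x)
  acgt <- c("A", "C", "G", "T")
  out <- list()
  for (u in 1:6) {
    thr <- thresholds[u]
    p <- 1L
    while (p + u * 2L - 1L <= n) {
      unit <- x[p:(p + u - 1L)]
      if (all(unit %in% acgt)) {
        # leftmost phase: the periodicity must not extend one base left
        left_ext <- p > 1L && x[p - 1L] %in% acgt &&
          x[p - 1L] == x[p - 1L + u]
        if (!left_ext) {
          e <- p + u - 1L
          while (e + 1L <= n && x[e + 1L] %in% acgt &&
                 x[e + 1L] == x[e + 1L - u]) {
            e <- e + 1L
          }
          cnt <- (e - p + 1L) %/% u
          motif <- paste(unit, collapse = "")
          if (cnt >= thr && (u == 1L || oracle_primitive(motif))) {
            out[[length(out) + 1L]] <- data.frame(
              start = p, end = p + u * cnt - 1L, motif = motif,
              unit = u, repeat_count = cnt, stringsAsFactors = FALSE)
          }
        }
      }
      p <- p + 1L
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      motif = character(0), unit = integer(0),
                      repeat_count = integer(0)))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$start, df$unit), , drop = FALSE]
  rownames(df) <- NULL
  df
}

oracle_primitive <- function(m) {
  n <- nchar(m)
  for (d in seq_len(n - 1L)) {
    if (n %% d == 0L) {
      reps <- paste(rep(substr(m, 1, d), n / d), collapse = "")
      if (reps == m) return(FALSE)
    }
  }
  TRUE
}

# Smallest rotation by explicit enumeration.
oracle_family <- function(m) {
  n <- nchar(m)
  rots <- vapply(seq_len(n), function(i) {
    paste0(substring(m, i, n), substring(m, 1, i - 1))
  }, character(1))
  sort(rots)[1]
}

# Quadratic ungapped local alignment: best-scoring interval on every
# diagonal (match +1 / mismatch -1), no seeding.
oracle_local_hits <- function(fragment, subject, min_score = 30L) {
  fx <- strsplit(fragment, "", fixed = TRUE)[[1]]
  sx <- strsplit(subject, "", fixed = TRUE)[[1]]
  m <- length(fx); n <- length(sx)
  hits <- list()
  for (d in (1L - m):(n - 1L)) {
    i0 <- max(1L, 1L - d); i1 <- min(m, n - d)
    if (i1 < i0) next
    best <- -Inf; cur <- 0; cur_from <- i0; bf <- i0; bt <- i0
    for (i in i0:i1) {
      if (cur <= 0) { cur <- 0; cur_from <- i }
      cur <- cur + (if (fx[i] == sx[i + d]) 1L else -1L)
      if (cur > best) { best <- cur; bf <- cur_from; bt <- i }
    }
    if (best >= min_score) {
      hits[[length(hits) + 1L]] <- data.frame(
        subject_start = bf + d, subject_end = bt + d, score = best)
    }
  }
  if (!length(hits)) {
    return(data.frame(subject_start = integer(0),
                      subject_end = integer(0), score = numeric(0)))
  }
  df <- do.call(rbind, hits)
  df[order(-df$score, df$subject_start), , drop = FALSE]
}

# Exhaustive primer-pair enumeration with its own Tm/GC/homopolymer
# arithmetic and explicit best-pair bookkeeping.
oracle_design <- function(fragment, tract_start, tract_end,
                          len_range = c(18L, 24L), tm_range = c(55, 62),
                          gc_range = c(0.40, 0.60), max_tm_diff = 3,
                          product_range = c(100L, 300L), max_homo = 4L) {
  x <- strsplit(fragment, "", fixed = TRUE)[[1]]
  n <- length(x)
  primer_ok <- function(a, b) {
    s <- x[a:b]
    gc <- sum(s == "G" | s == "C")
    at <- length(s) - gc
    tm <- 2 * at + 4 * gc
    run <- 1L; mx <- 1L
    if (length(s) > 1L) {
      for (i in 2:length(s)) {
        run <- if (s[i] == s[i - 1L]) run + 1L else 1L
        mx <- max(mx, run)
      }
    }
    gcf <- gc / length(s)
    if (tm < tm_range[1] || tm > tm_range[2]) return(NULL)
    if (gcf < gc_range[1] || gcf > gc_range[2]) return(NULL)
    if (mx > max_homo) return(NULL)
    tm
  }
  # pass 1: evaluate every window once on each side of the tract
  enumerate <- function(lo, hi) {
    out <- list()
    for (a in lo:hi) {
      for (l in len_range[1]:len_range[2]) {
        b <- a + l - 1L
        if (b > hi) next
        tm <- primer_ok(a, b)
        if (!is.null(tm)) {
          out[[length(out) + 1L]] <- c(a = a, b = b, tm = tm)
        }
      }
    }
    out
  }
  if (tract_start < 2L || tract_end >= n) return(NULL)
  fwd <- enumerate(1L, tract_start - 1L)
  rev <- enumerate(tract_end + 1L, n)
  # pass 2: all pairs of surviving windows
  best <- NULL
  for (f in fwd) {
    for (r in rev) {
      prod <- r[["b"]] - f[["a"]] + 1L
      if (prod < product_range[1] || prod > product_range[2]) next
      if (abs(f[["tm"]] - r[["tm"]]) > max_tm_diff) next
      pen <- abs(f[["tm"]] - 60) + abs(r[["tm"]] - 60) +
        abs(f[["tm"]] - r[["tm"]]) + 0.01 * abs(prod - 200)
      cand <- list(fwd_start = f[["a"]], fwd_end = f[["b"]],
                   rev_start = r[["a"]], rev_end = r[["b"]],
                   tm_f = f[["tm"]], tm_r = r[["tm"]],
                   product_size = prod, penalty = pen)
      if (is.null(best) || pen < best$penalty - 1e-12 ||
          (abs(pen - best$penalty) <= 1e-12 &&
           (cand$fwd_start < best$fwd_start ||
            (cand$fwd_start == best$fwd_start &&
             prod < best$product_size)))) {
        best <- cand
      }
    }
  }
  best
}

# A 300 bp fragment: GC-balanced flanks around a central 20 bp AT tract,
# flanks re-drawn until they carry no qualifying repeat of their own.
make_primer_fragment <- function() {
  repeat {
    left <- rand_dna(140, gc = 0.5)
    right <- rand_dna(140, gc = 0.5)
    frag <- paste0(left, strrep("AT", 10), right)
    if (nrow(scan_sequence("f", frag)) == 1L) {
      return(list(fragment = frag, tract_start = 141L, tract_end = 160L))
    }
  }
}

# Random tree over n leaves with positive branch lengths: repeatedly join
# two random active nodes; yields an additive distance matrix via
# tree_distances().
random_tree <- function(n, seed) {
  set.seed(seed)
  labels <- paste0("t", seq_len(n))
  nodes <- lapply(labels, function(l) list(label = l, children = list()))
  while (length(nodes) > 3L) {
    ij <- sort(sample(length(nodes), 2))
    lens <- round(stats::runif(2, 0.05, 1), 6)
    merged <- list(label = NULL, children = list(
      list(node = nodes[[ij[1]]], length = lens[1]),
      list(node = nodes[[ij[2]]], length = lens[2])))
    nodes <- c(nodes[-ij], list(merged))
  }
  lens <- round(stats::runif(length(nodes), 0.05, 1), 6)
  list(label = NULL,
       children = Map(function(nd, l) list(node = nd, length = l),
                      nodes, lens))
}

# Default five-plant layout on a 10 kb sequence, mixed motif classes.
default_plants <- function(seq_id = "seq1") {
  rbind(plant_spec(seq_id, 1000L, "AT", 10L),
        plant_spec(seq_id, 2500L, "AAG", 9L),
        plant_spec(seq_id, 4000L, "AC", 12L),
        plant_spec(seq_id, 5500L, "AAAT", 8L),
        plant_spec(seq_id, 7000L, "AGATC", 7L))
}
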