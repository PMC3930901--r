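#' Build a physical map of markers
#'
#' Sorts markers by position within each sequence and computes the gap to
#' the previous marker in kilobases. The marker position is the SSR tract
#' start (stable under primer redesign). The global mean gap averages over
#' adjacent pairs within sequences only (never across sequence
#' boundaries) and is reported in Kb to one decimal. Duplicate
#' (sequence, position) markers are kept with gap 0.
#'
#' @param markers data.frame with marker, seq_id, position (1-based bp)
#' @return list with `map` (data.frame seq_id, position, marker, gap_kb;
#'   gap_kb is NA for the first marker of a sequence), `counts`
#'   (per-sequence marker counts with Total row) and `mean_gap_kb`
#' @export
build_map <- function(markers) {
  stopifnot(all(c("marker", "seq_id", "position") %in% names(markers)))
  o <- order(markers$seq_id, markers$position, markers$marker)
  m <- markers[o, , drop = FALSE]
  gap <- rep(NA_real_, nrow(m))
  if (nrow(m) > 1L) {
    same <- m$seq_id[-1] == m$seq_id[-nrow(m)]
    gap[-1][same] <- (m$position[-1][same] -
                        m$position[-nrow(m)][same]) / 1000
  }
  map <- data.frame(seq_id = m$seq_id, position = m$position,
                    marker = m$marker, gap_kb = gap,
                    stringsAsFactors = FALSE)
  rownames(map) <- NULL
  counts <- map_summary(map)
  gaps <- gap[!is.na(gap)]
  mean_gap <- if (length(gaps)) round_half_up(mean(gaps), 1) else NA_real_
  list(map = map, counts = counts, mean_gap_kb = mean_gap)
}

#' Per-sequence marker counts of a map
#'
#' @param entries map data.frame (from [build_map()]`$map`, or anything
#'   with a seq_id column)
#' @return data.frame seq_id, n_markers, with a Total row
#' @export
map_summary <- function(entries) {
  if (!nrow(entries)) {
    return(data.frame(seq_id = "Total", n_markers = 0L,
                      stringsAsFactors = FALSE))
  }
  tab <- table(entries$seq_id)
  df <- data.frame(seq_id = names(tab), n_markers = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(df$seq_id), , drop = FALSE]
  rownames(df) <- NULL
  rbind(df, data.frame(seq_id = "Total", n_markers = sum(df$n_markers)))
}
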