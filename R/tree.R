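#' Nei's (1983) DA genetic distance between two frequency profiles
#'
#' `DA = 1 - (1/L) * sum over loci of sum over alleles of sqrt(x_a * y_a)`
#' where x and y are the two populations' allele frequencies at each of L
#' shared loci. DA is 0 iff the profiles are identical at every locus and
#' 1 when the allele sets are disjoint at every locus. DA satisfies the
#' symmetry and identity axioms but is not guaranteed to be metric.
#'
#' @param freqs_x,freqs_y lists of named numeric vectors (one per locus,
#'   names = alleles, each summing to 1), in the same locus order
#' @return DA in [0, 1]
#' @export
nei_da <- function(freqs_x, freqs_y) {
  L <- length(freqs_x)
  if (L == 0L || L != length(freqs_y)) {
    stop("no shared loci (or unequal locus lists)")
  }
  acc <- 0
  for (l in seq_len(L)) {
    x <- freqs_x[[l]]; y <- freqs_y[[l]]
    shared <- intersect(names(x), names(y))
    if (length(shared)) acc <- acc + sum(sqrt(x[shared] * y[shared]))
  }
  1 - acc / L
}

.accession_profile <- function(call) {
  al <- .parse_call(call)
  if (!length(al)) return(NULL)
  tab <- table(as.character(al))
  v <- as.numeric(tab) / sum(tab)
  names(v) <- names(tab)
  v
}

#' Pairwise Nei DA distance matrix from a genotype matrix
#'
#' Each accession's per-locus frequency profile comes from its own call
#' (homozygote: frequency 1; heterozygote: 1/2 and 1/2). With
#' `deletion = "pairwise"` each pair uses the loci where both accessions
#' are non-missing; `"complete"` first drops any marker with a missing
#' call. A pair with zero shared loci is an error.
#'
#' @param gm a [genotype_matrix()]
#' @param deletion "pairwise" or "complete"
#' @return symmetric numeric matrix with zero diagonal, dimnames =
#'   accession ids
#' @export
distance_matrix <- function(gm, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  acc <- gm$accessions
  if (length(acc) < 2L) stop("need >= 2 accessions")
  calls <- gm$calls
  if (deletion == "complete") {
    keep <- apply(!is.na(calls), 1, all)
    calls <- calls[keep, , drop = FALSE]
  }
  n <- length(acc)
  d <- matrix(0, n, n, dimnames = list(acc, acc))
  if (!any(grepl("/", calls, fixed = TRUE), na.rm = TRUE)) {
    # homozygous-only fast path: per locus, sum over alleles of
    # sqrt(x_a y_a) is 1 when the two calls match and 0 otherwise
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        x <- calls[, i]; y <- calls[, j]
        both <- !is.na(x) & !is.na(y)
        if (!any(both)) {
          stop("no shared loci between ", acc[i], " and ", acc[j])
        }
        d[i, j] <- d[j, i] <- 1 - sum(x[both] == y[both]) / sum(both)
      }
    }
    return(d)
  }
  profiles <- lapply(acc, function(a) {
    lapply(calls[, a], .accession_profile)
  })
  names(profiles) <- acc
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- which(!vapply(profiles[[i]], is.null, logical(1)) &
                      !vapply(profiles[[j]], is.null, logical(1)))
      if (!length(shared)) {
        stop("no shared loci between ", acc[i], " and ", acc[j])
      }
      d[i, j] <- d[j, i] <- nei_da(profiles[[i]][shared],
                                   profiles[[j]][shared])
    }
  }
  d
}

.leaf <- function(label) list(label = label, children = list())
.join <- function(children, lengths) {
  list(label = NULL,
       children = Map(function(ch, len) list(node = ch, length = len),
                      children, lengths))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q-criterion
#' `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)`. Ties in Q are
#' broken by the smallest (i,j) index pair, negative branch lengths are
#' clamped to 0 (the deficit is not redistributed), and for n = 2 the
#' single edge is split equally, so the result is deterministic. The tree
#' is unrooted; it is stored with a trifurcating (n > 2) or bifurcating
#' (n = 2) top-level node.
#'
#' @param dm symmetric numeric matrix, zero diagonal, non-negative entries
#' @return tree object (nested lists; see [write_newick()])
#' @export
neighbor_joining <- function(dm) {
  if (!isSymmetric(unname(dm))) stop("distance matrix must be symmetric")
  if (any(dm < 0)) stop("distance matrix must be non-negative")
  if (is.null(rownames(dm))) stop("distance matrix must have dimnames")
  labels <- rownames(dm)
  n <- length(labels)
  if (n < 2L) stop("need >= 2 taxa")
  nodes <- lapply(labels, .leaf)
  d <- unname(dm)
  if (n == 2L) {
    return(.join(nodes, c(d[1, 2] / 2, d[1, 2] / 2)))
  }
  while (n > 3L) {
    rs <- rowSums(d)
    q <- (n - 2) * d - outer(rs, rs, `+`)
    diag(q) <- Inf
    # smallest Q; ties -> smallest (i, j), i < j
    best <- c(NA_integer_, NA_integer_); bq <- Inf
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (q[i, j] < bq - 1e-12) { bq <- q[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    li <- d[i, j] / 2 + (rs[i] - rs[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    li <- max(0, li); lj <- max(0, lj)
    new_node <- .join(list(nodes[[i]], nodes[[j]]), c(li, lj))
    others <- setdiff(seq_len(n), c(i, j))
    nd <- (d[i, others] + d[j, others] - d[i, j]) / 2
    nd <- pmax(0, nd)
    d2 <- rbind(cbind(d[others, others, drop = FALSE], nd), c(nd, 0))
    nodes <- c(nodes[others], list(new_node))
    d <- d2
    n <- n - 1L
  }
  # resolve the final three nodes with the three-point formulas
  l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  .join(nodes, pmax(0, c(l1, l2, l3)))
}

#' Leaf labels of a tree
#' @param tree tree object
#' @return character vector
#' @export
tree_leaves <- function(tree) {
  if (!is.null(tree$label)) return(tree$label)
  unlist(lapply(tree$children, function(ch) tree_leaves(ch$node)))
}

#' Pairwise leaf path lengths of a tree
#' @param tree tree object
#' @return symmetric matrix of path lengths between leaves
#' @export
tree_distances <- function(tree) {
  leaves <- tree_leaves(tree)
  depth <- function(node, acc) {
    if (!is.null(node$label)) {
      return(stats::setNames(acc, node$label))
    }
    unlist(lapply(node$children,
                  function(ch) depth(ch$node, acc + ch$length)))
  }
  n <- length(leaves)
  d <- matrix(0, n, n, dimnames = list(leaves, leaves))
  walk <- function(node) {
    if (!is.null(node$label)) return(invisible())
    sets <- lapply(node$children, function(ch) depth(ch$node, ch$length))
    if (length(sets) > 1L) {
      for (a in seq_len(length(sets) - 1L)) {
        for (b in (a + 1L):length(sets)) {
          for (x in names(sets[[a]])) {
            for (y in names(sets[[b]])) {
              d[x, y] <<- d[y, x] <<- sets[[a]][[x]] + sets[[b]][[y]]
            }
          }
        }
      }
    }
    for (ch in node$children) walk(ch$node)
    invisible()
  }
  walk(tree)
  d
}

#' Edge bipartitions of an unrooted tree
#'
#' One leaf set per internal edge (and per leaf edge), read from the
#' stored orientation. A group of leaves is monophyletic in the unrooted
#' tree iff it (or its complement) equals one of these sets.
#'
#' @param tree tree object
#' @return list of character vectors
#' @export
tree_bipartitions <- function(tree) {
  parts <- list()
  walk <- function(node) {
    if (!is.null(node$label)) return(node$label)
    below <- lapply(node$children, function(ch) walk(ch$node))
    for (b in below) parts[[length(parts) + 1L]] <<- b
    unlist(below)
  }
  walk(tree)
  parts
}

#' Is a group of leaves monophyletic in an unrooted tree?
#' @param tree tree object
#' @param group character vector of leaf labels
#' @return logical
#' @export
is_group_monophyletic <- function(tree, group) {
  leaves <- tree_leaves(tree)
  group <- sort(intersect(group, leaves))
  if (!length(group)) return(FALSE)
  comp <- sort(setdiff(leaves, group))
  if (!length(comp)) return(TRUE)
  for (p in tree_bipartitions(tree)) {
    sp <- sort(p)
    if (identical(sp, group) || identical(sp, comp)) return(TRUE)
  }
  FALSE
}

.quote_label <- function(label) {
  specials <- c(" ", "(", ")", "[", "]", ":", ";", ",", "'")
  if (any(strsplit(label, "", fixed = TRUE)[[1]] %in% specials)) {
    paste0("'", gsub("'", "''", label), "'")
  } else {
    label
  }
}

#' Write a tree as a Newick string
#'
#' Branch lengths with 6 decimals; labels containing Newick specials are
#' single-quoted; a trailing semicolon ends the string. The output
#' round-trips through [read_newick()].
#'
#' @param tree tree object
#' @param path optional file to write to
#' @return the Newick string (invisibly when `path` is given)
#' @export
write_newick <- function(tree, path = NULL) {
  fmt <- function(node) {
    if (!is.null(node$label)) return(.quote_label(node$label))
    inner <- vapply(node$children, function(ch) {
      sprintf("%s:%.6f", fmt(ch$node), ch$length)
    }, character(1))
    paste0("(", paste(inner, collapse = ","), ")")
  }
  s <- paste0(fmt(tree), ";")
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' Parse a Newick string into a tree object
#'
#' Supports the subset emitted by [write_newick()]: nested parentheses,
#' branch lengths after ':', single-quoted labels.
#'
#' @param s Newick string (or a file path containing one)
#' @return tree object
#' @export
read_newick <- function(s) {
  if (file.exists(s)) s <- paste(readLines(s), collapse = "")
  s <- trimws(s)
  if (!endsWith(s, ";")) stop("Newick string must end with ';'")
  chars <- strsplit(substr(s, 1, nchar(s) - 1L), "", fixed = TRUE)[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(chars)) chars[pos] else ""
  advance <- function() { ch <- chars[pos]; pos <<- pos + 1L; ch }
  read_label <- function() {
    if (peek() == "'") {
      advance()
      out <- character(0)
      repeat {
        ch <- advance()
        if (ch == "'") {
          if (peek() == "'") { out <- c(out, "'"); advance() }
          else break
        } else out <- c(out, ch)
      }
      paste(out, collapse = "")
    } else {
      out <- character(0)
      while (!peek() %in% c("", ",", ")", ":", "(")) out <- c(out, advance())
      paste(out, collapse = "")
    }
  }
  read_length <- function() {
    out <- character(0)
    while (grepl("[0-9.eE+-]", peek())) out <- c(out, advance())
    as.numeric(paste(out, collapse = ""))
  }
  read_node <- function() {
    if (peek() == "(") {
      advance()
      children <- list()
      repeat {
        child <- read_node()
        len <- 0
        if (peek() == ":") { advance(); len <- read_length() }
        children[[length(children) + 1L]] <- list(node = child, length = len)
        if (peek() == ",") { advance(); next }
        if (peek() == ")") { advance(); break }
        stop("malformed Newick string")
      }
      list(label = NULL, children = children)
    } else {
      .leaf(read_label())
    }
  }
  read_node()
}

#' Write a distance matrix as square TSV with header
#' @param dm matrix from [distance_matrix()]
#' @param path file path
#' @export
write_distance_matrix <- function(dm, path) {
  df <- data.frame(accession = rownames(dm), dm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
}
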