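#' Construct a genotype matrix of amplicon sizes
#'
#' A marker x accession table of allele calls. A call is one allele size in
#' bp ("120"), two sizes for a heterozygote ("120/124"), or missing (NA;
#' written as "-" in CSV). Accessions may carry group labels (landrace,
#' cultivar, species name, ...).
#'
#' @param calls character matrix (markers in rows, accessions in columns);
#'   NA = missing
#' @param markers,accessions row/column ids (defaults from dimnames)
#' @param groups character vector of group labels per accession, or NULL
#' @return object of class `genotype_matrix`
#' @export
genotype_matrix <- function(calls, markers = rownames(calls),
                            accessions = colnames(calls), groups = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "character"
  if (is.null(markers) || is.null(accessions)) {
    stop("markers and accessions must be named")
  }
  if (!is.null(groups) && length(groups) != length(accessions)) {
    stop("groups must label every accession")
  }
  ok <- is.na(calls) | grepl("^[0-9]+(/[0-9]+)?$", calls)
  if (!all(ok)) stop("bad call(s): ", paste(unique(calls[!ok]), collapse = ", "))
  dimnames(calls) <- list(markers, accessions)
  structure(list(calls = calls, markers = markers, accessions = accessions,
                 groups = groups), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$markers), "markers x",
      length(x$accessions), "accessions\n")
  if (!is.null(x$groups)) {
    cat("groups:", paste(names(table(x$groups)), table(x$groups),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read / write a genotype CSV
#'
#' Format: first column marker id; header row of accession ids; optional
#' second header row of group labels (first cell empty or "group"); cells
#' are an allele size, "size1/size2", or "-" for missing.
#'
#' @param path CSV path
#' @return a [genotype_matrix()]
#' @export
read_genotypes <- function(path) {
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  accessions <- as.character(raw[1, -1])
  groups <- NULL
  body_start <- 2L
  if (nrow(raw) >= 2L && (raw[2, 1] == "" || tolower(raw[2, 1]) == "group")) {
    groups <- as.character(raw[2, -1])
    body_start <- 3L
  }
  body <- raw[seq(body_start, nrow(raw)), , drop = FALSE]
  markers <- as.character(body[, 1])
  calls <- as.matrix(body[, -1, drop = FALSE])
  calls[calls == "-" | calls == ""] <- NA_character_
  genotype_matrix(calls, markers, accessions, groups)
}

#' @rdname read_genotypes
#' @param gm a [genotype_matrix()]
#' @export
write_genotypes <- function(gm, path) {
  calls <- gm$calls
  calls[is.na(calls)] <- "-"
  lines <- c(paste(c("marker", gm$accessions), collapse = ","))
  if (!is.null(gm$groups)) {
    lines <- c(lines, paste(c("group", gm$groups), collapse = ","))
  }
  lines <- c(lines, vapply(seq_along(gm$markers), function(i) {
    paste(c(gm$markers[i], calls[i, ]), collapse = ",")
  }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

.parse_call <- function(call) {
  if (is.na(call)) return(numeric(0))
  as.numeric(strsplit(call, "/", fixed = TRUE)[[1]])
}

#' Allele frequencies of one marker
#'
#' A homozygous call contributes weight 1 to its allele, a heterozygous
#' call weight 1/2 to each of its two alleles; frequencies are normalized
#' over non-missing accessions and always sum to 1.
#'
#' @param gm a [genotype_matrix()]
#' @param marker marker id
#' @param accessions optional subset of accession ids
#' @return named numeric vector (names = allele sizes), all > 0
#' @export
allele_freqs <- function(gm, marker, accessions = NULL) {
  row <- gm$calls[marker, , drop = TRUE]
  if (!is.null(accessions)) row <- row[accessions]
  w <- list()
  for (call in row[!is.na(row)]) {
    al <- .parse_call(call)
    for (a in al) {
      key <- as.character(a)
      w[[key]] <- (w[[key]] %||% 0) + 1 / length(al)
    }
  }
  if (!length(w)) stop("no data: all calls missing for marker ", marker)
  v <- unlist(w)
  v <- v[order(as.numeric(names(v)))]
  v / sum(v)
}

#' Polymorphism information content (PIC)
#'
#' Botstein's informativeness measure of a marker:
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`.
#' It is 0 for a monomorphic marker and approaches 1 for many equifrequent
#' alleles.
#'
#' @param p numeric vector of allele frequencies (positive, summing to 1
#'   within 1e-6)
#' @return PIC value in [0, 1)
#' @export
pic <- function(p) {
  if (abs(sum(p) - 1) > 1e-6) stop("allele frequencies must sum to 1")
  if (any(p <= 0)) stop("allele frequencies must be positive")
  p2 <- p^2
  1 - sum(p2) - (sum(p2)^2 - sum(p2^2))
}

#' Per-marker allele counts and PIC
#'
#' @param gm a [genotype_matrix()]
#' @return data.frame marker, n_alleles, pic (NA for all-missing markers)
#' @export
marker_stats <- function(gm) {
  res <- data.frame(marker = gm$markers, n_alleles = NA_integer_,
                    pic = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(gm$markers)) {
    f <- tryCatch(allele_freqs(gm, gm$markers[i]), error = function(e) NULL)
    if (!is.null(f)) {
      res$n_alleles[i] <- length(f)
      res$pic[i] <- pic(f)
    }
  }
  res
}

#' Distribution of allele counts across markers
#'
#' @param gm a [genotype_matrix()]
#' @return list(histogram = named integer vector over allele counts,
#'   median, range); the median is the lower median for an even number of
#'   markers
#' @export
allele_count_distribution <- function(gm) {
  ms <- marker_stats(gm)
  k <- ms$n_alleles[!is.na(ms$n_alleles)]
  if (!length(k)) {
    return(list(histogram = integer(0), median = NA_real_,
                range = c(NA_integer_, NA_integer_)))
  }
  ks <- sort(k)
  lower_median <- ks[ceiling(length(ks) / 2)]
  list(histogram = table(k), median = lower_median, range = range(k))
}

#' Marker transferability into an accession group
#'
#' The percentage of markers that amplify in the group, where a marker
#' amplifies iff at least one accession of the group has a non-missing
#' call. One decimal, rounded half-up.
#'
#' @param gm a [genotype_matrix()] with group labels
#' @param group group label
#' @return percentage (0-100)
#' @export
transferability <- function(gm, group) {
  if (is.null(gm$groups)) stop("genotype matrix has no group labels")
  sel <- gm$groups == group
  if (!any(sel)) stop("unknown group: ", group)
  if (!length(gm$markers)) return(NA_real_)
  amp <- apply(!is.na(gm$calls[, sel, drop = FALSE]), 1, any)
  round_half_up(100 * sum(amp) / length(amp), 1)
}
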