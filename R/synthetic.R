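#' Specify an SSR to plant in a synthetic genome
#'
#' @param seq_id target sequence id
#' @param position 1-based start of the tract
#' @param motif repeat unit (uppercase ACGT, primitive)
#' @param repeat_count number of perfect copies
#' @return one-row data.frame
#' @export
plant_spec <- function(seq_id, position, motif, repeat_count) {
  .check_alphabet(motif)
  if (!is_primitive_motif(motif)) stop("motif must be primitive")
  data.frame(seq_id = seq_id, position = as.integer(position),
             motif = motif, repeat_count = as.integer(repeat_count),
             stringsAsFactors = FALSE)
}

.random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random background with no tract passing `config` thresholds, enforced by
# re-sampling offending windows (rejection keeps planted truth exact).
.clean_background <- function(n, config) {
  seq <- .random_bases(n)
  for (iter in 1:50) {
    found <- scan_sequence("bg", seq, config)
    if (!nrow(found)) return(seq)
    for (i in seq_len(nrow(found))) {
      a <- found$start[i]; b <- found$end[i]
      seq <- paste0(substr(seq, 1, a - 1L), .random_bases(b - a + 1L),
                    substr(seq, b + 1L, n))
    }
  }
  stop("could not generate repeat-free background")
}

#' Generate a synthetic genome with planted SSRs
#'
#' Background sequence is uniform-random ACGT, re-sampled in windows until
#' no unplanted tract passes the scan thresholds, so the planted loci are
#' exactly the loci a scan should report. Planted tracts must not overlap
#' and are required to be at least 200 bp apart so that flanks stay
#' repeat-free and anchorable.
#'
#' @param n_seqs number of sequences (named seq1..seqN by default)
#' @param length length of each sequence in bp
#' @param plants data.frame of [plant_spec()] rows
#' @param seed RNG seed
#' @param config [scan_config()] defining "qualifying repeat" for the
#'   background cleaner
#' @param seq_names optional sequence names
#' @return list(genome = named character vector, truth = data.frame
#'   seq_id, start, end, motif, family, class, repeat_count, tract_length)
#' @export
generate_genome <- function(n_seqs, length, plants = NULL, seed = 1L,
                            config = scan_config(),
                            seq_names = paste0("seq", seq_len(n_seqs))) {
  with_seed(seed, {
    genome <- stats::setNames(vapply(seq_len(n_seqs), function(i) {
      .clean_background(length, config)
    }, character(1)), seq_names)
    truth <- .empty_loci()[, -1]    # no locus_id in truth
    if (!is.null(plants) && nrow(plants)) {
      if (!all(plants$seq_id %in% seq_names)) {
        stop("plant seq_id not in genome")
      }
      plants <- plants[order(plants$seq_id, plants$position), , drop = FALSE]
      for (sid in unique(plants$seq_id)) {
        ps <- plants[plants$seq_id == sid, , drop = FALSE]
        tract <- strrep(ps$motif, ps$repeat_count)
        tlen <- nchar(tract)
        ends <- ps$position + tlen - 1L
        if (any(ends > length) || any(ps$position < 1L)) {
          stop("infeasible placement: tract outside sequence")
        }
        if (nrow(ps) > 1L &&
            any(ps$position[-1] - ends[-nrow(ps)] - 1L < 200L)) {
          stop("infeasible placement: planted tracts closer than 200 bp")
        }
        s <- genome[[sid]]
        for (i in seq_len(nrow(ps))) {
          s <- paste0(substr(s, 1, ps$position[i] - 1L), tract[i],
                      substr(s, ends[i] + 1L, length))
        }
        # re-clean: planting may create chance extensions at junctions
        ivs <- cbind(ps$position, ends)
        for (iter in 1:50) {
          found <- scan_sequence(sid, s, config)
          extra <- !(found$start %in% ps$position &
                       found$end %in% ends &
                       found$motif %in% ps$motif)
          if (!any(extra)) break
          for (i in which(extra)) {
            a <- found$start[i]; b <- found$end[i]
            resamp <- setdiff(a:b, unlist(apply(ivs, 1, function(r) r[1]:r[2])))
            for (p in resamp) {
              substr(s, p, p) <- .random_bases(1L)
            }
          }
        }
        genome[[sid]] <- s
        truth <- rbind(truth, data.frame(
          seq_id = sid, start = ps$position, end = ends,
          motif = ps$motif, family = canonical_family(ps$motif),
          class = motif_class_names()[nchar(ps$motif)],
          repeat_count = ps$repeat_count, tract_length = tlen,
          stringsAsFactors = FALSE))
      }
    }
    truth <- truth[order(truth$seq_id, truth$start), , drop = FALSE]
    rownames(truth) <- NULL
    list(genome = genome, truth = truth)
  })
}

#' Derive an alternate genotype from a synthetic genome
#'
#' Emulates a diverged assembly of another accession: each planted tract
#' is expanded or contracted by a per-locus repeat-count delta, and flank
#' positions outside the tracts are substituted at `snp_rate` - but never
#' within `anchor_protect` bases of a tract unless `mutate_anchors` is
#' set (a stress mode that makes loci unresolvable on purpose).
#'
#' @param genome named character vector (from [generate_genome()])
#' @param truth truth data.frame (from [generate_genome()])
#' @param deltas integer vector of repeat-count changes, one per truth row
#'   (resulting repeat count must stay >= 1)
#' @param snp_rate per-base substitution probability outside tracts
#' @param seed RNG seed
#' @param anchor_protect bases adjacent to each tract kept SNP-free
#' @param mutate_anchors allow SNPs inside the protected windows
#' @return list(genome = alternate assembly, truth = data.frame with
#'   delta_units, alt_repeat_count, alt_tract_length per planted locus)
#' @export
derive_genotype <- function(genome, truth, deltas, snp_rate = 0.005,
                            seed = 1L, anchor_protect = 60L,
                            mutate_anchors = FALSE) {
  stopifnot(length(deltas) == nrow(truth))
  if (any(truth$repeat_count + deltas < 1L)) {
    stop("delta would reduce repeat count below 1")
  }
  with_seed(seed, {
    alt <- genome
    new_truth <- truth
    new_truth$delta_units <- as.integer(deltas)
    new_truth$alt_repeat_count <- truth$repeat_count + as.integer(deltas)
    new_truth$alt_tract_length <- new_truth$alt_repeat_count *
      nchar(truth$motif)
    for (sid in names(genome)) {
      rows <- which(truth$seq_id == sid)
      s <- genome[[sid]]
      n <- nchar(s)
      protect <- rep(FALSE, n)
      in_tract <- rep(FALSE, n)
      for (r in rows) {
        a <- truth$start[r]; b <- truth$end[r]
        in_tract[a:b] <- TRUE
        pa <- max(1L, a - anchor_protect)
        pb <- min(n, b + anchor_protect)
        protect[pa:pb] <- TRUE
      }
      mutable <- !in_tract & (mutate_anchors | !protect)
      if (snp_rate > 0) {
        hit <- which(mutable & stats::runif(n) < snp_rate)
        for (p in hit) {
          cur <- substr(s, p, p)
          substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
        }
      }
      # apply tract deltas right-to-left so coordinates stay valid
      for (r in rev(rows)) {
        a <- truth$start[r]; b <- truth$end[r]
        tract <- strrep(truth$motif[r], new_truth$alt_repeat_count[r])
        s <- paste0(substr(s, 1, a - 1L), tract,
                    substr(s, b + 1L, nchar(s)))
      }
      alt[[sid]] <- s
    }
    list(genome = alt, truth = new_truth)
  })
}

.rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- rep(1, length(alpha))
  g / sum(g)
}

#' Simulate a genotype matrix with group structure
#'
#' Emulates a marker panel genotyped on accessions from several diverged
#' groups (e.g. landraces, cultivars and wild relatives). Per marker: an
#' allele count k is drawn, a shared base frequency profile is drawn from
#' a symmetric Dirichlet, each group's profile mixes the base profile with
#' its own independent Dirichlet draw using weight `divergence` (0 =
#' identical groups, 1 = independent), accession calls are sampled from
#' their group's profile (homozygous, matching an inbreeding species),
#' and calls are masked at `missing_rate` (or a per-group rate).
#'
#' @param n_markers number of markers
#' @param groups named integer vector: group label -> number of accessions
#' @param divergence mixing weight in [0, 1]
#' @param allele_counts function(n) returning n allele counts, or integer
#'   vector to sample from; default draws 2 + Binomial(14, 0.36), matching
#'   an SSR panel with alleles 2..16 and median near 7
#' @param concentration Dirichlet concentration for frequency profiles
#' @param missing_rate scalar or named per-group missing probability
#' @param seed RNG seed
#' @param unit_size step between allele sizes in bp (SSR unit length)
#' @return list(gm = [genotype_matrix()], truth = list per marker:
#'   alleles, base_freqs, group_freqs)
#' @export
simulate_genotype_matrix <- function(n_markers,
                                     groups = c(landrace = 8L, cultivar = 10L,
                                                wild = 10L),
                                     divergence = 0.6,
                                     allele_counts = NULL,
                                     concentration = 1,
                                     missing_rate = 0,
                                     seed = 1L,
                                     unit_size = 2L) {
  stopifnot(all(groups >= 1L))
  with_seed(seed, {
    glabels <- rep(names(groups), groups)
    acc <- paste0(glabels, "_", unlist(lapply(groups, seq_len)))
    n_acc <- length(acc)
    if (is.null(allele_counts)) {
      k_draw <- function(n) 2L + stats::rbinom(n, 14L, 0.36)
    } else if (is.function(allele_counts)) {
      k_draw <- allele_counts
    } else {
      k_draw <- function(n) sample(as.integer(allele_counts), n,
                                   replace = TRUE)
    }
    if (length(missing_rate) == 1L && is.null(names(missing_rate))) {
      miss <- stats::setNames(rep(missing_rate, length(groups)),
                              names(groups))
    } else {
      miss <- missing_rate[names(groups)]
    }
    markers <- sprintf("M%03d", seq_len(n_markers))
    calls <- matrix(NA_character_, n_markers, n_acc,
                    dimnames = list(markers, acc))
    ks <- k_draw(n_markers)
    truth <- vector("list", n_markers)
    for (m in seq_len(n_markers)) {
      k <- max(2L, ks[m])
      sizes <- 100L + unit_size * sample.int(40L, k)
      base <- .rdirichlet(rep(concentration, k))
      gf <- lapply(names(groups), function(g) {
        own <- .rdirichlet(rep(concentration, k))
        p <- (1 - divergence) * base + divergence * own
        p / sum(p)
      })
      names(gf) <- names(groups)
      for (j in seq_len(n_acc)) {
        g <- glabels[j]
        if (stats::runif(1) < miss[[g]]) next
        calls[m, j] <- as.character(sample(sizes, 1L, prob = gf[[g]]))
      }
      truth[[m]] <- list(alleles = sizes, base_freqs = base,
                         group_freqs = gf)
    }
    names(truth) <- markers
    list(gm = genotype_matrix(calls, markers, acc, glabels), truth = truth)
  })
}
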