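empty_discrepancies <- function() {
  data.frame(ref_id = character(), position = integer(), type = character(),
             ref_allele = character(), alt_allele = character(),
             depth = integer(), alt_support = integer(),
             alt_fraction = numeric(), homopolymer_base = character(),
             homopolymer_length = integer(), region = character(),
             gene_ids = character(), stringsAsFactors = FALSE)
}

#' Left-normalize an indel
#'
#' Shifts an insertion or deletion to its leftmost equivalent placement:
#' while the reference base at the current anchor equals the last base of the
#' allele, the anchor moves left by one and the allele rotates. Applying the
#' allele at the pre- and post-normalization anchors yields identical
#' corrected sequences; the operation is idempotent. Substitutions are
#' returned unchanged.
#'
#' Insertions use the anchor convention "0-based index of the column the
#' insertion follows" (-1 denotes insertion before the first base); deletions
#' use the 0-based index of the first deleted base, and the stored
#' \code{ref_allele} must match the reference there (contract error
#' otherwise).
#'
#' @param discrepancy a list or one-row data.frame with fields
#'   \code{position, type, ref_allele, alt_allele}.
#' @param genome [genome_record()] or DNA string.
#' @return the discrepancy with normalized \code{position} and allele.
#' @export
normalize_indel <- function(discrepancy, genome) {
  d <- as.list(discrepancy)
  seqs <- if (inherits(genome, "GenomeRecord")) genome$sequence else genome
  if (d$type == "substitution") return(d)
  if (d$type == "insertion") {
    allele <- d$alt_allele
    n <- nchar(allele)
    if (n < 1L) stop("normalize_indel: empty insertion allele")
    a <- d$position
    while (a >= 0L && substr(seqs, a + 1L, a + 1L) == substr(allele, n, n)) {
      allele <- paste0(substr(allele, n, n), substr(allele, 1L, n - 1L))
      a <- a - 1L
    }
    d$position <- a
    d$alt_allele <- allele
    d$ref_allele <- ""
  } else if (d$type == "deletion") {
    len <- nchar(d$ref_allele)
    if (len < 1L) stop("normalize_indel: empty deletion allele")
    p <- d$position
    if (substr(seqs, p + 1L, p + len) != d$ref_allele)
      stop("normalize_indel: deletion allele '", d$ref_allele,
           "' inconsistent with reference at position ", p)
    while (p >= 1L &&
           substr(seqs, p, p) == substr(seqs, p + len, p + len)) p <- p - 1L
    d$position <- p
    d$ref_allele <- substr(seqs, p + 1L, p + len)
    d$alt_allele <- ""
  } else stop("normalize_indel: type must be insertion or deletion")
  d
}

#' Call consensus discrepancies from a pileup
#'
#' The audit targets assembly errors in a clonal isolate, so calls are
#' consensus-level: at most one call per site, requiring a majority allele
#' fraction. A substitution is called where a non-reference base reaches
#' \code{min_alt_fraction} of depth at depth \code{>= min_depth}; an
#' insertion where one inserted string (after left-normalization of each
#' observation) is carried by that fraction of junction-spanning reads; a
#' deletion likewise from the deletion counts, with adjacent deleted columns
#' merged. Ties at a site go to the highest fraction, then the
#' lexicographically smallest allele.
#'
#' @param pileup a [build_pileup()] result.
#' @param genome the reference [genome_record()].
#' @param min_depth minimum spanning depth (default 10).
#' @param min_alt_fraction minimum consensus allele fraction (default 0.8;
#'   values \code{<= 0.5} are rejected, consensus semantics require a
#'   majority).
#' @return discrepancy data.frame (positions 0-based, left-normalized;
#'   homopolymer/region columns are filled by [annotate_homopolymers()] and
#'   [annotate_regions()]).
#' @export
call_discrepancies <- function(pileup, genome, min_depth = 10L,
                               min_alt_fraction = 0.8) {
  stopifnot(inherits(pileup, "Pileup"), inherits(genome, "GenomeRecord"))
  if (min_alt_fraction <= 0.5)
    stop("call_discrepancies: min_alt_fraction must exceed 0.5")
  L <- genome$length
  refchars <- strsplit(genome$sequence, "")[[1]]
  ridx <- match(refchars, .ga_bases)  # NA at reference N
  depth <- pileup$depth
  cm <- pileup$counts
  rows <- list()
  # substitutions
  alt <- cm[1:4, , drop = FALSE]
  known <- which(!is.na(ridx))
  alt[cbind(ridx[known], known)] <- -1L
  topv <- pmax(alt[1, ], alt[2, ], alt[3, ], alt[4, ])
  cand <- which(depth >= min_depth & topv > 0 &
                topv / pmax(depth, 1L) >= min_alt_fraction & !is.na(ridx))
  if (length(cand)) {
    topb <- apply(alt[, cand, drop = FALSE], 2L, which.max)  # ties: first ~ lexicographic
    rows$sub <- data.frame(
      ref_id = pileup$ref_id, position = cand - 1L, type = "substitution",
      ref_allele = refchars[cand], alt_allele = .ga_bases[topb],
      depth = depth[cand], alt_support = topv[cand],
      alt_fraction = topv[cand] / depth[cand], stringsAsFactors = FALSE)
  }
  # deletions: merge contiguous columns above threshold
  dfrac <- pileup$del / pmax(depth, 1L)
  dcand <- depth >= min_depth & dfrac >= min_alt_fraction
  if (any(dcand)) {
    r <- rle(dcand)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    segs <- which(r$values)
    del_rows <- lapply(segs, function(s) {
      p0 <- starts[s] - 1L; p1 <- ends[s] - 1L
      d <- list(position = p0, type = "deletion",
                ref_allele = substr(genome$sequence, p0 + 1L, p1 + 1L),
                alt_allele = "")
      d <- normalize_indel(d, genome)
      sup <- min(pileup$del[(p0 + 1L):(p1 + 1L)])
      dep <- max(depth[(p0 + 1L):(p1 + 1L)])
      data.frame(ref_id = pileup$ref_id, position = d$position,
                 type = "deletion", ref_allele = d$ref_allele,
                 alt_allele = "", depth = dep, alt_support = sup,
                 alt_fraction = sup / dep, stringsAsFactors = FALSE)
    })
    rows$del <- do.call(rbind, del_rows)
  }
  # insertions: normalize every observation, aggregate, then threshold
  ins <- pileup$ins
  if (nrow(ins)) {
    norm <- lapply(seq_len(nrow(ins)), function(i) {
      d <- normalize_indel(list(position = ins$pos[i], type = "insertion",
                                ref_allele = "", alt_allele = ins$allele[i]),
                           genome)
      data.frame(pos = d$position, allele = d$alt_allele,
                 count = ins$count[i], stringsAsFactors = FALSE)
    })
    norm <- do.call(rbind, norm)
    agg <- stats::aggregate(count ~ pos + allele, norm, sum)
    span <- vapply(agg$pos, function(a) {
      i1 <- a + 1L; i2 <- a + 2L
      if (i1 < 1L) return(depth[1L])
      if (i2 > L) return(depth[i1])
      min(depth[i1], depth[i2])
    }, 0L)
    keep <- span >= min_depth & agg$count / pmax(span, 1L) >= min_alt_fraction
    if (any(keep)) {
      rows$ins <- data.frame(
        ref_id = pileup$ref_id, position = agg$pos[keep], type = "insertion",
        ref_allele = "", alt_allele = agg$allele[keep],
        depth = span[keep], alt_support = agg$count[keep],
        alt_fraction = agg$count[keep] / span[keep], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_discrepancies())
  out <- do.call(rbind, rows)
  # one call per site: highest fraction, then lexicographically smallest allele
  allele_key <- ifelse(out$type == "deletion", out$ref_allele, out$alt_allele)
  o <- order(out$position, -out$alt_fraction, allele_key)
  out <- out[o, , drop = FALSE]
  out <- out[!duplicated(out$position), , drop = FALSE]
  out <- out[order(out$position), , drop = FALSE]
  out$homopolymer_base <- NA_character_
  out$homopolymer_length <- NA_integer_
  out$region <- NA_character_
  out$gene_ids <- NA_character_
  rownames(out) <- NULL
  out
}

#' Screen for large INDELs
#'
#' Flags (a) stretches of at least \code{min_len} bp whose depth falls below
#' \code{depth_factor} times the genome-wide median depth (candidate deletion
#' in the sequenced sample, i.e. sequence present in the reference only) and
#' (b) columns where at least \code{clip_frac} of spanning reads are
#' soft-clipped (candidate insertion in the sample: reads crossing a junction
#' absent from the reference clip there). Returns an empty table when
#' coverage is uniform and clip-free.
#'
#' @param pileup a [build_pileup()] result (built from clip-aware alignments
#'   for the insertion screen, see [mapper_params()] \code{allow_clip}).
#' @param min_len minimum low-depth stretch (default 100 bp).
#' @param depth_factor low-depth threshold as a fraction of the median.
#' @param clip_frac minimum soft-clip fraction.
#' @param min_clip minimum absolute clipped reads at a column.
#' @return data.frame with \code{type} (\code{deletion_in_sample} /
#'   \code{insertion_in_sample}), \code{start}, \code{end} (0-based
#'   half-open), \code{stat}.
#' @export
screen_large_indels <- function(pileup, min_len = 100L, depth_factor = 0.1,
                                clip_frac = 0.5, min_clip = 3L) {
  stopifnot(inherits(pileup, "Pileup"))
  out <- list()
  med <- median(pileup$depth)
  low <- pileup$depth < depth_factor * med
  if (any(low) && med > 0) {
    r <- rle(low)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    seg <- which(r$values & r$lengths >= min_len)
    if (length(seg))
      out$del <- data.frame(type = "deletion_in_sample",
                            start = starts[seg] - 1L, end = ends[seg],
                            stat = vapply(seg, function(s) mean(
                              pileup$depth[starts[s]:ends[s]]), 0),
                            stringsAsFactors = FALSE)
  }
  # pool clips over adjacent columns: the two flanks of an inserted segment
  # collapse onto neighbouring reference columns
  cl <- pileup$clip
  cw <- cl + c(0L, cl[-length(cl)]) + c(cl[-1L], 0L)
  cf <- cw / pmax(pileup$depth, 1L)
  hot <- which(cf >= clip_frac & cw >= min_clip)
  if (length(hot)) {
    grp <- cumsum(c(1L, diff(hot) > 10L))
    cl <- lapply(split(hot, grp), function(h)
      data.frame(type = "insertion_in_sample", start = min(h) - 1L,
                 end = max(h), stat = max(cf[h]), stringsAsFactors = FALSE))
    out$ins <- do.call(rbind, cl)
  }
  if (!length(out))
    return(data.frame(type = character(), start = integer(), end = integer(),
                      stat = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
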