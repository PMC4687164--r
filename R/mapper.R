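#' Build a k-mer index over one or more genomes
#'
#' All overlapping k-mers free of \code{N} are indexed; circular genomes also
#' index the k-mers spanning the origin. Positions are stored in a single
#' concatenated coordinate space with per-genome offsets, hashed in an
#' environment for O(1) lookup.
#'
#' @param genomes a [genome_record()] or list of them.
#' @param k k-mer size (default 15; at least 11 is recommended so seeds are
#'   near-unique in megabase genomes).
#' @return a \code{KmerIndex} list.
#' @export
build_index <- function(genomes, k = 15L) {
  if (inherits(genomes, "GenomeRecord")) genomes <- list(genomes)
  k <- as.integer(k)
  if (k < 1L) stop("build_index: k must be >= 1")
  lens <- vapply(genomes, `[[`, 0L, "length")
  if (k > min(lens)) stop("build_index: k exceeds shortest genome length")
  offsets <- c(0L, cumsum(lens))[seq_along(genomes)]
  allk <- character(0); allp <- integer(0)
  for (i in seq_along(genomes)) {
    g <- genomes[[i]]
    s <- g$sequence
    if (g$circular) s <- paste0(s, substr(g$sequence, 1L, k - 1L))
    nk <- nchar(s) - k + 1L
    kms <- substring(s, seq_len(nk), seq_len(nk) + k - 1L)
    keep <- !grepl("N", kms, fixed = TRUE)
    if (!any(keep)) {
      warning("build_index: genome '", g$id, "' contributed no k-mers (all N?)")
      next
    }
    allk <- c(allk, kms[keep])
    allp <- c(allp, offsets[i] + which(keep) - 1L)
  }
  env <- list2env(split(allp, allk), hash = TRUE, size = length(allp))
  structure(list(k = k, ids = vapply(genomes, `[[`, "", "id"),
                 seqs = vapply(genomes, `[[`, "", "sequence"),
                 lengths = lens, offsets = offsets,
                 circular = vapply(genomes, `[[`, TRUE, "circular"),
                 env = env),
            class = "KmerIndex")
}

#' Look up a k-mer in the index
#'
#' @param index a [build_index()] result.
#' @param kmer a k-length DNA string.
#' @return data.frame of \code{genome_id}, 0-based \code{position} (sorted),
#'   empty when absent.
#' @export
index_lookup <- function(index, kmer) {
  p <- index$env[[kmer]]
  if (is.null(p)) return(data.frame(genome_id = character(),
                                    position = integer(),
                                    stringsAsFactors = FALSE))
  gi <- findInterval(p, c(index$offsets, sum(index$lengths)))
  pos <- p - index$offsets[gi]
  # origin-spanning k-mers of circular genomes report their true start
  pos <- ifelse(index$circular[gi] & pos >= index$lengths[gi],
                pos - index$lengths[gi], pos)
  o <- order(gi, pos)
  data.frame(genome_id = index$ids[gi][o], position = as.integer(pos[o]),
             stringsAsFactors = FALSE)
}

#' Mapper parameters
#'
#' @param band half-width of the alignment window padding around the seeded
#'   locus (bp); bounds how far an alignment may drift off the seeded
#'   diagonal.
#' @param max_edit_frac alignments with edit distance above
#'   \code{ceiling(max_edit_frac * read length)} are reported unmapped.
#' @param discard_multi discard reads whose best score is tied at distinct
#'   loci (repeats), keeping false alleles out of the pileup.
#' @param allow_clip attempt a soft-clipped rescue alignment when the
#'   end-to-end alignment fails (used by the large-INDEL screen).
#' @param max_clusters number of top-voted seed clusters to align per strand.
#' @return list of parameters.
#' @export
mapper_params <- function(band = 16L, max_edit_frac = 0.1,
                          discard_multi = TRUE, allow_clip = FALSE,
                          max_clusters = 3L) {
  list(band = as.integer(band), max_edit_frac = max_edit_frac,
       discard_multi = isTRUE(discard_multi), allow_clip = isTRUE(allow_clip),
       max_clusters = as.integer(max_clusters))
}

rev_str <- function(s) vapply(strsplit(s, ""), function(x)
  paste(rev(x), collapse = ""), "")

# fast scalar reverse complement (hot path; no S4 dispatch)
rc1 <- function(s) rawToChar(rev(charToRaw(chartr("ACGTN", "TGCAN", s))))

rev_cigar <- function(cigar) {
  p <- parse_cigar(cigar)
  paste0(rev(p$len), rev(p$op), collapse = "")
}

# seed clusters for one oriented read sequence: candidate 0-based start
# positions in the concatenated coordinate space, with vote counts
seed_clusters <- function(seq, index, band) {
  k <- index$k
  rl <- nchar(seq)
  offs <- unique(c(seq.int(1L, rl - k + 1L, by = k), rl - k + 1L))
  kms <- substring(seq, offs, offs + k - 1L)
  hits <- mget(kms, envir = index$env, ifnotfound = list(NULL))
  nh <- lengths(hits)
  use <- nh > 0L & nh <= 50L
  if (!any(use)) return(NULL)
  cand <- sort(unlist(hits[use], use.names = FALSE) -
               rep.int(offs[use] - 1L, nh[use]))
  b <- which(diff(cand) > band)
  i0 <- c(1L, b + 1L); i1 <- c(b, length(cand))
  reps <- cand[(i0 + i1) %/% 2L]
  votes <- i1 - i0 + 1L
  o <- order(-votes, reps)
  list(rep = reps[o], votes = votes[o], n = length(o))
}

align_candidate <- function(seq, index, gi, s0, params) {
  L <- index$lengths[gi]
  gseq <- index$seqs[gi]
  rl <- nchar(seq)
  pad <- params$band
  max_edit <- as.integer(ceiling(params$max_edit_frac * rl))
  # exact fast path
  if (s0 >= 0L && s0 + rl <= L &&
      substr(gseq, s0 + 1L, s0 + rl) == seq)
    return(list(ref_start = s0, cigar = paste0(rl, "M"), edit = 0L))
  ws <- s0 - pad; we <- s0 + rl + pad
  if (index$circular[gi]) {
    ws_m <- ((ws %% L) + L) %% L
    dbl <- paste0(gseq, gseq)
    window <- substr(dbl, ws_m + 1L, ws_m + (we - ws))
    base0 <- ws_m
  } else {
    ws <- max(0L, ws); we <- min(L, we)
    window <- substr(gseq, ws + 1L, we)
    base0 <- ws
  }
  if (nchar(window) < 1L) return(NULL)
  fit <- fit_align_cpp(window, seq, max_edit = max_edit,
                       allow_suffix_clip = params$allow_clip)
  res <- NULL
  if (!is.na(fit$cigar) && (fit$clipped > 0 || fit$edit <= max_edit))
    res <- list(ref_start = base0 + fit$start, cigar = fit$cigar,
                edit = fit$edit)
  if (is.null(res) && params$allow_clip) {
    # prefix-clip rescue: align the reversed read against the reversed window
    rfit <- fit_align_cpp(rev_str(window), rev_str(seq), max_edit = max_edit,
                          allow_suffix_clip = TRUE)
    if (!is.na(rfit$cigar) && rfit$clipped > 0) {
      cg <- rev_cigar(rfit$cigar)
      span <- cigar_ref_span(cg)
      res <- list(ref_start = base0 + nchar(window) - rfit$start - span,
                  cigar = cg, edit = rfit$edit)
    }
  }
  if (!is.null(res) && index$circular[gi]) res$ref_start <- res$ref_start %% L
  if (!is.null(res) && !index$circular[gi] &&
      (res$ref_start < 0L || res$ref_start + cigar_ref_span(res$cigar) > L))
    return(NULL)
  res
}

#' Map a single read
#'
#' Seed-and-extend: non-overlapping k-mer seeds vote for candidate loci, the
#' top clusters are aligned end-to-end against a padded reference window
#' under unit edit costs, and the best-scoring locus wins. Ties are broken by
#' leftmost reference position then \code{+} strand; reads whose best edit
#' distance exceeds \code{ceiling(max_edit_frac * length)} or whose best
#' score is tied at distinct loci are unmapped.
#'
#' @param read read sequence (character) or a named list with \code{id},
#'   \code{seq}.
#' @param index a [build_index()] result over the target genomes.
#' @param params [mapper_params()].
#' @param read_id id used in the alignment record.
#' @return one-row alignment data.frame, or \code{NULL} when unmapped.
#' @export
map_read <- function(read, index, params = mapper_params(), read_id = "read") {
  if (is.list(read)) { read_id <- read$id %||% read_id; read <- read$seq }
  a <- map_read_core(toupper(read), index, params)
  if (is.null(a)) return(NULL)
  alignment_frame(read_id = read_id, ref_id = index$ids[a$gi],
                  ref_start = a$ref_start, strand = a$strand,
                  cigar = a$cigar, seq = a$seq, edit = a$edit)
}

map_read_core <- function(read, index, params) {
  rl <- nchar(read)
  if (rl < index$k) return(NULL)
  tries <- list(list(seq = read, strand = "+"),
                list(seq = rc1(read), strand = "-"))
  cands <- list()
  for (tr in tries) {
    cl <- seed_clusters(tr$seq, index, params$band)
    if (is.null(cl)) next
    nc <- min(cl$n, params$max_clusters)
    for (ci in seq_len(nc)) {
      rep <- cl$rep[ci]
      gi <- findInterval(rep, c(index$offsets, sum(index$lengths)))
      gi <- max(1L, min(gi, length(index$ids)))
      s0 <- rep - index$offsets[gi]
      if (index$circular[gi]) s0 <- ((s0 %% index$lengths[gi]) +
                                     index$lengths[gi]) %% index$lengths[gi]
      a <- align_candidate(tr$seq, index, gi, s0, params)
      if (!is.null(a))
        cands[[length(cands) + 1L]] <- c(a, list(strand = tr$strand, gi = gi,
                                                 seq = tr$seq))
      # a perfect end-to-end hit cannot be beaten; skip remaining work
      if (!is.null(a) && a$edit == 0L && nc == 1L && tr$strand == "+" &&
          params$max_clusters > 0L) break
    }
    if (length(cands) == 1L && cands[[1]]$edit == 0L && cl$n == 1L) break
  }
  if (!length(cands)) return(NULL)
  max_edit <- as.integer(ceiling(params$max_edit_frac * rl))
  edits <- vapply(cands, `[[`, 0L, "edit")
  clipped <- vapply(cands, function(a) grepl("S", a$cigar, fixed = TRUE), TRUE)
  keep <- edits <= max_edit | clipped
  if (!any(keep)) return(NULL)
  cands <- cands[keep]; edits <- edits[keep]
  top <- cands[edits == min(edits)]
  pos <- vapply(top, `[[`, 0L, "ref_start")
  gis <- vapply(top, `[[`, 0L, "gi")
  if ((length(unique(gis)) > 1L || max(abs(pos - pos[1])) > params$band) &&
      params$discard_multi)
    return(NULL)
  strands <- vapply(top, `[[`, "", "strand")
  o <- order(pos, strands != "+")
  best <- top[[o[1]]]
  best
}

#' Map a batch of reads or read pairs
#'
#' @param reads data.frame with \code{id, seq1[, seq2]} (as produced by
#'   [simulate_reads()] / [read_fastq()]) or a character vector.
#' @param index a [build_index()] result.
#' @param params [mapper_params()].
#' @param verbose log progress.
#' @return alignment data.frame (unmapped reads are absent).
#' @export
map_reads <- function(reads, index, params = mapper_params(), verbose = FALSE) {
  if (is.character(reads))
    reads <- data.frame(id = paste0("read_", seq_along(reads)), seq1 = reads,
                        stringsAsFactors = FALSE)
  paired <- !is.null(reads$seq2)
  n <- nrow(reads)
  nm <- n * (1L + paired)
  ids <- character(nm); ref_id <- character(nm); ref_start <- integer(nm)
  strand <- character(nm); cigar <- character(nm); seqs <- character(nm)
  edit <- integer(nm); got <- logical(nm)
  put <- function(slot, id, a) {
    ids[slot] <<- id; ref_id[slot] <<- index$ids[a$gi]
    ref_start[slot] <<- a$ref_start; strand[slot] <<- a$strand
    cigar[slot] <<- a$cigar; seqs[slot] <<- a$seq; edit[slot] <<- a$edit
    got[slot] <<- TRUE
  }
  for (i in seq_len(n)) {
    a1 <- map_read_core(reads$seq1[i], index, params)
    if (!is.null(a1))
      put(if (paired) 2L * i - 1L else i,
          if (paired) paste0(reads$id[i], "/1") else reads$id[i], a1)
    if (paired) {
      a2 <- map_read_core(reads$seq2[i], index, params)
      if (!is.null(a2)) put(2L * i, paste0(reads$id[i], "/2"), a2)
    }
    if (verbose && i %% 10000L == 0L)
      ga_log("mapped ", i, "/", n, " fragments")
  }
  alignment_frame(read_id = ids[got], ref_id = ref_id[got],
                  ref_start = ref_start[got], strand = strand[got],
                  cigar = cigar[got], seq = seqs[got], edit = edit[got])
}

#' Build a pileup from alignments
#'
#' M ops add to per-base counts, D ops to the deletion count of the spanned
#' columns, I ops are recorded as insertion observations anchored after the
#' preceding reference column, and soft clips are tallied at the adjacent
#' aligned column (they contribute neither depth nor alleles). Per-column
#' depth is the number of reads whose alignment spans the column.
#'
#' @param alignments alignment data.frame.
#' @param genome the [genome_record()] the alignments refer to.
#' @return a \code{Pileup} object: matrices/vectors \code{counts} (rows
#'   A,C,G,T,N), \code{del}, \code{clip}, \code{depth}, and data.frame
#'   \code{ins} of insertion observations.
#' @export
build_pileup <- function(alignments, genome) {
  stopifnot(inherits(genome, "GenomeRecord"))
  alignments <- alignments[alignments$ref_id == genome$id, , drop = FALSE]
  raw <- pileup_cpp(genome$length, alignments$ref_start, alignments$cigar,
                    alignments$seq, circular = genome$circular)
  counts <- raw$counts
  rownames(counts) <- c(.ga_bases, "N")
  depth <- as.integer(colSums(counts) + raw$del)
  structure(list(ref_id = genome$id, length = genome$length, counts = counts,
                 del = raw$del, clip = raw$clip, depth = depth,
                 ins = data.frame(pos = raw$ins_pos,
                                  allele = as.character(raw$ins_allele),
                                  count = raw$ins_count,
                                  stringsAsFactors = FALSE),
                 n_alignments = nrow(alignments), circular = genome$circular),
            class = "Pileup")
}

#' @export
print.Pileup <- function(x, ...) {
  cat(sprintf("Pileup on '%s' (%d bp): %d alignments, mean depth %.1f\n",
              x$ref_id, x$length, x$n_alignments, mean(x$depth)))
  invisible(x)
}

#' Extract one pileup column
#'
#' @param pileup a [build_pileup()] result.
#' @param position 0-based reference position.
#' @return list with \code{ref_id, position, depth, base_counts,
#'   deletion_count, insertion_observations} (insertions anchored AFTER this
#'   column).
#' @export
pileup_column <- function(pileup, position) {
  stopifnot(position >= 0L, position < pileup$length)
  i <- position + 1L
  ins <- pileup$ins[pileup$ins$pos == position, , drop = FALSE]
  list(ref_id = pileup$ref_id, position = position,
       depth = pileup$depth[i],
       base_counts = pileup$counts[, i],
       deletion_count = pileup$del[i],
       insertion_observations = setNames(ins$count, ins$allele))
}
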