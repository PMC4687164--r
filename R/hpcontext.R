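#' Maximal homopolymer runs of a sequence
#'
#' @param sequence DNA string or [genome_record()].
#' @return data.frame with columns \code{base, start, end, length}
#'   (0-based half-open), one row per maximal run, including length-1 runs.
#' @export
homopolymer_runs <- function(sequence) {
  if (inherits(sequence, "GenomeRecord")) sequence <- sequence$sequence
  r <- rle(strsplit(sequence, "")[[1]])
  ends <- cumsum(r$lengths)
  data.frame(base = r$values, start = ends - r$lengths, end = ends,
             length = r$lengths, stringsAsFactors = FALSE)
}

#' Homopolymer run length at a discrepancy site
#'
#' Measured on the (uncorrected) reference, the convention under which the
#' audit reports discrepancy context. For insertions the run of the inserted
#' base immediately following the left-normalized anchor is used (falling
#' back to the run at the anchor itself, then to length 1 when the inserted
#' base matches neither neighbour); for deletions and substitutions the
#' maximal run containing the site's reference base.
#'
#' @param genome [genome_record()] or DNA string.
#' @param position 0-based site: the anchor column for insertions, the
#'   affected base for deletions/substitutions.
#' @param base the discrepancy base (inserted base, deleted base, or the
#'   reference base at a substitution site).
#' @param type discrepancy type.
#' @param runs optional precomputed [homopolymer_runs()] table for repeated
#'   queries against the same genome.
#' @return list with \code{base, run_length, run_start, run_end}.
#' @export
run_length_at <- function(genome, position, base,
                          type = c("insertion", "deletion", "substitution"),
                          runs = NULL) {
  type <- match.arg(type)
  seqs <- if (inherits(genome, "GenomeRecord")) genome$sequence else genome
  if (!base %in% .ga_bases)
    stop("run_length_at: base must be one of A,C,G,T")
  L <- nchar(seqs)
  if (type != "insertion" && (position < 0L || position >= L))
    stop("run_length_at: position outside genome")
  if (type == "insertion" && (position < -1L || position >= L))
    stop("run_length_at: insertion anchor outside genome")
  if (is.null(runs)) runs <- homopolymer_runs(seqs)
  run_of <- function(p) runs[findInterval(p, runs$start), , drop = FALSE]
  site <- switch(type,
    insertion = {
      nxt <- position + 1L
      if (nxt < L && substr(seqs, nxt + 1L, nxt + 1L) == base) nxt
      else if (position >= 0L &&
               substr(seqs, position + 1L, position + 1L) == base) position
      else NA_integer_
    },
    position)
  if (is.na(site)) {
    at <- min(position + 1L, L - 1L)
    return(list(base = base, run_length = 1L,
                run_start = at, run_end = at + 1L))
  }
  r <- run_of(site)
  list(base = r$base, run_length = r$length, run_start = r$start,
       run_end = r$end)
}

#' Annotate discrepancies with region and overlapping genes
#'
#' A discrepancy is \code{coding} iff its site (for insertions, the base
#' following the anchor) lies inside at least one CDS interval; all
#' overlapping CDS ids are recorded, so a site shared by two annotated
#' fragments of a split gene lists both.
#'
#' @param discrepancies discrepancy data.frame.
#' @param features [cds_features()] on the same genome.
#' @return the discrepancies with \code{region} and \code{gene_ids} filled.
#' @export
annotate_regions <- function(discrepancies, features) {
  n <- nrow(discrepancies)
  if (n == 0L) {
    discrepancies$region <- character(0)
    discrepancies$gene_ids <- character(0)
    return(discrepancies)
  }
  site <- ifelse(discrepancies$type == "insertion",
                 discrepancies$position + 1L, discrepancies$position)
  if (nrow(features) == 0L) {
    discrepancies$region <- rep("noncoding", n)
    discrepancies$gene_ids <- rep("", n)
    return(discrepancies)
  }
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(start = site + 1L, width = 1L),
    IRanges::IRanges(start = features$start + 1L, end = features$end))
  ids <- vapply(seq_len(n), function(i) {
    j <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]
    paste(sort(features$id[j]), collapse = ",")
  }, "")
  discrepancies$region <- ifelse(nzchar(ids), "coding", "noncoding")
  discrepancies$gene_ids <- ids
  discrepancies
}

#' Fill homopolymer context on a discrepancy table
#'
#' @param discrepancies discrepancy data.frame.
#' @param genome the reference the discrepancies were called against.
#' @return discrepancies with \code{homopolymer_base} and
#'   \code{homopolymer_length} filled.
#' @export
annotate_homopolymers <- function(discrepancies, genome) {
  n <- nrow(discrepancies)
  if (n == 0L) {
    discrepancies$homopolymer_base <- character(0)
    discrepancies$homopolymer_length <- integer(0)
    return(discrepancies)
  }
  runs <- homopolymer_runs(genome)
  hb <- character(n); hl <- integer(n)
  for (i in seq_len(n)) {
    d <- discrepancies[i, ]
    b <- switch(d$type,
                insertion = substr(d$alt_allele, nchar(d$alt_allele),
                                   nchar(d$alt_allele)),
                deletion = substr(d$ref_allele, 1L, 1L),
                substitution = d$ref_allele)
    ann <- run_length_at(genome, d$position, b, d$type, runs = runs)
    hb[i] <- ann$base; hl[i] <- ann$run_length
  }
  discrepancies$homopolymer_base <- hb
  discrepancies$homopolymer_length <- hl
  discrepancies
}

#' Summarise a discrepancy set
#'
#' Exact integer tallies of the audit: totals by type, coding fraction, the
#' run-length histogram, and both homopolymer counters (runs longer than 4
#' and longer than 5, i.e. length >= 5 and >= 6) so either threshold reading
#' is checkable.
#'
#' @param discrepancies annotated discrepancy data.frame (run lengths and
#'   regions filled).
#' @return an \code{AuditSummary} list; its \code{histogram} element is the
#'   run-length count table.
#' @export
summarize_discrepancies <- function(discrepancies) {
  n <- nrow(discrepancies)
  tab <- function(t) sum(discrepancies$type == t)
  hl <- discrepancies$homopolymer_length
  hist <- if (n) table(factor(hl, levels = seq_len(max(hl)))) else table(integer(0))
  n_coding <- if (n) sum(discrepancies$region == "coding") else 0L
  out <- list(
    n_total = n,
    n_insertions = tab("insertion"),
    n_deletions = tab("deletion"),
    n_substitutions = tab("substitution"),
    n_coding = n_coding,
    fraction_coding = if (n) n_coding / n else 0,
    counts_by_run_length = hist,
    n_run_gt4 = if (n) sum(hl >= 5L) else 0L,
    n_run_gt5 = if (n) sum(hl >= 6L) else 0L,
    fraction_run_gt4 = if (n) sum(hl >= 5L) / n else 0)
  structure(out, class = "AuditSummary")
}

#' @export
print.AuditSummary <- function(x, ...) {
  cat(sprintf(paste0("Audit summary: %d discrepancies ",
                     "(%d ins / %d del / %d sub), %.1f%% coding, ",
                     "%.1f%% in homopolymer runs > 4\n"),
              x$n_total, x$n_insertions, x$n_deletions, x$n_substitutions,
              100 * x$fraction_coding, 100 * x$fraction_run_gt4))
  invisible(x)
}
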