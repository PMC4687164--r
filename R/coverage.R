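#' Per-position depth of coverage
#'
#' Depth at a position is the number of reads whose alignment spans it with
#' an M or D op (a read spans a base it carries a deletion of); soft-clipped
#' bases do not count.
#'
#' @param x a \code{Pileup} from [build_pileup()], or an alignment
#'   data.frame (in which case \code{genome} is required and a pileup is
#'   built internally).
#' @param genome the reference [genome_record()].
#' @return integer vector of length \code{genome$length}.
#' @export
depth_vector <- function(x, genome = NULL) {
  if (inherits(x, "Pileup")) return(x$depth)
  if (is.null(genome)) stop("depth_vector: genome required for alignments")
  build_pileup(x, genome)$depth
}

#' Genome-wide coverage moments and per-CDS breadth
#'
#' Computes the mean and (population) standard deviation of per-position
#' depth, the mean mapped read length, and for every CDS the fraction of its
#' positions covered at or above \code{min_depth}, summarised as the
#' percentage of CDSs fully covered at that depth and the percentage covered
#' over at least 60\% of their length.
#'
#' @param depth integer depth vector (see [depth_vector()]).
#' @param features [cds_features()] table.
#' @param min_depth breadth threshold (default 40).
#' @param alignments optional alignment data.frame used for read-length and
#'   read-count statistics.
#' @return \code{CoverageSummary} list with \code{mean_depth, sd_depth,
#'   mean_read_length, n_mapped_reads, per_cds,
#'   pct_cds_full_breadth, pct_cds_breadth60}.
#' @export
cds_breadth <- function(depth, features, min_depth = 40L, alignments = NULL) {
  L <- length(depth)
  if (nrow(features) && any(features$end > L))
    stop("cds_breadth: feature outside genome bounds")
  ok <- depth >= min_depth
  frac <- vapply(seq_len(nrow(features)), function(i)
    mean(ok[(features$start[i] + 1L):features$end[i]]), 0)
  per_cds <- data.frame(cds_id = features$id, breadth = frac,
                        stringsAsFactors = FALSE)
  mu <- mean(depth)
  structure(list(
    mean_depth = mu,
    sd_depth = sqrt(mean((depth - mu)^2)),
    mean_read_length = if (!is.null(alignments) && nrow(alignments))
      mean(nchar(alignments$seq)) else NA_real_,
    n_mapped_reads = if (!is.null(alignments)) nrow(alignments) else NA_integer_,
    min_depth = as.integer(min_depth),
    per_cds = per_cds,
    pct_cds_full_breadth = if (nrow(features)) 100 * mean(frac == 1) else NA_real_,
    pct_cds_breadth60 = if (nrow(features)) 100 * mean(frac >= 0.6) else NA_real_),
    class = "CoverageSummary")
}

#' @export
print.CoverageSummary <- function(x, ...) {
  cat(sprintf(paste0("Coverage: mean %.2f (sd %.2f); %.2f%% of CDSs fully ",
                     "covered at >= %dx, %.2f%% covered over >= 60%%\n"),
              x$mean_depth, x$sd_depth, x$pct_cds_full_breadth, x$min_depth,
              x$pct_cds_breadth60))
  invisible(x)
}

#' Export depth as bedGraph-style intervals
#'
#' @param depth integer depth vector.
#' @param ref_id reference name.
#' @param path output TSV (0-based half-open intervals).
#' @export
write_depth_bedgraph <- function(depth, ref_id, path) {
  r <- rle(depth)
  ends <- cumsum(r$lengths)
  df <- data.frame(chrom = ref_id, start = ends - r$lengths, end = ends,
                   depth = r$values)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
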