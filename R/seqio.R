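#' Create a genome record
#'
#' A genome record is the package's container for one nucleotide sequence:
#' an id, an uppercase DNA string over \code{A,C,G,T,N}, and a circularity
#' flag (bacterial chromosomes are typically circular; the flag controls
#' k-mer indexing across the origin, wrapped read simulation and wrapped
#' window extraction).
#'
#' @param id sequence name.
#' @param sequence DNA string; lowercase is accepted and uppercased.
#' @param circular logical; is the molecule circular?
#' @param on_invalid what to do with characters outside \code{A,C,G,T,N}:
#'   \code{"error"} rejects them, \code{"mask"} maps them to \code{N}.
#' @return an object of class \code{GenomeRecord} (a list with fields
#'   \code{id}, \code{sequence}, \code{circular}, \code{length}).
#' @export
genome_record <- function(id, sequence, circular = FALSE,
                          on_invalid = c("error", "mask")) {
  on_invalid <- match.arg(on_invalid)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L)
    stop("genome_record: empty sequence for '", id, "'")
  if (grepl("[^ACGTN]", sequence)) {
    if (on_invalid == "error")
      stop("genome_record: sequence '", id,
           "' contains characters outside {A,C,G,T,N}")
    sequence <- gsub("[^ACGTN]", "N", sequence)
  }
  structure(list(id = id, sequence = sequence, circular = isTRUE(circular),
                 length = nchar(sequence)),
            class = "GenomeRecord")
}

#' @export
print.GenomeRecord <- function(x, ...) {
  cat(sprintf("GenomeRecord '%s': %d bp%s\n", x$id, x$length,
              if (x$circular) " (circular)" else ""))
  invisible(x)
}

as_genome <- function(x) {
  if (inherits(x, "GenomeRecord")) return(x)
  if (is.character(x) && length(x) == 1L && !file.exists(x))
    return(genome_record("seq", x))
  stop("expected a GenomeRecord")
}

#' Read a FASTA file
#'
#' @param path FASTA file.
#' @param circular logical, recycled over records.
#' @param on_invalid see [genome_record()].
#' @return list of [genome_record()] objects, one per header.
#' @export
read_fasta <- function(path, circular = FALSE, on_invalid = c("error", "mask")) {
  on_invalid <- match.arg(on_invalid)
  if (!file.exists(path)) stop("read_fasta: no such file: ", path)
  ss <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                 error = function(e) stop("read_fasta: not valid FASTA (",
                                          conditionMessage(e), ")"))
  if (length(ss) == 0L) stop("read_fasta: empty FASTA: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) stop("read_fasta: duplicate record ids in ", path)
  if (any(Biostrings::width(ss) == 0L))
    stop("read_fasta: record with empty sequence in ", path)
  circular <- rep_len(circular, length(ss))
  out <- lapply(seq_along(ss), function(i)
    genome_record(ids[i], as.character(ss[[i]]), circular[i], on_invalid))
  names(out) <- ids
  out
}

#' Write genome records as FASTA
#'
#' @param genomes a GenomeRecord or list of them.
#' @param path output file.
#' @export
write_fasta <- function(genomes, path) {
  if (inherits(genomes, "GenomeRecord")) genomes <- list(genomes)
  ss <- Biostrings::DNAStringSet(vapply(genomes, `[[`, "", "sequence"))
  names(ss) <- vapply(genomes, `[[`, "", "id")
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Construct a CDS feature table
#'
#' Features use 0-based half-open coordinates in memory; [read_gff3()] and
#' [write_gff3()] convert to and from the 1-based closed GFF3 convention.
#' Lengths need not be multiples of 3: annotation of a frameshifted genome
#' legitimately contains pseudogene fragments.
#'
#' @param id,genome_id,start,end,strand,phase,product feature columns;
#'   \code{start}/\code{end} 0-based half-open, \code{strand} in \code{+,-}.
#' @param genome_length optional bound used to validate \code{end}.
#' @return data.frame with class \code{c("CdsFeatures","data.frame")}.
#' @export
cds_features <- function(id, genome_id, start, end, strand,
                         phase = 0L, product = "", genome_length = NULL) {
  n <- length(id)
  df <- data.frame(id = as.character(id),
                   genome_id = rep_len(as.character(genome_id), n),
                   start = as.integer(start), end = as.integer(end),
                   strand = rep_len(as.character(strand), n),
                   phase = rep_len(as.integer(phase), n),
                   product = rep_len(as.character(product), n),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(df$start < 0L) || any(df$start >= df$end))
      stop("cds_features: require 0 <= start < end")
    if (!all(df$strand %in% c("+", "-")))
      stop("cds_features: strand must be '+' or '-'")
    if (!all(df$phase %in% 0:2)) stop("cds_features: phase must be 0, 1 or 2")
    if (!is.null(genome_length) && any(df$end > genome_length))
      stop("cds_features: feature end exceeds genome length")
  }
  class(df) <- c("CdsFeatures", "data.frame")
  df
}

empty_features <- function() cds_features(character(), character(),
                                          integer(), integer(), character())

#' Read CDS features from GFF3
#'
#' Only \code{type == "CDS"} records are retained; 1-based closed GFF3
#' coordinates are converted to 0-based half-open.
#'
#' @param path GFF3 file.
#' @return a [cds_features()] table.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("read_gff3: no such file: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("read_gff3: not valid GFF3 (",
                                          conditionMessage(e), ")"))
  gr <- gr[as.character(gr$type) == "CDS"]
  if (length(gr) == 0L) return(empty_features())
  strand <- as.character(BiocGenerics::strand(gr))
  if (!all(strand %in% c("+", "-")))
    stop("read_gff3: CDS with unknown strand")
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else
    paste0("cds_", seq_along(gr))
  ids[is.na(ids)] <- paste0("cds_", which(is.na(ids)))
  phase <- if (!is.null(gr$phase)) as.integer(gr$phase) else 0L
  phase[is.na(phase)] <- 0L
  product <- if (!is.null(gr$product)) as.character(gr$product) else ""
  product[is.na(product)] <- ""
  cds_features(ids, as.character(GenomicRanges::seqnames(gr)),
               BiocGenerics::start(gr) - 1L, BiocGenerics::end(gr),
               strand, phase, product)
}

#' Write CDS features as GFF3
#'
#' @param features a [cds_features()] table (0-based half-open).
#' @param path output file.
#' @export
write_gff3 <- function(features, path) {
  if (nrow(features) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = features$genome_id,
    ranges = IRanges::IRanges(start = features$start + 1L, end = features$end),
    strand = features$strand)
  gr$source <- "genaudit"
  gr$type <- "CDS"
  gr$phase <- features$phase
  gr$ID <- features$id
  gr$product <- ifelse(nzchar(features$product), features$product, NA_character_)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Decode / encode Phred+33 quality strings
#'
#' @param qual character vector of quality strings.
#' @return for \code{phred_to_int}, a list of integer vectors.
#' @export
phred_to_int <- function(qual) {
  lapply(qual, function(q) as.integer(charToRaw(q)) - 33L)
}

#' @rdname phred_to_int
#' @param scores list of integer vectors (0--93).
#' @export
int_to_phred <- function(scores) {
  vapply(scores, function(s) rawToChar(as.raw(s + 33L)), "")
}

#' Read paired or single FASTQ (Phred+33)
#'
#' @param path1 FASTQ for mate 1.
#' @param path2 optional FASTQ for mate 2.
#' @param n,skip read at most \code{n} records after skipping \code{skip},
#'   allowing chunked streaming over large files.
#' @return data.frame with columns \code{id, seq1, qual1} and, for pairs,
#'   \code{seq2, qual2}.
#' @export
read_fastq <- function(path1, path2 = NULL, n = Inf, skip = 0L) {
  rd <- function(p) {
    tryCatch({
      ss <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(
        p, quality.scoring = "phred",
        nrec = if (is.finite(n)) as.integer(n) else -1L,
        skip = as.integer(skip)))  # metadata-column note is irrelevant here
      q <- as.character(Biostrings::quality(ss))
      s <- as.character(ss)
      if (any(nchar(q) != nchar(s)))
        stop("sequence/quality length mismatch")
      data.frame(id = sub("\\s.*$", "", names(ss)), seq = s, qual = q,
                 stringsAsFactors = FALSE)
    }, error = function(e) stop("read_fastq: invalid FASTQ '", p, "' (",
                                conditionMessage(e), ")"))
  }
  r1 <- rd(path1)
  out <- data.frame(id = r1$id, seq1 = r1$seq, qual1 = r1$qual,
                    stringsAsFactors = FALSE)
  if (!is.null(path2)) {
    r2 <- rd(path2)
    if (nrow(r2) != nrow(r1)) stop("read_fastq: mates differ in record count")
    out$seq2 <- r2$seq
    out$qual2 <- r2$qual
  }
  out
}

#' Write paired reads as two FASTQ files
#'
#' @param reads data.frame from [simulate_reads()] or [read_fastq()].
#' @param path1,path2 output FASTQ paths.
#' @export
write_read_pairs <- function(reads, path1, path2) {
  wr <- function(seqs, quals, ids, p) {
    if (length(seqs) == 0L) { file.create(p); return(invisible()) }
    qs <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(setNames(seqs, ids)),
      Biostrings::PhredQuality(quals))
    Biostrings::writeQualityScaledXStringSet(qs, p)
  }
  wr(reads$seq1, reads$qual1, paste0(reads$id, "/1"), path1)
  wr(reads$seq2, reads$qual2, paste0(reads$id, "/2"), path2)
  invisible(c(path1, path2))
}

# ---- CIGAR arithmetic -------------------------------------------------------

#' Parse a CIGAR string
#'
#' @param cigar a single CIGAR over ops \code{M,I,D,S}.
#' @return data.frame with columns \code{op}, \code{len}.
#' @export
parse_cigar <- function(cigar) {
  if (is.na(cigar) || !grepl("^([0-9]+[MIDS])+$", cigar))
    stop("parse_cigar: malformed CIGAR: ", cigar)
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDS]", cigar))[[1]]
  data.frame(op = ops, len = lens, stringsAsFactors = FALSE)
}

#' @rdname parse_cigar
#' @return \code{cigar_ref_span}: reference bases consumed (M+D);
#'   \code{cigar_read_span}: read bases consumed (M+I+S).
#' @export
cigar_ref_span <- function(cigar) {
  vapply(cigar, function(cg) {
    p <- parse_cigar(cg); sum(p$len[p$op %in% c("M", "D")])
  }, 0L, USE.NAMES = FALSE)
}

#' @rdname parse_cigar
#' @export
cigar_read_span <- function(cigar) {
  vapply(cigar, function(cg) {
    p <- parse_cigar(cg); sum(p$len[p$op %in% c("M", "I", "S")])
  }, 0L, USE.NAMES = FALSE)
}

alignment_frame <- function(read_id = character(), ref_id = character(),
                            ref_start = integer(), strand = character(),
                            cigar = character(), seq = character(),
                            edit = integer()) {
  data.frame(read_id = read_id, ref_id = ref_id,
             ref_start = as.integer(ref_start), strand = strand,
             cigar = cigar, seq = seq, edit = as.integer(edit),
             stringsAsFactors = FALSE)
}

# ---- SAM text import/export -------------------------------------------------

#' Read alignments from a SAM text file
#'
#' Parses the mandatory SAM columns (header lines are skipped), keeping ops
#' \code{M,I,D,S} (\code{=} and \code{X} are folded into \code{M}; hard clips
#' are dropped). 1-based \code{POS} is converted to the internal 0-based
#' convention. Unmapped records are skipped. \code{NM} is used for the edit
#' distance when present.
#'
#' @param path SAM file.
#' @param genomes list of [genome_record()]s the alignments refer to.
#' @return alignment data.frame (\code{read_id, ref_id, ref_start, strand,
#'   cigar, seq, edit}).
#' @export
read_sam <- function(path, genomes) {
  if (!file.exists(path)) stop("read_sam: no such file: ", path)
  if (inherits(genomes, "GenomeRecord")) genomes <- list(genomes)
  known <- vapply(genomes, `[[`, "", "id")
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(lines) == 0L) return(alignment_frame())
  fld <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(fld, length, 0L) < 11L
  if (any(bad)) stop("read_sam: line with fewer than 11 fields")
  flag <- as.integer(vapply(fld, `[[`, "", 2L))
  rname <- vapply(fld, `[[`, "", 3L)
  keep <- bitwAnd(flag, 4L) == 0L & rname != "*"
  fld <- fld[keep]; flag <- flag[keep]; rname <- rname[keep]
  if (length(fld) == 0L) return(alignment_frame())
  if (!all(rname %in% known))
    stop("read_sam: reference name(s) not in provided genomes: ",
         paste(unique(setdiff(rname, known)), collapse = ", "))
  cig <- vapply(fld, `[[`, "", 6L)
  cig <- gsub("[=X]", "M", cig)
  cig <- gsub("[0-9]+H", "", cig)
  nm <- vapply(fld, function(f) {
    hit <- grep("^NM:i:", f[-(1:11)], value = TRUE)
    if (length(hit)) as.integer(sub("^NM:i:", "", hit[1])) else NA_integer_
  }, 0L)
  alignment_frame(
    read_id = vapply(fld, `[[`, "", 1L),
    ref_id = rname,
    ref_start = as.integer(vapply(fld, `[[`, "", 4L)) - 1L,
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    cigar = cig,
    seq = toupper(vapply(fld, `[[`, "", 10L)),
    edit = nm)
}

#' Write alignments as SAM text
#'
#' @param alignments alignment data.frame (internal 0-based coordinates).
#' @param genomes list of [genome_record()]s (for \code{@SQ} header lines).
#' @param path output file.
#' @export
write_sam <- function(alignments, genomes, path) {
  if (inherits(genomes, "GenomeRecord")) genomes <- list(genomes)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           vapply(genomes, function(g)
             sprintf("@SQ\tSN:%s\tLN:%d", g$id, g$length), ""))
  flag <- ifelse(alignments$strand == "-", 16L, 0L)
  body <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*\tNM:i:%d",
                  alignments$read_id, flag, alignments$ref_id,
                  alignments$ref_start + 1L, alignments$cigar,
                  alignments$seq, alignments$edit)
  writeLines(c(hdr, body), path)
  invisible(path)
}
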