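# ---- coordinate maps --------------------------------------------------------

#' Build the coordinate map induced by a set of corrections
#'
#' The map records, as (old position, offset) breakpoints, how 0-based old
#' reference coordinates translate to corrected coordinates. Offsets change
#' only at correction sites and the total offset equals inserted minus
#' deleted bases.
#'
#' @param discrepancies normalized, non-conflicting discrepancy data.frame
#'   (columns \code{position, type, ref_allele, alt_allele}).
#' @param old_length length of the uncorrected sequence.
#' @return a \code{CoordinateMap} object.
#' @export
build_coordinate_map <- function(discrepancies, old_length) {
  d <- discrepancies[order(discrepancies$position), , drop = FALSE]
  if (anyDuplicated(d$position))
    stop("build_coordinate_map: conflicting corrections at site(s) ",
         paste(unique(d$position[duplicated(d$position)]), collapse = ", "))
  old <- 0L; off <- 0L
  cum <- 0L
  events <- d
  events$off_before <- integer(nrow(d))
  deleted <- list()
  for (i in seq_len(nrow(d))) {
    events$off_before[i] <- cum
    if (d$type[i] == "insertion") {
      l <- nchar(d$alt_allele[i])
      cum <- cum + l
      old <- c(old, d$position[i] + 1L); off <- c(off, cum)
    } else if (d$type[i] == "deletion") {
      l <- nchar(d$ref_allele[i])
      deleted[[length(deleted) + 1L]] <- c(d$position[i], d$position[i] + l)
      cum <- cum - l
      old <- c(old, d$position[i] + l); off <- c(off, cum)
    }
  }
  keep <- !duplicated(old, fromLast = TRUE)  # later events win at equal old
  deleted <- if (length(deleted)) do.call(rbind, deleted) else
    matrix(integer(), ncol = 2L)
  structure(list(breaks = data.frame(old = old[keep], offset = off[keep]),
                 deleted = deleted, events = events,
                 old_length = as.integer(old_length),
                 new_length = as.integer(old_length + cum)),
            class = "CoordinateMap")
}

#' Map old positions to corrected positions
#'
#' @param cmap a [build_coordinate_map()] result.
#' @param positions 0-based old coordinates.
#' @return list with \code{new} (0-based corrected coordinates; positions
#'   inside a deleted segment land on the deletion junction) and
#'   \code{deleted} (logical).
#' @export
map_positions <- function(cmap, positions) {
  idx <- findInterval(positions, cmap$breaks$old)
  new <- as.integer(positions + cmap$breaks$offset[pmax(idx, 1L)])
  deleted <- rep(FALSE, length(positions))
  if (nrow(cmap$deleted)) {
    for (r in seq_len(nrow(cmap$deleted))) {
      hit <- positions >= cmap$deleted[r, 1] & positions < cmap$deleted[r, 2]
      if (any(hit)) {
        deleted[hit] <- TRUE
        p0 <- cmap$deleted[r, 1]
        i0 <- findInterval(p0 - 0.5, cmap$breaks$old)
        new[hit] <- as.integer(p0 + cmap$breaks$offset[max(i0, 1L)])
      }
    }
  }
  list(new = new, deleted = deleted)
}

#' Invert a coordinate map
#'
#' @param cmap a [build_coordinate_map()] result.
#' @return the corrected-to-old \code{CoordinateMap}.
#' @export
invert_coordinate_map <- function(cmap) {
  ev <- cmap$events
  if (nrow(ev) == 0L) return(build_coordinate_map(ev, cmap$new_length))
  inv <- ev
  for (i in seq_len(nrow(ev))) {
    ob <- ev$off_before[i]
    if (ev$type[i] == "insertion") {
      inv$type[i] <- "deletion"
      inv$position[i] <- ev$position[i] + ob + 1L
      inv$ref_allele[i] <- ev$alt_allele[i]
      inv$alt_allele[i] <- ""
    } else if (ev$type[i] == "deletion") {
      inv$type[i] <- "insertion"
      inv$position[i] <- ev$position[i] + ob - 1L
      inv$alt_allele[i] <- ev$ref_allele[i]
      inv$ref_allele[i] <- ""
    } else {
      inv$position[i] <- ev$position[i] + ob
      tmp <- inv$ref_allele[i]
      inv$ref_allele[i] <- inv$alt_allele[i]
      inv$alt_allele[i] <- tmp
    }
  }
  inv$off_before <- NULL
  build_coordinate_map(inv, cmap$new_length)
}

# ---- applying corrections ---------------------------------------------------

#' Apply corrections to a genome
#'
#' Corrections are spliced in a single left-to-right pass over the old
#' sequence (equivalently, right-to-left application: coordinates always
#' refer to the old sequence). The exact length identity
#' \code{new = old + sum(nchar(alt) - nchar(ref))} is asserted on every run.
#'
#' @param genome the reference [genome_record()].
#' @param discrepancies normalized, non-conflicting discrepancy data.frame.
#' @return list with \code{genome} (corrected [genome_record()]) and
#'   \code{map} (the old-to-new [build_coordinate_map()]).
#' @export
apply_corrections <- function(genome, discrepancies) {
  stopifnot(inherits(genome, "GenomeRecord"))
  d <- discrepancies[order(discrepancies$position), , drop = FALSE]
  cmap <- build_coordinate_map(d, genome$length)  # errors on conflicts
  old <- genome$sequence
  parts <- character(0)
  cursor <- 0L  # next uncopied 0-based old index
  for (i in seq_len(nrow(d))) {
    if (d$type[i] == "insertion") {
      a <- d$position[i]
      if (a + 1L > cursor) parts <- c(parts, substr(old, cursor + 1L, a + 1L))
      parts <- c(parts, d$alt_allele[i])
      cursor <- a + 1L
    } else if (d$type[i] == "deletion") {
      p <- d$position[i]; l <- nchar(d$ref_allele[i])
      if (substr(old, p + 1L, p + l) != d$ref_allele[i])
        stop("apply_corrections: deletion allele mismatch at ", p)
      if (p > cursor) parts <- c(parts, substr(old, cursor + 1L, p))
      cursor <- p + l
    } else {
      p <- d$position[i]
      if (p > cursor) parts <- c(parts, substr(old, cursor + 1L, p))
      parts <- c(parts, d$alt_allele[i])
      cursor <- p + 1L
    }
  }
  parts <- c(parts, substr(old, cursor + 1L, genome$length))
  corrected <- paste(parts, collapse = "")
  delta <- sum(nchar(d$alt_allele)) - sum(nchar(d$ref_allele))
  stopifnot(nchar(corrected) == genome$length + delta)
  list(genome = genome_record(paste0(genome$id, "_corrected"), corrected,
                              genome$circular),
       map = cmap)
}

#' Lift features through a coordinate map
#'
#' Start/end are mapped so that an insertion strictly inside a feature grows
#' it while insertions at its boundary junctions leave it unchanged. Features
#' whose endpoints fall inside a deleted segment are lifted to the deletion
#' junction and flagged (\code{anomaly}), never silently dropped.
#'
#' @param features [cds_features()] on the old genome.
#' @param cmap [build_coordinate_map()] result.
#' @return features in corrected coordinates, with an \code{anomaly} column.
#' @export
lift_features <- function(features, cmap) {
  if (nrow(features) == 0L) { features$anomaly <- logical(0); return(features) }
  ms <- map_positions(cmap, features$start)
  me <- map_positions(cmap, features$end - 1L)
  out <- features
  out$start <- ms$new
  out$end <- me$new + 1L
  out$anomaly <- ms$deleted | me$deleted
  bad <- out$end <= out$start
  if (any(bad)) { out$end[bad] <- out$start[bad] + 1L; out$anomaly[bad] <- TRUE }
  out
}

# ---- translation and ORF scanning ------------------------------------------

#' Translate a DNA string (bacterial code, table 11)
#'
#' Internal stops appear as \code{*}; trailing bases short of a codon are
#' dropped; \code{N}-containing codons translate to \code{X}.
#'
#' @param dna DNA string.
#' @param genetic_code NCBI genetic code id (default "11").
#' @return amino-acid string.
#' @export
translate_dna <- function(dna, genetic_code = "11") {
  n <- nchar(dna) - nchar(dna) %% 3L
  if (n < 3L) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(dna, 1L, n)),
    genetic.code = Biostrings::getGeneticCode(genetic_code),
    no.init.codon = TRUE, if.fuzzy.codon = "solve"))
}

#' Translate an annotated CDS feature
#'
#' @param genome [genome_record()] the feature lies on.
#' @param feature one-row [cds_features()] slice.
#' @param genetic_code NCBI code id.
#' @return amino-acid string (may contain internal \code{*} for pseudogene
#'   fragments annotated across a frameshift).
#' @export
translate_feature <- function(genome, feature, genetic_code = "11") {
  s <- substr(genome$sequence, feature$start + 1L, feature$end)
  if (feature$strand == "-") s <- revcomp(s)
  if (feature$phase > 0L) s <- substr(s, feature$phase + 1L, nchar(s))
  translate_dna(s, genetic_code)
}

# annotated product length in aa: terminal stop codon excluded
annotated_aa_length <- function(genome, feature, genetic_code = "11") {
  aa <- translate_feature(genome, feature, genetic_code)
  if (nchar(aa) == 0L) return(0L)
  if (substr(aa, nchar(aa), nchar(aa)) == "*") nchar(aa) - 1L else nchar(aa)
}

#' Naive ORF scan of a (plus-strand) sequence
#'
#' Finds, per frame, every open reading frame running from a start codon
#' (ATG/GTG/TTG, bacterial convention) to the next in-frame stop; only the
#' first start after the previous stop is reported (maximal ORFs).
#'
#' @param sequence plus-strand DNA string.
#' @param genetic_code NCBI code id.
#' @return data.frame with 0-based half-open \code{start, end} (stop codon
#'   included), \code{frame}, \code{aa_len}.
#' @export
scan_orfs <- function(sequence, genetic_code = "11") {
  L <- nchar(sequence)
  gc <- Biostrings::getGeneticCode(genetic_code)
  out <- list()
  for (f in 0:2) {
    ss <- seq.int(f, L - 3L, by = 3L)
    if (!length(ss)) next
    codons <- substring(sequence, ss + 1L, ss + 3L)
    aa <- gc[codons]
    aa[is.na(aa)] <- "X"
    is_stop <- aa == "*"
    is_start <- codons %in% c("ATG", "GTG", "TTG")
    prev_stop <- 0L  # codon index after which the current ORF region begins
    stops <- which(is_stop)
    for (st in stops) {
      region <- (prev_stop + 1L):st
      starts_here <- region[is_start[region]]
      if (length(starts_here)) {
        i0 <- starts_here[1]
        out[[length(out) + 1L]] <- data.frame(
          start = ss[i0], end = ss[st] + 3L, frame = f,
          aa_len = st - i0, stringsAsFactors = FALSE)
      }
      prev_stop <- st
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(), frame = integer(),
                      aa_len = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# ---- coding impact ----------------------------------------------------------

contained_frac <- function(orf_start, orf_end, iv_start, iv_end) {
  ov <- max(0L, min(orf_end, iv_end) - max(orf_start, iv_start))
  ov / max(1L, iv_end - iv_start)
}

#' Classify the coding consequence of each correction
#'
#' For every correction falling in annotated coding sequence the corrected
#' locus is re-scanned for open reading frames on the annotated strand.
#' A correction whose repaired ORF contains two (or more) old same-strand
#' CDS fragments is a \code{gene_merge}; one whose annotated frame carried an
#' internal stop that the corrected frame lacks is \code{stop_removed}; a
#' 1-bp indel restoring the annotated product to a single ORF (within 5\% of
#' the expected ortholog length when one is supplied) is
#' \code{frameshift_repair}. Substitutions are \code{synonymous} or
#' \code{missense}; corrections outside CDS are \code{intergenic}.
#'
#' @param old_genome,corrected_genome reference and corrected
#'   [genome_record()]s.
#' @param old_features annotation of the reference.
#' @param discrepancies normalized discrepancy data.frame.
#' @param genetic_code NCBI code id (default "11", bacterial).
#' @param expected_lengths optional named vector of expected ortholog product
#'   lengths (aa) keyed by gene id.
#' @param merge_window how far (bp) to look for a same-strand merge partner.
#' @param flank bp of corrected context around the locus included in the ORF
#'   re-scan.
#' @return data.frame with one row per correction: \code{position,
#'   old_gene_ids, effect, old_protein_lengths} (comma-joined aa lengths),
#'   \code{new_protein_length}, \code{expected_ortholog_length},
#'   \code{new_protein} (the repaired product sequence, when any).
#' @export
assess_impact <- function(old_genome, corrected_genome, old_features,
                          discrepancies, genetic_code = "11",
                          expected_lengths = NULL, merge_window = 1000L,
                          flank = 300L) {
  stopifnot(inherits(old_genome, "GenomeRecord"),
            inherits(corrected_genome, "GenomeRecord"))
  if (nrow(old_features) && any(old_features$end > old_genome$length))
    stop("assess_impact: CDS outside genome bounds")
  cmap <- build_coordinate_map(discrepancies, old_genome$length)
  Lc <- corrected_genome$length
  rows <- vector("list", nrow(discrepancies))
  for (i in seq_len(nrow(discrepancies))) {
    d <- discrepancies[i, ]
    site <- if (d$type == "insertion") d$position + 1L else d$position
    prim <- old_features[old_features$start <= site & site < old_features$end,
                         , drop = FALSE]
    row <- data.frame(position = d$position, old_gene_ids = "",
                      effect = "intergenic", old_protein_lengths = "",
                      new_protein_length = NA_integer_,
                      expected_ortholog_length = NA_integer_,
                      new_protein = NA_character_, stringsAsFactors = FALSE)
    if (nrow(prim) == 0L) { rows[[i]] <- row; next }
    prim <- prim[order(prim$start), , drop = FALSE]
    row$old_gene_ids <- paste(prim$id, collapse = ",")
    old_lens <- vapply(seq_len(nrow(prim)), function(j)
      annotated_aa_length(old_genome, prim[j, ], genetic_code), 0L)
    row$old_protein_lengths <- paste(old_lens, collapse = ",")
    exp_len <- if (!is.null(expected_lengths))
      suppressWarnings(max(expected_lengths[prim$id], na.rm = TRUE)) else NA
    if (!is.na(exp_len) && is.infinite(exp_len)) exp_len <- NA
    row$expected_ortholog_length <- as.integer(exp_len)
    if (d$type == "substitution") {
      f <- prim[1, , drop = FALSE]
      aa_old <- translate_feature(old_genome, f, genetic_code)
      lf <- lift_features(f, cmap)
      aa_new <- translate_feature(corrected_genome, lf[1, ], genetic_code)
      row$effect <- if (identical(aa_old, aa_new)) "synonymous" else "missense"
      row$new_protein_length <- annotated_aa_length(corrected_genome, lf[1, ],
                                                    genetic_code)
      rows[[i]] <- row; next
    }
    # indel: re-scan the corrected locus for the repaired ORF
    strand <- prim$strand[1]
    part <- old_features[old_features$strand == strand &
                         old_features$start < max(prim$end) + merge_window &
                         old_features$end > min(prim$start) - merge_window,
                         , drop = FALSE]
    lifted <- lift_features(part, cmap)
    lp <- lifted[match(prim$id, lifted$id), , drop = FALSE]
    win_s <- max(0L, min(lp$start) - flank)
    win_e <- min(Lc, max(lifted$end) + flank)
    local <- substr(corrected_genome$sequence, win_s + 1L, win_e)
    if (strand == "-") local <- revcomp(local)
    orfs <- scan_orfs(local, genetic_code)
    if (nrow(orfs)) {
      if (strand == "+") {
        orfs$gstart <- win_s + orfs$start; orfs$gend <- win_s + orfs$end
      } else {
        orfs$gstart <- win_e - orfs$end; orfs$gend <- win_e - orfs$start
      }
      cover <- vapply(seq_len(nrow(orfs)), function(o)
        contained_frac(orfs$gstart[o], orfs$gend[o], lp$start[1], lp$end[1]),
        0)
      cand <- which(cover >= 0.9)
    } else cand <- integer(0)
    if (!length(cand)) { row$effect <- "other"; rows[[i]] <- row; next }
    main <- cand[which.max(orfs$aa_len[cand])]
    gstart <- orfs$gstart[main]; gend <- orfs$gend[main]
    contained_ids <- lifted$id[vapply(seq_len(nrow(lifted)), function(j)
      contained_frac(gstart, gend, lifted$start[j], lifted$end[j]) >= 0.9,
      TRUE)]
    # the repaired gene keeps its annotated start: trim the ORF to the
    # 5'-most contained annotated start when that start is in frame
    inorf <- lifted[lifted$id %in% union(contained_ids, prim$id), , drop = FALSE]
    if (strand == "+") {
      anchor <- min(inorf$start)
      if (anchor >= gstart && anchor < gend && (anchor - gstart) %% 3L == 0L)
        gstart <- anchor
    } else {
      anchor <- max(inorf$end)
      if (anchor <= gend && anchor > gstart && (gend - anchor) %% 3L == 0L)
        gend <- anchor
    }
    new_len <- (gend - gstart) %/% 3L - 1L
    pseq <- substr(corrected_genome$sequence, gstart + 1L, gend)
    if (strand == "-") pseq <- revcomp(pseq)
    prot <- translate_dna(pseq, genetic_code)
    prot <- sub("\\*$", "", prot)
    substr(prot, 1L, 1L) <- "M"  # initiator, whichever start codon
    row$new_protein_length <- new_len
    row$new_protein <- prot
    if (length(contained_ids) >= 2L) {
      merged <- old_features[old_features$id %in% contained_ids, , drop = FALSE]
      merged <- merged[order(merged$start), , drop = FALSE]
      row$effect <- "gene_merge"
      row$old_gene_ids <- paste(merged$id, collapse = ",")
      row$old_protein_lengths <- paste(vapply(seq_len(nrow(merged)),
        function(j) annotated_aa_length(old_genome, merged[j, ], genetic_code),
        0L), collapse = ",")
    } else {
      aa_old <- translate_feature(old_genome, prim[1, ], genetic_code)
      internal_old <- substr(aa_old, 1L, nchar(aa_old) - 1L)
      if (grepl("*", internal_old, fixed = TRUE)) {
        row$effect <- "stop_removed"
      } else if (is.na(exp_len) || abs(new_len - exp_len) / exp_len <= 0.05) {
        row$effect <- "frameshift_repair"
      } else row$effect <- "other"
    }
    rows[[i]] <- row
  }
  if (!length(rows))
    return(data.frame(position = integer(), old_gene_ids = character(),
                      effect = character(), old_protein_lengths = character(),
                      new_protein_length = integer(),
                      expected_ortholog_length = integer(),
                      new_protein = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- annotation transfer ----------------------------------------------------

aa_unit_matrix <- function(match = 2L, mismatch = -1L) {
  ab <- c(Biostrings::AA_STANDARD, "X", "*")
  m <- matrix(mismatch, length(ab), length(ab), dimnames = list(ab, ab))
  diag(m) <- match
  m
}

#' Combined-identity score for annotation transfer
#'
#' Aligns a query protein globally within the reference protein
#' (global-local) and scores the transfer as
#' \code{identity_fraction * coverage_fraction}, where identity is matches
#' over the aligned reference length and coverage is the aligned reference
#' length over the full reference length. A transfer is accepted when the
#' combined identity reaches \code{min_combined} (default 0.25: e.g. 50\%
#' identity over 50\% of the gene) and the raw alignment score clears
#' \code{min_score}, a declared significance proxy for a BLAST e-value
#' cutoff.
#'
#' @param query,reference protein strings.
#' @param min_combined acceptance threshold on the combined identity.
#' @param min_score minimum alignment score (match +2, mismatch -1, gap open
#'   5, gap extend 2).
#' @return list of class \code{TransferMatch}: \code{identity_fraction,
#'   coverage_fraction, combined_identity, score, accepted, class} (one of
#'   \code{perfect, length_mismatch, no_match}).
#' @export
combined_identity <- function(query, reference, min_combined = 0.25,
                              min_score = 15) {
  if (!nzchar(query) || !nzchar(reference))
    stop("combined_identity: empty protein sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(reference),
    type = "global-local", substitutionMatrix = aa_unit_matrix(),
    gapOpening = 5, gapExtension = 2)
  sr <- Biostrings::subject(pa)
  aligned_ref <- BiocGenerics::end(sr) - BiocGenerics::start(sr) + 1L
  m <- Biostrings::nmatch(pa)
  identity <- m / aligned_ref
  coverage <- aligned_ref / nchar(reference)
  combined <- identity * coverage
  sc <- Biostrings::score(pa)
  accepted <- combined >= min_combined && sc >= min_score
  cls <- if (accepted && identity == 1 && coverage == 1 &&
             nchar(query) == nchar(reference)) "perfect"
         else if (accepted) "length_mismatch" else "no_match"
  structure(list(identity_fraction = identity, coverage_fraction = coverage,
                 combined_identity = combined, score = sc,
                 accepted = accepted, class = cls),
            class = "TransferMatch")
}

#' Best-match annotation transfer between protein sets
#'
#' @param query_proteins,reference_proteins named character vectors of
#'   protein sequences.
#' @param ... thresholds passed to [combined_identity()].
#' @return data.frame: per query, the best-scoring accepted reference match
#'   (ties broken by reference id), or \code{no_match}.
#' @export
transfer_matches <- function(query_proteins, reference_proteins, ...) {
  ref_ids <- sort(names(reference_proteins))
  out <- lapply(names(query_proteins), function(qid) {
    best <- NULL; best_id <- NA_character_
    for (rid in ref_ids) {
      tm <- combined_identity(query_proteins[[qid]],
                              reference_proteins[[rid]], ...)
      if (tm$accepted &&
          (is.null(best) || tm$combined_identity > best$combined_identity)) {
        best <- tm; best_id <- rid
      }
    }
    data.frame(query_cds_id = qid, reference_cds_id = best_id,
               identity_fraction = if (is.null(best)) NA else best$identity_fraction,
               coverage_fraction = if (is.null(best)) NA else best$coverage_fraction,
               combined_identity = if (is.null(best)) NA else best$combined_identity,
               class = if (is.null(best)) "no_match" else best$class,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
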