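dna_unit_matrix <- function(match = 2, mismatch = -3) {
  Biostrings::nucleotideSubstitutionMatrix(match = match, mismatch = mismatch,
                                           baseOnly = FALSE)
}

#' Extract the two allele windows around a discrepancy
#'
#' Returns the sequence context of the site under the reference allele and
#' under the corrected allele, with \code{flank} bases each side (the
#' framing a confirmatory amplicon would use). Windows are truncated at the
#' ends of a linear genome and wrap on a circular one.
#'
#' @param genome the reference [genome_record()] the discrepancy was called
#'   on.
#' @param discrepancy list / one-row data.frame with \code{position, type,
#'   ref_allele, alt_allele}.
#' @param flank flank size in bp (default 250).
#' @return list with \code{reference}, \code{corrected} window strings and
#'   \code{truncated} flag.
#' @export
extract_window <- function(genome, discrepancy, flank = 250L) {
  d <- as.list(discrepancy)
  L <- genome$length
  site <- d$position
  lo <- site - flank
  hi <- site + flank  # inclusive
  truncated <- FALSE
  if (genome$circular) {
    dbl <- paste0(genome$sequence, genome$sequence)
    lo_m <- ((lo %% L) + L) %% L
    win <- substr(dbl, lo_m + 1L, lo_m + (hi - lo + 1L))
    site_off <- site - lo
  } else {
    if (lo < 0L || hi >= L) truncated <- TRUE
    lo <- max(0L, lo); hi <- min(L - 1L, hi)
    win <- substr(genome$sequence, lo + 1L, hi + 1L)
    site_off <- site - lo
  }
  corr <- switch(d$type,
    insertion = paste0(substr(win, 1L, site_off + 1L), d$alt_allele,
                       substr(win, site_off + 2L, nchar(win))),
    deletion = paste0(substr(win, 1L, site_off),
                      substr(win, site_off + nchar(d$ref_allele) + 1L,
                             nchar(win))),
    substitution = {
      w <- win; substr(w, site_off + 1L, site_off + 1L) <- d$alt_allele; w
    })
  list(reference = win, corrected = corr, truncated = truncated)
}

best_local_hit <- function(window, region, submat) {
  hit <- function(subj) Biostrings::pairwiseAlignment(
    Biostrings::DNAString(window), Biostrings::DNAString(subj),
    type = "local", substitutionMatrix = submat,
    gapOpening = 5, gapExtension = 2)
  fw <- hit(region)
  rv <- hit(revcomp(region))
  pa <- if (Biostrings::score(fw) >= Biostrings::score(rv)) fw else rv
  pr <- Biostrings::pattern(pa)
  aligned <- BiocGenerics::end(pr) - BiocGenerics::start(pr) + 1L
  list(score = Biostrings::score(pa),
       identity = Biostrings::nmatch(pa) / max(1L, aligned),
       coverage = aligned / nchar(window))
}

#' Which allele does a related genome support?
#'
#' Both allele windows are aligned locally (both strands) against the
#' homologous region of the related genome, located by k-mer seeding. The
#' region is \code{not_found} unless the better window aligns with at least
#' \code{min_identity} identity over \code{min_coverage} of its length;
#' otherwise the verdict goes to the strictly higher-scoring window, with
#' equal scores giving \code{neither} (determinism over optimism).
#'
#' @param window_corrected,window_reference strings from [extract_window()].
#' @param related_genome [genome_record()] of the related organism.
#' @param related_index optional prebuilt [build_index()] of it.
#' @param min_identity,min_coverage "found" thresholds (defaults 0.7 / 0.5).
#' @return list: \code{found}, \code{verdict} in \code{confirms_corrected,
#'   confirms_reference, neither, not_found}, and the two scores.
#' @export
allele_support <- function(window_corrected, window_reference, related_genome,
                           related_index = NULL, min_identity = 0.7,
                           min_coverage = 0.5) {
  if (is.null(related_index)) related_index <- build_index(related_genome)
  submat <- dna_unit_matrix()
  # seed with probe k-mers from the window centre, both strands
  k <- related_index$k
  locate <- function(win) {
    mid <- nchar(win) %/% 2L
    offs <- unique(pmax(1L, c(mid - 60L, mid - k %/% 2L, mid + 60L - k)))
    probes <- c(substring(win, offs, offs + k - 1L),
                substring(revcomp(win), offs, offs + k - 1L))
    pos <- unlist(lapply(probes, function(p) related_index$env[[p]]))
    if (is.null(pos) || !length(pos)) return(NULL)
    as.integer(round(median(pos)))
  }
  loc <- locate(window_corrected) %||% locate(window_reference)
  if (is.null(loc))
    return(list(found = FALSE, verdict = "not_found",
                score_corrected = NA_real_, score_reference = NA_real_))
  L <- related_genome$length
  span <- nchar(window_corrected) + 600L
  lo <- max(0L, loc - span %/% 2L - 300L); hi <- min(L, loc + span)
  region <- substr(related_genome$sequence, lo + 1L, hi)
  hc <- best_local_hit(window_corrected, region, submat)
  hr <- best_local_hit(window_reference, region, submat)
  best <- if (hc$score >= hr$score) hc else hr
  if (best$identity < min_identity || best$coverage < min_coverage)
    return(list(found = FALSE, verdict = "not_found",
                score_corrected = hc$score, score_reference = hr$score))
  verdict <- if (hc$score > hr$score) "confirms_corrected"
             else if (hr$score > hc$score) "confirms_reference"
             else "neither"
  list(found = TRUE, verdict = verdict,
       score_corrected = hc$score, score_reference = hr$score)
}

#' Protein-level identity fraction against a related product
#'
#' Global alignment of the corrected product against the related product.
#' \code{m} counts identically aligned residues; \code{n} is the alignment
#' length excluding overhangs of the related protein (so a truncated related
#' product yields \code{n} equal to the full corrected length). Reported as
#' the "m/n" identity fractions of cross-validation tables.
#'
#' @param corrected_protein,related_protein protein strings.
#' @return list with \code{m}, \code{n}, \code{identical}.
#' @export
protein_support <- function(corrected_protein, related_protein) {
  if (!nzchar(corrected_protein) || !nzchar(related_protein))
    stop("protein_support: empty protein sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(corrected_protein),
    Biostrings::AAString(related_protein),
    type = "global", substitutionMatrix = aa_unit_matrix(),
    gapOpening = 5, gapExtension = 2)
  # columns counted: the aligned region (internal gaps included) plus any
  # overhang of the corrected protein; overhangs of the related protein
  # (truncations) are excluded from neither m nor n's aligned span but do
  # not add columns of their own
  pr <- Biostrings::pattern(pa)
  ncols <- nchar(as.character(pr))  # aligned-region columns incl. gaps
  pat_span <- BiocGenerics::end(pr) - BiocGenerics::start(pr) + 1L
  overhang <- nchar(corrected_protein) - pat_span
  m <- Biostrings::nmatch(pa)
  n <- ncols + overhang
  list(m = m, n = n,
       identical = m == n &&
         nchar(corrected_protein) == nchar(related_protein))
}

#' Cross-validate corrected alleles against a related genome
#'
#' Runs [extract_window()] and [allele_support()] for every discrepancy and,
#' where a repaired product and a related product are available,
#' [protein_support()].
#'
#' @param discrepancies discrepancy data.frame.
#' @param genome the audited reference [genome_record()].
#' @param related_genome related [genome_record()].
#' @param related_features optional [cds_features()] of the related genome,
#'   used to pick the related product for protein-level comparison.
#' @param impacts optional [assess_impact()] table carrying repaired
#'   products.
#' @param flank window flank (default 250 bp).
#' @param ... thresholds for [allele_support()].
#' @return data.frame, one row per discrepancy: \code{position, found,
#'   verdict, m, n, identity, protein_identical}.
#' @export
cross_validate <- function(discrepancies, genome, related_genome,
                           related_features = NULL, impacts = NULL,
                           flank = 250L, ...) {
  n <- nrow(discrepancies)
  idx <- build_index(related_genome)
  related_prots <- NULL
  if (!is.null(related_features) && nrow(related_features)) {
    related_prots <- setNames(vapply(seq_len(nrow(related_features)),
      function(j) sub("\\*$", "", translate_feature(related_genome,
                                                    related_features[j, ])),
      ""), related_features$id)
  }
  rows <- lapply(seq_len(n), function(i) {
    d <- discrepancies[i, ]
    w <- extract_window(genome, d, flank)
    sup <- allele_support(w$corrected, w$reference, related_genome,
                          related_index = idx, ...)
    m <- NA_integer_; nn <- NA_integer_; ident <- NA
    if (!is.null(impacts) && !is.null(related_prots)) {
      imp <- impacts[impacts$position == d$position, , drop = FALSE]
      if (nrow(imp) && !is.na(imp$new_protein[1])) {
        tm <- transfer_matches(setNames(imp$new_protein[1], "q"),
                               related_prots)
        if (!is.na(tm$reference_cds_id[1])) {
          ps <- protein_support(imp$new_protein[1],
                                related_prots[[tm$reference_cds_id[1]]])
          m <- ps$m; nn <- ps$n; ident <- ps$identical
        }
      }
    }
    data.frame(position = d$position, found = sup$found,
               verdict = sup$verdict, m = m, n = nn,
               identity = ifelse(is.na(m), NA_character_,
                                 paste0(m, "/", nn)),
               protein_identical = ident, stringsAsFactors = FALSE)
  })
  if (!n)
    return(data.frame(position = integer(), found = logical(),
                      verdict = character(), m = integer(), n = integer(),
                      identity = character(), protein_identical = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
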