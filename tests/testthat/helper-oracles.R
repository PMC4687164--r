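# Independent oracles and constructed fixtures shared across tests.
# Oracles deliberately use different machinery than the implementation:
# brute-force string enumeration, naive scans, and Biostrings dynamic
# programming (the package's mapper uses its own compiled aligner).

random_dna <- function(n, gc = 0.31, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

rotate_right <- function(s) paste0(substr(s, nchar(s), nchar(s)),
                                   substr(s, 1, nchar(s) - 1))

# leftmost equivalent insertion anchor by exhaustive string insertion:
# try every anchor and every rotation of the allele, compare result strings
brute_left_insertion <- function(seqs, anchor, allele) {
  insert_at <- function(a, al) paste0(substr(seqs, 1, a + 1), al,
                                      substr(seqs, a + 2, nchar(seqs)))
  target <- insert_at(anchor, allele)
  rots <- character(nchar(allele))
  r <- allele
  for (i in seq_len(nchar(allele))) { rots[i] <- r; r <- rotate_right(r) }
  for (a in -1:anchor) {
    for (al in rots) {
      if (insert_at(a, al) == target) return(list(position = a, allele = al))
    }
  }
  stop("unreachable")
}

# naive maximal-run scanner
brute_run_length <- function(seqs, pos) {
  b <- substr(seqs, pos + 1, pos + 1)
  lo <- pos
  while (lo > 0 && substr(seqs, lo, lo) == b) lo <- lo - 1
  hi <- pos
  while (hi < nchar(seqs) - 1 && substr(seqs, hi + 2, hi + 2) == b) hi <- hi + 1
  list(base = b, length = hi - lo + 1, start = lo, end = hi + 1)
}

# Levenshtein fit alignment of a read inside a subject via Biostrings
# (unit costs; free subject ends). Returns edit distance and 0-based start.
oracle_fit <- function(read, subject) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 0, mismatch = -1,
                                                  baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(read), Biostrings::DNAString(subject),
    type = "global-local", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 1)
  list(edit = -as.integer(Biostrings::score(pa)),
       start = BiocGenerics::start(Biostrings::subject(pa)) - 1L)
}

# A frameshift-split locus in the style of a broken DNA-helicase gene:
# the corrected sequence carries one 722-aa ORF; the reference (one A
# deleted from an AAAA run after codon 279) annotates it as a 280-aa and a
# 433-aa product. Returns genomes, features, and the repairing discrepancy.
make_split_gene_locus <- function(seed = 42, flank = 400L) {
  set.seed(seed)
  sense <- setdiff(apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                     c("A","C","G","T")), 1, paste, collapse = ""),
                   c("TAA", "TAG", "TGA"))
  cod <- character(722)
  cod[1] <- "ATG"
  cod[2:721] <- sample(sense, 720, replace = TRUE)
  cod[279] <- "GGT"  # ends in T: bounds the A-run on the left
  cod[280] <- "AAA"
  cod[281] <- "ATA"
  cod[282] <- "AAA"
  cod[290] <- "ATG"  # start codon of the downstream annotated fragment
  cod[722] <- sample(sense, 1)
  gene_corr <- paste0(paste(cod, collapse = ""), "TAA")  # 2169 bp
  up <- random_dna(flank)
  down <- random_dna(flank)
  g0 <- flank  # gene start (0-based) in both genomes
  corrected_seq <- paste0(up, gene_corr, down)
  del_at <- g0 + 837L  # first A of codon 280
  reference_seq <- paste0(substr(corrected_seq, 1, del_at),
                          substr(corrected_seq, del_at + 2,
                                 nchar(corrected_seq)))
  reference <- genome_record("ref", reference_seq)
  corrected <- genome_record("ref_corrected", corrected_seq)
  feats <- cds_features(c("cds_A", "cds_B"), "ref",
                        c(g0, g0 + 866L), c(g0 + 843L, g0 + 2168L),
                        "+", 0L, c("helicase fragment 1", "helicase fragment 2"))
  disc <- data.frame(ref_id = "ref", position = g0 + 836L, type = "insertion",
                     ref_allele = "", alt_allele = "A", depth = 100L,
                     alt_support = 99L, alt_fraction = 0.99,
                     stringsAsFactors = FALSE)
  list(reference = reference, corrected = corrected, features = feats,
       discrepancy = disc, gene_start = g0)
}

# tiny deterministic simulation bundle reused by several tests
small_sim_bundle <- function(seed = 11, genome_length = 50000L,
                             n_errors = 20L, coverage = 50,
                             per_base_error = 0,
                             weights = c(`4` = 0.4, `5` = 0.4, `6` = 0.2),
                             n_cds = 15L) {
  cfg <- simulation_config(genome_length = genome_length, n_cds = n_cds,
                           n_planted_errors = n_errors,
                           coverage_target = coverage,
                           per_base_error = per_base_error,
                           run_length_weights = weights, seed = seed)
  sim <- simulate_genome(cfg)
  cor <- corrupt_assembly(sim$genome, sim$features, cfg)
  list(cfg = cfg, genome = sim$genome, features = sim$features,
       assembly = cor$assembly, truth = cor$truth,
       assembly_features = cor$features, map = cor$map)
}
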