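#' Configuration for the synthetic-data generator
#'
#' The generator emulates the statistical structure the audit assumes: an
#' AT-rich bacterial chromosome (default GC 0.31) whose "finished assembly"
#' has lost single bases from long homopolymer runs, plus a 2x250 bp
#' paired-end resequencing library at high coverage.
#'
#' \code{run_length_weights} is keyed by the homopolymer run length
#' \emph{observed at the discrepancy site on the corrupted assembly} (the
#' quantity the audit reports): planting a class-\code{w} error deletes one
#' base from a true-genome run of length \code{w + 1}. The default mass sits
#' on 4--8 with most weight at 6--8, so summaries reproduce the regime where
#' the large majority of discrepancies fall in runs longer than 4.
#'
#' @param genome_length genome size in bp.
#' @param gc_target target GC fraction (default 0.31).
#' @param n_cds number of planted non-overlapping CDSs.
#' @param cds_length_range CDS product length range in amino acids.
#' @param n_planted_errors number of errors planted in the assembly.
#' @param run_length_weights named numeric vector, probability mass per
#'   observed run-length class; must sum to 1.
#' @param substitution_fraction fraction of planted errors that are
#'   substitutions outside homopolymer runs (default 0: homopolymer
#'   under-calling produces essentially only insertions-to-be).
#' @param read_length read length in bp.
#' @param mean_insert,insert_sd fragment-length model (bp).
#' @param coverage_target expected fold coverage.
#' @param per_base_error per-base substitution error rate of simulated reads.
#' @param homopolymer_bias stay probability of the base-sampling Markov
#'   chain; 0 gives i.i.d. bases. The stationary base composition (hence GC)
#'   is unchanged, but run lengths lengthen, matching the run spectrum of
#'   AT-rich genomes.
#' @param circular simulate a circular chromosome?
#' @param end_margin on linear genomes, do not plant errors within this many
#'   bp of the sequence ends (coverage ramps down there); defaults to
#'   \code{mean_insert}.
#' @param seed integer seed governing all stages through derived streams
#'   (genome = seed+1, corruption = seed+2, reads = seed+3).
#' @return a \code{SimulationConfig} list.
#' @export
simulation_config <- function(genome_length = 200000L, gc_target = 0.31,
                              n_cds = 60L, cds_length_range = c(100L, 400L),
                              n_planted_errors = 100L,
                              run_length_weights = c(`4` = 0.07, `5` = 0.08,
                                                     `6` = 0.40, `7` = 0.25,
                                                     `8` = 0.20),
                              substitution_fraction = 0,
                              read_length = 250L, mean_insert = 600L,
                              insert_sd = 60L, coverage_target = 200,
                              per_base_error = 0.002,
                              homopolymer_bias = 0.15, circular = FALSE,
                              end_margin = NULL, seed = 1L) {
  if (gc_target <= 0 || gc_target >= 1) stop("simulation_config: need 0 < gc_target < 1")
  if (coverage_target < 0) stop("simulation_config: coverage_target must be >= 0")
  if (abs(sum(run_length_weights) - 1) > 1e-8)
    stop("simulation_config: run_length_weights must sum to 1")
  if (is.null(names(run_length_weights)) ||
      anyNA(suppressWarnings(as.integer(names(run_length_weights)))))
    stop("simulation_config: run_length_weights must be named by run length")
  if (substitution_fraction < 0 || substitution_fraction > 1)
    stop("simulation_config: substitution_fraction in [0,1]")
  if (read_length > mean_insert)
    stop("simulation_config: read_length must not exceed mean_insert")
  if (homopolymer_bias < 0 || homopolymer_bias >= 1)
    stop("simulation_config: homopolymer_bias in [0,1)")
  structure(list(genome_length = as.integer(genome_length),
                 gc_target = gc_target, n_cds = as.integer(n_cds),
                 cds_length_range = as.integer(cds_length_range),
                 n_planted_errors = as.integer(n_planted_errors),
                 run_length_weights = run_length_weights,
                 substitution_fraction = substitution_fraction,
                 read_length = as.integer(read_length),
                 mean_insert = as.integer(mean_insert),
                 insert_sd = as.numeric(insert_sd),
                 coverage_target = coverage_target,
                 per_base_error = per_base_error,
                 homopolymer_bias = homopolymer_bias,
                 circular = isTRUE(circular),
                 end_margin = as.integer(end_margin %||% mean_insert),
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

base_probs <- function(gc) c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)

# sense codons weighted by the product of base probabilities under the GC
# target, so coding regions do not bias realized genome GC
codon_table <- function(gc) {
  codons <- apply(expand.grid(.ga_bases, .ga_bases, .ga_bases,
                              stringsAsFactors = FALSE), 1L, paste, collapse = "")
  stops <- c("TAA", "TAG", "TGA")
  sense <- setdiff(codons, stops)
  p <- base_probs(gc)
  w <- vapply(strsplit(sense, ""), function(b) prod(p[b]), 0)
  list(sense = sense, weights = w / sum(w), stops = stops)
}

#' Simulate a genome with planted CDSs
#'
#' Background bases come from a stationary Markov chain with stay probability
#' \code{homopolymer_bias} and innovation distribution set by
#' \code{gc_target}; planted CDSs (start codon, stop-free sense codons
#' weighted to preserve GC, stop codon) then overwrite non-overlapping
#' intervals. Deterministic under the config seed.
#'
#' @param config a [simulation_config()].
#' @return list with \code{genome} (a [genome_record()]) and \code{features}
#'   (a [cds_features()] table).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 1L)
  L <- config$genome_length
  p <- base_probs(config$gc_target)
  innov <- sample(.ga_bases, L, replace = TRUE, prob = p)
  if (config$homopolymer_bias > 0) {
    stay <- runif(L) < config$homopolymer_bias
    stay[1L] <- FALSE
    iidx <- which(!stay)
    chars <- innov[iidx[findInterval(seq_len(L), iidx)]]
  } else chars <- innov
  ct <- codon_table(config$gc_target)
  n_cds <- config$n_cds
  feats <- empty_features()
  if (n_cds > 0L) {
    aalen <- sample(seq(config$cds_length_range[1], config$cds_length_range[2]),
                    n_cds, replace = TRUE)
    ntlen <- 3L * (aalen + 1L)
    gap_min <- 20L
    free <- L - sum(ntlen) - gap_min * (n_cds + 1L)
    if (free < 0L)
      stop("simulate_genome: CDS demand exceeds genome length")
    # stick-breaking placement: spread the free space over the gaps at
    # random, which always succeeds when the features fit at all
    cuts <- sort(sample.int(free + 1L, n_cds, replace = TRUE) - 1L)
    starts <- integer(n_cds)
    cursor <- 0L
    prev_cut <- 0L
    for (i in seq_len(n_cds)) {
      cursor <- cursor + gap_min + (cuts[i] - prev_cut)
      starts[i] <- cursor
      cursor <- cursor + ntlen[i]
      prev_cut <- cuts[i]
    }
    strands <- sample(c("+", "-"), n_cds, replace = TRUE)
    for (i in seq_len(n_cds)) {
      body <- sample(ct$sense, aalen[i] - 1L, replace = TRUE, prob = ct$weights)
      orf <- paste0("ATG", paste(body, collapse = ""), "TAA")
      if (strands[i] == "-") orf <- revcomp(orf)
      chars[(starts[i] + 1L):(starts[i] + ntlen[i])] <- strsplit(orf, "")[[1]]
    }
    ord <- order(starts)
    feats <- cds_features(sprintf("gene_%04d", seq_len(n_cds)), "sim_genome",
                          starts[ord], starts[ord] + ntlen[ord],
                          strands[ord], 0L,
                          sprintf("simulated protein %d", seq_len(n_cds)))
  }
  genome <- genome_record("sim_genome", paste(chars, collapse = ""),
                          circular = config$circular)
  list(genome = genome, features = feats)
}

#' Corrupt a genome into a homopolymer-deficient "finished assembly"
#'
#' Emulates the under-calling of homopolymer runs by long-read basecalling:
#' for each planted error a run-length class \code{w} is drawn from
#' \code{run_length_weights}, a true-genome homopolymer run of length
#' \code{w + 1} is selected without replacement, and one base is deleted from
#' it, so the read-vs-assembly audit should call an insertion at a run of
#' observed length \code{w}. Optional substitutions are placed outside runs.
#' Truth positions are stored left-normalized in corrupted-assembly
#' coordinates. The planted annotation is lifted onto the corrupted assembly;
#' coding features broken by a deletion are re-fragmented into the two
#' pseudogene pieces an annotation pipeline would emit (the piece up to the
#' premature stop in the annotated frame, and the downstream piece in the
#' true frame), which is what makes split-gene merging observable downstream.
#'
#' @param genome,features output of [simulate_genome()].
#' @param config the same [simulation_config()].
#' @return list with \code{assembly} (corrupted [genome_record()]),
#'   \code{truth} (truth table data.frame), \code{features} (annotation
#'   lifted onto the assembly), \code{map} (the true-to-corrupted
#'   \code{CoordinateMap}).
#' @export
corrupt_assembly <- function(genome, features, config) {
  stopifnot(inherits(genome, "GenomeRecord"), inherits(config, "SimulationConfig"))
  set.seed(config$seed + 2L)
  L <- genome$length
  n <- config$n_planted_errors
  seqs <- genome$sequence
  if (n == 0L) {
    asm <- genome_record(paste0(genome$id, "_assembly"), seqs, genome$circular)
    lifted <- features
    if (nrow(lifted)) lifted$genome_id <- asm$id
    return(list(assembly = asm,
                truth = empty_truth(),
                features = lifted,
                map = build_coordinate_map(empty_discrepancies(), L)))
  }
  n_sub <- as.integer(round(config$substitution_fraction * n))
  n_del <- n - n_sub
  margin <- if (genome$circular) 0L else config$end_margin
  runs <- homopolymer_runs(seqs)
  classes <- sort(as.integer(names(config$run_length_weights)))
  w <- config$run_length_weights[as.character(classes)]
  eligible <- runs[runs$base %in% .ga_bases &
                   runs$start > margin & runs$end < L - margin &
                   (runs$length - 1L) %in% classes, , drop = FALSE]
  avail <- table(factor(eligible$length - 1L, levels = classes))
  draw <- as.vector(stats::rmultinom(1L, n_del, w))
  if (any(draw > avail)) {
    msg <- paste(sprintf("class %d: need %d, have %d", classes, draw,
                         as.integer(avail)), collapse = "; ")
    stop("corrupt_assembly: insufficient eligible homopolymer runs (", msg, ")")
  }
  sel <- do.call(rbind, lapply(seq_along(classes), function(i) {
    pool <- eligible[eligible$length - 1L == classes[i], , drop = FALSE]
    pool[sample.int(nrow(pool), draw[i]), , drop = FALSE]
  }))
  sel <- sel[order(sel$start), , drop = FALSE]
  del_pos <- sel$start  # delete the first base of each selected run
  # substitutions: isolated positions away from selected runs
  sub_pos <- integer(0); sub_new <- character(0)
  if (n_sub > 0L) {
    iso <- runs[runs$length == 1L & runs$base %in% .ga_bases &
                runs$start > margin + 1L & runs$end < L - margin - 1L,
                , drop = FALSE]
    far <- vapply(iso$start, function(p) all(abs(p - del_pos) > 12L), TRUE)
    iso <- iso[far, , drop = FALSE]
    if (nrow(iso) < n_sub)
      stop("corrupt_assembly: insufficient isolated positions for substitutions")
    pick <- iso[sample.int(nrow(iso), n_sub), , drop = FALSE]
    sub_pos <- pick$start
    chars_nb <- cbind(substr(rep(seqs, n_sub), sub_pos, sub_pos),
                      substr(rep(seqs, n_sub), sub_pos + 2L, sub_pos + 2L),
                      pick$base)
    sub_new <- vapply(seq_len(n_sub), function(i)
      sample(setdiff(.ga_bases, chars_nb[i, ]), 1L), "")
  }
  chars <- strsplit(seqs, "")[[1]]
  if (n_sub > 0L) chars[sub_pos + 1L] <- sub_new
  chars <- chars[-(del_pos + 1L)]
  asm_seq <- paste(chars, collapse = "")
  asm <- genome_record(paste0(genome$id, "_assembly"), asm_seq, genome$circular)
  shift <- function(p) p - findInterval(p - 0.5, del_pos)  # #deletions strictly before p
  site_feats <- function(p) {
    if (nrow(features) == 0L) return(list(inc = FALSE, ids = ""))
    hit <- features$start <= p & p < features$end
    list(inc = any(hit), ids = paste(features$id[hit], collapse = ","))
  }
  del_ctx <- lapply(sel$start, site_feats)
  truth_del <- data.frame(
    position = as.integer(shift(sel$start) - 1L),  # left-normalized anchor
    type = "insertion",
    base = sel$base,
    run_length_at_site = as.integer(sel$length - 1L),
    in_cds = vapply(del_ctx, `[[`, TRUE, "inc"),
    affected_cds_ids = vapply(del_ctx, `[[`, "", "ids"),
    stringsAsFactors = FALSE)
  truth <- truth_del
  if (n_sub > 0L) {
    sub_ctx <- lapply(sub_pos, site_feats)
    truth_sub <- data.frame(
      position = as.integer(shift(sub_pos)),
      type = "substitution",
      base = substr(rep(seqs, n_sub), sub_pos + 1L, sub_pos + 1L),
      run_length_at_site = 1L,
      in_cds = vapply(sub_ctx, `[[`, TRUE, "inc"),
      affected_cds_ids = vapply(sub_ctx, `[[`, "", "ids"),
      stringsAsFactors = FALSE)
    truth <- rbind(truth, truth_sub)
  }
  truth <- truth[order(truth$position), , drop = FALSE]
  rownames(truth) <- NULL
  # lift annotation onto the corrupted assembly, re-fragmenting broken CDSs
  evts <- data.frame(position = del_pos, type = "deletion",
                     ref_allele = sel$base, alt_allele = "",
                     stringsAsFactors = FALSE)
  cmap <- build_coordinate_map(evts, L)
  lifted <- empty_features()
  if (nrow(features)) {
    lf <- lift_features(features, cmap)
    lf$anomaly <- NULL
    lf$genome_id <- asm$id
    pieces <- lapply(seq_len(nrow(lf)), function(i) {
      ndel <- sum(del_pos >= features$start[i] & del_pos < features$end[i])
      if (ndel == 0L) return(lf[i, , drop = FALSE])
      refragment_cds(asm_seq, lf[i, , drop = FALSE])
    })
    lifted <- do.call(rbind, pieces)
    class(lifted) <- c("CdsFeatures", "data.frame")
    rownames(lifted) <- NULL
  }
  list(assembly = asm, truth = truth, features = lifted, map = cmap)
}

empty_truth <- function() data.frame(position = integer(), type = character(),
                                     base = character(),
                                     run_length_at_site = integer(),
                                     in_cds = logical(),
                                     affected_cds_ids = character(),
                                     stringsAsFactors = FALSE)

# Split a frameshift-broken CDS on the corrupted assembly into the two
# fragments an ORF-based annotator would report: [start .. premature stop] in
# the annotated frame, and a 3'-anchored fragment in the true frame opening
# at a start codon. Falls back to the single lifted feature when no clean
# second fragment exists.
refragment_cds <- function(asm_seq, feat) {
  s <- feat$start; e <- feat$end
  region <- substr(asm_seq, s + 1L, e)
  if (feat$strand == "-") region <- revcomp(region)
  Lloc <- nchar(region)
  aa <- translate_dna(substr(region, 1L, Lloc - Lloc %% 3L))
  stop1 <- regexpr("*", aa, fixed = TRUE)[1]
  if (stop1 < 0L || stop1 * 3L >= Lloc) return(feat)
  f1_end <- stop1 * 3L
  f2_start <- NA_integer_
  p <- f1_end + (Lloc - f1_end) %% 3L  # candidate starts in the 3'-anchored frame
  while (p + 3L <= Lloc) {
    cod <- substr(region, p + 1L, p + 3L)
    if (cod %in% c("ATG", "GTG", "TTG")) {
      tailaa <- translate_dna(substr(region, p + 1L, Lloc))
      internal <- substr(tailaa, 1L, nchar(tailaa) - 1L)
      if (!grepl("*", internal, fixed = TRUE)) { f2_start <- p; break }
    }
    p <- p + 3L
  }
  if (is.na(f2_start)) return(feat)
  loc2gen <- function(a, b) if (feat$strand == "+") c(s + a, s + b) else c(e - b, e - a)
  i1 <- loc2gen(0L, f1_end); i2 <- loc2gen(f2_start, Lloc)
  out <- cds_features(paste0(feat$id, c("_1", "_2")), feat$genome_id,
                      c(i1[1], i2[1]), c(i1[2], i2[2]),
                      feat$strand, 0L, feat$product)
  if (feat$strand == "-") out <- out[order(out$start), , drop = FALSE]
  out
}

#' Simulate paired-end reads
#'
#' Fragments are sampled uniformly (wrapping on circular genomes), read in FR
#' orientation, and subjected to independent per-base substitution errors at
#' \code{per_base_error}; quality strings carry the Phred score implied by
#' that rate. The number of pairs is chosen so the expected coverage equals
#' \code{coverage_target}.
#'
#' @param genome a [genome_record()].
#' @param config a [simulation_config()].
#' @return data.frame with columns \code{id, seq1, qual1, seq2, qual2}.
#' @export
simulate_reads <- function(genome, config) {
  stopifnot(inherits(genome, "GenomeRecord"), inherits(config, "SimulationConfig"))
  set.seed(config$seed + 3L)
  L <- genome$length; rl <- config$read_length
  if (L <= config$mean_insert && !genome$circular)
    stop("simulate_reads: genome shorter than mean_insert")
  npairs <- as.integer(round(L * config$coverage_target / (2 * rl)))
  if (npairs == 0L)
    return(data.frame(id = character(), seq1 = character(), qual1 = character(),
                      seq2 = character(), qual2 = character(),
                      stringsAsFactors = FALSE))
  ins <- pmax(rl, as.integer(round(rnorm(npairs, config$mean_insert,
                                         config$insert_sd))))
  if (genome$circular) {
    ins <- pmin(ins, L)
    start <- sample.int(L, npairs, replace = TRUE) - 1L
    doubled <- paste0(genome$sequence, substr(genome$sequence, 1L, max(ins)))
    frag <- substring(doubled, start + 1L, start + ins)
  } else {
    ins <- pmin(ins, L)
    start <- vapply(ins, function(x) sample.int(L - x + 1L, 1L), 0L) - 1L
    frag <- substring(genome$sequence, start + 1L, start + ins)
  }
  r1 <- substr(frag, 1L, rl)
  r2 <- revcomp(substr(frag, nchar(frag) - rl + 1L, nchar(frag)))
  e <- config$per_base_error
  if (e > 0) {
    r1 <- add_read_errors(r1, e)
    r2 <- add_read_errors(r2, e)
  }
  q <- if (e > 0) min(40L, as.integer(round(-10 * log10(e)))) else 40L
  qstr <- strrep(rawToChar(as.raw(q + 33L)), rl)
  data.frame(id = sprintf("read_%07d", seq_len(npairs)),
             seq1 = r1, qual1 = qstr, seq2 = r2, qual2 = qstr,
             stringsAsFactors = FALSE)
}

add_read_errors <- function(reads, e) {
  rl <- nchar(reads[1])
  nerr <- rbinom(length(reads), rl, e)
  for (i in which(nerr > 0L)) {
    pos <- sample.int(rl, nerr[i])
    for (p in pos) {
      old <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(.ga_bases, old), 1L)
    }
  }
  reads
}

#' Score called discrepancies against the truth table
#'
#' A call matches a truth record iff it has the same left-normalized
#' position, type and allele. Both inputs must be in corrupted-assembly
#' coordinates; when \code{assembly} is supplied, indel calls are checked to
#' be left-normalized and a contract error is raised otherwise.
#'
#' @param calls discrepancy data.frame from [call_discrepancies()].
#' @param truth truth table from [corrupt_assembly()].
#' @param assembly optional [genome_record()] used to verify normalization.
#' @return list with \code{precision}, \code{recall}, counts and a per-class
#'   breakdown. Empty calls against empty truth score 1/1; empty calls
#'   against non-empty truth score precision 1 (vacuous), recall 0.
#' @export
score_recovery <- function(calls, truth, assembly = NULL) {
  if (!is.null(assembly)) {
    idx <- which(calls$type %in% c("insertion", "deletion"))
    for (i in idx) {
      nd <- normalize_indel(as.list(calls[i, ]), assembly)
      if (nd$position != calls$position[i])
        stop("score_recovery: call at position ", calls$position[i],
             " is not left-normalized")
    }
  }
  call_allele <- ifelse(calls$type == "deletion", calls$ref_allele,
                        calls$alt_allele)
  key_c <- paste(calls$position, calls$type, call_allele)
  key_t <- paste(truth$position, truth$type, truth$base)
  tp <- sum(key_c %in% key_t)
  fp <- length(key_c) - tp
  fn <- length(key_t) - sum(key_t %in% key_c)
  precision <- if (length(key_c) == 0L) 1 else tp / (tp + fp)
  recall <- if (length(key_t) == 0L) 1 else tp / (tp + fn)
  classes <- sort(unique(c(calls$type, truth$type)))
  by_class <- do.call(rbind, lapply(classes, function(cl) {
    kc <- key_c[calls$type == cl]; kt <- key_t[truth$type == cl]
    data.frame(type = cl, tp = sum(kc %in% kt),
               fp = sum(!kc %in% kt), fn = sum(!kt %in% kc),
               stringsAsFactors = FALSE)
  }))
  list(precision = precision, recall = recall, tp = tp, fp = fp, fn = fn,
       by_class = by_class)
}
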