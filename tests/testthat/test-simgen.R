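test_that("genome simulation is deterministic, GC-faithful and plants clean ORFs", {
  cfg <- simulation_config(genome_length = 10000L, n_cds = 5L,
                           n_planted_errors = 0L, seed = 1L)
  a <- simulate_genome(cfg)
  b <- simulate_genome(cfg)
  expect_identical(a$genome$sequence, b$genome$sequence)
  expect_identical(a$features, b$features)

  big <- simulate_genome(simulation_config(genome_length = 100000L,
                                           n_cds = 30L, seed = 2L))
  gc <- mean(strsplit(big$genome$sequence, "")[[1]] %in% c("G", "C"))
  expect_gte(gc, 0.29)
  expect_lte(gc, 0.33)

  f <- a$features
  expect_equal(nrow(f), 5L)
  expect_true(all((f$end - f$start) %% 3 == 0))
  o <- order(f$start)
  expect_true(all(f$end[o][-5] <= f$start[o][-1]))  # pairwise disjoint
  for (i in seq_len(5)) {
    aa <- translate_feature(a$genome, f[i, ])
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("*", substr(aa, 1, nchar(aa) - 1), fixed = TRUE))
  }
})

test_that("assembly corruption deletes one base per selected run with exact bookkeeping", {
  cfg <- simulation_config(genome_length = 20000L, n_cds = 5L,
                           n_planted_errors = 0L, seed = 3L)
  sim <- simulate_genome(cfg)
  cor0 <- corrupt_assembly(sim$genome, sim$features, cfg)
  expect_identical(cor0$assembly$sequence, sim$genome$sequence)
  expect_equal(nrow(cor0$truth), 0L)

  cfgk <- simulation_config(genome_length = 50000L, n_cds = 10L,
                            n_planted_errors = 12L, seed = 4L,
                            run_length_weights = c(`4` = 0.5, `5` = 0.5))
  simk <- simulate_genome(cfgk)
  cork <- corrupt_assembly(simk$genome, simk$features, cfgk)
  # conservation: corrupted length = true length - #deletions
  expect_equal(cork$assembly$length, simk$genome$length - 12L)
  expect_equal(nrow(cork$truth), 12L)
  expect_true(all(cork$truth$type == "insertion"))
  # every truth record reconstructs the true genome locally: inserting the
  # base after the anchor restores a substring of the true sequence
  # (sites closer than a window width to another site are skipped: their
  # windows straddle a second planted deletion)
  iso <- vapply(seq_len(nrow(cork$truth)), function(i)
    min(abs(cork$truth$position[-i] - cork$truth$position[i])) > 70L, TRUE)
  for (i in which(iso)) {
    t <- cork$truth[i, ]
    win <- extract_window(cork$assembly, list(position = t$position,
                                              type = "insertion",
                                              ref_allele = "",
                                              alt_allele = t$base), 30)
    expect_true(grepl(win$corrected, simk$genome$sequence, fixed = TRUE),
                info = paste("truth row", i))
    # observed run length on the corrupted assembly
    ann <- run_length_at(cork$assembly, t$position, t$base, "insertion")
    expect_equal(ann$run_length, t$run_length_at_site)
  }
  expect_error(corrupt_assembly(simk$genome, simk$features,
    simulation_config(genome_length = 50000L, n_planted_errors = 5000L,
                      seed = 4L, run_length_weights = c(`8` = 1))),
    "insufficient eligible")
})

test_that("a deletion in a CDS yields an in-CDS insertion truth record on a micro-genome", {
  # run of 6 Ts inside a planted CDS: Leu-Phe codons TTA TTT TTC give TTTTT
  # after the A?  Construct explicitly instead: CDS with codons CTT TTT G..
  up <- "CCGGACGATCGAC"
  gene <- paste0("ATG", "CTT", "TTT", "TGG", "GAC", "TAA")  # TTTTTT run? C TTTTT TGG -> run of 5 T then T: check
  down <- "GACCAGGACTAAGGC"
  g <- genome_record("m", paste0(up, gene, down))
  runs <- homopolymer_runs(g)
  run6 <- runs[runs$base == "T" & runs$length == 6L, ]
  expect_equal(nrow(run6), 1L)  # CTT TTT T = 6 Ts
  feats <- cds_features("cds1", "m", nchar(up), nchar(up) + nchar(gene), "+")
  cfg <- simulation_config(genome_length = nchar(g$sequence),
                           n_planted_errors = 1L,
                           run_length_weights = c(`5` = 1),
                           end_margin = 0L, seed = 1L)
  cor <- corrupt_assembly(g, feats, cfg)
  t <- cor$truth
  expect_equal(nrow(t), 1L)
  expect_equal(t$type, "insertion")
  expect_equal(t$base, "T")
  expect_equal(t$run_length_at_site, 5L)   # measured on the corrupted assembly
  expect_true(t$in_cds)
  expect_match(t$affected_cds_ids, "cds1")
  expect_equal(t$position, run6$start - 1L)  # left-normalized anchor
  # direct string comparison: deleting one T from the run
  expect_identical(cor$assembly$sequence,
                   paste0(substr(g$sequence, 1, run6$start),
                          substr(g$sequence, run6$start + 2,
                                 nchar(g$sequence))))
})

test_that("simulated reads are exact substrings at zero error and hit target coverage", {
  cfg <- simulation_config(genome_length = 10000L, n_cds = 0L,
                           n_planted_errors = 0L, coverage_target = 50,
                           per_base_error = 0, seed = 5L)
  g <- simulate_genome(cfg)$genome
  reads <- simulate_reads(g, cfg)
  expect_equal(nrow(reads), round(10000 * 50 / 500))
  for (i in sample(nrow(reads), 20)) {
    expect_true(grepl(reads$seq1[i], g$sequence, fixed = TRUE))
    expect_true(grepl(revcomp(reads$seq2[i]), g$sequence, fixed = TRUE))
  }
  # observed depth within 5% of target
  al <- map_reads(reads, build_index(g))
  depth <- depth_vector(al, g)
  expect_lt(abs(mean(depth) - 50) / 50, 0.05)

  cfg0 <- simulation_config(genome_length = 10000L, n_cds = 0L,
                            n_planted_errors = 0L, coverage_target = 0,
                            seed = 5L)
  r0 <- simulate_reads(g, cfg0)
  expect_equal(nrow(r0), 0L)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_read_pairs(r0, f1, f2)
  expect_true(file.exists(f1) && file.info(f1)$size == 0)
})

test_that("recovery scoring matches on normalized position, type and allele", {
  truth <- data.frame(position = c(10L, 50L), type = "insertion",
                      base = c("A", "T"), stringsAsFactors = FALSE)
  calls <- data.frame(position = c(10L, 50L), type = "insertion",
                      ref_allele = "", alt_allele = c("A", "T"),
                      stringsAsFactors = FALSE)
  s <- score_recovery(calls, truth)
  expect_equal(s$precision, 1)
  expect_equal(s$recall, 1)

  s0 <- score_recovery(calls[0, ], truth)
  expect_equal(s0$precision, 1)   # vacuous
  expect_equal(s0$recall, 0)
  se <- score_recovery(calls[0, ], truth[0, ])
  expect_equal(se$precision, 1)
  expect_equal(se$recall, 1)

  # off-by-one inside a homopolymer: mismatch without normalization,
  # match after normalizing against the assembly
  g <- genome_record("m", "GGCAAAATCGG")
  off <- data.frame(position = 5L, type = "insertion", ref_allele = "",
                    alt_allele = "A", stringsAsFactors = FALSE)
  truth1 <- data.frame(position = 2L, type = "insertion", base = "A",
                       stringsAsFactors = FALSE)
  expect_equal(score_recovery(off, truth1)$recall, 0)
  expect_error(score_recovery(off, truth1, assembly = g), "not left-normalized")
  nn <- as.data.frame(normalize_indel(as.list(off[1, ]), g),
                      stringsAsFactors = FALSE)
  expect_equal(score_recovery(nn, truth1, assembly = g)$recall, 1)
})
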