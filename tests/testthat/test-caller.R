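test_that("left-normalization matches the brute-force string oracle and is idempotent", {
  # spec-style micro case: "CAAAT", insertion A after position 3 -> after 0
  g <- genome_record("m", "CAAAT")
  d <- normalize_indel(list(position = 3L, type = "insertion",
                            ref_allele = "", alt_allele = "A"), g)
  expect_equal(d$position, 0L)
  d2 <- normalize_indel(d, g)
  expect_equal(d2$position, 0L)  # idempotent
  dg <- normalize_indel(list(position = 2L, type = "insertion",
                             ref_allele = "", alt_allele = "G"), g)
  expect_equal(dg$position, 2L)  # no equal neighbour: unchanged

  # 1000 random indels in random genomes vs the exhaustive oracle;
  # normalization must preserve the corrected string
  set.seed(71)
  insert_at <- function(seqs, a, al) paste0(substr(seqs, 1, a + 1), al,
                                            substr(seqs, a + 2, nchar(seqs)))
  for (rep in seq_len(1000L)) {
    L <- sample(30:60, 1)
    seqs <- random_dna(L, gc = runif(1, 0.2, 0.6))
    if (rep %% 2L == 0L) {
      a <- sample(0:(L - 1), 1)
      allele <- paste(sample(c("A", "C", "G", "T"),
                             sample(1:3, 1), replace = TRUE), collapse = "")
      d <- normalize_indel(list(position = a, type = "insertion",
                                ref_allele = "", alt_allele = allele), seqs)
      o <- brute_left_insertion(seqs, a, allele)
      expect_equal(d$position, o$position)
      expect_identical(insert_at(seqs, d$position, d$alt_allele),
                       insert_at(seqs, a, allele))
      dd <- normalize_indel(d, seqs)
      expect_equal(dd$position, d$position)
    } else {
      p <- sample(1:(L - 3), 1)
      len <- sample(1:2, 1)
      ref <- substr(seqs, p + 1, p + len)
      d <- normalize_indel(list(position = p, type = "deletion",
                                ref_allele = ref, alt_allele = ""), seqs)
      # deleting at the normalized position yields the same string
      del_at <- function(q, l) paste0(substr(seqs, 1, q),
                                      substr(seqs, q + l + 1, nchar(seqs)))
      expect_identical(del_at(d$position, nchar(d$ref_allele)),
                       del_at(p, len))
      dd <- normalize_indel(d, seqs)
      expect_equal(dd$position, d$position)
    }
  }
  expect_error(normalize_indel(list(position = 0L, type = "deletion",
                                    ref_allele = "G", alt_allele = ""),
                               genome_record("x", "CCCC")),
               "inconsistent")
})

test_that("consensus calling respects depth and fraction thresholds", {
  # hand-built pileup via constructed reads: 20 reads carry +T, 5 do not
  g <- genome_record("g", random_dna(500, seed = 43))
  with_ins <- paste0(substr(g$sequence, 21, 70), "T",
                     substr(g$sequence, 71, 140))
  without <- substr(g$sequence, 21, 140)
  idx <- build_index(g, k = 11L)
  al <- map_reads(c(rep(with_ins, 20), rep(without, 5)), idx)
  pu <- build_pileup(al, g)
  disc <- call_discrepancies(pu, g, min_depth = 10L, min_alt_fraction = 0.8)
  expect_equal(nrow(disc), 1L)
  expect_equal(disc$type, "insertion")
  expect_equal(disc$alt_allele, "T")
  expect_equal(disc$alt_fraction, 0.8)
  # at 50/50 no call is made at the default threshold
  al2 <- map_reads(c(rep(with_ins, 10), rep(without, 10)), idx)
  disc2 <- call_discrepancies(build_pileup(al2, g), g)
  expect_equal(nrow(disc2), 0L)
  expect_error(call_discrepancies(pu, g, min_alt_fraction = 0.5),
               "exceed 0.5")
})

test_that("planted deletions are recovered as insertion calls matching the truth table", {
  bundle <- small_sim_bundle(seed = 47, genome_length = 60000L,
                             n_errors = 50L, coverage = 60,
                             per_base_error = 0, n_cds = 15L,
                             weights = c(`4` = 0.3, `5` = 0.4, `6` = 0.3))
  reads <- simulate_reads(bundle$genome, bundle$cfg)
  al <- map_reads(reads, build_index(bundle$assembly))
  pu <- build_pileup(al, bundle$assembly)
  disc <- call_discrepancies(pu, bundle$assembly)
  expect_equal(nrow(disc), 50L)
  expect_true(all(disc$type == "insertion"))
  sc <- score_recovery(disc, bundle$truth, assembly = bundle$assembly)
  expect_equal(sc$precision, 1)
  expect_equal(sc$recall, 1)

  # fixed point: applying the called corrections and re-simulating
  # error-free reads yields zero calls
  corrected <- apply_corrections(bundle$assembly, disc)$genome
  expect_identical(corrected$sequence, bundle$genome$sequence)
  cfg2 <- simulation_config(genome_length = corrected$length, n_cds = 0L,
                            n_planted_errors = 0L, coverage_target = 40,
                            per_base_error = 0, seed = 48L)
  reads2 <- simulate_reads(corrected, cfg2)
  al2 <- map_reads(reads2, build_index(corrected))
  disc2 <- call_discrepancies(build_pileup(al2, corrected), corrected)
  expect_equal(nrow(disc2), 0L)
})

test_that("planted substitutions and deletions are called symmetrically", {
  cfg <- simulation_config(genome_length = 40000L, n_cds = 10L,
                           n_planted_errors = 20L, coverage_target = 50,
                           per_base_error = 0, substitution_fraction = 0.3,
                           run_length_weights = c(`4` = 0.5, `5` = 0.5),
                           seed = 53L)
  sim <- simulate_genome(cfg)
  cor <- corrupt_assembly(sim$genome, sim$features, cfg)
  expect_equal(sum(cor$truth$type == "substitution"), 6L)
  reads <- simulate_reads(sim$genome, cfg)
  al <- map_reads(reads, build_index(cor$assembly))
  disc <- call_discrepancies(build_pileup(al, cor$assembly), cor$assembly)
  sc <- score_recovery(disc, cor$truth, assembly = cor$assembly)
  expect_equal(sc$precision, 1)
  expect_equal(sc$recall, 1)
  expect_equal(sort(unique(disc$type)), c("insertion", "substitution"))
})

test_that("the large-INDEL screen flags constructed events and stays silent on uniform data", {
  truth <- random_dna(20000, seed = 21)
  ref <- genome_record("ref", truth)
  idx <- build_index(ref)
  cfg <- simulation_config(genome_length = 20500L, n_cds = 0L,
                           n_planted_errors = 0L, coverage_target = 40,
                           per_base_error = 0, seed = 5L)
  # uniform coverage: no candidates
  reads0 <- simulate_reads(ref, simulation_config(genome_length = 20000L,
    n_cds = 0L, n_planted_errors = 0L, coverage_target = 40,
    per_base_error = 0, seed = 5L))
  pu0 <- build_pileup(map_reads(reads0, idx), ref)
  expect_equal(nrow(screen_large_indels(pu0)), 0L)

  # 500 bp present in the sample but absent from the reference:
  # soft-clip cluster at the junction (position 10000)
  novel <- random_dna(500, seed = 22)
  sample_g <- genome_record("s", paste0(substr(truth, 1, 10000), novel,
                                        substr(truth, 10001, 20000)))
  reads <- simulate_reads(sample_g, cfg)
  pu <- build_pileup(map_reads(reads, idx, mapper_params(allow_clip = TRUE)),
                     ref)
  sc <- screen_large_indels(pu)
  ins <- sc[sc$type == "insertion_in_sample", ]
  expect_gte(nrow(ins), 1L)
  expect_true(any(ins$start <= 10000 & ins$end >= 9999))

  # 500 bp present in the reference but absent from the sample: low depth
  sample2 <- genome_record("s2", paste0(substr(truth, 1, 8000),
                                        substr(truth, 8501, 20000)))
  reads2 <- simulate_reads(sample2, simulation_config(genome_length = 19500L,
    n_cds = 0L, n_planted_errors = 0L, coverage_target = 40,
    per_base_error = 0, seed = 6L))
  pu2 <- build_pileup(map_reads(reads2, idx, mapper_params(allow_clip = TRUE)),
                      ref)
  sc2 <- screen_large_indels(pu2)
  del <- sc2[sc2$type == "deletion_in_sample", ]
  expect_equal(nrow(del), 1L)
  expect_lte(abs(del$start - 8000), 260)
  expect_lte(abs(del$end - 8500), 260)
})
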