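test_that("corrections apply with exact length conservation and coordinate maps", {
  g <- genome_record("g", random_dna(2000, seed = 3))
  none <- apply_corrections(g, empty_discrepancies())
  expect_identical(none$genome$sequence, g$sequence)
  expect_equal(map_positions(none$map, c(0L, 999L))$new, c(0L, 999L))

  # single insertion "T" at anchor 5 of a 10 bp genome: offsets 0 then +1
  g10 <- genome_record("t", "ACGTACGTAC")
  d <- data.frame(position = 5L, type = "insertion", ref_allele = "",
                  alt_allele = "T", stringsAsFactors = FALSE)
  dn <- as.data.frame(normalize_indel(as.list(d), g10), stringsAsFactors = FALSE)
  app <- apply_corrections(g10, dn)
  expect_equal(app$genome$length, 11L)
  # flanking substrings locate at mapped positions
  mp <- map_positions(app$map, 0:9)
  expect_equal(mp$new[1:(dn$position + 1)], 0:dn$position)
  expect_equal(mp$new[(dn$position + 2):10], (dn$position + 1):9 + 1L)
  for (p in c(2L, 8L)) {
    probe <- substr(g10$sequence, p + 1, p + 2)
    expect_equal(substr(app$genome$sequence, mp$new[p + 1] + 1,
                        mp$new[p + 1] + 2), probe)
  }

  dup <- rbind(dn, dn)
  expect_error(apply_corrections(g10, dup), "conflicting")
})

test_that("feature liftover shifts interiors, keeps flanks, and inverts exactly", {
  g <- genome_record("g", random_dna(3000, seed = 7))
  d <- data.frame(position = c(500L, 1200L), type = c("insertion", "deletion"),
                  ref_allele = c("", substr(g$sequence, 1201, 1202)),
                  alt_allele = c("G", ""), stringsAsFactors = FALSE)
  d <- do.call(rbind, lapply(1:2, function(i)
    as.data.frame(normalize_indel(as.list(d[i, ]), g), stringsAsFactors = FALSE)))
  cmap <- build_coordinate_map(d, g$length)
  expect_equal(cmap$new_length, 3000L + 1L - 2L)

  f <- cds_features(c("up", "hit", "down"), "g",
                    c(100L, 450L, 2000L), c(220L, 700L, 2300L), "+")
  lf <- lift_features(f, cmap)
  expect_equal(lf$start[1], 100L)          # upstream: unchanged
  expect_equal(lf$end[1], 220L)
  expect_equal(lf$start[2], 450L)          # contains the insertion
  expect_equal(lf$end[2], 701L)            # end shifted by +1
  expect_equal(lf$start[3], 2000L - 1L)    # past both edits: net -1
  expect_false(any(lf$anomaly))

  back <- lift_features(lf[, names(f)], invert_coordinate_map(cmap))
  expect_equal(back$start, f$start)
  expect_equal(back$end, f$end)

  # endpoint inside a deleted segment is flagged, not dropped
  f2 <- cds_features("edge", "g", 900L, d$position[2] + 2L, "+")
  lf2 <- lift_features(f2, cmap)
  expect_true(lf2$anomaly)
  expect_equal(nrow(lf2), 1L)
})

test_that("a repairing insertion merges split helicase-like fragments of 280 and 433 aa", {
  loc <- make_split_gene_locus()
  app <- apply_corrections(loc$reference, loc$discrepancy)
  expect_identical(app$genome$sequence, loc$corrected$sequence)
  imp <- assess_impact(loc$reference, app$genome, loc$features,
                       loc$discrepancy)
  expect_equal(imp$effect, "gene_merge")
  expect_equal(imp$old_gene_ids, "cds_A,cds_B")
  expect_equal(imp$old_protein_lengths, "280,433")
  expect_equal(imp$new_protein_length, 722L)
  expect_equal(nchar(imp$new_protein), 722L)
})

test_that("substitutions classify as synonymous or missense; no corrections give no coding impact", {
  g <- simulate_genome(simulation_config(genome_length = 9000L, n_cds = 3L,
                                         n_planted_errors = 0L, seed = 13L))
  f <- g$features[g$features$strand == "+", ][1, , drop = FALSE]
  # third codon position of an internal Leu codon: pick a CTx codon
  region <- substr(g$genome$sequence, f$start + 1, f$end)
  cods <- substring(region, seq(1, nchar(region) - 2, 3),
                    seq(3, nchar(region), 3))
  i <- which(substr(cods, 1, 2) == "CT")[2]
  pos <- f$start + (i - 1L) * 3L + 2L  # 0-based third position
  syn <- data.frame(position = pos, type = "substitution",
                    ref_allele = substr(g$genome$sequence, pos + 1, pos + 1),
                    alt_allele = "A", stringsAsFactors = FALSE)
  if (syn$ref_allele == "A") syn$alt_allele <- "G"
  app <- apply_corrections(g$genome, syn)
  imp <- assess_impact(g$genome, app$genome, g$features, syn)
  expect_equal(imp$effect, "synonymous")  # CTx codons all encode Leu
  # second codon position is missense for CTx
  pos2 <- f$start + (i - 1L) * 3L + 1L
  mis <- data.frame(position = pos2, type = "substitution",
                    ref_allele = substr(g$genome$sequence, pos2 + 1, pos2 + 1),
                    alt_allele = "G", stringsAsFactors = FALSE)
  app2 <- apply_corrections(g$genome, mis)
  imp2 <- assess_impact(g$genome, app2$genome, g$features, mis)
  expect_equal(imp2$effect, "missense")

  none <- assess_impact(g$genome, g$genome, g$features, empty_discrepancies())
  expect_equal(nrow(none), 0L)
})

test_that("gene merges on simulated data reconstruct the originally planted protein", {
  bundle <- small_sim_bundle(seed = 59, genome_length = 60000L,
                             n_errors = 25L, coverage = 0, n_cds = 40L,
                             weights = c(`4` = 0.3, `5` = 0.4, `6` = 0.3))
  disc <- data.frame(ref_id = bundle$assembly$id,
                     position = bundle$truth$position, type = "insertion",
                     ref_allele = "", alt_allele = bundle$truth$base,
                     depth = 50L, alt_support = 50L, alt_fraction = 1,
                     stringsAsFactors = FALSE)
  app <- apply_corrections(bundle$assembly, disc)
  expect_identical(app$genome$sequence, bundle$genome$sequence)
  imp <- assess_impact(bundle$assembly, app$genome, bundle$assembly_features,
                       disc)
  merges <- imp[imp$effect == "gene_merge", ]
  expect_gte(nrow(merges), 1L)
  planted <- setNames(
    vapply(seq_len(nrow(bundle$features)), function(j)
      sub("\\*$", "", translate_feature(bundle$genome,
                                        bundle$features[j, ])), ""),
    bundle$features$id)
  for (i in seq_len(nrow(merges))) {
    orig_id <- sub("_[12]$", "", strsplit(merges$old_gene_ids[i], ",")[[1]][1])
    expect_identical(merges$new_protein[i], unname(planted[orig_id]),
                     info = paste("merge at", merges$position[i]))
  }
})

test_that("combined identity scores the transfer rule exactly at the boundary", {
  set.seed(3)
  aa20 <- Biostrings::AA_STANDARD
  refp <- paste(sample(aa20, 100, replace = TRUE), collapse = "")
  tm0 <- combined_identity(refp, refp)
  expect_equal(tm0$combined_identity, 1)
  expect_equal(tm0$class, "perfect")

  mutate <- function(q, idx) {
    ch <- strsplit(q, "")[[1]]
    ch[idx] <- vapply(ch[idx], function(a) sample(setdiff(aa20, a), 1), "")
    paste(ch, collapse = "")
  }
  # 50% identity over 50% of the reference: combined exactly 0.25, accepted
  q50 <- mutate(substr(refp, 1, 50), seq(1, 49, 2))
  tm <- combined_identity(q50, refp)
  expect_equal(tm$identity_fraction, 0.5)
  expect_equal(tm$coverage_fraction, 0.5)
  expect_equal(tm$combined_identity, 0.25)
  expect_true(tm$accepted)
  # 40% identity over 50%: combined 0.20, rejected
  q40 <- mutate(substr(refp, 1, 50), sample(50, 30))
  tm2 <- combined_identity(q40, refp)
  expect_equal(tm2$combined_identity, 0.2, tolerance = 0.011)
  expect_false(tm2$accepted)
  expect_equal(tm2$class, "no_match")
  expect_error(combined_identity("", refp), "empty")
})
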