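test_that("FASTA records are read, uppercased, validated and written back", {
  p <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">g1", "ACGT"), p)
  g <- read_fasta(p)
  expect_length(g, 1L)
  expect_equal(g[[1]]$id, "g1")
  expect_equal(g[[1]]$sequence, "ACGT")

  writeLines(c(">a", "acgtn", ">b", "TTTT"), p)
  g <- read_fasta(p)
  expect_equal(g[["a"]]$sequence, "ACGTN")
  expect_equal(g[["b"]]$sequence, "TTTT")

  writeLines(">a", p)
  expect_error(read_fasta(p), "empty")
  writeLines(character(0), p)
  expect_error(read_fasta(p))
  writeLines(c(">a", "ACGT", ">a", "GGGG"), p)
  expect_error(read_fasta(p), "duplicate")

  # round trip
  p2 <- withr::local_tempfile(fileext = ".fasta")
  g1 <- genome_record("chr", strrep("ACGTT", 40))
  write_fasta(g1, p2)
  expect_equal(read_fasta(p2)[[1]]$sequence, g1$sequence)

  expect_error(genome_record("x", "ACGR"), "outside")
  expect_equal(genome_record("x", "ACGR", on_invalid = "mask")$sequence, "ACGN")
})

test_that("GFF3 CDS features convert to 0-based half-open and round-trip", {
  p <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "g1\t.\tCDS\t4\t9\t.\t+\t0\tID=x",
               "g1\t.\tCDS\t20\t40\t.\t-\t0\tID=y",
               "g1\t.\tgene\t1\t50\t.\t+\t.\tID=skipme"), p)
  f <- read_gff3(p)
  expect_equal(nrow(f), 2L)
  expect_equal(f$start, c(3L, 19L))
  expect_equal(f$end, c(9L, 40L))
  expect_equal(f$strand, c("+", "-"))

  p2 <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(f, p2)
  f2 <- read_gff3(p2)
  expect_equal(f2[, c("id", "start", "end", "strand", "phase")],
               f[, c("id", "start", "end", "strand", "phase")])

  writeLines(c("##gff-version 3", "g1\t.\tCDS\t9\t4\t.\t+\t0\tID=x"), p)
  expect_error(read_gff3(p))
  expect_error(cds_features("a", "g", 5L, 5L, "+"), "start < end")
  expect_error(cds_features("a", "g", 1L, 5L, "?"), "strand")
})

test_that("FASTQ reading decodes Phred+33 and round-trips through writing", {
  p1 <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII"), p1)
  r <- read_fastq(p1)
  expect_equal(r$seq1, "ACGT")
  expect_equal(phred_to_int(r$qual1)[[1]], rep(40L, 4))

  writeLines(c("@r1", "ACGT", "+", "III"), p1)
  expect_error(read_fastq(p1), "FASTQ")

  reads <- data.frame(id = c("a", "b"), seq1 = c("ACGTA", "TTTTT"),
                      qual1 = c("IIIII", "#####"), seq2 = c("GGGGG", "CCCCC"),
                      qual2 = c("IIIII", "IIIII"), stringsAsFactors = FALSE)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_read_pairs(reads, f1, f2)
  back <- read_fastq(f1, f2)
  expect_equal(back$seq1, reads$seq1)
  expect_equal(back$seq2, reads$seq2)
  expect_equal(back$qual1, reads$qual1)
})

test_that("CIGAR arithmetic follows the op definitions", {
  expect_equal(cigar_ref_span("3M1I2M"), 5L)   # 6-base read, 5 ref bases
  expect_equal(cigar_read_span("3M1I2M"), 6L)
  expect_equal(cigar_ref_span("10M2D5M"), 17L)
  expect_equal(cigar_read_span("10M2D5M"), 15L)
  expect_equal(cigar_read_span("5S10M"), 15L)
  expect_equal(cigar_ref_span("5S10M"), 10L)
  expect_error(parse_cigar("3M1X"), "malformed")
})

test_that("SAM import converts coordinates, filters and validates references", {
  g <- genome_record("chr", strrep("ACGT", 100))
  p <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6",
               "@SQ\tSN:chr\tLN:400",
               "r1\t0\tchr\t1\t60\t4M\t*\t0\t0\tACGT\tIIII\tNM:i:0",
               "r2\t16\tchr\t11\t60\t4M\t*\t0\t0\tGTAC\tIIII\tNM:i:1",
               "r3\t4\t*\t0\t0\t*\t*\t0\t0\tAAAA\tIIII"), p)
  al <- read_sam(p, g)
  expect_equal(nrow(al), 2L)           # unmapped r3 skipped
  expect_equal(al$ref_start, c(0L, 10L))  # POS=1 -> 0
  expect_equal(al$strand, c("+", "-"))
  expect_equal(al$edit, c(0L, 1L))

  writeLines(c("@SQ\tSN:other\tLN:10",
               "r1\t0\tother\t1\t60\t4M\t*\t0\t0\tACGT\tIIII"), p)
  expect_error(read_sam(p, g), "not in provided genomes")

  # write -> read round trip preserves the alignment fields
  p2 <- withr::local_tempfile(fileext = ".sam")
  write_sam(al, g, p2)
  al2 <- read_sam(p2, g)
  expect_equal(al2[, c("read_id", "ref_start", "strand", "cigar", "edit")],
               al[, c("read_id", "ref_start", "strand", "cigar", "edit")])
})

test_that("report writing produces valid tables for empty and populated audits", {
  bundle <- small_sim_bundle(seed = 31, genome_length = 30000L, n_errors = 6L,
                             coverage = 40, n_cds = 8L)
  cfg <- audit_config(reference = bundle$assembly,
                      annotation = bundle$assembly_features,
                      reads = simulate_reads(bundle$genome, bundle$cfg),
                      verbose = FALSE)
  audit <- run_audit(cfg)
  out <- withr::local_tempdir()
  write_reports(audit, out)
  expect_true(file.exists(file.path(out, "discrepancies.tsv")))
  tab <- read.delim(file.path(out, "discrepancies.tsv"))
  expect_equal(nrow(tab), nrow(audit$discrepancies))
  # reported positions are 1-based
  expect_equal(tab$position, audit$discrepancies$position + 1L)
  expect_true(file.exists(file.path(out, "MANIFEST.json")))
  expect_true(file.exists(file.path(out, "corrected.fasta")))
  corr <- read_fasta(file.path(out, "corrected.fasta"))[[1]]
  expect_equal(corr$length, audit$corrected$length)

  # zero-discrepancy audit: valid empty tables, total 0
  cfg0 <- audit_config(reference = bundle$genome,
                       annotation = bundle$features,
                       reads = simulate_reads(bundle$genome, bundle$cfg),
                       verbose = FALSE)
  audit0 <- run_audit(cfg0)
  expect_equal(audit0$summary$n_total, 0L)
  out0 <- withr::local_tempdir()
  write_reports(audit0, out0)
  s <- read.delim(file.path(out0, "summary.tsv"),
                  colClasses = c("character", "character"))
  expect_equal(s$value[s$metric == "n_total"], "0")
  expect_equal(nrow(read.delim(file.path(out0, "discrepancies.tsv"))), 0L)
})
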