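fmt1 <- function(x) formatC(x, format = "f", digits = 1)

#' Write the audit report bundle
#'
#' Emits (a) the discrepancy table (1-based positions, insertion/deletion/
#' substitution allele, gene ids, homopolymer length, product lengths before
#' and after correction, ortholog m/n identity and support verdict), (b) the
#' homopolymer run-length histogram, (c) a summary table (fractions to one
#' decimal place), and (d) the corrected FASTA with lifted GFF3 annotation.
#'
#' @param audit a \code{GenomeAudit} bundle from [run_audit()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest data.frame of written files.
#' @export
write_reports <- function(audit, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2L) != 0L)
    stop("write_reports: cannot write to ", out_dir)
  wt <- function(df, name) {
    p <- file.path(out_dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  d <- audit$discrepancies
  imp <- audit$impacts
  cv <- audit$crossval
  tab <- data.frame(
    position = if (nrow(d)) d$position + 1L else integer(),  # 1-based on disk
    type = d$type,
    allele = ifelse(d$type == "deletion", d$ref_allele, d$alt_allele),
    gene = d$gene_ids,
    homopolymer_length = d$homopolymer_length,
    stringsAsFactors = FALSE)
  if (!is.null(imp) && nrow(d)) {
    mi <- match(d$position, imp$position)
    tab$aa_length_corrected <- imp$new_protein_length[mi]
    tab$aa_length_reference <- imp$old_protein_lengths[mi]
    tab$effect <- imp$effect[mi]
  }
  if (!is.null(cv) && nrow(d)) {
    mc <- match(d$position, cv$position)
    tab$ortholog_identity <- cv$identity[mc]
    tab$support <- cv$verdict[mc]
  }
  files <- c(discrepancies = wt(tab, "discrepancies.tsv"))
  s <- audit$summary
  hist_df <- data.frame(run_length = as.integer(names(s$counts_by_run_length)),
                        count = as.integer(s$counts_by_run_length))
  files["homopolymer_histogram"] <- wt(hist_df, "homopolymer_histogram.tsv")
  sum_df <- data.frame(
    metric = c("n_total", "n_insertions", "n_deletions", "n_substitutions",
               "n_coding", "pct_coding", "n_run_gt4", "n_run_gt5",
               "pct_run_gt4", "mean_depth", "sd_depth",
               "pct_cds_full_breadth", "pct_cds_breadth60",
               "corrected_length"),
    value = c(s$n_total, s$n_insertions, s$n_deletions, s$n_substitutions,
              s$n_coding, fmt1(100 * s$fraction_coding), s$n_run_gt4,
              s$n_run_gt5, fmt1(100 * s$fraction_run_gt4),
              fmt1(audit$coverage$mean_depth %||% NA),
              fmt1(audit$coverage$sd_depth %||% NA),
              fmt1(audit$coverage$pct_cds_full_breadth %||% NA),
              fmt1(audit$coverage$pct_cds_breadth60 %||% NA),
              audit$corrected$length),
    stringsAsFactors = FALSE)
  files["summary"] <- wt(sum_df, "summary.tsv")
  files["corrected_fasta"] <- file.path(out_dir, "corrected.fasta")
  write_fasta(audit$corrected, files[["corrected_fasta"]])
  files["lifted_gff3"] <- file.path(out_dir, "lifted.gff3")
  write_gff3(audit$lifted_features, files[["lifted_gff3"]])
  if (!is.null(audit$large_indels))
    files["large_indels"] <- wt(audit$large_indels, "large_indel_candidates.tsv")
  if (!is.null(audit$coverage)) {
    files["cds_breadth"] <- wt(audit$coverage$per_cds, "cds_breadth.tsv")
    files["depth_bedgraph"] <- file.path(out_dir, "depth.bedgraph")
    write_depth_bedgraph(audit$depth, audit$reference$id,
                         files[["depth_bedgraph"]])
  }
  manifest <- data.frame(name = names(files), path = unname(files),
                         md5 = unname(tools::md5sum(unname(files))),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "MANIFEST.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(manifest)
}

#' Write discrepancies as a minimal VCF
#'
#' Left-aligned indels in the VCF 4 convention: 1-based POS, indels carry
#' the anchor base in REF/ALT.
#'
#' @param discrepancies discrepancy data.frame.
#' @param genome the reference [genome_record()].
#' @param path output file.
#' @export
write_vcf <- function(discrepancies, genome, path) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", genome$id, genome$length),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  lines <- character(0)
  for (i in seq_len(nrow(discrepancies))) {
    d <- discrepancies[i, ]
    if (d$type == "substitution") {
      pos <- d$position + 1L; ref <- d$ref_allele; alt <- d$alt_allele
    } else if (d$type == "insertion") {
      pos <- d$position + 1L  # anchor base, 1-based
      anchor <- if (d$position >= 0L)
        substr(genome$sequence, d$position + 1L, d$position + 1L) else ""
      ref <- anchor; alt <- paste0(anchor, d$alt_allele)
      if (pos == 0L) pos <- 1L
    } else {
      pos <- d$position  # base before the deleted run
      anchor <- if (pos >= 1L) substr(genome$sequence, pos, pos) else ""
      ref <- paste0(anchor, d$ref_allele); alt <- anchor
      if (pos == 0L) pos <- 1L
    }
    lines <- c(lines, sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                              genome$id, pos, ref, alt,
                              paste0("TYPE=", d$type)))
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}
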