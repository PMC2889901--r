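# Fixture builders shared across tests. Everything is generated in code.

# gene model from explicit exon fragment sequences (one isoform per list
# element; each element is a character vector of exon sequences)
fix_gene <- function(gene_id, iso_fragments) {
  isos <- lapply(seq_along(iso_fragments), function(k) {
    frags <- iso_fragments[[k]]
    len <- nchar(frags)
    start <- cumsum(c(0L, len[-length(len)] + 100L))
    isoform(sprintf("%s.%d", gene_id, k), gene_id,
            data.frame(chrom = sprintf("%s.%d", gene_id, k),
                       start = start, end = start + len, strand = "+",
                       stringsAsFactors = FALSE),
            paste(frags, collapse = ""))
  })
  gene_model(gene_id, isos)
}

# write a toy genome FASTA + GTF annotation; returns the two paths
fix_gtf_genome <- function(dir, chrom_seq, exons_df) {
  fasta <- file.path(dir, "genome.fa")
  writeLines(c(">chr1 toy", chrom_seq), fasta)
  gtf <- file.path(dir, "genes.gtf")
  lines <- sprintf(
    'chr1\ttoy\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    exons_df$start1, exons_df$end1, exons_df$strand,
    exons_df$gene_id, exons_df$transcript_id)
  writeLines(lines, gtf)
  list(gtf = gtf, fasta = fasta)
}

# a minimal intensity_matrix built directly from given channel matrices
fix_intensities <- function(cy3, cy5, is_self_self) {
  structure(list(cy3 = cy3, cy5 = cy5,
                 arrays = data.frame(array_id = colnames(cy3),
                                     is_self_self = is_self_self,
                                     stringsAsFactors = FALSE)),
            class = "intensity_matrix")
}

# a stub design whose spots are exactly the given kinds (no sequences);
# enough structure for preprocess()/estimate_variability()
fix_stub_design <- function(kind, gene_id = NA, probe_id = NULL,
                            control_id = NA, control_pos = NA, length = 36L) {
  probe_id <- probe_id %||% sprintf("p%04d", seq_along(kind))
  spots <- data.frame(probe_id = probe_id, kind = kind, gene_id = gene_id,
                      control_id = control_id, control_pos = control_pos,
                      length = length, stringsAsFactors = FALSE)
  spots$spot_id <- make.unique(spots$probe_id, sep = ".")
  probes <- spots[!duplicated(spots$probe_id), , drop = FALSE]
  structure(list(probes = probes, spots = spots, targets = NULL,
                 failures = NULL, config = design_config()),
            class = "array_design")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
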