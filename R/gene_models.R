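# Transcript/isoform data structures and readers/writers. Coordinates are
# 0-based half-open internally; GTF/GFF3 I/O converts from 1-based inclusive.

#' Construct an isoform
#'
#' An isoform is an ordered set of exons (transcription order) together with
#' its spliced sense-strand sequence. Exon coordinates are 0-based half-open.
#'
#' @param transcript_id,gene_id Identifiers.
#' @param exons `data.frame` with columns `chrom`, `start`, `end`, `strand`,
#'   one row per exon in transcription order.
#' @param sequence Spliced sense-strand DNA sequence; its length must equal
#'   the summed exon lengths.
#' @return An object of class `splice_isoform`.
#' @export
isoform <- function(transcript_id, gene_id, exons, sequence) {
  stopifnot(is.data.frame(exons),
            all(c("chrom", "start", "end", "strand") %in% names(exons)))
  if (any(exons$start >= exons$end)) {
    .stopf("zero_length_exon", "transcript %s has an exon with start >= end",
           transcript_id)
  }
  if (nchar(sequence) != sum(exons$end - exons$start)) {
    .stopf("sequence_length_mismatch",
           "transcript %s: sequence length %d != summed exon length %d",
           transcript_id, nchar(sequence), sum(exons$end - exons$start))
  }
  # non-overlap within the isoform (genomic coordinates, same chrom)
  o <- order(exons$start)
  if (length(o) > 1L) {
    ok <- all(exons$start[o][-1L] >= exons$end[o][-length(o)]) ||
      length(unique(exons$chrom)) > 1L
    if (!ok) {
      .stopf("overlapping_exons", "transcript %s has overlapping exons",
             transcript_id)
    }
  }
  rownames(exons) <- NULL
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 exons = exons, sequence = toupper(sequence)),
            class = "splice_isoform")
}

#' Construct a gene model
#'
#' @param gene_id Gene identifier shared by all isoforms.
#' @param isoforms List of [isoform()] objects.
#' @param name Optional human-readable gene name.
#' @return An object of class `splice_gene_model`.
#' @export
gene_model <- function(gene_id, isoforms, name = gene_id) {
  if (!length(isoforms)) .stopf("empty_gene", "gene %s has no isoforms", gene_id)
  ids <- vapply(isoforms, function(x) x$gene_id, "")
  if (!all(ids == gene_id)) {
    .stopf("gene_id_mismatch", "isoforms of %s carry a different gene_id", gene_id)
  }
  structure(list(gene_id = gene_id, name = name, isoforms = isoforms),
            class = "splice_gene_model")
}

#' @export
print.splice_gene_model <- function(x, ...) {
  cat(sprintf("<gene model %s (%s): %d isoform(s), %s bp spliced>\n",
              x$gene_id, x$name, length(x$isoforms),
              paste(vapply(x$isoforms, function(i) nchar(i$sequence), 0),
                    collapse = "/")))
  invisible(x)
}

# exon lengths and cumulative spliced-coordinate starts of an isoform
.spliced_layout <- function(iso) {
  len <- iso$exons$end - iso$exons$start
  list(len = len, start = cumsum(c(0L, len[-length(len)])), total = sum(len))
}

#' Read gene models from a GTF/GFF3 annotation and a genome FASTA
#'
#' Extracts every transcript of every gene, sorts exons in transcription
#' order, and attaches the spliced sense-strand sequence (minus-strand
#' transcripts are reverse-complemented).
#'
#' @param annotation Path to a GTF or GFF3 file. Exon records must carry
#'   `gene_id` and `transcript_id` attributes.
#' @param genome Path to a FASTA file containing every chromosome referenced
#'   by the annotation.
#' @return A list of [gene_model()] objects.
#' @export
read_gene_models <- function(annotation, genome) {
  gr <- rtracklayer::import(annotation)
  gr <- gr[!is.na(gr$type) & gr$type == "exon"]
  md <- S4Vectors::mcols(gr)
  if (is.null(md$gene_id) || is.null(md$transcript_id)) {
    .stopf("missing_attributes",
           "annotation exons must carry gene_id and transcript_id")
  }
  fa <- Biostrings::readDNAStringSet(genome)
  names(fa) <- sub("\\s.*$", "", names(fa))
  ex <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start1 = GenomicRanges::start(gr),   # 1-based inclusive as imported
    end1 = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = md$gene_id,
    transcript_id = md$transcript_id,
    stringsAsFactors = FALSE
  )
  missing_chrom <- setdiff(unique(ex$chrom), names(fa))
  if (length(missing_chrom)) {
    .stopf("missing_chromosome", "chromosome(s) not in FASTA: %s",
           paste(missing_chrom, collapse = ", "))
  }
  if (any(ex$end1 < ex$start1)) {
    .stopf("zero_length_exon", "annotation contains a zero/negative-length exon")
  }
  models <- list()
  for (g in unique(ex$gene_id)) {
    exg <- ex[ex$gene_id == g, , drop = FALSE]
    isos <- list()
    for (tx in unique(exg$transcript_id)) {
      et <- exg[exg$transcript_id == tx, , drop = FALSE]
      et <- et[order(et$start1), , drop = FALSE]
      minus <- et$strand[1] == "-"
      seqs <- vapply(seq_len(nrow(et)), function(i) {
        as.character(Biostrings::subseq(fa[[et$chrom[i]]],
                                        start = et$start1[i], end = et$end1[i]))
      }, "")
      if (minus) {
        et <- et[rev(seq_len(nrow(et))), , drop = FALSE]   # transcription order
        seqs <- .revcomp(rev(seqs))
      }
      exons <- data.frame(chrom = et$chrom, start = et$start1 - 1L,
                          end = et$end1, strand = et$strand,
                          stringsAsFactors = FALSE)
      isos[[tx]] <- isoform(tx, g, exons, paste(seqs, collapse = ""))
    }
    models[[g]] <- gene_model(g, unname(isos))
  }
  unname(models)
}

# shared constructor from a fragments table so that table-derived and
# simulated models are bit-identical and round-trip exactly
.models_from_fragments <- function(df) {
  df$exon_index <- as.integer(df$exon_index)
  models <- list()
  for (g in unique(df$gene_id)) {
    dg <- df[df$gene_id == g, , drop = FALSE]
    isos <- list()
    for (tx in unique(dg$transcript_id)) {
      dt <- dg[dg$transcript_id == tx, , drop = FALSE]
      if (anyDuplicated(dt$exon_index)) {
        .stopf("duplicate_exon_index",
               "duplicate (transcript_id, exon_index) for %s", tx)
      }
      dt <- dt[order(dt$exon_index), , drop = FALSE]
      len <- nchar(dt$sequence)
      # synthetic layout: exons laid on a per-transcript contig, 100-bp gaps
      start <- cumsum(c(0L, len[-length(len)] + 100L))
      exons <- data.frame(chrom = tx, start = start, end = start + len,
                          strand = "+", stringsAsFactors = FALSE)
      isos[[length(isos) + 1L]] <- isoform(tx, g, exons,
                                           paste(dt$sequence, collapse = ""))
    }
    models[[length(models) + 1L]] <- gene_model(g, isos)
  }
  models
}

#' Read gene models from a per-isoform exon-fragment table
#'
#' Simple plain-text transcript format used for synthetic fixtures: one row
#' per exon with columns `gene_id`, `transcript_id`, `exon_index` and
#' `sequence` (the exon's contribution to the spliced transcript). Rows may
#' appear in any order; exons are sorted by `exon_index`.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @return A list of [gene_model()] objects. Round-trips with
#'   [write_isoform_table()].
#' @export
read_isoform_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("gene_id", "transcript_id", "exon_index", "sequence")
  if (!all(need %in% names(df))) {
    .stopf("missing_columns", "isoform table needs columns: %s",
           paste(need, collapse = ", "))
  }
  if (!nrow(df)) return(list())
  .models_from_fragments(df)
}

#' Write gene models to a per-isoform exon-fragment table
#'
#' @param models List of [gene_model()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_isoform_table <- function(models, path) {
  rows <- list()
  for (m in models) {
    for (iso in m$isoforms) {
      lay <- .spliced_layout(iso)
      for (i in seq_along(lay$len)) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = m$gene_id, transcript_id = iso$transcript_id,
          exon_index = i,
          sequence = substr(iso$sequence, lay$start[i] + 1L,
                            lay$start[i] + lay$len[i]),
          stringsAsFactors = FALSE)
      }
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(gene_id = character(), transcript_id = character(),
               exon_index = integer(), sequence = character())
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
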