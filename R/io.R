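# Readers/writers for the standard formats the pipeline speaks: FASTA/FASTQ
# through Biostrings, GFF3/BED through rtracklayer, JSON through jsonlite.
# Collapsed reads use the ">seq<i>_x<count>" FASTA header dialect.

#' Write a genome to FASTA
#' @param genome [Biostrings::DNAStringSet] or named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  if (!inherits(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read a genome (or any FASTA) as a DNAStringSet
#' @param path FASTA file.
#' @return [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write reads to FASTQ (constant quality) or FASTA
#' @param reads named character vector (names become read ids).
#' @param path output file; format chosen by `format`.
#' @param format `"fastq"` or `"fasta"`.
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  x <- Biostrings::DNAStringSet(reads)
  if (format == "fastq") {
    quals <- Biostrings::BStringSet(strrep("I", nchar(reads)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals)
  } else {
    Biostrings::writeXStringSet(x, path, format = "fasta")
  }
  invisible(path)
}

#' Read small-RNA reads from FASTQ/FASTA
#' @param path input file.
#' @param format `"auto"` (by extension), `"fastq"` or `"fasta"`.
#' @return named character vector of reads.
#' @export
read_reads <- function(path, format = c("auto", "fastq", "fasta")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.f(ast)?q(\\.gz)?$", path)) "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = format)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write collapsed reads as count-bearing FASTA
#'
#' Headers follow the `>seq<i>_x<count>` dialect common in small-RNA tools.
#'
#' @param collapsed data.frame from [collapse_reads()].
#' @param path output FASTA.
#' @return `path`, invisibly.
#' @export
write_collapsed_fasta <- function(collapsed, path) {
  x <- Biostrings::DNAStringSet(collapsed$seq)
  names(x) <- sprintf("seq%d_x%d", seq_len(nrow(collapsed)),
                      collapsed$count)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read count-bearing collapsed FASTA
#' @param path FASTA with `>seq<i>_x<count>` headers.
#' @return collapsed-read data.frame (`seq`, `count`, `length`).
#' @export
read_collapsed_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  counts <- as.integer(sub("^.*_x(\\d+)$", "\\1", names(x)))
  if (anyNA(counts))
    stop("headers do not follow the seq<i>_x<count> dialect")
  data.frame(seq = as.character(x), count = counts,
             length = nchar(as.character(x)), stringsAsFactors = FALSE)
}

mappings_to_granges <- function(mappings) {
  GenomicRanges::GRanges(
    seqnames = mappings$contig,
    ranges = IRanges::IRanges(start = mappings$start + 1L,
                              end = mappings$end),
    strand = mappings$strand)
}

#' Write mappings as BED6 plus a sidecar TSV
#'
#' The BED6 carries interval, read sequence as name, copy count as score and
#' strand; the sidecar TSV adds mismatch counts and `n_loci`.
#'
#' @param mappings mapping data.frame from [map_reads()].
#' @param bed_path,tsv_path output paths (`tsv_path` defaults to the BED path
#'   with a `.tsv` extension).
#' @return `bed_path`, invisibly.
#' @export
write_mappings_bed <- function(mappings, bed_path,
                               tsv_path = sub("\\.bed$", ".tsv", bed_path)) {
  gr <- mappings_to_granges(mappings)
  S4Vectors::mcols(gr)$name <- mappings$seq
  S4Vectors::mcols(gr)$score <- mappings$count
  rtracklayer::export(gr, bed_path, format = "BED")
  write.table(mappings, tsv_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(bed_path)
}

#' Read mappings from the sidecar TSV written by [write_mappings_bed()]
#' @param tsv_path the sidecar TSV.
#' @return mapping data.frame.
#' @export
read_mappings_tsv <- function(tsv_path) {
  read.delim(tsv_path, stringsAsFactors = FALSE)
}

#' Export a truth set as GFF3
#' @param truth `srna_truth` from [simulate_genome()].
#' @param path output GFF3.
#' @return `path`, invisibly.
#' @export
write_truth_gff3 <- function(truth, path) {
  f <- truth$features
  if (nrow(f) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = f$contig,
    ranges = IRanges::IRanges(start = f$start + 1L, end = f$end),
    strand = ifelse(f$strand %in% c("+", "-"), f$strand, "*"))
  S4Vectors::mcols(gr)$type <- f$class
  S4Vectors::mcols(gr)$ID <- f$feature_id
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Export truth parameters and read attribution as JSON
#' @param truth `srna_truth` from [simulate_genome()].
#' @param path output JSON.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  cfg <- truth$params
  cfg$features <- lapply(cfg$features, unclass)
  cfg$family_table <- NULL
  jsonlite::write_json(list(params = unclass(cfg),
                            features = truth$features,
                            read_plan = truth$read_plan),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
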