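# Readers and writers for the pipeline's on-disk formats: FASTA contigs and
# proteins (Biostrings), GFF3 ORF annotations (rtracklayer), and plain TSV for
# read pairs, truth tables, SNV tables and MGE annotations.

#' Write a MAG's contigs as FASTA
#' @param mag a `mag_record`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mag_fasta <- function(mag, path) {
  x <- Biostrings::DNAStringSet(mag$contigs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read contigs from FASTA into a minimal MAG record
#' @param path FASTA file.
#' @param mag_id label for the MAG.
#' @param orfs optional ORF table (e.g. from [read_orfs_gff3()]).
#' @return a `mag_record`.
#' @export
read_mag_fasta <- function(path, mag_id, orfs = NULL) {
  x <- Biostrings::readDNAStringSet(path)
  contigs <- as.character(x)
  names(contigs) <- sub("\\s.*$", "", names(x))
  if (is.null(orfs))
    orfs <- data.frame(orf_id = character(0), contig = character(0),
                       start = integer(0), end = integer(0),
                       strand = character(0), stringsAsFactors = FALSE)
  new_mag(mag_id, contigs, orfs)
}

#' Write ORF annotations as GFF3 (1-based, closed intervals)
#' @param mag a `mag_record`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_orfs_gff3 <- function(mag, path) {
  o <- mag$orfs
  gr <- GenomicRanges::GRanges(
    seqnames = o$contig,
    ranges = IRanges::IRanges(start = o$start, end = o$end),
    strand = o$strand)
  gr$source <- "parasnv"
  gr$type <- "CDS"
  gr$phase <- 0L
  gr$ID <- o$orf_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read ORF annotations from GFF3
#' @param path GFF3 file.
#' @return data.frame with orf_id, contig, start, end, strand.
#' @export
read_orfs_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  data.frame(orf_id = if (!is.null(gr$ID)) as.character(gr$ID) else
               sprintf("orf%05d", seq_along(gr)),
             contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Write / read tab-separated tables (lossless round trip)
#'
#' Thin wrappers fixing the conventions used throughout the pipeline:
#' tab-separated, header, no quoting surprises, no factor coercion.
#' @param df a data.frame.
#' @param path file path.
#' @return `write_tsv()` returns `path` invisibly; `read_tsv()` a data.frame.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  # read as character and retype conservatively: single-letter base columns
  # ("T") must never be mistaken for logicals
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "", na.strings = "NA")
  for (j in seq_along(df)) {
    x <- df[[j]]; v <- x[!is.na(x)]
    if (length(v) == 0) next
    if (all(v %in% c("TRUE", "FALSE"))) df[[j]] <- as.logical(x)
    else {
      num <- suppressWarnings(as.numeric(v))
      if (!anyNA(num)) {
        df[[j]] <- as.numeric(x)
        if (all(num == trunc(num)) && all(abs(num) < .Machine$integer.max))
          df[[j]] <- as.integer(df[[j]])
      }
    }
  }
  df
}

#' Write a simulated scenario to a directory
#'
#' Emits, per MAG: `<id>.fna` (contigs), `<id>.gff3` (ORFs), `<id>.faa`
#' (proteins); plus truth tables (`truth_snvs.tsv`, `truth_tracts.tsv`,
#' `truth_mges.tsv`) and the scenario config (`config.yaml`).
#'
#' @param scenario a `sim_scenario`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(scenario$mags)) {
    mag <- scenario$mags[[id]]
    write_mag_fasta(mag, file.path(dir, paste0(id, ".fna")))
    write_orfs_gff3(mag, file.path(dir, paste0(id, ".gff3")))
    aa <- mag_proteins(mag)
    Biostrings::writeXStringSet(aa, file.path(dir, paste0(id, ".faa")))
  }
  write_tsv(scenario$truth$snvs, file.path(dir, "truth_snvs.tsv"))
  write_tsv(scenario$truth$tracts, file.path(dir, "truth_tracts.tsv"))
  write_tsv(scenario$truth$mges, file.path(dir, "truth_mges.tsv"))
  write_config(scenario$config, file.path(dir, "config.yaml"))
  invisible(dir)
}
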