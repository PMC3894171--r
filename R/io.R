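# Format readers/writers and run manifests. BED input is 0-based half-open;
# TSS-relative offsets elsewhere in the package are 0 at the first
# transcribed base.

#' Read sequences from FASTA / FASTQ
#'
#' Wrapped lines are handled, sequences are uppercased and U canonicalized
#' to T; FASTQ qualities are parsed but ignored. An empty file yields a
#' zero-row result with a warning.
#'
#' @param path file path.
#' @return data.frame with columns `id` (first whitespace-delimited token of
#'   the header) and `sequence`.
#' @export
read_fasta <- function(path) .read_seqfile(path, "fasta")

#' @rdname read_fasta
#' @export
read_fastq <- function(path) .read_seqfile(path, "fastq")

.read_seqfile <- function(path, format) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path, format = format)
  if (length(set) == 0L) {
    warning("no records in ", path)
    return(data.frame(id = character(0L), sequence = character(0L)))
  }
  ids <- sub("\\s.*$", "", names(set))
  data.frame(id = ids,
             sequence = canonicalize_seq(as.character(set)),
             row.names = NULL)
}

#' Write sequences as FASTA
#'
#' @param df data.frame with columns `id` and `sequence` (or `gene_id` and
#'   `sequence`).
#' @param path output path.
#' @export
write_fasta <- function(df, path) {
  id_col <- if ("id" %in% names(df)) "id" else "gene_id"
  writeLines(paste0(">", df[[id_col]], "\n", df$sequence), path)
  invisible(path)
}

#' Extract TSS-anchored promoter windows from a genome and a BED6 table
#'
#' BED is 0-based half-open with the TSS at `start` on the + strand and at
#' `end - 1` on the - strand. For a + strand TSS at 0-based position p the
#' window covers genomic interval [p + window[1], p + window[2]] (1-based
#' p+1+window[1] .. p+1+window[2]); minus-strand windows are
#' reverse-complemented so offsets run 5' to 3' along the gene with offset 0
#' at the TSS base. Genes whose window exceeds the contig are skipped with a
#' warning.
#'
#' @param bed_path path to a BED6 file (chrom, start, end, name, score,
#'   strand).
#' @param genome a named character vector of contig sequences, a
#'   `Biostrings::DNAStringSet`, or a path to a genome FASTA.
#' @param window inclusive TSS-relative span, default -50..+150.
#' @return data.frame with columns `gene_id`, `sequence` ready for
#'   [scan_windows()].
#' @export
read_tss_bed <- function(bed_path, genome, window = c(-50L, 150L)) {
  gr <- rtracklayer::import(bed_path, format = "BED")
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  if (inherits(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-"))) {
    stop("BED strands must be + or -")
  }
  chrom <- as.character(GenomicRanges::seqnames(gr))
  name <- gr$name
  # rtracklayer converts BED to 1-based closed intervals
  tss1 <- ifelse(strand == "+", GenomicRanges::start(gr),
                 GenomicRanges::end(gr))
  out <- vector("list", length(gr))
  skipped <- 0L
  for (i in seq_along(gr)) {
    ci <- match(chrom[i], names(genome))
    if (is.na(ci)) stop("contig not in genome: ", chrom[i])
    contig <- genome[[ci]]
    if (strand[i] == "+") {
      lo <- tss1[i] + window[1L]; hi <- tss1[i] + window[2L]
    } else {
      lo <- tss1[i] - window[2L]; hi <- tss1[i] - window[1L]
    }
    if (lo < 1L || hi > nchar(contig)) {
      skipped <- skipped + 1L
      next
    }
    s <- substr(contig, lo, hi)
    if (strand[i] == "-") s <- revcomp(s)
    out[[i]] <- data.frame(gene_id = name[i],
                           sequence = canonicalize_seq(s))
  }
  if (skipped > 0L) {
    warning(skipped, " gene(s) with out-of-bounds windows were skipped")
  }
  res <- do.call(rbind, out)
  if (is.null(res)) stop("no in-bounds windows")
  res
}

#' Write a similarity-track table as TSV
#'
#' Long format: gene_id, offset, score_bits, p_value, similarity_index, with
#' a stable column order and fixed float precision.
#'
#' @param tracks an `nbe_tracks` from [scan_windows()].
#' @param path output path.
#' @export
write_tracks_tsv <- function(tracks, path) {
  df <- data.frame(gene_id = tracks$gene_id, offset = tracks$offset,
                   score_bits = sprintf("%.6f", tracks$score),
                   p_value = sprintf("%.6g", tracks$p_value),
                   similarity_index = sprintf("%.6f",
                                              tracks$similarity_index))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a similarity-track table written by [write_tracks_tsv()]
#'
#' @param path TSV path.
#' @param k motif length of the scan that produced the table.
#' @return an `nbe_tracks` data.frame.
#' @export
read_tracks_tsv <- function(path, k) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  tracks <- data.frame(gene_id = as.character(df$gene_id),
                       offset = as.integer(df$offset),
                       score = as.numeric(df$score_bits),
                       p_value = as.numeric(df$p_value),
                       similarity_index = as.numeric(df$similarity_index))
  attr(tracks, "k") <- as.integer(k)
  attr(tracks, "window_start") <- min(tracks$offset)
  class(tracks) <- c("nbe_tracks", "data.frame")
  tracks
}

#' Write a generic result table as TSV with stable formatting
#'
#' @param df data.frame.
#' @param path output path.
#' @export
write_tsv_result <- function(df, path) {
  num <- vapply(df, is.double, logical(1L))
  df[num] <- lapply(df[num], function(x) sprintf("%.6g", x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the package version, the configuration (seeds included) and md5
#' checksums of the listed input files, so a run can be reproduced exactly.
#'
#' @param path output JSON path.
#' @param config named list of parameters (must include any seeds used).
#' @param inputs character vector of input file paths to checksum.
#' @export
write_run_manifest <- function(path, config, inputs = character(0L)) {
  manifest <- list(
    package = "nbescan",
    version = as.character(utils::packageVersion("nbescan")),
    config = config,
    input_md5 = if (length(inputs)) {
      as.list(tools::md5sum(inputs))
    } else {
      stats::setNames(list(), character(0L))
    })
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
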