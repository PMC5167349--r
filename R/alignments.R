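# Ingestion of mapped reads into a read_set.

#' Extract per-transcript read start positions from alignments
#'
#' Reads a SAM/BAM file of reads mapped to transcript sequences (one
#' reference per transcript; the input is expected to contain uniquely
#' mapped records, e.g. Bowtie `-m 1` output) or the TSV dialect written by
#' [write_read_set], and collects 0-based read 5' start positions per
#' transcript.  Secondary and supplementary alignments are dropped.
#' Records on references absent from the annotation are skipped with a
#' tally; records whose start lies beyond the transcript length are
#' discarded with a tally.
#'
#' @param path SAM, BAM or TSV file.
#' @param annotation Transcript lengths: a data frame with columns `id` and
#'   `length`, or a named numeric vector.
#' @param five_prime If `TRUE`, reads aligned to the reverse strand use
#'   their biological 5' end (rightmost aligned base) instead of the
#'   leftmost aligned coordinate.
#' @param exclude_ids Optional transcript ids to drop (e.g. rRNA entries).
#' @return A [read_set] covering every annotation transcript (zero-read
#'   transcripts included); `metadata` records the source and the skip /
#'   discard tallies.
#' @export
read_alignments <- function(path, annotation, five_prime = FALSE,
                            exclude_ids = NULL) {
  if (is.data.frame(annotation)) {
    if (!all(c("id", "length") %in% names(annotation))) {
      stop("annotation data frame needs columns 'id' and 'length'")
    }
    ann <- stats::setNames(as.numeric(annotation$length),
                           as.character(annotation$id))
  } else {
    ann <- annotation
    if (is.null(names(ann))) stop("annotation vector must be named")
  }
  if (!is.null(exclude_ids)) ann <- ann[!names(ann) %in% exclude_ids]
  if (anyDuplicated(names(ann))) stop("annotation ids must be unique")

  if (grepl("\\.tsv$", path, ignore.case = TRUE)) {
    df <- data.table::fread(path, sep = "\t", data.table = FALSE)
    hits <- data.frame(ref = as.character(df$transcript_id),
                       start = as.numeric(df$read_start))
  } else {
    for (pkg in c("Rsamtools", "GenomicAlignments")) {
      if (!requireNamespace(pkg, quietly = TRUE)) {
        stop("package '", pkg, "' is required to read SAM/BAM input")
      }
    }
    bam <- path
    if (grepl("\\.sam$", path, ignore.case = TRUE)) {
      bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                              indexDestination = FALSE)
    }
    flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                    isSecondaryAlignment = FALSE,
                                    isSupplementaryAlignment = FALSE)
    ga <- GenomicAlignments::readGAlignments(
      bam, param = Rsamtools::ScanBamParam(flag = flags))
    start0 <- BiocGenerics::start(ga) - 1           # SAM POS is 1-based
    if (five_prime) {
      rev <- as.character(BiocGenerics::strand(ga)) == "-"
      start0[rev] <- BiocGenerics::end(ga)[rev] - 1
    }
    hits <- data.frame(ref = as.character(GenomicAlignments::seqnames(ga)),
                       start = as.numeric(start0))
  }

  known <- hits$ref %in% names(ann)
  n_unknown <- sum(!known)
  if (n_unknown > 0) {
    warning(n_unknown, " record(s) on references absent from the ",
            "annotation were skipped")
  }
  hits <- hits[known, , drop = FALSE]
  lim <- ann[hits$ref]
  ok <- hits$start >= 0 & hits$start < lim
  n_discard <- sum(!ok)
  if (n_discard > 0) {
    warning(n_discard, " record(s) with start positions outside ",
            "[0, length) were discarded")
  }
  hits <- hits[ok, , drop = FALSE]
  reads <- split(hits$start, factor(hits$ref, levels = names(ann)))
  read_set(names(ann), unname(ann), lapply(reads, as.numeric),
           metadata = list(source = path,
                           five_prime = five_prime,
                           skipped_unknown_reference = n_unknown,
                           discarded_out_of_range = n_discard,
                           excluded_ids = exclude_ids))
}
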