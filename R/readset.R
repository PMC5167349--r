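# Per-transcript read start positions.
#
# A read_set holds, for each transcript, its id, its length l and the list
# of read 5' start positions in [0, l).  Positions are continuous reals;
# integer base coordinates are treated as real-valued.  Ingested positions
# equal to l are clamped to l * (1 - 1e-9) so the half-open convention holds.

#' Construct a read set
#'
#' @param ids Character vector of unique transcript ids.
#' @param lengths Numeric vector of transcript lengths (> 0), parallel to
#'   `ids`.
#' @param reads List of numeric vectors of read start positions (one per
#'   transcript, possibly empty), or `NULL` for an empty read set.  Names,
#'   if present, must match `ids`.
#' @param metadata List of provenance fields (source file, seed, true
#'   simulation parameters, filters applied).
#' @return Object of class `read_set` with elements `transcripts` (data
#'   frame `id`, `length`), `reads` (named list) and `metadata`.
#' @export
read_set <- function(ids, lengths, reads = NULL, metadata = list()) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("transcript ids must be unique")
  if (length(lengths) != length(ids)) stop("ids and lengths differ in length")
  if (any(!is.finite(lengths) | lengths <= 0)) {
    stop("transcript lengths must be positive")
  }
  if (is.null(reads)) reads <- rep(list(numeric(0)), length(ids))
  if (is.null(names(reads))) {
    if (length(reads) != length(ids)) stop("reads and ids differ in length")
    names(reads) <- ids
  }
  reads <- reads[ids]
  for (i in seq_along(ids)) {
    x <- as.numeric(reads[[i]])
    li <- lengths[i]
    bad <- x < 0 | x > li
    if (any(bad)) {
      stop("transcript ", ids[i], ": ", sum(bad),
           " read position(s) outside [0, length]")
    }
    x[x == li] <- li * (1 - 1e-9)  # half-open [0, l)
    reads[[i]] <- x
  }
  structure(list(transcripts = data.frame(id = ids, length = as.numeric(lengths),
                                          stringsAsFactors = FALSE),
                 reads = reads, metadata = metadata),
            class = "read_set")
}

#' Number of reads per transcript (or in total)
#' @param rs A [read_set].
#' @param total If `TRUE`, return the grand total.
#' @export
n_reads <- function(rs, total = TRUE) {
  stopifnot(inherits(rs, "read_set"))
  n <- vapply(rs$reads, length, integer(1))
  if (total) sum(n) else n
}

#' @export
print.read_set <- function(x, ...) {
  cat("read_set: ", nrow(x$transcripts), " transcripts, ",
      n_reads(x), " reads; lengths ",
      signif(min(x$transcripts$length), 4), "-",
      signif(max(x$transcripts$length), 4), " bases\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.read_set <- function(x, ...) {
  n <- vapply(x$reads, length, integer(1))
  data.frame(
    transcript_id = rep(x$transcripts$id, n),
    length = rep(x$transcripts$length, n),
    read_start = unlist(x$reads, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

# Cheap order-invariant fingerprint used to verify that model fits being
# compared were computed on the identical data.
.readset_checksum <- function(rs) {
  n <- n_reads(rs)
  s <- sum(vapply(rs$reads, sum, numeric(1)))
  sprintf("%d|%.6f|%.6f", n, s, sum(rs$transcripts$length))
}

#' Write a read set to disk
#'
#' TSV with columns `transcript_id`, `length`, `read_start` (transcripts
#' with zero reads are preserved via a header-only sidecar entry), or BED6
#' with the transcript as contig and 1-base intervals at read starts.  A
#' JSON sidecar `<path>.meta.json` records the metadata (seed and true
#' parameters for simulated sets).  Writes are atomic (temp file + rename).
#'
#' @param rs A [read_set].
#' @param path Output file.
#' @param format `"tsv"` or `"bed"`.
#' @export
write_read_set <- function(rs, path, format = c("tsv", "bed")) {
  stopifnot(inherits(rs, "read_set"))
  format <- match.arg(format)
  df <- as.data.frame(rs)
  .atomic_write(path, function(tmp) {
    if (format == "tsv") {
      data.table::fwrite(df, tmp, sep = "\t")
    } else {
      bed <- data.frame(chrom = df$transcript_id,
                        start = floor(df$read_start),
                        end = floor(df$read_start) + 1L,
                        name = "read", score = 0L, strand = "+")
      data.table::fwrite(bed, tmp, sep = "\t", col.names = FALSE)
    }
  })
  meta <- c(rs$metadata,
            list(format = format,
                 transcripts = rs$transcripts$id,
                 lengths = rs$transcripts$length))
  .atomic_write(paste0(path, ".meta.json"), function(tmp) {
    jsonlite::write_json(meta, tmp, auto_unbox = TRUE, digits = NA)
  })
  invisible(path)
}

#' Read a TSV read set
#'
#' Reads the TSV dialect written by [write_read_set] (columns
#' `transcript_id`, `length`, `read_start`).  Transcripts listed in the
#' metadata sidecar but absent from the table (zero reads) are restored if
#' the sidecar exists.
#'
#' @param path TSV file.
#' @return A [read_set].
#' @export
read_read_set_tsv <- function(path) {
  df <- data.table::fread(path, sep = "\t", data.table = FALSE)
  need <- c("transcript_id", "length", "read_start")
  if (!all(need %in% names(df))) {
    stop("TSV must have columns ", paste(need, collapse = ", "))
  }
  meta_path <- paste0(path, ".meta.json")
  metadata <- list(source = path)
  ids <- unique(df$transcript_id)
  lengths <- df$length[match(ids, df$transcript_id)]
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!is.null(meta$transcripts)) {
      ids <- as.character(meta$transcripts)
      lengths <- as.numeric(meta$lengths)
    }
    metadata <- c(metadata, meta[setdiff(names(meta),
                                         c("transcripts", "lengths"))])
  }
  reads <- split(df$read_start, factor(df$transcript_id, levels = ids))
  reads <- lapply(reads, as.numeric)
  read_set(ids, lengths, reads, metadata)
}
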