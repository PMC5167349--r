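# Descriptive coverage diagnostics and bias-corrected quantification.

#' Shannon entropy of a proportion vector
#'
#' Natural-log entropy with the convention 0*log(0) = 0; maximal (log of
#' the number of bins) iff the vector is uniform.
#'
#' @param p Nonnegative numeric vector summing to 1 (renormalized if not).
#' @return Numeric scalar.
#' @export
shannon_entropy <- function(p) {
  if (any(p < 0)) stop("proportions must be nonnegative")
  s <- sum(p)
  if (s <= 0) stop("proportions sum to zero")
  p <- p[p > 0] / s
  -sum(p * log(p))
}

#' Binned coverage matrix
#'
#' Divides every transcript into `n_bins` equal-width bins (read start `x`
#' falls in bin `floor(n_bins * x / l)`, clamped to the last bin) and
#' returns per-transcript bin proportions, rows ordered from the shortest
#' transcript (top) to the longest (bottom).  Transcripts without reads are
#' excluded.
#'
#' @param readset A [read_set].
#' @param n_bins Number of bins (default 20).
#' @return Object of class `coverage_matrix` with elements
#'   `transcript_ids`, `lengths` (ascending) and `matrix`
#'   (transcripts x bins, rows summing to 1).
#' @export
bin_coverage <- function(readset, n_bins = 20L) {
  stopifnot(inherits(readset, "read_set"))
  if (n_bins < 1) stop("n_bins must be >= 1")
  n <- vapply(readset$reads, length, integer(1))
  keep <- which(n > 0)
  ord <- keep[order(readset$transcripts$length[keep])]
  mat <- matrix(0, length(ord), n_bins)
  for (r in seq_along(ord)) {
    i <- ord[r]
    l <- readset$transcripts$length[i]
    b <- pmin(floor(n_bins * readset$reads[[i]] / l), n_bins - 1L)
    mat[r, ] <- tabulate(b + 1L, nbins = n_bins) / length(b)
  }
  structure(list(transcript_ids = readset$transcripts$id[ord],
                 lengths = readset$transcripts$length[ord],
                 matrix = mat, n_bins = as.integer(n_bins)),
            class = "coverage_matrix")
}

#' @export
print.coverage_matrix <- function(x, ...) {
  cat("coverage_matrix: ", length(x$transcript_ids), " transcripts x ",
      x$n_bins, " bins (rows ordered shortest to longest)\n", sep = "")
  invisible(x)
}

#' Plot a coverage matrix as a heatmap
#'
#' Transcripts (shortest at the top) against position bins; per-bin read
#' proportions on a capped color scale.
#'
#' @param x A `coverage_matrix`.
#' @param cap Proportion at which the color scale saturates (default 0.1).
#' @param ... Passed to [graphics::image].
#' @export
plot.coverage_matrix <- function(x, cap = 0.1, ...) {
  m <- pmin(x$matrix, cap)
  graphics::image(seq_len(x$n_bins), seq_along(x$transcript_ids),
                  t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  xlab = "position bin (5' to 3')",
                  ylab = "transcripts (longest at bottom)",
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  invisible(x)
}

#' Export a coverage matrix as TSV
#'
#' @param cm A `coverage_matrix`.
#' @param path Output file.
#' @export
write_coverage_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "coverage_matrix"))
  df <- data.frame(transcript_id = cm$transcript_ids, length = cm$lengths,
                   cm$matrix)
  names(df)[-(1:2)] <- paste0("bin", seq_len(cm$n_bins))
  .atomic_write(path, function(tmp) data.table::fwrite(df, tmp, sep = "\t"))
  invisible(path)
}

#' Entropy-based coverage uniformity comparison
#'
#' Compares how uniform read coverage is between two samples.  Genes with at
#' least one read count as detected; the sample with more detected genes is
#' randomly subsampled to the other's count so equal numbers of genes are
#' processed.  Each gene's 20-bin coverage proportions are scored by Shannon
#' entropy (maximal, `log(20)`, for uniform coverage) and the ratio of the
#' two median entropies is returned.
#'
#' @param readset_a,readset_b [read_set]s to compare (a in the numerator).
#' @param seed Seed for the equal-gene subsampling.
#' @param n_bins Bins per transcript (default 20).
#' @return List with `ratio` (median entropy a / median entropy b),
#'   `median_a`, `median_b`, `n_genes` (genes used per sample) and the
#'   per-gene entropy vectors `entropies_a`, `entropies_b`.
#' @export
uniformity_entropy_ratio <- function(readset_a, readset_b, seed = 1L,
                                     n_bins = 20L) {
  stopifnot(inherits(readset_a, "read_set"), inherits(readset_b, "read_set"))
  det <- function(rs) which(vapply(rs$reads, length, integer(1)) > 0)
  da <- det(readset_a)
  db <- det(readset_b)
  if (!length(da) || !length(db)) {
    stop("a read set has zero detected genes")
  }
  ng <- min(length(da), length(db))
  set.seed(seed)
  if (length(da) > ng) da <- sample(da, ng)
  if (length(db) > ng) db <- sample(db, ng)
  ent <- function(rs, idx) {
    vapply(idx, function(i) {
      l <- rs$transcripts$length[i]
      b <- pmin(floor(n_bins * rs$reads[[i]] / l), n_bins - 1L)
      shannon_entropy(tabulate(b + 1L, nbins = n_bins) / length(b))
    }, numeric(1))
  }
  ea <- ent(readset_a, da)
  eb <- ent(readset_b, db)
  list(ratio = stats::median(ea) / stats::median(eb),
       median_a = stats::median(ea), median_b = stats::median(eb),
       n_genes = ng, entropies_a = ea, entropies_b = eb)
}

#' Area-corrected transcript abundances
#'
#' Divides each transcript's raw read count by the area under the fitted
#' model's coverage function at that transcript's length — the expected
#' relative read yield — removing the protocol's length bias.  With model A
#' at `theta1 = theta2 = 0`, `h = 0` the area is proportional to `l` and the
#' correction reduces to the FPKM-like `count / l`.
#'
#' @param readset A [read_set].
#' @param model Model id (typically the best-fitting model for the
#'   protocol).
#' @param params Fitted [model_params].
#' @param standardize If `TRUE`, add a z-score column (mean/SD over the
#'   table).
#' @return Data frame with columns `transcript_id`, `length`,
#'   `raw_read_count`, `corrected_abundance` and optionally `z`.
#' @export
corrected_abundance <- function(readset, model, params, standardize = TRUE) {
  stopifnot(inherits(readset, "read_set"))
  model <- match_model(model)
  params <- .check_params(model, params)
  lens <- readset$transcripts$length
  areas <- coverage_area(model, params, lens)
  bad <- !is.finite(areas) | areas <= 0
  if (any(bad)) {
    stop("zero/non-finite coverage area for transcript length(s) ",
         paste(utils::head(lens[bad], 5), collapse = ", "))
  }
  counts <- vapply(readset$reads, length, integer(1))
  corrected <- counts / areas
  out <- data.frame(transcript_id = readset$transcripts$id,
                    length = lens,
                    raw_read_count = as.integer(counts),
                    corrected_abundance = corrected,
                    stringsAsFactors = FALSE)
  if (standardize) {
    out$z <- (corrected - mean(corrected)) / stats::sd(corrected)
  }
  out
}

#' Spike-in FPKM
#'
#' Standard FPKM for spike-in probes:
#' `1e9 * reads / (probe_length * total_spikein_reads)`, with the total
#' taken over reads mapping to spike-in probes only.
#'
#' @param read_count Reads mapped to the probe (vectorized).
#' @param probe_length Probe length in bases (> 0).
#' @param total_spikein_reads Total reads mapped to all spike-in probes
#'   (> 0).
#' @return Numeric vector of FPKM values.
#' @export
spikein_fpkm <- function(read_count, probe_length, total_spikein_reads) {
  if (any(probe_length <= 0)) stop("probe_length must be > 0")
  if (any(total_spikein_reads <= 0)) stop("total_spikein_reads must be > 0")
  1e9 * read_count / (probe_length * total_spikein_reads)
}

#' Read representation by transcript-length category
#'
#' Computes, per length category (`[0, w)`, `[w, 2w)`, ... with
#' `w = bin_width`), the fraction of reads mapping to transcripts in that
#' category in each read set, and the test/reference ratio of the fractions.
#' Higher processivity enriches long transcripts, so lowering `theta1`
#' raises the ratios of the upper categories.
#'
#' @param readset_test,readset_reference [read_set]s to compare.
#' @param bin_width Category width in bases (default 2000).
#' @param max_length If given, transcripts at or beyond this length are
#'   excluded (drops the open-ended top category).
#' @return Data frame with `category_start`, `category_end`,
#'   `frac_test`, `frac_reference`, `ratio` (`NA` where the reference
#'   category is empty).
#' @export
length_representation_ratio <- function(readset_test, readset_reference,
                                        bin_width = 2000, max_length = NULL) {
  stopifnot(inherits(readset_test, "read_set"),
            inherits(readset_reference, "read_set"))
  frac <- function(rs) {
    lens <- rs$transcripts$length
    counts <- vapply(rs$reads, length, integer(1))
    if (!is.null(max_length)) {
      keep <- lens < max_length
      lens <- lens[keep]
      counts <- counts[keep]
    }
    if (sum(counts) == 0) stop("a read set has no reads in range")
    cat_ <- floor(lens / bin_width)
    tapply(counts, cat_, sum) / sum(counts)
  }
  ft <- frac(readset_test)
  fr <- frac(readset_reference)
  cats <- sort(unique(as.integer(c(names(ft), names(fr)))))
  gt <- function(k, f) if (as.character(k) %in% names(f))
    unname(f[as.character(k)]) else 0
  out <- data.frame(
    category_start = cats * bin_width,
    category_end = (cats + 1) * bin_width,
    frac_test = vapply(cats, gt, numeric(1), f = ft),
    frac_reference = vapply(cats, gt, numeric(1), f = fr))
  out$ratio <- ifelse(out$frac_reference > 0,
                      out$frac_test / out$frac_reference, NA_real_)
  out
}
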