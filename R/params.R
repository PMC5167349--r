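#' Model identifiers
#'
#' The five library-preparation scenarios and the B&D mixture:
#' \describe{
#'   \item{A}{full-length first- and second-strand synthesis enforced
#'     (idealized template-switching / SMART-like selection).}
#'   \item{B}{second strand primed at the first-strand end; only complete
#'     second strands (reaching the transcript 3' end) are kept
#'     (idealized poly-A tagging with full-length PCR selection).}
#'   \item{C}{full-length first strands selected, second strand may stop
#'     anywhere.}
#'   \item{D}{no selection: first strand primed at the 3' end, second strand
#'     primed at the first-strand end, both may stop anywhere.}
#'   \item{E}{random priming of both strands; multiple priming is absorbed
#'     into modified rates theta1' = theta1 + alpha1, theta2' = theta2 +
#'     alpha2.}
#'   \item{BD}{mixture alpha * B + (1 - alpha) * D.}
#' }
#' @format Character vector of valid model names.
#' @export
MODEL_IDS <- c("A", "B", "C", "D", "E", "BD")

#' Validate a model identifier
#'
#' @param model Character scalar, one of [MODEL_IDS].
#' @return The matched model id (character scalar).
#' @export
match_model <- function(model) {
  if (!is.character(model) || length(model) != 1L || !(model %in% MODEL_IDS)) {
    stop("unknown model '", paste(model, collapse = ","),
         "'; must be one of ", paste(MODEL_IDS, collapse = ", "))
  }
  model
}

#' Parameter set for the coverage models
#'
#' One container holds every parameter any model can use; each model reads
#' the subset it needs and ignores the rest.
#'
#' @param theta1 Inverse processivity of first-strand synthesis, per base
#'   (>= 0). `1/theta1` is the mean synthesis length of the reverse
#'   transcriptase.
#' @param theta2 Inverse processivity of second-strand synthesis, per base
#'   (>= 0).
#' @param d Fragmentation edge divisor (> 0). Within distance `h` of a cDNA
#'   end the read-start weight is `1/d`; in the interior it is `1/d + 1`,
#'   i.e. interior coverage is higher by a factor `d + 1`.
#' @param h End-effect distance in bases (>= 0), shared between both cDNA
#'   ends.
#' @param alpha Mixture weight of model B in the BD mixture (in `[0, 1]`);
#'   ignored by the pure models.
#' @param alpha1,alpha2 Per-base priming probabilities for model E (>= 0).
#'   Model E uses the modified rates `theta1 + alpha1` and
#'   `theta2 + alpha2`, which must be positive when E is evaluated. Fits of
#'   model E report the modified rates directly (with `alpha1 = alpha2 = 0`),
#'   since only the sums are identifiable.
#' @return An object of class `model_params` (a named list).
#' @examples
#' p <- model_params(theta1 = 2e-4, theta2 = 5e-4, d = 4, h = 150)
#' coverage_density("D", p, x = 500, l = 6000)
#' @export
model_params <- function(theta1 = 0, theta2 = 0, d = 1, h = 0,
                         alpha = 0.5, alpha1 = 0, alpha2 = 0) {
  p <- list(theta1 = theta1, theta2 = theta2, d = d, h = h,
            alpha = alpha, alpha1 = alpha1, alpha2 = alpha2)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("parameter '", nm, "' must be a finite numeric scalar")
    }
  }
  if (theta1 < 0 || theta2 < 0) stop("theta1 and theta2 must be >= 0")
  if (d <= 0) stop("d must be > 0")
  if (h < 0) stop("h must be >= 0")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (alpha1 < 0 || alpha2 < 0) stop("alpha1 and alpha2 must be >= 0")
  structure(p, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("model_params:",
      paste(names(x), signif(unlist(x), 6), sep = "=", collapse = "  "),
      "\n")
  invisible(x)
}

# Per-model validation used by every operation taking (model, params).
.check_params <- function(model, p) {
  model <- match_model(model)
  if (!inherits(p, "model_params")) p <- do.call(model_params, as.list(p))
  if (model == "E") {
    if (p$theta1 + p$alpha1 <= 0 || p$theta2 + p$alpha2 <= 0) {
      stop("model E requires positive modified rates theta1 + alpha1 and ",
           "theta2 + alpha2")
    }
  }
  p
}

# Effective exponential rates for model E.
.e_rates <- function(p) {
  c(t1p = p$theta1 + p$alpha1, t2p = p$theta2 + p$alpha2)
}

# alpha1*alpha2 prefactor of model E; a pure scale that cancels in every
# normalized quantity.  Replaced by 1 when either alpha is 0 so that fits
# reporting only the modified rates still yield a usable intensity.
.e_prefactor <- function(p) {
  if (p$alpha1 > 0 && p$alpha2 > 0) p$alpha1 * p$alpha2 else 1
}

#' Serialize / deserialize a parameter configuration
#'
#' Flat key-value representation (`model`, `theta1`, `theta2`, `d`, `h`,
#' `alpha`, `alpha1`, `alpha2`) written as YAML or JSON depending on the
#' file extension (.yaml/.yml vs .json).
#'
#' @param model Model id.
#' @param params A [model_params] object.
#' @param path File to write or read.
#' @return `read_params_config` returns `list(model =, params =)`.
#' @export
write_params_config <- function(model, params, path) {
  model <- match_model(model)
  params <- .check_params(model, params)
  conf <- c(list(model = model), unclass(params))
  .atomic_write(path, function(tmp) {
    if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
      writeLines(yaml::as.yaml(conf), tmp)
    } else {
      jsonlite::write_json(conf, tmp, auto_unbox = TRUE, digits = NA)
    }
  })
  invisible(path)
}

#' @rdname write_params_config
#' @export
read_params_config <- function(path) {
  conf <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  model <- match_model(conf$model)
  keys <- intersect(names(conf),
                    c("theta1", "theta2", "d", "h", "alpha", "alpha1", "alpha2"))
  params <- do.call(model_params, lapply(conf[keys], as.numeric))
  list(model = model, params = params)
}

# Atomic file write: write to a temp file in the same directory, then rename.
.atomic_write <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("failed to move temporary file onto ", path)
  invisible(path)
}
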