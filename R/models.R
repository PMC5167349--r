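# Closed-form coverage models.
#
# Coordinates: x = 0 at the transcript 5' end, x in [0, l], continuous.
# First-strand synthesis runs 3' -> 5' (from s1 down to e1), second-strand
# synthesis 5' -> 3' (from s2 up to e2).  Synthesis lengths are exponential
# with rates theta1/theta2 (inverse processivities), with a point mass at the
# end of the template for runs that reach it.
#
# Each model's unnormalized read-start intensity decomposes as
#   f(x) = g0(x)/d + [h < x < l - h] * gh(x)
# where g0(x) = P(s2 < x < e2) (read anywhere on the double-stranded cDNA,
# edge weight 1/d) and gh(x) = P(s2 + h < x < e2 - h) (positions further than
# h from both fragment ends, extra weight 1).  Interior coverage therefore
# exceeds edge coverage by the factor d + 1.

# (1 - exp(-a)) / a, stable at a = 0.
.e1m <- function(a) ifelse(a == 0, 1, -expm1(-a) / a)

# Edge (g0) and conditional interior (gh) components, vectorized over x.
.cov_parts <- function(model, p, x, l) {
  t1 <- p$theta1; t2 <- p$theta2; h <- p$h
  th <- t1 + t2
  switch(model,
    A = {
      v <- rep(exp(-l * th), length(x))
      list(g0 = v, gh = v)
    },
    B = {
      if (th == 0) {
        list(g0 = rep(1, length(x)), gh = rep(1, length(x)))
      } else {
        k <- t2 * exp(-th * l)
        list(g0 = (t1 * exp(th * (x - l)) + k) / th,
             gh = (t1 * exp(th * (x - h - l)) + k) / th)
      }
    },
    C = list(g0 = exp(-t1 * l - t2 * x),
             gh = exp(-t1 * l - t2 * (x + h))),
    D = {
      if (th == 0) {
        list(g0 = rep(1, length(x)), gh = rep(1, length(x)))
      } else {
        list(g0 = (t1 * exp(-t1 * (l - x)) + t2 * exp(-t1 * l - t2 * x)) / th,
             gh = (t1 * exp(-t1 * (l - x) - t1 * h - 2 * t2 * h) +
                     t2 * exp(-t1 * l - t2 * (x + h))) / th)
      }
    },
    E = {
      r <- .e_rates(p); t1p <- r[["t1p"]]; t2p <- r[["t2p"]]
      tp <- t1p + t2p
      cE <- .e_prefactor(p) / (t1p * tp)
      list(g0 = cE * (1 - exp(-x * tp) - exp(-(l - x) * t1p) +
                        exp(-l * t1p - x * t2p)),
           gh = cE * (exp(-2 * h * tp) - exp(-(h + x) * tp) -
                        exp(-2 * h * t2p - (l + h - x) * t1p) +
                        exp(-l * t1p - (h + x) * t2p)))
    },
    stop("internal: no parts for model ", model)
  )
}

# Edge (A0 = integral of g0 over [0, l]) and interior
# (Ah = integral of gh over [h, l - h], only valid when h < l/2) areas.
.area_parts <- function(model, p, l) {
  t1 <- p$theta1; t2 <- p$theta2; h <- p$h
  th <- t1 + t2
  switch(model,
    A = list(A0 = l * exp(-l * th), Ah = (l - 2 * h) * exp(-l * th)),
    B = {
      if (th == 0) {
        list(A0 = l, Ah = l - 2 * h)
      } else {
        list(A0 = (t1 * l * .e1m(l * th) + t2 * l * exp(-l * th)) / th,
             Ah = (t1 * (exp(-2 * h * th) - exp(-l * th)) / th +
                     t2 * (l - 2 * h) * exp(-l * th)) / th)
      }
    },
    C = list(A0 = exp(-t1 * l) * l * .e1m(l * t2),
             Ah = exp(-t1 * l) *
               (if (t2 == 0) l - 2 * h
                else (exp(-2 * h * t2) - exp(-l * t2)) / t2)),
    D = {
      if (th == 0) {
        list(A0 = l, Ah = l - 2 * h)
      } else {
        list(A0 = l * .e1m(l * th),
             Ah = (exp(-2 * h * th) - exp(-l * th)) / th)
      }
    },
    E = {
      r <- .e_rates(p); t1p <- r[["t1p"]]; t2p <- r[["t2p"]]
      tp <- t1p + t2p
      cE <- .e_prefactor(p) / (t1p * tp)
      list(
        A0 = cE * (l - l * .e1m(l * tp) - l * .e1m(l * t1p) +
                     exp(-l * t1p) * l * .e1m(l * t2p)),
        Ah = cE * ((l - 2 * h) * exp(-2 * h * tp) -
                     (exp(-2 * h * tp) - exp(-l * tp)) / tp -
                     exp(-2 * h * t2p) *
                       (exp(-2 * h * t1p) - exp(-l * t1p)) / t1p +
                     exp(-l * t1p) *
                       (exp(-2 * h * t2p) - exp(-l * t2p)) / t2p)
      )
    },
    stop("internal: no area for model ", model)
  )
}

#' Semi-continuous density of a synthesis end point
#'
#' Distribution of the end point of a cDNA synthesis run that starts at
#' `start` and proceeds toward one transcript terminus.  The run length is
#' exponential with rate `theta`; runs that would pass the terminus stop
#' there, producing a Dirac point mass at the boundary (position 0 for
#' first-strand synthesis toward the 5' end, position `l` for second-strand
#' synthesis toward the 3' end) with mass `exp(-theta * run_max)`, the
#' survival probability of the run.
#'
#' @param start Start position in `[0, l]`.
#' @param theta Per-base stop rate (>= 0).
#' @param direction `"toward_5prime"` (first strand) or `"toward_3prime"`
#'   (second strand).
#' @param l Transcript length (> 0).
#' @return An object of class `position_density` with elements `continuous`
#'   (a vectorized density function of position), `point_masses` (data frame
#'   with columns `position`, `mass`), `support` (the admissible interval)
#'   and `total_mass()`.
#' @examples
#' pd <- synthesis_end_density(6000, 2e-4, "toward_5prime", 6000)
#' pd$point_masses      # mass exp(-1.2) of full-length synthesis at x = 0
#' @export
synthesis_end_density <- function(start, theta,
                                  direction = c("toward_5prime",
                                                "toward_3prime"),
                                  l) {
  direction <- match.arg(direction)
  if (!is.numeric(l) || l <= 0) stop("l must be > 0")
  if (start < 0 || start > l) stop("start must lie in [0, l]")
  if (theta < 0) stop("theta must be >= 0")
  if (direction == "toward_5prime") {
    run_max <- start
    boundary <- 0
    dens <- function(x) {
      ifelse(x >= 0 & x <= start, theta * exp(-theta * (start - x)), 0)
    }
    support <- c(0, start)
  } else {
    run_max <- l - start
    boundary <- l
    dens <- function(x) {
      ifelse(x >= start & x <= l, theta * exp(-theta * (x - start)), 0)
    }
    support <- c(start, l)
  }
  mass <- exp(-theta * run_max)
  structure(
    list(continuous = dens,
         point_masses = data.frame(position = boundary, mass = mass),
         support = support,
         total_mass = function(rel.tol = 1e-10) {
           cont <- if (theta == 0 || run_max == 0) 0 else
             stats::integrate(dens, support[1], support[2],
                              rel.tol = rel.tol)$value
           cont + mass
         }),
    class = "position_density")
}

#' @export
print.position_density <- function(x, ...) {
  cat("position_density on [", x$support[1], ", ", x$support[2],
      "]; point mass ", signif(x$point_masses$mass, 6), " at ",
      x$point_masses$position, "\n", sep = "")
  invisible(x)
}

#' Closed-form read-start coverage density
#'
#' Unnormalized intensity of sequencing-read start positions, including the
#' fragmentation end effect: positions within `h` of a fragment end carry
#' weight `1/d`, interior positions `1/d + 1`.  For positions with
#' `x <= h` or `x >= l - h` (and everywhere when `h >= l/2`) only the edge
#' branch applies.
#'
#' @param model Model id (see [MODEL_IDS]).
#' @param params [model_params].
#' @param x Position(s) in `[0, l]` (vectorized).
#' @param l Transcript length (> 0).
#' @return Nonnegative numeric vector, same length as `x`.
#' @export
coverage_density <- function(model, params, x, l) {
  model <- match_model(model)
  params <- .check_params(model, params)
  if (!is.numeric(l) || length(l) != 1L || l <= 0) stop("l must be > 0")
  if (any(x < 0 | x > l)) stop("positions x must lie in [0, l]")
  if (model == "BD") {
    a <- params$alpha
    return(a * coverage_density("B", params, x, l) +
             (1 - a) * coverage_density("D", params, x, l))
  }
  parts <- .cov_parts(model, params, x, l)
  interior <- x > params$h & x < l - params$h
  parts$g0 / params$d + ifelse(interior, parts$gh, 0)
}

#' Area under the coverage density (correction factor)
#'
#' Closed-form integral of [coverage_density] over `[0, l]`.  This is the
#' model's length-dependent correction factor: the expected number of reads
#' a transcript yields is proportional to it, so dividing raw read counts by
#' it removes the length bias (see [corrected_abundance]).
#'
#' @inheritParams coverage_density
#' @return Positive numeric scalar (vectorized over `l`).
#' @export
coverage_area <- function(model, params, l) {
  model <- match_model(model)
  params <- .check_params(model, params)
  if (any(l <= 0)) stop("l must be > 0")
  if (length(l) > 1L) {
    return(vapply(l, function(li) coverage_area(model, params, li),
                  numeric(1)))
  }
  if (model == "BD") {
    a <- params$alpha
    return(a * coverage_area("B", params, l) +
             (1 - a) * coverage_area("D", params, l))
  }
  ap <- .area_parts(model, params, l)
  ap$A0 / params$d + if (params$h < l / 2) ap$Ah else 0
}

#' Per-read log-likelihood
#'
#' Log of the per-transcript normalized read-start density,
#' `log(coverage_density(x) / coverage_area(l))`.  The exponentiated value
#' integrates to 1 over `[0, l]`; read positions are modeled conditional on
#' their transcript.
#'
#' @inheritParams coverage_density
#' @return Numeric vector of log-densities; `-Inf` where the density
#'   vanishes.  Degenerate parameters with zero or non-finite area yield
#'   `-Inf` throughout (so an MCMC proposal is rejected rather than erroring).
#' @export
read_log_likelihood <- function(model, params, x, l) {
  area <- coverage_area(model, params, l)
  if (!is.finite(area) || area <= 0) {
    return(rep(-Inf, length(x)))
  }
  f <- coverage_density(model, params, x, l)
  ifelse(f > 0, log(f) - log(area), -Inf)
}
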