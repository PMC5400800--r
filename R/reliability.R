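#' Composite (construct) reliability from factor loadings
#'
#' `CR = (sum lambda_i)^2 / ((sum lambda_i)^2 + sum delta_i)`, the
#' reliability of the unit-weighted composite implied by a one-factor
#' model with standardized loadings `lambda` and error variances `delta`.
#'
#' @param loadings a [factor_loading_set()].
#' @return CR in `[0, 1]`.
#' @examples
#' construct_reliability(factor_loading_set(paste0("V", 1:6), rep(0.7, 6)))
#' @export
construct_reliability <- function(loadings) {
  stopifnot(inherits(loadings, "factor_loading_set"))
  if (length(loadings$lambda) == 0) stop("empty loading set")
  s <- sum(loadings$lambda)^2
  s / (s + sum(loadings$delta))
}

#' Variance extracted from factor loadings
#'
#' `VE = sum(lambda_i^2) / n`: the mean squared standardized loading, i.e.
#' the average share of item variance the common factor explains. Values
#' near or above 0.5 are conventionally read as the construct explaining
#' more variance than error.
#'
#' @param loadings a [factor_loading_set()].
#' @return VE in `[0, 1]`.
#' @examples
#' variance_extracted(factor_loading_set(c("a", "b"), c(0.6, 0.8)))  # 0.5
#' @export
variance_extracted <- function(loadings) {
  stopifnot(inherits(loadings, "factor_loading_set"))
  if (length(loadings$lambda) == 0) stop("empty loading set")
  mean(loadings$lambda^2)
}

#' Compare reliability of a full and a reduced scale
#'
#' Computes CR and VE for both loading sets and their differences
#' (reduced minus full), and flags the reduced scale as acceptable when
#' its CR meets the conventional 0.7 threshold.
#'
#' @param full loadings of the complete scale.
#' @param reduced loadings of the reduced scale.
#' @param cr_threshold acceptability cut for the reduced scale's CR
#'   (default 0.7).
#' @return An object of class `scale_comparison`: list with `full`,
#'   `reduced` (each `cr`, `ve`, `n_items`), `cr_diff`, `ve_diff`,
#'   `reliability_acceptable`.
#' @export
compare_scales <- function(full, reduced, cr_threshold = 0.7) {
  summ <- function(l) list(cr = construct_reliability(l),
                           ve = variance_extracted(l),
                           n_items = length(l$lambda))
  f <- summ(full)
  r <- summ(reduced)
  structure(list(full = f, reduced = r,
                 cr_diff = r$cr - f$cr, ve_diff = r$ve - f$ve,
                 reliability_acceptable = r$cr >= cr_threshold),
            class = "scale_comparison")
}

#' @export
print.scale_comparison <- function(x, ...) {
  cat("scale_comparison\n")
  cat(sprintf("  full    (%2d items): CR = %.3f, VE = %.3f\n",
              x$full$n_items, x$full$cr, x$full$ve))
  cat(sprintf("  reduced (%2d items): CR = %.3f, VE = %.3f\n",
              x$reduced$n_items, x$reduced$cr, x$reduced$ve))
  cat(sprintf("  reduced scale reliability acceptable: %s\n",
              if (x$reliability_acceptable) "yes" else "no"))
  invisible(x)
}
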