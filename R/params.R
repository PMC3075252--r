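#' Congruence parameters
#'
#' Bundles the five user parameters that control track construction and
#' congruence: the point-deduplication radius (\code{cut_value}), the two
#' distance bounds of congruence rule 1 (\code{lmin}, \code{lmax}), the
#' full-overlap bound of rule 2 (\code{lmax_line}), and the similarity
#' threshold used to collapse redundant tracks (\code{min_si}). All
#' distances are in decimal degrees. The parameters must satisfy the
#' constraining rule \code{cut_value <= lmin <= lmax <= lmax_line}; any
#' violation signals an error naming the violated inequality.
#'
#' @param cut_value minimum Euclidean distance below which occurrence
#'   points of a species are collapsed to one point (degrees, >= 0).
#' @param lmin upper bound on the minimum inter-segment distance for
#'   rule 1 (degrees).
#' @param lmax upper bound on the maximum inter-segment distance for
#'   rule 1 (degrees).
#' @param lmax_line upper bound on the maximum perpendicular distance in
#'   the full-overlap configuration for rule 2 (degrees).
#' @param min_si similarity threshold in \code{[0, 1]}; track pairs whose
#'   max-direction similarity index reaches it are merged.
#' @return an object of class \code{congruence_params}.
#' @examples
#' congruence_params(2, 2.5, 3, 4, 0.8)
#' @export
congruence_params <- function(cut_value, lmin, lmax, lmax_line, min_si) {
  vals <- c(cut_value = cut_value, lmin = lmin, lmax = lmax,
            lmax_line = lmax_line, min_si = min_si)
  if (!is.numeric(vals) || anyNA(vals) || any(!is.finite(vals)))
    .param_error("all parameters must be finite numbers")
  if (cut_value < 0)
    .param_error("0 <= cut_value is violated")
  if (cut_value > lmin)
    .param_error("cut_value <= lmin is violated")
  if (lmin > lmax)
    .param_error("lmin <= lmax is violated")
  if (lmax > lmax_line)
    .param_error("lmax <= lmax_line is violated")
  if (min_si < 0 || min_si > 1)
    .param_error("min_si must lie in [0, 1]")
  structure(list(cut_value = cut_value, lmin = lmin, lmax = lmax,
                 lmax_line = lmax_line, min_si = min_si),
            class = "congruence_params")
}

.param_error <- function(msg) {
  stop(structure(class = c("gt_param_error", "error", "condition"),
                 list(message = paste0("invalid congruence parameters: ", msg),
                      call = NULL)))
}

.check_params <- function(params) {
  if (!inherits(params, "congruence_params"))
    .param_error("use congruence_params() to build the parameter set")
  invisible(params)
}

#' @export
print.congruence_params <- function(x, ...) {
  cat("Congruence parameters (degrees):\n")
  cat(sprintf("  cut value = %g, lmin = %g, lmax = %g, lmax.line = %g, min-SI = %g\n",
              x$cut_value, x$lmin, x$lmax, x$lmax_line, x$min_si))
  invisible(x)
}
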