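#' Construct a test result
#'
#' Light-weight container for the outcome of one association test on one
#' gene.
#'
#' @param method method tag: one of \code{"TH"}, \code{"RCS"},
#'   \code{"RCS-C"}, \code{"CA"}, \code{"CA-P"}, \code{"SK"}, \code{"SK-R"}.
#' @param statistic test statistic value.
#' @param p_value p-value in [0, 1].
#' @param mode inference mode: \code{"asymptotic"}, \code{"permutation"},
#'   \code{"bootstrap"} or \code{"resampling"}.
#' @param n_resamples number of resampling draws, or NA for asymptotic
#'   inference.
#' @param degenerate logical flag: the statistic was degenerate (e.g. no
#'   carriers, constant carriage, zero null variance) and the p-value was
#'   set to 1.
#' @return an object of class \code{rv_test_result}.
#' @export
test_result <- function(method, statistic, p_value, mode,
                        n_resamples = NA_integer_, degenerate = FALSE) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(method = method, statistic = statistic, p_value = p_value,
                 mode = mode, n_resamples = n_resamples,
                 degenerate = degenerate),
            class = "rv_test_result")
}

#' @export
print.rv_test_result <- function(x, ...) {
  cat(sprintf("%s test (%s%s): statistic = %.4g, p = %.4g%s\n",
              x$method, x$mode,
              if (is.na(x$n_resamples)) "" else
                sprintf(", B = %d", x$n_resamples),
              x$statistic, x$p_value,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' @export
as.data.frame.rv_test_result <- function(x, ...) {
  data.frame(method = x$method, statistic = x$statistic,
             p_value = x$p_value, mode = x$mode,
             n_resamples = x$n_resamples, degenerate = x$degenerate)
}
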