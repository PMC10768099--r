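#' Four-parameter logistic (4PL) dose-response value
#'
#' \eqn{y = d + (a - d) / (1 + (x/c)^b)}: `a` is the response at zero dose,
#' `d` the response at infinite dose, `c` the midpoint concentration (EC50)
#' and `b` the slope factor. With `d > a` and `b > 0` the curve increases
#' monotonically in `x`, the shape of a reporter-cell absorbance readout.
#'
#' @param x Concentration(s), same units as `c`.
#' @param curve A `standard_curve` object or list with elements `a`, `d`,
#'   `c`, `b`.
#' @return Predicted response(s).
#' @export
fourpl <- function(x, curve) {
  curve$d + (curve$a - curve$d) / (1 + (x / curve$c)^curve$b)
}

#' Fit a 4PL standard curve to calibration data
#'
#' Unweighted least squares via Levenberg-Marquardt, restarted from a fixed
#' grid of initial values so the fit is deterministic for given data.
#' Technical replicates (duplicate concentrations) are averaged before
#' fitting.
#'
#' @param concentration Standard concentrations; at least 5 distinct values
#'   spanning at least two orders of magnitude.
#' @param absorbance Measured responses, same length.
#' @return A `standard_curve`: list with `a`, `d`, `c`, `b`, `sse`, `rmse`,
#'   `n` and the averaged calibration data.
#' @examples
#' x <- c(0.1, 1, 3, 10, 30, 100)
#' y <- fourpl(x, list(a = 0.05, d = 2, c = 10, b = 1.2))
#' fit_4pl(x, y)
#' @export
fit_4pl <- function(concentration, absorbance) {
  if (length(concentration) != length(absorbance)) {
    stop("fit_4pl: concentration and absorbance lengths differ")
  }
  keep <- is.finite(concentration) & is.finite(absorbance)
  x <- concentration[keep]
  y <- absorbance[keep]
  if (any(x <= 0)) stop("fit_4pl: concentrations must be positive")
  # average technical replicates at identical concentrations
  agg <- tapply(y, x, mean)
  x <- as.numeric(names(agg))
  y <- as.numeric(agg)
  o <- order(x)
  x <- x[o]
  y <- y[o]
  if (length(x) < 5) stop("fit_4pl: need >= 5 distinct concentrations")
  if (max(x) / min(x) < 100) {
    stop("fit_4pl: standards must span >= 2 orders of magnitude")
  }
  if (stats::var(y) == 0) stop("fit_4pl: constant absorbance, cannot fit")

  span <- max(y) - min(y)
  a0 <- min(y) - 0.05 * span
  d0 <- max(y) + 0.05 * span
  c_grid <- exp(seq(log(min(x)), log(max(x)), length.out = 5))
  b_grid <- c(0.5, 1, 2, -0.5, -1, -2)
  best <- NULL
  for (c0 in c_grid) {
    for (b0 in b_grid) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          y ~ d + (a - d) / (1 + (x / c)^b),
          start = list(a = a0, d = d0, c = c0, b = b0),
          lower = c(a = -Inf, d = -Inf, c = .Machine$double.xmin, b = -Inf),
          control = minpack.lm::nls.lm.control(maxiter = 200)
        ),
        error = function(e) NULL
      )
      if (is.null(fit)) next
      sse <- sum(stats::resid(fit)^2)
      if (is.null(best) || sse < best$sse - 1e-12 * (1 + best$sse)) {
        best <- list(fit = fit, sse = sse)
      }
    }
  }
  if (is.null(best)) stop("fit_4pl: no start converged; data may be degenerate")
  p <- as.list(stats::coef(best$fit))
  # canonical orientation: report with d as the upper asymptote
  if (p$a > p$d) {
    p <- list(a = p$d, d = p$a, c = p$c, b = -p$b)
  }
  if (!(p$d > p$a) || p$c <= 0 || !is.finite(p$b) || p$b == 0) {
    stop("fit_4pl: fitted parameters violate 4PL constraints (a=",
         signif(p$a, 4), ", d=", signif(p$d, 4), ", c=", signif(p$c, 4),
         ", b=", signif(p$b, 4), ")")
  }
  structure(
    list(a = p$a, d = p$d, c = p$c, b = p$b,
         sse = best$sse, rmse = sqrt(best$sse / length(x)),
         n = length(x), data = data.frame(concentration = x, absorbance = y)),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("4PL standard curve: a =", signif(x$a, 4), " d =", signif(x$d, 4),
      " c =", signif(x$c, 4), " b =", signif(x$b, 4), "\n")
  cat("  fit on", x$n, "points, rmse =", signif(x$rmse, 3), "\n")
  invisible(x)
}

#' Invert a 4PL curve: concentration from response
#'
#' \eqn{x = c \left( \frac{a - d}{y - d} - 1 \right)^{1/b}}; the exact
#' algebraic inverse of [fourpl()], defined for responses strictly between
#' the asymptotes.
#'
#' @param curve A `standard_curve`.
#' @param y Response value(s), each strictly inside `(a, d)`.
#' @return Concentration(s).
#' @export
invert_4pl <- function(curve, y) {
  lo <- min(curve$a, curve$d)
  hi <- max(curve$a, curve$d)
  if (any(y <= lo) || any(y >= hi)) {
    stop("invert_4pl: response outside the open interval (",
         signif(lo, 4), ", ", signif(hi, 4), "); use another dilution")
  }
  curve$c * ((curve$a - curve$d) / (y - curve$d) - 1)^(1 / curve$b)
}

#' Back-calculate a neat concentration from a dilution series
#'
#' Of the readings falling strictly within the curve's usable window (the
#' asymptotes shrunk by a 5% margin), the one closest to the midpoint
#' absorbance \eqn{(a+d)/2} is inverted and multiplied by its dilution
#' factor; the midpoint is where the inverse curve amplifies noise least.
#' Ties are broken toward the lower dilution factor.
#'
#' @param dilution_factors Numeric vector `>= 1`, strictly increasing.
#' @param absorbance Readings, same length.
#' @param curve A `standard_curve`.
#' @param margin Usable-window margin as a fraction of `d - a` (default 0.05).
#' @param censor With no in-range reading, substitute the nearest
#'   quantifiable bound (limit of detection at the lowest dilution, upper
#'   limit of quantification at the highest) instead of erroring; the
#'   substitution is flagged in the `censored` field. Default `FALSE`:
#'   out-of-range series are an error.
#' @return List with `concentration` (neat, standard-equivalent units),
#'   `dilution_used`, `absorbance_used`, `censored` (`"none"`, `"below"`
#'   or `"above"`).
#' @export
quantify_dilution_series <- function(dilution_factors, absorbance, curve,
                                     margin = 0.05, censor = FALSE) {
  if (length(dilution_factors) != length(absorbance)) {
    stop("quantify: dilution_factors and absorbance lengths differ")
  }
  if (any(dilution_factors < 1)) stop("quantify: dilution factors must be >= 1")
  if (is.unsorted(dilution_factors, strictly = TRUE)) {
    stop("quantify: dilution factors must be strictly increasing")
  }
  m <- margin * (curve$d - curve$a)
  lo <- curve$a + m
  hi <- curve$d - m
  ok <- absorbance > lo & absorbance < hi
  if (!any(ok)) {
    mid <- (curve$a + curve$d) / 2
    if (censor) {
      if (max(absorbance) >= mid) {
        return(list(concentration = invert_4pl(curve, hi) *
                      max(dilution_factors),
                    dilution_used = max(dilution_factors),
                    absorbance_used = hi, censored = "above"))
      }
      return(list(concentration = invert_4pl(curve, lo) *
                    min(dilution_factors),
                  dilution_used = min(dilution_factors),
                  absorbance_used = lo, censored = "below"))
    }
    if (all(absorbance >= hi)) {
      stop("quantify: outside dynamic range (saturated at all dilutions)")
    } else if (all(absorbance <= lo)) {
      stop("quantify: outside dynamic range (below detection at all dilutions)")
    } else {
      stop("quantify: outside dynamic range (mixed saturated/below-detection)")
    }
  }
  mid <- (curve$a + curve$d) / 2
  cand <- which(ok)
  dist <- abs(absorbance[cand] - mid)
  # which.min takes the first minimum; candidates are ordered by increasing
  # dilution, so ties already resolve toward the lower dilution
  pick <- cand[which.min(dist)]
  conc <- invert_4pl(curve, absorbance[pick]) * dilution_factors[pick]
  list(concentration = conc,
       dilution_used = dilution_factors[pick],
       absorbance_used = absorbance[pick], censored = "none")
}

#' Quantify bioactive MAMP levels for a whole assay table
#'
#' Fits one standard curve per analyte from the standards table, then
#' back-calculates every sample's neat concentration from its dilution
#' series.
#'
#' @param assay Long data frame with columns `sample_id`, `analyte`
#'   (`"lps"` or `"flagellin"`), `dilution_factor`, `absorbance`.
#' @param standards Data frame with columns `analyte`, `concentration`,
#'   `absorbance`.
#' @param margin,censor Passed to [quantify_dilution_series()].
#' @return Data frame `sample_id`, `analyte`, `concentration`,
#'   `dilution_used`, `censored`, with the fitted curves in attribute
#'   `"curves"`.
#' @export
quantify_mamp <- function(assay, standards, margin = 0.05, censor = FALSE) {
  need <- c("sample_id", "analyte", "dilution_factor", "absorbance")
  if (!all(need %in% names(assay))) {
    stop("quantify_mamp: assay table needs columns ",
         paste(need, collapse = ", "))
  }
  analytes <- unique(assay$analyte)
  curves <- lapply(stats::setNames(analytes, analytes), function(an) {
    st <- standards[standards$analyte == an, ]
    if (nrow(st) == 0) stop("quantify_mamp: no standards for analyte ", an)
    fit_4pl(st$concentration, st$absorbance)
  })
  keys <- unique(assay[, c("sample_id", "analyte")])
  out <- vector("list", nrow(keys))
  for (k in seq_len(nrow(keys))) {
    rows <- assay$sample_id == keys$sample_id[k] &
      assay$analyte == keys$analyte[k]
    ser <- assay[rows, ]
    ser <- ser[order(ser$dilution_factor), ]
    q <- quantify_dilution_series(ser$dilution_factor, ser$absorbance,
                                  curves[[keys$analyte[k]]], margin = margin,
                                  censor = censor)
    out[[k]] <- data.frame(sample_id = keys$sample_id[k],
                           analyte = keys$analyte[k],
                           concentration = q$concentration,
                           dilution_used = q$dilution_used,
                           censored = q$censored,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "curves") <- curves
  res
}
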