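#' Fit a first-order decay rate to a survival curve
#'
#' Log-linear least squares on log S(t) = -k t; suitable for recovering a
#' first-order (implicit-water or scavenging) rate from a simulated
#' survival fraction.
#'
#' @param data Data frame with a time column (s) and a survival-fraction
#'   column in (0, 1\].
#' @param time,value Column names.
#' @return Object of class `rate_fit` (see [tidy()] / [glance()] methods).
#' @export
fit_first_order <- function(data, time = "time", value = "survival") {
  tt <- data[[time]]
  ss <- data[[value]]
  keep <- is.finite(ss) & ss > 0
  if (sum(keep) < 2L) stop("need at least 2 positive survival points",
                           call. = FALSE)
  fit <- lm(log(ss[keep]) ~ 0 + tt[keep])
  rate <- -unname(coef(fit)[1])
  se <- sqrt(diag(vcov(fit)))[1]
  structure(list(type = "first_order", rate = rate, se = unname(se),
                 fit = fit, nobs = sum(keep)),
            class = "rate_fit")
}

#' Fit a second-order rate constant to a homogeneous decay
#'
#' For a single species decaying by A + A -> products with
#' d\[A\]/dt = -2k\[A\]^2 (the default tabulated-rate convention),
#' 1/\[A\](t) is linear in t with slope 2k.  The count trajectory is
#' converted to concentration via the box volume and the slope fitted by
#' least squares.
#'
#' @param data Data frame with time (s) and count columns.
#' @param volume_dm3 Simulation box volume in dm^3.
#' @param time,count Column names.
#' @param aa_convention `"obs2"` (slope = 2k) or `"k1"` (slope = k),
#'   matching [reaction_table()].
#' @return Object of class `rate_fit` with element `k`
#'   (dm^3 mol^-1 s^-1).
#' @export
fit_second_order <- function(data, volume_dm3, time = "time",
                             count = "count",
                             aa_convention = c("obs2", "k1")) {
  aa_convention <- match.arg(aa_convention)
  tt <- data[[time]]
  nn <- data[[count]]
  keep <- is.finite(nn) & nn > 0
  if (sum(keep) < 3L) stop("need at least 3 positive counts", call. = FALSE)
  conc <- nn[keep] / (AVOGADRO * volume_dm3)
  fit <- lm(I(1 / conc) ~ tt[keep])
  slope <- unname(coef(fit)[2])
  se <- sqrt(diag(vcov(fit)))[2]
  div <- if (aa_convention == "obs2") 2 else 1
  structure(list(type = "second_order", k = slope / div,
                 se = unname(se) / div, fit = fit, nobs = sum(keep),
                 aa_convention = aa_convention),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  if (x$type == "first_order") {
    cat(sprintf("<rate_fit> first-order: k = %.4g s^-1 (se %.2g, n = %d)\n",
                x$rate, x$se, x$nobs))
  } else {
    cat(sprintf(
      "<rate_fit> second-order (%s): k = %.4g dm^3 mol^-1 s^-1 (se %.2g, n = %d)\n",
      x$aa_convention, x$k, x$se, x$nobs))
  }
  invisible(x)
}

#' Tidy a rate fit
#'
#' @param x A `rate_fit`.
#' @param ... Unused.
#' @return One-row tibble with `term`, `estimate`, `std.error`.
#' @method tidy rate_fit
#' @export
tidy.rate_fit <- function(x, ...) {
  if (x$type == "first_order") {
    tibble::tibble(term = "rate", estimate = x$rate, std.error = x$se)
  } else {
    tibble::tibble(term = "k", estimate = x$k, std.error = x$se)
  }
}

#' Summarise a rate fit
#'
#' @param x A `rate_fit`.
#' @param ... Unused.
#' @return One-row tibble with the estimate, its standard error, the
#'   R-squared of the linearized fit and the number of points used.
#' @method glance rate_fit
#' @export
glance.rate_fit <- function(x, ...) {
  tibble::tibble(
    estimate = if (x$type == "first_order") x$rate else x$k,
    std.error = x$se,
    r.squared = summary(x$fit)$r.squared,
    nobs = x$nobs,
    type = x$type
  )
}
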