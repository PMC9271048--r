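# Coefficient of determination without summary.lm (stable for exact fits).
.rsq <- function(residuals, y) {
  tot <- sum((y - mean(y))^2)
  if (tot == 0) return(1)
  1 - sum(residuals^2) / tot
}

#' Germination rate
#'
#' \eqn{GR\% = 100 \cdot N_{gs} / N_{ts}}: germinated over total seeds per
#' well.
#'
#' @param Ngs germinated seeds per well (integer >= 0); vectorized.
#' @param Nts total seeds per well (integer > 0); vectorized.
#' @return data.frame with columns \code{Ngs}, \code{Nts}, \code{GR}
#'   (percent).
#' @examples
#' germinationRate(30, 60)$GR  # 50
#' @export
germinationRate <- function(Ngs, Nts) {
  Ngs <- as.integer(Ngs); Nts <- as.integer(Nts)
  if (any(Nts <= 0L)) stop("Nts must be > 0")
  if (any(Ngs < 0L)) stop("Ngs must be >= 0")
  if (any(Ngs > Nts)) stop("Ngs cannot exceed Nts")
  data.frame(Ngs = Ngs, Nts = Nts, GR = 100 * Ngs / Nts)
}

#' Initial linear hydrolysis rate from a fluorogenic-substrate time course
#'
#' Ordinary least-squares slope of background-corrected fluorescence
#' versus time over the initial linear window (default the first 8
#' minutes, where substrate turnover is far from saturation).
#'
#' @param times time points in minutes.
#' @param fluorescence fluorescence readings (AU), same length.
#' @param background background-hydrolysis readings to subtract: a series
#'   of the same length or a single constant (default 0).
#' @param window \code{c(t_start, t_end)} in minutes, closed (default
#'   \code{c(0, 8)}); must contain >= 3 points.
#' @return list with \code{slope} (AU/min), \code{intercept},
#'   \code{window}, \code{r_squared}, \code{n}.
#' @export
ylgInitialRate <- function(times, fluorescence, background = 0,
                           window = c(0, 8)) {
  stopifnot(length(times) == length(fluorescence))
  if (length(background) == 1L)
    background <- rep(background, length(times))
  if (length(background) != length(times))
    stop("background must match the fluorescence series length")
  if (window[1L] < min(times) - 1e-9 || window[2L] > max(times) + 1e-9)
    stop("window must lie within the data time range")
  keep <- times >= window[1L] & times <= window[2L]
  if (sum(keep) < 3L)
    stop(sprintf("need >= 3 points inside the window, found %d", sum(keep)))
  y <- fluorescence[keep] - background[keep]
  t <- times[keep]
  fit <- stats::lm(y ~ t)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       window = window,
       r_squared = .rsq(stats::resid(fit), y),
       n = sum(keep))
}

#' Relative inhibition of the initial rate
#'
#' \eqn{100 (1 - v_{compound}/v_{control})}, clipped to [0, 100] with the
#' clipping flagged in the \code{clipped} attribute (a negative value
#' means apparent activation, > 100 an over-corrected background).
#'
#' @param slopeCompound initial rate with the compound present.
#' @param slopeControl uninhibited control initial rate (> 0).
#' @return inhibition percentage in [0, 100] with attribute
#'   \code{clipped}.
#' @examples
#' relativeInhibition(0.25, 1)  # 75
#' @export
relativeInhibition <- function(slopeCompound, slopeControl) {
  if (any(slopeControl <= 0)) stop("control slope must be > 0")
  raw <- 100 * (1 - slopeCompound / slopeControl)
  out <- pmin(pmax(raw, 0), 100)
  attr(out, "clipped") <- raw < 0 | raw > 100
  out
}

#' Four-parameter logistic dose-response fit (IC50 / EC50)
#'
#' Fits \deqn{y = bottom + \frac{top - bottom}{1 + 10^{h (\log_{10} m -
#' \log_{10} c)}}}{y = bottom + (top - bottom)/(1 + 10^(h(log10(m) -
#' log10(c))))} in log10 concentration by Levenberg-Marquardt least
#' squares and reports the midpoint m as the IC50 or EC50.  The
#' initialization is fixed and documented (top/bottom from the response
#' extremes, midpoint at the concentration whose response is nearest the
#' half-range, Hill slope of magnitude 1 signed by the observed
#' concentration-response trend), so the fit is deterministic given the
#' data.  Non-convergence and degenerate inputs are reported via
#' \code{converged = FALSE} with a diagnostic message, never silently.
#'
#' @param conc concentrations (M), > 0, >= 4 distinct values.
#' @param response responses in percent (inhibition or germination).
#' @param mode \code{"ic50"} or \code{"ec50"} (labels the midpoint).
#' @param constrain fix top = 100 and bottom = 0 instead of fitting them
#'   (default FALSE).
#' @return list with \code{ic50} or \code{ec50} (M), \code{log10_mid},
#'   \code{hill}, \code{top}, \code{bottom}, \code{converged},
#'   \code{r_squared}, \code{message}.
#' @export
fitDoseResponse <- function(conc, response, mode = c("ic50", "ec50"),
                            constrain = FALSE) {
  mode <- match.arg(mode)
  stopifnot(length(conc) == length(response))
  if (any(conc <= 0)) stop("concentrations must be > 0")
  if (length(unique(conc)) < 4L)
    stop("need >= 4 distinct concentrations")
  lx <- log10(conc)
  fail <- function(msg) {
    out <- list(NA_real_, log10_mid = NA_real_, hill = NA_real_,
                top = NA_real_, bottom = NA_real_, converged = FALSE,
                r_squared = NA_real_, message = msg)
    names(out)[1L] <- mode
    out
  }
  if (stats::sd(response) == 0)
    return(fail("constant response: midpoint not identifiable"))

  top0 <- max(response); bot0 <- min(response)
  half <- (top0 + bot0) / 2
  mid0 <- lx[which.min(abs(response - half))]
  trend <- stats::cor(lx, response, method = "spearman")
  hill0 <- if (!is.na(trend) && trend < 0) -1 else 1

  df <- data.frame(lx = lx, y = response)
  fit <- tryCatch({
    if (constrain) {
      minpack.lm::nlsLM(
        y ~ 100 / (1 + 10^(hill * (mid - lx))),
        data = df, start = list(mid = mid0, hill = hill0),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + 10^(hill * (mid - lx))),
        data = df,
        start = list(bottom = bot0, top = top0, mid = mid0, hill = hill0),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) e)
  if (inherits(fit, "error")) return(fail(conditionMessage(fit)))

  cf <- stats::coef(fit)
  resid <- stats::resid(fit)
  rsq <- 1 - sum(resid^2) / sum((response - mean(response))^2)
  out <- list(10^unname(cf["mid"]),
              log10_mid = unname(cf["mid"]),
              hill = unname(cf["hill"]),
              top = if (constrain) 100 else unname(cf["top"]),
              bottom = if (constrain) 0 else unname(cf["bottom"]),
              converged = TRUE, r_squared = rsq, message = "")
  names(out)[1L] <- mode
  out
}

#' First-order decay fit and half-life
#'
#' Fits \eqn{\ln(remaining) = \ln(R_0) - k t} by ordinary least squares
#' (the standard analysis of percent-remaining HPLC peak-area series) and
#' reports \eqn{t_{1/2} = \ln 2 / k}.  A non-decaying series yields
#' \code{k <= 0} with \code{t_half = Inf} and a flag, not an error.
#'
#' @param times time points in hours (>= 3).
#' @param remaining percent remaining at each time (> 0).
#' @return list with \code{k} (per hour), \code{t_half} (hours; Inf when
#'   k <= 0), \code{r_squared}, \code{decaying} flag.
#' @examples
#' t <- 0:6
#' fitDecay(t, 100 * exp(-log(2) / 3 * t))$t_half  # 3
#' @export
fitDecay <- function(times, remaining) {
  stopifnot(length(times) == length(remaining))
  if (length(times) < 3L) stop("need >= 3 time points")
  if (any(remaining <= 0))
    stop("remaining fractions must be > 0 (log-linear fit)")
  fit <- stats::lm(log(remaining) ~ times)
  k <- -unname(stats::coef(fit)[2L])
  # guard against pure floating-point slopes on constant series
  tiny <- 1e-12 * max(1, max(abs(log(remaining))))
  decaying <- k > tiny
  list(k = k,
       t_half = if (decaying) log(2) / k else Inf,
       r_squared = .rsq(stats::resid(fit), log(remaining)),
       decaying = decaying)
}

#' Percent hydrolysis relative to a blank control
#'
#' \eqn{100 (1 - A_{sample}/A_{blank})} from HPLC peak areas, the blank
#' (no-enzyme) incubation serving as the reference amount.
#'
#' @param areaBlank peak area of the blank control (> 0).
#' @param areaSample peak area after incubation with the receptor (>= 0).
#' @return hydrolysis percentage.
#' @examples
#' hydrolysisPercent(1000, 481)  # 51.9
#' @export
hydrolysisPercent <- function(areaBlank, areaSample) {
  if (any(areaBlank <= 0)) stop("blank area must be > 0")
  if (any(areaSample < 0)) stop("sample area must be >= 0")
  100 * (1 - areaSample / areaBlank)
}

#' Replicate summary (mean and SD)
#'
#' Per-condition mean and standard deviation over replicates, the
#' reporting convention for triplicate assays.
#'
#' @param values numeric vector of replicate measurements.
#' @param group grouping factor/vector of the same length.
#' @return data.frame with columns \code{group}, \code{n}, \code{mean},
#'   \code{sd}.
#' @export
replicateSummary <- function(values, group) {
  stopifnot(length(values) == length(group))
  g <- factor(group, levels = unique(group))
  out <- data.frame(
    group = levels(g),
    n = as.integer(tapply(values, g, length)),
    mean = as.numeric(tapply(values, g, mean)),
    sd = as.numeric(tapply(values, g, stats::sd)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
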