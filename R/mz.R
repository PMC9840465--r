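# Monoisotopic masses of the lightest stable isotopes (Da).
# C is exactly 12 by definition of the unified atomic mass unit.
.ISOTOPE_MASS <- c(
  H = 1.0078250319,
  C = 12,
  N = 14.0030740052,
  O = 15.9949146221,
  P = 30.97376151,
  S = 31.97207069
)

# Mass of a proton (Da); the electron-mass refinement is folded into this
# conventional value, which reproduces published [M-H]- m/z to 4 dp.
.PROTON_MASS <- 1.007276

#' Parse a molecular formula string
#'
#' Converts a Hill-style formula such as \code{"C9H14N5O4P"} into a named
#' integer vector of element counts. Only single-letter element symbols
#' present in the isotope table (C, H, N, O, P, S) are supported.
#'
#' @param formula character scalar, e.g. \code{"H2O"}.
#' @return named integer vector of element counts.
#' @examples
#' parse_formula("C9H14N5O4P")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (length(toks) == 0L || sum(attr(m, "match.length")) != nchar(formula))
    stop("cannot parse molecular formula: ", formula)
  el <- sub("[0-9]*$", "", toks)
  n <- sub("^[A-Za-z]+", "", toks)
  n <- ifelse(nzchar(n), as.integer(n), 1L)
  counts <- tapply(n, el, sum)
  counts <- counts[counts > 0]
  if (length(counts) == 0L) stop("formula has no elements: ", formula)
  storage.mode(counts) <- "integer"
  c(counts)
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of element counts times the monoisotopic isotope mass of each element.
#'
#' @param formula character formula string or named count vector
#'   (see \code{\link{parse_formula}}).
#' @return mass in Da.
#' @examples
#' monoisotopic_mass("H2O")      # 18.0106
#' monoisotopic_mass("C9H14N5O4P")  # tenofovir, 287.0783
#' @export
monoisotopic_mass <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  stopifnot(is.numeric(formula), !is.null(names(formula)))
  if (length(formula) == 0L || all(formula == 0))
    stop("formula has no elements")
  if (any(formula < 0)) stop("negative element count")
  unknown <- setdiff(names(formula), names(.ISOTOPE_MASS))
  if (length(unknown))
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  sum(formula * .ISOTOPE_MASS[names(formula)])
}

#' m/z of the deprotonated [M-H]- ion
#'
#' @param mass neutral monoisotopic mass in Da.
#' @return m/z of the singly deprotonated anion.
#' @examples
#' deprotonated_mz(monoisotopic_mass("C9H14N5O4P"))  # 286.0711
#' @export
deprotonated_mz <- function(mass) {
  stopifnot(is.numeric(mass))
  if (any(mass <= .PROTON_MASS))
    stop("mass must exceed the proton mass (", .PROTON_MASS, " Da)")
  mass - .PROTON_MASS
}

#' Symmetric ppm mass window
#'
#' @param mz target m/z (> 0).
#' @param ppm relative half-width in parts per million (> 0).
#' @return numeric c(lo, hi) = mz * (1 -/+ ppm * 1e-6).
#' @export
ppm_window <- function(mz, ppm) {
  stopifnot(is.numeric(mz), is.numeric(ppm), mz > 0, ppm > 0)
  c(lo = mz * (1 - ppm * 1e-6), hi = mz * (1 + ppm * 1e-6))
}

#' Define an ion target for XIC extraction
#'
#' @param name metabolite name.
#' @param formula molecular formula of the neutral species.
#' @param ppm_tolerance half-width of the extraction window in ppm (default 3).
#' @return list with name, formula, theoretical_mz, ppm_tolerance.
#' @export
ion_target <- function(name, formula, ppm_tolerance = 3) {
  stopifnot(ppm_tolerance > 0)
  mz <- deprotonated_mz(monoisotopic_mass(formula))
  structure(
    list(name = name, formula = formula, adduct = "[M-H]-",
         theoretical_mz = mz, ppm_tolerance = ppm_tolerance),
    class = "ion_target")
}

#' Validate a centroided MS1 peak series
#'
#' @param peaks data.frame with columns rt_min, mz, intensity, rt-sorted.
#' @return the validated data.frame.
#' @export
spectrum_series <- function(peaks) {
  stopifnot(is.data.frame(peaks),
            all(c("rt_min", "mz", "intensity") %in% names(peaks)))
  if (nrow(peaks) > 0) {
    stopifnot(all(peaks$intensity >= 0), !is.unsorted(peaks$rt_min))
  }
  peaks
}

#' Extract an ion chromatogram over a ppm window
#'
#' For each distinct retention time in the series, sums the intensities of
#' peaks whose m/z falls inside the half-open window \code{[lo, hi)} around
#' the target m/z; retention times with no in-window peak contribute zero.
#'
#' @param series data.frame of (rt_min, mz, intensity), rt-sorted
#'   (see \code{\link{spectrum_series}}).
#' @param target an \code{\link{ion_target}}.
#' @return data.frame (rt_min, intensity): the XIC.
#' @export
extract_xic <- function(series, target) {
  series <- spectrum_series(series)
  stopifnot(inherits(target, "ion_target"))
  if (nrow(series) == 0L)
    return(data.frame(rt_min = numeric(0), intensity = numeric(0)))
  w <- ppm_window(target$theoretical_mz, target$ppm_tolerance)
  rts <- unique(series$rt_min)
  inw <- series$mz >= w[["lo"]] & series$mz < w[["hi"]]
  s <- rowsum(series$intensity * inw, group = match(series$rt_min, rts))
  data.frame(rt_min = rts, intensity = as.numeric(s))
}

#' Integrate the area under an XIC peak
#'
#' Locates the global apex, expands to the contiguous region where intensity
#' exceeds the baseline, and integrates with the trapezoidal rule. Baseline
#' \code{"zero"} is flat zero; \code{"linear_endpoints"} is the straight line
#' between the first and last XIC points.
#'
#' @param xic data.frame (rt_min, intensity).
#' @param baseline \code{"zero"} or \code{"linear_endpoints"}.
#' @return list(area, apex_rt); \code{apex_rt} is NA with
#'   \code{undefined = TRUE} for an all-zero XIC.
#' @export
integrate_area <- function(xic, baseline = c("zero", "linear_endpoints")) {
  baseline <- match.arg(baseline)
  stopifnot(is.data.frame(xic), nrow(xic) >= 3,
            all(c("rt_min", "intensity") %in% names(xic)))
  y <- xic$intensity
  x <- xic$rt_min
  base <- switch(baseline,
    zero = rep(0, length(y)),
    linear_endpoints = y[1] + (y[length(y)] - y[1]) *
      (x - x[1]) / (x[length(x)] - x[1]))
  ycorr <- y - base
  if (all(ycorr <= 0))
    return(list(area = 0, apex_rt = NA_real_, undefined = TRUE))
  apex <- which.max(ycorr)
  above <- ycorr > 0
  lo <- apex; while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
  hi <- apex; while (hi < length(y) && above[hi + 1L]) hi <- hi + 1L
  idx <- lo:hi
  area <- if (length(idx) >= 2) pracma::trapz(x[idx], ycorr[idx]) else 0
  list(area = area, apex_rt = x[apex], undefined = FALSE)
}

#' Targeted quantification of ion targets in an MS1 series
#'
#' Convenience wrapper: extracts an XIC per target and integrates the peak.
#'
#' @param series centroided MS1 peak series (rt_min, mz, intensity).
#' @param targets list of \code{\link{ion_target}} objects.
#' @param baseline passed to \code{\link{integrate_area}}.
#' @return data.frame (name, theoretical_mz, apex_rt, area).
#' @export
quantify_targets <- function(series, targets, baseline = "zero") {
  stopifnot(length(targets) > 0)
  rows <- lapply(targets, function(tg) {
    xic <- extract_xic(series, tg)
    res <- if (nrow(xic) >= 3) integrate_area(xic, baseline)
           else list(area = 0, apex_rt = NA_real_)
    data.frame(name = tg$name, theoretical_mz = tg$theoretical_mz,
               apex_rt = res$apex_rt, area = res$area)
  })
  do.call(rbind, rows)
}
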