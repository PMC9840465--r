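# Ordered phases of a Mito Stress Test run: baseline, then sequential
# injection of oligomycin (ATP synthase inhibitor), FCCP (uncoupler), and
# rotenone + antimycin A (complex I/III inhibitors).
.OCR_PHASES <- c("basal", "post_oligomycin", "post_fccp", "post_rot_aa")

#' Validate an oxygen consumption rate (OCR) trace
#'
#' A trace is an ordered table of measurement cycles with columns
#' \code{time_min}, \code{ocr} (pmol O2/min) and \code{phase}; phases must
#' appear in the canonical Mito Stress Test order (basal, post_oligomycin,
#' post_fccp, post_rot_aa) with at least one cycle each.
#'
#' @param trace data.frame with columns time_min, ocr, phase.
#' @return the validated trace with \code{phase} as an ordered factor.
#' @export
ocr_trace <- function(trace) {
  stopifnot(is.data.frame(trace),
            all(c("time_min", "ocr", "phase") %in% names(trace)))
  miss <- setdiff(.OCR_PHASES, unique(as.character(trace$phase)))
  if (length(miss))
    stop("missing OCR phase(s): ", paste(miss, collapse = ", "))
  ph <- factor(as.character(trace$phase), levels = .OCR_PHASES, ordered = TRUE)
  if (anyNA(ph)) stop("unknown phase label in trace")
  if (is.unsorted(as.integer(ph)))
    stop("phases out of order: expected ", paste(.OCR_PHASES, collapse = " -> "))
  trace$phase <- ph
  trace
}

#' Mito Stress Test respiration parameters
#'
#' Partitions an OCR trace into the standard respiration parameters.
#' Following the common plate-assay convention, the reference cycle per phase
#' is: last basal cycle, minimum post-oligomycin cycle, maximum post-FCCP
#' cycle, and the last post-rotenone/antimycin-A cycle (non-mitochondrial
#' floor); \code{cycle_rule = "mean"} uses the phase mean instead for every
#' phase.
#'
#' Definitions (all minus the non-mitochondrial floor where applicable):
#' basal = basal cycle - non_mito; atp_linked = basal cycle - oligomycin
#' cycle; proton_leak = oligomycin cycle - non_mito; maximal = FCCP cycle -
#' non_mito; spare = maximal - basal; spare_pct = 100 * maximal / basal.
#' By construction basal = atp_linked + proton_leak exactly.
#'
#' @param trace an OCR trace (see \code{\link{ocr_trace}}).
#' @param cycle_rule \code{"convention"} (default, see above) or \code{"mean"}.
#' @return list with non_mito, basal_resp, atp_linked, proton_leak, maximal,
#'   spare (all pmol O2/min) and spare_pct (\%); \code{spare_pct} is NA when
#'   basal respiration is not positive.
#' @examples
#' tr <- data.frame(
#'   time_min = seq(0, 66, by = 6),
#'   ocr = c(105, 102, 100, 55, 45, 40, 150, 160, 155, 12, 11, 10),
#'   phase = rep(c("basal", "post_oligomycin", "post_fccp", "post_rot_aa"),
#'               each = 3))
#' mito_stress_params(tr)
#' @export
mito_stress_params <- function(trace, cycle_rule = c("convention", "mean")) {
  cycle_rule <- match.arg(cycle_rule)
  trace <- ocr_trace(trace)
  by_phase <- split(trace$ocr, trace$phase)
  pick <- switch(cycle_rule,
    convention = list(
      basal = function(x) x[length(x)],
      post_oligomycin = min,
      post_fccp = max,
      post_rot_aa = function(x) x[length(x)]),
    mean = list(basal = mean, post_oligomycin = mean,
                post_fccp = mean, post_rot_aa = mean))
  v <- vapply(.OCR_PHASES, function(p) pick[[p]](by_phase[[p]]), numeric(1))
  non_mito <- v[["post_rot_aa"]]
  basal <- v[["basal"]] - non_mito
  atp_linked <- v[["basal"]] - v[["post_oligomycin"]]
  leak <- v[["post_oligomycin"]] - non_mito
  maximal <- v[["post_fccp"]] - non_mito
  spare <- maximal - basal
  spare_pct <- if (basal > 0) 100 * maximal / basal else NA_real_
  list(non_mito = non_mito, basal_resp = basal, atp_linked = atp_linked,
       proton_leak = leak, maximal = maximal, spare = spare,
       spare_pct = spare_pct)
}

#' Relative abundance by the 2^-ddCt method
#'
#' Computes the fold change of a target gene relative to a reference gene,
#' treated versus control: dCt = Ct_target - Ct_reference per condition,
#' ddCt = dCt_treated - dCt_control, fold change = 2^(-ddCt).
#'
#' @param ct_target_treated,ct_reference_treated,ct_target_control,ct_reference_control
#'   qPCR cycle-threshold values (positive, finite).
#' @return fold change (1 = no change).
#' @examples
#' ddct_ratio(25, 20, 24, 21)  # ddCt = 2 -> 0.25
#' @export
ddct_ratio <- function(ct_target_treated, ct_reference_treated,
                       ct_target_control, ct_reference_control) {
  cts <- c(ct_target_treated, ct_reference_treated,
           ct_target_control, ct_reference_control)
  stopifnot(is.numeric(cts), all(is.finite(cts)), all(cts > 0))
  ddct <- (ct_target_treated - ct_reference_treated) -
    (ct_target_control - ct_reference_control)
  2^(-ddct)
}

#' ATP content normalized to protein
#'
#' Fits a least-squares line luminescence ~ ATP amount through the standard
#' curve, inverts it at the sample luminescence, and divides by protein mass.
#'
#' @param sample_lum sample luminescence reading.
#' @param standard data.frame with columns \code{atp} (amount) and \code{lum}
#'   (luminescence); at least two distinct amounts, strictly monotone in
#'   luminescence.
#' @param protein_mg protein mass in mg (> 0).
#' @return list(atp_per_mg, atp, extrapolated); \code{extrapolated} is TRUE
#'   (with a warning) when the sample luminescence lies outside the standard
#'   range.
#' @export
atp_per_protein <- function(sample_lum, standard, protein_mg) {
  stopifnot(is.data.frame(standard), all(c("atp", "lum") %in% names(standard)),
            length(unique(standard$atp)) >= 2, protein_mg > 0)
  o <- order(standard$atp)
  lum_sorted <- standard$lum[o]
  d <- diff(tapply(standard$lum, standard$atp, mean))
  if (!(all(d > 0) || all(d < 0)))
    stop("standard curve is not strictly monotone in luminescence")
  fit <- stats::lm(lum ~ atp, data = standard)
  b <- stats::coef(fit)
  atp <- (sample_lum - b[[1]]) / b[[2]]
  extrap <- sample_lum < min(standard$lum) || sample_lum > max(standard$lum)
  if (extrap)
    warning("sample luminescence outside the standard range; extrapolating")
  list(atp_per_mg = atp / protein_mg, atp = atp, extrapolated = extrap)
}

#' Reduced/oxidized glutathione ratio
#'
#' @param gsh abundance of reduced glutathione (>= 0).
#' @param gssg abundance of oxidized glutathione (>= 0).
#' @return list(ratio, undefined); ratio is NA with undefined = TRUE when
#'   gssg is zero.
#' @export
gsh_gssg_ratio <- function(gsh, gssg) {
  stopifnot(is.numeric(gsh), is.numeric(gssg))
  if (gsh < 0 || gssg < 0) stop("glutathione abundances must be non-negative")
  if (gssg == 0) return(list(ratio = NA_real_, undefined = TRUE))
  list(ratio = gsh / gssg, undefined = FALSE)
}

#' Biopsy respiratory-chain Z-scores
#'
#' Per-tubule immunofluorescence quantification: raw optical densities are
#' background-corrected by subtracting the per-fluorophore mean of a
#' no-primary control (clipped at zero), normalized to the mitochondrial-mass
#' marker VDAC1 of the same tubule, and expressed as Z-scores relative to the
#' control-group tubules (sample, n-1, standard deviation).
#'
#' @param intensities long data.frame with columns tubule_id, subject, group
#'   ("case"/"control"), marker, raw_od. One VDAC1 row per tubule is required.
#' @param background data.frame with columns marker, background_mean (the
#'   no-primary control mean optical density per fluorophore).
#' @param mass_marker the normalization marker (default \code{"VDAC1"}).
#' @return data.frame (tubule_id, subject, group, marker, normalized, z);
#'   tubules whose corrected mass-marker intensity is not positive are
#'   excluded and listed in attribute \code{"excluded"}.
#' @export
biopsy_zscores <- function(intensities, background, mass_marker = "VDAC1") {
  stopifnot(is.data.frame(intensities),
            all(c("tubule_id", "subject", "group", "marker", "raw_od") %in%
                  names(intensities)),
            all(c("marker", "background_mean") %in% names(background)))
  if (!any(intensities$group == "control")) stop("control group is empty")
  bg <- stats::setNames(background$background_mean, background$marker)
  miss <- setdiff(unique(intensities$marker), names(bg))
  if (length(miss))
    stop("no background entry for marker(s): ", paste(miss, collapse = ", "))
  x <- intensities
  x$corrected <- pmax(x$raw_od - bg[as.character(x$marker)], 0)

  vd <- x[x$marker == mass_marker, ]
  if (nrow(vd) == 0L) stop("no ", mass_marker, " rows present")
  vmap <- stats::setNames(vd$corrected, vd$tubule_id)
  excluded <- unique(vd$tubule_id[vd$corrected <= 0])
  x <- x[x$marker != mass_marker & !(x$tubule_id %in% excluded), ]
  if (anyNA(vmap[as.character(x$tubule_id)]))
    stop("tubule(s) lack a ", mass_marker, " measurement")
  x$normalized <- x$corrected / vmap[as.character(x$tubule_id)]

  out <- do.call(rbind, lapply(split(x, x$marker, drop = TRUE), function(d) {
    ctrl <- d$normalized[d$group == "control"]
    if (length(ctrl) < 2) stop("need >= 2 control tubules for marker ",
                               d$marker[1])
    s <- stats::sd(ctrl)
    if (s == 0) stop("control standard deviation is zero for marker ",
                     d$marker[1])
    d$z <- (d$normalized - mean(ctrl)) / s
    d
  }))
  rownames(out) <- NULL
  out <- out[, c("tubule_id", "subject", "group", "marker", "normalized", "z")]
  attr(out, "excluded") <- excluded
  out
}
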