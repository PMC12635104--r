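# Reference GA: second/third-trimester biometry dating and first-trimester
# crown-rump length (CRL) dating with elapsed-time propagation to the
# examination date.

#' Biometry set constructor
#'
#' @param bpd_mm,hc_mm,ac_mm,fl_mm biparietal diameter, head circumference,
#'   abdominal circumference and femur length, millimetres; must be finite
#'   and non-negative.
#' @return A `biometry_set`.
#' @export
biometry_set <- function(bpd_mm, hc_mm, ac_mm, fl_mm) {
  vals <- c(bpd_mm = bpd_mm, hc_mm = hc_mm, ac_mm = ac_mm, fl_mm = fl_mm)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("biometry measurements must be finite and non-negative (mm)",
         call. = FALSE)
  }
  structure(as.list(vals), class = "biometry_set")
}

#' Gestational age from fetal biometry
#'
#' The combined-biometry dating formula (Hadlock-type), measurements in
#' millimetres:
#' `GA_days = 7 * (10.85 + 0.0006*HC*FL + 0.067*BPD + 0.0168*AC)`.
#'
#' @param biometry a [biometry_set()], or `bpd_mm` as a plain number when
#'   the remaining measurements are given separately.
#' @param hc_mm,ac_mm,fl_mm measurements in mm (scalar interface).
#' @return GA in days.
#' @export
biometry_ga <- function(biometry, hc_mm = NULL, ac_mm = NULL, fl_mm = NULL) {
  b <- if (inherits(biometry, "biometry_set")) biometry
       else biometry_set(biometry, hc_mm, ac_mm, fl_mm)
  7 * (10.85 + 0.0006 * b$hc_mm * b$fl_mm + 0.067 * b$bpd_mm +
         0.0168 * b$ac_mm)
}

#' Gestational age from crown-rump length
#'
#' First-trimester dating. The default curve is the Robinson–Fleming
#' relationship `GA_days = 8.052 * sqrt(CRL_mm) + 23.73`; any other dating
#' chart can be plugged in via `formula`.
#'
#' @param crl_mm crown-rump length in millimetres; values outside the
#'   plausible 2–95 mm range trigger a warning but are still evaluated.
#' @param formula function of CRL (mm) returning GA in days.
#' @return GA in days.
#' @export
crl_to_ga <- function(crl_mm,
                      formula = function(crl) 8.052 * sqrt(crl) + 23.73) {
  stopifnot(is.numeric(crl_mm), all(crl_mm > 0))
  out_of_range <- crl_mm < 2 | crl_mm > 95
  if (any(out_of_range)) {
    warning("CRL outside the plausible 2-95 mm range; value(s) still dated",
            call. = FALSE)
  }
  formula(crl_mm)
}

#' Propagate a gold-standard dating forward to the examination date
#'
#' The gold standard GA at any examination is the CRL-derived GA at the
#' dating scan plus the days elapsed since. Only dating scans performed
#' between 9+0 and 13+6 weeks (63–97 days) are eligible as gold standard.
#'
#' @param dating_ga_days GA at the dating scan, days.
#' @param days_elapsed non-negative days between the dating scan and the
#'   examination.
#' @return GA at the examination, days.
#' @export
propagate_gold_standard <- function(dating_ga_days, days_elapsed) {
  stopifnot(is.numeric(dating_ga_days), is.numeric(days_elapsed))
  if (any(days_elapsed < 0)) {
    stop("days_elapsed must be non-negative", call. = FALSE)
  }
  if (any(dating_ga_days < 63 | dating_ga_days > 97)) {
    stop("dating-scan GA outside the 9+0 to 13+6 week eligibility window",
         call. = FALSE)
  }
  dating_ga_days + days_elapsed
}
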