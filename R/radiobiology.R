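#' Linear-quadratic radiobiology parameters
#'
#' Parameter set for EQD2 accumulation across external beam and
#' brachytherapy components: alpha/beta 10 Gy for tumour, 3 Gy for
#' late-responding organs at risk; the default external beam course is
#' 45 Gy in 25 fractions, followed by 4 brachytherapy fractions.
#'
#' @param alpha_beta_tumor Gy (default 10).
#' @param alpha_beta_oar Gy (default 3).
#' @param ebrt_total Total external-beam dose, Gy.
#' @param ebrt_fractions Number of external-beam fractions.
#' @param bt_fractions Number of brachytherapy fractions.
#' @return Object of class `radiobiology_params`.
#' @export
radiobiology_params <- function(alpha_beta_tumor = 10,
                                alpha_beta_oar = 3,
                                ebrt_total = 45,
                                ebrt_fractions = 25L,
                                bt_fractions = 4L) {
  stopifnot(alpha_beta_tumor > 0, alpha_beta_oar > 0, ebrt_total > 0,
            ebrt_fractions >= 1, bt_fractions >= 1)
  structure(
    list(alpha_beta_tumor = alpha_beta_tumor,
         alpha_beta_oar = alpha_beta_oar,
         ebrt_total = ebrt_total,
         ebrt_fractions = as.integer(ebrt_fractions),
         bt_fractions = as.integer(bt_fractions)),
    class = "radiobiology_params"
  )
}

#' Equieffective dose in 2 Gy fractions
#'
#' EQD2 = D (d + alpha/beta) / (2 + alpha/beta), with D the total dose
#' and d the dose per fraction, under the linear-quadratic model.
#'
#' @param total_dose Total physical dose D, Gy (> 0).
#' @param dose_per_fraction Dose per fraction d, Gy (> 0).
#' @param alpha_beta Tissue alpha/beta ratio, Gy (> 0).
#' @return EQD2 in Gy. At d = 2 Gy, EQD2 = D for any alpha/beta.
#' @export
eqd2 <- function(total_dose, dose_per_fraction, alpha_beta) {
  if (any(alpha_beta <= 0)) stop("alpha/beta must be positive")
  stopifnot(all(total_dose > 0), all(dose_per_fraction > 0))
  total_dose * (dose_per_fraction + alpha_beta) / (2 + alpha_beta)
}

#' Accumulate EQD2 over treatment components
#'
#' Sums component EQD2 values, e.g. the external beam course plus each
#' brachytherapy fraction evaluated at its D2cc.
#'
#' @param components List of lists with `total_dose` and
#'   `dose_per_fraction` (Gy).
#' @param alpha_beta Tissue alpha/beta ratio, Gy.
#' @return Accumulated EQD2, Gy.
#' @examples
#' # 45 Gy / 25 fx EBRT plus 4 brachytherapy fractions with
#' # bladder D2cc 5.40 Gy each, alpha/beta = 3:
#' accumulate_eqd2(list(
#'   list(total_dose = 45, dose_per_fraction = 1.8),
#'   list(total_dose = 4 * 5.40, dose_per_fraction = 5.40)), alpha_beta = 3)
#' @export
accumulate_eqd2 <- function(components, alpha_beta) {
  sum(vapply(components, function(cp) {
    eqd2(cp$total_dose, cp$dose_per_fraction, alpha_beta)
  }, numeric(1)))
}

#' EQD2 constraint audit for organ-at-risk D2cc values
#'
#' Accumulates the external-beam EQD2 plus the brachytherapy EQD2 at the
#' per-fraction D2cc (assumed equal across fractions, as when the same
#' plan is delivered each time) and flags constraint violations:
#' bladder < 80 Gy, rectum/sigmoid/bowel < 75 Gy by default.
#'
#' @param d2cc_per_fraction Named numeric of per-fraction D2cc (Gy) per
#'   organ.
#' @param params A [radiobiology_params()].
#' @param limits Named numeric EQD2 limits in Gy; organs missing from it
#'   get the rectum-style 75 Gy default.
#' @return data.frame with organ, per-fraction D2cc, accumulated EQD2,
#'   limit and a pass flag.
#' @export
eqd2_audit <- function(d2cc_per_fraction,
                       params = radiobiology_params(),
                       limits = c(bladder = 80, rectum = 75,
                                  sigmoid = 75, bowel = 75)) {
  stopifnot(inherits(params, "radiobiology_params"),
            !is.null(names(d2cc_per_fraction)))
  ebrt_d <- params$ebrt_total / params$ebrt_fractions
  ebrt_eqd2 <- eqd2(params$ebrt_total, ebrt_d, params$alpha_beta_oar)
  organs <- names(d2cc_per_fraction)
  total <- vapply(organs, function(org) {
    d <- d2cc_per_fraction[[org]]
    ebrt_eqd2 + eqd2(params$bt_fractions * d, d, params$alpha_beta_oar)
  }, numeric(1))
  lim <- vapply(organs, function(org) {
    if (org %in% names(limits)) limits[[org]] else 75
  }, numeric(1))
  data.frame(organ = organs,
             d2cc_fx_gy = as.numeric(d2cc_per_fraction),
             eqd2_gy = as.numeric(total),
             limit_gy = as.numeric(lim),
             within_limit = as.numeric(total) < as.numeric(lim),
             row.names = NULL)
}
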