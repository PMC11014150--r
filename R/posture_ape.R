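# Walking-referenced posture estimation. The device orientation during
# recognized walking is taken as the upright reference vector u-hat; the angle
# for posture estimation (APE) of a stationary epoch is the angle between the
# epoch's mean orientation e-hat and the most recent u-hat. Only epochs that
# pass the sedentary gate (MAD < 22.5 mg, i.e. MET < 1.5 under the low-
# intensity conversion) are assigned an APE and a posture label.

#' Epoch orientation vector
#'
#' Normalizes an epoch's mean acceleration vector to unit length.
#'
#' @param mean_vec Numeric length-3 vector (or n x 3 matrix) of epoch means in g.
#' @return Unit vector(s); `NA` where the mean vector has zero norm.
#' @export
orientation_vector <- function(mean_vec) {
  if (is.null(dim(mean_vec))) {
    nrm <- sqrt(sum(mean_vec^2))
    if (!is.finite(nrm) || nrm == 0) {
      warning("undefined orientation: zero-norm mean vector")
      return(rep(NA_real_, 3))
    }
    return(mean_vec / nrm)
  }
  nrm <- sqrt(rowSums(mean_vec^2))
  out <- mean_vec / nrm
  out[!is.finite(nrm) | nrm == 0, ] <- NA_real_
  out
}

#' Walking-recognition criteria
#'
#' An epoch qualifies as a reference-setting walking epoch when all three
#' hold: MAD within 150-350 mg (normal walking intensity), 8-13 detected
#' steps, and movement steadiness MADxyz/MAD strictly below 1.6.
#'
#' @param mad_mg,steps,madxyz_mg Epoch features (vectorized).
#' @param mad_range MAD bounds in mg (inclusive), default `c(150, 350)`.
#' @param step_range Step-count bounds (inclusive), default `c(8, 13)`.
#' @param ratio_max Strict upper bound on MADxyz/MAD, default 1.6.
#' @return Logical vector.
#' @export
is_walking_reference <- function(mad_mg, steps, madxyz_mg,
                                 mad_range = c(150, 350),
                                 step_range = c(8, 13), ratio_max = 1.6) {
  ok <- mad_mg >= mad_range[1] & mad_mg <= mad_range[2] &
    steps >= step_range[1] & steps <= step_range[2] &
    mad_mg > 0 & madxyz_mg / mad_mg < ratio_max
  ok & !is.na(ok)
}

#' Track the upright reference vector over an epoch stream
#'
#' Each qualifying walking epoch sets its own orientation vector as the new
#' upright reference; every epoch is assigned the most recent setting at or
#' before it. Epochs before the first setting carry an undefined reference
#' unless `backfill = TRUE`, in which case the first setting is carried
#' backwards (whole-file batch analysis).
#'
#' @param epochs Epoch data frame from [compute_epochs()] (time-ordered).
#' @param mad_range,step_range,ratio_max Walking criteria; see
#'   [is_walking_reference()].
#' @param backfill Carry the first reference backwards (default `FALSE`).
#' @return `epochs` with added columns `is_reference`, `ux`, `uy`, `uz`, and a
#'   `settings_log` attribute (data frame of setting times and vectors).
#' @export
track_reference <- function(epochs, mad_range = c(150, 350),
                            step_range = c(8, 13), ratio_max = 1.6,
                            backfill = FALSE) {
  n <- nrow(epochs)
  e <- orientation_vector(as.matrix(epochs[, c("xave_g", "yave_g", "zave_g")]))
  is_ref <- is_walking_reference(epochs$mad_mg, epochs$steps, epochs$madxyz_mg,
                                 mad_range, step_range, ratio_max) &
    epochs$wear & !is.na(e[, 1])
  ref_idx <- cummax(ifelse(is_ref, seq_len(n), 0L))
  if (backfill && any(is_ref)) {
    first <- which(is_ref)[1]
    ref_idx[ref_idx == 0L] <- first
  }
  u <- matrix(NA_real_, n, 3)
  has <- ref_idx > 0L
  u[has, ] <- e[ref_idx[has], , drop = FALSE]
  out <- epochs
  out$is_reference <- is_ref
  out$ux <- u[, 1]; out$uy <- u[, 2]; out$uz <- u[, 3]
  settings <- data.frame(time = epochs$start_time[is_ref],
                         ux = e[is_ref, 1], uy = e[is_ref, 2], uz = e[is_ref, 3])
  attr(out, "settings_log") <- settings
  out
}

#' Angle between orientation and reference vectors
#'
#' `APE = acos(e . u)` in degrees, with the inner product clamped to
#' `[-1, 1]` to absorb rounding; always in `[0, 180]`.
#'
#' @param e_hat,u_hat Unit 3-vectors, or n x 3 matrices of unit rows.
#' @return Angle(s) in degrees; `NA` where either vector is undefined.
#' @export
compute_ape <- function(e_hat, u_hat) {
  if (is.null(dim(e_hat))) e_hat <- matrix(e_hat, nrow = 1)
  if (is.null(dim(u_hat))) u_hat <- matrix(u_hat, nrow = 1)
  if (nrow(u_hat) == 1L && nrow(e_hat) > 1L)
    u_hat <- u_hat[rep(1L, nrow(e_hat)), , drop = FALSE]
  dot <- rowSums(e_hat * u_hat)
  out <- acos(pmin(1, pmax(-1, dot))) * 180 / pi
  as.numeric(out)
}

#' Classify a stationary epoch's posture from its APE
#'
#' Four-way classification at the validated cut-points: standing below 11.6
#' degrees, sitting in 11.6-30, reclining in 30-73.9 and lying at or above
#' 73.9 (lower bounds inclusive).
#'
#' @param ape_deg APE in degrees (vectorized).
#' @param cutpoints Named numeric vector `c(stand_sit, sit_recline,
#'   recline_lie)` in increasing order; defaults `c(11.6, 30, 73.9)`.
#' @return Factor with levels standing, sitting, reclining, lying (`NA` where
#'   APE is undefined).
#' @export
classify_posture <- function(ape_deg, cutpoints = c(stand_sit = 11.6,
                                                    sit_recline = 30,
                                                    recline_lie = 73.9)) {
  if (length(cutpoints) != 3L || is.unsorted(cutpoints, strictly = TRUE))
    stop_config("cutpoints must be three increasing angles")
  lv <- c("standing", "sitting", "reclining", "lying")
  idx <- findInterval(ape_deg, cutpoints) + 1L
  factor(lv[idx], levels = lv)
}

#' Annotate an epoch table with APE and posture
#'
#' Flags stationary epochs (wear epochs passing the sedentary gate
#' `MAD < sb_gate_mg`), computes their APE against the tracked reference and
#' classifies their posture. Epochs that are not stationary, or precede the
#' first reference setting, carry `NA`.
#'
#' @param epochs Epoch data frame from [track_reference()].
#' @param sb_gate_mg Sedentary gate on MAD in mg (default 22.5, the printed
#'   operational equivalent of MET < 1.5).
#' @param cutpoints Posture cut-points; see [classify_posture()].
#' @return `epochs` with added columns `stationary`, `ape_deg`, `posture`.
#' @export
annotate_postures <- function(epochs, sb_gate_mg = 22.5,
                              cutpoints = c(stand_sit = 11.6, sit_recline = 30,
                                            recline_lie = 73.9)) {
  if (!all(c("ux", "uy", "uz") %in% names(epochs)))
    stop_format("run track_reference() before annotate_postures()")
  e <- orientation_vector(as.matrix(epochs[, c("xave_g", "yave_g", "zave_g")]))
  u <- as.matrix(epochs[, c("ux", "uy", "uz")])
  out <- epochs
  out$stationary <- epochs$wear & !is.na(epochs$mad_mg) & epochs$mad_mg < sb_gate_mg
  ape <- rep(NA_real_, nrow(epochs))
  ok <- out$stationary & !is.na(u[, 1]) & !is.na(e[, 1])
  if (any(ok)) ape[ok] <- compute_ape(e[ok, , drop = FALSE], u[ok, , drop = FALSE])
  out$ape_deg <- ape
  out$posture <- classify_posture(ape, cutpoints)
  out
}

# Descriptive annotation of the 18 five-degree APE bins.
.ape_bin_annotation <- c("standing", "standing",
                         "standing_sitting_transition",
                         rep("desk_sitting", 3),
                         rep("sofa_sitting", 5),
                         rep("sitting_lying_transition", 4),
                         rep("lying", 3))

#' APE histogram over stationary epochs
#'
#' Accumulates stationary-epoch minutes into 18 five-degree bins:
#' `[0,5), [5,10), ..., [80,85), [85,180]`. Each 6 s epoch contributes 0.1
#' min, so the bins sum to the stationary time with defined APE.
#'
#' @param epochs Annotated epoch data frame from [annotate_postures()].
#' @param epoch_s Epoch length in seconds (default 6).
#' @return Data frame with `bin_low_deg`, `bin_high_deg`, `annotation`,
#'   `minutes`.
#' @export
build_ape_histogram <- function(epochs, epoch_s = 6) {
  breaks <- c(seq(0, 85, by = 5), Inf)
  lo <- breaks[-length(breaks)]
  hi <- breaks[-1]
  ape <- epochs$ape_deg[!is.na(epochs$ape_deg) &
                          (epochs$stationary %||% TRUE)]
  counts <- if (length(ape)) {
    tabulate(findInterval(ape, breaks[-1]) + 1L, nbins = 18L)
  } else rep(0L, 18L)
  data.frame(bin_low_deg = lo, bin_high_deg = hi,
             annotation = .ape_bin_annotation,
             minutes = counts * epoch_s / 60)
}
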