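#' @import methods
NULL

setClassUnion("integerOrNULL", c("integer", "NULL"))

#' DeflectionTrain: one whisker-deflection stimulus train
#'
#' A single stimulus train of brief vibrissa deflections delivered at a fixed
#' rate (typically seven deflections at 10 Hz). At most one deflection — the
#' deviant — differs in amplitude from the preceding baseline deflections.
#' Onset times are train-relative seconds; deflection positions are 0-based.
#'
#' @slot train_id character scalar identifier.
#' @slot onsets strictly increasing deflection onset times (s, train-relative).
#' @slot amplitudes per-deflection peak velocities (mm/s), all positive.
#' @slot baseline_amplitude baseline deflection velocity (mm/s).
#' @slot deviant_index 0-based position of the deviant, or `NULL` when the
#'   train contains none.
#' @slot deviant_sign +1L for an amplitude increase, -1L for a decrease,
#'   0L when no deviant is present.
#' @slot opto_condition one of `"control"`, `"weak_laser"`, `"strong_laser"`.
#'
#' @seealso [buildTrain()]
#' @export
setClass("DeflectionTrain",
  representation(
    train_id = "character",
    onsets = "numeric",
    amplitudes = "numeric",
    baseline_amplitude = "numeric",
    deviant_index = "integerOrNULL",
    deviant_sign = "integer",
    opto_condition = "character"
  )
)

setValidity("DeflectionTrain", function(object) {
  msg <- character()
  n <- length(object@onsets)
  if (length(object@amplitudes) != n)
    msg <- c(msg, "onsets and amplitudes must have equal length")
  if (n > 1L && any(diff(object@onsets) <= 0))
    msg <- c(msg, "onsets must be strictly increasing")
  if (any(object@amplitudes <= 0))
    msg <- c(msg, "all amplitudes must be positive")
  di <- object@deviant_index
  if (is.null(di)) {
    if (object@deviant_sign != 0L)
      msg <- c(msg, "deviant_sign must be 0 when no deviant_index is present")
  } else {
    if (object@deviant_sign == 0L)
      msg <- c(msg, "deviant_sign must be nonzero when a deviant is present")
    if (di < 1L || di >= n)
      msg <- c(msg, "deviant_index must lie in 1..(n-1) (0-based; a deviant needs preceding baseline deflections)")
    pre <- seq_len(di)  # 0-based positions 0..di-1
    if (length(pre) &&
        any(abs(object@amplitudes[pre] - object@baseline_amplitude) > 1e-9))
      msg <- c(msg, "amplitudes before the deviant must equal baseline_amplitude")
  }
  if (!object@opto_condition %in% c("control", "weak_laser", "strong_laser"))
    msg <- c(msg, "opto_condition must be control, weak_laser or strong_laser")
  if (length(msg)) msg else TRUE
})

#' SessionBundle: one recording session
#'
#' Container for a session's stimulus trains, sorted units and spike events.
#' Trains are stored as a wide table (one row per train, `onset_<k>`/`amp_<k>`
#' columns); spikes as a long table of `(unit_id, train_id, t_s)` with times
#' relative to the start of the per-trial recording window, which opens
#' `metadata$pre_window_s` seconds before the first deflection.
#'
#' @slot trains data.frame, one row per train.
#' @slot spikes data.frame with columns `unit_id`, `train_id`, `t_s`.
#' @slot units data.frame with columns `unit_id`, `depth_um`,
#'   `waveform_width_ms` plus derived `layer`, `cell_class`.
#' @slot metadata named list; must carry `pre_window_s` and `post_window_s`.
#'
#' @seealso [readSession()], [writeSession()], [simulatePopulationSpikes()]
#' @export
setClass("SessionBundle",
  representation(
    trains = "data.frame",
    spikes = "data.frame",
    units = "data.frame",
    metadata = "list"
  )
)

setValidity("SessionBundle", function(object) {
  msg <- character()
  tr <- object@trains; sp <- object@spikes; un <- object@units
  need_tr <- c("train_id", "baseline_amplitude", "deviant_index",
               "deviant_sign", "opto_condition", "n_deflections")
  if (!all(need_tr %in% names(tr)))
    msg <- c(msg, paste("trains table missing column(s):",
                        paste(setdiff(need_tr, names(tr)), collapse = ", ")))
  if (!all(c("unit_id", "train_id", "t_s") %in% names(sp)))
    msg <- c(msg, "spikes table must have unit_id, train_id, t_s")
  if (!all(c("unit_id", "depth_um", "waveform_width_ms") %in% names(un)))
    msg <- c(msg, "units table must have unit_id, depth_um, waveform_width_ms")
  if (!length(msg)) {
    if (anyDuplicated(tr$train_id))
      msg <- c(msg, "train_id values must be unique")
    if (anyDuplicated(un$unit_id))
      msg <- c(msg, "unit_id values must be unique")
    bad_tr <- setdiff(unique(sp$train_id), tr$train_id)
    if (length(bad_tr))
      msg <- c(msg, paste0("spikes reference unknown train_id: ",
                           paste(utils::head(bad_tr, 5L), collapse = ", ")))
    bad_un <- setdiff(unique(sp$unit_id), un$unit_id)
    if (length(bad_un))
      msg <- c(msg, paste0("spikes reference unknown unit_id: ",
                           paste(utils::head(bad_un, 5L), collapse = ", ")))
    if (nrow(sp) && any(sp$t_s < 0))
      msg <- c(msg, "spike times must be non-negative (trial-window relative)")
    if (is.null(object@metadata$pre_window_s))
      msg <- c(msg, "metadata must carry pre_window_s")
  }
  if (length(msg)) msg else TRUE
})

#' CountTensor: spike counts per (unit, train, deflection)
#'
#' Integer counts of spikes inside a half-open window `[onset, onset + w)`
#' anchored at each deflection. Deflections after a train's first deviant are
#' flagged in `excluded` and skipped by downstream coding statistics.
#'
#' @slot counts integer array, dim (unit, train, deflection), dimnames carry
#'   unit and train ids.
#' @slot window_ms count-window length (ms).
#' @slot excluded logical matrix (train, deflection): TRUE after the deviant.
#' @slot train_info data.frame aligned with the train dimension
#'   (`train_id`, `deviant_index`, `deviant_sign`, `opto_condition`,
#'   `baseline_amplitude`, `deviant_amplitude`).
#'
#' @seealso [perDeflectionCounts()]
#' @export
setClass("CountTensor",
  representation(
    counts = "array",
    window_ms = "numeric",
    excluded = "matrix",
    train_info = "data.frame"
  )
)

setValidity("CountTensor", function(object) {
  msg <- character()
  d <- dim(object@counts)
  if (length(d) != 3L) msg <- c(msg, "counts must be a 3-D array (unit, train, deflection)")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (length(d) == 3L) {
    if (!identical(dim(object@excluded), d[2:3]))
      msg <- c(msg, "excluded must be a (train x deflection) matrix")
    if (nrow(object@train_info) != d[2L])
      msg <- c(msg, "train_info rows must match the train dimension")
  }
  if (length(msg)) msg else TRUE
})

#' MatchedSets: histogram-matched deflection sets
#'
#' Two sets of deflection references (rows of `(train_id, position)` or
#' trial indices) whose histograms over the matching key — position in the
#' train, or deviant amplitude — are identical, so that comparisons between
#' them are free of position/adaptation or amplitude confounds.
#'
#' @slot set_a data.frame of references (deviant set for position matching).
#' @slot set_b data.frame of references (matched baseline set).
#' @slot matched_on `"position"` or `"amplitude_distribution"`.
#' @export
setClass("MatchedSets",
  representation(
    set_a = "data.frame",
    set_b = "data.frame",
    matched_on = "character"
  )
)

#' ChangeCoefficientSet: per-unit deviant change coefficients
#'
#' Per-unit mean spike-count difference (per deflection) between responses to
#' amplitude-increase and amplitude-decrease deviants, with provenance.
#'
#' @slot coefficients data.frame with columns `unit_id`, `coeff`, `n_increase`,
#'   `n_decrease`, plus any unit metadata joined in (layer, cell class).
#' @slot condition condition label (e.g. "control", "weak_laser").
#' @slot provenance list describing the matched sets used.
#' @export
setClass("ChangeCoefficientSet",
  representation(
    coefficients = "data.frame",
    condition = "character",
    provenance = "list"
  )
)

setValidity("ChangeCoefficientSet", function(object) {
  cf <- object@coefficients
  if (!all(c("unit_id", "coeff") %in% names(cf)))
    return("coefficients needs unit_id and coeff columns")
  if (any(!is.finite(cf$coeff)))
    return("coefficients must be finite (drop units with missing groups upstream)")
  TRUE
})

#' SurrogatePopulation: null change-coefficient draws
#'
#' Each row is one surrogate population: per unit, position-matched baseline
#' deflections were randomly split into two pseudo-groups of the true
#' increase/decrease sizes and the pseudo change coefficient computed.
#'
#' @slot draws numeric matrix (n_draws x units).
#' @slot n_draws number of surrogate draws.
#' @slot seed RNG seed used.
#' @export
setClass("SurrogatePopulation",
  representation(draws = "matrix", n_draws = "integer", seed = "integer")
)

#' BroadeningStats: population broadening test result
#'
#' Compares the spread of an observed change-coefficient population against
#' its within-cell surrogate null via the interquartile range and Shannon
#' entropy (shared bin edges), plus a median-shift test.
#'
#' @slot iqr_obs observed IQR (spikes/deflection).
#' @slot iqr_surr median surrogate IQR.
#' @slot delta_H entropy difference H(observed) - H(surrogate), bits.
#' @slot bin_edges shared histogram bin edges.
#' @slot p_iqr,p_entropy one-sided surrogate p-values (add-one convention).
#' @slot p_median_shift signed-rank p for median vs 0.
#' @slot ci_median bootstrap `[lo, med, hi]` of the population median.
#' @export
setClass("BroadeningStats",
  representation(
    iqr_obs = "numeric", iqr_surr = "numeric", delta_H = "numeric",
    bin_edges = "numeric", p_iqr = "numeric", p_entropy = "numeric",
    p_median_shift = "numeric", ci_median = "numeric"
  )
)

#' RoiTraceSet: ROI fluorescence traces and derived dF/F
#'
#' @slot F ROI x frame raw fluorescence (a.u.).
#' @slot F_neuropil ROI x frame neuropil (annulus) fluorescence, same shape.
#' @slot frame_times frame timestamps (s).
#' @slot F0 sliding-percentile baseline, same shape as F (may be empty before
#'   [computeDff()] is run).
#' @slot dff (F - F0)/F0, same shape as F (may be empty).
#' @slot masks optional integer label image (0 = background, k = ROI k).
#' @slot trial_info data.frame of stimulus trials (onset/offset times,
#'   condition labels) or empty.
#' @slot responsive named logical vector or empty.
#' @export
setClass("RoiTraceSet",
  representation(
    F = "matrix", F_neuropil = "matrix", frame_times = "numeric",
    F0 = "matrix", dff = "matrix", masks = "matrix",
    trial_info = "data.frame", responsive = "logical"
  )
)

setValidity("RoiTraceSet", function(object) {
  msg <- character()
  if (ncol(object@F) != length(object@frame_times))
    msg <- c(msg, "frame_times length must equal the frame dimension of F")
  if (length(object@F_neuropil) && !identical(dim(object@F_neuropil), dim(object@F)))
    msg <- c(msg, "F_neuropil must match the shape of F")
  if (length(object@F0) && !identical(dim(object@F0), dim(object@F)))
    msg <- c(msg, "F0 must match the shape of F")
  if (length(object@F0) && any(object@F0 <= 0))
    msg <- c(msg, "F0 must be positive")
  if (length(object@frame_times) > 1L) {
    fr <- 1 / stats::median(diff(object@frame_times))
    if (fr < 5 - 1e-6) msg <- c(msg, "frame rate must be >= 5 Hz")
  }
  if (length(msg)) msg else TRUE
})

#' GlmDesign: design for the penalized per-neuron Poisson GLM
#'
#' @slot Y spike-count vector per analyzed deflection.
#' @slot X feature matrix with named columns; blocks are recorded in `blocks`.
#' @slot blocks named list mapping block name (`constant`, `deviation`,
#'   `baseline_amplitude`, `history`, `adaptation`) to column indices.
#' @slot Q symmetric positive semidefinite penalty matrix (constant unpenalized).
#' @export
setClass("GlmDesign",
  representation(Y = "numeric", X = "matrix", blocks = "list", Q = "matrix")
)

setValidity("GlmDesign", function(object) {
  msg <- character()
  if (nrow(object@X) != length(object@Y))
    msg <- c(msg, "rows of X must align with Y")
  if (any(object@Y < 0) || any(object@Y != round(object@Y)))
    msg <- c(msg, "Y must be non-negative integers (spike counts)")
  if (!isTRUE(all.equal(object@Q, t(object@Q))))
    msg <- c(msg, "Q must be symmetric")
  if (length(msg)) msg else TRUE
})

#' GlmFit: penalized GLM solution
#'
#' @slot w coefficient vector (named).
#' @slot objective penalized negative log-likelihood at the solution.
#' @slot gradient_norm max-norm of the penalized gradient at the solution.
#' @slot converged logical.
#' @slot ci optional per-coefficient bootstrap CI matrix (coef x c(lo, hi)).
#' @export
setClass("GlmFit",
  representation(
    w = "numeric", objective = "numeric", gradient_norm = "numeric",
    converged = "logical", ci = "matrix"
  )
)

#' PsychometricFit: cumulative-Gaussian detection curve
#'
#' @slot mu threshold amplitude (median point of the scaled curve).
#' @slot sigma slope parameter.
#' @slot guess guess (false-alarm floor) rate.
#' @slot lapse lapse rate.
#' @slot converged logical; FALSE flags a non-identifiable fit.
#' @slot loglik binomial log-likelihood at the solution.
#' @export
setClass("PsychometricFit",
  representation(
    mu = "numeric", sigma = "numeric", guess = "numeric", lapse = "numeric",
    converged = "logical", loglik = "numeric"
  )
)
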