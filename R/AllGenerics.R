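#' Accessors for the core containers
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @param ... unused.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("trainTable", function(x, ...) standardGeneric("trainTable"))
#' @rdname accessors
#' @export
setGeneric("unitTable", function(x, ...) standardGeneric("unitTable"))
#' @rdname accessors
#' @export
setGeneric("spikeTable", function(x, ...) standardGeneric("spikeTable"))
#' @rdname accessors
#' @export
setGeneric("sessionMetadata", function(x, ...) standardGeneric("sessionMetadata"))
#' @rdname accessors
#' @export
setGeneric("counts", function(x, ...) standardGeneric("counts"))
#' @rdname accessors
#' @export
setGeneric("coefficientTable", function(x, ...) standardGeneric("coefficientTable"))
#' @rdname accessors
#' @export
setGeneric("surrogateDraws", function(x, ...) standardGeneric("surrogateDraws"))
#' @rdname accessors
#' @export
setGeneric("dff", function(x, ...) standardGeneric("dff"))

#' @rdname accessors
#' @export
setMethod("trainTable", "SessionBundle", function(x, ...) x@trains)
#' @rdname accessors
#' @export
setMethod("unitTable", "SessionBundle", function(x, ...) x@units)
#' @rdname accessors
#' @export
setMethod("spikeTable", "SessionBundle", function(x, ...) x@spikes)
#' @rdname accessors
#' @export
setMethod("sessionMetadata", "SessionBundle", function(x, ...) x@metadata)
#' @rdname accessors
#' @export
setMethod("counts", "CountTensor", function(x, ...) x@counts)
#' @rdname accessors
#' @export
setMethod("coefficientTable", "ChangeCoefficientSet", function(x, ...) x@coefficients)
#' @rdname accessors
#' @export
setMethod("surrogateDraws", "SurrogatePopulation", function(x, ...) x@draws)
#' @rdname accessors
#' @export
setMethod("dff", "RoiTraceSet", function(x, ...) x@dff)

setMethod("show", "DeflectionTrain", function(object) {
  dev <- if (is.null(object@deviant_index)) "no deviant" else
    sprintf("deviant at position %d (sign %+d, %.3g mm/s)",
            object@deviant_index, object@deviant_sign,
            object@amplitudes[object@deviant_index + 1L])
  cat(sprintf("DeflectionTrain '%s': %d deflections, baseline %.3g mm/s, %s, %s\n",
              object@train_id, length(object@onsets),
              object@baseline_amplitude, dev, object@opto_condition))
})

setMethod("show", "SessionBundle", function(object) {
  cat(sprintf("SessionBundle: %d trains, %d units, %d spikes\n",
              nrow(object@trains), nrow(object@units), nrow(object@spikes)))
  if (!is.null(object@metadata$session_id))
    cat("  session:", object@metadata$session_id, "\n")
})

setMethod("show", "CountTensor", function(object) {
  d <- dim(object@counts)
  cat(sprintf("CountTensor: %d units x %d trains x %d deflections, window %g ms\n",
              d[1], d[2], d[3], object@window_ms))
})

setMethod("show", "ChangeCoefficientSet", function(object) {
  cf <- object@coefficients$coeff
  cat(sprintf("ChangeCoefficientSet (%s): %d units, median %.4g spikes/deflection\n",
              object@condition, length(cf),
              if (length(cf)) stats::median(cf) else NA_real_))
})

setMethod("show", "BroadeningStats", function(object) {
  cat(sprintf(paste0(
    "BroadeningStats:\n  IQR obs %.4g vs surrogate %.4g (p = %.4g)\n",
    "  delta entropy %.4g bits (p = %.4g)\n",
    "  median shift p = %.4g, median CI [%.4g, %.4g, %.4g]\n"),
    object@iqr_obs, object@iqr_surr, object@p_iqr,
    object@delta_H, object@p_entropy, object@p_median_shift,
    object@ci_median[1], object@ci_median[2], object@ci_median[3]))
})

setMethod("show", "RoiTraceSet", function(object) {
  cat(sprintf("RoiTraceSet: %d ROIs x %d frames (%.3g Hz)%s\n",
              nrow(object@F), ncol(object@F),
              if (length(object@frame_times) > 1)
                1 / stats::median(diff(object@frame_times)) else NA_real_,
              if (length(object@dff)) ", dF/F computed" else ""))
})

setMethod("show", "GlmFit", function(object) {
  cat(sprintf("GlmFit: %d coefficients, objective %.6g, |grad| %.3g, %s\n",
              length(object@w), object@objective, object@gradient_norm,
              if (object@converged) "converged" else "NOT converged"))
})

setMethod("show", "PsychometricFit", function(object) {
  cat(sprintf("PsychometricFit: mu = %.4g, sigma = %.4g, guess = %.3g, lapse = %.3g%s\n",
              object@mu, object@sigma, object@guess, object@lapse,
              if (object@converged) "" else " (non-identifiable)"))
})
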