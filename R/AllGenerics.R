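#' @rdname EITSequence-class
#' @param object,x an object.
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname EITSequence-class
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' @rdname EITSequence-class
#' @export
setGeneric("lungMask", function(x) standardGeneric("lungMask"))

#' @rdname EITSequence-class
#' @export
setGeneric("orientation", function(x) standardGeneric("orientation"))

#' @rdname EITSequence-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @describeIn EITSequence-class the frame array (time x height x width).
#' @export
setMethod("frames", "EITSequence", function(x) x@frames)

#' @describeIn EITSequence-class frames per second.
#' @export
setMethod("frameRate", "EITSequence", function(x) x@frameRate)

#' @describeIn EITSequence-class the logical lung-region mask.
#' @export
setMethod("lungMask", "EITSequence", function(x) x@lungMask)

#' @describeIn EITSequence-class the orientation tag.
#' @export
setMethod("orientation", "EITSequence", function(x) x@orientation)

#' @describeIn EITSequence-class number of frames.
#' @export
setMethod("nFrames", "EITSequence", function(x) dim(x@frames)[1])

#' @rdname AirwaySignals-class
#' @param x an `AirwaySignals` object.
#' @param row.names,optional,... passed on as in [base::as.data.frame].
#' @export
setMethod("as.data.frame", "AirwaySignals",
          function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(time_s = x@time, flow_lps = x@flow,
             paw_cmh2o = x@paw, pco2_mmhg = x@pco2)
})

#' @rdname AirwaySignals-class
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @describeIn AirwaySignals-class samples per second.
#' @export
setMethod("sampleRate", "AirwaySignals", function(x) x@sampleRate)
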