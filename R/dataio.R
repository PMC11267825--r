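## On-disk dataset layout (one directory per subject):
##   eit_frames.bin  float32 little-endian, T x H x W, row-major
##                   (frame index slowest, column fastest)
##   eit_meta.json   dims, frame_rate, orientation, dtype, byte_order
##   lung_mask.csv   H rows x W comma-separated 0/1 values, no header
##   airway.csv      time_s, flow_lps, paw_cmh2o, pco2_mmhg
##   events.csv      event, time_s
##   truth_breaths.csv  per-breath generator ground truth (synthetic data)

#' Write one subject's dataset
#'
#' @param subject a list as returned by [simulateSubject()] (elements
#'   `eit`, `airway`, `events`, optionally `truth`).
#' @param dir subject directory (created if needed).
#' @return invisibly, `dir`.
#' @seealso [readSubject()] for the reverse operation.
#' @export
writeSubject <- function(subject, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create subject directory: ", dir)
  eit <- subject$eit
  d <- dim(frames(eit))
  con <- file(file.path(dir, "eit_frames.bin"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.vector(aperm(frames(eit), c(3, 2, 1))), con, size = 4,
           endian = "little")
  meta <- list(n_frames = d[1], height = d[2], width = d[3],
               frame_rate = frameRate(eit), orientation = orientation(eit),
               dtype = "float32", byte_order = "little")
  jsonlite::write_json(meta, file.path(dir, "eit_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(matrix(as.integer(lungMask(eit)), d[2], d[3]),
                     file.path(dir, "lung_mask.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  write.csv(as.data.frame(subject$airway),
            file.path(dir, "airway.csv"), row.names = FALSE)
  ev <- subject$events
  write.csv(data.frame(event = c("apnea_start", "apnea_end",
                                 "injection_start", "injection_end"),
                       time_s = c(ev@apneaStart, ev@apneaEnd,
                                  ev@injectionStart, ev@injectionEnd)),
            file.path(dir, "events.csv"), row.names = FALSE)
  if (!is.null(subject$truth))
    write.csv(subject$truth, file.path(dir, "truth_breaths.csv"),
              row.names = FALSE)
  invisible(dir)
}

.requireFile <- function(dir, name) {
  p <- file.path(dir, name)
  if (!file.exists(p)) stop("missing file: ", p)
  p
}

#' Read one subject's dataset
#'
#' Round-trip lossless counterpart of [writeSubject()] up to float32
#' precision of the frames.  Errors name the offending file and field on
#' missing files or dimension mismatches.
#'
#' @param dir subject directory.
#' @return a list with `eit` ([EITSequence]), `airway` ([AirwaySignals]),
#'   `events` ([EventLog]) and, when present on disk, `truth`.
#' @export
readSubject <- function(dir) {
  meta <- jsonlite::read_json(.requireFile(dir, "eit_meta.json"),
                              simplifyVector = TRUE)
  for (f in c("n_frames", "height", "width", "frame_rate"))
    if (is.null(meta[[f]]))
      stop("eit_meta.json: missing field '", f, "'")
  d <- as.integer(c(meta$n_frames, meta$height, meta$width))
  binPath <- .requireFile(dir, "eit_frames.bin")
  expect <- 4 * prod(d)
  if (file.size(binPath) != expect)
    stop("eit_frames.bin: dimension mismatch with eit_meta.json (",
         file.size(binPath), " bytes on disk, ", expect, " expected)")
  con <- file(binPath, "rb")
  on.exit(close(con), add = TRUE)
  raw <- readBin(con, "numeric", n = prod(d), size = 4, endian = "little")
  fr <- aperm(array(raw, dim = d[c(3, 2, 1)]), c(3, 2, 1))
  maskTab <- utils::read.table(.requireFile(dir, "lung_mask.csv"), sep = ",")
  if (!identical(dim(as.matrix(maskTab)), d[2:3]))
    stop("lung_mask: grid has dimensions ", nrow(maskTab), " x ",
         ncol(maskTab), " but eit_meta.json declares ", d[2], " x ", d[3])
  mask <- as.matrix(maskTab) > 0
  dimnames(mask) <- NULL
  aw <- read.csv(.requireFile(dir, "airway.csv"))
  for (f in c("time_s", "flow_lps", "paw_cmh2o", "pco2_mmhg"))
    if (is.null(aw[[f]])) stop("airway.csv: missing column '", f, "'")
  ev <- read.csv(.requireFile(dir, "events.csv"))
  evGet <- function(nm) {
    v <- ev$time_s[ev$event == nm]
    if (length(v) != 1) stop("events.csv: missing event '", nm, "'")
    v
  }
  out <- list(
    eit = eitSequence(fr, meta$frame_rate, mask,
                      orientation = meta$orientation %||%
                        .defaultOrientation),
    airway = airwaySignals(aw$time_s, aw$flow_lps, aw$paw_cmh2o,
                           aw$pco2_mmhg),
    events = eventLog(evGet("apnea_start"), evGet("apnea_end"),
                      evGet("injection_start"), evGet("injection_end")))
  truthPath <- file.path(dir, "truth_breaths.csv")
  if (file.exists(truthPath)) out$truth <- read.csv(truthPath)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write per-breath feature tables
#'
#' Writes `breaths.csv`, `features_eit.csv`, `features_vcap.csv` and
#' `features_mech.csv` (whichever are present in `tables`) with one row
#' per subject x breath.
#'
#' @param tables named list of data.frames (`breaths`, `eit`, `vcap`,
#'   `mech`).
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
writeFeatures <- function(tables, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  fileOf <- c(breaths = "breaths.csv", eit = "features_eit.csv",
              vcap = "features_vcap.csv", mech = "features_mech.csv")
  paths <- character()
  for (nm in intersect(names(fileOf), names(tables))) {
    p <- file.path(dir, fileOf[[nm]])
    write.csv(tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
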