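#' @include AllClasses.R
NULL

#' Write / read a respirometry trace as CSV + YAML
#'
#' The trace samples go to a CSV with columns `time_s`, `o2_uM`, `fluo_V`
#' (empty when absent) and `state_label` (injection artifacts are labelled
#' `"transient"`); the event schedule goes to a YAML file with one entry
#' per event (`time_s`, `substance`, `final_conc`, `units`).
#'
#' @param trace a [RespirometryTrace-class].
#' @param csvFile path of the sample CSV.
#' @param yamlFile path of the event YAML.
#' @return `writeTrace` returns the trace invisibly; `readTrace` returns
#'   the reconstructed [RespirometryTrace-class].
#' @export
writeTrace <- function(trace, csvFile, yamlFile) {
  lab <- stateLabels(trace)
  lab[transientMask(trace)] <- "transient"
  f <- fluorescence(trace)
  df <- data.frame(time_s = traceTime(trace),
                   o2_uM = o2Concentration(trace),
                   fluo_V = if (length(f)) f else NA_real_,
                   state_label = lab)
  utils::write.csv(df, csvFile, row.names = FALSE)
  ev <- traceEvents(trace)
  yaml::write_yaml(list(
    chamber_volume_ml = chamberVolume(trace),
    sample_mass_mg = sampleMass(trace),
    events = lapply(seq_len(nrow(ev)), function(i)
      list(time_s = ev$time_s[i], substance = ev$substance[i],
           final_conc = ev$final_conc[i], units = ev$units[i]))),
    yamlFile)
  invisible(trace)
}

#' @rdname writeTrace
#' @export
readTrace <- function(csvFile, yamlFile) {
  df <- utils::read.csv(csvFile, stringsAsFactors = FALSE)
  meta <- yaml::read_yaml(yamlFile)
  ev <- do.call(rbind, lapply(meta$events, function(e)
    data.frame(time_s = as.numeric(e$time_s), substance = e$substance,
               final_conc = if (is.null(e$final_conc) ||
                                length(e$final_conc) == 0) NA_real_
                            else as.numeric(e$final_conc),
               units = if (is.null(e$units)) "" else e$units)))
  transient <- df$state_label == "transient"
  lab <- df$state_label
  lab[transient] <- ""
  fluo <- df$fluo_V
  fluo <- if (all(is.na(fluo))) numeric(0) else as.numeric(fluo)
  respirometryTrace(time = df$time_s, o2 = df$o2_uM, events = ev,
                    chamberVolume = meta$chamber_volume_ml,
                    sampleMass = meta$sample_mass_mg,
                    fluo = fluo, transient = transient, stateLabel = lab)
}

#' Write a flux table (with ratios) to tidy CSV
#'
#' One row per state with the three normalizations, the fit diagnostics,
#' flags, and (when supplied) the flux control ratio.
#'
#' @param fluxTable a [FluxTable-class].
#' @param file output path.
#' @param fcr optional named FCR vector from [fluxControlRatios()].
#' @return the written data.frame, invisibly.
#' @export
writeFluxCsv <- function(fluxTable, file, fcr = NULL) {
  tb <- fluxes(fluxTable)
  if (!is.null(fcr)) tb$fcr <- unname(fcr[tb$state])
  tb$rox_corrected <- isRoxCorrected(fluxTable)
  utils::write.csv(tb, file, row.names = FALSE)
  invisible(tb)
}

#' Write / read an AmR calibration as JSON
#'
#' @param calibration an [AmrCalibration-class].
#' @param file path of the JSON file.
#' @return `writeCalibrationJson` returns the path invisibly;
#'   `readCalibrationJson` the [AmrCalibration-class].
#' @export
writeCalibrationJson <- function(calibration, file) {
  jsonlite::write_json(list(
    background_intercept_v = calibration@backgroundIntercept,
    background_slope_v_per_s = calibration@backgroundSlope,
    knots = calibration@knots,
    residual_sd_v = calibration@residualSd), file,
    auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname writeCalibrationJson
#' @export
readCalibrationJson <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  new("AmrCalibration", backgroundIntercept = j$background_intercept_v,
      backgroundSlope = j$background_slope_v_per_s,
      knots = as.data.frame(j$knots), residualSd = j$residual_sd_v)
}

#' Write a rendered cell image to disk
#'
#' Writes the intensity image and the ground-truth label image as 16-bit
#' grayscale TIFFs plus a JSON sidecar with the generator's ground truth.
#'
#' @param rendered output of [renderCellImage()].
#' @param prefix path prefix; writes `<prefix>.tif`,
#'   `<prefix>_labels.tif`, `<prefix>_truth.json`.
#' @return the three paths, invisibly.
#' @export
writeCellImage <- function(rendered, prefix) {
  img <- rendered$image
  img16 <- pmin(pmax(img / (2 * max(img, 1)), 0), 1)
  pImg <- paste0(prefix, ".tif")
  pLab <- paste0(prefix, "_labels.tif")
  pJson <- paste0(prefix, "_truth.json")
  EBImage::writeImage(EBImage::Image(img16), pImg, type = "tiff",
                      bits.per.sample = 16L)
  EBImage::writeImage(EBImage::Image(rendered$labels / 65535), pLab,
                      type = "tiff", bits.per.sample = 16L)
  jsonlite::write_json(c(unclass(rendered$truth),
                         list(areas = rendered$areas)),
                       pJson, auto_unbox = TRUE, digits = NA)
  invisible(c(pImg, pLab, pJson))
}
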