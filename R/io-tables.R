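#' Read a reference-measurement table
#'
#' A reference table holds, per object, the field/laboratory reference value
#' and each device's detection flag and estimate, in a CSV with columns
#' `id`, `reference`, then `<device>_detected` (yes/no or TRUE/FALSE) and
#' `<device>_est` pairs. Undetected objects must carry no estimate; any
#' estimate present on an undetected row is dropped with a warning.
#'
#' @param path CSV file path.
#' @return A data frame of class `reference_table` with attribute `devices`
#'   (character vector of device labels found).
#' @export
read_reference_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("reference table is empty: ", path)
  miss <- setdiff(c("id", "reference"), names(df))
  if (length(miss) > 0L)
    stop("reference table is missing columns: ", paste(miss, collapse = ", "))
  if (!is.numeric(df$reference) || any(!is.finite(df$reference)) ||
      any(df$reference <= 0))
    stop("reference values must be positive numbers")
  det_cols <- grep("_detected$", names(df), value = TRUE)
  devices <- sub("_detected$", "", det_cols)
  est_missing <- setdiff(paste0(devices, "_est"), names(df))
  if (length(est_missing) > 0L)
    stop("reference table is missing columns: ",
         paste(est_missing, collapse = ", "))
  for (dev in devices) {
    det <- df[[paste0(dev, "_detected")]]
    if (!is.logical(det))
      det <- tolower(trimws(as.character(det))) %in% c("yes", "true", "1")
    df[[paste0(dev, "_detected")]] <- det
    est <- as.numeric(df[[paste0(dev, "_est")]])
    if (any(!det & !is.na(est))) {
      warning(sprintf("device '%s': dropping estimates on undetected rows", dev))
      est[!det] <- NA_real_
    }
    df[[paste0(dev, "_est")]] <- est
  }
  structure(df, devices = devices, class = c("reference_table", "data.frame"))
}

#' Path to a packaged laboratory reference table
#'
#' The package ships the two indoor calibration tables used in its worked
#' examples: per-tube reference diameters (cm) and reference lengths (cm)
#' with the estimates obtained by four devices. The smartphone failed to
#' detect the two 2.6 cm tubes in the diameter experiment and two tubes in
#' the length experiment, so those rows carry no estimate for it.
#'
#' @param which `"diameter"` or `"height"`.
#' @return File path to the packaged CSV.
#' @export
lab_reference_path <- function(which = c("diameter", "height")) {
  which <- match.arg(which)
  fn <- switch(which, diameter = "lab_tube_diameters.csv",
               height = "lab_tube_heights.csv")
  system.file("extdata", fn, package = "tlsbench", mustWork = TRUE)
}
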