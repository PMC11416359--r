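#' Measurement record
#'
#' Tidy table of distance measurements for one specimen and modality:
#' per tumor-bearing slice the tumor thickness (TT) and the cranial, deep
#' and caudal margins; per specimen the anterior and posterior margins.
#' All values are physical millimetres.
#'
#' @param specimen specimen id.
#' @param modality one of `"US-manual"`, `"US-auto"`, `"histology"`.
#' @param slice data.frame with columns `slide`, `TT`, `cranial`, `deep`,
#'   `caudal` (mm; NA = absent), or NULL.
#' @param anterior,posterior per-specimen end margins, mm (NA = absent).
#' @return data.frame of class `measurement_record` with columns
#'   `specimen`, `modality`, `slide`, `measure`, `value_mm`.
#' @export
measurement_record <- function(specimen, modality, slice = NULL,
                               anterior = NA_real_, posterior = NA_real_) {
  modality <- match.arg(modality, c("US-manual", "US-auto", "histology"))
  rows <- list()
  if (!is.null(slice) && nrow(slice)) {
    for (meas in c("TT", "cranial", "deep", "caudal")) {
      v <- slice[[meas]]
      keep <- !is.na(v)
      if (any(keep))
        rows[[meas]] <- data.frame(specimen = specimen, modality = modality,
                                   slide = slice$slide[keep], measure = meas,
                                   value_mm = v[keep])
    }
  }
  ends <- data.frame(specimen = specimen, modality = modality,
                     slide = NA_integer_,
                     measure = c("anterior", "posterior"),
                     value_mm = c(anterior, posterior))
  ends <- ends[!is.na(ends$value_mm), ]
  rec <- do.call(rbind, c(rows, list(ends)))
  rownames(rec) <- NULL
  if (any(rec$value_mm < 0)) stopf("negative distance in measurement record")
  class(rec) <- c("measurement_record", "data.frame")
  rec
}

#' Write / read measurement records as CSV
#'
#' One row per measurement: columns `specimen`, `modality`, `slide`,
#' `measure`, `value_mm`.
#'
#' @param rec a `measurement_record` (or plain data.frame in that schema).
#' @param path CSV path.
#' @return `write_measurements`: the path, invisibly;
#'   `read_measurements`: a `measurement_record`.
#' @export
write_measurements <- function(rec, path) {
  utils::write.csv(as.data.frame(rec), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen", "modality", "slide", "measure", "value_mm")
  miss <- setdiff(need, names(rec))
  if (length(miss)) stopf("measurement CSV lacks column(s): %s",
                          paste(miss, collapse = ", "))
  class(rec) <- c("measurement_record", "data.frame")
  rec
}
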