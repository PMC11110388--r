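serialise_vitals <- function(v) {
  if (is.null(v) || nrow(v) == 0) return(rep("", 4))
  vapply(c("sbp", "rr", "spo2", "gcs"),
         function(s) paste(v[[s]], collapse = ";"), character(1))
}

#' Write incident records to flat CSV
#'
#' One row per incident. Serial vital signs are serialised one column per
#' signal as `;`-delimited ordered lists (`sbp_series`, `rr_series`,
#' `spo2_series`, `gcs_series`); injuries as `;`-separated
#' `region:severity:open` triples (`open` is 0/1); interventions as a
#' `;`-separated label list. [read_records_csv()] inverts the encoding
#' losslessly up to vital-sign timestamps, which are reconstructed on a
#' ten-minute grid. For a fully lossless round trip use
#' [write_records_jsonl()].
#'
#' @param records Tibble of incident records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(records, path) {
  vit <- t(vapply(records$vitals, serialise_vitals, character(4)))
  colnames(vit) <- paste0(c("sbp", "rr", "spo2", "gcs"), "_series")
  inj <- vapply(records$injuries, function(x) {
    if (is.null(x) || nrow(x) == 0) return("")
    paste(sprintf("%s:%d:%d", x$region, as.integer(x$severity),
                  as.integer(x$open_fracture)), collapse = ";")
  }, character(1))
  ivn <- vapply(records$interventions, paste, character(1), collapse = ";")
  flat <- dplyr::select(records, -dplyr::any_of(c("vitals", "injuries", "interventions")))
  flat <- dplyr::bind_cols(flat, tibble::as_tibble(vit),
                           tibble::tibble(injuries = inj, interventions = ivn))
  utils::write.csv(flat, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read incident records from flat CSV
#'
#' @param path CSV produced by [write_records_csv()].
#' @return Tibble of incident records with `vitals`, `injuries` and
#'   `interventions` list-columns reconstructed.
#' @export
read_records_csv <- function(path) {
  flat <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  parse_series <- function(s) if (is.na(s) || s == "") numeric() else
    as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
  vitals <- purrr::pmap(list(flat$sbp_series, flat$rr_series,
                             flat$spo2_series, flat$gcs_series),
                        function(sbp, rr, spo2, gcs) {
    x <- parse_series(sbp)
    data.frame(minute = 10 * (seq_along(x) - 1), sbp = x, rr = parse_series(rr),
               spo2 = parse_series(spo2), gcs = parse_series(gcs))
  })
  injuries <- purrr::map(flat$injuries, function(s) {
    if (is.na(s) || s == "")
      return(data.frame(region = character(), severity = integer(),
                        open_fracture = logical()))
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    data.frame(region = vapply(parts, `[`, "", 1),
               severity = as.integer(vapply(parts, `[`, "", 2)),
               open_fracture = vapply(parts, `[`, "", 3) == "1")
  })
  interventions <- purrr::map(flat$interventions, function(s)
    if (is.na(s) || s == "") character() else strsplit(s, ";", fixed = TRUE)[[1]])
  out <- tibble::as_tibble(flat[, setdiff(names(flat),
    c("sbp_series", "rr_series", "spo2_series", "gcs_series",
      "injuries", "interventions"))])
  out$vitals <- vitals; out$injuries <- injuries; out$interventions <- interventions
  out
}

#' Write incident records as JSON lines (lossless)
#'
#' @param records Tibble of incident records.
#' @param path Output `.jsonl` path.
#' @return `path`, invisibly.
#' @export
write_records_jsonl <- function(records, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    row <- as.list(records[i, setdiff(names(records),
                                      c("vitals", "injuries", "interventions"))])
    row$vitals <- records$vitals[[i]]
    row$injuries <- records$injuries[[i]]
    row$interventions <- as.list(records$interventions[[i]])
    writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA, null = "null",
                                na = "null", dataframe = "columns"), con)
  }
  invisible(path)
}

#' Read incident records from JSON lines
#'
#' @param path `.jsonl` file written by [write_records_jsonl()].
#' @return Tibble of incident records.
#' @export
read_records_jsonl <- function(path) {
  lines <- readLines(path)
  rows <- purrr::map(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    scalars <- x[setdiff(names(x), c("vitals", "injuries", "interventions"))]
    scalars <- purrr::map(scalars, ~ if (is.null(.x)) NA else .x)
    row <- tibble::as_tibble(scalars)
    row$vitals <- list(as.data.frame(x$vitals))
    inj <- as.data.frame(x$injuries)
    if (nrow(inj) == 0)
      inj <- data.frame(region = character(), severity = integer(),
                        open_fracture = logical())
    row$injuries <- list(inj)
    row$interventions <- list(unlist(x$interventions) %||% character())
    row
  })
  dplyr::bind_rows(rows)
}
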