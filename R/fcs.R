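# Minimal FCS 3.1 reader/writer.
#
# No FCS-capable package is assumed; this implements the subset of the
# standard the pipeline needs: list-mode (MODE L) numeric data, DATATYPE F
# (float) or D (double), little- or big-endian, required $PnN/$PnB/$PnE/$PnR
# parameter keywords, and the $SPILLOVER keyword. Doubles are written by
# default so a write/read round trip is bit-exact.

FCS_DELIM <- "/"

#' Write an event matrix to an FCS 3.1 file
#'
#' @param sample An [event_matrix()] (scatter + fluorescence columns are
#'   written in order; truth labels are not persisted — FCS has no slot for
#'   them).
#' @param path Output file path.
#' @param datatype `"D"` (double, default, lossless) or `"F"` (float32).
#' @param spillover Optional [spillover_matrix()] stored under `$SPILLOVER`.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(sample, path, datatype = c("D", "F"),
                      spillover = NULL) {
  datatype <- match.arg(datatype)
  M <- cbind(sample$scatter, sample$fluorescence)
  n_par <- ncol(M)
  n_tot <- nrow(M)
  bytes_per <- if (datatype == "D") 8L else 4L
  data_len <- n_par * n_tot * bytes_per

  kw <- c("$MODE" = "L", "$DATATYPE" = datatype, "$BYTEORD" = "1,2,3,4",
          "$NEXTDATA" = "0", "$PAR" = as.character(n_par),
          "$TOT" = as.character(n_tot),
          "$FIL" = sample$metadata$sample_id %||% "sample")
  for (i in seq_len(n_par)) {
    kw[paste0("$P", i, "N")] <- colnames(M)[i]
    kw[paste0("$P", i, "B")] <- as.character(bytes_per * 8)
    kw[paste0("$P", i, "E")] <- "0,0"
    kw[paste0("$P", i, "R")] <- format(2^24, scientific = FALSE)
  }
  if (!is.null(spillover)) {
    kw["$SPILLOVER"] <- paste(
      c(length(spillover$detectors), spillover$detectors,
        format(as.vector(t(spillover$S)), digits = 17, trim = TRUE,
               scientific = FALSE)),
      collapse = ",")
  }

  render_text <- function(begin_data, end_data) {
    all_kw <- c(kw, "$BEGINDATA" = sprintf("%012d", begin_data),
                "$ENDDATA" = sprintf("%012d", end_data),
                "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
                "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0")
    paste0(FCS_DELIM,
           paste0(names(all_kw), FCS_DELIM, unname(all_kw), FCS_DELIM,
                  collapse = ""))
  }
  text0 <- render_text(0, 0)  # fixed-width offsets: length is final
  text_begin <- 58L
  text_end <- text_begin + nchar(text0, type = "bytes") - 1L
  data_begin <- text_end + 1L
  data_end <- data_begin + data_len - 1L
  text <- render_text(data_begin, data_end)

  hdr_off <- function(x) {
    if (x > 99999999) "       0" else sprintf("%8d", x)
  }
  header <- paste0("FCS3.1    ",
                   hdr_off(text_begin), hdr_off(text_end),
                   hdr_off(data_begin), hdr_off(data_end),
                   hdr_off(0), hdr_off(0))

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.vector(t(M)), con, size = bytes_per, endian = "little")
  invisible(path)
}

parse_fcs_text <- function(raw_text) {
  delim <- rawToChar(raw_text[1])
  body <- rawToChar(raw_text[-1])
  parts <- strsplit(body, delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  keys <- parts[seq(1, length(parts), by = 2)]
  vals <- parts[seq(2, length(parts), by = 2)]
  as.list(stats::setNames(vals, toupper(trimws(keys))))
}

#' Read an FCS 2.0/3.0/3.1 file
#'
#' Supports list-mode numeric data (`$DATATYPE` F or D). Returns the raw
#' event table plus the keyword set; [read_events()] wraps this into an
#' [event_matrix()].
#'
#' @param path FCS file path.
#' @return List with `data` (numeric matrix, columns named from `$PnN`),
#'   `keywords`, and `spillover` (a [spillover_matrix()] parsed from
#'   `$SPILLOVER` when present, else `NULL`).
#' @export
read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- rawToChar(readBin(con, "raw", 58))
  if (!startsWith(header, "FCS"))
    stopf("'%s' is not an FCS file", path)
  off <- function(i) {
    as.integer(trimws(substr(header, 10 + (i - 1) * 8 + 1, 10 + i * 8)))
  }
  text_begin <- off(1); text_end <- off(2)
  seek(con, text_begin)
  kw <- parse_fcs_text(readBin(con, "raw", text_end - text_begin + 1))

  data_begin <- off(3); data_end <- off(4)
  if (is.na(data_begin) || data_begin == 0)
    data_begin <- as.integer(kw[["$BEGINDATA"]])
  if (is.na(data_end) || data_end == 0)
    data_end <- as.integer(kw[["$ENDDATA"]])

  datatype <- kw[["$DATATYPE"]]
  if (!datatype %in% c("F", "D"))
    stopf("unsupported FCS $DATATYPE '%s' (only F and D)", datatype)
  if (!is.null(kw[["$MODE"]]) && kw[["$MODE"]] != "L")
    stopf("unsupported FCS $MODE '%s'", kw[["$MODE"]])
  endian <- if (startsWith(kw[["$BYTEORD"]], "1")) "little" else "big"
  n_par <- as.integer(kw[["$PAR"]])
  n_tot <- as.integer(kw[["$TOT"]])
  bytes_per <- if (datatype == "D") 8L else 4L

  seek(con, data_begin)
  vals <- readBin(con, "double", n = n_par * n_tot, size = bytes_per,
                  endian = endian)
  M <- matrix(vals, nrow = n_tot, ncol = n_par, byrow = TRUE)
  colnames(M) <- vapply(seq_len(n_par), function(i)
    kw[[paste0("$P", i, "N")]] %||% paste0("P", i), character(1))

  spill <- NULL
  sp_kw <- kw[["$SPILLOVER"]] %||% kw[["SPILL"]] %||% kw[["$COMP"]]
  if (!is.null(sp_kw)) {
    toks <- strsplit(sp_kw, ",", fixed = TRUE)[[1]]
    k <- as.integer(toks[1])
    dets <- toks[2:(k + 1)]
    S <- matrix(as.numeric(toks[-(1:(k + 1))]), nrow = k, byrow = TRUE,
                dimnames = list(dets, dets))
    spill <- spillover_matrix(S, dets)
  }
  list(data = M, keywords = kw, spillover = spill)
}
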