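#' Minimal FCS 3.1 writer and reader
#'
#' Writes an [event_table()] as a single-dataset FCS 3.1 file: list-mode
#' float32 data (`$DATATYPE/F`, little-endian `$BYTEORD/1,2,3,4`), one
#' parameter per detector plus the three scatter channels and, when
#' truth labels are present, a `TruthIndex` parameter holding the 1-based
#' index into the label dictionary stored in the sidecar.  Channel names,
#' event order and values round-trip to float32 precision; unknown
#' keywords found on read are preserved in the returned attributes.
#' Ground-truth labels, abundances and the seed round-trip through a
#' JSON sidecar written next to the FCS file ([write_event_sidecar()]).
#'
#' @param events an [event_table()].
#' @param path output path (`.fcs`).
#' @param sidecar write the JSON sidecar alongside (default `TRUE` when
#'   truth labels are present).
#' @return `write_fcs()` returns `path` invisibly; `read_fcs()` returns
#'   an [event_table()] (truth fields restored from the sidecar if one
#'   is found next to the file).
#' @export
write_fcs <- function(events, path, sidecar = !is.null(events$truth_labels)) {
  chans <- c(colnames(events$raw), scatter_channels())
  data <- cbind(events$raw, as.matrix(events$scatter[, scatter_channels()]))
  labels <- events$truth_labels
  if (!is.null(labels)) {
    dict <- sort(unique(labels))
    data <- cbind(data, TruthIndex = match(labels, dict))
    chans <- c(chans, "TruthIndex")
  }
  n <- nrow(data); p <- ncol(data)
  kw <- c("$DATATYPE", "F", "$MODE", "L", "$BYTEORD", "1,2,3,4",
          "$NEXTDATA", "0", "$TOT", as.character(n), "$PAR", as.character(p))
  for (i in seq_len(p)) {
    kw <- c(kw,
            sprintf("$P%dN", i), chans[i],
            sprintf("$P%dB", i), "32",
            sprintf("$P%dE", i), "0,0",
            sprintf("$P%dR", i), format(ceiling(max(data[, i], 1)),
                                        scientific = FALSE))
  }
  delim <- "/"
  ## fixed-point iteration: text offsets depend on the text length
  begin_text <- 58L
  data_begin <- 0L; data_len <- n * p * 4L
  text <- ""
  for (pass in 1:3) {
    body <- paste0(delim, paste(kw, collapse = delim), delim,
                   "$BEGINDATA", delim, data_begin, delim,
                   "$ENDDATA", delim, data_begin + data_len - 1L, delim)
    end_text <- begin_text + nchar(body, type = "bytes") - 1L
    data_begin_new <- end_text + 1L
    if (data_begin_new == data_begin) break
    data_begin <- data_begin_new
  }
  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    begin_text, end_text,
                    if (data_begin <= 99999999) data_begin else 0L,
                    if (data_begin + data_len - 1 <= 99999999)
                      data_begin + data_len - 1L else 0L,
                    0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(body, con, eos = NULL)
  writeBin(as.vector(t(data)), con, size = 4L, endian = "little")
  if (sidecar) write_event_sidecar(events, paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_fcs
#' @param layout expected [detector_layout()]; a detector-channel count
#'   mismatch is a structural error.
#' @export
read_fcs <- function(path, layout = detector_layout()) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58L, useBytes = TRUE)
  if (substr(header, 1, 6) != "FCS3.1" && substr(header, 1, 6) != "FCS3.0")
    stop("malformed FCS header at offset 0: ", substr(header, 1, 6))
  off <- suppressWarnings(as.integer(substring(
    header, seq(11, 51, by = 8), seq(18, 58, by = 8))))
  if (anyNA(off[1:2])) stop("malformed FCS header: unreadable TEXT offsets")
  seek(con, off[1])
  text <- readChar(con, off[2] - off[1] + 1L, useBytes = TRUE)
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  kw <- stats::setNames(parts[seq(2, length(parts), 2)],
                        parts[seq(1, length(parts), 2)])
  p <- as.integer(kw[["$PAR"]]); n <- as.integer(kw[["$TOT"]])
  if (!identical(kw[["$DATATYPE"]], "F"))
    stop("only $DATATYPE/F (float) FCS data is supported")
  endian <- if (identical(kw[["$BYTEORD"]], "4,3,2,1")) "big" else "little"
  dbeg <- as.integer(kw[["$BEGINDATA"]] %||% off[3])
  seek(con, dbeg)
  vals <- readBin(con, "numeric", n * p, size = 4L, endian = endian)
  data <- matrix(vals, nrow = n, ncol = p, byrow = TRUE)
  chans <- vapply(seq_len(p), function(i) kw[[sprintf("$P%dN", i)]],
                  character(1))
  colnames(data) <- chans
  known <- c("$DATATYPE", "$MODE", "$BYTEORD", "$NEXTDATA", "$TOT", "$PAR",
             "$BEGINDATA", "$ENDDATA",
             unlist(lapply(seq_len(p), function(i)
               sprintf(c("$P%dN", "$P%dB", "$P%dE", "$P%dR"), i))))
  extra <- kw[setdiff(names(kw), known)]
  det <- setdiff(chans, c(scatter_channels(), "TruthIndex"))
  if (length(det) != layout$n)
    stop("file has ", length(det), " detector channels; layout expects ",
         layout$n)
  truth_labels <- NULL; truth_ab <- NULL; alive <- NULL
  seed <- NA_integer_
  sc_path <- paste0(path, ".json")
  if (file.exists(sc_path)) {
    sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
    seed <- sc$seed %||% NA_integer_
    alive <- sc$alive
    if ("TruthIndex" %in% chans && !is.null(sc$label_dictionary))
      truth_labels <- sc$label_dictionary[data[, "TruthIndex"]]
    if (!is.null(sc$truth_abundances))
      truth_ab <- as.matrix(sc$truth_abundances)
  }
  out <- event_table(data[, det, drop = FALSE],
                     as.data.frame(data[, scatter_channels(), drop = FALSE],
                                   check.names = FALSE),
                     truth_labels = truth_labels,
                     truth_abundances = truth_ab,
                     alive = alive, seed = seed, layout = layout)
  attr(out, "keywords") <- extra
  out
}

#' @rdname write_fcs
#' @export
write_event_sidecar <- function(events, path) {
  labels <- events$truth_labels
  dict <- if (!is.null(labels)) sort(unique(labels))
  jsonlite::write_json(
    list(seed = events$seed,
         label_dictionary = dict,
         alive = events$alive,
         truth_abundances = events$truth_abundances),
    path, auto_unbox = TRUE, null = "null", digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Write or read an event table as CSV
#'
#' A plain-text mirror of the FCS representation: detector columns in
#' layout order, the scatter channels, and optional `truth_label` /
#' `alive` columns.
#'
#' @param events an [event_table()].
#' @param path file path.
#' @param layout a [detector_layout()] (for reading).
#' @return `write_events_csv()` returns `path` invisibly;
#'   `read_events_csv()` returns an [event_table()].
#' @export
write_events_csv <- function(events, path) {
  df <- data.frame(events$raw, check.names = FALSE)
  df <- cbind(df, events$scatter[, scatter_channels()])
  if (!is.null(events$truth_labels)) df$truth_label <- events$truth_labels
  if (!is.null(events$alive)) df$alive <- events$alive
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path, layout = detector_layout()) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(layout$detectors %in% colnames(df)))
    stop("CSV is missing detector columns for this layout")
  event_table(as.matrix(df[, layout$detectors]),
              df[, scatter_channels(), drop = FALSE],
              truth_labels = df$truth_label,
              alive = df$alive, layout = layout)
}
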