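#' Single-lead ECG recording
#'
#' Container for a sampled single-lead voltage series.
#'
#' @param samples numeric vector of voltages (any consistent unit; raw ADC
#'   units are kept unchanged by the readers, amplitude scaling is handled
#'   once inside the CS-ECM builder).
#' @param fs sampling rate in Hz (> 0).
#' @param record_id record identifier string.
#' @param label optional class code, one of N, A, O, P.
#' @return An object of class `ecg_recording`.
#' @export
ecg_recording <- function(samples, fs, record_id = "rec", label = NULL) {
  samples <- as.numeric(samples)
  if (!length(samples)) stop("`samples` must be non-empty")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("`fs` must be a positive scalar")
  if (!is.null(label) && !label %in% ecg_classes())
    stop("invalid label: ", label)
  structure(
    list(record_id = as.character(record_id), samples = samples,
         fs = as.numeric(fs), label = label),
    class = "ecg_recording"
  )
}

#' @export
print.ecg_recording <- function(x, ...) {
  cat(sprintf("ECG recording '%s': %d samples @ %g Hz (%.1f s)%s\n",
              x$record_id, length(x$samples), x$fs,
              length(x$samples) / x$fs,
              if (is.null(x$label)) "" else paste0(", label ", x$label)))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an `ecg_recording`.
#' @return Duration in seconds.
#' @export
duration_s <- function(rec) length(rec$samples) / rec$fs

## ---------------------------------------------------------------------------
## Minimal MAT v5 container, restricted to the single-variable numeric-vector
## dialect used by the CinC 2017 challenge files (one matrix named "val").
## No installed R package reads MAT files, so the subset is implemented here;
## the writer/reader pair is cross-checked against scipy.io in the tests.
## ---------------------------------------------------------------------------

.mat_mi_sizes <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 2L, `5` = 4L,
                   `6` = 4L, `7` = 4L, `9` = 8L, `12` = 8L, `13` = 8L)

.mat_read_numeric <- function(con, mitype, nbytes, endian) {
  n <- nbytes %/% .mat_mi_sizes[[as.character(mitype)]]
  switch(as.character(mitype),
    `1` = readBin(con, integer(), n, size = 1L, signed = TRUE, endian = endian),
    `2` = readBin(con, integer(), n, size = 1L, signed = FALSE, endian = endian),
    `3` = readBin(con, integer(), n, size = 2L, signed = TRUE, endian = endian),
    `4` = readBin(con, integer(), n, size = 2L, signed = FALSE, endian = endian),
    `5` = readBin(con, integer(), n, size = 4L, endian = endian),
    `6` = as.numeric(readBin(con, integer(), n, size = 4L, endian = endian)),
    `7` = readBin(con, numeric(), n, size = 4L, endian = endian),
    `9` = readBin(con, numeric(), n, size = 8L, endian = endian),
    stop("unsupported MAT data type: ", mitype)
  )
}

.mat_parse_matrix <- function(raw_data, endian) {
  con <- rawConnection(raw_data)
  on.exit(close(con))
  name <- NULL; dims <- NULL; values <- NULL
  while (length(hdr <- readBin(con, integer(), 2L, size = 4L, endian = endian)) == 2L) {
    type <- hdr[1]; nbytes <- hdr[2]
    small <- bitwAnd(type, -65536L) != 0L        # small data element format
    if (small) {
      nbytes <- bitwShiftR(bitwAnd(type, -65536L), 16L)
      type <- bitwAnd(type, 65535L)
      # the 4 data bytes sit in the second half of the 8-byte tag, which
      # was read above as hdr[2]; reconstruct them with the same endianness
      payload <- writeBin(hdr[2], raw(), size = 4L, endian = endian)
      pcon <- rawConnection(payload[seq_len(nbytes)])
      dat <- if (type == 1L && is.null(name) && !is.null(dims))
        rawToChar(payload[seq_len(nbytes)])
      else .mat_read_numeric(pcon, type, nbytes, endian)
      close(pcon)
    } else {
      if (type == 1L && !is.null(dims) && is.null(name)) {
        dat <- rawToChar(readBin(con, raw(), nbytes))
      } else {
        dat <- .mat_read_numeric(con, type, nbytes, endian)
      }
      pad <- (8L - nbytes %% 8L) %% 8L
      if (pad) readBin(con, raw(), pad)
    }
    if (is.null(dims) && type == 6L) {
      # array flags (first subelement, miUINT32 x2) -- class byte unused here
    } else if (is.null(dims) && type == 5L) {
      dims <- dat
    } else if (is.null(name)) {
      name <- if (is.character(dat)) dat else intToUtf8(dat)
    } else if (is.null(values)) {
      values <- as.numeric(dat)
    }
  }
  list(name = name, dims = dims, values = values)
}

#' Read a CinC-2017 style MAT record
#'
#' Reads a MAT v5 file holding a single numeric vector variable (the CinC
#' 2017 dialect stores an int16 vector named `val`).  The sampling rate of
#' that dialect is fixed at 300 Hz.  Raw sample units are preserved.
#'
#' @param path path to the `.mat` file.
#' @param record_id record id; defaults to the file name without extension.
#' @param label optional class code to attach.
#' @return An [ecg_recording()] with `fs = 300`.
#' @export
read_cinc_record <- function(path, record_id = NULL, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, raw(), 128L)
  if (length(header) < 128L) stop("not a MAT v5 file (truncated header): ", path)
  endmark <- rawToChar(header[127:128])
  endian <- if (endmark == "IM") "little" else if (endmark == "MI") "big" else
    stop("not a MAT v5 file (bad endian mark): ", path)
  values <- NULL
  repeat {
    hdr <- readBin(con, integer(), 2L, size = 4L, endian = endian)
    if (length(hdr) < 2L) break
    type <- hdr[1]; nbytes <- hdr[2]
    body <- readBin(con, raw(), nbytes + (8L - nbytes %% 8L) %% 8L)
    body <- body[seq_len(nbytes)]
    if (type == 15L) {                      # zlib-compressed element
      body <- tryCatch(memDecompress(body, type = "gzip"),
                       error = function(e)
                         stop("cannot decompress MAT element in ", path))
      inner <- rawConnection(body)
      hdr2 <- readBin(inner, integer(), 2L, size = 4L, endian = endian)
      body <- readBin(inner, raw(), hdr2[2])
      close(inner)
      type <- hdr2[1]
    }
    if (type == 14L) {                      # miMATRIX
      parsed <- .mat_parse_matrix(body, endian)
      values <- parsed$values
      break
    }
  }
  if (is.null(values))
    stop("no sample vector found in MAT file: ", path)
  if (!length(values))
    stop("empty sample vector in MAT file: ", path)
  if (is.null(record_id))
    record_id <- sub("\\.[Mm][Aa][Tt]$", "", basename(path))
  ecg_recording(values, fs = 300, record_id = record_id, label = label)
}

#' Write a recording as a CinC-style MAT file
#'
#' Writes a MAT v5 file with one vector variable named `val`.  Integral
#' samples within the int16 range are stored as int16 (the on-disk type of
#' the CinC files); anything else is stored as double, so the round trip is
#' lossless either way.
#'
#' @param rec an [ecg_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cinc_record <- function(rec, path) {
  stopifnot(inherits(rec, "ecg_recording"))
  x <- rec$samples
  as_int16 <- all(x == round(x)) && all(abs(x) <= 32767)
  con <- file(path, "wb")
  on.exit(close(con))
  desc <- sprintf("MATLAB 5.0 MAT-file, written by bitecg")
  header <- charToRaw(format(desc, width = 116))
  writeBin(header[1:116], con)
  writeBin(raw(8L), con)                                 # subsys offset
  writeBin(as.raw(c(0x00, 0x01)), con)                   # version 0x0100
  writeBin(charToRaw("IM"), con)                         # little endian
  name <- "val"
  n <- length(x)
  data_bytes <- n * if (as_int16) 2L else 8L
  data_pad <- (8L - data_bytes %% 8L) %% 8L
  name_pad <- (8L - nchar(name) %% 8L) %% 8L
  total <- 16L + 16L + (8L + nchar(name) + name_pad) + (8L + data_bytes + data_pad)
  writeBin(c(14L, total), con, size = 4L, endian = "little")   # miMATRIX
  writeBin(c(6L, 8L), con, size = 4L, endian = "little")       # array flags
  writeBin(c(if (as_int16) 10L else 6L, 0L), con, size = 4L, endian = "little")
  writeBin(c(5L, 8L), con, size = 4L, endian = "little")       # dims
  writeBin(c(1L, n), con, size = 4L, endian = "little")
  writeBin(c(1L, nchar(name)), con, size = 4L, endian = "little")
  writeBin(charToRaw(name), con)
  if (name_pad) writeBin(raw(name_pad), con)
  if (as_int16) {
    writeBin(c(3L, data_bytes), con, size = 4L, endian = "little")
    writeBin(as.integer(x), con, size = 2L, endian = "little")
  } else {
    writeBin(c(9L, data_bytes), con, size = 4L, endian = "little")
    writeBin(as.numeric(x), con, size = 8L, endian = "little")
  }
  if (data_pad) writeBin(raw(data_pad), con)
  invisible(path)
}

#' Read a class-label reference table
#'
#' Two-column CSV (record id, class code), no header, as distributed with
#' the CinC 2017 dataset (`REFERENCE.csv`).
#'
#' @param path path to the CSV file.
#' @return A data frame with columns `record_id` and `label`, zero rows for
#'   an empty file.
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0)
    return(data.frame(record_id = character(), label = character()))
  tab <- utils::read.csv(path, header = FALSE, colClasses = "character",
                         strip.white = TRUE)
  if (ncol(tab) < 2) stop("reference file must have two columns: ", path)
  tab <- data.frame(record_id = tab[[1]], label = tab[[2]])
  bad <- setdiff(unique(tab$label), ecg_classes())
  if (length(bad))
    stop("invalid class code(s) in reference: ", paste(bad, collapse = ", "))
  dup <- tab$record_id[duplicated(tab$record_id)]
  if (length(dup))
    stop("duplicate record id(s): ", paste(unique(dup), collapse = ", "))
  tab
}

#' Write a reference table
#' @param ref data frame with `record_id` and `label` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path) {
  utils::write.table(ref[, c("record_id", "label")], path, sep = ",",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a plain CSV voltage series
#'
#' Accepts one value per line or a single comma-separated row.  CSV carries
#' no sampling rate, so `fs` must be supplied.
#'
#' @param path path to the CSV file.
#' @param fs sampling rate in Hz.
#' @param record_id record id; defaults to the file name.
#' @return An [ecg_recording()].
#' @export
read_signal_csv <- function(path, fs, record_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty signal file: ", path)
  vals <- as.numeric(unlist(strsplit(lines, ",")))
  if (anyNA(vals)) stop("non-numeric values in signal file: ", path)
  if (is.null(record_id))
    record_id <- sub("\\.[Cc][Ss][Vv]$", "", basename(path))
  ecg_recording(vals, fs = fs, record_id = record_id)
}

## ---------------------------------------------------------------------------
## CS-ECM persistence
## ---------------------------------------------------------------------------

#' Write a CS-ECM matrix
#'
#' `binary` is a small array container (magic, int32 dims, doubles) and is
#' bit-lossless; `csv` writes one matrix row per line (lossless via full
#' precision); `png` renders the matrix with a blue-to-red colormap over its
#' value range, one pixel per matrix cell (so a 180x240 matrix gives a
#' 240:180 raster before any decoration).
#'
#' @param m a `csecm` object (see [build_csecms()]) or a plain matrix.
#' @param path output path.
#' @param format one of `"binary"`, `"csv"`, `"png"`.
#' @return `path`, invisibly.
#' @export
write_csecm <- function(m, path, format = c("binary", "csv", "png")) {
  format <- match.arg(format)
  mat <- if (inherits(m, "csecm")) m$matrix else as.matrix(m)
  if (format == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw("CSECM1\n\n"), con)
    writeBin(c(nrow(mat), ncol(mat)), con, size = 4L, endian = "little")
    writeBin(as.numeric(mat), con, size = 8L, endian = "little")
  } else if (format == "csv") {
    lines <- apply(mat, 1L, function(r)
      paste(formatC(r, format = "g", digits = 17), collapse = ","))
    writeLines(lines, path)
  } else {
    rng <- range(mat)
    z <- if (diff(rng) > 0) (mat - rng[1]) / diff(rng) else mat * 0
    ramp <- grDevices::colorRamp(c("#2166AC", "#F7F7F7", "#B2182B"))(as.vector(z))
    img <- array(ramp / 255, dim = c(nrow(mat), ncol(mat), 3L))
    png::writePNG(img, path)
  }
  invisible(path)
}

#' Read a CS-ECM matrix written by [write_csecm()]
#'
#' @param path input path.
#' @param format `"binary"` or `"csv"`; inferred from the extension when
#'   missing (`.csv` means CSV, anything else binary).
#' @return A numeric matrix.
#' @export
read_csecm <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format))
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "binary"
  if (format == "csv") {
    rows <- lapply(readLines(path), function(l)
      as.numeric(strsplit(l, ",")[[1]]))
    return(do.call(rbind, rows))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, raw(), 8L))
  if (magic != "CSECM1\n\n") stop("not a CS-ECM binary file: ", path)
  dims <- readBin(con, integer(), 2L, size = 4L, endian = "little")
  vals <- readBin(con, numeric(), prod(dims), size = 8L, endian = "little")
  matrix(vals, dims[1], dims[2])
}
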