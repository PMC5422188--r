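# Binary acquisition-frame codec.
#
# One acquisition record carries three triaxial accelerometers, a gyroscope,
# a magnetometer, a barometer, four device temperatures, battery status, the
# real-time-clock registers and a running sample counter: a 94-byte payload,
# zero-padded to a 128-byte frame. Multi-byte fields are little-endian;
# sensor channels are IEEE-754 single precision; the clock registers are six
# unsigned bytes (year stored as offset from 2000); the counter is a 4-byte
# unsigned integer.

FLOAT32_MAX <- 3.4028234663852886e38

#' Describe one field of a frame layout
#'
#' @param name unique field identifier.
#' @param channels number of channels (e.g. 3 for a triaxial sensor).
#' @param bytes_per_channel storage width of one channel.
#' @param encoding one of `"ieee-754-single"`, `"unsigned-int"`,
#'   `"signed-int"`, `"packed-datetime"`.
#' @return a `field_spec` object.
#' @export
field_spec <- function(name, channels, bytes_per_channel,
                       encoding = c("ieee-754-single", "unsigned-int",
                                    "signed-int", "packed-datetime")) {
  encoding <- match.arg(encoding)
  channels <- as.integer(channels)
  bytes_per_channel <- as.integer(bytes_per_channel)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            channels >= 1L, bytes_per_channel >= 1L)
  if (encoding == "ieee-754-single" && bytes_per_channel != 4L) {
    stop("ieee-754-single fields use 4 bytes per channel", call. = FALSE)
  }
  structure(list(name = name, channels = channels,
                 bytes_per_channel = bytes_per_channel, encoding = encoding),
            class = "field_spec")
}

#' Assemble a frame layout
#'
#' @param fields list of [field_spec()] objects, in on-disk order.
#' @param frame_bytes total padded frame size (default 128).
#' @return a `frame_layout` object.
#' @export
frame_layout <- function(fields, frame_bytes = 128L) {
  stopifnot(is.list(fields), all(vapply(fields, inherits, TRUE, "field_spec")))
  nms <- vapply(fields, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("field names must be unique", call. = FALSE)
  layout <- structure(list(fields = fields, frame_bytes = as.integer(frame_bytes)),
                      class = "frame_layout")
  if (payload_size(layout) > layout$frame_bytes) {
    stop("payload exceeds frame size", call. = FALSE)
  }
  layout
}

#' Default acquisition layout (94-byte payload in a 128-byte frame)
#'
#' Three accelerometers, gyroscope and magnetometer at 12 bytes each,
#' barometer 4, temperatures 16, battery 4, clock registers 6, counter 4.
#'
#' @return a `frame_layout`.
#' @export
default_frame_layout <- function() {
  frame_layout(list(
    field_spec("acc1", 3L, 4L, "ieee-754-single"),
    field_spec("acc2", 3L, 4L, "ieee-754-single"),
    field_spec("acc3", 3L, 4L, "ieee-754-single"),
    field_spec("gyro", 3L, 4L, "ieee-754-single"),
    field_spec("mag", 3L, 4L, "ieee-754-single"),
    field_spec("baro", 1L, 4L, "ieee-754-single"),
    field_spec("temps", 4L, 4L, "ieee-754-single"),
    field_spec("battery", 1L, 4L, "ieee-754-single"),
    field_spec("rtc", 6L, 1L, "packed-datetime"),
    field_spec("counter", 1L, 4L, "unsigned-int")
  ), frame_bytes = 128L)
}

#' Payload size of a layout in bytes (padding excluded)
#'
#' @param layout a [frame_layout()]; may hold zero fields.
#' @return integer byte count, `sum(channels * bytes_per_channel)`.
#' @export
payload_size <- function(layout) {
  if (length(layout$fields) == 0L) return(0L)
  sum(vapply(layout$fields,
             function(f) f$channels * f$bytes_per_channel, integer(1)))
}

#' Construct one acquisition record
#'
#' @param acc1,acc2,acc3 triaxial accelerometer readings in G.
#' @param gyro triaxial gyroscope reading in degrees per second.
#' @param mag triaxial magnetometer reading in gauss.
#' @param baro barometric pressure in mbar.
#' @param temps four device temperatures in degrees Celsius.
#' @param battery battery status.
#' @param rtc clock registers `c(year, month, day, hour, minute, second)`.
#' @param counter non-negative sample counter.
#' @return a `sample_frame` object.
#' @export
sample_frame <- function(acc1 = c(0, 0, 0), acc2 = c(0, 0, 0),
                         acc3 = c(0, 0, 0), gyro = c(0, 0, 0),
                         mag = c(0, 0, 0), baro = 0, temps = rep(0, 4),
                         battery = 0, rtc = c(2000, 1, 1, 0, 0, 0),
                         counter = 0) {
  f <- list(acc1 = as.numeric(acc1), acc2 = as.numeric(acc2),
            acc3 = as.numeric(acc3), gyro = as.numeric(gyro),
            mag = as.numeric(mag), baro = as.numeric(baro),
            temps = as.numeric(temps), battery = as.numeric(battery),
            rtc = as.numeric(rtc), counter = as.numeric(counter))
  stopifnot(lengths(f[c("acc1", "acc2", "acc3", "gyro", "mag")]) == 3L,
            length(f$baro) == 1L, length(f$temps) == 4L,
            length(f$battery) == 1L, length(f$rtc) == 6L,
            length(f$counter) == 1L)
  validate_rtc(f$rtc)
  if (f$counter < 0) stop("counter must be non-negative", call. = FALSE)
  structure(f, class = "sample_frame")
}

validate_rtc <- function(rtc) {
  ok <- rtc[1] >= 2000 && rtc[1] <= 2255 && rtc[2] >= 1 && rtc[2] <= 12 &&
    rtc[3] >= 1 && rtc[3] <= 31 && rtc[4] >= 0 && rtc[4] <= 23 &&
    rtc[5] >= 0 && rtc[5] <= 59 && rtc[6] >= 0 && rtc[6] <= 59
  if (!ok) stop("rtc registers outside calendar ranges", call. = FALSE)
  invisible(TRUE)
}

encode_uint <- function(value, nbytes, name) {
  if (any(value < 0) || any(value >= 256^nbytes)) {
    stop(sprintf("field '%s' out of range for %d-byte unsigned encoding",
                 name, nbytes), call. = FALSE)
  }
  out <- raw(length(value) * nbytes)
  for (i in seq_along(value)) {
    v <- value[i]
    for (j in seq_len(nbytes)) {  # little-endian
      out[(i - 1L) * nbytes + j] <- as.raw(v %% 256)
      v <- v %/% 256
    }
  }
  out
}

decode_uint <- function(bytes, nbytes) {
  m <- matrix(as.numeric(bytes), nrow = nbytes)
  as.numeric(256^(seq_len(nbytes) - 1L) %*% m)
}

encode_field <- function(f, value) {
  if (length(value) != f$channels) {
    stop(sprintf("field '%s' expects %d channels", f$name, f$channels),
         call. = FALSE)
  }
  switch(f$encoding,
    "ieee-754-single" = {
      if (any(!is.finite(value)) || any(abs(value) > FLOAT32_MAX)) {
        stop(sprintf("field '%s' out of single-precision range", f$name),
             call. = FALSE)
      }
      writeBin(as.numeric(value), raw(), size = 4L, endian = "little")
    },
    "unsigned-int" = encode_uint(value, f$bytes_per_channel, f$name),
    "signed-int" = {
      half <- 256^f$bytes_per_channel / 2
      if (any(value < -half) || any(value >= half)) {
        stop(sprintf("field '%s' out of signed range", f$name), call. = FALSE)
      }
      encode_uint(ifelse(value < 0, value + 2 * half, value),
                  f$bytes_per_channel, f$name)
    },
    "packed-datetime" = {
      validate_rtc(value)
      encode_uint(value - c(2000, 0, 0, 0, 0, 0), 1L, f$name)
    })
}

decode_field <- function(f, bytes) {
  switch(f$encoding,
    "ieee-754-single" = readBin(bytes, "numeric", n = f$channels, size = 4L,
                                endian = "little"),
    "unsigned-int" = decode_uint(bytes, f$bytes_per_channel),
    "signed-int" = {
      half <- 256^f$bytes_per_channel / 2
      v <- decode_uint(bytes, f$bytes_per_channel)
      ifelse(v >= half, v - 2 * half, v)
    },
    "packed-datetime" = {
      v <- decode_uint(bytes, 1L) + c(2000, 0, 0, 0, 0, 0)
      validate_rtc(v)
      v
    })
}

#' Encode a frame to its padded binary form
#'
#' Fields are written in layout order, little-endian, and the remainder of
#' the frame is zero-padded.
#'
#' @param frame a [sample_frame()].
#' @param layout a [frame_layout()] (default acquisition layout).
#' @return raw vector of `layout$frame_bytes` bytes.
#' @export
encode_frame <- function(frame, layout = default_frame_layout()) {
  stopifnot(inherits(frame, "sample_frame"), inherits(layout, "frame_layout"))
  out <- raw(layout$frame_bytes)
  pos <- 0L
  for (f in layout$fields) {
    enc <- encode_field(f, frame[[f$name]])
    out[pos + seq_along(enc)] <- enc
    pos <- pos + length(enc)
  }
  out
}

#' Decode one padded binary frame
#'
#' Inverse of [encode_frame()] on its image; padding bytes are ignored.
#'
#' @param bytes raw vector of exactly `layout$frame_bytes` bytes.
#' @param layout a [frame_layout()].
#' @return a [sample_frame()].
#' @export
decode_frame <- function(bytes, layout = default_frame_layout()) {
  if (!is.raw(bytes) || length(bytes) != layout$frame_bytes) {
    stop(sprintf("frame must be exactly %d bytes, got %d",
                 layout$frame_bytes, length(bytes)), call. = FALSE)
  }
  vals <- list()
  pos <- 0L
  for (f in layout$fields) {
    nb <- f$channels * f$bytes_per_channel
    vals[[f$name]] <- decode_field(f, bytes[pos + seq_len(nb)])
    pos <- pos + nb
  }
  do.call(sample_frame, vals)
}

SESSION_MAGIC <- charToRaw("N3S1")

layout_checksum <- function(layout) {
  desc <- paste(vapply(layout$fields, function(f) {
    paste(f$name, f$channels, f$bytes_per_channel, f$encoding, sep = ":")
  }, ""), collapse = ";")
  b <- as.integer(charToRaw(desc))
  h <- 2166136261
  for (x in b) h <- ((h %% 2^24) * 16777619 + x * 31) %% 2^32  # FNV-flavoured
  h
}

session_header <- function(layout, rate_hz) {
  c(SESSION_MAGIC,
    as.raw(1L),                               # format version
    as.raw(0L),                               # reserved
    encode_uint(rate_hz, 2L, "rate"),
    encode_uint(layout_checksum(layout), 4L, "checksum"),
    encode_uint(layout$frame_bytes, 2L, "frame_bytes"),
    as.raw(c(0L, 0L)))                        # pad to 16 bytes
}

#' Write a session of frames to a binary .n3s file
#'
#' A fixed 16-byte header (magic, version, sampling rate, layout checksum,
#' frame size) followed by consecutive encoded frames.
#'
#' @param frames list of [sample_frame()] objects sharing one layout.
#' @param path output file.
#' @param rate_hz nominal sampling rate recorded in the header.
#' @param layout a [frame_layout()].
#' @return `path`, invisibly.
#' @export
write_session <- function(frames, path, rate_hz = 50L,
                          layout = default_frame_layout()) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(session_header(layout, rate_hz), con)
  for (fr in frames) writeBin(encode_frame(fr, layout), con)
  invisible(path)
}

#' Read a binary .n3s session
#'
#' Frame order is preserved. A non-increasing sample counter raises a warning
#' (gaps are reported, never repaired); a trailing partial frame is an error
#' reporting the index of the first incomplete frame.
#'
#' @param path session file.
#' @param layout expected [frame_layout()]; checked against the header.
#' @return list with `frames` (list of [sample_frame()]) and `rate_hz`.
#' @export
read_session <- function(path, layout = default_frame_layout()) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 16L || !identical(bytes[1:4], SESSION_MAGIC)) {
    stop("not a .n3s session file (bad magic)", call. = FALSE)
  }
  rate_hz <- decode_uint(bytes[7:8], 2L)
  cks <- decode_uint(bytes[9:12], 4L)
  fb <- decode_uint(bytes[13:14], 2L)
  if (fb != layout$frame_bytes || cks != layout_checksum(layout)) {
    stop("session header does not match the supplied layout", call. = FALSE)
  }
  body <- bytes[-(1:16)]
  n_complete <- length(body) %/% layout$frame_bytes
  if (length(body) %% layout$frame_bytes != 0L) {
    stop(sprintf("truncated session: partial frame at index %d", n_complete),
         call. = FALSE)
  }
  frames <- vector("list", n_complete)
  for (i in seq_len(n_complete)) {
    off <- (i - 1L) * layout$frame_bytes
    frames[[i]] <- decode_frame(body[off + seq_len(layout$frame_bytes)], layout)
  }
  counters <- vapply(frames, `[[`, numeric(1), "counter")
  if (length(counters) > 1L && any(diff(counters) <= 0)) {
    warning(sprintf("sample counter not strictly increasing at frame %d",
                    which(diff(counters) <= 0)[1] + 1L), call. = FALSE)
  }
  list(frames = frames, rate_hz = rate_hz)
}

frame_columns <- function() {
  c(paste0("acc1_", c("x", "y", "z")), paste0("acc2_", c("x", "y", "z")),
    paste0("acc3_", c("x", "y", "z")), paste0("gyro_", c("x", "y", "z")),
    paste0("mag_", c("x", "y", "z")), "baro", paste0("temp_", 1:4),
    "battery", "counter")
}

#' Tabulate a list of frames (one row per frame)
#'
#' Adds an ISO-8601 `timestamp` column from the clock registers.
#'
#' @param frames list of [sample_frame()] objects.
#' @return data.frame.
#' @export
frames_to_df <- function(frames) {
  m <- t(vapply(frames, function(fr) {
    c(fr$acc1, fr$acc2, fr$acc3, fr$gyro, fr$mag, fr$baro, fr$temps,
      fr$battery, fr$counter)
  }, numeric(22)))
  df <- as.data.frame(m)
  names(df) <- frame_columns()
  df$timestamp <- vapply(frames, function(fr) {
    sprintf("%04d-%02d-%02dT%02d:%02d:%02d", fr$rtc[1], fr$rtc[2], fr$rtc[3],
            fr$rtc[4], fr$rtc[5], fr$rtc[6])
  }, "")
  df[c("timestamp", frame_columns())]
}

#' Rebuild frames from the tabular form produced by [frames_to_df()]
#'
#' @param df data.frame with a `timestamp` column and the 21 channel columns.
#' @return list of [sample_frame()] objects.
#' @export
df_to_frames <- function(df) {
  need <- c("timestamp", frame_columns())
  if (!all(need %in% names(df))) {
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "),
         call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    ts <- as.numeric(strsplit(gsub("[-T:]", " ", df$timestamp[i]), " ")[[1]])
    sample_frame(
      acc1 = as.numeric(df[i, paste0("acc1_", c("x", "y", "z"))]),
      acc2 = as.numeric(df[i, paste0("acc2_", c("x", "y", "z"))]),
      acc3 = as.numeric(df[i, paste0("acc3_", c("x", "y", "z"))]),
      gyro = as.numeric(df[i, paste0("gyro_", c("x", "y", "z"))]),
      mag = as.numeric(df[i, paste0("mag_", c("x", "y", "z"))]),
      baro = df$baro[i], temps = as.numeric(df[i, paste0("temp_", 1:4)]),
      battery = df$battery[i], rtc = ts, counter = df$counter[i])
  })
}

#' Convert a session between .n3s and CSV
#'
#' Direction is inferred from file extensions. CSV rows carry an ISO-8601
#' timestamp plus all 21 channels; conversion is lossless because sensor
#' channels are stored in single precision in both representations.
#'
#' @param infile input .n3s or .csv path.
#' @param outfile output path with the opposite extension.
#' @param rate_hz sampling rate recorded when writing .n3s from CSV.
#' @return `outfile`, invisibly.
#' @export
convert_session <- function(infile, outfile, rate_hz = 50L) {
  ext <- function(p) tolower(tools::file_ext(p))
  if (ext(infile) == "n3s" && ext(outfile) == "csv") {
    ses <- read_session(infile)
    write.csv(frames_to_df(ses$frames), outfile, row.names = FALSE)
  } else if (ext(infile) == "csv" && ext(outfile) == "n3s") {
    df <- read.csv(infile, stringsAsFactors = FALSE)
    write_session(df_to_frames(df), outfile, rate_hz = rate_hz)
  } else {
    stop("convert_session handles .n3s <-> .csv only", call. = FALSE)
  }
  invisible(outfile)
}

#' @export
print.frame_layout <- function(x, ...) {
  cat(sprintf("<frame_layout> %d fields, payload %d bytes in %d-byte frames\n",
              length(x$fields), payload_size(x), x$frame_bytes))
  for (f in x$fields) {
    cat(sprintf("  %-8s %d x %dB  %s\n", f$name, f$channels,
                f$bytes_per_channel, f$encoding))
  }
  invisible(x)
}
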