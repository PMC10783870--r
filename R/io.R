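#' Read a WAV audio file
#'
#' Minimal RIFF/WAVE reader for PCM 16/24-bit and 32/64-bit float files.
#' Returns a mono [time_series()] scaled to `[-1, 1]`; stereo (or more
#' channels) is downmixed by averaging, with a warning. Compressed formats
#' are rejected.
#'
#' @param path Path to a `.wav` file.
#' @return A single-component `time_series` at the file's sampling rate.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1L, 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(fmt_raw[1:2], "integer", 1L, 2L, endian = "little"),
        n_channels = readBin(fmt_raw[3:4], "integer", 1L, 2L, endian = "little"),
        sample_rate = readBin(fmt_raw[5:8], "integer", 1L, 4L, endian = "little"),
        bits = readBin(fmt_raw[15:16], "integer", 1L, 2L, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("malformed WAV (missing fmt or data chunk): ", path, call. = FALSE)
  }
  # 0xFFFE = extensible; treat sub-format by bit depth
  af <- fmt$audio_format
  if (!(af %in% c(1L, 3L, -2L, 65534L))) {
    stop("unsupported (compressed?) WAV format code ", af, call. = FALSE)
  }
  is_float <- af == 3L || (af != 1L && fmt$bits >= 32L)
  x <- if (is_float && fmt$bits == 32L) {
    readBin(data_raw, "double", length(data_raw) / 4L, 4L, endian = "little")
  } else if (is_float && fmt$bits == 64L) {
    readBin(data_raw, "double", length(data_raw) / 8L, 8L, endian = "little")
  } else if (fmt$bits == 16L) {
    readBin(data_raw, "integer", length(data_raw) / 2L, 2L, signed = TRUE,
            endian = "little") / 32768
  } else if (fmt$bits == 24L) {
    n <- length(data_raw) / 3L
    b <- matrix(as.integer(data_raw), 3L, n)
    v <- b[1L, ] + 256L * b[2L, ] + 65536L * b[3L, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    v / 8388608
  } else {
    stop("unsupported WAV bit depth: ", fmt$bits, call. = FALSE)
  }
  if (fmt$n_channels > 1L) {
    warning("downmixing ", fmt$n_channels, " channels to mono by averaging")
    x <- colMeans(matrix(x, fmt$n_channels))
  }
  time_series(x, time_axis(0, 1 / fmt$sample_rate, length(x)), "audio",
              kind = "scalar")
}

#' Write a mono WAV file
#'
#' Companion writer used for fixtures and round-trip checks; writes 16-bit
#' PCM (default) or 32-bit float.
#'
#' @param ts Single-component [time_series()] with values in `[-1, 1]`.
#' @param path Output path.
#' @param bits 16 (PCM) or 32 (float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(ts, path, bits = 16L) {
  stopifnot(inherits(ts, "time_series"), n_components(ts) == 1L)
  x <- ts$values[1L, ]
  rate <- as.integer(round(sampling_rate(ts)))
  con <- file(path, "wb")
  on.exit(close(con))
  bytes_per <- bits / 8L
  data_size <- length(x) * bytes_per
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(c(if (bits == 32L) 3L else 1L, 1L), con, 2L, endian = "little")
  writeBin(rate, con, 4L, endian = "little")
  writeBin(as.integer(rate * bytes_per), con, 4L, endian = "little")
  writeBin(c(as.integer(bytes_per), as.integer(bits)), con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4L, endian = "little")
  if (bits == 32L) {
    writeBin(x, con, 4L, endian = "little")
  } else {
    writeBin(as.integer(pmax(-32768, pmin(32767, round(x * 32767)))), con, 2L,
             endian = "little")
  }
  invisible(path)
}

#' Read an event table from CSV/TSV
#'
#' Requires an `onset` column (seconds); optional `value` (default 1.0) and
#' `label` columns. Rows are sorted by onset; non-numeric onsets are rejected
#' with the offending row number.
#'
#' @param path Path to a delimited text file; the delimiter is inferred from
#'   the extension (`.tsv` = tab, else comma).
#' @param sep Override the field separator.
#' @return An [event_table()].
#' @export
read_events <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, colClasses = NA)
  if (!"onset" %in% names(df)) {
    stop("event file must have an `onset` column: ", path, call. = FALSE)
  }
  onset <- suppressWarnings(as.numeric(df$onset))
  if (anyNA(onset)) {
    stop("non-numeric onset in row(s): ",
         paste(which(is.na(onset)), collapse = ", "), call. = FALSE)
  }
  value <- if ("value" %in% names(df)) as.numeric(df$value) else rep(1.0, nrow(df))
  label <- if ("label" %in% names(df)) as.character(df$label) else rep("", nrow(df))
  event_table(onset, value, label)
}

container_version <- 1L

#' Serialize objects to a portable JSON container
#'
#' Round-trip serialization for [time_series()], [trf_kernel()], fit results
#' and [cluster_permutation_test()] results, as schema-versioned JSON with
#' full-precision numbers. `read_container()` refuses files written by a
#' different schema version and, when `expect` is given, a mismatching
#' object type.
#'
#' @param obj Object to serialize.
#' @param path Output path (conventionally `.json`).
#' @return `write_container()` returns `path` invisibly; `read_container()`
#'   the reconstructed object.
#' @export
write_container <- function(obj, path) {
  payload <- serialize_obj(obj)
  doc <- list(schema = "trfboost-container", version = container_version,
              type = payload$type, payload = payload$data)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_container
#' @param expect Optional expected type (`"time_series"`, `"trf_kernel"`,
#'   `"trf_fit"`, `"cluster_result"`, `"event_table"`).
#' @export
read_container <- function(path, expect = NULL) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "trfboost-container")) {
    stop("not a trfboost container: ", path, call. = FALSE)
  }
  if (!identical(as.integer(doc$version), container_version)) {
    stop(sprintf("container schema version %s, reader supports %d",
                 doc$version, container_version), call. = FALSE)
  }
  if (!is.null(expect) && !identical(doc$type, expect)) {
    stop(sprintf("container holds a %s, expected a %s", doc$type, expect),
         call. = FALSE)
  }
  deserialize_obj(doc$type, doc$payload)
}

serialize_obj <- function(obj) {
  if (inherits(obj, "time_series")) {
    list(type = "time_series",
         data = list(values = as.vector(obj$values), n_comp = nrow(obj$values),
                     tstart = obj$axis$tstart, tstep = obj$axis$tstep,
                     n_samples = obj$axis$n_samples, labels = obj$labels,
                     kind = obj$kind,
                     band_centers = obj$band_centers))
  } else if (inherits(obj, "trf_kernel")) {
    list(type = "trf_kernel",
         data = list(values = as.vector(obj$values), dim = dim(obj$values),
                     tmin = obj$lag_axis$tstart, tstep = obj$lag_axis$tstep,
                     predictor_labels = obj$predictor_labels,
                     channel_labels = obj$channel_labels,
                     scale_info = obj$scale_info))
  } else if (inherits(obj, "trf_fit")) {
    list(type = "trf_fit",
         data = list(kernel = serialize_obj(obj$kernel)$data,
                     proportion_explained = as.list(obj$proportion_explained),
                     residual_error = as.list(obj$residual_error),
                     cross_validated = obj$cross_validated,
                     history = as.list(obj$history),
                     config = obj$config[setdiff(names(obj$config), "seed")],
                     seed = obj$config$seed,
                     partitions = list(k = obj$partitions$k,
                                       test = obj$partitions$test,
                                       n_samples = obj$partitions$n_samples)))
  } else if (inherits(obj, "cluster_result")) {
    list(type = "cluster_result",
         data = list(t_map = as.vector(obj$t_map),
                     labels = as.vector(obj$cluster_labels),
                     sensors = obj$sensors, times = obj$times,
                     clusters = as.list(obj$clusters),
                     threshold = obj$threshold, alpha = obj$alpha,
                     n_permutations = obj$n_permutations,
                     exhaustive = obj$exhaustive, n_subjects = obj$n_subjects))
  } else if (inherits(obj, "event_table")) {
    list(type = "event_table",
         data = list(onset = obj$onset, value = obj$value, label = obj$label))
  } else {
    stop("no container serialization for class ",
         paste(class(obj), collapse = "/"), call. = FALSE)
  }
}

deserialize_obj <- function(type, d) {
  switch(type,
    time_series = {
      v <- matrix(d$values, nrow = d$n_comp)
      ts <- time_series(v, time_axis(d$tstart, d$tstep, d$n_samples),
                        d$labels, d$kind)
      if (!is.null(d$band_centers)) {
        ts$band_centers <- d$band_centers
        class(ts) <- c("spectrogram", class(ts))
      }
      ts
    },
    trf_kernel = {
      trf_kernel(array(d$values, d$dim), d$tmin, d$tstep,
                 d$predictor_labels, d$channel_labels,
                 scale_info = d$scale_info)
    },
    trf_fit = {
      structure(
        list(kernel = deserialize_obj("trf_kernel", d$kernel),
             proportion_explained = unlist(d$proportion_explained),
             residual_error = unlist(d$residual_error),
             cross_validated = d$cross_validated,
             history = tibble::as_tibble(d$history),
             config = d$config, partitions = d$partitions),
        class = "trf_fit")
    },
    cluster_result = {
      structure(
        list(t_map = stats::setNames(d$t_map, if (is.null(d$times)) d$sensors else NULL),
             cluster_labels = d$labels, sensors = d$sensors, times = d$times,
             clusters = tibble::as_tibble(d$clusters),
             threshold = d$threshold, alpha = d$alpha,
             n_permutations = d$n_permutations, exhaustive = d$exhaustive,
             n_subjects = d$n_subjects),
        class = "cluster_result")
    },
    event_table = event_table(d$onset, d$value, d$label),
    stop("unknown container type: ", type, call. = FALSE)
  )
}

#' Write a run manifest
#'
#' Records what a pipeline invocation did: command, configuration, seeds,
#' input digests, package version and timestamp. The command-line interface
#' writes one next to each output.
#'
#' @param path Output path for the manifest JSON.
#' @param command Command name.
#' @param config List of configuration values.
#' @param inputs Character vector of input file paths (digested with MD5).
#' @param seed Seed used.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, config = list(), inputs = character(),
                           seed = NULL) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  doc <- list(command = command, config = config, seed = seed,
              input_digests = digests,
              package_version = as.character(utils::packageVersion("trfboost")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
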