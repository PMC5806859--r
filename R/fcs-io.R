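#' @title Minimal FCS list-mode I/O for WDF event data
#' @description
#' Reads FCS 2.0/3.0/3.1 list-mode files (integer, float, or double data)
#' and writes FCS 3.1 float list-mode files. Only the features needed to
#' carry four-signal WDF event data are supported; anything else (analysis
#' segments, chained data sets, mixed integer widths) is rejected loudly
#' rather than guessed.
#' @name fcs_io
NULL

#' Resolve FCS parameter names to the four WDF signals
#'
#' Vendor exports name the WDF parameters inconsistently, so channels are
#' resolved by case-insensitive name patterns: pulse width first (`FSC-W`,
#' `FSC_W`, or anything containing "width"), then forward scatter (`FSC` /
#' "forward"), side scatter (`SSC` / "side scatter"), and side fluorescence
#' (`SFL` / "fluor"). An explicit `mapping` always overrides the patterns.
#'
#' @param param_names character vector of the file's parameter names, in
#'   column order.
#' @param mapping optional named list/vector with entries `fsc`, `ssc`,
#'   `sfl`, `fscw`, each an exact parameter name or a 1-based column index.
#' @return a `channel_assignment`: list with integer indices `fsc`, `ssc`,
#'   `sfl`, `fscw` and the original `source_names`.
#' @export
resolve_channels <- function(param_names, mapping = NULL) {
  param_names <- as.character(param_names)
  idx <- integer(0)

  if (!is.null(mapping)) {
    mapping <- as.list(mapping)
    missing <- setdiff(WDF_SIGNALS, names(mapping))
    if (length(missing)) {
      stop("channel mapping must name all of fsc, ssc, sfl, fscw; missing: ",
           paste(missing, collapse = ", "))
    }
    idx <- vapply(WDF_SIGNALS, function(sig) {
      m <- mapping[[sig]]
      if (is.numeric(m)) {
        i <- as.integer(m)
      } else {
        i <- match(as.character(m), param_names)
      }
      if (is.na(i) || i < 1L || i > length(param_names)) {
        stop("channel mapping for '", sig, "' (", m,
             ") does not match any parameter; available: ",
             paste(param_names, collapse = ", "))
      }
      i
    }, integer(1))
  } else {
    lower <- tolower(param_names)
    is_width <- grepl("fsc-w|fsc_w|width", lower)
    pick <- function(sig, candidates) {
      hits <- which(candidates)
      if (length(hits) == 0L) {
        stop("cannot resolve ", sig, " channel by name; available parameters: ",
             paste(param_names, collapse = ", "),
             " (supply an explicit mapping)")
      }
      if (length(hits) > 1L) {
        stop("ambiguous ", sig, " channel: ",
             paste(param_names[hits], collapse = ", "),
             " (supply an explicit mapping)")
      }
      hits
    }
    fscw <- pick("fscw", is_width)
    fsc  <- pick("fsc", grepl("fsc|forward", lower) & !is_width)
    ssc  <- pick("ssc", grepl("ssc|side.?scatter", lower))
    sfl  <- pick("sfl", grepl("sfl|fluor", lower))
    idx <- c(fsc = fsc, ssc = ssc, sfl = sfl, fscw = fscw)
  }

  if (anyDuplicated(idx)) {
    stop("channel assignment is not distinct: ",
         paste(sprintf("%s=%d", WDF_SIGNALS, idx), collapse = ", "))
  }
  structure(
    list(fsc = idx[["fsc"]], ssc = idx[["ssc"]], sfl = idx[["sfl"]],
         fscw = idx[["fscw"]], source_names = param_names),
    class = "channel_assignment"
  )
}

#' Read a channel-mapping override from JSON
#'
#' @param path JSON file holding an object `{"fsc": ..., "ssc": ...,
#'   "sfl": ..., "fscw": ...}` whose values are parameter names or 1-based
#'   column indices.
#' @return a named list usable as the `mapping` argument of [read_fcs()].
#' @export
read_channel_mapping <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Read an FCS list-mode file into an event cloud
#'
#' Supports FCS versions 2.0, 3.0 and 3.1 with list-mode (`$MODE L`) data in
#' integer, float, or double format and either byte order. Chained data sets
#' (`$NEXTDATA` != 0) and non-list modes are rejected.
#'
#' @param path path to the FCS file.
#' @param mapping optional explicit channel mapping (see
#'   [resolve_channels()]).
#' @return an [event_cloud()] with one event per data row, signals in native
#'   channel units, `channel_range` taken from the `$PnR` keywords, and all
#'   TEXT keywords in `meta$keywords`.
#' @export
read_fcs <- function(path, mapping = NULL) {
  if (!file.exists(path)) stop("FCS file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  size <- file.info(path)$size

  header <- readChar(con, 58L, useBytes = TRUE)
  if (nchar(header, type = "bytes") < 58L) {
    stop("malformed FCS HEADER segment: file shorter than 58 bytes")
  }
  version <- substr(header, 1L, 6L)
  if (!version %in% c("FCS2.0", "FCS3.0", "FCS3.1")) {
    stop("malformed FCS HEADER segment: unsupported version '", version, "'")
  }
  offs <- suppressWarnings(as.numeric(vapply(0:5, function(i) {
    trimws(substr(header, 11L + 8L * i, 18L + 8L * i))
  }, character(1))))
  if (any(is.na(offs[1:2])) || offs[1] <= 0 || offs[2] < offs[1]) {
    stop("malformed FCS HEADER segment: invalid TEXT offsets")
  }

  seek(con, offs[1])
  text_raw <- readChar(con, offs[2] - offs[1] + 1L, useBytes = TRUE)
  delim <- substr(text_raw, 1L, 1L)
  parts <- strsplit(substr(text_raw, 2L, nchar(text_raw)), delim,
                    fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1L) parts <- c(parts, "")
  kw <- trimws(parts[seq(2L, length(parts), by = 2L)])
  names(kw) <- toupper(trimws(parts[seq(1L, length(parts), by = 2L)]))

  getkw <- function(key, default = NULL) {
    v <- kw[[key]] %||% default
    if (is.null(v)) stop("malformed FCS TEXT segment: missing ", key)
    v
  }

  if (toupper(getkw("$MODE")) != "L") {
    stop("only list-mode ($MODE L) FCS data is supported")
  }
  if (as.numeric(getkw("$NEXTDATA", "0")) != 0) {
    stop("chained FCS data sets ($NEXTDATA != 0) are not supported")
  }

  npar <- as.integer(getkw("$PAR"))
  ntot <- as.integer(getkw("$TOT"))
  dtype <- toupper(getkw("$DATATYPE"))
  byteord <- getkw("$BYTEORD")
  endian <- if (startsWith(byteord, "1")) "little" else "big"

  data_begin <- as.numeric(kw[["$BEGINDATA"]] %||% offs[3])
  data_end <- as.numeric(kw[["$ENDDATA"]] %||% offs[4])
  if (ntot > 0 && (is.na(data_begin) || data_begin <= 0)) {
    stop("malformed FCS DATA segment: no data offsets in HEADER or TEXT")
  }

  bits <- vapply(seq_len(npar), function(i) {
    as.integer(getkw(sprintf("$P%dB", i)))
  }, integer(1))
  pnames <- vapply(seq_len(npar), function(i) {
    getkw(sprintf("$P%dN", i), sprintf("P%d", i))
  }, character(1))
  ranges <- vapply(seq_len(npar), function(i) {
    as.numeric(getkw(sprintf("$P%dR", i), "262144"))
  }, numeric(1))

  nvals <- npar * ntot
  if (nvals > 0) {
    if (length(unique(bits)) != 1L) {
      stop("mixed per-parameter bit widths are not supported")
    }
    bytes <- bits[1] %/% 8L
    if (data_end > size) stop("malformed FCS DATA segment: extends past EOF")
    seek(con, data_begin)
    vals <- switch(dtype,
      F = readBin(con, "double", n = nvals, size = 4L, endian = endian),
      D = readBin(con, "double", n = nvals, size = 8L, endian = endian),
      I = {
        if (!bytes %in% c(1L, 2L, 4L)) {
          stop("unsupported integer width: ", bits[1], " bits")
        }
        if (bytes == 4L) {
          v <- readBin(con, "integer", n = nvals, size = 4L, endian = endian)
          v <- as.numeric(v)
          v[v < 0] <- v[v < 0] + 2^32   # recover unsigned 32-bit values
          v
        } else {
          as.numeric(readBin(con, "integer", n = nvals, size = bytes,
                             signed = FALSE, endian = endian))
        }
      },
      stop("unsupported $DATATYPE '", dtype, "' (only I, F, D)")
    )
    if (length(vals) != nvals) {
      stop("malformed FCS DATA segment: expected ", nvals, " values, read ",
           length(vals))
    }
    mat <- matrix(vals, ncol = npar, byrow = TRUE)
  } else {
    mat <- matrix(numeric(0), ncol = max(npar, 1L))
  }

  assign4 <- resolve_channels(pnames, mapping = mapping)
  sel <- c(assign4$fsc, assign4$ssc, assign4$sfl, assign4$fscw)
  ev <- mat[, sel, drop = FALSE]
  colnames(ev) <- WDF_SIGNALS
  event_cloud(
    ev,
    channel_range = stats::setNames(ranges[sel], WDF_SIGNALS),
    meta = list(keywords = as.list(kw), version = version,
                assignment = assign4)
  )
}

#' Write an event cloud as a minimal FCS 3.1 file
#'
#' Emits single-precision float list-mode data, little-endian, with
#' parameters named `FSC`, `SSC`, `SFL`, `FSC-W` and `$PnR` set from the
#' cloud's channel ranges. [read_fcs()] round-trips the result within float
#' precision.
#'
#' @param cloud an [event_cloud()] (empty clouds are legal).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(cloud, path) {
  stopifnot(inherits(cloud, "event_cloud"))
  n <- n_events(cloud)
  pnames <- c("FSC", "SSC", "SFL", "FSC-W")
  delim <- "/"

  kw <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BEGINDATA" = "%BD%", "$ENDDATA" = "%ED%",
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0", "$PAR" = "4", "$TOT" = as.character(n)
  )
  for (i in 1:4) {
    kw[sprintf("$P%dN", i)] <- pnames[i]
    kw[sprintf("$P%dB", i)] <- "32"
    kw[sprintf("$P%dE", i)] <- "0,0"
    kw[sprintf("$P%dR", i)] <- format(cloud$channel_range[i],
                                      scientific = FALSE, trim = TRUE)
  }

  # Data offsets appear inside TEXT, so reserve fixed-width numeric slots
  # before measuring the segment length.
  build_text <- function(bd, ed) {
    k <- kw
    k["$BEGINDATA"] <- sprintf("%010d", bd)
    k["$ENDDATA"] <- sprintf("%010d", ed)
    paste0(delim, paste0(names(k), delim, unname(k), delim, collapse = ""))
  }
  text_begin <- 58L
  text_len <- nchar(build_text(0L, 0L), type = "bytes")
  text_end <- text_begin + text_len - 1L
  data_begin <- if (n > 0) text_end + 1L else 0L
  data_end <- if (n > 0) data_begin + 4L * 4L * n - 1L else 0L
  text <- build_text(data_begin, data_end)

  hdr_off <- function(x) formatC(x, width = 8L, flag = " ")
  header <- paste0(
    "FCS3.1    ",
    hdr_off(text_begin), hdr_off(text_end),
    hdr_off(data_begin), hdr_off(data_end),
    hdr_off(0L), hdr_off(0L)
  )

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL, useBytes = TRUE)
  writeChar(text, con, eos = NULL, useBytes = TRUE)
  if (n > 0) {
    writeBin(as.numeric(t(cloud$events)), con, size = 4L, endian = "little")
  }
  invisible(path)
}
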