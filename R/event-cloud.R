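#' @title WDF event clouds
#' @description
#' An `event_cloud` holds one row per cell event with the four WDF-channel
#' signals: forward scatter (`fsc`, cell volume), side scatter (`ssc`,
#' internal structure), side fluorescence (`sfl`, nucleic-acid content), and
#' forward-scatter pulse width (`fscw`, "time of flight", elevated for
#' doublets and clumps). Signals are stored in native channel units together
#' with the per-channel maximum, so gating can normalize to the unit square
#' on demand.
#' @name event_cloud
NULL

WDF_SIGNALS <- c("fsc", "ssc", "sfl", "fscw")

#' Construct an event cloud
#'
#' @param events numeric matrix (or coercible) with one row per event and
#'   four columns; columns are taken in the order `fsc, ssc, sfl, fscw`
#'   unless already named.
#' @param channel_range named numeric vector of per-channel maxima (one per
#'   signal); values must be positive.
#' @param meta list of free-form acquisition metadata.
#' @param labels optional character vector of per-event population tags
#'   (used by the simulator for ground truth).
#' @return an object of class `event_cloud`.
#' @export
event_cloud <- function(events, channel_range, meta = list(), labels = NULL) {
  events <- as.matrix(events)
  if (length(events) == 0L) {
    events <- matrix(numeric(0), ncol = 4L)
  }
  if (ncol(events) != 4L) {
    stop("events must have exactly four signal columns (fsc, ssc, sfl, fscw)")
  }
  if (!is.null(colnames(events))) {
    if (!setequal(colnames(events), WDF_SIGNALS)) {
      stop("event column names must be ", paste(WDF_SIGNALS, collapse = ", "))
    }
    events <- events[, WDF_SIGNALS, drop = FALSE]
  } else {
    colnames(events) <- WDF_SIGNALS
  }
  storage.mode(events) <- "double"
  channel_range <- as_channel_range(channel_range)
  if (nrow(events) > 0L) {
    if (any(!is.finite(events))) stop("event signals must be finite")
    if (any(events < 0)) stop("event signals must be non-negative")
    over <- sweep(events, 2L, channel_range, ">")
    if (any(over)) {
      stop("event signals exceed channel_range in channel(s): ",
           paste(WDF_SIGNALS[apply(over, 2L, any)], collapse = ", "))
    }
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(events)) {
      stop("labels must carry exactly one tag per event")
    }
  }
  structure(
    list(events = events, channel_range = channel_range, meta = meta,
         labels = labels),
    class = "event_cloud"
  )
}

as_channel_range <- function(channel_range) {
  channel_range <- unlist(channel_range)
  if (length(channel_range) == 1L) {
    channel_range <- rep(channel_range, 4L)
  }
  if (length(channel_range) != 4L) {
    stop("channel_range needs one maximum per WDF signal")
  }
  if (is.null(names(channel_range))) {
    names(channel_range) <- WDF_SIGNALS
  }
  channel_range <- channel_range[WDF_SIGNALS]
  if (any(is.na(channel_range)) || any(channel_range <= 0)) {
    stop("channel_range must be positive for all four signals")
  }
  channel_range
}

#' Number of events in a cloud
#' @param cloud an `event_cloud`.
#' @return integer event count.
#' @export
n_events <- function(cloud) {
  stopifnot(inherits(cloud, "event_cloud"))
  nrow(cloud$events)
}

#' @export
print.event_cloud <- function(x, ...) {
  cat(sprintf("<event_cloud: %d events, 4 WDF signals>\n", n_events(x)))
  cat("  channel_range:",
      paste(sprintf("%s=%g", WDF_SIGNALS, x$channel_range), collapse = " "),
      "\n")
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("  labels:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = " "),
        "\n")
  }
  invisible(x)
}

is_normalized <- function(cloud) {
  all(cloud$channel_range == 1)
}
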