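#' @title Two-rule malignancy gating on the WDF scattergram
#' @description
#' The gating model works in normalized signal space (each channel divided by
#' its range, so every event lives in the unit hypercube). Events are first
#' classified into debris, PMN (polymorphonuclear: neutrophils +
#' eosinophils), MN (mononuclear: lymphocytes + monocytes), or HF-BF
#' (high-fluorescence body-fluid cells: mesothelial cells, macrophages and
#' malignant cells, above the fluorescence cutoff and excluded from the WBC
#' count). Two gates then screen the HF-BF events for malignancy:
#'
#' * **Rule 1 (Area 1)**, on the (pulse width, forward scatter) plane,
#'   captures aggregated cell clumps: long "time of flight" and high
#'   fluorescence relative to WBCs.
#' * **Rule 2 (Area 2)**, on the (forward scatter, fluorescence) plane,
#'   captures isolated malignant cells with fluorescence intermediate
#'   between WBCs and typical HF-BF cells, and lower forward scatter than
#'   macrophages.
#'
#' A sample is called malignant when at least one rule fires.
#' @name gating
NULL

#' Define a polygonal gate region
#'
#' @param plane character pair naming the x and y signals (from
#'   `fsc, ssc, sfl, fscw`).
#' @param vertices two-column numeric matrix of polygon vertices in
#'   normalized units, in order; the polygon is closed implicitly. Must be
#'   simple (non-self-intersecting) with at least 3 vertices inside the unit
#'   square.
#' @return a `gate_region` object.
#' @export
gate_region <- function(plane, vertices) {
  plane <- as.character(plane)
  if (length(plane) != 2L || !all(plane %in% WDF_SIGNALS)) {
    stop("gate plane must name two WDF signals (fsc, ssc, sfl, fscw)")
  }
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 3L) {
    stop("a gate polygon needs at least 3 (x, y) vertices")
  }
  storage.mode(vertices) <- "double"
  if (any(!is.finite(vertices)) || any(vertices < 0) || any(vertices > 1)) {
    stop("gate vertices must lie within the normalized unit square")
  }
  if (polygon_area(vertices) == 0) {
    stop("degenerate gate polygon: zero area")
  }
  if (self_intersects(vertices)) {
    stop("gate polygon must be simple (non-self-intersecting)")
  }
  structure(list(plane = plane, vertices = vertices), class = "gate_region")
}

#' Axis-aligned rectangular gate
#'
#' @param plane as in [gate_region()].
#' @param xlim,ylim numeric length-2 ranges on the x and y signals.
#' @return a `gate_region`.
#' @export
rect_gate <- function(plane, xlim, ylim) {
  gate_region(plane, cbind(
    c(xlim[1], xlim[2], xlim[2], xlim[1]),
    c(ylim[1], ylim[1], ylim[2], ylim[2])
  ))
}

polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  j <- c(nrow(v), seq_len(nrow(v) - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

seg_intersects <- function(p1, p2, q1, q2) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(q1, q2, p1); d2 <- d(q1, q2, p2)
  d3 <- d(p1, p2, q1); d4 <- d(p1, p2, q2)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

self_intersects <- function(v) {
  n <- nrow(v)
  if (n <= 3L) return(FALSE)
  nxt <- c(seq_len(n)[-1], 1L)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      # skip adjacent edges (share a vertex)
      if (j == i || nxt[i] == j || nxt[j] == i) next
      if (seg_intersects(v[i, ], v[nxt[i], ], v[j, ], v[nxt[j], ])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Gating configuration: cutoffs, gate geometry and rule thresholds
#'
#' The instrument vendor's numeric cutoffs are proprietary; these defaults
#' are declared conventions in normalized units, calibrated so the
#' simulator's canonical populations land where the algorithm expects them.
#' Every value can be overridden, or loaded from JSON/YAML with
#' [read_gating_config()].
#'
#' @param hfbf_sfl_cutoff fluorescence threshold separating WBC (below) from
#'   HF-BF (at or above); normalized units.
#' @param debris_fsc_floor forward-scatter floor below which events are
#'   debris.
#' @param pmn_mn_boundary [gate_region()] on (ssc, sfl): WBC events inside
#'   are PMN, outside MN.
#' @param area1 [gate_region()] on (fscw, fsc): the Rule 1 clump gate.
#' @param area2 [gate_region()] on (fsc, sfl): the Rule 2 isolated-cell gate.
#' @param rule_min_events minimum gated-event count for a rule to fire.
#' @param rule_min_conc minimum gated-cell concentration (cells/uL) for a
#'   rule to fire.
#' @param volume_factor analyzed sample volume (uL) converting event counts
#'   to concentrations.
#' @return a `gating_config` object.
#' @export
gating_config <- function(hfbf_sfl_cutoff = 0.62,
                          debris_fsc_floor = 0.02,
                          pmn_mn_boundary = rect_gate(c("ssc", "sfl"),
                                                      c(0.35, 1.0),
                                                      c(0.0, 0.62)),
                          area1 = rect_gate(c("fscw", "fsc"),
                                            c(0.45, 1.0), c(0.35, 1.0)),
                          area2 = rect_gate(c("fsc", "sfl"),
                                            c(0.15, 0.55), c(0.45, 0.75)),
                          rule_min_events = 10L,
                          rule_min_conc = 10,
                          volume_factor = 5) {
  if (!is.numeric(hfbf_sfl_cutoff) || hfbf_sfl_cutoff <= 0 ||
      hfbf_sfl_cutoff >= 1) {
    stop("hfbf_sfl_cutoff must lie strictly between 0 and 1")
  }
  if (debris_fsc_floor < 0 || debris_fsc_floor >= 1) {
    stop("debris_fsc_floor must lie in [0, 1)")
  }
  if (rule_min_events < 1L) stop("rule_min_events must be >= 1")
  if (rule_min_conc < 0) stop("rule_min_conc must be non-negative")
  if (volume_factor <= 0) stop("volume_factor must be positive")
  stopifnot(inherits(pmn_mn_boundary, "gate_region"),
            inherits(area1, "gate_region"),
            inherits(area2, "gate_region"))
  if (!identical(area1$plane, c("fscw", "fsc"))) {
    stop("area1 must be defined on the (fscw, fsc) plane")
  }
  if (!identical(area2$plane, c("fsc", "sfl"))) {
    stop("area2 must be defined on the (fsc, sfl) plane")
  }
  structure(
    list(hfbf_sfl_cutoff = hfbf_sfl_cutoff,
         debris_fsc_floor = debris_fsc_floor,
         pmn_mn_boundary = pmn_mn_boundary,
         area1 = area1, area2 = area2,
         rule_min_events = as.integer(rule_min_events),
         rule_min_conc = rule_min_conc,
         volume_factor = volume_factor),
    class = "gating_config"
  )
}

#' Serialize / load a gating configuration
#'
#' JSON (default) or YAML, chosen by file extension. Gate polygons are
#' stored as vertex lists.
#'
#' @param config a [gating_config()].
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @return `read_gating_config` returns a `gating_config`;
#'   `write_gating_config` returns `path` invisibly.
#' @export
write_gating_config <- function(config, path) {
  stopifnot(inherits(config, "gating_config"))
  gate_to_list <- function(g) {
    list(plane = g$plane, vertices = unname(apply(g$vertices, 1L, as.list,
                                                  simplify = FALSE)))
  }
  x <- list(
    hfbf_sfl_cutoff = config$hfbf_sfl_cutoff,
    debris_fsc_floor = config$debris_fsc_floor,
    pmn_mn_boundary = gate_to_list(config$pmn_mn_boundary),
    area1 = gate_to_list(config$area1),
    area2 = gate_to_list(config$area2),
    rule_min_events = config$rule_min_events,
    rule_min_conc = config$rule_min_conc,
    volume_factor = config$volume_factor
  )
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_gating_config
#' @export
read_gating_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  gate_from_list <- function(g) {
    v <- do.call(rbind, lapply(g$vertices, function(p) unlist(p)))
    gate_region(unlist(g$plane), v)
  }
  gating_config(
    hfbf_sfl_cutoff = x$hfbf_sfl_cutoff,
    debris_fsc_floor = x$debris_fsc_floor,
    pmn_mn_boundary = gate_from_list(x$pmn_mn_boundary),
    area1 = gate_from_list(x$area1),
    area2 = gate_from_list(x$area2),
    rule_min_events = x$rule_min_events,
    rule_min_conc = x$rule_min_conc,
    volume_factor = x$volume_factor
  )
}

#' Normalize an event cloud to the unit hypercube
#'
#' Divides every signal by its channel range. Idempotent: a normalized cloud
#' (all ranges 1) is returned unchanged.
#'
#' @param cloud an [event_cloud()].
#' @return an `event_cloud` with all channel ranges equal to 1.
#' @export
normalize_events <- function(cloud) {
  stopifnot(inherits(cloud, "event_cloud"))
  if (any(cloud$channel_range <= 0)) {
    stop("cannot normalize: non-positive channel range")
  }
  if (is_normalized(cloud)) return(cloud)
  ev <- sweep(cloud$events, 2L, cloud$channel_range, "/")
  event_cloud(ev, channel_range = rep(1, 4L), meta = cloud$meta,
              labels = cloud$labels)
}

#' Point-in-gate membership test
#'
#' Even-odd (crossing-number) rule with the boundary counted as inside —
#' events sitting exactly on a gate edge are gated in, consistent with the
#' screening orientation of the algorithm.
#'
#' @param points numeric matrix with columns (x, y) in normalized units, or
#'   a length-2 vector for a single point.
#' @param gate a [gate_region()].
#' @return logical vector, one entry per point.
#' @export
point_in_gate <- function(points, gate) {
  stopifnot(inherits(gate, "gate_region"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 2L)
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("points must be (x, y) pairs")
  v <- gate$vertices
  n <- nrow(v)
  px <- points[, 1]; py <- points[, 2]
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]
    xj <- v[j, 1]; yj <- v[j, 2]
    # boundary: point collinear with edge and within its bounding box
    cross <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    on_seg <- cross == 0 &
      px >= pmin(xi, xj) & px <= pmax(xi, xj) &
      py >= pmin(yi, yj) & py <= pmax(yi, yj)
    on_edge <- on_edge | on_seg
    # crossing-number parity flip
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Classify normalized events into debris / PMN / MN / HF-BF
#'
#' Labels are exhaustive and mutually exclusive: an event is debris when its
#' forward scatter falls below the debris floor; otherwise HF-BF when its
#' fluorescence reaches the cutoff (the boundary belongs to HF-BF);
#' otherwise PMN when inside the PMN/MN boundary gate on the (ssc, sfl)
#' plane, else MN.
#'
#' @param cloud a normalized [event_cloud()] (see [normalize_events()]).
#' @param config a [gating_config()].
#' @return character vector of labels in
#'   `c("debris", "PMN", "MN", "HFBF")`, one per event.
#' @export
classify_events <- function(cloud, config = gating_config()) {
  stopifnot(inherits(cloud, "event_cloud"), inherits(config, "gating_config"))
  if (!is_normalized(cloud) || (n_events(cloud) > 0 && max(cloud$events) > 1)) {
    stop("cloud must be normalized to [0, 1] (use normalize_events)")
  }
  n <- n_events(cloud)
  if (n == 0L) return(character(0))
  ev <- cloud$events
  labels <- rep("MN", n)
  pmn <- point_in_gate(ev[, c("ssc", "sfl"), drop = FALSE],
                       config$pmn_mn_boundary)
  labels[pmn] <- "PMN"
  labels[ev[, "sfl"] >= config$hfbf_sfl_cutoff] <- "HFBF"
  labels[ev[, "fsc"] < config$debris_fsc_floor] <- "debris"
  labels
}

#' Count Rule 1 / Rule 2 gated events
#'
#' Rule 1 counts HF-BF-labeled events inside Area 1 on the (fscw, fsc)
#' plane; Rule 2 counts HF-BF-labeled events inside Area 2 on the
#' (fsc, sfl) plane. An event may count toward both rules; debris and WBC
#' events never count.
#'
#' @param cloud a normalized [event_cloud()].
#' @param labels per-event labels from [classify_events()].
#' @param config a [gating_config()].
#' @return named integer vector `c(rule1_events, rule2_events)`.
#' @export
apply_rule_gates <- function(cloud, labels, config = gating_config()) {
  stopifnot(inherits(cloud, "event_cloud"))
  if (length(labels) != n_events(cloud)) {
    stop("labels must align with the event cloud")
  }
  hf <- labels == "HFBF"
  ev <- cloud$events
  r1 <- sum(point_in_gate(ev[hf, c("fscw", "fsc"), drop = FALSE],
                          config$area1))
  r2 <- sum(point_in_gate(ev[hf, c("fsc", "sfl"), drop = FALSE],
                          config$area2))
  c(rule1_events = as.integer(r1), rule2_events = as.integer(r2))
}

#' Derive population counts from event labels
#'
#' Converts label counts to concentrations through the analyzed volume and
#' computes the derived quantities: TNC = WBC + HF-BF#, WBC = PMN + MN, and
#' HF-BF% = 100 x HF-BF# / WBC (reported to one decimal, half away from
#' zero; may exceed 100). When the WBC count is zero HF-BF% is undefined
#' and reported as `NA`, never an error.
#'
#' @param labels per-event labels from [classify_events()].
#' @param rule1_events,rule2_events gated-event counts from
#'   [apply_rule_gates()].
#' @param config a [gating_config()] supplying `volume_factor`.
#' @return a `population_counts` list with fields `wbc_count`, `pmn_count`,
#'   `mn_count`, `hfbf_count`, `hfbf_percent`, `tnc` (all cells/uL except
#'   the percentage), and the two gated-event counts.
#' @export
compute_counts <- function(labels, rule1_events, rule2_events,
                           config = gating_config()) {
  vol <- config$volume_factor
  if (vol <= 0) stop("volume_factor must be positive")
  pmn <- sum(labels == "PMN") / vol
  mn <- sum(labels == "MN") / vol
  hfbf <- sum(labels == "HFBF") / vol
  wbc <- pmn + mn
  pct <- if (wbc > 0) round_half_up(100 * hfbf / wbc, 1) else NA_real_
  structure(
    list(wbc_count = wbc, pmn_count = pmn, mn_count = mn,
         hfbf_count = hfbf, hfbf_percent = pct, tnc = wbc + hfbf,
         rule1_events = as.integer(rule1_events),
         rule2_events = as.integer(rule2_events)),
    class = "population_counts"
  )
}

#' Make the per-sample malignancy call
#'
#' A rule is positive when its gated-event count reaches `rule_min_events`
#' and the corresponding gated-cell concentration reaches `rule_min_conc`;
#' the sample is called malignant when at least one rule is positive.
#'
#' @param counts a `population_counts` from [compute_counts()].
#' @param config a [gating_config()].
#' @return a `sample_result` list: `counts`, `rule1_positive`,
#'   `rule2_positive`, `malignant_call`.
#' @export
call_sample <- function(counts, config = gating_config()) {
  stopifnot(inherits(counts, "population_counts"))
  rule_pos <- function(nev) {
    nev >= config$rule_min_events &&
      nev / config$volume_factor >= config$rule_min_conc
  }
  r1 <- rule_pos(counts$rule1_events)
  r2 <- rule_pos(counts$rule2_events)
  structure(
    list(counts = counts, rule1_positive = r1, rule2_positive = r2,
         malignant_call = r1 || r2),
    class = "sample_result"
  )
}

#' Gate one sample end to end
#'
#' Convenience pipeline: normalize, classify, apply the rule gates, count,
#' and call.
#'
#' @param cloud an [event_cloud()] in native channel units (or already
#'   normalized).
#' @param config a [gating_config()].
#' @return a `sample_result` (see [call_sample()]).
#' @export
gate_sample <- function(cloud, config = gating_config()) {
  norm <- normalize_events(cloud)
  labels <- classify_events(norm, config)
  gates <- apply_rule_gates(norm, labels, config)
  counts <- compute_counts(labels, gates[["rule1_events"]],
                           gates[["rule2_events"]], config)
  call_sample(counts, config)
}

#' @export
print.sample_result <- function(x, ...) {
  c0 <- x$counts
  cat("<sample_result>\n")
  cat(sprintf("  TNC %.1f /uL = WBC %.1f + HF-BF# %.1f; HF-BF%% %s\n",
              c0$tnc, c0$wbc_count, c0$hfbf_count,
              ifelse(is.na(c0$hfbf_percent), "undefined",
                     format(c0$hfbf_percent))))
  cat(sprintf("  Rule 1: %d events (%s); Rule 2: %d events (%s)\n",
              c0$rule1_events, ifelse(x$rule1_positive, "+", "-"),
              c0$rule2_events, ifelse(x$rule2_positive, "+", "-")))
  cat(sprintf("  malignant call: %s\n",
              ifelse(x$malignant_call, "POSITIVE", "negative")))
  invisible(x)
}
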