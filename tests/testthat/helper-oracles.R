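# Independent oracles and fixture builders used across the suite.

# Brute-force ray caster, written as explicit segment/ray parameter
# intersection (a different formulation from the package's crossing-number
# parity loop). Boundary points are NOT guaranteed consistent here; callers
# use random points, which avoid edges almost surely.
oracle_point_in_poly <- function(points, verts) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2L)
  n <- nrow(verts)
  vapply(seq_len(nrow(points)), function(i) {
    px <- points[i, 1]; py <- points[i, 2]
    hits <- 0L
    for (e in seq_len(n)) {
      a <- verts[e, ]
      b <- verts[if (e == n) 1L else e + 1L, ]
      if ((a[2] <= py && b[2] > py) || (b[2] <= py && a[2] > py)) {
        t <- (py - a[2]) / (b[2] - a[2])
        x_at <- a[1] + t * (b[1] - a[1])
        if (x_at > px) hits <- hits + 1L
      }
    }
    hits %% 2L == 1L
  }, logical(1))
}

# Random simple (star-shaped) polygon inside the unit square: one vertex
# per angular sector around an interior center, so edges cannot cross.
random_convex_polygon <- function(n_vertices, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sector <- 2 * pi / n_vertices
  ang <- sector * (seq_len(n_vertices) - 1L) +
    stats::runif(n_vertices, 0.05 * sector, 0.95 * sector)
  r <- stats::runif(n_vertices, 0.15, 0.4)
  cx <- stats::runif(1, 0.4, 0.6); cy <- stats::runif(1, 0.4, 0.6)
  cbind(pmin(pmax(cx + r * cos(ang), 0), 1),
        pmin(pmax(cy + r * sin(ang), 0), 1))
}

# Mann-Whitney exact p by a pairwise-counting enumeration: for every
# assignment of the pooled values to group 1, U is recomputed by direct
# pair comparisons (not via the midrank-sum identity the package uses).
oracle_mwu_exact <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); N <- length(pooled)
  u_pairs <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_pairs(x, y)
  mu <- n1 * (N - n1) / 2
  combs <- utils::combn(N, n1)
  u_all <- apply(combs, 2L, function(idx) {
    u_pairs(pooled[idx], pooled[-idx])
  })
  list(u = u_obs,
       p = mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9))
}

# Minimal independent FCS 3.1 writer for arbitrary parameter sets, used to
# build files the package's own writer cannot produce (permuted columns,
# integer data).
helper_write_fcs <- function(mat, param_names, path, ranges = NULL) {
  npar <- ncol(mat); n <- nrow(mat)
  if (is.null(ranges)) ranges <- rep(1024, npar)
  kw <- c("$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
          "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
          "$BEGINDATA" = "%BD%", "$ENDDATA" = "%ED%",
          "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
          "$NEXTDATA" = "0", "$PAR" = as.character(npar),
          "$TOT" = as.character(n))
  for (i in seq_len(npar)) {
    kw[sprintf("$P%dN", i)] <- param_names[i]
    kw[sprintf("$P%dB", i)] <- "32"
    kw[sprintf("$P%dE", i)] <- "0,0"
    kw[sprintf("$P%dR", i)] <- as.character(ranges[i])
  }
  build <- function(bd, ed) {
    k <- kw
    k["$BEGINDATA"] <- sprintf("%010d", bd)
    k["$ENDDATA"] <- sprintf("%010d", ed)
    paste0("/", paste0(names(k), "/", unname(k), "/", collapse = ""))
  }
  tb <- 58L
  te <- tb + nchar(build(0L, 0L), type = "bytes") - 1L
  db <- if (n > 0) te + 1L else 0L
  de <- if (n > 0) db + 4L * npar * n - 1L else 0L
  hdr <- paste0("FCS3.1    ",
                paste(formatC(c(tb, te, db, de, 0L, 0L), width = 8L),
                      collapse = ""))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)
  writeChar(build(db, de), con, eos = NULL, useBytes = TRUE)
  if (n > 0) writeBin(as.numeric(t(mat)), con, size = 4L, endian = "little")
  invisible(path)
}

# Toy study-record builder for degenerate-input tests.
make_records <- function(cytology, rule1 = FALSE, rule2 = FALSE,
                         micro_diff = FALSE, micro_count = FALSE,
                         wbc = 100, hfbf = 10) {
  n <- length(cytology)
  data.frame(
    sample_id = seq_len(n),
    material = rep("PE", n),
    histology = rep("N/D", n),
    cytology_class = parse_cytology_class(cytology),
    total_cells = rep(wbc + hfbf, n),
    wbc = rep(wbc, n),
    hfbf = rep(hfbf, n),
    hfbf_percent = rep(round_half_up(100 * hfbf / wbc, 1), n),
    rule1 = rep_len(rule1, n),
    rule2 = rep_len(rule2, n),
    micro_diff = rep_len(micro_diff, n),
    micro_count = rep_len(micro_count, n),
    stringsAsFactors = FALSE
  )
}
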