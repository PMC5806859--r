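#' @title Synthetic WDF event-cloud simulator
#' @description
#' Generates labeled four-signal event clouds emulating the distinct
#' populations a body-fluid sample presents on the WDF channel: small
#' low-fluorescence lymphocytes, granular neutrophils and eosinophils (high
#' side scatter), monocytes, large strongly fluorescent
#' macrophages/mesothelial cells, isolated malignant cells with intermediate
#' fluorescence and modest size, and malignant cell clumps whose pulse width
#' ("time of flight") grows with the number of aggregated cells. Each
#' population is a truncated correlated 4-variate location-scale (Gaussian)
#' model on the normalized unit hypercube; clumping multiplies the seed
#' cell's signals by sub-linear per-cell gains. Real WDF correlation
#' structure is unpublished, so correlations are user parameters, not
#' claims.
#' @name simulator
NULL

SIM_POPULATIONS <- c("lymphocyte", "monocyte", "neutrophil", "eosinophil",
                     "macrophage_mesothelial", "malignant_isolated",
                     "malignant_clump_seed")

#' Specify one generative event population
#'
#' @param name population tag, one of
#'   `lymphocyte, monocyte, neutrophil, eosinophil, macrophage_mesothelial,
#'   malignant_isolated, malignant_clump_seed`.
#' @param mean length-4 numeric vector of normalized means
#'   (fsc, ssc, sfl, fscw).
#' @param sd length-4 vector of positive spreads.
#' @param fraction expected share of the sample's events.
#' @param correlation 4x4 symmetric positive-definite correlation matrix
#'   (identity by default).
#' @return a `population_spec`.
#' @export
population_spec <- function(name, mean, sd, fraction,
                            correlation = diag(4)) {
  if (!name %in% SIM_POPULATIONS) {
    stop("unknown population name '", name, "'")
  }
  mean <- as.numeric(mean); sd <- as.numeric(sd)
  stopifnot(length(mean) == 4L, length(sd) == 4L, all(sd > 0),
            fraction >= 0, fraction <= 1)
  if (any(mean < 0) || any(mean > 1)) {
    stop("population means must be in normalized [0, 1] units")
  }
  correlation <- as.matrix(correlation)
  if (!isTRUE(all.equal(correlation, t(correlation))) ||
      any(eigen(correlation, symmetric = TRUE,
                only.values = TRUE)$values <= 1e-12)) {
    stop("correlation must be symmetric positive-definite")
  }
  structure(list(name = name, mean = mean, sd = sd, fraction = fraction,
                 correlation = correlation),
            class = "population_spec")
}

#' Cell-clump signal model
#'
#' A clump of k cells passes the laser as one event: per-cell multiplicative
#' gains act sub-linearly through the exponent form `gain^(log2 k)`
#' (equivalently `k^(log2 gain)`), so each doubling of clump size multiplies
#' the signal by `gain` once. Resulting signals are clipped to the channel
#' range.
#'
#' @param size_distribution function `(n)` returning n integer clump sizes
#'   k >= 2; default a geometric distribution shifted to start at 2 and
#'   truncated at `max_k`.
#' @param fscw_gain,fsc_gain,sfl_gain per-doubling multiplicative gains
#'   (all >= 1).
#' @param prob success probability of the default geometric size law.
#' @param max_k truncation cap of the default size law.
#' @return a `clump_model`.
#' @export
clump_model <- function(size_distribution = NULL, fscw_gain = 1.6,
                        fsc_gain = 1.25, sfl_gain = 1.3,
                        prob = 0.45, max_k = 8L) {
  stopifnot(fscw_gain >= 1, fsc_gain >= 1, sfl_gain >= 1)
  if (is.null(size_distribution)) {
    size_distribution <- function(n) {
      pmin(2L + stats::rgeom(n, prob = prob), max_k)
    }
  }
  structure(list(size_distribution = size_distribution,
                 fscw_gain = fscw_gain, fsc_gain = fsc_gain,
                 sfl_gain = sfl_gain),
            class = "clump_model")
}

#' Describe a whole synthetic sample
#'
#' @param populations list of [population_spec()]s; fractions must sum
#'   to 1.
#' @param n_events number of events to draw.
#' @param clump optional [clump_model()] applied to `malignant_clump_seed`
#'   events.
#' @param volume_factor analyzed volume in uL (event count / volume =
#'   concentration).
#' @param channel_range per-channel maxima of the emitted cloud (signals
#'   are drawn normalized, then scaled).
#' @return a `sample_profile` whose `truth_malignant` flag is TRUE iff a
#'   malignant population has nonzero fraction.
#' @export
sample_profile <- function(populations, n_events, clump = NULL,
                           volume_factor = 5, channel_range = rep(1023, 4)) {
  stopifnot(length(populations) >= 1L, n_events >= 0, volume_factor > 0)
  lapply(populations, function(p) stopifnot(inherits(p, "population_spec")))
  fr <- vapply(populations, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-9) {
    stop("population fractions must sum to 1 (got ", sum(fr), ")")
  }
  names(populations) <- vapply(populations, `[[`, character(1), "name")
  malignant <- any(fr[names(populations) %in%
                        c("malignant_isolated", "malignant_clump_seed")] > 0)
  structure(
    list(populations = populations, n_events = as.integer(n_events),
         clump = clump, volume_factor = volume_factor,
         channel_range = as_channel_range(channel_range),
         truth_malignant = malignant),
    class = "sample_profile"
  )
}

#' Draw events from one population
#'
#' Truncated correlated Gaussian draw on the unit hypercube by rejection
#' sampling (at most 1000 rounds; population specs are expected to place
#' nearly all mass inside the cube, so rejection is cheap).
#'
#' @param spec a [population_spec()].
#' @param n number of events.
#' @param seed integer seed; identical (spec, n, seed) give identical
#'   events.
#' @return a normalized labeled [event_cloud()] (channel ranges 1).
#' @export
draw_population <- function(spec, n, seed) {
  stopifnot(inherits(spec, "population_spec"), n >= 0)
  sigma <- diag(spec$sd) %*% spec$correlation %*% diag(spec$sd)
  with_seed(seed, {
    out <- matrix(numeric(0), ncol = 4L)
    rounds <- 0L
    need <- n
    while (need > 0L) {
      rounds <- rounds + 1L
      if (rounds > 1000L) {
        stop("rejection sampling failed to fill ", n, " events in 1000 ",
             "rounds; population places too little mass in [0,1]^4")
      }
      draw <- MASS::mvrnorm(max(need, 2L), mu = spec$mean, Sigma = sigma)
      keep <- draw[apply(draw >= 0 & draw <= 1, 1L, all), , drop = FALSE]
      if (nrow(keep) > need) keep <- keep[seq_len(need), , drop = FALSE]
      out <- rbind(out, keep)
      need <- n - nrow(out)
    }
    colnames(out) <- WDF_SIGNALS
    event_cloud(out, channel_range = rep(1, 4L),
                labels = rep(spec$name, n))
  })
}

#' Apply the clump model to clump-seed events
#'
#' Each `malignant_clump_seed` event is assigned a clump size k from the
#' model's size distribution; its signals are multiplied by the sub-linear
#' gains and clipped to the channel range, and its label is rewritten to
#' `malignant_clump`. All other events are untouched and event count is
#' conserved.
#'
#' @param cloud a labeled [event_cloud()].
#' @param model a [clump_model()].
#' @param seed integer seed for the size draws.
#' @return the transformed `event_cloud`.
#' @export
apply_clumps <- function(cloud, model, seed) {
  stopifnot(inherits(cloud, "event_cloud"), inherits(model, "clump_model"))
  if (is.null(cloud$labels)) stop("apply_clumps needs a labeled cloud")
  seeds <- which(cloud$labels == "malignant_clump_seed")
  if (length(seeds) == 0L) return(cloud)
  k <- with_seed(seed, model$size_distribution(length(seeds)))
  if (any(k < 2)) stop("clump sizes must be >= 2")
  gain <- function(g) g^(log2(k))
  ev <- cloud$events
  rng <- cloud$channel_range
  ev[seeds, "fscw"] <- pmin(rng[["fscw"]], ev[seeds, "fscw"] * gain(model$fscw_gain))
  ev[seeds, "fsc"] <- pmin(rng[["fsc"]], ev[seeds, "fsc"] * gain(model$fsc_gain))
  ev[seeds, "sfl"] <- pmin(rng[["sfl"]], ev[seeds, "sfl"] * gain(model$sfl_gain))
  labels <- cloud$labels
  labels[seeds] <- "malignant_clump"
  event_cloud(ev, channel_range = rng, meta = cloud$meta, labels = labels)
}

#' Simulate one sample
#'
#' Splits `n_events` multinomially across the profile's populations, draws
#' each population, applies the clump model, scales to channel units, and
#' shuffles the events. The truth record carries the generative
#' per-population counts and the malignancy truth.
#'
#' @param profile a [sample_profile()].
#' @param seed integer master seed; the per-population draws use child
#'   seeds derived deterministically from it.
#' @return list with elements `cloud` (labeled [event_cloud()] in channel
#'   units) and `truth` (list: `population_counts`, `n_events`,
#'   `truth_malignant`, `volume_factor`).
#' @export
simulate_sample <- function(profile, seed) {
  stopifnot(inherits(profile, "sample_profile"))
  pops <- profile$populations
  fr <- vapply(pops, `[[`, numeric(1), "fraction")
  seeds <- derive_seeds(seed, length(pops) + 2L)
  counts <- as.integer(with_seed(seeds[1],
    stats::rmultinom(1L, profile$n_events, prob = fr)))
  clouds <- Map(function(p, n, s) draw_population(p, n, s),
                pops, counts, seeds[seq_along(pops) + 1L])
  ev <- do.call(rbind, lapply(clouds, `[[`, "events"))
  labels <- unlist(lapply(clouds, `[[`, "labels"), use.names = FALSE)
  cloud <- event_cloud(ev %||% matrix(numeric(0), ncol = 4L),
                       channel_range = rep(1, 4L), labels = labels)
  if (!is.null(profile$clump) && any(labels == "malignant_clump_seed")) {
    cloud <- apply_clumps(cloud, profile$clump, seeds[length(seeds)])
  }
  perm <- with_seed(seeds[length(seeds)] + 1L,
                    sample.int(n_events(cloud)))
  scaled <- sweep(cloud$events[perm, , drop = FALSE], 2L,
                  profile$channel_range, "*")
  out <- event_cloud(scaled, channel_range = profile$channel_range,
                     labels = cloud$labels[perm],
                     meta = list(seed = seed))
  list(
    cloud = out,
    truth = list(
      population_counts = stats::setNames(counts, names(pops)),
      n_events = profile$n_events,
      truth_malignant = profile$truth_malignant,
      volume_factor = profile$volume_factor
    )
  )
}

#' Simulate a cohort of samples
#'
#' @param profiles list of [sample_profile()]s.
#' @param seed master seed; each sample gets an independent child seed, so
#'   the whole cohort is reproducible bit-for-bit.
#' @return list of `simulate_sample` results, aligned with `profiles`.
#' @export
simulate_cohort <- function(profiles, seed) {
  stopifnot(length(profiles) >= 1L)
  seeds <- derive_seeds(seed, length(profiles))
  Map(function(p, s) simulate_sample(p, s), profiles, seeds)
}

#' Canonical population parameter sets
#'
#' The shipped defaults placing each population where the default gating
#' geometry expects it: WBC populations below the fluorescence cutoff,
#' macrophages/mesothelial cells large and strongly fluorescent (outside
#' both rule gates), isolated malignant cells in the Area 2 band
#' (intermediate fluorescence, lower forward scatter than macrophages), and
#' clump seeds that land in Area 1 once the clump gains act on pulse width.
#' These co-evolve with [gating_config()] defaults as one versioned
#' convention.
#'
#' @param fractions named numeric vector of population fractions; names are
#'   population tags, entries must sum to 1.
#' @return list of [population_spec()]s.
#' @export
canonical_populations <- function(fractions) {
  base <- list(
    lymphocyte = list(mean = c(0.25, 0.18, 0.30, 0.22),
                      sd = c(0.030, 0.030, 0.035, 0.025)),
    monocyte = list(mean = c(0.35, 0.25, 0.45, 0.25),
                    sd = c(0.035, 0.030, 0.035, 0.025)),
    neutrophil = list(mean = c(0.35, 0.55, 0.35, 0.25),
                      sd = c(0.035, 0.045, 0.040, 0.025)),
    eosinophil = list(mean = c(0.35, 0.75, 0.50, 0.25),
                      sd = c(0.035, 0.045, 0.030, 0.025)),
    macrophage_mesothelial = list(mean = c(0.72, 0.45, 0.82, 0.28),
                                  sd = c(0.045, 0.050, 0.040, 0.030)),
    malignant_isolated = list(mean = c(0.35, 0.30, 0.68, 0.25),
                              sd = c(0.040, 0.040, 0.025, 0.025)),
    malignant_clump_seed = list(mean = c(0.40, 0.35, 0.66, 0.30),
                                sd = c(0.040, 0.040, 0.025, 0.030))
  )
  stopifnot(!is.null(names(fractions)),
            all(names(fractions) %in% names(base)))
  lapply(names(fractions), function(nm) {
    population_spec(nm, base[[nm]]$mean, base[[nm]]$sd,
                    fraction = unname(fractions[nm]))
  })
}

#' Canonical benign / malignant sample profiles
#'
#' Mixes emulating the study's specimen variety: benign effusions dominated
#' by leukocytes with a macrophage/mesothelial background, and malignant
#' effusions carrying both isolated malignant cells and clump seeds.
#'
#' @param malignant logical; include malignant populations?
#' @param n_events events per sample.
#' @param volume_factor analyzed volume (uL).
#' @return a [sample_profile()].
#' @export
canonical_profile <- function(malignant, n_events = 5000,
                              volume_factor = 5) {
  fr <- if (malignant) {
    c(lymphocyte = 0.25, monocyte = 0.10, neutrophil = 0.25,
      eosinophil = 0.02, macrophage_mesothelial = 0.08,
      malignant_isolated = 0.20, malignant_clump_seed = 0.10)
  } else {
    c(lymphocyte = 0.40, monocyte = 0.15, neutrophil = 0.30,
      eosinophil = 0.05, macrophage_mesothelial = 0.10)
  }
  sample_profile(
    canonical_populations(fr),
    n_events = n_events,
    clump = if (malignant) clump_model() else NULL,
    volume_factor = volume_factor
  )
}
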