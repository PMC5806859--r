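test_that("normalization divides by channel range and is idempotent", {
  ev <- rbind(c(0, 0, 0, 0), c(1023, 512, 2047, 255))
  cloud <- event_cloud(ev, channel_range = c(fsc = 1023, ssc = 512,
                                             sfl = 2047, fscw = 255))
  norm <- normalize_events(cloud)
  expect_equal(unname(norm$events[1, ]), c(0, 0, 0, 0))
  expect_equal(unname(norm$events[2, ]), c(1, 1, 1, 1))
  expect_identical(normalize_events(norm), norm)

  set.seed(3)
  rng <- c(fsc = 200, ssc = 300, sfl = 150, fscw = 100)
  r <- event_cloud(sweep(matrix(runif(400), ncol = 4L), 2L, rng, "*"),
                   channel_range = rng)
  got <- normalize_events(r)
  expect_equal(apply(got$events, 2L, max),
               apply(r$events, 2L, max) / rng)

  expect_error(event_cloud(ev, channel_range = c(0, 1, 1, 1)), "positive")
})

test_that("point_in_gate handles interior, exterior and boundary points", {
  sq <- rect_gate(c("fscw", "fsc"), c(0.2, 0.6), c(0.2, 0.6))
  expect_true(point_in_gate(c(0.4, 0.4), sq))       # centroid
  expect_false(point_in_gate(c(0.9, 0.9), sq))      # outside bounding box
  # boundary belongs to the gate: edge and vertex
  expect_true(point_in_gate(c(0.2, 0.4), sq))
  expect_true(point_in_gate(c(0.6, 0.6), sq))
})

test_that("point_in_gate matches a brute-force ray-casting oracle", {
  set.seed(101)
  for (rep in 1:10) {
    v <- random_convex_polygon(5L)
    g <- gate_region(c("fsc", "sfl"), v)
    pts <- cbind(runif(1000), runif(1000))
    expect_identical(point_in_gate(pts, g), oracle_point_in_poly(pts, v))
  }
})

test_that("degenerate and self-intersecting polygons are rejected", {
  expect_error(gate_region(c("fsc", "sfl"),
                           rbind(c(0.1, 0.1), c(0.5, 0.5), c(0.9, 0.9))),
               "degenerate")
  bowtie <- rbind(c(0.1, 0.1), c(0.9, 0.9), c(0.9, 0.1), c(0.1, 0.9))
  expect_error(gate_region(c("fsc", "sfl"), bowtie), "simple")
  expect_error(gate_region(c("fsc", "bad"), rbind(c(0, 0), c(1, 0), c(1, 1))),
               "WDF")
})

test_that("event classification follows the debris/HF-BF/PMN/MN precedence", {
  cfg <- gating_config()
  mk <- function(fsc, ssc, sfl, fscw = 0.25) {
    event_cloud(rbind(c(fsc, ssc, sfl, fscw)), channel_range = rep(1, 4))
  }
  empty <- event_cloud(matrix(numeric(0), ncol = 4), channel_range = rep(1, 4))
  expect_identical(classify_events(empty, cfg), character(0))

  # fluorescence exactly at the cutoff belongs to HF-BF
  expect_identical(classify_events(mk(0.5, 0.3, cfg$hfbf_sfl_cutoff), cfg),
                   "HFBF")
  # debris floor wins over everything
  expect_identical(classify_events(mk(0.01, 0.3, 0.9), cfg), "debris")
  # granular, low fluorescence -> PMN; agranular -> MN
  expect_identical(classify_events(mk(0.35, 0.55, 0.35), cfg), "PMN")
  expect_identical(classify_events(mk(0.25, 0.18, 0.30), cfg), "MN")

  raw <- event_cloud(rbind(c(500, 100, 100, 100)),
                     channel_range = rep(1023, 4))
  expect_error(classify_events(raw, cfg), "normalized")
})

test_that("label conservation holds on random clouds", {
  cfg <- gating_config()
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(0:500, 1)
    cloud <- event_cloud(matrix(runif(n * 4), ncol = 4L),
                         channel_range = rep(1, 4))
    labels <- classify_events(cloud, cfg)
    expect_identical(length(labels), n)
    expect_identical(sum(table(factor(labels,
                                      c("debris", "PMN", "MN", "HFBF")))),
                     n)
  }
})

test_that("well-separated simulated populations recover their labels", {
  # means at least ~4 sd from every classification boundary
  specs <- list(
    population_spec("lymphocyte", c(0.25, 0.15, 0.25, 0.2),
                    c(0.02, 0.02, 0.02, 0.02), 0.4),
    population_spec("neutrophil", c(0.35, 0.60, 0.30, 0.2),
                    c(0.02, 0.02, 0.02, 0.02), 0.4),
    population_spec("macrophage_mesothelial", c(0.75, 0.45, 0.85, 0.3),
                    c(0.02, 0.02, 0.02, 0.02), 0.2)
  )
  prof <- sample_profile(specs, n_events = 5000)
  s <- simulate_sample(prof, seed = 5)
  labels <- classify_events(normalize_events(s$cloud), gating_config())
  truth <- s$cloud$labels
  expected <- c(lymphocyte = "MN", neutrophil = "PMN",
                macrophage_mesothelial = "HFBF")[truth]
  expect_gte(mean(labels == expected), 0.99)
})

test_that("rule gates count HF-BF events inside their areas", {
  cfg <- gating_config()
  # no HF-BF labels -> (0, 0) regardless of geometry
  cloud <- event_cloud(matrix(runif(400), ncol = 4L),
                       channel_range = rep(1, 4))
  expect_equal(unname(apply_rule_gates(cloud, rep("MN", 100), cfg)),
               c(0L, 0L))

  # one HF-BF event at area1's centroid, outside area2
  v1 <- cfg$area1$vertices
  ev <- rbind(c(mean(v1[, 2]), 0.5, 0.9, mean(v1[, 1])))
  one <- event_cloud(ev, channel_range = rep(1, 4))
  expect_equal(unname(apply_rule_gates(one, "HFBF", cfg)), c(1L, 0L))

  # oracle: counts equal the sum of per-event membership
  set.seed(33)
  big <- event_cloud(matrix(runif(2000 * 4), ncol = 4L),
                     channel_range = rep(1, 4))
  labels <- classify_events(big, cfg)
  got <- apply_rule_gates(big, labels, cfg)
  hf <- labels == "HFBF"
  expect_equal(got[["rule1_events"]],
               sum(oracle_point_in_poly(big$events[hf, c("fscw", "fsc")],
                                        cfg$area1$vertices)))
  expect_equal(got[["rule2_events"]],
               sum(oracle_point_in_poly(big$events[hf, c("fsc", "sfl")],
                                        cfg$area2$vertices)))
})

test_that("enlarging a gate never decreases its rule count", {
  set.seed(44)
  for (rep in 1:10) {
    lo <- runif(2, 0.1, 0.4); hi <- lo + runif(2, 0.1, 0.4)
    pad <- runif(1, 0.01, 0.1)
    small1 <- rect_gate(c("fscw", "fsc"), c(lo[1], hi[1]), c(lo[2], hi[2]))
    big1 <- rect_gate(c("fscw", "fsc"),
                      c(max(0, lo[1] - pad), min(1, hi[1] + pad)),
                      c(max(0, lo[2] - pad), min(1, hi[2] + pad)))
    cfg_s <- gating_config(area1 = small1)
    cfg_b <- gating_config(area1 = big1)
    cloud <- event_cloud(matrix(runif(500 * 4), ncol = 4L),
                         channel_range = rep(1, 4))
    labels <- classify_events(cloud, cfg_s)
    expect_gte(apply_rule_gates(cloud, labels, cfg_b)[["rule1_events"]],
               apply_rule_gates(cloud, labels, cfg_s)[["rule1_events"]])
  }
})

test_that("derived counts reproduce the clinical count identities", {
  cfg1 <- gating_config(volume_factor = 1)
  # WBC 998 with HF-BF 830 -> TNC 1828, HF-BF% 83.2
  labels <- c(rep("PMN", 600), rep("MN", 398), rep("HFBF", 830))
  counts <- compute_counts(labels, 0L, 0L, cfg1)
  expect_equal(counts$wbc_count, 998)
  expect_equal(counts$tnc, 1828)
  expect_equal(counts$hfbf_percent, 83.2)

  # HF-BF% may exceed 100
  labels2 <- c(rep("MN", 342), rep("HFBF", 1127))
  expect_equal(compute_counts(labels2, 0L, 0L, cfg1)$hfbf_percent, 329.5)

  # zero WBC: undefined percentage is flagged NA, not an error
  zero <- compute_counts(rep("debris", 5), 0L, 0L, cfg1)
  expect_equal(zero$tnc, 0)
  expect_true(is.na(zero$hfbf_percent))
})

test_that("count identities hold for random label mixes", {
  cfg <- gating_config()
  set.seed(55)
  for (rep in 1:25) {
    labels <- sample(c("debris", "PMN", "MN", "HFBF"),
                     sample(0:300, 1), replace = TRUE)
    counts <- compute_counts(labels, 0L, 0L, cfg)
    expect_equal(counts$tnc, counts$wbc_count + counts$hfbf_count)
    expect_equal(counts$wbc_count, counts$pmn_count + counts$mn_count)
    if (counts$wbc_count > 0) {
      expect_equal(counts$hfbf_percent,
                   round_half_up(100 * counts$hfbf_count / counts$wbc_count))
    }
  }
})

test_that("the malignancy call is either-rule OR with dual thresholds", {
  cfg <- gating_config(rule_min_events = 10, rule_min_conc = 10,
                       volume_factor = 1)
  mk <- function(r1, r2) compute_counts(rep("HFBF", 100), r1, r2, cfg)
  expect_false(call_sample(mk(0L, 0L), cfg)$malignant_call)
  r1only <- call_sample(mk(50L, 0L), cfg)
  expect_true(r1only$rule1_positive && !r1only$rule2_positive)
  expect_true(r1only$malignant_call)
  both <- call_sample(mk(50L, 60L), cfg)
  expect_true(both$rule1_positive && both$rule2_positive &&
                both$malignant_call)
  # below either threshold the rule stays negative
  expect_false(call_sample(mk(9L, 0L), cfg)$rule1_positive)
  low_conc <- gating_config(rule_min_events = 10, rule_min_conc = 10,
                            volume_factor = 10)
  expect_false(call_sample(compute_counts(rep("HFBF", 100), 50L, 0L,
                                          low_conc),
                           low_conc)$rule1_positive)  # 5 cells/uL < 10
})

test_that("adding a gated event never turns a positive call negative", {
  cfg <- gating_config(volume_factor = 1)
  set.seed(66)
  for (rep in 1:10) {
    r1 <- sample(0:40, 1)
    before <- call_sample(compute_counts(rep("HFBF", 50), r1, 0L, cfg), cfg)
    after <- call_sample(compute_counts(rep("HFBF", 51), r1 + 1L, 0L, cfg),
                         cfg)
    if (before$malignant_call) expect_true(after$malignant_call)
  }
})

test_that("gating configs round-trip through JSON and YAML", {
  cfg <- gating_config(hfbf_sfl_cutoff = 0.58, rule_min_events = 25)
  for (ext in c(".json", ".yaml")) {
    path <- withr::local_tempfile(fileext = ext)
    write_gating_config(cfg, path)
    back <- read_gating_config(path)
    expect_equal(back$hfbf_sfl_cutoff, 0.58)
    expect_equal(back$rule_min_events, 25L)
    expect_equal(back$area1$vertices, cfg$area1$vertices)
    expect_equal(back$area2$plane, c("fsc", "sfl"))
  }
})
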