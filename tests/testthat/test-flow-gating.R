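# Gating stages: saturation filter, density scatter gate, singlet gate,
# log transform and thresholds, plus the nesting/idempotence contracts.

make_events <- function(df, ceiling = 2^18 - 1) {
  base <- data.frame(fsc_a = 1e5, ssc_a = 3e4, fsc_h = 1e5,
                     green = 100, blue = 100)
  out <- base[rep(1L, nrow(df)), ]
  out[names(df)] <- df
  rownames(out) <- NULL
  # fluorescence ceilings under test; scatter ceilings out of the way
  flow_events(out, c(fsc_a = 1e9, ssc_a = 1e9, fsc_h = 1e9,
                     green = ceiling, blue = ceiling))
}

test_that("saturation filter removes exactly the events touching a ceiling", {
  ceil <- 1000
  df <- data.frame(green = c(rep(500, 15), rep(ceil, 3), 999, 1000),
                   blue = c(rep(400, 18), ceil, 250))
  ev <- make_events(df, ceiling = ceil)
  # brute-force count on the 20-row fixture (scatter ceilings never bind)
  k <- sum(apply(as.data.frame(ev)[c("green", "blue")], 1,
                 function(r) any(r >= ceil)))
  pop <- filter_saturated(ev)
  expect_equal(sum(survivors(pop)), nrow(df) - k)
  expect_equal(k, 5L)
  # all-below table: identity
  ev_ok <- make_events(data.frame(green = rep(10, 8)), ceiling = ceil)
  expect_true(all(survivors(filter_saturated(ev_ok))))
  # unknown ceilings refuse to guess
  bad <- ev
  attr(bad, "ceilings") <- NULL
  expect_error(filter_saturated(bad), "ceiling")
})

test_that("scatter gate retains the requested fraction of a unimodal cloud", {
  set.seed(1)
  n <- 10000L
  ev <- make_events(data.frame(fsc_a = 10^rnorm(n, 5, 0.15),
                               ssc_a = 10^rnorm(n, 4.5, 0.2),
                               fsc_h = 1e5))
  pop <- scatter_gate(filter_saturated(ev), retain_fraction = 0.5)
  expect_equal(sum(survivors(pop)) / n, 0.5, tolerance = 0.02)
  pop8 <- scatter_gate(filter_saturated(ev), retain_fraction = 0.8)
  expect_equal(sum(survivors(pop8)) / n, 0.8, tolerance = 0.02)
  # retain_fraction = 1 is the identity
  pop1 <- scatter_gate(filter_saturated(ev), retain_fraction = 1)
  expect_true(all(survivors(pop1)))
  expect_error(scatter_gate(filter_saturated(ev[1:10, ])), "at least")
})

test_that("scatter gate excludes a well-separated diffuse minority cluster", {
  set.seed(2)
  n_maj <- 9000L
  n_min <- 1000L
  ev <- make_events(data.frame(
    fsc_a = 10^c(rnorm(n_maj, 5.0, 0.05), rnorm(n_min, 5.8, 0.3)),
    ssc_a = 10^c(rnorm(n_maj, 4.5, 0.05), rnorm(n_min, 5.3, 0.3)),
    fsc_h = 1e5))
  pop <- scatter_gate(filter_saturated(ev), retain_fraction = 0.85)
  kept <- survivors(pop)
  expect_equal(sum(kept[(n_maj + 1):(n_maj + n_min)]), 0L)
  expect_gt(mean(kept[1:n_maj]), 0.9)
})

test_that("singlet gate removes generated doublets and keeps unit-ratio events", {
  cfg <- flow_sim_config(n_events = 10000L, doublet_fraction = 0.2, seed = 3L)
  ev <- simulate_flow_experiment(cfg)
  gt <- attr(ev, "ground_truth")
  pop <- singlet_gate(filter_saturated(ev))
  kept <- survivors(pop)
  removed_frac <- 1 - sum(kept & gt$is_doublet) / sum(gt$is_doublet)
  expect_gte(removed_frac, 0.95)
  # unit-ratio event is retained; unbounded band is the identity
  one <- make_events(data.frame(fsc_a = 1e5, fsc_h = 1e5))
  expect_true(all(survivors(singlet_gate(filter_saturated(one)))))
  wide <- singlet_gate(filter_saturated(ev), band = c(1e-12, Inf))
  expect_identical(wide$masks$singlet, wide$masks$saturation) # identity stage
  expect_error(singlet_gate(filter_saturated(ev), band = c(2, 1)),
               "increasing")
})

test_that("gates are nested, monotone and idempotent", {
  cfg <- flow_sim_config(n_events = 8000L, doublet_fraction = 0.1, seed = 4L)
  ev <- simulate_flow_experiment(cfg)
  pop <- singlet_gate(scatter_gate(filter_saturated(ev)))
  counts <- retention_counts(pop)$retained
  expect_true(all(diff(counts) <= 0))
  # each stage's survivors are a subset of the previous stage's
  cum <- pop$masks[[1]]
  for (m in pop$masks[-1]) {
    expect_false(any(m & !cum)) # a later stage never resurrects an event
    cum <- cum & m
  }
  # re-applying the last gate with identical settings changes nothing
  expect_identical(singlet_gate(pop)$masks, pop$masks)
  pop_s <- scatter_gate(filter_saturated(ev), retain_fraction = 0.6)
  expect_identical(scatter_gate(pop_s, retain_fraction = 0.6)$masks,
                   pop_s$masks)
  expect_identical(filter_saturated(gated_events(filter_saturated(ev)))$masks$saturation,
                   rep(TRUE, counts[2]))
})

test_that("log transform replaces channels and drops non-positives with a count", {
  ev <- make_events(data.frame(green = c(100, 1, 0, 50),
                               blue = c(10, 10, 10, 0)))
  lt <- log_transform(filter_saturated(ev))
  expect_equal(lt$green, c(2, 0))
  expect_equal(lt$blue, c(1, 1))
  expect_equal(attr(lt, "n_dropped_nonpositive"), 2L)
  # background subtraction happens before the log and can create drops
  lt2 <- log_transform(filter_saturated(ev), background = c(green = 60, blue = 5))
  expect_equal(nrow(lt2), 1L)
  expect_equal(lt2$green, log10(40))
})

test_that("thresholds reproduce known quantiles of the control", {
  ev <- make_events(data.frame(green = 10^seq(0, 2, length.out = 101),
                               blue = 10^seq(1, 3, length.out = 101)))
  lt <- log_transform(filter_saturated(ev))
  thr <- fit_thresholds(lt, quantile = 0.5)
  expect_equal(unname(thr["green"]), 1, tolerance = 1e-9)
  expect_equal(unname(thr["blue"]), 2, tolerance = 1e-9)
  const <- make_events(data.frame(green = rep(100, 20), blue = rep(10, 20)))
  thr_c <- fit_thresholds(log_transform(filter_saturated(const)), 0.999)
  expect_equal(unname(thr_c["green"]), 2)
  expect_error(fit_thresholds(lt[0, ], 0.999))
  above <- apply_thresholds(lt, thr)
  expect_true(all(above$green > thr["green"] & above$blue > thr["blue"]))
})
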