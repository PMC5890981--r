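test_that("traces are deterministic under a fixed seed", {
  d <- tibble::tibble(cag = c(254, 255), weight = c(0.3, 0.7))
  a <- simulate_trace(d, trace_model(), seed = 7)
  b <- simulate_trace(d, trace_model(), seed = 7)
  expect_identical(a, b)
  c_ <- simulate_trace(d, trace_model(), seed = 8)
  expect_false(identical(a, c_))
})

test_that("a noiseless single allele is recovered exactly by call_peaks", {
  tm <- trace_model(stutter_decay = 0, noise_sd = 0, size_jitter_sd = 0,
                    n_points = 4001)
  d <- tibble::tibble(cag = 255, weight = 1)
  tr <- simulate_trace(d, tm, seed = 1)
  pk <- call_peaks(tr)
  expect_equal(nrow(pk), 1L)
  # grid quantization only: half the sample spacing in repeat units
  spacing <- diff(tr$size_bp[1:2])
  expect_lt(abs(pk$cag - 255), bp_to_cag(122 + spacing) - bp_to_cag(122))
})

test_that("the stutter ladder decays geometrically from the true allele", {
  tm <- trace_model(stutter_decay = 0.3, noise_sd = 0, size_jitter_sd = 0,
                    n_points = 4001)
  tr <- simulate_trace(tibble::tibble(cag = 255, weight = 1), tm, seed = 1)
  pk <- call_peaks(tr, min_rel_height = 0.01)
  expect_gte(nrow(pk), 3L)
  o <- order(-pk$intensity)
  modal <- pk$cag[o[1]]
  minus1 <- pk[which.min(abs(pk$cag - (modal - 1))), ]
  expect_equal(minus1$intensity / max(pk$intensity), 0.3, tolerance = 0.02)
  # stutter runs toward shorter fragments only
  expect_lt(min(pk$cag), modal)
  expect_lt(max(pk$cag), modal + 0.5)
})

test_that("week-8 preset animals show zero modal drift", {
  sim <- simulate_animal(drift_preset("week8_null"), trace_model(),
                         tissues = "striatum", animal = "BRM1001", seed = 3)
  dists <- build_distributions(sim$traces)
  man <- build_manifest(sim$traces["sample_id"],
                        tibble::tibble(animal = "BRM1001", group = "R6/2-Veh",
                                       age_weeks = 8))
  dd <- delta_distributions(dists, man)
  expect_lt(abs(modal_repeat(dd)), 0.5)
})

test_that("expansion_summary recovers the programmed mean shift", {
  tm <- trace_model(noise_sd = 0, size_jitter_sd = 0, stutter_decay = 0,
                    n_points = 6000)
  dm <- drift_model(mean_shift = 8, skew = 0, within_sd = 0.1,
                    inter_animal_sd = 0)
  sim <- simulate_animal(dm, tm, "striatum", "BRM1001", seed = 4)
  dists <- build_distributions(sim$traces, min_rel_height = 0.01)
  man <- build_manifest(sim$traces["sample_id"],
                        tibble::tibble(animal = "BRM1001", group = "g", age_weeks = 12))
  dd <- delta_distributions(dists, man)
  s <- expansion_summary(dd)
  expect_equal(s$mean_dcag, 8, tolerance = 0.1)
  # with a right tail the mean is still mean_shift by construction
  dm2 <- drift_model(mean_shift = 8, skew = 4, within_sd = 3, inter_animal_sd = 0)
  dd2 <- cagdrift:::.discrete_delta(8, 3, 4)
  expect_equal(sum(dd2$dcag * dd2$weight), 8, tolerance = 0.02)
})

test_that("germline modals vary across animals with the configured SD", {
  tm <- trace_model()
  sims <- lapply(1:20, function(i)
    simulate_animal(drift_preset("week8_null"), tm, "striatum",
                    sprintf("BRM10%02d", i), seed = 100 + i))
  tails <- vapply(sims, function(s)
    s$truth$germline_modal[s$truth$tissue == "tail"], numeric(1))
  expect_gt(sd(tails), 0.4)
  expect_lt(sd(tails), 2.5)
  expect_equal(mean(tails), 255, tolerance = 1)
})

test_that("cohort bookkeeping matches the design", {
  co <- simulate_cohort(
    drift = list("R6/2-Veh" = drift_preset("week12_veh"),
                 "R6/2-XJB" = drift_preset("week12_xjb")),
    n_per_group = 3, tissues = c("striatum", "cerebellum"),
    tm = trace_model(n_points = 300), seed = 5)
  expect_equal(nrow(co$design), 6L)
  expect_equal(dplyr::n_distinct(co$peaks$sample_id), 18L)  # 6 x (tail + 2 tissues)
  expect_equal(sort(unique(co$manifest$tissue)),
               c("cerebellum", "striatum", "tail"))
  expect_equal(as.vector(table(co$design$group)), c(3L, 3L))
  # sexes encoded in the ids and parsed back
  expect_setequal(unique(co$manifest$sex), c("male", "female"))
  # determinism end to end
  co2 <- simulate_cohort(
    drift = list("R6/2-Veh" = drift_preset("week12_veh"),
                 "R6/2-XJB" = drift_preset("week12_xjb")),
    n_per_group = 3, tissues = c("striatum", "cerebellum"),
    tm = trace_model(n_points = 300), seed = 5)
  expect_identical(co$peaks, co2$peaks)
  expect_identical(co$truth, co2$truth)
})

test_that("written cohorts round-trip through the pipeline input formats", {
  co <- simulate_cohort(drift = list(A = drift_preset("week12_veh"),
                                     B = drift_preset("week12_xjb")),
                        n_per_group = 2, tm = trace_model(n_points = 300),
                        seed = 6)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(
    dir, c("peaks.tsv", "design.tsv", "manifest.json", "truth.json")))))
  back <- read_peak_table(file.path(dir, "peaks.tsv"))
  expect_equal(dplyr::n_distinct(back$sample_id),
               dplyr::n_distinct(co$peaks$sample_id))
})
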