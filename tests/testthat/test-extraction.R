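test_that("profile centroiding finds weighted peak centers", {
  # single symmetric triangular peak at 500.0
  mz <- seq(499.96, 500.04, by = 0.01)
  inten <- c(0, 1, 2, 3, 4, 3, 2, 1, 0)
  cp <- centroid_profile(mz, inten)
  expect_length(cp$mz, 1)
  expect_equal(cp$mz, 500.0, tolerance = 1e-9)
  expect_equal(cp$intensity, sum(inten))

  # two baseline-separated peaks, order preserved
  mz2 <- c(mz, seq(600.96, 601.04, by = 0.01))
  inten2 <- c(inten, 0, 2, 4, 6, 8, 6, 4, 2, 0)
  cp2 <- centroid_profile(mz2, inten2)
  expect_length(cp2$mz, 2)
  expect_equal(cp2$mz, c(500.0, 601.0), tolerance = 1e-9)

  # all-zero scan
  cp3 <- centroid_profile(mz, rep(0, length(mz)))
  expect_length(cp3$mz, 0)
})

test_that("cosine similarity is scale-invariant and handles degenerate input", {
  expect_equal(cosine_similarity(c(0.6, 0.3, 0.1), c(6, 3, 1)), 1.0, tolerance = 1e-12)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0.0)
  v <- c(0.2, 0.5, 0.3)
  expect_equal(cosine_similarity(v, v), 1.0, tolerance = 1e-12)
  expect_equal(cosine_similarity(c(1, 1), c(0, 0)), 0)
})

test_that("envelope matching classifies present, absent and chimeric states", {
  p <- parse_peptide("PEPTIDEK")
  cm <- composition_and_mass(p)
  env <- isotope_envelope(cm$composition)
  cfg <- extraction_config()

  # exact rendering: present with cosine 1, zero offsets
  scan <- render_exact_scan(p, c(0, 1, 0, 0, 0))
  m2 <- match_envelope(scan, env, cm$mass, 2, cfg)
  expect_equal(m2$status, "present")
  expect_equal(m2$cosine, 1.0, tolerance = 1e-12)
  expect_lt(m2$max_ppm, 1e-6)
  expect_equal(m2$intensity, 1e6, tolerance = 1e-6)

  # empty region at another charge: absent with zero intensity
  m3 <- match_envelope(scan, env, cm$mass, 3, cfg)
  expect_equal(m3$status, "absent")
  expect_equal(m3$intensity, 0)

  # injected peak between isotopes above the relative threshold: rejected
  chim_mz <- envelope_mz(cm$mass, 2, 0) + 1.0033548 / 4
  scan_ch <- list(mz = sort(c(scan$mz, chim_mz)),
                  intensity = append(scan$intensity, 1.5 * max(scan$intensity),
                                     after = which(sort(c(scan$mz, chim_mz)) == chim_mz) - 1))
  m2c <- match_envelope(scan_ch, env, cm$mass, 2, cfg)
  expect_equal(m2c$status, "rejected")
  expect_true(m2c$chimera)
})

test_that("per-scan extraction requires confident estimates for all five states", {
  p <- parse_peptide("PEPTIDEK")
  cm <- composition_and_mass(p)
  env <- isotope_envelope(cm$composition)
  cfg <- extraction_config()

  truth <- c(0.2, 0.8, 0, 0, 0)
  scan <- render_exact_scan(p, truth)
  res <- extract_scan_csd(scan, env, cm$mass, cfg)
  expect_true(res$accepted)
  expect_equal(res$csd, truth, tolerance = 1e-9)

  # chimera on one charge state discards the whole scan
  chim_mz <- envelope_mz(cm$mass, 2, 1) + 1.0033548 / 4
  ord <- order(c(scan$mz, chim_mz))
  scan_ch <- list(mz = c(scan$mz, chim_mz)[ord],
                  intensity = c(scan$intensity, max(scan$intensity))[ord])
  expect_false(extract_scan_csd(scan_ch, env, cm$mass, cfg)$accepted)

  # all five absent: no reading
  expect_false(extract_scan_csd(list(mz = numeric(0), intensity = numeric(0)),
                                env, cm$mass, cfg)$accepted)
})

test_that("aggregation is the intensity-weighted average", {
  csds <- rbind(c(1, 0, 0, 0, 0), c(0, 1, 0, 0, 0))
  expect_equal(aggregate_readings(csds, c(3, 1)), c(0.75, 0.25, 0, 0, 0))
  same <- rbind(c(0.2, 0.8, 0, 0, 0), c(0.2, 0.8, 0, 0, 0))
  expect_equal(aggregate_readings(same, c(5, 2)), c(0.2, 0.8, 0, 0, 0))
})

test_that("noise-free extraction round-trips the planted CSDs", {
  ps <- fixture_peptides(60, 5)
  cfg <- run_sim_config(seed = 7, scans_per_peptide = 3, noise_sd = 0,
                        threshold = 0, chimera_rate = 0)
  run <- simulate_run(ps, cfg = cfg)
  tab <- extract_run(run$scans, run$id_table)
  expect_equal(nrow(tab), length(ps))
  expect_true(all(tv_vs_truth(tab, run) < 1e-6))
  # simplex invariant on every emitted reading
  expect_equal(rowSums(as.matrix(tab[, paste0("p", 1:5)])), rep(1, nrow(tab)),
               tolerance = 1e-9)
})

test_that("extraction ignores the MS2 triggered charge entirely", {
  ps <- fixture_peptides(20, 4)
  cfg <- run_sim_config(seed = 8, scans_per_peptide = 2, noise_sd = 0.1,
                        threshold = 0, chimera_rate = 0.1)
  run <- simulate_run(ps, cfg = cfg)
  tab1 <- extract_run(run$scans, run$id_table)
  idp <- run$id_table
  idp$triggered_charge <- rev(idp$triggered_charge)
  tab2 <- extract_run(run$scans, idp)
  expect_identical(tab1, tab2)
})

test_that("a 1+ charge state is recovered from MS1 alone", {
  # a model concentrating CSDs on 1+/2+ even though MS2 never triggers on 1+
  m1 <- ground_truth_model(a = c(-1, -20, -20, -20), w_mass = 0, w_bs = 0,
                           beta_aa_under = numeric(0), beta_aa_over = numeric(0),
                           beta_nt_under = numeric(0), beta_nt_over = numeric(0))
  p <- parse_peptide("PEPTIDEK")
  truth <- ground_truth_csd(p, m1)
  expect_gt(truth[1], 0.5)
  cfg <- run_sim_config(seed = 3, scans_per_peptide = 2, noise_sd = 0,
                        threshold = 0, chimera_rate = 0)
  run <- simulate_run(list(p), m1, cfg)
  expect_true(all(run$id_table$triggered_charge >= 2))
  tab <- extract_run(run$scans, run$id_table)
  expect_equal(as.numeric(tab[1, paste0("p", 1:5)]), truth, tolerance = 1e-6)
})

test_that("raising the cosine threshold never increases emitted readings", {
  ps <- fixture_peptides(40, 6)
  cfg <- run_sim_config(seed = 9, scans_per_peptide = 3, noise_sd = 0.3,
                        threshold = 0, chimera_rate = 0.3)
  run <- simulate_run(ps, cfg = cfg)
  counts <- vapply(c(0.9, 0.98, 0.999, 0.9999999), function(ct) {
    nrow(extract_run(run$scans, run$id_table, extraction_config(cosine_threshold = ct)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  # tightening the ppm tolerance likewise
  counts2 <- vapply(c(10, 5, 1, 0.01), function(tp) {
    nrow(extract_run(run$scans, run$id_table, extraction_config(tolerance_ppm = tp)))
  }, numeric(1))
  expect_true(all(diff(counts2) <= 0))
})

test_that("rows without a retention window are skipped with a warning", {
  ps <- fixture_peptides(20, 4)[1:3]
  cfg <- run_sim_config(seed = 2, scans_per_peptide = 2, noise_sd = 0,
                        threshold = 0, chimera_rate = 0)
  run <- simulate_run(ps, cfg = cfg)
  idt <- run$id_table
  idt$rt_start[2] <- NA
  expect_warning(tab <- extract_run(run$scans, idt), "retention window")
  expect_equal(nrow(tab), 2)
})
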