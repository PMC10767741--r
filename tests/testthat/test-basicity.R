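test_that("feature vectors count residues and flag the N-terminal identity", {
  f <- build_features("AAK")
  expect_equal(unname(f["count_A"]), 2)
  expect_equal(unname(f["count_K"]), 1)
  expect_equal(unname(f["nterm_A"]), 1)
  expect_equal(sum(f[startsWith(names(f), "nterm_")]), 1)
  expect_equal(sum(f[startsWith(names(f), "count_")]), 3)

  expect_equal(unname(build_features("RTNSTFNQVVLK")["nterm_R"]), 1)

  fa <- build_features("PEPK"); fb <- build_features("EPPK")
  expect_equal(fa[startsWith(names(fa), "count_")],
               fb[startsWith(names(fb), "count_")])
  expect_false(all(fa == fb))

  # modified cysteine occupies the single C* slot
  expect_equal(unname(build_features(parse_peptide("_AC(cam)K_"))["count_C"]), 1)
})

test_that("region eligibility uses the strict >100 both-nonzero rule", {
  rd <- function(n_nz, n_extra = 0) {
    data.frame(sequence = "AAK", modifications = "AAK", mass = 1, y = 0.5,
               both_nonzero = c(rep(TRUE, n_nz), rep(FALSE, n_extra)))
  }
  expect_false(region_eligible(rd(100)))
  expect_true(region_eligible(rd(101)))
  expect_false(region_eligible(rd(50, 450)))
})

test_that("the penalized logistic fit recovers planted coefficients", {
  ps <- fixture_peptides(5000, 21)
  seqs <- vapply(ps, write_peptide, character(1))
  X <- t(vapply(seqs, build_features, numeric(40)))
  beta <- stats::setNames(numeric(40), basicity_feature_names())
  beta["count_Q"] <- 0.5; beta["count_D"] <- -0.5
  beta["count_A"] <- 0.2; beta["count_P"] <- 0.3
  beta["nterm_R"] <- -0.8
  y <- plogis(0.3 + as.vector(X %*% beta))
  rd <- data.frame(modifications = seqs, y = y, both_nonzero = TRUE,
                   stringsAsFactors = FALSE)
  fit <- fit_effective_basicity(rd)
  expect_true(fit$converged)
  nb <- paste0("count_", setdiff(names(residue_masses()), c("R", "K", "H")))
  err <- abs(fit$beta[nb] - beta[nb])
  expect_lt(median(err), 0.05)
  expect_lt(abs(fit$beta["count_Q"] - 0.5), 0.05)
  expect_lt(abs(fit$beta["count_D"] + 0.5), 0.05)

  # link identity: intercept + X beta equals logit(yhat) by construction
  eta <- fit$intercept + as.vector(X %*% fit$beta)
  expect_equal(plogis(eta), y, tolerance = 1e-3)
})

test_that("batch transforms shift only the intercept of the fit", {
  ps <- fixture_peptides(5000, 21)
  seqs <- vapply(ps, write_peptide, character(1))
  X <- t(vapply(seqs, build_features, numeric(40)))
  beta <- stats::setNames(numeric(40), basicity_feature_names())
  beta["count_Q"] <- 0.4; beta["count_E"] <- -0.3; beta["nterm_P"] <- 0.5
  y <- plogis(-0.2 + as.vector(X %*% beta))
  rd <- data.frame(modifications = seqs, y = y, both_nonzero = TRUE,
                   stringsAsFactors = FALSE)
  fit0 <- fit_effective_basicity(rd)
  lg <- 0.25
  rd2 <- rd; rd2$y <- plogis(qlogis(y) + lg)  # the batch transform on y
  fit1 <- fit_effective_basicity(rd2)
  expect_equal(fit1$intercept - fit0$intercept, lg, tolerance = 1e-4)
  expect_lt(max(abs(fit1$beta - fit0$beta)), 1e-4)
})

test_that("the fit matches an unpenalized GLM in prediction space", {
  ps <- fixture_peptides(400, 23)
  seqs <- vapply(ps, write_peptide, character(1))
  X <- t(vapply(seqs, build_features, numeric(40)))
  set.seed(12)
  y <- plogis(0.1 + X %*% stats::rnorm(40, 0, 0.1))
  rd <- data.frame(modifications = seqs, y = as.vector(y), both_nonzero = TRUE,
                   stringsAsFactors = FALSE)
  ours <- fit_effective_basicity(rd, basicity_config(lambda = 1e-10),
                                 check_eligibility = TRUE)
  g <- suppressWarnings(stats::glm.fit(cbind(1, X), as.vector(y),
                                       family = stats::quasibinomial()))
  eta_ours <- ours$intercept + as.vector(X %*% ours$beta)
  expect_equal(plogis(eta_ours), g$fitted.values, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("duplicating every row leaves the solution nearly unchanged", {
  ps <- fixture_peptides(400, 23)
  seqs <- vapply(ps, write_peptide, character(1))
  X <- t(vapply(seqs, build_features, numeric(40)))
  set.seed(13)
  y <- as.vector(plogis(X %*% stats::rnorm(40, 0, 0.1)))
  rd <- data.frame(modifications = seqs, y = y, both_nonzero = TRUE,
                   stringsAsFactors = FALSE)
  f1 <- fit_effective_basicity(rd, check_eligibility = FALSE)
  f2 <- fit_effective_basicity(rbind(rd, rd), check_eligibility = FALSE)
  # loss doubles but lambda is fixed, so coefficients barely move
  expect_lt(max(abs(f2$beta - f1$beta)), 1e-3)
})

test_that("degenerate symmetric data gives the zero solution", {
  rd <- data.frame(modifications = rep("AAK", 200), y = 0.5,
                   both_nonzero = TRUE, stringsAsFactors = FALSE)
  fit <- fit_effective_basicity(rd, check_eligibility = FALSE)
  # zero-variance features: objective is minimized with eta = 0 everywhere
  eta <- fit$intercept + sum(fit$beta * build_features("AAK"))
  expect_equal(eta, 0, tolerance = 1e-6)
})

test_that("ineligible regions are refused", {
  rd <- data.frame(modifications = rep("AAK", 50), y = 0.5, both_nonzero = TRUE,
                   stringsAsFactors = FALSE)
  expect_error(fit_effective_basicity(rd), "ineligible")
})

test_that("score correlations are computed over the 17 nonbasic residues", {
  mk <- function(v) {
    b <- stats::setNames(numeric(40), basicity_feature_names())
    b[paste0("count_", setdiff(names(residue_masses()), c("R", "K", "H")))] <- v
    structure(list(beta = b, region = "#2O", run = "r"), class = "basicity_scores")
  }
  set.seed(3)
  v <- rnorm(17)
  expect_equal(score_correlation(mk(v), mk(v)), 1.0)
  expect_equal(score_correlation(mk(v), mk(-v)), -1.0)
  expect_true(is.na(score_correlation(mk(rep(1, 17)), mk(v))))
  # R/K/H coefficients are ignored
  a <- mk(v); a$beta[c("count_R", "count_K", "count_H")] <- 99
  expect_equal(score_correlation(a, mk(v)), 1.0)
})

test_that("correlation matrices are symmetric with unit diagonal", {
  mk <- function(v, lab, run) {
    b <- stats::setNames(numeric(40), basicity_feature_names())
    b[paste0("count_", setdiff(names(residue_masses()), c("R", "K", "H")))] <- v
    structure(list(beta = b, region = lab, run = run), class = "basicity_scores")
  }
  set.seed(4)
  sl <- list(mk(rnorm(17), "#2O", "r1"), mk(rnorm(17), "#3U", "r1"),
             mk(rnorm(17), "#2O", "r2"))
  M <- correlation_matrix(sl)
  expect_equal(M, t(M))
  expect_equal(unname(diag(M)), rep(1, 3))
  expect_true(all(M >= -1 & M <= 1))
  # permuting inputs permutes rows and columns consistently
  M2 <- correlation_matrix(sl[c(2, 3, 1)])
  expect_equal(unname(M2), unname(M[c(2, 3, 1), c(2, 3, 1)]))
})

test_that("mass adjustment removes the mass trend robustly", {
  nb <- setdiff(names(residue_masses()), c("R", "K", "H"))
  m <- residue_masses("carbamidomethyl")[nb]
  mk <- function(s) {
    b <- stats::setNames(numeric(40), basicity_feature_names())
    b[paste0("count_", nb)] <- s
    structure(list(beta = b, region = "#2O", run = "r"), class = "basicity_scores")
  }
  # exactly linear scores: zero residuals
  lin <- 0.05 + 0.003 * m
  expect_lt(max(abs(mass_adjust(mk(lin)))), 1e-9)
  # a +0.3 bump on Q survives the robust fit; others stay near zero
  bump <- lin; bump["Q"] <- bump["Q"] + 0.3
  r <- mass_adjust(mk(bump))
  expect_equal(unname(r["Q"]), 0.3, tolerance = 0.02)
  expect_lt(max(abs(r[names(r) != "Q"])), 0.02)
  # adding a constant leaves residuals unchanged
  r2 <- mass_adjust(mk(bump + 5))
  expect_equal(r, r2, tolerance = 1e-9)
  # brute-force oracle for the Huber argmin
  obj <- function(ab) {
    res <- bump - ab[1] - ab[2] * m; d <- 0.01
    sum(ifelse(abs(res) <= d, 0.5 * res^2, d * (abs(res) - d / 2)))
  }
  o <- stats::optim(c(0, 0), obj, method = "Nelder-Mead",
                    control = list(reltol = 1e-14, maxit = 20000))
  hf <- csdtools:::huber_fit(m, bump, 0.01)
  expect_equal(hf, o$par, tolerance = 1e-5)
})

test_that("planted under/over coefficient sets give the two-cluster structure", {
  m <- ground_truth_model()
  scores <- list()
  for (r in 1:2) {
    ps <- fixture_peptides(2500, 100 + r)
    tab <- ground_truth_csd_table(ps, m, run_id = paste0("run", r),
                                  noise_sd = 0.15, seed = 200 + r)
    for (sp in region_specs()) {
      rdat <- region_table(tab, sp)
      expect_true(region_eligible(rdat))
      scores[[length(scores) + 1L]] <-
        fit_effective_basicity(rdat, region_label = sp$label,
                               run_id = paste0("run", r))
    }
  }
  M <- correlation_matrix(scores)
  regime <- vapply(scores, function(s) region_spec(s$region)$regime, character(1))
  within <- between <- c()
  for (i in 1:(length(scores) - 1)) for (j in (i + 1):length(scores)) {
    if (regime[i] == regime[j]) within <- c(within, M[i, j])
    else between <- c(between, M[i, j])
  }
  expect_gt(min(within), max(between))
  # the named contrasts: same-regime regions agree strongly, opposite weakly
  lab <- vapply(scores, function(s) paste0(s$region, s$run), character(1))
  expect_gt(M[lab == "#2Orun1", lab == "#3Orun1"], 0.9)
  expect_lt(M[lab == "#2Orun1", lab == "#3Urun1"], 0.5)
})
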