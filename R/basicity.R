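## Effective-basicity scores: fractional-target penalized logistic
## regression of the conditional higher-charge probability on amino acid
## composition, per charging region and run; eligibility filtering;
## cross-region score correlations; robust (Huber) mass adjustment.

#' Basicity regression configuration
#'
#' @param lambda L2 penalty strength on the 40 feature coefficients
#'   (intercept unpenalized), default 0.01.
#' @param delta Huber parameter of the mass-adjustment regression
#'   (default 0.01): quadratic within `delta`, linear beyond.
#' @param eligibility_threshold A region-run pair is fitted only when the
#'   number of member peptides with strictly positive probability on both
#'   charge states exceeds this (strict; default 100).
#' @param tol Optimizer convergence tolerance (gradient norm).
#' @param max_iter Maximum Newton iterations.
#' @return Object of class `basicity_config`.
#' @export
basicity_config <- function(lambda = 0.01, delta = 0.01,
                            eligibility_threshold = 100L,
                            tol = 1e-8, max_iter = 100L) {
  stopifnot(lambda >= 0, delta > 0, eligibility_threshold >= 0)
  structure(list(lambda = lambda, delta = delta,
                 eligibility_threshold = as.integer(eligibility_threshold),
                 tol = tol, max_iter = as.integer(max_iter)),
            class = "basicity_config")
}

#' Feature names of the basicity regression
#'
#' 20 amino acid counts (`count_A`..`count_Y`; the C slot is "C*", the
#' run's fixed cysteine chemistry) followed by 20 N-terminal identity
#' indicators (`nterm_A`..`nterm_Y`).
#' @return Character vector of length 40.
#' @export
basicity_feature_names <- function() {
  c(paste0("count_", AMINO_ACIDS), paste0("nterm_", AMINO_ACIDS))
}

#' Build the 40-dimensional feature vector of a peptide
#'
#' 20 amino acid counts plus 20 binary indicators for the N-terminal
#' residue identity (exactly one set). Modified cysteines occupy the
#' single C ("C*") slot.
#'
#' @param p A [peptide()] or plain sequence string.
#' @return Named numeric vector of length 40; counts sum to the sequence
#'   length.
#' @export
build_features <- function(p) {
  if (is.character(p)) p <- parse_peptide(p)
  counts <- tabulate(match(p$residues, AMINO_ACIDS), 20)
  nterm <- as.numeric(AMINO_ACIDS == p$residues[1])
  stats::setNames(c(counts, nterm), basicity_feature_names())
}

## feature matrix for a vector of modified-sequence strings
feature_matrix <- function(mod_sequences) {
  X <- t(vapply(mod_sequences, function(s) build_features(s),
                numeric(40)))
  rownames(X) <- NULL
  X
}

#' Is a region-run dataset eligible for fitting?
#'
#' @param region_data Data frame from [region_table()] (needs column
#'   `both_nonzero`).
#' @param cfg A [basicity_config()].
#' @return `TRUE` iff the count of members with strictly positive
#'   probability on both charge states exceeds the threshold (strict).
#' @export
region_eligible <- function(region_data, cfg = basicity_config()) {
  sum(region_data$both_nonzero) > cfg$eligibility_threshold
}

## penalized fractional-target cross-entropy: objective, gradient, Hessian
## theta = c(intercept, beta); penalty lambda * sum(beta^2)
bce_objective <- function(theta, X, y, lambda) {
  eta <- theta[1] + X %*% theta[-1]
  ## -[y*eta - log(1+e^eta)] summed, + penalty
  sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) + lambda * sum(theta[-1]^2)
}

bce_gradient <- function(theta, X, y, lambda) {
  eta <- as.vector(theta[1] + X %*% theta[-1])
  f <- stats::plogis(eta)
  r <- f - y
  c(sum(r), as.vector(crossprod(X, r)) + 2 * lambda * theta[-1])
}

#' Fit effective basicity scores for one region-run dataset
#'
#' Minimizes the fractional-target binary cross entropy
#' `sum(-y*log f(eta) - (1-y)*log(1-f(eta)))` with `eta = intercept +
#' X beta` and an L2 penalty `lambda * ||beta||^2` (intercept
#' unpenalized), by damped Newton iteration on the convex objective.
#' Fractional targets `y` in `[0, 1]` (including exact 0/1) are
#' supported.
#'
#' @param region_data Data frame from [region_table()]: columns `sequence`
#'   or `modifications` (features are built from the modified sequence),
#'   `y`, `both_nonzero`.
#' @param cfg A [basicity_config()].
#' @param region_label,run_id Metadata carried into the result.
#' @param check_eligibility Refuse ineligible datasets (default `TRUE`).
#' @param both_nonzero_only If `TRUE`, restrict the fit to rows with
#'   strictly positive probability on both charge states; the default
#'   keeps all members (target defined whenever `p_k + p_{k+1} > 0`).
#' @return Object of class `basicity_scores`: list with `intercept`,
#'   `beta` (named, length 40), `region`, `run`, `n`, `converged`,
#'   `iterations`, `gradient_norm`.
#' @export
fit_effective_basicity <- function(region_data, cfg = basicity_config(),
                                   region_label = NA_character_,
                                   run_id = NA_character_,
                                   check_eligibility = TRUE,
                                   both_nonzero_only = FALSE) {
  if (check_eligibility && !region_eligible(region_data, cfg))
    stop(sprintf("region-run dataset ineligible: %d both-nonzero members (need > %d)",
                 sum(region_data$both_nonzero), cfg$eligibility_threshold))
  if (both_nonzero_only) region_data <- region_data[region_data$both_nonzero, ]
  seqs <- if ("modifications" %in% names(region_data))
    region_data$modifications else region_data$sequence
  X <- feature_matrix(seqs)
  y <- region_data$y
  stopifnot(all(y >= 0 & y <= 1))
  theta <- numeric(41)
  pen <- c(0, rep(2 * cfg$lambda, 40))
  converged <- FALSE
  iter <- 0L
  gnorm <- Inf
  while (iter < cfg$max_iter) {
    iter <- iter + 1L
    eta <- as.vector(theta[1] + X %*% theta[-1])
    f <- stats::plogis(eta)
    g <- bce_gradient(theta, X, y, cfg$lambda)
    gnorm <- sqrt(sum(g^2))
    if (gnorm < cfg$tol) { converged <- TRUE; break }
    w <- pmax(f * (1 - f), 1e-12)
    Xi <- cbind(1, X)
    H <- crossprod(Xi * sqrt(w)) + diag(pen, 41)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) stop("Hessian solve failed (degenerate design)")
    ## damped Newton: halve until the objective decreases
    f0 <- bce_objective(theta, X, y, cfg$lambda)
    alpha <- 1
    repeat {
      cand <- theta - alpha * step
      if (bce_objective(cand, X, y, cfg$lambda) <= f0 + 1e-12 || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    theta <- as.vector(theta - alpha * step)
  }
  theta <- unname(as.vector(theta))
  if (!converged && gnorm > 1e-6)
    stop(sprintf("effective-basicity fit did not converge (|grad| = %.3g after %d iterations)",
                 gnorm, iter))
  structure(list(intercept = theta[1],
                 beta = stats::setNames(theta[-1], basicity_feature_names()),
                 region = region_label, run = run_id, n = nrow(X),
                 converged = converged, iterations = iter,
                 gradient_norm = gnorm),
            class = "basicity_scores")
}

## the 17 nonbasic amino-acid count coefficients of a score set
nonbasic_coefs <- function(scores) {
  scores$beta[paste0("count_", NONBASIC_AMINO_ACIDS)]
}

#' Pearson correlation between two score sets
#'
#' Computed over exactly the 17 nonbasic amino-acid count coefficients
#' (R, K, H excluded).
#'
#' @param scoresA,scoresB `basicity_scores` objects.
#' @return Pearson r in `[-1, 1]`, or `NA` if either side has zero
#'   variance.
#' @export
score_correlation <- function(scoresA, scoresB) {
  a <- nonbasic_coefs(scoresA)
  b <- nonbasic_coefs(scoresB)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Correlation matrix over a list of region-run score sets
#'
#' @param scores_list List of `basicity_scores`.
#' @return Symmetric matrix with unit diagonal; dimnames are
#'   `"region/run"` labels.
#' @export
correlation_matrix <- function(scores_list) {
  stopifnot(length(scores_list) >= 2L)
  n <- length(scores_list)
  labs <- vapply(scores_list, function(s) paste(s$region, s$run, sep = "/"),
                 character(1))
  M <- diag(1, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    M[i, j] <- M[j, i] <- score_correlation(scores_list[[i]], scores_list[[j]])
  }
  dimnames(M) <- list(labs, labs)
  M
}

## Huber loss regression y ~ a + b x by iteratively reweighted least
## squares with fixed delta (no scale re-estimation).
huber_fit <- function(x, y, delta, tol = 1e-10, max_iter = 500L) {
  if (stats::sd(x) == 0) stop("degenerate mass vector")
  X <- cbind(1, x)
  beta <- solve(crossprod(X), crossprod(X, y))  # OLS start
  for (i in seq_len(max_iter)) {
    r <- as.vector(y - X %*% beta)
    w <- ifelse(abs(r) <= delta, 1, delta / abs(r))
    beta_new <- solve(crossprod(X * w, X), crossprod(X * w, y))
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  as.vector(beta)
}

#' Mass-adjusted effective basicity scores
#'
#' Removes the portion of the 17 nonbasic amino-acid scores explained by
#' residue mass: the residuals of a robust linear regression (Huber loss
#' with fixed `delta`, solved by IRLS) of score on residue monoisotopic
#' mass plus an intercept. The cysteine mass is the modified C* mass of
#' the run's chemistry.
#'
#' @param scores A `basicity_scores` object.
#' @param cfg A [basicity_config()] (supplies `delta`).
#' @param modified_c Cysteine chemistry of the run, as in
#'   [residue_masses()].
#' @return Named vector of 17 residuals (mass-adjusted scores).
#' @export
mass_adjust <- function(scores, cfg = basicity_config(),
                        modified_c = "carbamidomethyl") {
  s <- nonbasic_coefs(scores)
  m <- residue_masses(modified_c)[NONBASIC_AMINO_ACIDS]
  beta <- huber_fit(m, s, cfg$delta)
  stats::setNames(s - (beta[1] + beta[2] * m), NONBASIC_AMINO_ACIDS)
}
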