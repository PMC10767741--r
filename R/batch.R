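## Total-variation error between CSDs and the one-parameter multiplicative
## batch correction between run pairs.

check_simplex <- function(p, tol = 1e-6) {
  if (any(!is.finite(p)) || any(p < -tol) || abs(sum(p) - 1) > tol)
    stop("input is not a probability simplex vector")
  invisible(TRUE)
}

#' Total variation between two CSDs
#'
#' Half the sum of absolute differences between the two probability
#' vectors: 0 for identical distributions, 1 for disjoint supports.
#'
#' @param p,q Probability vectors of equal length.
#' @return Value in `[0, 1]`.
#' @export
total_variation <- function(p, q) {
  if (length(p) != length(q)) stop("p and q must have equal length")
  check_simplex(p)
  check_simplex(q)
  sum(abs(p - q)) / 2
}

#' Batch parameters
#'
#' A run-pair batch effect is modelled by a single scalar `gamma > 0`;
#' `gamma = 1` is the identity.
#'
#' @param gamma Positive scalar.
#' @return Object of class `batch_params` with fields `gamma`, `log_gamma`.
#' @export
batch_params <- function(gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma <= 0)
    stop("gamma must be a positive finite scalar")
  structure(list(gamma = gamma, log_gamma = log(gamma)), class = "batch_params")
}

#' Apply the one-parameter batch correction to a CSD
#'
#' Scales the probability of charge state k by `gamma^k` and renormalizes.
#' Equivalently, shifts every consecutive log-odds
#' `log(p[k+1]/p[k])` by `log(gamma)`. The transform forms a group:
#' identity at `gamma = 1`, composition multiplies gammas, `1/gamma`
#' inverts. Zero entries are preserved.
#'
#' @param p CSD simplex vector over charges `1..length(p)`.
#' @param b A [batch_params()] object or a positive scalar gamma.
#' @return Transformed CSD simplex vector.
#' @export
apply_batch_correction <- function(p, b) {
  if (is.numeric(b)) b <- batch_params(b)
  check_simplex(p)
  k <- seq_along(p)
  ## work on the log scale to stay finite for extreme gamma^k
  logw <- log(p) + k * b$log_gamma
  m <- max(logw[p > 0])
  w <- ifelse(p > 0, exp(logw - m), 0)
  w / sum(w)
}

csd_matrix <- function(tab) {
  as.matrix(tab[, c("p1", "p2", "p3", "p4", "p5")])
}

## Average duplicate readings within a run and pair shared peptides between
## two CSD tables by (sequence, modifications).
pair_shared_csds <- function(tableA, tableB) {
  key <- function(tab) paste(tab$sequence, tab$modifications, sep = "\r")
  avg <- function(tab) {
    k <- key(tab)
    m <- rowsum(csd_matrix(tab), k)        # sums per key, sorted by key
    m <- m / as.vector(table(k)[rownames(m)])
    m / rowSums(m)                         # renormalize averaged duplicates
  }
  A <- avg(tableA)
  B <- avg(tableB)
  shared <- intersect(rownames(A), rownames(B))
  if (length(shared) < 1L) stop("no shared peptides between the two runs")
  list(A = A[shared, , drop = FALSE], B = B[shared, , drop = FALSE])
}

batch_objective <- function(log_gamma, A, B) {
  k <- seq_len(ncol(A))
  logw <- sweep(log(A), 2, k * log_gamma, `+`)
  m <- apply(logw, 1, function(r) max(r[is.finite(r)]))
  w <- exp(logw - m)
  w[A == 0] <- 0
  Acorr <- w / rowSums(w)
  sum(abs(Acorr - B)) / 2
}

#' Fit the batch parameter between two runs
#'
#' Chooses gamma to minimize the total error: the sum of total variation
#' between the corrected CSDs of run A and the CSDs of run B over all
#' peptides shared between both runs (duplicate readings within a run are
#' averaged first). A coarse grid on `log(gamma)` in `[-3, 3]` (step 0.01)
#' is refined by golden-section/parabolic search.
#'
#' @param tableA,tableB CSD tables (data frames with columns `sequence`,
#'   `modifications`, `p1`..`p5`).
#' @return List with `params` ([batch_params()]), `uncorrected_error` and
#'   `corrected_error` (both the summed total variation), plus the shared
#'   peptide count `n_shared`.
#' @export
fit_gamma <- function(tableA, tableB) {
  sh <- pair_shared_csds(tableA, tableB)
  ## degenerate case: every shared CSD is a point mass, objective is flat
  if (all(rowSums(sh$A > 0) == 1L)) {
    warning("all shared CSDs are point masses; objective flat, gamma = 1")
    err <- sum(abs(sh$A - sh$B)) / 2
    return(list(params = batch_params(1), uncorrected_error = err,
                corrected_error = err, n_shared = nrow(sh$A)))
  }
  grid <- seq(-3, 3, by = 0.01)
  vals <- vapply(grid, batch_objective, numeric(1), A = sh$A, B = sh$B)
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(batch_objective, c(lo, hi), A = sh$A, B = sh$B,
                         tol = 1e-10)
  uncorrected <- batch_objective(0, sh$A, sh$B)
  corrected <- opt$objective
  if (uncorrected < corrected) {  # guard: grid/refine can never beat gamma=1 by construction
    opt$minimum <- 0
    corrected <- uncorrected
  }
  list(params = batch_params(exp(opt$minimum)),
       uncorrected_error = uncorrected,
       corrected_error = corrected,
       n_shared = nrow(sh$A))
}

#' Mean total variation between two runs over shared peptides
#'
#' @param tableA,tableB CSD tables.
#' @param corrected If `TRUE`, run A is first batch-corrected with the
#'   fitted gamma from [fit_gamma()].
#' @return Arithmetic mean of per-peptide total variation.
#' @export
run_pair_error <- function(tableA, tableB, corrected = FALSE) {
  sh <- pair_shared_csds(tableA, tableB)
  lg <- if (corrected) fit_gamma(tableA, tableB)$params$log_gamma else 0
  batch_objective(lg, sh$A, sh$B) / nrow(sh$A)
}
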