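## Mean charge, under/exact/over-charging classification, dataset regime
## summaries, mass-trend curves and charging-region assignment.

#' Mean charge of a CSD
#'
#' @param p CSD simplex vector over charges 1..5.
#' @return Expectation of the charge state, in `[1, 5]`.
#' @export
mean_charge <- function(p) {
  check_simplex(p)
  sum(seq_along(p) * p)
}

#' Classify a CSD against its basic-site count
#'
#' A peptide is undercharged when its mean charge is below the basic-site
#' count `b` (beyond tolerance `epsilon`), overcharged when above, exact
#' otherwise. The `pure` flag records whether the CSD is (numerically) a
#' point mass on the charge equal to `b` (clipped to 5).
#'
#' @param p CSD simplex vector.
#' @param b Basic-site count (>= 0; `b = 0` classifies everything as
#'   overcharged, with a warning).
#' @param epsilon Tolerance on the mean-charge comparison (default `1e-6`).
#' @return List with `label` (`"under"`, `"exact"`, `"over"`) and `pure`.
#' @export
classify_regime <- function(p, b, epsilon = 1e-6) {
  check_simplex(p)
  if (b < 0) stop("b must be >= 0")
  if (b == 0) warning("b = 0: every CSD is overcharged by definition")
  mc <- mean_charge(p)
  label <- if (mc < b - epsilon) "under" else if (mc > b + epsilon) "over" else "exact"
  bb <- min(b, 5L)
  pure <- b > 0 && p[bb] >= 1 - epsilon
  list(label = label, pure = pure, mean_charge = mc)
}

## average duplicate readings per unique peptide, keep first b/mass
unique_peptide_csds <- function(tab) {
  k <- paste(tab$sequence, tab$modifications, sep = "\r")
  m <- rowsum(csd_matrix(tab), k)
  m <- m / as.vector(table(k)[rownames(m)])
  m <- m / rowSums(m)
  first <- !duplicated(k)
  meta <- tab[first, , drop = FALSE]
  meta <- meta[match(rownames(m), k[first]), , drop = FALSE]
  list(csd = m, basic_sites = meta$basic_sites, mass = meta$mass,
       sequence = meta$sequence, modifications = meta$modifications)
}

#' Summarize charging regimes over a CSD table
#'
#' Computed over unique peptides (duplicate readings averaged first).
#'
#' @param tab CSD table with columns `sequence`, `modifications`,
#'   `basic_sites`, `p1`..`p5`.
#' @param epsilon Mean-charge tolerance, as in [classify_regime()].
#' @return List with `fractions` (named simplex over under/exact/over),
#'   `pure_fraction`, and `n` unique peptides.
#' @export
summarize_regimes <- function(tab, epsilon = 1e-6) {
  if (nrow(tab) == 0L) stop("empty CSD table")
  u <- unique_peptide_csds(tab)
  labels <- character(nrow(u$csd))
  pure <- logical(nrow(u$csd))
  for (i in seq_len(nrow(u$csd))) {
    cl <- classify_regime(u$csd[i, ], u$basic_sites[i], epsilon)
    labels[i] <- cl$label
    pure[i] <- cl$pure
  }
  fr <- c(under = mean(labels == "under"),
          exact = mean(labels == "exact"),
          over = mean(labels == "over"))
  list(fractions = fr, pure_fraction = mean(pure), n = nrow(u$csd),
       labels = labels, pure = pure)
}

#' Binned mean-charge-versus-mass trend for one basic-site group
#'
#' The presentation-layer spline of mean charge versus mass is replaced by
#' binned means with optional isotonic (pool-adjacent-violators)
#' smoothing, which preserves the monotone structure without smoothing
#' parameters.
#'
#' @param tab CSD table.
#' @param b Basic-site group to select.
#' @param bin_width Mass bin width in Da (default 100).
#' @param monotone If `TRUE`, apply isotonic regression across bins
#'   (weighted by bin count) so the returned trend is non-decreasing.
#' @return Data frame with `mass_lo`, `mass_hi`, `mass_mid`, `mean_charge`,
#'   `n` (empty bins are dropped).
#' @export
mass_trend <- function(tab, b, bin_width = 100, monotone = FALSE) {
  u <- unique_peptide_csds(tab)
  sel <- u$basic_sites == b
  if (!any(sel)) stop(sprintf("no peptides with %d basic sites", b))
  mass <- u$mass[sel]
  mc <- apply(u$csd[sel, , drop = FALSE], 1, mean_charge)
  lo <- floor(min(mass) / bin_width) * bin_width
  bins <- floor((mass - lo) / bin_width)
  agg <- tapply(mc, bins, mean)
  cnt <- as.vector(table(bins))
  idx <- as.integer(names(agg))
  out <- data.frame(mass_lo = lo + idx * bin_width,
                    mass_hi = lo + (idx + 1) * bin_width,
                    mass_mid = lo + (idx + 0.5) * bin_width,
                    mean_charge = as.vector(agg), n = cnt)
  if (monotone && nrow(out) > 1L) {
    ## weighted PAVA via isoreg on count-replicated points would be costly;
    ## use the classic pool-adjacent-violators pass directly
    out$mean_charge <- pava(out$mean_charge, out$n)
  }
  out
}

## weighted pool-adjacent-violators (non-decreasing fit)
pava <- function(y, w) {
  val <- numeric(0); wt <- numeric(0); cnt <- integer(0)
  for (i in seq_along(y)) {
    val <- c(val, y[i]); wt <- c(wt, w[i]); cnt <- c(cnt, 1L)
    while (length(val) > 1L && val[length(val)] < val[length(val) - 1L]) {
      m <- length(val)
      pooled <- (val[m] * wt[m] + val[m - 1L] * wt[m - 1L]) / (wt[m] + wt[m - 1L])
      val[m - 1L] <- pooled
      wt[m - 1L] <- wt[m] + wt[m - 1L]
      cnt[m - 1L] <- cnt[m] + cnt[m - 1L]
      val <- val[-m]; wt <- wt[-m]; cnt <- cnt[-m]
    }
  }
  rep(val, cnt)
}

#' Charging-region specifications
#'
#' The four regions used for the effective-basicity regressions: a region
#' fixes a basic-site count `b` and a consecutive charge pair `(k, k+1)`.
#' `#2O` (b = 2, k = 2) and `#3O` (b = 3, k = 3) sit at or above the
#' basic-site count (overcharging side); `#3U` (b = 3, k = 2) and `#4U`
#' (b = 4, k = 3) below it (undercharging side).
#'
#' @param label One of `"#2O"`, `"#3O"`, `"#3U"`, `"#4U"`.
#' @return List with `label`, `b`, `k`, and `regime` (`"over"`/`"under"`).
#' @export
region_spec <- function(label = c("#2O", "#3O", "#3U", "#4U")) {
  label <- match.arg(label)
  switch(label,
    "#2O" = list(label = "#2O", b = 2L, k = 2L, regime = "over"),
    "#3O" = list(label = "#3O", b = 3L, k = 3L, regime = "over"),
    "#3U" = list(label = "#3U", b = 3L, k = 2L, regime = "under"),
    "#4U" = list(label = "#4U", b = 4L, k = 3L, regime = "under"))
}

#' @rdname region_spec
#' @export
region_specs <- function() lapply(c("#2O", "#3O", "#3U", "#4U"), region_spec)

#' Assign a CSD to a charging region and compute its conditional target
#'
#' A peptide is a member of a region when its basic-site count equals the
#' region's `b` and `p[k] + p[k+1] > 0`. The regression target is the
#' conditional probability `y = p[k+1] / (p[k] + p[k+1])` of the higher
#' charge state; `both_nonzero` (both probabilities strictly positive) is
#' recorded for the eligibility count.
#'
#' @param p CSD simplex vector.
#' @param b Basic-site count of the peptide.
#' @param spec A [region_spec()].
#' @return List with `member`; for members, `y` and `both_nonzero`.
#' @export
assign_region <- function(p, b, spec) {
  check_simplex(p)
  k <- spec$k
  if (b != spec$b || p[k] + p[k + 1L] <= 0)
    return(list(member = FALSE, y = NA_real_, both_nonzero = FALSE))
  list(member = TRUE,
       y = p[k + 1L] / (p[k] + p[k + 1L]),
       both_nonzero = p[k] > 0 && p[k + 1L] > 0)
}

#' Build a region dataset from a CSD table
#'
#' Applies [assign_region()] to every unique peptide in a run's CSD table
#' (duplicates averaged) and returns the member rows.
#'
#' @param tab CSD table.
#' @param spec A [region_spec()].
#' @return Data frame with `sequence`, `modifications`, `mass`, `y`,
#'   `both_nonzero`.
#' @export
region_table <- function(tab, spec) {
  u <- unique_peptide_csds(tab)
  k <- spec$k
  memb <- u$basic_sites == spec$b & (u$csd[, k] + u$csd[, k + 1L]) > 0
  y <- u$csd[memb, k + 1L] / (u$csd[memb, k] + u$csd[memb, k + 1L])
  data.frame(sequence = u$sequence[memb],
             modifications = u$modifications[memb],
             mass = u$mass[memb],
             y = as.vector(y),
             both_nonzero = u$csd[memb, k] > 0 & u$csd[memb, k + 1L] > 0,
             stringsAsFactors = FALSE)
}
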