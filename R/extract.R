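## CSD extraction from centroided MS1 scans: per-scan isotope-envelope
## matching with presence/absence/chimera filtering, per-scan CSD
## normalization, and intensity-weighted aggregation into one CSD per
## peptide per run. A reading is only emitted when all five charge states
## have a confident estimate (present, or confidently absent with
## intensity 0); any rejected charge state discards the whole scan.

#' Extraction configuration
#'
#' @param tolerance_ppm Peak matching tolerance in ppm (default 10).
#' @param cosine_threshold Minimum cosine similarity between theoretical
#'   and observed isotope patterns for a charge state to count as present
#'   (default 0.98).
#' @param absence_factor Absence window, as a multiple of the matching
#'   tolerance, around the two most abundant theoretical isotope positions
#'   (default 2): a charge state is absent when no peak falls inside.
#' @param chimera_frac Maximum allowed intensity of an unmatched peak
#'   inside the envelope span, as a fraction of the matched base peak
#'   (default 0.2); above this the charge state is rejected as chimeric.
#' @param min_matched Minimum matched isotope peaks for presence (default 2).
#' @param min_total_intensity Minimum summed extracted intensity for a
#'   per-scan reading to be retained (default 0).
#' @param charges Charge range, fixed at 1..5.
#' @return Object of class `extraction_config`.
#' @export
extraction_config <- function(tolerance_ppm = 10, cosine_threshold = 0.98,
                              absence_factor = 2, chimera_frac = 0.2,
                              min_matched = 2L, min_total_intensity = 0,
                              charges = 1:5) {
  stopifnot(tolerance_ppm > 0, cosine_threshold > 0, cosine_threshold <= 1,
            absence_factor > 0, chimera_frac > 0, min_matched >= 1L,
            identical(as.integer(charges), 1:5))
  structure(list(tolerance_ppm = tolerance_ppm,
                 cosine_threshold = cosine_threshold,
                 absence_factor = absence_factor,
                 chimera_frac = chimera_frac,
                 min_matched = as.integer(min_matched),
                 min_total_intensity = min_total_intensity,
                 charges = 1:5),
            class = "extraction_config")
}

#' Centroid a profile-mode scan
#'
#' Local-maximum detection over contiguous runs of nonzero intensity; each
#' peak's m/z is the intensity-weighted centroid of the points above half
#' the local maximum, and its intensity is the run's summed intensity.
#'
#' @param mz Ascending m/z vector of the profile scan.
#' @param intensity Matching intensity vector (>= 0).
#' @return List with centroided `mz` and `intensity` vectors (empty for an
#'   all-zero scan).
#' @export
centroid_profile <- function(mz, intensity) {
  stopifnot(length(mz) == length(intensity), !is.unsorted(mz))
  nz <- intensity > 0
  if (!any(nz)) return(list(mz = numeric(0), intensity = numeric(0)))
  runs <- rle(nz)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values
  cm <- numeric(0); ci <- numeric(0)
  for (r in which(keep)) {
    idx <- starts[r]:ends[r]
    imax <- max(intensity[idx])
    top <- idx[intensity[idx] >= imax / 2]
    cm <- c(cm, sum(mz[top] * intensity[top]) / sum(intensity[top]))
    ci <- c(ci, sum(intensity[idx]))
  }
  list(mz = cm, intensity = ci)
}

#' Cosine similarity between theoretical and observed isotope patterns
#'
#' Standard cosine of the two non-negative vectors; scale-invariant in
#' each argument. An all-zero observed vector is reported as 0.
#'
#' @param theoretical,observed Equal-length non-negative vectors.
#' @return Value in `[0, 1]`.
#' @export
cosine_similarity <- function(theoretical, observed) {
  stopifnot(length(theoretical) == length(observed), length(theoretical) >= 1)
  if (any(theoretical < 0) || any(observed < 0)) stop("negative entries")
  no <- sqrt(sum(observed^2))
  if (no == 0) return(0)
  sum(theoretical * observed) / (sqrt(sum(theoretical^2)) * no)
}

#' Match one theoretical isotope envelope against a centroided scan
#'
#' For each isotope index the nearest peak within the ppm tolerance is
#' taken. The charge state is `present` when at least `min_matched`
#' isotopes match, the cosine between the full theoretical envelope and
#' the observed pattern (zeros at unmatched indices) reaches the
#' threshold, and no unmatched peak inside the envelope span exceeds
#' `chimera_frac` of the matched base peak. It is `absent` when no peak
#' lies within the absence window of the two most abundant isotope
#' positions. Otherwise it is `rejected`. The intensity estimate of a
#' present state is the summed matched intensity divided by the summed
#' theoretical abundance of the matched indices (completeness
#' correction); absent states have intensity 0.
#'
#' @param scan List with ascending `mz` and `intensity` vectors.
#' @param envelope Theoretical abundance vector from [isotope_envelope()].
#' @param mass Monoisotopic mass, Da.
#' @param k Charge state.
#' @param cfg An [extraction_config()].
#' @return List with `status` (`"present"`, `"absent"`, `"rejected"`),
#'   `intensity`, `cosine`, `max_ppm`, `matched` (observed intensities per
#'   isotope index) and `chimera` flag.
#' @export
match_envelope <- function(scan, envelope, mass, k, cfg = extraction_config()) {
  J <- length(envelope)
  pos <- (mass + k * PROTON_MASS + (seq_len(J) - 1L) * ISOTOPE_SPACING) / k
  tol <- pos * cfg$tolerance_ppm * 1e-6
  mz <- scan$mz
  res <- list(status = "rejected", intensity = 0, cosine = NA_real_,
              max_ppm = NA_real_, matched = rep(NA_real_, J), chimera = FALSE)
  if (length(mz) == 0L) {
    res$status <- "absent"
    res$matched <- rep(0, J)
    return(res)
  }
  ## nearest peak per isotope position
  idx <- findInterval(pos, mz)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(mz))
  d_lo <- abs(mz[lo] - pos)
  d_hi <- abs(mz[hi] - pos)
  nearest <- ifelse(d_lo <= d_hi, lo, hi)
  dist <- pmin(d_lo, d_hi)
  hit <- dist <= tol
  ## absence: no peak within the absence window of the two most abundant
  ## isotope positions
  top2 <- order(envelope, decreasing = TRUE)[1:min(2L, J)]
  if (all(dist[top2] > cfg$absence_factor * tol[top2])) {
    res$status <- "absent"
    res$matched <- rep(0, J)
    return(res)
  }
  obs <- ifelse(hit, scan$intensity[nearest], 0)
  matched_idx <- unique(nearest[hit])
  nmatched <- sum(hit)
  res$matched <- obs
  res$cosine <- cosine_similarity(envelope, obs)
  res$max_ppm <- if (nmatched) max(dist[hit] / pos[hit]) * 1e6 else NA_real_
  ## chimera: any unmatched peak inside the envelope span above the
  ## relative-intensity threshold
  if (nmatched) {
    span <- c(pos[1] - cfg$absence_factor * tol[1],
              pos[J] + cfg$absence_factor * tol[J])
    inside <- which(mz >= span[1] & mz <= span[2])
    stray <- setdiff(inside, matched_idx)
    base_peak <- max(obs)
    if (length(stray) && any(scan$intensity[stray] > cfg$chimera_frac * base_peak))
      res$chimera <- TRUE
  }
  if (!res$chimera && nmatched >= cfg$min_matched &&
      res$cosine >= cfg$cosine_threshold) {
    res$status <- "present"
    res$intensity <- sum(obs[hit]) / sum(envelope[hit])
  }
  res
}

#' Extract a single scan's CSD for one peptide
#'
#' Runs [match_envelope()] for charges 1..5. If any charge state is
#' rejected, or all five are absent, the scan contributes nothing;
#' otherwise the present intensities (0 for absent) are normalized to a
#' per-scan CSD.
#'
#' @param scan List with ascending `mz` and `intensity` vectors.
#' @param envelope Theoretical abundance vector.
#' @param mass Monoisotopic mass, Da.
#' @param cfg An [extraction_config()].
#' @return List with `accepted`; when accepted, `csd` (simplex over 1..5)
#'   and `total_intensity`.
#' @export
extract_scan_csd <- function(scan, envelope, mass, cfg = extraction_config()) {
  intens <- numeric(5)
  for (k in 1:5) {
    m <- match_envelope(scan, envelope, mass, k, cfg)
    if (m$status == "rejected" || m$chimera)
      return(list(accepted = FALSE, csd = NULL, total_intensity = 0))
    intens[k] <- m$intensity
  }
  total <- sum(intens)
  if (total <= 0 || total < cfg$min_total_intensity)
    return(list(accepted = FALSE, csd = NULL, total_intensity = 0))
  list(accepted = TRUE, csd = intens / total, total_intensity = total)
}

#' Intensity-weighted aggregation of per-scan CSDs
#'
#' @param csds Matrix (scans x 5) or list of per-scan CSD vectors.
#' @param weights Per-scan total extracted intensities (> 0).
#' @return Aggregated CSD simplex vector.
#' @export
aggregate_readings <- function(csds, weights) {
  if (is.list(csds)) csds <- do.call(rbind, csds)
  stopifnot(nrow(csds) >= 1L, length(weights) == nrow(csds), all(weights > 0))
  p <- colSums(csds * weights) / sum(weights)
  p / sum(p)
}

## split a long scan data frame into per-scan peak lists
split_scans <- function(scans) {
  stopifnot(all(c("scan_id", "rt", "mz", "intensity") %in% names(scans)))
  ids <- unique(scans$scan_id)
  f <- match(scans$scan_id, ids)
  mzs <- split(scans$mz, f)
  ints <- split(scans$intensity, f)
  rts <- scans$rt[!duplicated(scans$scan_id)]
  list(ids = ids, rt = rts, mz = mzs, intensity = ints)
}

#' Extract one CSD reading per identified peptide from a run
#'
#' For each row of the identification table, all MS1 scans inside the
#' peptide's retention window are searched; accepted per-scan CSDs are
#' combined by intensity-weighted averaging. Peptides with no accepted
#' scan are omitted. Extraction uses MS1 content only: the table's
#' `triggered_charge` column is never consulted.
#'
#' @param scans Long scan data frame (`scan_id`, `rt`, `mz`, `intensity`)
#'   or a list as returned in `simulate_run()$scans`.
#' @param id_table Identification table with columns `run`, `sequence`,
#'   `modifications`, `rt_start`, `rt_stop` (and, unused, `triggered_charge`).
#' @param cfg An [extraction_config()].
#' @param verbose Log per-filter rejection counts.
#' @return CSD table: data frame with `run`, `sequence`, `modifications`,
#'   `mass`, `basic_sites`, `p1`..`p5`, `n_scans`, `total_intensity`.
#' @export
extract_run <- function(scans, id_table, cfg = extraction_config(),
                        verbose = FALSE) {
  sp <- split_scans(scans)
  rows <- vector("list", nrow(id_table))
  n_scan_rej <- 0L
  for (r in seq_len(nrow(id_table))) {
    if (is.na(id_table$rt_start[r]) || is.na(id_table$rt_stop[r])) {
      warning(sprintf("row %d (%s): missing retention window, skipped",
                      r, id_table$sequence[r]))
      next
    }
    p <- parse_peptide(id_table$modifications[r])
    cm <- composition_and_mass(p)
    env <- isotope_envelope(cm$composition)
    in_win <- which(sp$rt >= id_table$rt_start[r] & sp$rt <= id_table$rt_stop[r])
    if (!length(in_win)) next
    csds <- vector("list", length(in_win))
    wts <- numeric(length(in_win))
    acc <- 0L
    for (s in in_win) {
      scan <- list(mz = sp$mz[[s]], intensity = sp$intensity[[s]])
      res <- extract_scan_csd(scan, env, cm$mass, cfg)
      if (res$accepted) {
        acc <- acc + 1L
        csds[[acc]] <- res$csd
        wts[acc] <- res$total_intensity
      } else n_scan_rej <- n_scan_rej + 1L
    }
    if (acc == 0L) next
    agg <- aggregate_readings(csds[seq_len(acc)], wts[seq_len(acc)])
    rows[[r]] <- data.frame(run = id_table$run[r],
                            sequence = p$sequence,
                            modifications = write_peptide(p),
                            mass = cm$mass,
                            basic_sites = count_basic_sites(p),
                            p1 = agg[1], p2 = agg[2], p3 = agg[3],
                            p4 = agg[4], p5 = agg[5],
                            n_scans = acc,
                            total_intensity = sum(wts[seq_len(acc)]),
                            stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(run = character(0), sequence = character(0),
               modifications = character(0), mass = numeric(0),
               basic_sites = integer(0), p1 = numeric(0), p2 = numeric(0),
               p3 = numeric(0), p4 = numeric(0), p5 = numeric(0),
               n_scans = integer(0), total_intensity = numeric(0))
  rownames(out) <- NULL
  if (verbose)
    message(sprintf("extract_run: %d/%d peptides emitted, %d scans rejected",
                    nrow(out), nrow(id_table), n_scan_rej))
  out
}
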