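## Synthetic peptides with planted ground-truth CSDs, and rendering of
## synthetic MS1 runs (noise, chimeras, intensity threshold, m/z window,
## batch effects) so every downstream stage has a test bed with known truth.

#' Planted ground-truth CSD model
#'
#' CSDs are generated from the same sequential log-odds structure the
#' inference stage estimates: for each consecutive charge pair (k, k+1),
#' `log(p[k+1]/p[k]) = a[k] + w_mass * mass + w_bs * max(0, b - k) +
#' sum(beta_aa * counts) + beta_nt[first residue]`, with the per-residue
#' and N-terminal scores drawn from an "under" set when the pair sits
#' below the basic-site count (k < b) and an "over" set otherwise.
#' Probabilities over charges 1..5 follow by normalizing the cumulative
#' log-odds (softmax).
#'
#' The defaults are fixtures chosen to reproduce, qualitatively, the
#' charging phenomenology of tryptic peptides in positive-mode ESI: mean
#' charge increasing with mass; an under-to-over transition whose mass
#' location rises with basic-site count; basic sites mattering in the
#' undercharging but not the overcharging regime; glutamine raising and
#' aspartate lowering charging on the over side; N-terminal R/K/H
#' suppressing and proline promoting charging on the under side.
#'
#' @param a Intercepts for pairs k = 1..4 (log-odds).
#' @param w_mass Mass coefficient (log-odds per Da), shared across pairs.
#' @param w_bs Coefficient per remaining basic site, applied as
#'   `w_bs * max(0, b - k)`.
#' @param beta_aa_under,beta_aa_over Named per-residue scores (log-odds per
#'   residue count) for under/over pairs; unnamed residues are 0.
#' @param beta_nt_under,beta_nt_over Named N-terminal identity scores.
#' @return Object of class `ground_truth_model`.
#' @export
ground_truth_model <- function(a = -0.0067 * c(800, 1710, 2600, 3500),
                               w_mass = 0.0067,
                               w_bs = 3.0,
                               beta_aa_under = c(P = 0.6, G = -0.35, S = -0.25, T = 0.25),
                               beta_aa_over = c(Q = 0.6, D = -0.6, E = -0.35, N = -0.25,
                                                A = 0.35, V = 0.35, I = 0.35, L = 0.35),
                               beta_nt_under = c(R = -0.8, K = -0.8, H = -0.8, P = 0.4),
                               beta_nt_over = numeric(0)) {
  expand <- function(v) {
    full <- stats::setNames(numeric(20), AMINO_ACIDS)
    if (length(v)) full[names(v)] <- v
    full
  }
  stopifnot(length(a) == 4, is.finite(a), is.finite(w_mass), is.finite(w_bs))
  structure(list(a = a, w_mass = w_mass, w_bs = w_bs,
                 beta_aa_under = expand(beta_aa_under),
                 beta_aa_over = expand(beta_aa_over),
                 beta_nt_under = expand(beta_nt_under),
                 beta_nt_over = expand(beta_nt_over)),
            class = "ground_truth_model")
}

## consecutive log-odds eta_k for k = 1..4 of one peptide
model_log_odds <- function(p, model,
                           mass = peptide_mass(p),
                           b = count_basic_sites(p)) {
  counts <- stats::setNames(tabulate(match(p$residues, AMINO_ACIDS), 20), AMINO_ACIDS)
  nt <- p$residues[1]
  eta <- numeric(4)
  for (k in 1:4) {
    regime_under <- k < b
    baa <- if (regime_under) model$beta_aa_under else model$beta_aa_over
    bnt <- if (regime_under) model$beta_nt_under else model$beta_nt_over
    eta[k] <- model$a[k] + model$w_mass * mass + model$w_bs * max(0, b - k) +
      sum(baa * counts) + bnt[[nt]]
  }
  eta
}

#' Ground-truth CSD of a peptide under a planted model
#'
#' @param p A [peptide()].
#' @param model A [ground_truth_model()].
#' @return CSD simplex vector over charges 1..5 (deterministic; computed
#'   with log-sum-exp, finite for cumulative log-odds up to about 500).
#' @export
ground_truth_csd <- function(p, model = ground_truth_model()) {
  eta <- model_log_odds(p, model)
  logp <- c(0, cumsum(eta))
  logp <- logp - max(logp)
  w <- exp(logp)
  w / sum(w)
}

#' Run-simulation configuration
#'
#' @param seed Integer seed for all randomness of the run.
#' @param scans_per_peptide MS1 scans over which each peptide elutes
#'   (default 40: an ~40 s elution at ~1 Hz MS1 rate).
#' @param noise_sd Log-scale sd of multiplicative intensity noise, applied
#'   per (peptide, scan, charge state) so the isotope-envelope shape is
#'   preserved (isotope ratios are chemistry, not spray noise).
#' @param intensity_meanlog,intensity_sdlog Log-normal parameters of the
#'   per-peptide base intensity (arbitrary units).
#' @param threshold Instrument intensity threshold; peaks below it are not
#'   recorded.
#' @param chimera_rate Probability per peptide-scan of injecting one
#'   interfering (chimeric) peak inside a matched envelope's span.
#' @param mz_window Acquisition window in Th (default `c(300, 1800)`).
#' @param gamma Batch parameter of the run (> 0; 1 = reference conditions).
#' @param rt_step Seconds between consecutive MS1 scans.
#' @return Object of class `run_sim_config`.
#' @export
run_sim_config <- function(seed = 1L, scans_per_peptide = 40L, noise_sd = 0.2,
                           intensity_meanlog = log(1e6), intensity_sdlog = 1,
                           threshold = 0, chimera_rate = 0.05,
                           mz_window = c(300, 1800), gamma = 1, rt_step = 1) {
  stopifnot(scans_per_peptide >= 1L, noise_sd >= 0, threshold >= 0,
            chimera_rate >= 0, chimera_rate <= 1,
            length(mz_window) == 2L, mz_window[1] < mz_window[2], gamma > 0)
  structure(list(seed = as.integer(seed), scans_per_peptide = as.integer(scans_per_peptide),
                 noise_sd = noise_sd, intensity_meanlog = intensity_meanlog,
                 intensity_sdlog = intensity_sdlog, threshold = threshold,
                 chimera_rate = chimera_rate, mz_window = mz_window,
                 gamma = gamma, rt_step = rt_step),
            class = "run_sim_config")
}

## default internal residue frequencies for the sampler: roughly natural
## abundances, with internal K/R suppressed to a missed-cleavage level and
## H at its natural rate.
SAMPLER_INTERNAL_FREQ <- c(
  A = 0.090, C = 0.015, D = 0.055, E = 0.070, F = 0.040, G = 0.070,
  H = 0.025, I = 0.060, K = 0.010, L = 0.100, M = 0.025, N = 0.040,
  P = 0.050, Q = 0.045, R = 0.010, S = 0.070, T = 0.060, V = 0.070,
  W = 0.012, Y = 0.033
)

#' Sample synthetic tryptic-like peptides
#'
#' Sequences of length 7-40 with internal residues drawn from a fixed
#' frequency table (internal K/R at missed-cleavage levels), a C-terminal
#' K/R except for a configurable non-tryptic fraction, carbamidomethyl on
#' every cysteine, occasional methionine oxidation and N-terminal
#' acetylation. Candidates are rejection-sampled to monoisotopic mass in
#' `[700, 4600]` Da and - because the study population consists of
#' peptides whose CSDs are measurable - to full observability: every
#' charge state carrying ground-truth probability of at least `obs_cutoff`
#' must have its whole isotope envelope inside the m/z window.
#'
#' @param n Number of peptides.
#' @param seed Integer seed (the global RNG state is restored on exit).
#' @param model Planted model used for the observability check.
#' @param mz_window Acquisition window, Th.
#' @param mass_range Mass acceptance range, Da.
#' @param nontryptic_frac Fraction of candidates with a non-K/R C-terminus.
#' @param acetyl_frac Probability of N-terminal acetylation.
#' @param oxidation_frac Per-methionine probability of oxidation.
#' @param obs_cutoff Ground-truth probability below which a clipped charge
#'   state is considered negligible (default `1e-7`).
#' @return List of [peptide()] objects (deterministic given `seed`).
#' @export
sample_peptides <- function(n, seed, model = ground_truth_model(),
                            mz_window = c(300, 1800),
                            mass_range = c(700, 4600),
                            nontryptic_frac = 0.05, acetyl_frac = 0.03,
                            oxidation_frac = 0.1, obs_cutoff = 1e-7) {
  stopifnot(n >= 1)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  lengths_support <- 7:40
  length_weights <- exp(-0.08 * lengths_support)
  out <- vector("list", n)
  got <- 0L
  while (got < n) {
    L <- sample(lengths_support, 1L, prob = length_weights)
    cterm <- if (stats::runif(1) < nontryptic_frac)
      sample(setdiff(AMINO_ACIDS, c("K", "R")), 1L)
    else sample(c("K", "R"), 1L)
    internal <- sample(names(SAMPLER_INTERNAL_FREQ), L - 1L, replace = TRUE,
                       prob = SAMPLER_INTERNAL_FREQ)
    seq_chars <- c(internal, cterm)
    mods <- list()
    if (stats::runif(1) < acetyl_frac)
      mods[[length(mods) + 1L]] <- data.frame(pos = 0L, name = "acetyl-Nterm")
    for (i in which(seq_chars == "C"))
      mods[[length(mods) + 1L]] <- data.frame(pos = i, name = "carbamidomethyl-C")
    for (i in which(seq_chars == "M"))
      if (stats::runif(1) < oxidation_frac)
        mods[[length(mods) + 1L]] <- data.frame(pos = i, name = "oxidation-M")
    cand <- peptide(paste(seq_chars, collapse = ""),
                    if (length(mods)) do.call(rbind, mods) else NULL)
    cm <- composition_and_mass(cand)
    if (cm$mass < mass_range[1] || cm$mass > mass_range[2]) next
    csd <- ground_truth_csd(cand, model)
    env <- isotope_envelope(cm$composition)
    J <- length(env) - 1L
    observable <- TRUE
    for (k in which(csd >= obs_cutoff)) {
      if (envelope_mz(cm$mass, k, 0) < mz_window[1] ||
          envelope_mz(cm$mass, k, J) > mz_window[2]) {
        observable <- FALSE
        break
      }
    }
    if (!observable) next
    got <- got + 1L
    cand$id <- sprintf("pep%05d", got)
    out[[got]] <- cand
  }
  out
}

#' Render a synthetic MS1 run for a peptide set
#'
#' Each peptide elutes over `scans_per_peptide` consecutive MS1 scans of
#' its own (retention windows do not overlap). In each scan, isotope
#' peaks are placed at the theoretical m/z positions of charges 1..5 with
#' intensity `base * q_k * abundance_j * exp(noise)`, where `q` is the
#' peptide's ground-truth CSD after the run's gamma batch transform and
#' the log-normal noise is drawn per (peptide, scan, charge). Peaks below
#' the intensity threshold or outside the m/z window are dropped. With
#' probability `chimera_rate` per peptide-scan, one interfering peak is
#' injected half an isotope spacing above a randomly chosen isotope of a
#' randomly chosen rendered charge, at half the local base-peak intensity.
#'
#' @param peptides List of [peptide()] objects.
#' @param model A [ground_truth_model()].
#' @param cfg A [run_sim_config()].
#' @param run_id Run identifier written to the id table.
#' @return List with `scans` (long data frame: `scan_id`, `rt`, `mz`,
#'   `intensity`, m/z ascending within scan), `id_table` (one row per
#'   peptide: `run`, `sequence`, `modifications`, `rt_start`, `rt_stop`,
#'   `triggered_charge`), and `truth` (ground-truth CSD matrix before the
#'   gamma transform). Pure function of (inputs, seed).
#' @export
simulate_run <- function(peptides, model = ground_truth_model(),
                         cfg = run_sim_config(), run_id = "run1") {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)
  S <- cfg$scans_per_peptide
  n <- length(peptides)
  truth <- matrix(0, n, 5, dimnames = list(NULL, paste0("p", 1:5)))
  scan_frames <- vector("list", n)
  id_rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- peptides[[i]]
    cm <- composition_and_mass(p)
    env <- isotope_envelope(cm$composition)
    J <- length(env)
    csd <- ground_truth_csd(p, model)
    truth[i, ] <- csd
    q <- apply_batch_correction(csd, cfg$gamma)
    base <- stats::rlnorm(1, cfg$intensity_meanlog, cfg$intensity_sdlog)
    ## theoretical peak grid: 5 charges x J isotopes
    mz_grid <- outer(seq_len(J) - 1L, 1:5, function(j, k) envelope_mz(cm$mass, k, j))
    scans_i <- vector("list", S)
    first_scan <- (i - 1L) * S + 1L
    for (s in seq_len(S)) {
      noise <- if (cfg$noise_sd > 0) exp(stats::rnorm(5, 0, cfg$noise_sd)) else rep(1, 5)
      inten <- base * outer(env, q * noise)       # J x 5
      mz <- as.vector(mz_grid)
      ints <- as.vector(inten)
      ## chimera injection: half a spacing above a random isotope of a
      ## random charge, at 0.5 x that envelope's local base peak
      if (cfg$chimera_rate > 0 && stats::runif(1) < cfg$chimera_rate) {
        ## interfere with an envelope that is actually observed: charge
        ## states with non-negligible probability whose peaks sit inside
        ## the acquisition window
        kk <- which(q > 1e-6 &
                      envelope_mz(cm$mass, 1:5, 0) >= cfg$mz_window[1] &
                      envelope_mz(cm$mass, 1:5, J - 1L) <= cfg$mz_window[2])
        if (length(kk)) {
          k <- kk[sample.int(length(kk), 1L)]
          j <- sample.int(J - 1L, 1L) - 1L
          cmz <- envelope_mz(cm$mass, k, j) + ISOTOPE_SPACING / (2 * k)
          cint <- 0.5 * max(inten[, k])
          mz <- c(mz, cmz)
          ints <- c(ints, cint)
        }
      }
      keep <- ints >= cfg$threshold & ints > 0 &
        mz >= cfg$mz_window[1] & mz <= cfg$mz_window[2]
      mz <- mz[keep]; ints <- ints[keep]
      ord <- order(mz)
      sid <- first_scan + s - 1L
      scans_i[[s]] <- data.frame(scan_id = rep.int(sid, length(mz)),
                                 rt = rep.int(sid * cfg$rt_step, length(mz)),
                                 mz = mz[ord], intensity = ints[ord])
    }
    scan_frames[[i]] <- do.call(rbind, scans_i)
    trig_support <- which(q[2:5] > 1e-12) + 1L
    trig <- if (length(trig_support) > 0L) {
      pr <- q[trig_support] / sum(q[trig_support])
      trig_support[sample.int(length(trig_support), 1L, prob = pr)]
    } else which.max(q)
    id_rows[[i]] <- data.frame(run = run_id, sequence = p$sequence,
                               modifications = write_peptide(p),
                               rt_start = first_scan * cfg$rt_step,
                               rt_stop = (first_scan + S - 1L) * cfg$rt_step,
                               triggered_charge = trig,
                               stringsAsFactors = FALSE)
  }
  list(scans = do.call(rbind, scan_frames),
       id_table = do.call(rbind, id_rows),
       truth = truth)
}

#' Ground-truth CSD table for a peptide set
#'
#' Builds a CSD table directly from the planted model, bypassing spectrum
#' rendering and extraction: each peptide's CSD is its ground truth,
#' optionally gamma-transformed and perturbed by log-scale noise (one
#' normal draw per charge state, renormalized) to emulate between-run
#' measurement scatter.
#'
#' @param peptides List of [peptide()] objects.
#' @param model A [ground_truth_model()].
#' @param run_id Run identifier.
#' @param gamma Batch parameter applied to every CSD.
#' @param noise_sd Log-scale sd of the per-state perturbation (0 = exact).
#' @param seed Seed for the perturbation.
#' @return CSD table in the same schema as [extract_run()].
#' @export
ground_truth_csd_table <- function(peptides, model = ground_truth_model(),
                                   run_id = "truth", gamma = 1,
                                   noise_sd = 0, seed = 1L) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  n <- length(peptides)
  P <- matrix(0, n, 5)
  mass <- numeric(n)
  bs <- integer(n)
  mods <- character(n)
  seqs <- character(n)
  for (i in seq_len(n)) {
    p <- peptides[[i]]
    csd <- ground_truth_csd(p, model)
    if (gamma != 1) csd <- apply_batch_correction(csd, gamma)
    if (noise_sd > 0) {
      w <- csd * exp(stats::rnorm(5, 0, noise_sd))
      csd <- w / sum(w)
    }
    P[i, ] <- csd
    mass[i] <- peptide_mass(p)
    bs[i] <- count_basic_sites(p)
    seqs[i] <- p$sequence
    mods[i] <- write_peptide(p)
  }
  data.frame(run = run_id, sequence = seqs, modifications = mods,
             mass = mass, basic_sites = bs,
             p1 = P[, 1], p2 = P[, 2], p3 = P[, 3], p4 = P[, 4], p5 = P[, 5],
             n_scans = 1L, total_intensity = 1,
             stringsAsFactors = FALSE)
}

#' Simulate a pair of runs sharing one peptide set
#'
#' Both runs render the identical peptide list; only seeds, gamma and
#' noise settings differ, which is the setting the batch-correction fit
#' is designed for.
#'
#' @param peptides List of [peptide()] objects.
#' @param model A [ground_truth_model()].
#' @param cfgA,cfgB [run_sim_config()]s for the two runs.
#' @return List with elements `A` and `B`, each as [simulate_run()].
#' @export
simulate_run_pair <- function(peptides, model = ground_truth_model(),
                              cfgA = run_sim_config(seed = 1L),
                              cfgB = run_sim_config(seed = 2L)) {
  stopifnot(cfgA$gamma > 0, cfgB$gamma > 0)
  list(A = simulate_run(peptides, model, cfgA, run_id = "runA"),
       B = simulate_run(peptides, model, cfgB, run_id = "runB"))
}
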