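## Readers and writers for the tabular formats, plus the end-to-end
## pipeline driver. A simple long-format scan TSV is first-class so tests
## and analyses never require mzML tooling; mzML reading is an adapter
## over mzR when that package is available.

#' Write / read the long-format scan table
#'
#' Columns: `scan_id`, `rt`, `mz`, `intensity`. Floats are written with 9
#' significant digits so files are byte-stable across identical runs.
#'
#' @param scans Long scan data frame.
#' @param path File path.
#' @return `read_scan_table()` returns the data frame, sorted by retention
#'   time then m/z.
#' @export
write_scan_table <- function(scans, path) {
  df <- scans
  df$rt <- signif(df$rt, 9)
  df$mz <- signif(df$mz, 9)
  df$intensity <- signif(df$intensity, 9)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scan_table
#' @export
read_scan_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("scan_id", "rt", "mz", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop(sprintf("scan table missing column '%s'", miss[1]))
  df[order(df$rt, df$scan_id, df$mz), need]
}

#' Read MS1 spectra from a file
#'
#' @param path Scan table TSV or an mzML file.
#' @param format `"tabular"` or `"mzML"` (mzML requires the mzR package;
#'   only MS-level-1 spectra are read, profile spectra are centroided with
#'   [centroid_profile()] when `centroid = TRUE`).
#' @param centroid Centroid profile spectra read from mzML.
#' @return Long scan data frame (`scan_id`, `rt`, `mz`, `intensity`),
#'   scans sorted by retention time, m/z ascending within scan.
#' @export
read_spectra <- function(path, format = c("tabular", "mzML"), centroid = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  if (format == "tabular") return(read_scan_table(path))
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("mzML support requires the mzR package")
  h <- NULL
  ms <- mzR::openMSfile(path)
  on.exit(mzR::close(ms))
  hdr <- mzR::header(ms)
  ms1 <- which(hdr$msLevel == 1L)
  if (!length(ms1)) stop("no MS1 scans in mzML file")
  frames <- vector("list", length(ms1))
  for (i in seq_along(ms1)) {
    pk <- mzR::peaks(ms, ms1[i])
    mz <- pk[, 1]; inten <- pk[, 2]
    if (centroid) {
      cp <- centroid_profile(mz, inten)
      mz <- cp$mz; inten <- cp$intensity
    }
    frames[[i]] <- data.frame(scan_id = hdr$acquisitionNum[ms1[i]],
                              rt = hdr$retentionTime[ms1[i]],
                              mz = mz, intensity = inten)
  }
  out <- do.call(rbind, frames)
  out[order(out$rt, out$scan_id, out$mz), ]
}

#' Read an identification table
#'
#' Accepts the simulator's TSV (`run`, `sequence`, `modifications`,
#' `rt_start`, `rt_stop`, `triggered_charge`) or a MaxQuant-evidence-like
#' header (`Raw.file`, `Sequence`, `Modified.sequence`, `Retention.time`
#' in minutes, `Retention.length`, `Charge`), which is mapped onto the
#' internal schema. Duplicate (run, peptide) rows are merged to the union
#' of their retention windows.
#'
#' @param path TSV path.
#' @return Data frame in the internal schema, one row per (run, peptide).
#' @export
read_id_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = TRUE)
  if (nrow(df) == 0L) stop("empty identification table")
  evidence_cols <- c("Raw.file", "Sequence", "Modified.sequence",
                     "Retention.time", "Retention.length", "Charge")
  if (all(evidence_cols %in% names(df))) {
    df <- data.frame(run = df$Raw.file,
                     sequence = df$Sequence,
                     modifications = df$Modified.sequence,
                     rt_start = (df$Retention.time - df$Retention.length / 2) * 60,
                     rt_stop = (df$Retention.time + df$Retention.length / 2) * 60,
                     triggered_charge = df$Charge,
                     stringsAsFactors = FALSE)
  }
  need <- c("run", "sequence", "modifications", "rt_start", "rt_stop",
            "triggered_charge")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop(sprintf("identification table missing column '%s'", miss[1]))
  key <- paste(df$run, df$sequence, df$modifications, sep = "\r")
  if (anyDuplicated(key)) {
    lo <- tapply(df$rt_start, key, min)
    hi <- tapply(df$rt_stop, key, max)
    first <- !duplicated(key)
    df <- df[first, , drop = FALSE]
    k <- key[first]
    df$rt_start <- as.vector(lo[k])
    df$rt_stop <- as.vector(hi[k])
  }
  rownames(df) <- NULL
  df[need]
}

#' Write / read a CSD table
#'
#' @param tab CSD table from [extract_run()].
#' @param path File path.
#' @return `read_csd_table()` returns the data frame.
#' @export
write_csd_table <- function(tab, path) {
  df <- tab
  for (cl in c("mass", "p1", "p2", "p3", "p4", "p5", "total_intensity"))
    df[[cl]] <- signif(df[[cl]], 9)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_csd_table
#' @export
read_csd_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("run", "sequence", "modifications", "mass", "basic_sites",
            paste0("p", 1:5), "n_scans", "total_intensity")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop(sprintf("CSD table missing column '%s'", miss[1]))
  df
}

#' Run the full synthetic pipeline: simulate, extract, classify, regress
#'
#' Thin orchestration of the package stages, returning all artifacts in
#' memory and optionally writing them as TSVs. Deterministic given the
#' configuration seeds.
#'
#' @param n_peptides Peptides to sample.
#' @param seed Master seed (peptide sampling; the run config seeds derive
#'   from it).
#' @param model A [ground_truth_model()].
#' @param sim_cfg A [run_sim_config()]; its seed is overridden by `seed + 1`.
#' @param ext_cfg An [extraction_config()].
#' @param bas_cfg A [basicity_config()].
#' @param epsilon Regime classification tolerance.
#' @param out_dir Optional directory for TSV artifacts.
#' @return List with `peptides`, `run` (scans + id table + truth), `csd`
#'   (extracted CSD table), `regimes`, `trends` (per basic-site group),
#'   `regions` (datasets), `scores` (fitted score sets for eligible
#'   regions), `correlations` (matrix or NULL), and per-stage `counts`.
#' @export
pipeline_run <- function(n_peptides = 200L, seed = 1L,
                         model = ground_truth_model(),
                         sim_cfg = run_sim_config(),
                         ext_cfg = extraction_config(),
                         bas_cfg = basicity_config(),
                         epsilon = 1e-6, out_dir = NULL) {
  peptides <- sample_peptides(n_peptides, seed, model,
                              mz_window = sim_cfg$mz_window)
  sim_cfg$seed <- as.integer(seed + 1L)
  run <- simulate_run(peptides, model, sim_cfg, run_id = sprintf("sim%d", seed))
  csd <- extract_run(run$scans, run$id_table, ext_cfg)
  reg <- summarize_regimes(csd, epsilon)
  trends <- list()
  for (b in sort(unique(csd$basic_sites))) {
    if (sum(csd$basic_sites == b) >= 5)
      trends[[as.character(b)]] <- mass_trend(csd, b, monotone = TRUE)
  }
  regions <- lapply(region_specs(), function(sp) region_table(csd, sp))
  names(regions) <- vapply(region_specs(), `[[`, character(1), "label")
  scores <- list()
  for (sp in region_specs()) {
    rd <- regions[[sp$label]]
    if (region_eligible(rd, bas_cfg)) {
      scores[[sp$label]] <- fit_effective_basicity(rd, bas_cfg,
                                                   region_label = sp$label,
                                                   run_id = unique(csd$run)[1])
    }
  }
  correlations <- if (length(scores) >= 2L) correlation_matrix(unname(scores)) else NULL
  counts <- list(peptides_in = length(peptides), readings_out = nrow(csd),
                 regions_eligible = length(scores))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_scan_table(run$scans, file.path(out_dir, "scans.tsv"))
    utils::write.table(run$id_table, file.path(out_dir, "id_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_csd_table(csd, file.path(out_dir, "csd.tsv"))
  }
  list(peptides = peptides, run = run, csd = csd, regimes = reg,
       trends = trends, regions = regions, scores = scores,
       correlations = correlations, counts = counts)
}
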