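# Shared fixtures, built in code at test time.

# cache sampled peptide sets across tests within one run
.fixture_cache <- new.env(parent = emptyenv())

fixture_peptides <- function(n, seed) {
  key <- sprintf("pep_%d_%d", n, seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- sample_peptides(n, seed)
  .fixture_cache[[key]]
}

# render a noise-free centroided scan containing exactly the isotope
# peaks of `csd` over charges 1..5 for one peptide (no window, no noise)
render_exact_scan <- function(p, csd, base = 1e6,
                              model_envelope = NULL) {
  cm <- composition_and_mass(p)
  env <- if (is.null(model_envelope)) isotope_envelope(cm$composition) else model_envelope
  mz <- c(); inten <- c()
  for (k in 1:5) {
    if (csd[k] <= 0) next
    pos <- envelope_mz(cm$mass, k, seq_along(env) - 1L)
    mz <- c(mz, pos)
    inten <- c(inten, base * csd[k] * env)
  }
  ord <- order(mz)
  list(mz = mz[ord], intensity = inten[ord])
}

# exact multinomial enumeration oracle for isotope envelopes of tiny
# compositions (<= ~10 atoms): every atom independently picks an isotope
oracle_envelope <- function(composition) {
  dists <- list()
  for (el in names(composition)) {
    n <- composition[[el]]
    if (n == 0) next
    for (i in seq_len(n)) dists[[length(dists) + 1L]] <- csdtools:::ELEMENT_ISOTOPES[[el]]
  }
  if (!length(dists)) return(1.0)
  grid <- do.call(expand.grid, lapply(dists, function(d) seq_along(d) - 1L))
  probs <- do.call(expand.grid, lapply(dists, function(d) d))
  p <- apply(as.matrix(probs), 1, prod)
  offset <- rowSums(as.matrix(grid))
  agg <- tapply(p, offset, sum)
  out <- numeric(max(offset) + 1L)
  out[as.integer(names(agg)) + 1L] <- agg
  out
}

# per-peptide total variation of an extracted table against the
# simulator's ground-truth matrix
tv_vs_truth <- function(csd_table, run) {
  idx <- match(paste(csd_table$sequence, csd_table$modifications),
               paste(run$id_table$sequence, run$id_table$modifications))
  vapply(seq_len(nrow(csd_table)), function(i) {
    p <- as.numeric(csd_table[i, paste0("p", 1:5)])
    sum(abs(p - run$truth[idx[i], ])) / 2
  }, numeric(1))
}

random_simplex <- function(n, d = 5) {
  w <- matrix(stats::rexp(n * d), n, d)
  w / rowSums(w)
}
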