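# run expr with a fixed RNG seed, restoring caller RNG state afterwards
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Baseline amino-acid frequencies
#'
#' A yeast-like average proteome composition used as the generator default.
#'
#' @return Named numeric 20-vector summing to 1.
#' @export
yeast_aa_freqs <- function() {
  c(A = 0.055, R = 0.044, N = 0.061, D = 0.058, C = 0.013, Q = 0.039,
    E = 0.064, G = 0.050, H = 0.022, I = 0.066, L = 0.096, K = 0.073,
    M = 0.021, F = 0.045, P = 0.044, S = 0.090, T = 0.059, W = 0.010,
    Y = 0.034, V = 0.056)
}

# shift prob mass onto `onto` residues (boost split equally), scaling the
# remaining residues down proportionally; result still sums to 1
.boost_freqs <- function(freqs, onto, boost) {
  if (boost <= 0) return(freqs)
  other <- setdiff(names(freqs), onto)
  freqs[onto] <- freqs[onto] + boost / length(onto)
  freqs[other] <- freqs[other] * (1 - sum(freqs[onto])) / sum(freqs[other])
  freqs / sum(freqs)
}

#' Generate a synthetic proteome with planted structure
#'
#' Emulates the features of a curated proteome that the charge-landscape
#' analyses consume: lognormal length distribution, a baseline residue
#' composition, an N-terminal K/R enrichment over chosen positions (and a
#' mild D/E enrichment elsewhere, mimicking the negative core), optional
#' signal-peptide-like hydrophobic prefixes, and optional planted
#' supercharged 30-residue stretches at a known offset. Every protein
#' starts with methionine. The planted truth is returned alongside the
#' sequences.
#'
#' Planted stretches put their charged residues at both block edges and are
#' flanked by four counter-charged residues, so the planted window start is
#' the unique first qualifying window; this localization is exact for
#' target magnitudes up to `threshold + 1` of the intended detection
#' threshold.
#'
#' @param n_proteins number of proteins.
#' @param length_meanlog,length_sdlog lognormal length parameters (aa);
#'   defaults centre near 400 aa.
#' @param min_length minimum protein length (default 60).
#' @param residue_freqs baseline composition, see [yeast_aa_freqs()].
#' @param kr_boost added K/R probability mass (split equally) at
#'   `kr_positions` (default 0.08 over positions 3..10).
#' @param kr_positions residue positions carrying the K/R boost.
#' @param de_boost added D/E probability mass at all other non-initiator
#'   positions (default 0.02).
#' @param n_supercharged number of proteins given a planted supercharged
#'   stretch.
#' @param supercharged_charge signed target net charge of the planted
#'   window (|charge| <= 30).
#' @param supercharged_offset window start (residue position) of the
#'   planted stretch; must be >= 6 to leave room for flanks.
#' @param signal_fraction fraction of proteins given a signal-peptide-like
#'   prefix (positively charged then hydrophobic, residues 2..18).
#' @param nterm_charges optional integer vector (recycled over proteins)
#'   forcing the rounded net charge of each protein's first 30 residues:
#'   the window is rebuilt as methionine plus |q| charged residues (K or E)
#'   padded with alanine, so window 1 has exactly the requested charge
#'   (|q| <= 29). `NA` entries leave the protein's natural N-terminus.
#'   Overrides the positional bias and signal prefix inside window 1.
#' @param seed RNG seed (required; generation is bit-reproducible).
#' @return List with `proteome` (a [proteome()]), `truth` (data frame:
#'   id, length, signal_peptide, planted, offset, target_charge) and
#'   `params`.
#' @export
gen_proteome <- function(n_proteins = 2000L,
                         length_meanlog = log(400), length_sdlog = 0.45,
                         min_length = 60L,
                         residue_freqs = yeast_aa_freqs(),
                         kr_boost = 0.08, kr_positions = 3:10,
                         de_boost = 0.02,
                         n_supercharged = 0L, supercharged_charge = 15L,
                         supercharged_offset = 40L,
                         signal_fraction = 0, nterm_charges = NULL, seed) {
  stopifnot(!missing(seed))
  if (!is.null(nterm_charges)) {
    stopifnot(all(abs(nterm_charges) <= 29L, na.rm = TRUE))
    nterm_charges <- rep_len(as.integer(nterm_charges), n_proteins)
  }
  if (abs(supercharged_charge) > 30L)
    stop("infeasible supercharged target: |charge| exceeds the window length")
  if (n_supercharged > 0L && supercharged_offset < 6L)
    stop("supercharged_offset must be >= 6 (room for flanking residues)")
  stopifnot(abs(sum(residue_freqs) - 1) < 1e-8)
  aa <- names(residue_freqs)
  base <- .boost_freqs(residue_freqs, c("D", "E"), de_boost)
  biased <- .boost_freqs(residue_freqs, c("K", "R"), kr_boost)
  .with_seed(seed, {
    len <- pmax(as.integer(round(stats::rlnorm(n_proteins, length_meanlog,
                                               length_sdlog))), min_length)
    planted <- rep(FALSE, n_proteins)
    if (n_supercharged > 0L) {
      planted[sample.int(n_proteins, n_supercharged)] <- TRUE
      len[planted] <- pmax(len[planted], supercharged_offset + 40L)
    }
    signal <- stats::runif(n_proteins) < signal_fraction
    seqs <- character(n_proteins)
    for (i in seq_len(n_proteins)) {
      L <- len[i]
      res <- sample(aa, L, replace = TRUE, prob = base)
      res[1L] <- "M"
      kp <- kr_positions[kr_positions >= 2L & kr_positions <= L]
      if (length(kp))
        res[kp] <- sample(aa, length(kp), replace = TRUE, prob = biased)
      if (signal[i]) {
        res[2L] <- sample(c("K", "R"), 1L)
        hyd <- sample(c("L", "A", "V", "F", "I"), 16L, replace = TRUE,
                      prob = c(0.45, 0.2, 0.15, 0.1, 0.1))
        res[3:18] <- hyd
      }
      if (!is.null(nterm_charges) && !is.na(nterm_charges[i])) {
        qn <- nterm_charges[i]
        win <- rep("A", 30L)
        win[1L] <- "M"
        if (qn != 0L)
          win[2L:(abs(qn) + 1L)] <- if (qn > 0L) "K" else "E"
        res[1:30] <- win
      }
      if (planted[i]) {
        qa <- abs(supercharged_charge)
        charged <- if (supercharged_charge > 0) "K" else "E"
        flank <- if (supercharged_charge > 0) "E" else "K"
        front <- ceiling(qa / 2); back <- qa - front
        block <- c(rep(charged, front), rep("A", 30L - qa),
                   rep(charged, back))
        o <- supercharged_offset
        res[(o - 4L):(o - 1L)] <- flank
        res[o:(o + 29L)] <- block
        res[(o + 30L):(o + 33L)] <- flank
      }
      seqs[i] <- paste(res, collapse = "")
    }
    ids <- sprintf("SYN%05d", seq_len(n_proteins))
    prot <- proteome(ids, seqs, organism = "synthetic")
    prot$has_signal_peptide <- signal
    truth <- data.frame(
      id = ids, length = len, signal_peptide = signal, planted = planted,
      offset = ifelse(planted, supercharged_offset, NA_integer_),
      target_charge = ifelse(planted, supercharged_charge, NA_integer_),
      forced_nterm_charge = if (is.null(nterm_charges)) NA_integer_
                            else nterm_charges,
      stringsAsFactors = FALSE)
    list(proteome = prot, truth = truth,
         params = list(seed = seed, kr_boost = kr_boost,
                       kr_positions = kr_positions, de_boost = de_boost,
                       length_meanlog = length_meanlog,
                       length_sdlog = length_sdlog,
                       signal_fraction = signal_fraction))
  })
}

#' Default charge-dependent occupancy multiplier
#'
#' Piecewise response of early-elongation ribosome density to the
#' N-terminal (window 1) net charge q: 1.0 for -5 <= q <= +4, rising
#' linearly to 2.0 at q >= +8, and dropping to 0.8 at q <= -6 — the shape
#' of a roughly two-fold occupancy gain for strongly basic N-termini and a
#' mild deficit for acidic ones.
#'
#' @param q integer net charge(s) of the first 30 residues.
#' @return Multiplier(s) > 0.
#' @export
occupancy_multiplier <- function(q) {
  ifelse(q >= 8, 2,
         ifelse(q > 4, 1 + (q - 4) / 4,
                ifelse(q >= -5, 1, 0.8)))
}

#' Generate per-codon ribosome count profiles with a planted charge effect
#'
#' For each protein long enough to carry a first 30-residue window, draws a
#' gene depth (mean reads/codon) from a lognormal, applies a multiplicative
#' occupancy factor `m_fun(q)` over the first `effect_codons` (codons 0..90
#' by default, mirroring the span of the exit-tunnel peptide), and draws
#' negative-binomial (default) or Poisson counts per codon. One codon per
#' residue; counts are reproducible bit-for-bit given the seed.
#'
#' The generator also derives the analytic expectation of the AUC-ratio
#' readout for each charge group: for a gene of `L` codons with multiplier
#' `m` over `e` effect codons, the expected depth-normalized occupancy over
#' the effect region is `m * L / (e * m + L - e)`, and the expected AUC
#' ratio of a group is the gene-mean of this quantity divided by that of
#' the reference group. Recovery tests compare the pipeline estimate with
#' this closed form, not with another simulation.
#'
#' @param prot a [proteome()] (e.g. from [gen_proteome()]).
#' @param table a [charge_table()] used to compute window-1 charges.
#' @param depth_meanlog,depth_sdlog lognormal parameters for the gene mean
#'   reads/codon (defaults centre at 2 reads/codon).
#' @param noise `"nb"` (negative binomial, overdispersed as is typical of
#'   profiling data) or `"poisson"`.
#' @param dispersion NB size parameter (larger = closer to Poisson).
#' @param m_fun multiplier as a function of window-1 charge.
#' @param effect_codons inclusive codon range carrying the multiplier.
#' @param scheme charge grouping used for the expectation table.
#' @param seed RNG seed (required).
#' @return List with `counts` (a `ribo_counts`), `expectation` (data frame:
#'   group, n_genes, expected_auc_ratio), `charges` (named window-1
#'   charges) and `params`.
#' @export
gen_ribo_counts <- function(prot, table = charge_table(),
                            depth_meanlog = log(2), depth_sdlog = 0.5,
                            noise = c("nb", "poisson"), dispersion = 10,
                            m_fun = occupancy_multiplier,
                            effect_codons = c(0L, 90L),
                            scheme = charge_group_scheme(), seed) {
  stopifnot(!missing(seed))
  noise <- match.arg(noise)
  keep <- nchar(prot$sequence) >= 30L
  seqs <- prot$sequence[keep]
  ids <- prot$id[keep]
  lut <- charge_lookup(table)
  q <- vapply(substr(seqs, 1L, 30L),
              function(s) sum(lut[utf8ToInt(s) - 64L]), numeric(1),
              USE.NAMES = FALSE)
  q <- round(q)
  m <- m_fun(q)
  stopifnot(all(m > 0))
  Lc <- nchar(seqs)
  .with_seed(seed, {
    lambda <- stats::rlnorm(length(ids), depth_meanlog, depth_sdlog)
    counts <- vector("list", length(ids))
    for (i in seq_along(ids)) {
      mu <- rep(lambda[i], Lc[i])
      eff <- seq(effect_codons[1] + 1L, min(effect_codons[2] + 1L, Lc[i]))
      mu[eff] <- mu[eff] * m[i]
      counts[[i]] <- if (noise == "nb")
        stats::rnbinom(Lc[i], size = dispersion, mu = mu)
      else stats::rpois(Lc[i], mu)
    }
    names(counts) <- ids
    names(q) <- ids
    # closed-form expected AUC ratio per charge group
    e <- pmin(effect_codons[2] - effect_codons[1] + 1L, Lc)
    v <- ifelse(e == Lc, 1, m * Lc / (e * m + Lc - e))
    grp <- assign_charge_group(q, scheme)
    gs <- split(v, grp)
    if (!"0" %in% names(gs))
      warning("no genes in the reference charge group '0'")
    ref <- if ("0" %in% names(gs)) mean(gs[["0"]]) else 1
    expectation <- data.frame(
      group = names(gs),
      n_genes = as.integer(lengths(gs)),
      expected_auc_ratio = vapply(gs, mean, numeric(1)) / ref,
      stringsAsFactors = FALSE)
    rownames(expectation) <- NULL
    list(counts = structure(counts, class = "ribo_counts"),
         expectation = expectation, charges = q,
         params = list(seed = seed, depth_meanlog = depth_meanlog,
                       depth_sdlog = depth_sdlog, noise = noise,
                       dispersion = dispersion,
                       effect_codons = effect_codons))
  })
}

#' Write per-codon counts as TSV
#'
#' Long-format companion to [read_ribo_counts()] (columns `gene`, `codon`,
#' `count`); zero-count codons are written too, so files round-trip.
#'
#' @param counts a `ribo_counts` list.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_ribo_counts <- function(counts, path) {
  df <- data.frame(
    gene = rep(names(counts), lengths(counts)),
    codon = unlist(lapply(counts, function(v) seq_along(v) - 1L),
                   use.names = FALSE),
    count = unlist(counts, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate monosome:polysome scores coupled to length and charge
#'
#' Scores emulate a log-ratio of monosome over polysome abundance: longer
#' ORFs score lower (polysome-skewed) and positively charged N-termini
#' score higher (monosome-skewed), plus Gaussian noise. With both
#' couplings zero the score — and hence the category assignment — is
#' independent of charge, the null used to validate the bin-percentage
#' readout. ORF lengths are set to `3 * (length + 1)` nt (stop codon
#' included) where not already annotated.
#'
#' @param prot a [proteome()].
#' @param table a [charge_table()].
#' @param charge_coupling score units per unit window-1 net charge
#'   (default 0.15).
#' @param length_coupling score units per log2 ORF-length unit, centred on
#'   the proteome mean (default -1).
#' @param noise_sd Gaussian noise SD (default 1).
#' @param seed RNG seed (required).
#' @return The proteome with `mp_score` and `orf_length_nt` filled;
#'   generator parameters attached as attribute `mp_params`.
#' @export
gen_mp_scores <- function(prot, table = charge_table(),
                          charge_coupling = 0.15, length_coupling = -1,
                          noise_sd = 1, seed) {
  stopifnot(!missing(seed))
  len <- nchar(prot$sequence)
  orf <- prot$orf_length_nt
  orf[is.na(orf)] <- 3L * (len[is.na(orf)] + 1L)
  prot$orf_length_nt <- orf
  lut <- charge_lookup(table)
  q <- numeric(nrow(prot))
  long <- len >= 30L
  q[long] <- vapply(substr(prot$sequence[long], 1L, 30L),
                    function(s) sum(lut[utf8ToInt(s) - 64L]), numeric(1),
                    USE.NAMES = FALSE)
  .with_seed(seed, {
    prot$mp_score <- length_coupling * (log2(orf) - mean(log2(orf))) +
      charge_coupling * q + stats::rnorm(nrow(prot), 0, noise_sd)
  })
  attr(prot, "mp_params") <- list(seed = seed,
                                  charge_coupling = charge_coupling,
                                  length_coupling = length_coupling,
                                  noise_sd = noise_sd)
  prot
}
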