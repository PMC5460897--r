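#' Sliding-window net-charge scan of one protein
#'
#' Computes the net charge of every `W`-residue window of a sequence (the
#' default W = 30 matches the stretch of nascent peptide held in the
#' ribosome exit tunnel). Window `i` covers residues `i .. i+W-1` (1-based,
#' inclusive), so a protein of length L yields `L - W + 1` windows. The scan
#' is a single-pass rolling sum; in integer rounding mode the arithmetic is
#' exact.
#'
#' @param sequence amino-acid string, or a single-row [proteome()].
#' @param table a [charge_table()].
#' @param W window length in residues.
#' @param id identifier stored in the profile (taken from the proteome row
#'   when one is supplied).
#' @return A `charge_profile`: list with `id`, `window_length`,
#'   `window_charges` (named by window start), `residue_charges`, and
#'   `sequence`. Sequences shorter than `W` give zero windows with a
#'   warning.
#' @export
window_scan <- function(sequence, table = charge_table(), W = 30L,
                        id = NULL) {
  if (inherits(sequence, "proteome")) {
    stopifnot(nrow(sequence) == 1L)
    id <- sequence$id
    sequence <- sequence$sequence
  }
  rc <- residue_charges(sequence, table)
  L <- length(rc)
  if (L < W) {
    warning("sequence shorter than window (", L, " < ", W, "): no windows")
    wc <- numeric(0)
  } else {
    cs <- cumsum(c(0, rc))
    wc <- cs[(W + 1L):(L + 1L)] - cs[1L:(L - W + 1L)]
    if (table$rounding == "integer") wc <- round(wc)  # guard fp drift
    names(wc) <- seq_len(L - W + 1L)
  }
  structure(
    list(id = if (is.null(id)) NA_character_ else id,
         window_length = as.integer(W),
         window_charges = wc,
         residue_charges = rc,
         sequence = toupper(sequence)),
    class = "charge_profile"
  )
}

#' @export
print.charge_profile <- function(x, ...) {
  cat("Charge profile", if (!is.na(x$id)) paste0("[", x$id, "]"), "\n")
  cat("  length:", length(x$residue_charges), "aa;",
      length(x$window_charges), "windows of", x$window_length, "\n")
  if (length(x$window_charges))
    cat("  window charge range:", min(x$window_charges), "to",
        max(x$window_charges), "\n")
  invisible(x)
}

#' @method plot charge_profile
#' @export
plot.charge_profile <- function(x, ...) {
  if (!length(x$window_charges)) stop("profile has no windows")
  graphics::plot(as.integer(names(x$window_charges)), x$window_charges,
                 type = "h", xlab = "window start (residue)",
                 ylab = "window net charge", main = x$id, ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Window scans for a whole proteome
#'
#' Applies [window_scan()] to every protein; proteins shorter than `W` are
#' skipped with a single summary warning.
#'
#' @param records a [proteome()].
#' @inheritParams window_scan
#' @return Named list of `charge_profile`s (names = protein ids).
#' @export
charge_profiles <- function(records, table = charge_table(), W = 30L) {
  len <- nchar(records$sequence)
  short <- len < W
  if (any(short))
    warning("skipped ", sum(short), " protein(s) shorter than ", W, " aa")
  keep <- which(!short)
  out <- lapply(keep, function(i)
    window_scan(records$sequence[i], table, W, id = records$id[i]))
  names(out) <- records$id[keep]
  out
}

#' Mean residue charge at each aligned terminal position
#'
#' Average charge at each of the first (or last) 30 residue positions
#' across a proteome, the positional fingerprint of terminal charge bias.
#' Proteins shorter than 30 residues are excluded; `last30` positions are
#' aligned to the C-terminal residue and labelled -30..-1.
#'
#' @param records a [proteome()].
#' @param table a [charge_table()].
#' @param region `"first30"` or `"last30"`.
#' @return Data frame with `position`, `mean_charge`, `n`.
#' @export
per_position_mean_charge <- function(records, table = charge_table(),
                                     region = c("first30", "last30")) {
  region <- match.arg(region)
  seqs <- records$sequence[nchar(records$sequence) >= 30L]
  if (!length(seqs)) stop("no proteins of length >= 30")
  lut <- charge_lookup(table)
  segs <- if (region == "first30") substr(seqs, 1L, 30L)
          else substr(seqs, nchar(seqs) - 29L, nchar(seqs))
  codes <- matrix(unlist(lapply(segs, function(s) utf8ToInt(s) - 64L)),
                  nrow = 30L)
  m <- matrix(lut[codes], nrow = 30L)
  data.frame(
    position = if (region == "first30") 1:30 else -30:-1,
    mean_charge = rowMeans(m),
    n = length(seqs)
  )
}

#' Sign fractions of a set of window charges
#'
#' Fractions of windows with positive, exactly zero, and negative net
#' charge. Under integer rounding "neutral" means charge 0; in
#' three-decimal mode it means exactly 0.000.
#'
#' @param window_charges numeric vector (pool windows across proteins as
#'   desired).
#' @return Named numeric vector `c(positive=, neutral=, negative=)`,
#'   summing to 1.
#' @export
sign_fractions <- function(window_charges) {
  if (!length(window_charges)) stop("no window charges supplied")
  n <- length(window_charges)
  c(positive = sum(window_charges > 0) / n,
    neutral  = sum(window_charges == 0) / n,
    negative = sum(window_charges < 0) / n)
}

#' Integer charge histogram
#'
#' @param window_charges numeric vector of (integer-mode) window charges.
#' @return Data frame `charge`, `count`, sorted by charge.
#' @export
charge_histogram <- function(window_charges) {
  tab <- table(factor(window_charges,
                      levels = sort(unique(as.integer(window_charges)))))
  data.frame(charge = as.integer(names(tab)), count = as.integer(tab))
}

#' Negative/positive ratio curve
#'
#' For each charge magnitude q, the ratio of the number of windows with net
#' charge -q to those with +q. A ratio of 1 means charge symmetry; the
#' proteome-wide curve rises steeply around magnitude 14, the supercharged-
#' positive deficit. Magnitudes with no positive windows give `NA` (missing,
#' distinct from 0).
#'
#' @param hist a [charge_histogram()] data frame (or numeric vector of
#'   window charges, converted internally).
#' @return Data frame `q`, `n_neg`, `n_pos`, `ratio` for q = 1..max |charge|.
#' @export
neg_pos_ratio_curve <- function(hist) {
  if (is.numeric(hist)) hist <- charge_histogram(hist)
  stopifnot(all(c("charge", "count") %in% names(hist)))
  qmax <- max(abs(hist$charge), 0)
  if (qmax == 0)
    return(data.frame(q = integer(0), n_neg = integer(0),
                      n_pos = integer(0), ratio = numeric(0)))
  q <- seq_len(qmax)
  cnt <- function(v) {
    i <- match(v, hist$charge)
    ifelse(is.na(i), 0L, hist$count[i])
  }
  n_neg <- cnt(-q)
  n_pos <- cnt(q)
  data.frame(q = q, n_neg = n_neg, n_pos = n_pos,
             ratio = ifelse(n_pos > 0, n_neg / n_pos, NA_real_))
}

# column (window start) labels for each heat-map region; cterm starts are
# relative to the sequence end (last residue = -1, last window starts at -30)
.region_starts <- function(region) {
  switch(region,
    nterm = 1:100,
    core  = 130:230,
    cterm = -129:-30,
    stop("unknown region: ", region))
}

#' Region heat-map matrix of mean window charges
#'
#' Mean window net charge per window-start offset within a region of the
#' protein: `nterm` (starts 1..100), `core` (starts 130..230) or `cterm`
#' (the last 100 window starts, labelled -129..-30 relative to the sequence
#' end). Proteins contribute only the tiles they possess; each tile records
#' its support (number of contributing proteins), and tiles with zero
#' support are `NA`, never zero.
#'
#' @param profiles list of `charge_profile`s (from [charge_profiles()]),
#'   computed with W = 30.
#' @param region `"nterm"`, `"core"` or `"cterm"`.
#' @param groups optional factor/character vector, parallel to `profiles`
#'   (or named by protein id), giving one heat-map row per group; default is
#'   one row per protein.
#' @return A `charge_heatmap`: list with `values` (rows x 100/101 starts),
#'   `support`, `region`.
#' @export
heatmap_matrix <- function(profiles, region = c("nterm", "core", "cterm"),
                           groups = NULL) {
  region <- match.arg(region)
  starts <- .region_starts(region)
  if (inherits(profiles, "charge_profile")) profiles <- list(profiles)
  ids <- vapply(profiles, function(p) p$id, character(1))
  if (is.null(groups)) {
    groups <- ids
  } else if (!is.null(names(groups))) {
    groups <- unname(groups[ids])
  }
  groups <- as.character(groups)
  stopifnot(length(groups) == length(profiles))
  rows <- unique(groups[!is.na(groups)])
  vals <- matrix(0, length(rows), length(starts),
                 dimnames = list(rows, starts))
  supp <- matrix(0L, length(rows), length(starts),
                 dimnames = list(rows, starts))
  for (k in seq_along(profiles)) {
    g <- groups[k]
    if (is.na(g)) next
    wc <- profiles[[k]]$window_charges
    nw <- length(wc)
    if (!nw) next
    abs_starts <- if (region == "cterm") starts + nw + 30L else starts
    ok <- abs_starts >= 1L & abs_starts <= nw
    if (!any(ok)) next
    r <- match(g, rows)
    vals[r, ok] <- vals[r, ok] + wc[abs_starts[ok]]
    supp[r, ok] <- supp[r, ok] + 1L
  }
  vals <- ifelse(supp > 0L, vals / supp, NA_real_)
  structure(list(values = vals, support = supp, region = region),
            class = "charge_heatmap")
}

#' @export
print.charge_heatmap <- function(x, ...) {
  cat("Charge heat-map matrix (", x$region, "): ", nrow(x$values), " row(s) x ",
      ncol(x$values), " window starts\n", sep = "")
  rng <- range(x$values, na.rm = TRUE)
  cat("  tile mean charge range:", sprintf("%.2f", rng[1]), "to",
      sprintf("%.2f", rng[2]), "\n")
  invisible(x)
}

#' Long-format view of a heat-map matrix
#'
#' @param x a `charge_heatmap`.
#' @param ... unused.
#' @return Data frame `row`, `region`, `start`, `mean_charge`, `support`
#'   (zero-support tiles omitted).
#' @method as.data.frame charge_heatmap
#' @export
as.data.frame.charge_heatmap <- function(x, ...) {
  df <- expand.grid(row = rownames(x$values),
                    start = as.integer(colnames(x$values)),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$region <- x$region
  df$mean_charge <- as.vector(x$values)
  df$support <- as.vector(x$support)
  df <- df[df$support > 0, c("row", "region", "start", "mean_charge", "support")]
  rownames(df) <- NULL
  df
}

#' Group mean window-charge profile over the first part of proteins
#'
#' Mean window net charge at each window start 1..`upto_start`, per group of
#' proteins (e.g. subcellular localization, chaperone clientele). Proteins
#' contribute the windows they possess; support is recorded per start.
#'
#' @param records a [proteome()].
#' @param table a [charge_table()].
#' @param upto_start last window start to include (default 100).
#' @param group_by grouping: a column name of the proteome, a vector
#'   parallel to its rows, or a named vector keyed by protein id. Proteins
#'   with `NA` group are excluded; empty groups are dropped with a warning.
#' @param W window length.
#' @return Data frame `group`, `start`, `mean_charge`, `support`.
#' @export
group_mean_window_profile <- function(records, table = charge_table(),
                                      upto_start = 100L, group_by,
                                      W = 30L) {
  if (is.character(group_by) && length(group_by) == 1L &&
      group_by %in% names(records)) {
    grp <- records[[group_by]]
  } else if (!is.null(names(group_by))) {
    grp <- unname(group_by[records$id])
  } else {
    stopifnot(length(group_by) == nrow(records))
    grp <- group_by
  }
  grp <- as.character(grp)
  levels <- unique(grp[!is.na(grp)])
  if (!length(levels)) stop("no proteins carry a group")
  profs <- suppressWarnings(charge_profiles(records, table, W))
  grp <- grp[match(names(profs), records$id)]
  out <- list()
  for (g in levels) {
    sel <- which(!is.na(grp) & grp == g)
    if (!length(sel)) {
      warning("group '", g, "' has no members with windows; omitted")
      next
    }
    sums <- numeric(upto_start)
    supp <- integer(upto_start)
    for (i in sel) {
      wc <- profs[[i]]$window_charges
      k <- min(length(wc), upto_start)
      if (!k) next
      sums[1:k] <- sums[1:k] + wc[1:k]
      supp[1:k] <- supp[1:k] + 1L
    }
    keep <- supp > 0L
    out[[g]] <- data.frame(group = g, start = seq_len(upto_start)[keep],
                           mean_charge = sums[keep] / supp[keep],
                           support = supp[keep])
  }
  if (!length(out)) stop("all groups empty")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Correlation between N-terminal and C-terminal window charges
#'
#' Pearson correlation between the net charge of the first 30 residues
#' (window 1) and that of the last 30 residues (the final window), across
#' proteins of length >= 60 (so the two windows cannot overlap).
#'
#' @param records a [proteome()].
#' @param table a [charge_table()].
#' @return List with `r_squared`, `p_value`, `n`, `estimate`. A zero-
#'   variance margin gives `NA` coefficient and p with a warning.
#' @export
nc_terminal_correlation <- function(records, table = charge_table()) {
  len <- nchar(records$sequence)
  keep <- len >= 60L
  if (sum(!keep))
    message("nc_terminal_correlation: excluded ", sum(!keep),
            " protein(s) shorter than 60 aa")
  seqs <- records$sequence[keep]
  n <- length(seqs)
  if (n < 3L) stop("need at least 3 proteins of length >= 60")
  lut <- charge_lookup(table)
  qwin <- function(segs) {
    vapply(segs, function(s) sum(lut[utf8ToInt(s) - 64L]), numeric(1),
           USE.NAMES = FALSE)
  }
  first <- qwin(substr(seqs, 1L, 30L))
  last <- qwin(substr(seqs, nchar(seqs) - 29L, nchar(seqs)))
  if (stats::sd(first) == 0 || stats::sd(last) == 0) {
    warning("zero variance in terminal charges; correlation undefined")
    return(list(r_squared = NA_real_, p_value = NA_real_, n = n,
                estimate = NA_real_))
  }
  ct <- stats::cor.test(first, last, method = "pearson")
  list(r_squared = unname(ct$estimate^2), p_value = ct$p.value, n = n,
       estimate = unname(ct$estimate))
}

#' Find supercharged stretches in a charge profile
#'
#' A supercharged stretch is a run of 30-residue windows whose |net charge|
#' meets a threshold (default 14, where positively charged stretches become
#' depleted proteome-wide). Overlapping qualifying windows of the same sign
#' are collapsed into maximal runs; each run is reported with its first
#' qualifying window start, its peak charge, and the stretch sequence plus
#' the following `context` residues (60 aa total by default, truncated at
#' the protein end and flagged).
#'
#' @param profile a `charge_profile`, or a list of them.
#' @param threshold minimum |window net charge|.
#' @param context residues of downstream context appended to the window.
#' @return Data frame `id`, `sign`, `start`, `end`, `peak_charge`,
#'   `context_seq`, `truncated` (zero rows if none).
#' @export
find_supercharged <- function(profile, threshold = 14, context = 30L) {
  if (!inherits(profile, "charge_profile")) {
    out <- do.call(rbind, lapply(profile, find_supercharged,
                                 threshold = threshold, context = context))
    if (is.null(out))
      out <- find_supercharged(window_scan(strrep("A", 30)))[0, ]
    rownames(out) <- NULL
    return(out)
  }
  wc <- profile$window_charges
  W <- profile$window_length
  L <- length(profile$residue_charges)
  res <- list()
  for (sgn in c(1, -1)) {
    qual <- which(sgn * wc >= threshold)
    if (!length(qual)) next
    runs <- split(qual, cumsum(c(1L, diff(qual) != 1L)))
    for (r in runs) {
      first <- r[1L]
      peak <- wc[r][which.max(sgn * wc[r])]
      end_res <- first + W - 1L + context
      res[[length(res) + 1L]] <- data.frame(
        id = profile$id,
        sign = if (sgn > 0) "positive" else "negative",
        start = first,
        end = r[length(r)],
        peak_charge = unname(peak),
        context_seq = substr(profile$sequence, first, min(end_res, L)),
        truncated = end_res > L,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(res))
    return(data.frame(id = character(0), sign = character(0),
                      start = integer(0), end = integer(0),
                      peak_charge = numeric(0), context_seq = character(0),
                      truncated = logical(0)))
  out <- do.call(rbind, res)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed sample skewness and kurtosis z-scores into
#' K2 = z_skew^2 + z_kurt^2, referred to a chi-squared distribution with 2
#' degrees of freedom. Requires n >= 8.
#'
#' @param x numeric vector, finite values.
#' @return List `statistic` (K2), `p_value`, `z_skew`, `z_kurt`, `n`.
#' @export
dagostino_pearson_test <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L) stop("D'Agostino-Pearson omnibus test requires n >= 8")
  xc <- x - mean(x)
  m2 <- mean(xc^2); m3 <- mean(xc^3); m4 <- mean(xc^4)
  if (m2 == 0) stop("zero variance")
  # skewness z (D'Agostino 1970)
  g1 <- m3 / m2^1.5
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(W2))
  alpha <- sqrt(2 / (W2 - 1))
  if (y == 0) y <- 1
  z_skew <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis z (Anscombe-Glynn 1983)
  b2 <- m4 / m2^2
  E <- 3 * (n - 1) / (n + 1)
  var_b2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - E) / sqrt(var_b2)
  sqrt_b1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqrt_b1 * (2 / sqrt_b1 + sqrt(1 + 4 / sqrt_b1^2))
  term1 <- 1 - 2 / (9 * A)
  denom <- 1 + xk * sqrt(2 / (A - 4))
  term2 <- sign(denom) * abs((1 - 2 / A) / abs(denom))^(1 / 3)
  z_kurt <- (term1 - term2) / sqrt(2 / (9 * A))
  k2 <- z_skew^2 + z_kurt^2
  list(statistic = k2, p_value = stats::pchisq(k2, 2, lower.tail = FALSE),
       z_skew = z_skew, z_kurt = z_kurt, n = n)
}

#' Normality-gated correlation of a charge statistic with a trait
#'
#' Tests both margins with the D'Agostino-Pearson omnibus normality test at
#' alpha = 0.05: if both look Gaussian the Pearson correlation is used,
#' otherwise Spearman. The chosen method is reported alongside the
#' coefficient.
#'
#' @param x,y paired numeric vectors (finite pairs kept), n >= 8.
#' @param alpha normality-test significance level.
#' @return List `method`, `estimate`, `r_squared`, `p_value`, `n`. A
#'   constant margin gives `NA` estimate with a warning.
#' @export
correlate_with_trait <- function(x, y, alpha = 0.05) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 8L)
    stop("n < 8: too few pairs for the normality gate; ",
         "choose Pearson or Spearman explicitly via stats::cor.test")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant margin; correlation undefined")
    return(list(method = NA_character_, estimate = NA_real_,
                r_squared = NA_real_, p_value = NA_real_, n = n))
  }
  gaussian <- dagostino_pearson_test(x)$p_value > alpha &&
    dagostino_pearson_test(y)$p_value > alpha
  method <- if (gaussian) "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(method = method, estimate = unname(ct$estimate),
       r_squared = unname(ct$estimate)^2, p_value = ct$p.value, n = n)
}
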