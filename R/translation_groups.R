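#' Classify genes into monosome/polysome translation categories
#'
#' Five categories: `orf_lt_590` (ORF shorter than 590 nt, regardless of
#' score — initiation dominates for these short genes), `monosome`,
#' `no_enrichment`, `polysome`, and `top300_polysome` (the 300 most
#' polysome-skewed scores among polysome-classified genes). Precomputed
#' labels take precedence; otherwise the monosome:polysome log-ratio score
#' is thresholded (score at or above `thresholds[2]` is monosome-enriched,
#' at or below `thresholds[1]` polysome-enriched, in between no
#' enrichment). An ORF of exactly 590 nt goes to the score/label branch.
#'
#' @param records a [proteome()] with `orf_length_nt` and `mp_label` or
#'   `mp_score` filled (see [attach_annotations()]).
#' @param thresholds numeric length-2 score cutoffs (polysome, monosome),
#'   symmetric about 0 by default.
#' @param top_n size of the extreme-polysome class (default 300).
#' @return Data frame `id`, `category`, `source` (`"label"` or `"score"`);
#'   genes with neither label nor score get `NA` category and are counted
#'   in a message.
#' @export
classify_mp <- function(records, thresholds = c(-0.5, 0.5), top_n = 300L) {
  stopifnot(length(thresholds) == 2L, thresholds[1] <= thresholds[2])
  n <- nrow(records)
  category <- rep(NA_character_, n)
  source <- rep(NA_character_, n)
  has_label <- !is.na(records$mp_label)
  has_score <- !is.na(records$mp_score)
  orf <- records$orf_length_nt
  short <- !is.na(orf) & orf < 590L
  category[short] <- "orf_lt_590"
  source[short] <- ifelse(has_label[short], "label", "score")
  rest <- which(!short)
  lab <- rest[has_label[rest]]
  category[lab] <- records$mp_label[lab]
  source[lab] <- "label"
  sc <- rest[!has_label[rest] & has_score[rest]]
  s <- records$mp_score[sc]
  category[sc] <- ifelse(s >= thresholds[2], "monosome",
                         ifelse(s <= thresholds[1], "polysome",
                                "no_enrichment"))
  source[sc] <- "score"
  # extreme-polysome class: most polysome-skewed (lowest) scores among
  # score-classified polysome genes
  poly <- sc[category[sc] == "polysome"]
  if (length(poly)) {
    k <- min(top_n, length(poly))
    top <- poly[order(records$mp_score[poly])][seq_len(k)]
    category[top] <- "top300_polysome"
  }
  uncl <- is.na(category)
  if (any(uncl))
    message("classify_mp: ", sum(uncl),
            " gene(s) without label or score left unclassified")
  valid <- c("orf_lt_590", "monosome", "no_enrichment", "polysome",
             "top300_polysome")
  bad <- setdiff(unique(category[!is.na(category)]), valid)
  if (length(bad))
    stop("unknown mp_label value(s): ", paste(bad, collapse = ", "))
  data.frame(id = records$id, category = category, source = source,
             stringsAsFactors = FALSE)
}

# window-1 net charges of proteins long enough, named by id
.first_window_charges <- function(records, table, W = 30L) {
  keep <- nchar(records$sequence) >= W
  seqs <- records$sequence[keep]
  lut <- charge_lookup(table)
  q <- vapply(substr(seqs, 1L, W),
              function(s) sum(lut[utf8ToInt(s) - 64L]), numeric(1),
              USE.NAMES = FALSE)
  names(q) <- records$id[keep]
  q
}

#' Per-category N-terminal charge histograms and sign fractions
#'
#' For each monosome/polysome category: the integer histogram of window-1
#' (first 30 residues) net charges and the fractions of positive, neutral
#' and negative sequences.
#'
#' @param records a [proteome()].
#' @param classification result of [classify_mp()].
#' @param table a [charge_table()].
#' @return List with `histogram` (data frame: category, charge, count) and
#'   `fractions` (category, positive, neutral, negative, n). Empty
#'   categories are omitted with a warning.
#' @export
group_charge_histogram <- function(records, classification,
                                   table = charge_table()) {
  q <- .first_window_charges(records, table)
  cat_ <- classification$category[match(names(q), classification$id)]
  cats <- c("orf_lt_590", "monosome", "no_enrichment", "polysome",
            "top300_polysome")
  cats <- cats[cats %in% unique(classification$category)]
  hists <- list(); fracs <- list()
  for (g in cats) {
    qs <- q[!is.na(cat_) & cat_ == g]
    if (!length(qs)) {
      warning("category '", g, "' has no proteins with windows; omitted")
      next
    }
    h <- charge_histogram(qs)
    hists[[g]] <- cbind(category = g, h)
    sf <- sign_fractions(qs)
    fracs[[g]] <- data.frame(category = g, positive = sf["positive"],
                             neutral = sf["neutral"],
                             negative = sf["negative"], n = length(qs))
  }
  if (!length(hists)) stop("no classified proteins with windows")
  out <- list(histogram = do.call(rbind, hists),
              fractions = do.call(rbind, fracs))
  rownames(out$histogram) <- rownames(out$fractions) <- NULL
  out
}

#' Per-category mean charge of N-terminal, core and C-terminal segments
#'
#' Mean (with standard error) of the window-1 net charge (N-terminal), the
#' window starting at `core_start` (default 121, i.e. residues 121-150),
#' and the last window (final 30 residues), per category. Proteins too
#' short for a segment simply do not contribute to it.
#'
#' @param records a [proteome()].
#' @param classification result of [classify_mp()].
#' @param table a [charge_table()].
#' @param core_start window start defining the core segment (121 by
#'   default; 130 reproduces the alternative convention).
#' @return Data frame `category`, `segment`, `mean_charge`, `se`, `n`.
#' @export
group_segment_means <- function(records, classification,
                                table = charge_table(), core_start = 121L) {
  lut <- charge_lookup(table)
  qseg <- function(s) sum(lut[utf8ToInt(s) - 64L])
  len <- nchar(records$sequence)
  cat_ <- classification$category[match(records$id, classification$id)]
  segs <- list(
    nterm = list(keep = len >= 30L,
                 get = function(s) substr(s, 1L, 30L)),
    core = list(keep = len >= core_start + 29L,
                get = function(s) substr(s, core_start, core_start + 29L)),
    cterm = list(keep = len >= 30L,
                 get = function(s) substr(s, nchar(s) - 29L, nchar(s))))
  out <- list()
  for (g in unique(stats::na.omit(cat_))) {
    for (sname in names(segs)) {
      sel <- which(!is.na(cat_) & cat_ == g & segs[[sname]]$keep)
      if (!length(sel)) next
      qs <- vapply(segs[[sname]]$get(records$sequence[sel]), qseg,
                   numeric(1), USE.NAMES = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        category = g, segment = sname, mean_charge = mean(qs),
        se = stats::sd(qs) / sqrt(length(qs)), n = length(qs))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Category percentages per N-terminal charge bin
#'
#' Proteins are binned by window-1 net charge into 16 bins: "-7 and below",
#' each integer charge -6..+7, and "+8 and higher". For each bin the
#' percentage of its proteins falling in each monosome/polysome category is
#' reported (rows sum to 100%), together with the baseline category
#' percentages over all classified proteins. Empty bins are missing rows,
#' not zeros.
#'
#' @param records a [proteome()].
#' @param classification result of [classify_mp()].
#' @param table a [charge_table()].
#' @return List with `percentages` (data frame: bin, category columns, n)
#'   and `baseline` (named percentages over all proteins).
#' @export
charge_bin_group_percentages <- function(records, classification,
                                         table = charge_table()) {
  q <- .first_window_charges(records, table)
  cat_ <- classification$category[match(names(q), classification$id)]
  ok <- !is.na(cat_)
  q <- round(q[ok]); cat_ <- cat_[ok]
  if (!length(q)) stop("no classified proteins with windows")
  bins <- c("<=-7", as.character(-6:7), ">=+8")
  binned <- ifelse(q <= -7, "<=-7", ifelse(q >= 8, ">=+8", as.character(q)))
  binned <- factor(binned, levels = bins)
  cats <- c("orf_lt_590", "monosome", "no_enrichment", "polysome",
            "top300_polysome")
  cats <- cats[cats %in% unique(cat_)]
  catf <- factor(cat_, levels = cats)
  counts <- table(binned, catf)
  n_bin <- rowSums(counts)
  present <- n_bin > 0
  pct <- sweep(counts[present, , drop = FALSE], 1,
               n_bin[present], "/") * 100
  out <- data.frame(bin = rownames(pct),
                    as.data.frame.matrix(pct, stringsAsFactors = FALSE),
                    n = as.integer(n_bin[present]),
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  baseline <- 100 * colSums(counts) / sum(counts)
  list(percentages = out, baseline = baseline)
}
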