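#' Read per-codon ribosome-profiling counts
#'
#' Input is a TSV with columns `gene`, `codon` (0-based position from the
#' start codon) and `count` (non-negative integer reads). Codons missing
#' within a gene are filled with 0; each gene's length is taken from its
#' largest codon index.
#'
#' @param path TSV file.
#' @return A named list of integer count vectors (class `ribo_counts`),
#'   one per gene, indexed from codon 0.
#' @export
read_ribo_counts <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "codon", "count")
  if (!all(need %in% names(tab)))
    stop("counts table needs columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(tab$count)) || any(tab$count < 0) ||
      any(tab$count != round(tab$count)))
    stop("counts must be non-negative integers")
  if (any(tab$codon < 0) || any(tab$codon != round(tab$codon)))
    stop("codon positions must be non-negative integers")
  key <- paste(tab$gene, tab$codon)
  if (anyDuplicated(key))
    stop("duplicate (gene, codon) row: ", key[duplicated(key)][1L])
  out <- lapply(split(tab[c("codon", "count")], tab$gene), function(d) {
    v <- integer(max(d$codon) + 1L)
    v[d$codon + 1L] <- as.integer(d$count)
    v
  })
  structure(out, class = "ribo_counts")
}

#' @export
print.ribo_counts <- function(x, ...) {
  cat("Ribosome count profiles:", length(x), "genes\n")
  if (length(x))
    cat("  length (codons):", min(lengths(x)), "-", max(lengths(x)), "\n")
  invisible(x)
}

#' Coverage filter
#'
#' Removes genes in which fewer than `min_covered` of codon positions carry
#' at least one read (the boundary itself is retained: the rule eliminates
#' strictly below the cutoff).
#'
#' @param profiles a `ribo_counts` list.
#' @param min_covered minimum covered fraction (default 0.5).
#' @return Filtered `ribo_counts`; the number removed is reported.
#' @export
coverage_filter <- function(profiles, min_covered = 0.5) {
  cov <- vapply(profiles, function(v) mean(v >= 1L), numeric(1))
  keep <- cov >= min_covered
  if (any(!keep))
    message("coverage_filter: removed ", sum(!keep), " of ",
            length(profiles), " genes (<", min_covered * 100, "% covered)")
  structure(profiles[keep], class = "ribo_counts")
}

#' Normalize a count profile to its gene mean
#'
#' Divides each position's count by the gene's mean count, so the
#' normalized profile has mean exactly 1 (the metagene baseline). With
#' `divisor = "total"` the counts are divided by the gene's total instead;
#' the two differ only by the gene length factor.
#'
#' @param counts integer vector of per-codon counts.
#' @param divisor `"mean"` (default) or `"total"`.
#' @return Numeric vector, same length.
#' @export
normalize_profile <- function(counts, divisor = c("mean", "total")) {
  divisor <- match.arg(divisor)
  tot <- sum(counts)
  if (tot == 0) stop("cannot normalize a gene with zero total reads")
  if (divisor == "mean") counts / (tot / length(counts)) else counts / tot
}

#' Default N-terminal charge grouping scheme
#'
#' The eight categories used to stratify genes by the net charge of their
#' first 30 residues: `>=+8` (charges +8..+13), `+7`, `+6`, `+5`, `0`,
#' `-1`, `-6` and `<=-7` (charges -7..-15). Charges outside these ranges
#' are unassigned. The `0` category is the reference for AUC ratios.
#'
#' @return Data frame `label`, `lo`, `hi` (inclusive bounds).
#' @export
charge_group_scheme <- function() {
  data.frame(
    label = c(">=+8", "+7", "+6", "+5", "0", "-1", "-6", "<=-7"),
    lo = c(8L, 7L, 6L, 5L, 0L, -1L, -6L, -15L),
    hi = c(13L, 7L, 6L, 5L, 0L, -1L, -6L, -7L),
    stringsAsFactors = FALSE
  )
}

#' Assign an N-terminal charge to its group
#'
#' @param nterm_charge integer net charge(s) of window 1 (first 30
#'   residues).
#' @param scheme a [charge_group_scheme()]-style data frame.
#' @return Character vector of labels; `NA` where unassigned.
#' @export
assign_charge_group <- function(nterm_charge, scheme = charge_group_scheme()) {
  out <- rep(NA_character_, length(nterm_charge))
  for (i in seq_len(nrow(scheme))) {
    hit <- nterm_charge >= scheme$lo[i] & nterm_charge <= scheme$hi[i]
    out[hit & is.na(out)] <- scheme$label[i]
  }
  out
}

#' Metagene occupancy curve of a gene group
#'
#' At each codon 0..`C`, the unweighted mean of the normalized read values
#' across the genes long enough to reach that codon; the number of
#' contributing genes (support) is recorded per position.
#'
#' @param norm_profiles list of normalized profiles (see
#'   [normalize_profile()]); must be non-empty.
#' @param C last codon of the curve (default 150).
#' @return Data frame `codon`, `mean_occupancy`, `support` (class
#'   `metagene`).
#' @export
metagene <- function(norm_profiles, C = 150L) {
  if (!length(norm_profiles)) stop("empty gene group")
  codons <- 0:C
  sums <- numeric(C + 1L)
  supp <- integer(C + 1L)
  for (v in norm_profiles) {
    k <- min(length(v), C + 1L)
    if (!k) next
    sums[1:k] <- sums[1:k] + v[1:k]
    supp[1:k] <- supp[1:k] + 1L
  }
  out <- data.frame(codon = codons,
                    mean_occupancy = ifelse(supp > 0, sums / supp, NA_real_),
                    support = supp)
  class(out) <- c("metagene", "data.frame")
  out
}

#' Area-under-curve ratio of two metagene curves
#'
#' Trapezoidal area of the group curve over `codon_range` (default codons
#' 0..90, the span of the first 30 amino acids) divided by the area of the
#' reference (charge 0) curve over the same range.
#'
#' @param group_curve,reference_curve `metagene` data frames.
#' @param codon_range inclusive codon bounds, default `c(0, 90)`.
#' @return Single numeric ratio.
#' @export
auc_ratio <- function(group_curve, reference_curve, codon_range = c(0L, 90L)) {
  area <- function(curve) {
    sel <- curve$codon >= codon_range[1] & curve$codon <= codon_range[2]
    y <- curve$mean_occupancy[sel]
    if (any(is.na(y))) stop("curve undefined over the requested codon range")
    pracma::trapz(curve$codon[sel], y)
  }
  ref <- area(reference_curve)
  if (ref == 0) stop("reference curve has zero area")
  area(group_curve) / ref
}

#' Ribosome occupancy by N-terminal charge group
#'
#' End-to-end Fig-style analysis: filters gene count profiles by coverage,
#' normalizes each gene to its mean, groups genes by the net charge of the
#' first 30 residues of the encoded protein (plus an optional annotation
#' group of mitochondrial proteins), and computes per-group metagene curves
#' and AUC ratios against the charge-0 reference.
#'
#' @param records a [proteome()] whose ids match the count profiles' gene
#'   ids.
#' @param counts a `ribo_counts` list.
#' @param table a [charge_table()] (integer rounding recommended).
#' @param scheme a [charge_group_scheme()].
#' @param C metagene length in codons.
#' @param min_covered coverage cutoff.
#' @param divisor normalization divisor, see [normalize_profile()].
#' @param include_mito also report the mitochondrial-protein group (uses
#'   the `is_mitochondrial` annotation)?
#' @return List (class `ribo_occupancy`) with `metagene` (long data frame:
#'   group, codon, mean_occupancy, support), `auc` (group, n_genes, auc,
#'   auc_ratio), and `groups` (gene -> group map).
#' @export
ribosome_occupancy <- function(records, counts, table = charge_table(),
                               scheme = charge_group_scheme(), C = 150L,
                               min_covered = 0.5,
                               divisor = c("mean", "total"),
                               include_mito = FALSE) {
  divisor <- match.arg(divisor)
  counts <- coverage_filter(counts, min_covered)
  ids <- intersect(names(counts), records$id[nchar(records$sequence) >= 30L])
  if (!length(ids)) stop("no genes shared between counts and proteome")
  lut <- charge_lookup(table)
  seqs <- records$sequence[match(ids, records$id)]
  q <- vapply(substr(seqs, 1L, 30L),
              function(s) sum(lut[utf8ToInt(s) - 64L]), numeric(1),
              USE.NAMES = FALSE)
  grp <- assign_charge_group(round(q), scheme)
  names(grp) <- ids
  norm <- lapply(counts[ids], normalize_profile, divisor = divisor)
  group_sets <- split(ids, grp)
  if (include_mito) {
    mito_ids <- intersect(ids, records$id[records$is_mitochondrial %in% TRUE])
    if (length(mito_ids)) group_sets$mitochondrial <- mito_ids
  }
  if (!"0" %in% names(group_sets))
    stop("reference charge group '0' has no genes")
  curves <- lapply(group_sets, function(g) metagene(norm[g], C))
  ref <- curves[["0"]]
  mg <- do.call(rbind, lapply(names(curves), function(g) {
    cbind(group = g, curves[[g]])
  }))
  rownames(mg) <- NULL
  auc <- data.frame(
    group = names(curves),
    n_genes = vapply(group_sets, length, integer(1)),
    auc = vapply(curves, function(cu) {
      sel <- cu$codon <= 90
      pracma::trapz(cu$codon[sel], cu$mean_occupancy[sel])
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  auc$auc_ratio <- vapply(curves, auc_ratio, numeric(1),
                          reference_curve = ref)
  rownames(auc) <- NULL
  structure(list(metagene = mg, auc = auc, groups = grp),
            class = "ribo_occupancy")
}

#' @export
print.ribo_occupancy <- function(x, ...) {
  cat("Ribosome occupancy by N-terminal charge group\n")
  print(x$auc, row.names = FALSE, ...)
  invisible(x)
}

#' Export N-terminal peptides as FASTA
#'
#' Writes the first `n` residues of each protein (e.g. as input for an
#' external localization-signal predictor). Proteins shorter than `n` are
#' skipped with a message.
#'
#' @param records a [proteome()].
#' @param path output FASTA.
#' @param n peptide length (default 30).
#' @return `path`, invisibly.
#' @export
export_nterm_fasta <- function(records, path, n = 30L) {
  keep <- nchar(records$sequence) >= n
  if (any(!keep))
    message("export_nterm_fasta: skipped ", sum(!keep),
            " protein(s) shorter than ", n, " aa")
  seqs <- substr(records$sequence[keep], 1L, n)
  names(seqs) <- records$id[keep]
  write_proteome_fasta(seqs, path)
}
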