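#' Build a proteome table
#'
#' A proteome is a data frame (class `proteome`) with one row per protein:
#' `id`, `sequence`, `organism`, plus annotation columns that start unknown
#' (`NA`) and are filled by [attach_annotations()]: `has_signal_peptide`,
#' `orf_length_nt`, `mp_score`, `mp_label`, `is_mitochondrial`, and the
#' list-columns `go_locations` (GO IDs) and `chaperones` (chaperone ids the
#' protein is a client of).
#'
#' @param id character vector of unique accessions.
#' @param sequence amino-acid strings (letters only).
#' @param organism organism name(s), recycled.
#' @return A `proteome` data frame.
#' @export
proteome <- function(id, sequence, organism = "") {
  stopifnot(length(id) == length(sequence))
  if (anyDuplicated(id))
    stop("duplicate protein id: ", id[duplicated(id)][1L])
  if (length(sequence) && any(grepl("[^A-Za-z]", sequence)))
    stop("sequences must contain only letters")
  n <- length(id)
  df <- data.frame(
    id = as.character(id),
    sequence = toupper(as.character(sequence)),
    organism = rep_len(as.character(organism), n),
    has_signal_peptide = rep(NA, n),
    orf_length_nt = rep(NA_integer_, n),
    mp_score = rep(NA_real_, n),
    mp_label = rep(NA_character_, n),
    is_mitochondrial = rep(NA, n),
    stringsAsFactors = FALSE
  )
  df$go_locations <- rep(list(character(0)), n)
  df$chaperones <- rep(list(character(0)), n)
  class(df) <- c("proteome", "data.frame")
  df
}

#' @export
print.proteome <- function(x, ...) {
  cat("Proteome:", nrow(x), "proteins\n")
  if (nrow(x)) {
    len <- nchar(x$sequence)
    cat("  length range:", min(len), "-", max(len),
        " median:", stats::median(len), "\n")
    orgs <- unique(x$organism[nzchar(x$organism)])
    if (length(orgs)) cat("  organisms:", paste(utils::head(orgs, 5), collapse = ", "),
                          if (length(orgs) > 5) "..." else "", "\n")
  }
  invisible(x)
}

# keep proteome class (and list-columns) through [ subsetting
#' @export
`[.proteome` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("id", "sequence") %in% names(out)))
    class(out) <- c("proteome", "data.frame")
  out
}

#' Read a proteome from FASTA
#'
#' UniProt-style headers (`db|ACC|NAME ... OS=Organism ...`) are parsed for
#' accession and organism; otherwise the first whitespace-delimited token is
#' the id. Entry order is preserved and the count reported.
#'
#' @param path FASTA file.
#' @return A [proteome()].
#' @export
read_proteome_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonblank <- lines[nzchar(trimws(lines))]
  if (!length(nonblank)) {
    warning("empty FASTA file: ", path)
    return(proteome(character(0), character(0)))
  }
  if (!startsWith(nonblank[1L], ">"))
    stop("malformed FASTA: sequence data before first header in ", path)
  seqs <- Biostrings::readAAStringSet(path)
  headers <- names(seqs)
  first_tok <- sub("\\s.*$", "", headers)
  uniprot <- grepl("^[A-Za-z]+\\|[^|]+\\|", first_tok)
  ids <- ifelse(uniprot, sub("^[A-Za-z]+\\|([^|]+)\\|.*$", "\\1", first_tok),
                first_tok)
  if (anyDuplicated(ids))
    stop("duplicate protein id in FASTA: ", ids[duplicated(ids)][1L])
  organism <- character(length(headers))
  hit <- grepl("OS=", headers)
  # organism runs from OS= to the next XX= field (OX=, GN=, PE=, SV=) or EOL
  organism[hit] <- trimws(sub("\\s+[A-Z]{2}=.*$", "",
                              sub("^.*OS=", "", headers[hit])))
  message("read_proteome_fasta: ", length(ids), " proteins from ", path)
  proteome(ids, as.character(seqs), organism)
}

#' Write a proteome (or any named sequence set) to FASTA
#'
#' @param x a [proteome()] or a named character vector of sequences.
#' @param path output file.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_proteome_fasta <- function(x, path, width = 60L) {
  if (inherits(x, "proteome")) {
    seqs <- x$sequence
    names(seqs) <- x$id
  } else {
    seqs <- x
  }
  aa <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(aa, path, width = width)
  invisible(path)
}

#' Attach sidecar annotations to a proteome
#'
#' Annotation tables are TSVs with a header row and an `accession` column.
#' Required extra columns by kind:
#' \describe{
#'   \item{signal}{`has_signal_peptide` (logical or 0/1).}
#'   \item{go}{`go_id`; a protein may appear on several rows, IDs accumulate.}
#'   \item{orf_length}{`orf_length_nt` (integer). Also flags a protein
#'     mitochondrial if a `is_mitochondrial` column is present.}
#'   \item{mp}{`mp_score` and/or `mp_label` (monosome:polysome data).}
#'   \item{chaperone}{`chaperone`: each row maps a chaperone to a client
#'     accession. Chaperones with 30 clients or fewer are dropped before
#'     attaching.}
#' }
#' Table rows whose accession matches no record are counted and reported.
#'
#' @param records a [proteome()].
#' @param table_path path to the TSV.
#' @param kind one of `"signal"`, `"go"`, `"orf_length"`, `"mp"`,
#'   `"chaperone"`.
#' @return The updated proteome.
#' @export
attach_annotations <- function(records, table_path,
                               kind = c("signal", "go", "orf_length", "mp",
                                        "chaperone")) {
  kind <- match.arg(kind)
  tab <- utils::read.delim(table_path, stringsAsFactors = FALSE)
  if (!"accession" %in% names(tab))
    stop("annotation table lacks required column 'accession'")
  need <- switch(kind,
    signal = "has_signal_peptide",
    go = "go_id",
    orf_length = "orf_length_nt",
    mp = c("mp_score", "mp_label"),
    chaperone = "chaperone")
  present <- intersect(need, names(tab))
  if (kind == "mp") {
    if (!length(present))
      stop("mp table needs column 'mp_score' or 'mp_label'")
  } else if (!all(need %in% names(tab))) {
    stop("annotation table lacks required column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  }
  if (kind == "chaperone") {
    sizes <- table(tab$chaperone)
    keep <- names(sizes)[sizes > 30L]
    dropped <- setdiff(names(sizes), keep)
    if (length(dropped))
      message("attach_annotations: dropped ", length(dropped),
              " chaperone group(s) with <= 30 clients")
    tab <- tab[tab$chaperone %in% keep, , drop = FALSE]
  }
  idx <- match(tab$accession, records$id)
  unmatched <- sum(is.na(idx))
  if (unmatched)
    message("attach_annotations: ", unmatched,
            " table row(s) matched no protein")
  hit <- which(!is.na(idx))
  if (!length(hit)) {
    warning("attach_annotations: no table rows matched any protein")
    return(records)
  }
  ti <- idx[hit]
  switch(kind,
    signal = {
      records$has_signal_peptide[ti] <- as.logical(tab$has_signal_peptide[hit])
    },
    go = {
      for (k in seq_along(hit)) {
        i <- ti[k]
        records$go_locations[[i]] <-
          union(records$go_locations[[i]], tab$go_id[hit[k]])
      }
      annotated <- lengths(records$go_locations) > 0
      mito <- vapply(records$go_locations, function(g) "GO:0005739" %in% g,
                     logical(1))
      records$is_mitochondrial[annotated] <- mito[annotated]
    },
    orf_length = {
      len <- as.integer(tab$orf_length_nt[hit])
      records$orf_length_nt[ti] <- len
      short <- len < 3L * nchar(records$sequence[ti])
      if (any(short, na.rm = TRUE))
        message("attach_annotations: ", sum(short, na.rm = TRUE),
                " ORF length(s) shorter than 3x protein length (kept as given)")
    },
    mp = {
      if ("mp_score" %in% names(tab))
        records$mp_score[ti] <- as.numeric(tab$mp_score[hit])
      if ("mp_label" %in% names(tab))
        records$mp_label[ti] <- as.character(tab$mp_label[hit])
    },
    chaperone = {
      for (k in seq_along(hit)) {
        i <- ti[k]
        records$chaperones[[i]] <-
          union(records$chaperones[[i]], tab$chaperone[hit[k]])
      }
    })
  records
}

#' Select a subset of proteins
#'
#' Filters a proteome by an expression over its columns (evaluated within
#' the table, like [subset()]), plus convenience filters used throughout the
#' analyses: minimum sequence length, GO membership, and signal-peptide
#' exclusion. Filters compose; the selection size is reported.
#'
#' @param records a [proteome()].
#' @param expr optional logical expression over proteome columns
#'   (e.g. `orf_length_nt < 590`). `NA` evaluates to not-selected.
#' @param min_length keep proteins with at least this many residues.
#' @param go keep proteins annotated with this GO ID (exact match).
#' @param exclude_signal_peptide if `TRUE`, drop proteins flagged
#'   `has_signal_peptide`.
#' @return The filtered proteome.
#' @export
select_proteins <- function(records, expr = NULL, min_length = NULL,
                            go = NULL, exclude_signal_peptide = FALSE) {
  keep <- rep(TRUE, nrow(records))
  e <- substitute(expr)
  if (!is.null(e) && !identical(e, quote(NULL))) {
    vars <- all.vars(e)
    unknown <- setdiff(vars, names(records))
    if (length(unknown))
      stop("unknown field(s) in filter: ", paste(unknown, collapse = ", "))
    v <- eval(e, records, parent.frame())
    keep <- keep & !is.na(v) & v
  }
  if (!is.null(min_length))
    keep <- keep & nchar(records$sequence) >= min_length
  if (!is.null(go))
    keep <- keep & vapply(records$go_locations, function(g) go %in% g, logical(1))
  if (exclude_signal_peptide)
    keep <- keep & !(records$has_signal_peptide %in% TRUE)
  out <- records[keep, , drop = FALSE]
  message("select_proteins: ", nrow(out), " of ", nrow(records), " retained")
  out
}
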