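#' Run the charge-landscape pipeline end to end
#'
#' Orchestrates the analysis stages over a proteome (read from FASTA or
#' synthesized), writing every result as a TSV/FASTA under `outdir` and a
#' `manifest.tsv` listing each output with its md5 and the hash of the
#' config that produced it. Re-running with an identical config (and seed)
#' reproduces identical files.
#'
#' Config keys (a YAML file path or an R list):
#' \describe{
#'   \item{outdir}{output directory (required).}
#'   \item{seed}{integer seed used by all simulation stages (default 1).}
#'   \item{stages}{character vector from `simulate`, `scan`, `stats`,
#'     `heatmap`, `supercharged`, `ribo`, `mp`; default all.}
#'   \item{charge}{list passed to [charge_table()] (pH, his_mode, rounding,
#'     include_termini, pKa).}
#'   \item{proteome_fasta}{input FASTA, required unless `simulate` runs.}
#'   \item{annotations}{named list kind -> TSV path, see
#'     [attach_annotations()].}
#'   \item{window}{window length W (default 30).}
#'   \item{threshold}{supercharged |charge| cutoff (default 14).}
#'   \item{simulate}{list of [gen_proteome()] arguments (minus seed); set
#'     `ribo: yes` / `mp: yes` inside it to also simulate counts/scores.}
#'   \item{ribo_counts}{per-codon counts TSV, required for the `ribo` stage
#'     unless simulated.}
#' }
#'
#' @param config list or path to a YAML config.
#' @return Data frame manifest (invisibly): `file`, `md5`, `config_hash`.
#' @export
run_charge_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$outdir)) stop("config must name an 'outdir'")
  all_stages <- c("simulate", "scan", "stats", "heatmap", "supercharged",
                  "ribo", "mp")
  stages <- if (is.null(config$stages)) all_stages else config$stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  W <- if (is.null(config$window)) 30L else as.integer(config$window)
  threshold <- if (is.null(config$threshold)) 14 else config$threshold
  table <- do.call(charge_table, as.list(config$charge))

  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit_tsv <- function(df, name) {
    p <- file.path(config$outdir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <<- c(outputs, p)
    p
  }
  note_file <- function(p) outputs <<- c(outputs, p)

  # canonical config snapshot; its md5 stamps every manifest row
  cfg_path <- file.path(config$outdir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  note_file(cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))

  needs_proteome <- length(intersect(
    stages, c("scan", "stats", "heatmap", "supercharged", "ribo", "mp"))) > 0
  prot <- NULL; truth <- NULL; sim_ribo <- NULL
  if ("simulate" %in% stages) {
    sim_args <- as.list(config$simulate)
    want_ribo <- isTRUE(sim_args$ribo) ||
      identical(sim_args$ribo, "yes")
    want_mp <- isTRUE(sim_args$mp) || identical(sim_args$mp, "yes")
    sim_args$ribo <- NULL; sim_args$mp <- NULL
    sim_args$seed <- seed
    gen <- do.call(gen_proteome, sim_args)
    prot <- gen$proteome; truth <- gen$truth
    fa <- file.path(config$outdir, "proteome.fasta")
    write_proteome_fasta(prot, fa); note_file(fa)
    emit_tsv(truth, "proteome_truth.tsv")
    if (want_ribo) {
      sim_ribo <- gen_ribo_counts(prot, table, seed = seed + 1L)
      write_ribo_counts(sim_ribo$counts,
                        file.path(config$outdir, "ribo_counts.tsv"))
      note_file(file.path(config$outdir, "ribo_counts.tsv"))
      emit_tsv(sim_ribo$expectation, "ribo_expectation.tsv")
    }
    if (want_mp) prot <- gen_mp_scores(prot, table, seed = seed + 2L)
  } else if (needs_proteome) {
    if (is.null(config$proteome_fasta))
      stop("stage(s) need a proteome but neither stage 'simulate' nor ",
           "'proteome_fasta' is configured")
    prot <- read_proteome_fasta(config$proteome_fasta)
  }
  for (kind in names(config$annotations))
    prot <- attach_annotations(prot, config$annotations[[kind]], kind)

  profs <- NULL
  get_profiles <- function() {
    if (is.null(profs))
      profs <<- suppressWarnings(charge_profiles(prot, table, W))
    profs
  }

  if ("scan" %in% stages) {
    pr <- get_profiles()
    emit_tsv(data.frame(
      id = rep(names(pr), vapply(pr, function(p) length(p$window_charges),
                                 integer(1))),
      start = unlist(lapply(pr, function(p)
        as.integer(names(p$window_charges))), use.names = FALSE),
      charge = unlist(lapply(pr, function(p) unname(p$window_charges)),
                      use.names = FALSE)), "window_charges.tsv")
  }
  if ("stats" %in% stages) {
    pr <- get_profiles()
    allq <- unlist(lapply(pr, function(p) p$window_charges),
                   use.names = FALSE)
    emit_tsv(charge_histogram(allq), "charge_histogram.tsv")
    sf <- sign_fractions(allq)
    emit_tsv(data.frame(sign = names(sf), fraction = unname(sf)),
             "sign_fractions.tsv")
    emit_tsv(neg_pos_ratio_curve(allq), "ratio_curve.tsv")
    emit_tsv(per_position_mean_charge(prot, table, "first30"),
             "per_position_first30.tsv")
    emit_tsv(per_position_mean_charge(prot, table, "last30"),
             "per_position_last30.tsv")
  }
  if ("heatmap" %in% stages) {
    pr <- get_profiles()
    for (region in c("nterm", "core", "cterm"))
      emit_tsv(as.data.frame(heatmap_matrix(pr, region)),
               paste0("heatmap_", region, ".tsv"))
  }
  if ("supercharged" %in% stages) {
    pr <- get_profiles()
    sc <- find_supercharged(pr, threshold = threshold)
    emit_tsv(sc, "supercharged.tsv")
    if (nrow(sc)) {
      seqs <- sc$context_seq
      names(seqs) <- sprintf("%s_start%d_%s", sc$id, sc$start, sc$sign)
      fa <- file.path(config$outdir, "supercharged.fasta")
      write_proteome_fasta(seqs, fa); note_file(fa)
    }
  }
  if ("ribo" %in% stages) {
    counts <- if (!is.null(sim_ribo)) sim_ribo$counts
      else if (!is.null(config$ribo_counts)) read_ribo_counts(config$ribo_counts)
      else stop("stage 'ribo' needs counts: configure 'ribo_counts' or ",
                "simulate with ribo: yes")
    occ <- ribosome_occupancy(prot, counts, table)
    emit_tsv(occ$metagene, "metagene.tsv")
    emit_tsv(occ$auc, "auc_ratios.tsv")
  }
  if ("mp" %in% stages) {
    if (all(is.na(prot$mp_score)) && all(is.na(prot$mp_label)))
      stop("stage 'mp' needs monosome:polysome data: attach an 'mp' ",
           "annotation or simulate with mp: yes")
    cls <- classify_mp(prot)
    emit_tsv(cls, "mp_classification.tsv")
    gh <- group_charge_histogram(prot, cls, table)
    emit_tsv(gh$histogram, "mp_histograms.tsv")
    emit_tsv(gh$fractions, "mp_fractions.tsv")
    emit_tsv(group_segment_means(prot, cls, table), "mp_segment_means.tsv")
    bp <- charge_bin_group_percentages(prot, cls, table)
    emit_tsv(bp$percentages, "mp_bin_percentages.tsv")
    emit_tsv(data.frame(category = names(bp$baseline),
                        percent = unname(bp$baseline)),
             "mp_baseline.tsv")
  }

  manifest <- data.frame(file = basename(outputs),
                         md5 = unname(tools::md5sum(outputs)),
                         config_hash = cfg_hash,
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(config$outdir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
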