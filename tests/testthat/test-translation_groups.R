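mp_proteome <- function(n, scores, orf = NULL, labels = NA_character_,
                        charges = NULL) {
  seqs <- if (is.null(charges)) {
    vapply(rep(160, n), function(L) paste0("M", random_seq(L - 1)), character(1))
  } else {
    paste0(vapply(rep_len(charges, n), nterm_window, character(1)),
           vapply(rep(130, n), random_seq, character(1)))
  }
  prot <- make_proteome(seqs)
  prot$mp_score <- rep_len(scores, n)
  prot$mp_label <- rep_len(labels, n)
  prot$orf_length_nt <- if (is.null(orf)) 3L * (nchar(seqs) + 1L)
                        else rep_len(orf, n)
  prot
}

test_that("ORF length and score thresholds classify genes as specified", {
  set.seed(37)
  prot <- mp_proteome(4, scores = c(2, 2, 0, -2), orf = c(500L, 590L, 900L, 900L))
  cls <- classify_mp(prot)
  expect_equal(cls$category,
               c("orf_lt_590",       # <590 nt wins regardless of score
                 "monosome",         # 590 itself goes to the score branch
                 "no_enrichment",
                 "top300_polysome")) # lone polysome gene is also most extreme
  # precomputed labels take precedence over scores
  prot <- mp_proteome(2, scores = c(5, 5), orf = 900L,
                      labels = c("polysome", "no_enrichment"))
  cls <- classify_mp(prot)
  expect_equal(cls$category, c("polysome", "no_enrichment"))
  expect_equal(cls$source, c("label", "label"))
  # genes with neither label nor score stay unclassified
  prot <- mp_proteome(2, scores = NA_real_, orf = 900L)
  expect_message(cls <- classify_mp(prot), "unclassified")
  expect_true(all(is.na(cls$category)))
  expect_error(classify_mp(mp_proteome(1, scores = 1, orf = 900L,
                                       labels = "weird")), "unknown mp_label")
})

test_that("the extreme-polysome class is the 300 lowest scores among polysome genes", {
  set.seed(43)
  n <- 1000
  scores <- rnorm(n, -3, 1)  # mostly polysome-side
  prot <- mp_proteome(n, scores = scores, orf = 900L)
  cls <- classify_mp(prot)
  n_poly <- sum(scores <= -0.5)
  top <- cls$id[cls$category == "top300_polysome"]
  expect_length(top, 300L)
  expect_setequal(top, prot$id[order(prot$mp_score)][1:300])
  expect_equal(sum(cls$category == "polysome"), n_poly - 300L)
  # category sizes partition the classified genes
  expect_equal(sum(table(cls$category)), n)
})

test_that("per-category histograms and sign fractions summarise window-1 charges", {
  set.seed(47)
  prot <- mp_proteome(8, scores = 0, orf = 900L,
                      charges = c(1, 2, 0, -1, 1, 2, 0, -1))
  prot$mp_label <- rep(c("monosome", "polysome"), each = 4)
  cls <- classify_mp(prot)
  gh <- group_charge_histogram(prot, cls)
  mono <- gh$fractions[gh$fractions$category == "monosome", ]
  expect_equal(unname(unlist(mono[c("positive", "neutral", "negative")])),
               c(0.5, 0.25, 0.25))
  # identical charge sets give identical histograms
  h <- gh$histogram
  expect_equal(h[h$category == "monosome", c("charge", "count")],
               h[h$category == "polysome", c("charge", "count")],
               ignore_attr = TRUE)
})

test_that("segment means cover N-terminal, core and C-terminal windows", {
  prot <- make_proteome(strrep("K", 200), "pk")
  prot$mp_label <- "monosome"; prot$orf_length_nt <- 900L
  cls <- classify_mp(prot)
  sm <- group_segment_means(prot, cls)
  expect_setequal(sm$segment, c("nterm", "core", "cterm"))
  expect_equal(sm$mean_charge, rep(30, 3))
  expect_equal(sm$n, rep(1L, 3))
  # single-protein category: means equal that protein's window charges
  set.seed(53)
  s <- random_seq(200)
  prot <- make_proteome(s, "x")
  prot$mp_label <- "polysome"; prot$orf_length_nt <- 900L
  cls <- classify_mp(prot)
  sm <- group_segment_means(prot, cls)
  wc <- window_scan(s)$window_charges
  expect_equal(sm$mean_charge[sm$segment == "nterm"], unname(wc[1]))
  expect_equal(sm$mean_charge[sm$segment == "core"], unname(wc[121]))
  expect_equal(sm$mean_charge[sm$segment == "cterm"], unname(wc[171]))
  # short proteins drop out of the core segment only
  prot <- make_proteome(random_seq(100), "short")
  prot$mp_label <- "monosome"; prot$orf_length_nt <- 900L
  sm <- group_segment_means(prot, classify_mp(prot))
  expect_setequal(sm$segment, c("nterm", "cterm"))
})

test_that("charge-bin percentages sum to 100 and reconstruct the baseline", {
  set.seed(59)
  n <- 600
  charges <- sample(-9:9, n, replace = TRUE)
  prot <- mp_proteome(n, scores = rnorm(n), orf = 900L, charges = charges)
  cls <- classify_mp(prot, top_n = 50L)
  bp <- charge_bin_group_percentages(prot, cls)
  pct <- bp$percentages
  cats <- setdiff(names(pct), c("bin", "n"))
  expect_true(all(abs(rowSums(pct[cats]) - 100) < 1e-9))
  # size-weighted average of bin rows equals the overall baseline
  wavg <- colSums(pct[cats] * pct$n) / sum(pct$n)
  expect_equal(unname(wavg), unname(bp$baseline[cats]), tolerance = 1e-12)
  expect_equal(sum(pct$n), n)

  # all proteins in one category: every bin 100% that category
  prot <- mp_proteome(40, scores = 5, orf = 900L,
                      charges = sample(-2:2, 40, replace = TRUE))
  bp <- charge_bin_group_percentages(prot, classify_mp(prot))
  expect_true(all(bp$percentages$monosome == 100))

  # an empty bin is a missing row, not zeros
  prot <- mp_proteome(10, scores = 5, orf = 900L, charges = 2)
  bp <- charge_bin_group_percentages(prot, classify_mp(prot))
  expect_equal(bp$percentages$bin, "2")
})
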