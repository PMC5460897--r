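test_that("window scan matches hand examples and the brute-force oracle", {
  tab <- charge_table()
  p <- window_scan(strrep("K", 30), tab)
  expect_equal(unname(p$window_charges), 30)
  p <- window_scan(paste0(strrep("K", 30), "D"), tab)
  expect_equal(unname(p$window_charges), c(30, 28))
  expect_equal(as.integer(names(p$window_charges)), 1:2)
  set.seed(5)
  for (mode in c("integer", "three_decimals")) {
    tb <- charge_table(rounding = mode)
    for (i in 1:25) {
      s <- random_seq(sample(30:250, 1))
      expect_equal(unname(window_scan(s, tb)$window_charges),
                   brute_window_charges(s, tb))
    }
  }
  expect_warning(short <- window_scan("MKA", tab), "shorter than window")
  expect_length(short$window_charges, 0L)
})

test_that("proteome-level scans skip short proteins with a counted warning", {
  prot <- make_proteome(c(random_seq(100), random_seq(29), random_seq(10)))
  expect_warning(profs <- charge_profiles(prot), "skipped 2")
  expect_length(profs, 1L)
  expect_equal(length(profs[[1]]$window_charges), 71L)
})

test_that("per-position terminal means align as specified", {
  tab <- charge_table()
  set.seed(21)
  seqs <- paste0("M", vapply(rep(59, 50), random_seq, character(1)))
  pm <- per_position_mean_charge(make_proteome(seqs), tab, "first30")
  expect_equal(pm$mean_charge[1], 0)  # initiator methionine
  one <- per_position_mean_charge(make_proteome("MKAAADDDKK" |> strrep(5)), tab)
  expect_equal(one$mean_charge[2], 1)
  last <- per_position_mean_charge(
    make_proteome(paste0(random_seq(40), strrep("K", 5))), tab, "last30")
  expect_equal(last$position, -30:-1)
  expect_equal(last$mean_charge[26:30], rep(1, 5))
  expect_error(per_position_mean_charge(make_proteome("MK"), tab), "length >= 30")
})

test_that("sign fractions partition windows and sum to one", {
  expect_equal(sign_fractions(c(1, 0, -1)),
               c(positive = 1/3, neutral = 1/3, negative = 1/3))
  expect_equal(sign_fractions(rep(0, 7)),
               c(positive = 0, neutral = 1, negative = 0))
  set.seed(3)
  for (i in 1:10) {
    x <- sample(-15:15, 200, replace = TRUE)
    f <- sign_fractions(x)
    # exact as rationals: numerators over the common denominator n
    expect_identical(sum(round(f * length(x))), 200)
    expect_equal(sum(f), 1)
  }
  expect_error(sign_fractions(numeric(0)), "no window charges")
})

test_that("negative/positive ratio curve handles symmetry, asymmetry and missing sides", {
  sym <- charge_histogram(c(-3, -2, -1, 1, 2, 3))
  rc <- neg_pos_ratio_curve(sym)
  expect_equal(rc$ratio, rep(1, 3))
  rc <- neg_pos_ratio_curve(data.frame(charge = c(2, -2), count = c(10, 20)))
  expect_equal(rc$ratio[rc$q == 2], 2)
  rc <- neg_pos_ratio_curve(data.frame(charge = c(-5), count = c(7)))
  expect_true(is.na(rc$ratio[rc$q == 5]))
  expect_equal(rc$n_neg[rc$q == 5], 7L)
  # charge negation gives elementwise reciprocals where both sides exist
  set.seed(9)
  x <- sample(c(-8:-1, 1:8), 500, replace = TRUE)
  a <- neg_pos_ratio_curve(x)
  b <- neg_pos_ratio_curve(-x)
  expect_equal(a$ratio, 1 / b$ratio)
})

test_that("heat-map matrices average per tile with correct support and coordinates", {
  tab <- charge_table()
  polyk <- window_scan(strrep("K", 300), tab, id = "pk")
  hm <- heatmap_matrix(list(polyk), "nterm")
  expect_equal(dim(hm$values), c(1L, 100L))
  expect_true(all(hm$values == 30))
  expect_true(all(hm$support == 1L))

  # a 129-aa protein has exactly 100 windows: its last 100 window starts
  # are the same 100 windows, so nterm and cterm rows coincide
  set.seed(13)
  s <- random_seq(129)
  pr <- window_scan(s, tab, id = "x")
  expect_length(pr$window_charges, 100L)
  n <- heatmap_matrix(list(pr), "nterm")
  expect_true(all(n$support == 1L))
  expect_equal(unname(n$values[1, ]), unname(pr$window_charges))
  co <- heatmap_matrix(list(pr), "core")
  expect_true(all(co$support == 0L))
  expect_true(all(is.na(co$values)))
  ct <- heatmap_matrix(list(pr), "cterm")
  expect_equal(unname(ct$values[1, ]), unname(pr$window_charges))

  # group averaging: tiles mean contributing proteins, support counts them
  p1 <- window_scan(paste0("M", strrep("K", 2), strrep("A", 47)), tab, id = "p1") # +2 windows
  p2 <- window_scan(paste0("M", strrep("D", 4), strrep("A", 45)), tab, id = "p2") # -4 windows
  hm <- heatmap_matrix(list(p1, p2), "nterm", groups = c("g", "g"))
  expect_equal(unname(hm$values[1, 1]), -1)
  expect_equal(unname(hm$support[1, 1]), 2L)
  expect_true(all(hm$support <= 2L))
  # long format drops zero-support tiles
  df <- as.data.frame(hm)
  expect_equal(nrow(df), sum(hm$support > 0))
  expect_true(all(df$support > 0))
})

test_that("cterm heat-map columns align to the sequence end", {
  tab <- charge_table()
  # 160 aa, last 30 residues all K: only the final window (-30) is +30
  s <- paste0(random_seq(130), strrep("K", 30))
  pr <- window_scan(s, tab, id = "e")
  hm <- heatmap_matrix(list(pr), "cterm")
  expect_equal(unname(hm$values[1, "-30"]), 30)
  expect_equal(colnames(hm$values)[1], "-129")
})

test_that("group mean window profiles aggregate with support", {
  tab <- charge_table()
  set.seed(17)
  seqs <- c(strrep("K", 140), random_seq(140), random_seq(80))
  prot <- make_proteome(seqs)
  grp <- c("solo", "mix", "mix")
  res <- group_mean_window_profile(prot, tab, upto_start = 100, group_by = grp)
  solo <- res[res$group == "solo", ]
  expect_equal(solo$mean_charge, rep(30, 100))
  mix <- res[res$group == "mix", ]
  expect_equal(mix$support, c(rep(2L, 51), rep(1L, 49)))  # 80-aa protein stops at start 51
  p2 <- window_scan(seqs[2], tab)
  p3 <- window_scan(seqs[3], tab)
  expect_equal(mix$mean_charge[1],
               unname(p2$window_charges[1] + p3$window_charges[1]) / 2)
  expect_warning(
    group_mean_window_profile(prot, tab, group_by = c("a", NA, NA)),
    NA)  # single-group runs clean
})

test_that("N-vs-C terminal correlation follows the Pearson contract", {
  tab <- charge_table()
  # mirror-symmetric proteins: first and last windows identical
  set.seed(23)
  halves <- vapply(rep(40, 30), random_seq, character(1))
  seqs <- paste0(halves, vapply(strsplit(halves, ""), function(x)
    paste(rev(x), collapse = ""), character(1)))
  r <- suppressMessages(nc_terminal_correlation(make_proteome(seqs), tab))
  expect_equal(r$r_squared, 1)
  expect_equal(r$n, 30L)
  # independent termini: r^2 near zero
  seqs <- vapply(rep(120, 1000), random_seq, character(1))
  r0 <- suppressMessages(nc_terminal_correlation(make_proteome(seqs), tab))
  expect_lt(r0$r_squared, 0.01)
  # constant margin is undefined, not zero
  seqs <- paste0(strrep("A", 30), vapply(rep(40, 5), random_seq, character(1)))
  expect_warning(
    rc <- suppressMessages(nc_terminal_correlation(make_proteome(seqs), tab)),
    "zero variance")
  expect_true(is.na(rc$estimate))
  expect_error(suppressMessages(
    nc_terminal_correlation(make_proteome(c("M", "MK")), tab)), "at least 3")
})

test_that("supercharged stretches collapse to maximal runs with 60-aa context", {
  tab <- charge_table()
  p <- window_scan(paste0(strrep("K", 30), strrep("A", 30)), tab, id = "pos")
  sc <- find_supercharged(p)
  expect_equal(nrow(sc), 1L)
  expect_equal(sc$start, 1L)
  expect_equal(sc$peak_charge, 30)
  expect_equal(sc$sign, "positive")
  expect_equal(nchar(sc$context_seq), 60L)
  expect_false(sc$truncated)

  expect_equal(nrow(find_supercharged(window_scan(strrep("A", 60), tab))), 0L)

  # truncation at the protein end is flagged
  p <- window_scan(paste0(strrep("A", 10), strrep("D", 30)), tab, id = "neg")
  sc <- find_supercharged(p)
  expect_equal(sc$sign, "negative")
  expect_true(sc$truncated)
  expect_equal(sc$peak_charge, -30)
  expect_lt(nchar(sc$context_seq), 60L)

  # consecutive qualifying windows collapse into one run
  p <- window_scan(paste0("AA", strrep("K", 32), strrep("A", 40)), tab, id = "run")
  sc <- find_supercharged(p)
  expect_equal(nrow(sc), 1L)
  expect_equal(sc$start, 1L)  # window 1 already holds 28 lysines
  expect_gt(sc$end, sc$start)
  # a negative prefix delays the first qualifying start
  p <- window_scan(paste0(strrep("D", 20), strrep("K", 34), strrep("A", 40)),
                   tab, id = "run2")
  sc <- find_supercharged(p)
  expect_equal(sc$start[sc$sign == "positive"],
               min(which(brute_window_charges(p$sequence, tab) >= 14)))
})

test_that("the omnibus normality statistic matches an independent reference", {
  # expected values frozen from an external implementation of the
  # D'Agostino-Pearson K2 test on the same data
  x1 <- c(2.3, -1.1, 0.4, 0.9, -0.6, 1.8, -2.2, 0.1, 0.7, -0.3, 1.2, -1.7,
          0.5, 2.9, -0.8, 0.2, -1.3, 1.1, 0.6, -0.9)
  r1 <- dagostino_pearson_test(x1)
  expect_equal(r1$statistic, 0.15940379565099294, tolerance = 1e-10)
  expect_equal(r1$p_value, 0.9233915703972132, tolerance = 1e-10)
  expect_equal(r1$z_skew, 0.367738261319269, tolerance = 1e-10)
  expect_equal(r1$z_kurt, -0.15547465006512784, tolerance = 1e-10)
  x2 <- c(0.5, 1.2, 2.1, 3.3, 4.0, 5.2, 6.1, 7.4, 8.8, 10.1, 12.5, 15.9,
          21.3, 29.8, 45.2, 80.6)
  r2 <- dagostino_pearson_test(x2)
  expect_equal(r2$statistic, 20.963707292849943, tolerance = 1e-10)
  expect_equal(r2$p_value, 2.8040696785073795e-05, tolerance = 1e-8)
  expect_error(dagostino_pearson_test(1:7), "n >= 8")
})

test_that("trait correlation picks Pearson for Gaussian margins, Spearman otherwise", {
  set.seed(31)
  x <- rnorm(500)
  y <- 2 * x + 0.5 * rnorm(500)
  r <- correlate_with_trait(x, y)
  expect_equal(r$method, "pearson")
  expect_gt(r$estimate, 0.9)
  xl <- exp(rnorm(500, sd = 1.5))
  yl <- xl + exp(rnorm(500, sd = 1.5))
  r <- correlate_with_trait(xl, yl)
  expect_equal(r$method, "spearman")
  expect_warning(rc <- correlate_with_trait(rep(1, 50), rnorm(50)), "constant")
  expect_true(is.na(rc$estimate))
  expect_error(correlate_with_trait(1:5, 1:5), "n < 8")
})
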