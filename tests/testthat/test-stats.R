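test_that("correlation PCA reproduces closed-form eigenstructure", {
  # rank-1 case: two perfectly correlated variables
  x <- rnorm(50)
  p1 <- pca_metrics(data.frame(a = x, b = 2 * x + 3),
                    metric_cols = c("a", "b"))
  expect_equal(p1$variance_pct[1], 100, tolerance = 1e-9)

  # population correlation 0.5: eigenvalues (1 +/- rho)/2 -> 75% / 25%
  set.seed(123)
  n <- 1e5
  u <- rnorm(n)
  v <- 0.5 * u + sqrt(1 - 0.25) * rnorm(n)
  p2 <- pca_metrics(data.frame(a = u, b = v), metric_cols = c("a", "b"))
  expect_equal(p2$variance_pct, c(75, 25), tolerance = 0.01)

  expect_equal(sum(p2$variance_pct), 100, tolerance = 1e-12)
  # scores are centered and sized like the variance shares
  expect_lt(max(abs(colMeans(p2$scores))), 1e-10)
  sc_var <- apply(p2$scores, 2, var)
  expect_equal(unname(sc_var / sum(sc_var)), p2$variance_pct / 100,
               tolerance = 1e-12)

  expect_error(pca_metrics(data.frame(a = rnorm(5), b = rep(1, 5)),
                           metric_cols = c("a", "b")), "zero-variance.*b")
})

test_that("PCA sign convention makes the dominant loading positive", {
  set.seed(4)
  d <- as.data.frame(matrix(rnorm(200), ncol = 4))
  p <- pca_metrics(d, metric_cols = names(d), group = rep(c("x", "y"), 25))
  for (j in seq_len(ncol(p$loadings)))
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  expect_named(p$hulls, c("x", "y"))
})

test_that("one-way ANOVA matches the hand-decomposed 3x3 table", {
  v <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- one_way_anova(v, g)
  expect_equal(res$table$df, c(2, 6))
  expect_equal(res$table$sum_sq, c(6, 6))  # SSB = 6, SSW = 6
  expect_equal(res$table$F[1], 3)
  expect_equal(res$table$sum_sq[1] + res$table$sum_sq[2],
               sum((v - mean(v))^2), tolerance = 1e-10)
})

test_that("degenerate and well-separated group structures are handled", {
  res <- suppressWarnings(one_way_anova(rep(5, 9), rep(c("a", "b", "c"), 3)))
  expect_true(res$undefined_f)

  set.seed(2)
  v <- c(rnorm(10, 0, 0.1), rnorm(10, 50, 0.1))
  res2 <- one_way_anova(v, rep(c("lo", "hi"), each = 10))
  expect_true(all(res2$pairwise$p_adjusted < 0.001))
  expect_false(res2$letters[["hi"]] == res2$letters[["lo"]])
})

test_that("Tukey adjusted p agrees with direct studentized-range computation", {
  set.seed(31)
  v <- rnorm(24, rep(c(0, 0.5, 2), each = 8))
  g <- rep(c("a", "b", "c"), each = 8)
  res <- one_way_anova(v, g)
  mse <- res$table$mean_sq[2]; dfe <- res$table$df[2]
  means <- tapply(v, g, mean)
  for (i in seq_len(nrow(res$pairwise))) {
    pr <- strsplit(res$pairwise$contrast[i], "-")[[1]]
    q <- unname(abs(means[pr[1]] - means[pr[2]])) / sqrt(mse / 8)
    expect_equal(res$pairwise$p_adjusted[i],
                 ptukey(q, 3, dfe, lower.tail = FALSE), tolerance = 1e-8)
  }
  expect_true(all(res$pairwise$p_adjusted >= res$pairwise$p_raw - 1e-12))
  expect_true(all(res$pairwise$p_adjusted <= 1))
})

test_that("compact letters join exactly the non-different groups", {
  lt <- ergtune:::compact_letters(
    contrasts = c("b-a", "c-a", "c-b"),
    p_adj = c(0.5, 0.001, 0.001),
    group_levels = c("a", "b", "c"))
  expect_equal(unname(lt["a"]), "a")
  expect_equal(unname(lt["b"]), "a")
  expect_equal(unname(lt["c"]), "b")
})

test_that("two-way ANOVA: additive balanced designs give zero interaction SS", {
  a <- rep(c("w1", "w2"), each = 4)
  b <- rep(rep(c("g1", "g2"), each = 2), 2)
  y <- ifelse(a == "w2", 1, 0) + ifelse(b == "g2", 3, 0)
  res <- suppressWarnings(two_way_anova(y, a, b))
  expect_lt(res$table$sum_sq[res$table$term == "A:B"], 1e-10)
})

test_that("two-way F values match a brute-force model-comparison oracle", {
  # oracle: Type II SS by explicit residual-SS differences
  oracle_ss <- function(y, A, B) {
    d <- data.frame(y = y, A = A, B = B)
    rss <- function(fm) sum(resid(lm(fm, data = d))^2)
    full2 <- rss(y ~ A + B)
    list(A = rss(y ~ B) - full2,
         B = rss(y ~ A) - full2,
         AB = full2 - rss(y ~ A + B + A:B))
  }
  set.seed(55)
  for (i in 1:5) {
    nA <- sample(2:4, 1); nB <- sample(2:3, 1)
    reps <- sample(3:5, 1)
    A <- factor(rep(seq_len(nA), each = nB * reps))
    B <- factor(rep(rep(seq_len(nB), each = reps), nA))
    y <- rnorm(length(A)) + as.numeric(A) * 0.3 + as.numeric(B) * 0.5
    res <- two_way_anova(y, A, B)
    os <- oracle_ss(y, A, B)
    tab <- res$table
    expect_equal(tab$sum_sq[tab$term == "A"], os$A, tolerance = 1e-8)
    expect_equal(tab$sum_sq[tab$term == "B"], os$B, tolerance = 1e-8)
    expect_equal(tab$sum_sq[tab$term == "A:B"], os$AB, tolerance = 1e-8)
    dfe <- tab$df[tab$term == "Residuals"]
    mse <- tab$sum_sq[tab$term == "Residuals"] / dfe
    expect_equal(tab$F[tab$term == "A"],
                 (os$A / (nA - 1)) / mse, tolerance = 1e-8)
  }
})

test_that("incomplete wavelength levels are dropped with a warning", {
  A <- c("350", "350", "400", "400", "400", "400", "450", "450", "450", "450")
  B <- c("apo", "apo", "apo", "apo", "cry", "cry", "apo", "apo", "cry", "cry")
  y <- rnorm(10)
  expect_warning(res <- two_way_anova(y, A, B), "350")
  expect_equal(res$dropped_levels, "350")
})

test_that("Bonferroni adjustment multiplies raw p capped at 1", {
  expect_equal(p.adjust(0.01, "bonferroni", n = 6), 0.06)
  set.seed(77)
  y <- rnorm(60, rep(c(0, 0, 3), 20))
  A <- rep(c("w1", "w2"), each = 30)
  B <- rep(rep(c("g1", "g2", "g3"), each = 10), 2)
  res <- two_way_anova(y, A, B)
  expect_true(all(res$pairwise$p_adjusted >= res$pairwise$p_raw))
  expect_true(all(res$pairwise$p_adjusted <= 1))
})

test_that("simple effects appear only when the interaction is significant", {
  set.seed(88)
  A <- rep(c("w450", "w550", "w650"), each = 20)
  B <- rep(rep(c("pop", "cem"), each = 10), 3)
  y0 <- rnorm(60, 0, 0.5)
  res0 <- two_way_anova(y0, A, B)
  expect_true(all(res0$pairwise$level == "marginal"))
  y1 <- y0 + ifelse(A == "w450" & B == "pop", -4, 0)
  res1 <- two_way_anova(y1, A, B)
  expect_true(any(res1$pairwise$level == "w450"))
  w450 <- res1$pairwise[res1$pairwise$level == "w450", ]
  expect_lt(w450$p_adjusted, 0.001)
})

test_that("assumption screen runs Levene and per-group normality", {
  set.seed(9)
  v <- rnorm(400)
  g <- rep(c("a", "b"), each = 200)
  ch <- assumption_checks(v, g)
  expect_false(ch$levene$degenerate)
  expect_true(ch$levene$p > 0 && ch$levene$p <= 1)
  expect_equal(nrow(ch$normality), 2)
  expect_false(any(ch$normality$degenerate))

  # a constant group degenerates the screen
  ch2 <- assumption_checks(c(rep(1, 10), rnorm(10)), rep(c("a", "b"), each = 10))
  expect_true(ch2$levene$degenerate)
  expect_true(ch2$normality$degenerate[ch2$normality$group == "a"])

  # uniform data are flagged as non-normal with high power
  rej <- replicate(100, {
    u <- runif(400)
    assumption_checks(c(u, rnorm(400)),
                      rep(c("u", "n"), each = 400))$normality$p[2] < 0.01
  })
  expect_gte(mean(rej), 0.95)
})

test_that("naive KS variant is exposed alongside Lilliefors", {
  set.seed(10)
  v <- rnorm(100); g <- rep(c("a", "b"), each = 50)
  lil <- assumption_checks(v, g, normality = "lilliefors")
  ks <- assumption_checks(v, g, normality = "ks_naive")
  expect_false(identical(lil$normality$p, ks$normality$p))
})

test_that("matched-filter report mirrors the printed morph examples", {
  wl <- c(400, 450, 500, 550, 600, 650)
  # Popa-like: thresholds minimized at 550, reflectance peaking at 560
  tun_p <- data.frame(group = "Popa", wavelength_nm = wl,
                      mean_threshold = c(-1, -2, -2.5, -3.2, -2.8, -1.5),
                      se = 0.1, n = 5)
  ref_p <- summarize_group(list(gaussian_curve(center = 560, sigma = 45)),
                           group_key = "Popa")
  rp <- matched_filter_report(tun_p, ref_p)
  expect_equal(rp$sensitivity_peak_nm, 550)
  expect_equal(rp$reflectance_peak_nm, 560)
  expect_equal(rp$mismatch_nm, 10)

  # Cemetery-like: reflectance peak 642, minimum threshold 600
  tun_c <- data.frame(group = "Cemetery", wavelength_nm = wl,
                      mean_threshold = c(-1, -1.8, -2.2, -2.8, -3.1, -2.0),
                      se = 0.1, n = 5)
  ref_c <- summarize_group(list(gaussian_curve(center = 642, sigma = 50)),
                           group_key = "Cemetery")
  rc <- matched_filter_report(tun_c, ref_c)
  expect_equal(rc$mismatch_nm, 42)

  # coincident peaks give zero mismatch
  tun_0 <- transform(tun_p, mean_threshold = ifelse(wavelength_nm == 550, -4, -1))
  ref_0 <- summarize_group(list(gaussian_curve(center = 550, sigma = 40)),
                           group_key = "Popa")
  expect_equal(matched_filter_report(tun_0, ref_0)$mismatch_nm, 0)

  # non-overlapping ranges are rejected
  ref_short <- summarize_group(list(gaussian_curve(center = 560, sigma = 45,
                                                   range_nm = c(500, 600))),
                               group_key = "Popa")
  expect_error(matched_filter_report(tun_p, ref_short), "cover")
  expect_error(matched_filter_report(tun_p[1:2, ], ref_p), "fewer than 3")
})
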