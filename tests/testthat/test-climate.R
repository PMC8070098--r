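# Thornthwaite chain and drought-index aggregation.

test_that("heat index handles frozen months and matches direct evaluation", {
  expect_equal(heat_index(rep(0, 12)), 0)
  expect_equal(heat_index(rep(-10, 12)), 0)
  expect_equal(heat_index(rep(5, 12)), 12) # (5/5)^1.514 = 1 per month
  # direct evaluation: 12 * exp(1.514 * log(4))
  expect_equal(heat_index(rep(20, 12)), 12 * exp(1.514 * log(4)),
               tolerance = 1e-12)
  # frozen months contribute nothing
  Tm <- c(rep(-3, 6), rep(20, 6))
  expect_equal(heat_index(Tm), 6 * exp(1.514 * log(4)), tolerance = 1e-12)
  expect_error(heat_index(rep(5, 11)), "12")
})

test_that("PET exponent is the published cubic of the heat index", {
  expect_equal(thorn_exponent(0), 0.49239)
  # polynomial written out term by term as the oracle
  for (I in c(12, 50, 97.9, 100)) {
    expect_equal(thorn_exponent(I),
                 6.75e-7 * I^3 - 7.71e-5 * I^2 + 1.792e-2 * I + 0.49239,
                 tolerance = 1e-12)
  }
  expect_error(thorn_exponent(-1), "non-negative")
})

test_that("day length behaves at the equator, poles and mid-latitudes", {
  # equatorial day length is ~12 h all year (slight excess from the
  # 0.8333-degree sun-altitude correction)
  for (m in 1:12) expect_equal(day_length(0, m), 12, tolerance = 0.2)
  expect_true(all(abs(day_length(0, 1:12) - 12.1) < 0.05))
  # polar day and night via arccos clamping
  expect_equal(day_length(80, 6), 24)
  expect_equal(day_length(-80, 6), 0)
  # independent step-by-step evaluation at latitude 30, June (J = 166)
  A <- asin(0.39795 * cos(0.2163108 +
                            2 * atan(0.9671396 * tan(0.00860 * (166 - 186)))))
  arg <- (sin(0.8333 * pi / 180) + sin(30 * pi / 180) * sin(A)) /
    (cos(30 * pi / 180) * cos(A))
  expect_equal(day_length(30, 6), 24 - 24 / pi * acos(arg), tolerance = 1e-12)
  # equinox months are near 12 h at non-polar latitudes
  for (lat in c(-60, -30, 0, 30, 60))
    expect_equal(day_length(lat, 3), 12, tolerance = 0.6)
})

test_that("monthly PET follows the Thornthwaite formula and its zero branch", {
  Tm <- c(-5, rep(20, 11))
  cl <- monthly_climate("a", 10, Tm, rep(50, 12))
  prof <- monthly_pet(cl)
  expect_equal(prof$pet[1], 0) # T <= 0 branch
  expect_true(all(prof$pet[-1] > 0))
  expect_equal(prof$radiation, prof$day_length / 12)
  # direct evaluation of the chain for month 6 (cm -> mm conversion)
  I <- sum((Tm[Tm > 0] / 5)^1.514)
  a <- 6.75e-7 * I^3 - 7.71e-5 * I^2 + 1.792e-2 * I + 0.49239
  L6 <- day_length(10, 6) / 12
  expect_equal(prof$pet[6], 1.6 * L6 * (10 * 20 / I)^a * 10, tolerance = 1e-12)
  # PET increases with temperature at fixed I, a, L (a > 0)
  p1 <- 1.6 * L6 * (10 * 18 / I)^a
  p2 <- 1.6 * L6 * (10 * 22 / I)^a
  expect_true(p2 > p1)
})

test_that("drought index compares PET with precipitation and is capped at 100", {
  cl <- monthly_climate("a", 0, rep(20, 12), rep(0, 12))
  prof <- monthly_pet(cl)
  # P = 0 -> DI = 100
  expect_equal(monthly_di(prof, cl)$di, rep(100, 12))
  # P = PET -> DI = 0; P = 2 PET -> DI = -100
  pet <- prof$pet
  cl0 <- monthly_climate("a", 0, rep(20, 12), pet)
  expect_equal(monthly_di(prof, cl0)$di, rep(0, 12))
  cl2 <- monthly_climate("a", 0, rep(20, 12), 2 * pet)
  expect_equal(monthly_di(prof, cl2)$di, rep(-100, 12))
  # frozen month: PET = 0 -> DI defined as 0
  clf <- monthly_climate("a", 0, c(-2, rep(20, 11)), rep(10, 12))
  di <- monthly_di(monthly_pet(clf), clf)$di
  expect_equal(di[1], 0)
  # DI strictly decreases in P and never exceeds 100
  for (P in c(0, 10, 50, 200)) {
    clP <- monthly_climate("a", 0, rep(20, 12), rep(P, 12))
    expect_true(all(monthly_di(prof, clP)$di <= 100))
  }
  d1 <- monthly_di(prof, monthly_climate("a", 0, rep(20, 12), rep(10, 12)))$di
  d2 <- monthly_di(prof, monthly_climate("a", 0, rep(20, 12), rep(20, 12)))$di
  expect_true(all(d2 < d1))
})

test_that("timeframe aggregation does window means with wrapping", {
  cl <- monthly_climate("a", 0, rep(20, 12), rep(0, 12))
  prof <- monthly_di(monthly_pet(cl), cl)
  prof$di <- c(100, 100, 100, rep(0, 9))
  expect_equal(aggregate_di(prof, "m3"), 100)
  expect_equal(aggregate_di(prof, "m6"), 50)
  expect_equal(aggregate_di(prof, "m12"), 25)
  expect_equal(aggregate_di(prof, "T1"), 100)
  expect_equal(aggregate_di(prof, "T2"), 0)
  # wrapping: anchored at December the 3-month window is Dec, Jan, Feb
  expect_equal(aggregate_di(prof, "m3", anchor_month = 12), 200 / 3)
  # constant DI -> every aggregate equals it; aggregates bounded by min/max
  prof$di <- rep(7, 12)
  for (tf in c("m3", "m6", "m12", "T1", "T2", "T3", "T4"))
    expect_equal(aggregate_di(prof, tf), 7)
  prof$di <- rnorm(12)
  for (tf in c("m3", "m6", "T3"))
    expect_true(aggregate_di(prof, tf) >= min(prof$di) &&
                  aggregate_di(prof, tf) <= max(prof$di))
  expect_error(aggregate_di(prof, "m9"), "unknown timeframe")
})

test_that("index scaling is a sample-sd z-score and idempotent", {
  tab <- data.frame(accession = c("a", "b"), taxon = c("x", "x"),
                    m3 = c(0, 2), m6 = c(1, 1))
  expect_warning(out <- scale_indices(tab), "zero variance")
  expect_equal(out$m3_z, c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(out$m6_z, c(0, 0))
  expect_equal(mean(out$m3_z), 0)
  expect_equal(sd(out$m3_z), 1)
  # scaling again refreshes the _z columns to the same values
  out2 <- suppressWarnings(scale_indices(out))
  expect_equal(out2$m3_z, out$m3_z)
})

test_that("drought_index_table runs the chain per accession", {
  ct <- data.frame(accession = c("a1", "a2"), taxon = c("w", "c"),
                   latitude = c(25, 30), longitude = -110)
  for (m in 1:12) ct[[sprintf("t%02d", m)]] <- c(22, 18)
  for (m in 1:12) ct[[sprintf("p%02d", m)]] <- c(10, 80)
  tab <- drought_index_table(ct, scale = TRUE)
  expect_equal(nrow(tab), 2)
  expect_true(all(c("m3", "m6", "m12", "T1", "T2", "T3", "T4", "m3_z")
                  %in% names(tab)))
  # the dry accession is more drought stressed on every timeframe
  expect_true(all(tab[1, c("m3", "m6", "m12")] > tab[2, c("m3", "m6", "m12")]))
})

test_that("group comparison routes by normality and matches the exact rank-sum", {
  # identical distributions in every group -> nonparametric route, p = 1
  tab <- data.frame(taxon = rep(c("a", "b"), each = 4),
                    m3 = rep(c(1, 1, 1, 10), 2)) # skewed -> nonparametric
  cmp <- compare_groups(tab, "m3")
  expect_equal(cmp$route, "kruskal_wilcoxon")
  expect_equal(cmp$pairs$p, 1)

  # non-overlapping groups, no ties: exact rank-sum tail via exhaustive
  # permutation of ranks
  # heavy right skew keeps the Shapiro screen from routing to ANOVA
  x1 <- c(seq(0.1, 0.7, 0.1), 50)
  x2 <- x1 + 100
  tab2 <- data.frame(taxon = rep(c("a", "b"), each = 8), m3 = c(x1, x2))
  cmp2 <- compare_groups(tab2, "m3")
  expect_equal(cmp2$route, "kruskal_wilcoxon")
  expect_equal(cmp2$pairs$p, min(1, oracle_ranksum_p(x1, x2)),
               tolerance = 1e-10)

  # three clean normal groups -> ANOVA + Tukey with one p per pair
  set.seed(7)
  tab3 <- data.frame(taxon = rep(c("a", "b", "c"), each = 10),
                     m3 = rnorm(30) + rep(c(0, 0, 3), each = 10))
  cmp3 <- compare_groups(tab3, "m3")
  expect_equal(cmp3$route, "anova_tukey")
  expect_equal(nrow(cmp3$pairs), 3)
  expect_true(cmp3$pairs$p[cmp3$pairs$pair == "c-a"] < 0.01)

  # Bonferroni: adjusted p = min(1, p * n_pairs) against a direct wilcox run
  set.seed(11)
  tab4 <- data.frame(taxon = rep(c("a", "b", "c"), each = 6),
                     m3 = c(rexp(6), rexp(6), rexp(6) + 4))
  cmp4 <- compare_groups(tab4, "m3")
  if (cmp4$route == "kruskal_wilcoxon") {
    raw <- suppressWarnings(
      wilcox.test(tab4$m3[tab4$taxon == "a"],
                  tab4$m3[tab4$taxon == "b"]))$p.value
    expect_equal(cmp4$pairs$p[cmp4$pairs$pair == "b-a"],
                 min(1, raw * 3), tolerance = 1e-10)
  }

  # undersized groups are excluded with a warning
  tab5 <- data.frame(taxon = c(rep("a", 5), rep("b", 5), "c"),
                     m3 = c(rnorm(10), 5))
  expect_warning(cmp5 <- compare_groups(tab5, "m3"), "fewer than 2")
})
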