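# Effect sizes, dispatch policy, summary tables, pipeline determinism.

test_that("Hedge's g matches its closed form and is antisymmetric", {
  set.seed(3)
  x <- rnorm(30)
  expect_equal(hedges_g(x, x + 0), 0, tolerance = 1e-12)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(hedges_g(a, b), -hedges_g(b, a), tolerance = 1e-12)
  # two unit-variance groups one mean apart: g ~ 0.98 after correction
  a1 <- scale(rnorm(20))[, 1] # exactly mean 0, sd 1
  b1 <- a1[sample(20)] + 1
  g <- hedges_g(b1, a1)
  df <- 38
  j <- exp(lgamma(df / 2) - log(sqrt(df / 2)) - lgamma((df - 1) / 2))
  expect_equal(g, j * 1, tolerance = 1e-9)
  expect_equal(g, 0.98, tolerance = 0.01)
  expect_error(hedges_g(rep(1, 5), rep(1, 5)), "pooled variance")
  expect_error(hedges_g(1, c(1, 2)), "at least 2")
})

test_that("dispatch picks the path the data call for", {
  mk <- function(vals) grouped_measure(vals,
    rep(c("+/+", "+/-", "-/-"), each = length(vals) / 3))
  # normal, equal variance -> ANOVA + Tukey
  set.seed(2)
  r1 <- compare_groups(mk(rnorm(45, rep(c(0, 0.5, 1), each = 15))))
  expect_equal(r1$path, "anova")
  expect_true(all(c("p", "hedges_g") %in% names(r1$posthoc)))
  # normal, strongly unequal variance -> Welch + Games-Howell
  set.seed(2)
  vals_h <- c(rnorm(15, 0, 0.3), rnorm(15, 0.5, 0.3), rnorm(15, 1, 4))
  r2 <- compare_groups(mk(vals_h))
  expect_equal(r2$path, "welch")
  # heavy-tailed -> Kruskal-Wallis + Dunn
  set.seed(1)
  r3 <- compare_groups(mk(rcauchy(45)))
  expect_equal(r3$path, "kruskal")
  expect_true("p_adj" %in% names(r3$posthoc))
  # too few observations: skipped, not an error
  r4 <- compare_groups(grouped_measure(c(1, 2, 3, 4),
                                       c("a", "a", "b", "b")))
  expect_equal(r4$path, "skipped")
})

test_that("dispatch is a pure function of the screening outcomes", {
  # identical data always dispatch identically
  set.seed(21)
  for (rep_i in 1:5) {
    vals <- rnorm(36, rep(c(0, 1, 2), each = 12), rep(c(1, 1, 3), each = 12))
    gm <- grouped_measure(vals, rep(c("+/+", "+/-", "-/-"), each = 12))
    p1 <- compare_groups(gm)$path
    p2 <- compare_groups(gm)$path
    expect_identical(p1, p2)
    # and matches the screening recomputed independently
    grp <- rep(c("a", "b", "c"), each = 12)
    normal <- all(vapply(split(vals, grp),
                         function(x) stats::shapiro.test(x)$p.value, 0)
                  > 0.05)
    homo <- car::leveneTest(vals ~ factor(grp))[1, "Pr(>F)"] > 0.05
    expected <- if (!normal) "kruskal" else if (homo) "anova" else "welch"
    expect_identical(p1, expected)
  }
})

test_that("summary tables carry mean, SEM and n per cell", {
  gm <- grouped_measure(c(1, 2, 3, 10), c("+/+", "+/+", "+/+", "-/-"),
                        zone = "LES", measure = "x")
  tab <- summarize_table(gm)
  expect_equal(sum(tab$n), 4)
  wt <- tab[tab$genotype == "+/+", ]
  expect_equal(wt$mean, 2)
  expect_equal(wt$sem, sd(1:3) / sqrt(3))
  ko <- tab[tab$genotype == "-/-", ]
  expect_true(is.na(ko$sem))
  expect_match(ko$formatted, "\\(1\\)")
})

test_that("the pipeline is deterministic and robust to empty input", {
  expect_warning(rep0 <- run_pipeline(character(0)), "empty")
  expect_equal(nrow(rep0$cells), 0)
  presets <- c("type_I:+/+:LES", "type_I:-/-:LES")
  r1 <- run_pipeline(presets, n_per_group = 2, seed = 9,
                     analyses = "gv")
  r2 <- run_pipeline(presets, n_per_group = 2, seed = 9,
                     analyses = "gv")
  expect_identical(r1$cells, r2$cells)
  expect_equal(nrow(r1$cells), 4)
  expect_equal(length(r1$failures), 0)
  # the genotype contrast survives the cohort analysis
  vh <- tapply(r1$cells$v_half, r1$cells$genotype, mean)
  expect_lt(vh[["+/+"]], -75)
  expect_gt(vh[["-/-"]], -45)
})

test_that("median-range style and age partial correlation work", {
  gm <- grouped_measure(c(14, 22, 287, 45), rep("+/+", 4), zone = "LES",
                        measure = "age")
  tab <- summarize_table(gm, style = "median_range")
  expect_equal(tab$median, median(c(14, 22, 287, 45)))
  expect_match(tab$formatted, "14–287")
  # partial correlation: a pure age effect survives group adjustment
  set.seed(8)
  n <- 60
  geno <- rep(c("+/+", "-/-"), each = n / 2)
  age <- runif(n, 5, 300)
  vals <- 2 * (geno == "-/-") - 0.01 * age + rnorm(n, 0, 0.3)
  pc <- age_partial_cor(grouped_measure(vals, geno), age)
  expect_lt(pc$r, -0.5)
  expect_lt(pc$p, 1e-3)
  # no age effect: correlation near zero
  vals0 <- 2 * (geno == "-/-") + rnorm(n, 0, 0.3)
  pc0 <- age_partial_cor(grouped_measure(vals0, geno), age)
  expect_lt(abs(pc0$r), 0.3)
})

test_that("the pipeline analyses saved recordings alongside presets", {
  d <- withr::local_tempdir()
  rec <- simulate_voltage_clamp(
    make_preset("type_I", "-/-", "LES"),
    build_protocol("type_I", step_voltages = seq(-124, 40, 10)))
  rec_dir <- file.path(d, "cell01")
  write_recording(rec, rec_dir)
  rep <- run_pipeline(c(rec_dir, "type_I:-/-:LES"), n_per_group = 1,
                      seed = 4, analyses = "gv")
  expect_equal(nrow(rep$cells), 2)
  expect_equal(length(rep$failures), 0)
  # the saved and the freshly simulated knockout agree on the midpoint
  expect_lt(diff(range(rep$cells$v_half)), 3)
  # and a directly analysed recording returns the same measures
  row <- analyze_recording(rec, "gv")
  expect_equal(row$v_half, -40.2, tolerance = 0.01)
})
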