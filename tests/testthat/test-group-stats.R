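# independent rank-arithmetic Kruskal-Wallis H, as a brute-force oracle
hOracle <- function(values, groups) {
  r <- rank(values)
  N <- length(r)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, sum)^2 / tabulate(factor(groups))) - 3 * (N + 1)
  tt <- table(values)
  H / (1 - sum(tt^3 - tt) / (N^3 - N))
}

test_that("the two-sample worked example gives H = 3.857 and exact p = 0.10", {
  kw <- kruskalWallis(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(kw@H, 3.857, tolerance = 1e-3)
  expect_equal(kw@H, hOracle(1:6, rep(1:2, each = 3)))
  expect_equal(kw@method, "exact permutation")
  # oracle: enumerate all 20 assignments of labels to the fixed ranks
  hs <- apply(combn(6, 3), 2, function(sel)
    hOracle(1:6, replace(rep(2, 6), sel, 1)))
  expect_equal(mean(hs >= kw@H - 1e-9), 0.10)
  expect_equal(kw@pValue, 0.10)
})

test_that("identical samples give a null omnibus result", {
  kw <- kruskalWallis(list(a = rep(2, 3), b = rep(2, 4), c = rep(2, 3)))
  expect_equal(kw@H, 0)
  expect_equal(kw@pValue, 1)
})

test_that("the chi-square route matches base R and the exact route at moderate N", {
  set.seed(31)
  x <- rnorm(18); g <- rep(1:3, each = 6)
  kw <- kruskalWallis(x, g)
  expect_equal(kw@method, "chi-square")
  ref <- kruskal.test(x, g)
  expect_equal(kw@H, unname(ref$statistic))
  expect_equal(kw@pValue, unname(ref$p.value))
  y <- rnorm(15); h <- rep(1:2, c(8, 7))
  exact <- kruskalWallis(y, h, exact = TRUE)
  approx <- kruskalWallis(y, h, exact = FALSE)
  expect_lt(abs(exact@pValue - approx@pValue), 0.05)
})

test_that("H is invariant under strictly monotone transforms of the data", {
  set.seed(5)
  x <- rlnorm(20); g <- rep(1:4, each = 5)
  expect_equal(kruskalWallis(x, g)@H, kruskalWallis(log(x), g)@H)
  expect_equal(kruskalWallis(x, g)@H, kruskalWallis(x^3, g)@H)
})

test_that("degenerate group layouts are rejected", {
  expect_error(kruskalWallis(1:5, rep("a", 5)), "2 groups")
  expect_error(kruskalWallis(list(a = 1:3, b = numeric(0))),
               "groups|observation")
})

test_that("Dunn z statistics match an independent rank computation", {
  set.seed(17)
  x <- c(rnorm(5), rnorm(6, 1), rnorm(4, 3), rnorm(5, 3))
  g <- rep(c("a", "b", "c", "d"), c(5, 6, 4, 5))
  tab <- posthocPairwise(x, g, method = "none")
  # oracle: direct pooled-rank arithmetic
  r <- rank(x); N <- length(x)
  tt <- table(x)
  s2 <- N * (N + 1) / 12 - sum(tt^3 - tt) / (12 * (N - 1))
  for (i in seq_len(nrow(tab))) {
    g1 <- tab$group1[i]; g2 <- tab$group2[i]
    z <- (mean(r[g == g1]) - mean(r[g == g2])) /
      sqrt(s2 * (1 / sum(g == g1) + 1 / sum(g == g2)))
    expect_equal(tab$z[i], z, tolerance = 1e-10)
  }
  expect_equal(posthocPairwise(x, g, method = "holm")$pAdj,
               p.adjust(tab$p, "holm"))
})

test_that("post-hoc ordering reflects group separation and ties give p = 1", {
  idtab <- posthocPairwise(list(a = rep(1, 4), b = rep(1, 4), c = rep(1, 4)))
  expect_true(all(idtab$pAdj == 1))
  set.seed(2)
  x <- c(rnorm(6), rnorm(6, 0.5), rnorm(6, 8))
  g <- rep(c("a", "b", "c"), each = 6)
  tab <- posthocPairwise(x, g)
  expect_equal(tab$group1, c("a", "a", "b"))     # lexicographic rows
  expect_lt(max(tab$pAdj[tab$group2 == "c"]), tab$pAdj[1])
  expect_error(posthocPairwise(list(a = 1:3, b = 4:6)), "3 groups")
})

test_that("metric correlation reproduces hand-computed R squared", {
  tab <- data.frame(subject = rep(sprintf("s%d", 1:5), 2), group = "g",
                    metric = rep(c("A", "B"), each = 5),
                    value = c(1, 2, 3, 4, 5, 2, 1, 4, 3, 5))
  mc <- metricCorrelation(tab, "A", "B")
  expect_equal(mc$r, 0.8)
  expect_equal(mc$rSquared, 0.64)
  # y = x exactly
  tab2 <- tab; tab2$value <- rep(1:5, 2)
  expect_equal(metricCorrelation(tab2, "A", "B")$rSquared, 1)
  # independence at large n
  set.seed(3)
  n <- 2000
  tab3 <- data.frame(subject = rep(sprintf("s%d", 1:n), 2), group = "g",
                     metric = rep(c("A", "B"), each = n), value = rnorm(2 * n))
  expect_lt(metricCorrelation(tab3, "A", "B")$rSquared, 0.01)
  tab4 <- tab; tab4$value[1:5] <- 2
  expect_warning(mc4 <- metricCorrelation(tab4, "A", "B"), "constant")
  expect_true(mc4$degenerate)
})

test_that("the group report mirrors the lesion/location comparison layout", {
  set.seed(41)
  pre <- groupPresets()
  rows <- do.call(rbind, lapply(names(pre), function(nm) {
    n <- pre[[nm]]@nSubjects
    data.frame(subject = paste0(nm, seq_len(n)), group = nm, metric = "Ki",
               value = influxConstant(pre[[nm]]) * rlnorm(n, 0, 0.2))
  }))
  rep <- runGroupAnalysis(rows, metrics = "Ki",
                          contrasts = defaultLesionContrasts())
  expect_named(rep$results$Ki,
               c("subcutaneous_lesions", "in_situ_lesions",
                 "tumors_by_location", "inflammations_by_location"))
  omni <- rep$results$Ki$in_situ_lesions$omnibus
  expect_s4_class(omni, "GroupComparisonResult")
  expect_lt(omni@pValue, 0.05)
  # pairwise table only appears for significant omnibus with >= 3 groups
  sub <- rep$results$Ki$subcutaneous_lesions$omnibus
  if (sub@pValue < 0.05) expect_gt(nrow(sub@pairwise), 0)
  expect_equal(nrow(omni@pairwise), 0)           # two-group contrast
})

test_that("group reports on identical values are all-null and degenerate tables error", {
  tab <- data.frame(subject = sprintf("s%d", 1:8),
                    group = rep(c("a", "b"), each = 4),
                    metric = "Ki", value = rep(1, 8))
  rep <- runGroupAnalysis(tab)
  omni <- rep$results$Ki$all_groups$omnibus
  expect_equal(omni@pValue, 1)
  s <- rep$results$Ki$all_groups$summary
  expect_equal(s$mean, c(1, 1))
  one <- tab[tab$group == "a", ]
  expect_error(runGroupAnalysis(one), "missing contrast groups")
  expect_error(runGroupAnalysis(tab, metrics = "SUVmax"), "no values")
})
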