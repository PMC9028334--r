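test_that("functional-state classification is inclusive and monotone", {
  tbl <- data.frame(condition = "x", channel = 1, block = 1:6,
                    water_count = c(0, 4, 5, 6, 12, 5))
  calls <- classify_blocks(tbl, threshold = 5)
  expect_equal(calls$functional, c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE))
  # all-zero table: all non-functional
  z <- classify_blocks(data.frame(water_count = rep(0, 10)))
  expect_false(any(z$functional))
  # monotone in threshold: raising it never increases the functional count
  set.seed(5)
  counts <- data.frame(water_count = rpois(200, 5))
  nfun <- vapply(0:15, function(th) sum(classify_blocks(counts, th)$functional),
                 numeric(1))
  expect_true(all(diff(nfun) <= 0))
})

test_that("block table bookkeeping yields the expected replication counts", {
  # 250 ns, 4 channels, 2 conditions, 10 ns blocks
  set.seed(3)
  mk_channel <- function() permeation_events(sort(runif(60, 0, 250)), 250)
  conds <- list(control = replicate(4, mk_channel(), simplify = FALSE),
                DEX = replicate(4, mk_channel(), simplify = FALSE))
  tbl <- build_block_table(conds, block_length = 10)
  expect_equal(nrow(tbl), 200)
  expect_equal(sum(tbl$condition == "control"), 100)  # repetitions per condition
  expect_equal(sum(tbl$condition == "DEX" & tbl$channel == 2), 25)  # per channel
  expect_equal(sort(unique(tbl$block)), 1:25)
})

test_that("chi-square equals the closed form and rejects zero margins", {
  ct <- contingency_chi2(matrix(c(10, 0, 0, 10), 2))
  expect_equal(ct$statistic, 20)
  expect_lt(ct$p_value, 1e-4)
  # independence: balanced table gives 0 / p = 1
  ct0 <- contingency_chi2(matrix(c(5, 5, 5, 5), 2))
  expect_equal(ct0$statistic, 0)
  expect_equal(ct0$p_value, 1)
  # matches the manual Sum (O-E)^2/E oracle on an arbitrary table
  expect_equal(contingency_chi2(matrix(c(7, 3, 2, 11), 2))$statistic,
               brute_chi2(7, 2, 3, 11))
  # brute-force agreement on a randomized sample of small tables
  set.seed(11)
  for (i in 1:50) {
    t4 <- rmultinom(1, sample(8:40, 1), rep(0.25, 4))
    m <- matrix(t4, 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(contingency_chi2(m)$statistic,
                 brute_chi2(m[1, 1], m[1, 2], m[2, 1], m[2, 2]))
  }
  expect_error(contingency_chi2(matrix(c(0, 0, 3, 4), 2)), "zero margin")
  # vector interface builds the 2x2 table
  f <- rep(c(TRUE, FALSE), c(12, 8)); h <- rep(c(TRUE, FALSE, TRUE), c(10, 8, 2))
  ctv <- contingency_chi2(f, h)
  expect_equal(sum(ctv$table), 20)
})

test_that("test selection routes to the branch the assumptions dictate", {
  set.seed(71)
  # two gaussian equal-variance groups: Student's t
  r <- compare_groups(c(rnorm(25), rnorm(25, 2)), rep(c("a", "b"), each = 25))
  expect_match(r$test_name, "Student")
  expect_true(r$parametric)
  expect_lt(r$p_value, 0.01)
  # heavy-tailed data: Mann-Whitney
  rh <- compare_groups(exp(c(rnorm(25, sd = 2), rnorm(25, sd = 2))),
                       rep(c("a", "b"), each = 25))
  expect_match(rh$test_name, "Mann-Whitney")
  expect_false(rh$parametric)
  # identical heavy-tailed groups: rank test with p = 1
  v <- exp(seq(-3, 3, length.out = 12))
  ri <- compare_groups(c(v, v), rep(c("a", "b"), each = 12))
  expect_false(ri$parametric)
  expect_equal(ri$p_value, 1)
  # constant group forces the rank branch with a note
  rc <- compare_groups(c(rep(1, 5), rnorm(5, 3)), rep(c("a", "b"), each = 5))
  expect_false(rc$parametric)
  expect_match(rc$notes, "constant")
  # three gaussian groups: ANOVA + Tukey with pairwise table
  r3 <- compare_groups(c(rnorm(20), rnorm(20, 3), rnorm(20)),
                       rep(c("a", "b", "c"), each = 20))
  expect_match(r3$test_name, "ANOVA")
  expect_equal(nrow(r3$pairwise), 3)
  # three heavy-tailed groups: pairwise Wilcoxon + Bonferroni
  r3h <- compare_groups(exp(c(rnorm(20, sd = 2), rnorm(20, 2, 2), rnorm(20, sd = 2))),
                        rep(c("a", "b", "c"), each = 20))
  expect_match(r3h$test_name, "Wilcoxon")
  expect_equal(r3h$correction, "Bonferroni")
  expect_error(compare_groups(rnorm(4), c("a", "a", "b", "b")), "n >= 3")
})

test_that("two shifted groups are detected with high power", {
  set.seed(81)
  hits <- mean(replicate(500, {
    compare_groups(c(rnorm(25), rnorm(25, 2)), rep(c("a", "b"), each = 25))$p_value < 0.01
  }))
  expect_gte(hits, 0.95)
})

test_that("slab-wise Spearman correlation handles coverage and nulls", {
  # identical series in every slab: rho = 1 wherever testable
  set.seed(14)
  a <- runif(300, 0, 180); z <- runif(300, 0, 40)
  sc <- slice_dipole_correlation(a, a, z, slab_width = 10, z_range = c(0, 40))
  expect_equal(sc$rho[sc$status == "ok"], rep(1, sum(sc$status == "ok")))
  # independent series at n = 1e4: |rho| below 0.05
  b <- runif(1e4, 0, 180); c2 <- runif(1e4, 0, 180)
  sc0 <- slice_dipole_correlation(b, c2, rep(5, 1e4), slab_width = 10,
                                  z_range = c(0, 10))
  expect_lt(abs(sc0$rho[1]), 0.05)
  # a single all-covering slab equals the global Spearman rho
  sg <- slice_dipole_correlation(a, sin(a / 50) + a, z, slab_width = 40,
                                 z_range = c(0, 40))
  expect_equal(sg$rho[1], cor(a, sin(a / 50) + a, method = "spearman"))
  # slabs with < 5 frames report insufficient data
  si <- slice_dipole_correlation(a[1:3], a[1:3], c(1, 2, 3), slab_width = 10,
                                 z_range = c(0, 20))
  expect_true(all(si$status == "insufficient data"))
  expect_true(all(is.na(si$rho)))
  # pattern recovery: correlated in one slab, null elsewhere
  d1 <- generate_dipole_pair(0.8, 4000, seed = 6)
  d0 <- generate_dipole_pair(0, 4000, seed = 7)
  ang1 <- c(d1$angle1, d0$angle1); ang2 <- c(d1$angle2, d0$angle2)
  zz <- c(rep(5, 4000), rep(15, 4000))
  sp <- slice_dipole_correlation(ang1, ang2, zz, slab_width = 10, z_range = c(0, 20))
  expect_equal(sp$rho[1], 6 / pi * asin(0.4), tolerance = 0.1 / (6 / pi * asin(0.4)))
  expect_lt(abs(sp$rho[2]), 0.1)
})

test_that("reports are schema-stable and deterministic", {
  r0 <- build_report()
  expect_equal(r0$provenance$package, "poreflux")
  expect_length(r0$results, 0)
  tbl <- data.frame(condition = "x", channel = 1, block = 1:3, water_count = 1:3)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  build_report(list(blocks = tbl), file = f1, seed = 42,
               parameters = list(threshold = 5), csv = TRUE)
  build_report(list(blocks = tbl), file = f2, seed = 42,
               parameters = list(threshold = 5))
  expect_identical(readLines(f1), readLines(f2))  # byte-identical body
  expect_true(file.exists(sub("\\.json$", "_blocks.csv", f1)))
  parsed <- jsonlite::read_json(f1)
  expect_equal(parsed$provenance$seed, 42)
  expect_named(parsed$results, "blocks")
  expect_error(build_report(list(tbl)), "named")
})
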