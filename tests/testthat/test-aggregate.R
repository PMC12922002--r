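fake_table <- function(scores, condition = "A", day = 1L,
                       ids = sprintf("s%02d", seq_along(scores))) {
  data.frame(experiment = "E", spheroid_id = ids, condition = condition,
             day = day, object_id = 1L, mesenchymal_score = scores,
             stringsAsFactors = FALSE)
}

test_that("CSV export writes header plus one line per row and round-trips", {
  tab <- fake_table(c(1.5, 2.25, 3.125))
  tab$area <- c(100.1, 200.2, 300.3)
  f <- file.path(tempdir(), "meas.csv")
  n <- export_csv(tab, f)
  expect_equal(n, 3L)
  expect_length(readLines(f), 4L)
  back <- read.csv(f)
  expect_equal(back$mesenchymal_score, tab$mesenchymal_score,
               tolerance = 1e-5)
  expect_equal(back$area, tab$area, tolerance = 1e-5)
  # empty table allowed -> header only
  export_csv(tab[0, ], f)
  expect_length(readLines(f), 1L)
  expect_error(export_csv(tab[0, ], f, allow_empty = FALSE), "empty")
})

test_that("summaries compute per-group mean and sample sd", {
  s <- summarize_scores(fake_table(c(2, 4)))
  expect_equal(s$n, 2L)
  expect_equal(s$mean_ms, 3)
  expect_equal(s$sd_ms, sqrt(2))
})

test_that("a fully crossed design yields one summary per cell", {
  tabs <- list()
  for (cond in c("A", "B", "C", "D")) for (d in 1:5)
    tabs[[paste(cond, d)]] <- fake_table(runif(3, 1, 5), cond, d)
  s <- summarize_scores(do.call(rbind, tabs))
  expect_equal(nrow(s), 20L)
  expect_true(all(s$n == 3L))
})

test_that("summaries equal a brute-force group-by recomputation", {
  set.seed(51)
  tab <- do.call(rbind, lapply(c("A", "B", "C"), function(cond)
    do.call(rbind, lapply(1:4, function(d)
      fake_table(rlnorm(6, 0.5, 0.4), cond, d)))))
  s <- summarize_scores(tab)
  for (i in seq_len(nrow(s))) {
    x <- tab$mesenchymal_score[tab$condition == s$condition[i] &
                               tab$day == s$day[i]]
    expect_equal(s$mean_ms[i], mean(x))
    expect_equal(s$sd_ms[i], sd(x))
  }
})

test_that("objects are averaged within spheroid before summarizing", {
  tab <- rbind(fake_table(c(1, 3), ids = c("s1", "s1")),  # one spheroid, 2 objects
               fake_table(4, ids = "s2"))
  s <- summarize_scores(tab)
  expect_equal(s$n, 2L)           # two spheroids, not three objects
  expect_equal(s$mean_ms, 3)      # mean of {2, 4}
})

test_that("missing condition or day is a schema error", {
  tab <- fake_table(c(1, 2))
  tab$day[2] <- NA
  expect_error(summarize_scores(tab), "missing condition/day")
})

test_that("normalization maps the control baseline to exactly 1", {
  tab <- rbind(fake_table(c(1.9, 2.1), "BSA", 1L),
               fake_table(c(4.9, 5.1), "OA", 1L),
               fake_table(c(2.9, 3.1), "BSA", 5L))
  s <- normalize_to_control(summarize_scores(tab), "BSA", 1L)
  expect_identical(s$normalized_mean_ms[s$condition == "BSA" & s$day == 1], 1)
  expect_equal(s$normalized_mean_ms[s$condition == "OA"], 2.5)
  expect_error(normalize_to_control(summarize_scores(tab), "XX", 1L), "control")
})

test_that("normalized summaries are invariant under global rescaling", {
  set.seed(52)
  tab <- rbind(fake_table(runif(5, 1, 2), "BSA", 1L),
               fake_table(runif(5, 2, 4), "OA", 1L))
  s1 <- normalize_to_control(summarize_scores(tab), "BSA", 1L)
  tab2 <- tab; tab2$mesenchymal_score <- tab2$mesenchymal_score * 7.3
  s2 <- normalize_to_control(summarize_scores(tab2), "BSA", 1L)
  expect_equal(s1$normalized_mean_ms, s2$normalized_mean_ms)
})

test_that("the t-test matches the pooled-variance closed form", {
  tab <- rbind(fake_table(1:5, "A", 1L), fake_table(2:6, "B", 1L))
  r <- compare_conditions(tab, "A", "B", 1L)
  # hand-computed pooled form: means 3 and 4, s^2 = 2.5 in both groups
  sp2 <- (4 * 2.5 + 4 * 2.5) / 8
  t_expected <- (3 - 4) / sqrt(sp2 * (1 / 5 + 1 / 5))
  expect_equal(r$statistic, t_expected)
  expect_equal(r$p_value, 2 * pt(t_expected, df = 8))
  expect_equal(c(r$n_a, r$n_b), c(5L, 5L))

  same <- rbind(fake_table(c(3, 3, 3), "A", 1L), fake_table(c(3, 3, 3), "B", 1L))
  r0 <- compare_conditions(same, "A", "B", 1L)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
})

test_that("group exchange flips t and preserves p", {
  set.seed(53)
  tab <- rbind(fake_table(rnorm(6, 2), "A", 1L), fake_table(rnorm(6, 3), "B", 1L))
  r1 <- compare_conditions(tab, "A", "B", 1L)
  r2 <- compare_conditions(tab, "B", "A", 1L)
  expect_equal(r1$statistic, -r2$statistic)
  expect_equal(r1$p_value, r2$p_value)
  expect_error(compare_conditions(fake_table(1, "A", 1L), "A", "B", 1L),
               ">= 2")
})

test_that("the test holds its nominal type-I error under the null", {
  set.seed(54)
  hits <- 0L
  for (i in 1:1000) {
    tab <- rbind(fake_table(rnorm(15, 2, 0.5), "A", 1L),
                 fake_table(rnorm(15, 2, 0.5), "B", 1L))
    if (compare_conditions(tab, "A", "B", 1L)$p_value <= 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 1000, 0.03)
  expect_lte(hits / 1000, 0.07)
})

test_that("exported summaries survive a write/read/re-summarize cycle", {
  set.seed(55)
  tab <- rbind(fake_table(rlnorm(8, 0.2, 0.3), "BSA", 1L),
               fake_table(rlnorm(8, 0.8, 0.3), "OA", 1L))
  f <- file.path(tempdir(), "roundtrip.csv")
  export_csv(tab, f)
  back <- read.csv(f, stringsAsFactors = FALSE)
  s1 <- summarize_scores(tab); s2 <- summarize_scores(back)
  expect_equal(s2$mean_ms, s1$mean_ms, tolerance = 1e-5)
  expect_equal(s2$sd_ms, s1$sd_ms, tolerance = 1e-4)
})

test_that("per-day control comparisons assemble into a report", {
  set.seed(56)
  tab <- do.call(rbind, lapply(c("BSA", "OA50", "OA150"), function(cond)
    do.call(rbind, lapply(c(1L, 5L), function(d)
      fake_table(rnorm(5, ifelse(cond == "BSA", 1, 2), 0.3), cond, d)))))
  rep <- compare_all_to_control(tab, "BSA")
  expect_equal(nrow(rep), 4L)                # 2 conditions x 2 days
  expect_true(all(rep$control == "BSA"))
  expect_true(all(rep$n_control == 5L))
  repf <- compare_all_to_control(tab, "BSA", fdr = TRUE)
  expect_true("p_adjusted" %in% names(repf))
  expect_true(all(repf$p_adjusted >= repf$p_value))
})
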