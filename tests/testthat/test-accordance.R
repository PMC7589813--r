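test_that("Fisher Z' transform: closed forms, round trip, worked values", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3))
  expect_equal(round(inverse_fisher_z(2.51), 3), 0.987)
  r <- seq(-0.99, 0.99, by = 0.03)
  expect_equal(inverse_fisher_z(fisher_z(r)), r, tolerance = 1e-12)
  expect_true(all(diff(fisher_z(r)) > 0))   # monotone increasing
  expect_error(fisher_z(1))
  expect_error(fisher_z(-1.2))
})

test_that("shared variance is the squared correlation in percent", {
  expect_equal(round(shared_variance(0.987), 2), 97.42)
  expect_equal(shared_variance(0), 0)
  expect_equal(shared_variance(1), 100)
  expect_equal(shared_variance(-0.5), 25)
})

fake_segments <- function(n, participant = "p1", group = "adult",
                          condition = "daytime", activity = NA_character_,
                          ln_sd1, ln_hf, seed = 1) {
  set.seed(seed)
  out <- tibble::tibble(
    participant = participant, group = group,
    segment_start = seq(0, by = 30, length.out = n),
    condition = condition, activity = activity,
    overall_valid = TRUE, ln_sd1 = ln_sd1)
  for (b in paste0("ln_hf", 1:6)) out[[b]] <- ln_hf
  out
}

test_that("per-participant accordance: clamping, nulls, and cell floors", {
  # perfectly duplicated variable: r clamps just below 1
  s <- fake_segments(50, ln_sd1 = rnorm(50), ln_hf = NA)
  for (b in paste0("ln_hf", 1:6)) s[[b]] <- s$ln_sd1
  acc <- participant_accordance(s)
  expect_equal(unique(acc$pearson_r), 1)
  expect_equal(unique(acc$fisher_z), fisher_z(1 - 1e-12))

  # independent noise: |r| < 0.2 almost always at n = 200
  small <- vapply(1:40, function(i) {
    set.seed(i)
    s <- fake_segments(200, ln_sd1 = rnorm(200), ln_hf = rnorm(200), seed = i)
    abs(participant_accordance(s)$pearson_r[1])
  }, numeric(1))
  expect_gte(mean(small < 0.2), 0.95)

  # fewer valid segments than the floor: cell missing
  s2 <- fake_segments(8, ln_sd1 = rnorm(8), ln_hf = rnorm(8))
  expect_true(all(is.na(participant_accordance(s2, min_segments = 10)$pearson_r)))

  # zero variance in one variable: missing, not an error
  s3 <- fake_segments(30, ln_sd1 = rep(2, 30), ln_hf = rnorm(30))
  expect_true(all(is.na(participant_accordance(s3)$pearson_r)))
})

test_that("activity sub-conditions are carved out of daytime", {
  s <- fake_segments(60, ln_sd1 = rnorm(60), ln_hf = rnorm(60))
  s$activity <- rep(c("low", "high", NA), 20)
  acc <- participant_accordance(s, min_segments = 5)
  expect_setequal(unique(acc$condition),
                  c("daytime", "low_activity", "high_activity"))
  n_day <- acc$n_segments[acc$condition == "daytime"][1]
  n_low <- acc$n_segments[acc$condition == "low_activity"][1]
  expect_equal(n_day, 60)
  expect_equal(n_low, 20)
})

# simulated accordance-level data for the ANOVA design
sim_anova_data <- function(n_per_group = 8, band_group_effect = 0,
                           sd_noise = 0.3, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(
    participant = paste0("s", seq_len(2 * n_per_group)),
    band = paste0("hf", 1:6),
    condition = c("sleep", "daytime"),
    stringsAsFactors = FALSE)
  grid$group <- ifelse(as.integer(sub("s", "", grid$participant)) <=
                         n_per_group, "toddler", "adult")
  subj_int <- stats::setNames(rnorm(2 * n_per_group, 2, 0.3),
                              unique(grid$participant))
  grid$z <- subj_int[grid$participant] +
    0.1 * (grid$condition == "sleep") +
    band_group_effect * (grid$band %in% c("hf3", "hf4")) *
      (grid$group == "toddler") +
    rnorm(nrow(grid), 0, sd_noise)
  tibble::as_tibble(grid)
}

test_that("mixed ANOVA degrees of freedom match the split-plot design", {
  d <- sim_anova_data(n_per_group = 10, band_group_effect = 0.6)
  fit <- mixed_anova(d, dv = "z", within = c("band", "condition"),
                     between = "group")
  tab <- tidy(fit)
  bg <- tab[tab$effect == "band:group", ]
  expect_equal(bg$df1, 5)
  expect_equal(bg$df2, 5 * (20 - 2))   # 5 x (N - groups)
  g <- tab[tab$effect == "group", ]
  expect_equal(g$df2, 20 - 2)
  bcg <- tab[tab$effect == "band:condition:group", ]
  expect_equal(bcg$df1, 5)
  expect_equal(glance(fit)$n_subjects, 20)
})

test_that("ANOVA sums of squares decompose the total exactly", {
  d <- sim_anova_data(n_per_group = 6, band_group_effect = 0.4, seed = 3)
  fit <- mixed_anova(d, dv = "z", within = c("band", "condition"),
                     between = "group")
  tab <- tidy(fit)
  resid_ss <- sum(vapply(summary(fit$fit), function(s) {
    t <- s[[1]]
    t[trimws(rownames(t)) == "Residuals", "Sum Sq"]
  }, numeric(1)))
  total_ss <- sum((d$z - mean(d$z))^2)
  expect_equal(sum(tab$sumsq) + resid_ss, total_ss, tolerance = 1e-8)
})

test_that("null and non-null interaction effects are detected at the right rates", {
  # type-I error of the band x group interaction near the nominal level
  pvals <- vapply(1:300, function(i) {
    d <- sim_anova_data(n_per_group = 6, band_group_effect = 0, seed = i)
    fit <- mixed_anova(d, dv = "z", within = c("band", "condition"),
                       between = "group")
    t <- tidy(fit)
    t$p.value[t$effect == "band:group"]
  }, numeric(1))
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0.01)
  expect_lte(rate, 0.10)

  # power at a programmed band x group effect
  hits <- vapply(1:60, function(i) {
    d <- sim_anova_data(n_per_group = 8, band_group_effect = 0.5,
                        seed = 1000 + i)
    fit <- mixed_anova(d, dv = "z", within = c("band", "condition"),
                       between = "group")
    t <- tidy(fit)
    t$p.value[t$effect == "band:group"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("flat within-subject data yield near-zero within-effect F", {
  d <- sim_anova_data(n_per_group = 5, band_group_effect = 0, sd_noise = 0)
  d$z <- stats::setNames(rnorm(10, 2, 0.5),
                         unique(d$participant))[d$participant]
  d$z <- d$z + rnorm(nrow(d), 0, 1e-8)  # break exact degeneracy
  fit <- mixed_anova(d, dv = "z", within = c("band", "condition"),
                     between = "group")
  tab <- tidy(fit)
  wf <- tab[tab$effect %in% c("band", "condition", "band:condition"), ]
  expect_true(all(wf$statistic < 10))   # no spurious within-subject signal
  expect_true(all(wf$p.value > 1e-4))
})

test_that("participants with incomplete cells are dropped listwise", {
  d <- sim_anova_data(n_per_group = 6, band_group_effect = 0.3, seed = 9)
  d <- d[!(d$participant == "s1" & d$band == "hf2"), ]
  fit <- mixed_anova(d, dv = "z", within = c("band", "condition"),
                     between = "group")
  expect_equal(glance(fit)$n_subjects, 11)
  expect_equal(glance(fit)$n_dropped, 1)
})

test_that("summary tables have the expected layout and degenerate behaviour", {
  s <- fake_segments(40, ln_sd1 = rnorm(40, 3, 0.3), ln_hf = rnorm(40, 5, 0.5))
  s$mean_hr <- 90; s$sdnn <- 40; s$ln_sd2 <- 4; s$median_resp_rate <- 16
  tab <- summarize_tables(s)
  hr <- tab[tab$variable == "mean_hr", ]
  expect_equal(hr$n, 1)
  expect_equal(hr$mean, 90)
  expect_equal(hr$sd, 0)

  acc <- participant_accordance(s, min_segments = 5)
  at <- summarize_tables(acc)
  expect_equal(sort(unique(at$band)), paste0("hf", 1:6))
  expect_equal(nrow(at), 6)   # one condition present
})
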