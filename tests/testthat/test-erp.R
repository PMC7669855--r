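# Conventional sensor-level analysis: evoked averaging, the sliding-window
# species x expression ANOVA, the contiguity reporting rule, and planned
# paired contrasts.

test_that("evoked averaging is the arithmetic mean over kept trials", {
  d <- array(0, c(4, 1, 8))
  d[1, 1, ] <- 0; d[2, 1, ] <- 2; d[3, 1, ] <- 2; d[4, 1, ] <- 99
  ep <- tiny_epochs(d, labels = c("S", "S", "S", "OB"))
  ev <- average_evoked(ep, "S")
  expect_equal(unique(as.vector(ev$data)), 4 / 3)
  expect_equal(ev$n_trials, 3)

  # identical trials: average equals any trial
  ep2 <- tiny_epochs(array(rep(5, 3 * 1 * 8), c(3, 1, 8)))
  expect_equal(as.vector(average_evoked(ep2)$data), rep(5, 8))

  # rejected trials are excluded
  ep$kept[2] <- FALSE
  expect_equal(unique(as.vector(average_evoked(ep, "S")$data)), 1)
  expect_error(average_evoked(ep, "HD"), "no kept trials")
})

test_that("grand average of equal-trial subjects equals the pooled mean", {
  set.seed(4)
  pool <- array(rnorm(6 * 2 * 16), c(6, 2, 16))
  ep_a <- tiny_epochs(pool[1:3, , , drop = FALSE])
  ep_b <- tiny_epochs(pool[4:6, , , drop = FALSE], subject = "sub02")
  ga <- grand_average(list(average_evoked(ep_a), average_evoked(ep_b)))
  expect_equal(ga$data, apply(pool, c(2, 3), mean), tolerance = 1e-12)
  expect_equal(ga$subject, "grand")
})

test_that("the sliding-window grid enumerates 59 windows over 0-250 ms", {
  evokeds <- face_evokeds(n_subjects = 4, n_channels = 1, seed = 2)
  stats <- sliding_window_anova(evokeds)
  expect_equal(nrow(stats), 59)
  expect_equal(min(stats$start), 0)
  expect_equal(max(stats$start), 232)
  expect_equal(unique(stats$end - stats$start), 16)
  expect_true(all(stats$end <= 250))
  expect_true(all(stats$p_species >= 0 & stats$p_species <= 1))
})

test_that("a missing condition is reported with the subject", {
  evokeds <- face_evokeds(n_subjects = 3, n_channels = 1)
  evokeds[[2]]$HD <- NULL
  expect_error(sliding_window_anova(evokeds), "subject 2.*HD")
})

test_that("species effect F equals the squared paired t on species means", {
  evokeds <- face_evokeds(n_subjects = 8, n_channels = 1, seed = 6)
  stats <- sliding_window_anova(evokeds, range = c(0, 20))
  w <- stats[1, ]
  times <- evokeds[[1]][[1]]$times
  sel <- times >= w$start & times < w$end
  dog <- sapply(evokeds, function(e)
    mean(sapply(c("AD", "ND", "HD"), function(cc) mean(e[[cc]]$data[1, sel]))))
  human <- sapply(evokeds, function(e)
    mean(sapply(c("AH", "NH", "HH"), function(cc) mean(e[[cc]]$data[1, sel]))))
  pc <- planned_contrast(dog, human)
  expect_equal(w$F_species, pc$t^2, tolerance = 1e-8)
  expect_equal(w$p_species, pc$p, tolerance = 1e-8)
})

test_that("contiguity filter reports only runs of >= 2 adjacent windows", {
  mk <- function(starts, p_sig) {
    df <- data.frame(channel = "P4", start = seq(0, 96, 4))
    df$end <- df$start + 16
    df$p_species <- 0.5
    df$p_expression <- 0.5
    df$p_interaction <- 0.5
    df$p_species[df$start %in% starts] <- p_sig
    attr(df, "step") <- 4
    class(df) <- c("sliding_window_stats", "data.frame")
    df
  }
  # single isolated significant window: nothing reported
  expect_equal(nrow(contiguity_filter(mk(40, 0.01))), 0)
  # run 28, 32, 36 -> one interval [28, 52)
  out <- contiguity_filter(mk(c(28, 32, 36), 0.01))
  expect_equal(nrow(out), 1)
  expect_equal(out$start, 28)
  expect_equal(out$end, 52)
  expect_equal(out$n_windows, 3)
  # gap splits runs: 28,32 and 44,48 -> two intervals
  out2 <- contiguity_filter(mk(c(28, 32, 44, 48), 0.01))
  expect_equal(nrow(out2), 2)
  expect_equal(out2$start, c(28, 44))
  expect_equal(out2$end, c(48, 64))
  # deterministic and order-independent
  df <- mk(c(28, 32, 44, 48), 0.01)
  df_shuffled <- df[sample(nrow(df)), ]
  attr(df_shuffled, "step") <- 4
  class(df_shuffled) <- c("sliding_window_stats", "data.frame")
  expect_equal(contiguity_filter(df_shuffled), out2,
               ignore_attr = TRUE)
})

test_that("planned paired contrast matches the hand-computed t", {
  x <- c(1, 2, 1, 2, 1, 2, 1, 2)
  pc <- planned_contrast(x + 10, rep(10, 8))
  expect_equal(pc$t, 1.5 / (sd(x) / sqrt(8)), tolerance = 1e-6)
  expect_equal(pc$t, 7.937254, tolerance = 1e-4)
  expect_equal(pc$df, 7)
  # identical pairs
  same <- planned_contrast(rep(2, 5), rep(2, 5))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # sign flip negates t, p unchanged
  flip <- planned_contrast(rep(10, 8), x + 10)
  expect_equal(flip$t, -pc$t, tolerance = 1e-10)
  expect_equal(flip$p, pc$p, tolerance = 1e-10)
  expect_error(planned_contrast(1, 1), "at least 2")
  expect_error(planned_contrast(1:3, 1:2), "paired")
})

test_that("a planted species effect is reported at the planted channel", {
  evokeds <- face_evokeds(
    n_subjects = 8, n_channels = 2, noise_sd = 0.5,
    effect = list(conditions = c("AD", "ND", "HD"), channel = 2,
                  window = c(60, 90), amplitude = 3), seed = 11)
  stats <- sliding_window_anova(evokeds)
  found <- contiguity_filter(stats)
  sp <- found[found$effect == "species" & found$channel == "ch2", ]
  expect_gt(nrow(sp), 0)
  expect_true(any(sp$start <= 60 & sp$end >= 90))
})

test_that("Greenhouse-Geisser adjustment rescales the dfs by a valid epsilon", {
  n_subj <- 6
  evokeds <- face_evokeds(n_subjects = n_subj, n_channels = 1, seed = 9)
  raw <- sliding_window_anova(evokeds, range = c(0, 40))
  gg <- sliding_window_anova(evokeds, range = c(0, 40), gg = TRUE)
  # textbook oracle: eps = tr(CSC)^2 / ((k-1) tr((CSC)^2)) on the
  # covariance of the per-subject expression means (averaged over
  # species), clamped to [1/(k-1), 1]; adjusted p = pf(F, 2e, 2(n-1)e)
  times <- evokeds[[1]][[1]]$times
  for (i in seq_len(nrow(gg))) {
    sel <- times >= gg$start[i] & times < gg$end[i]
    ex_means <- t(vapply(evokeds, function(e) c(
      (mean(e$AD$data[1, sel]) + mean(e$AH$data[1, sel])) / 2,
      (mean(e$ND$data[1, sel]) + mean(e$NH$data[1, sel])) / 2,
      (mean(e$HD$data[1, sel]) + mean(e$HH$data[1, sel])) / 2
    ), numeric(3)))
    S <- cov(ex_means)
    C <- diag(3) - 1 / 3
    Sc <- C %*% S %*% C
    eps <- max(min(sum(diag(Sc))^2 / (2 * sum(Sc^2)), 1), 0.5)
    p_expected <- stats::pf(gg$F_expression[i], 2 * eps,
                            2 * (n_subj - 1) * eps, lower.tail = FALSE)
    expect_equal(gg$p_expression[i], p_expected, tolerance = 1e-8)
  }
  expect_equal(gg$p_species, raw$p_species)  # 2 levels: no correction
})
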