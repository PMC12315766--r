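# Two-cluster burst sets around distinct templates are the workhorse fixture
# for the shape-space tests.
two_cluster_bursts <- function(n_per = 60, fs = 250, noise = 0.5, seed = 1) {
  set.seed(seed)
  t1 <- make_burst_waveform(burst_family(18, n_cycles = 3), fs)
  t2 <- make_burst_waveform(burst_family(27, n_cycles = 4), fs)
  w <- rbind(
    matrix(rep(t1, n_per), n_per, byrow = TRUE),
    matrix(rep(t2, n_per), n_per, byrow = TRUE)) +
    matrix(rnorm(2 * n_per * length(t1), sd = noise), 2 * n_per)
  list(w = w, cluster = rep(1:2, each = n_per), t1 = t1, t2 = t2)
}

test_that("trial sampling is fractional, seeded and whole-trial", {
  e <- make_test_epochs(n_trials = 240, n_channels = 1, fs = 5,
                        timing = default_timing(trial_end = 1, post_end = 1))
  w <- matrix(rnorm(480 * 11), 480)
  b <- fake_bursts(trial = rep(1:240, each = 2), channel = "C3",
                   period = "task", class = "left_hand", waveforms = w)
  s <- sample_bursts(b, e, fraction = 0.1, seed = 3)
  expect_equal(length(unique(s$info$trial)), 24)        # ceil(0.1 * 240)
  expect_equal(nrow(s$info), 48)                        # whole trials
  s2 <- sample_bursts(b, e, fraction = 0.1, seed = 3)
  expect_identical(s$info, s2$info)                     # seeded
  all_b <- sample_bursts(b, e, fraction = 1, seed = 1)
  expect_equal(nrow(all_b$info), nrow(b$info))          # identity
  expect_error(sample_bursts(b, e, fraction = 0), "fraction")
})

test_that("waveform space: degenerate, orthonormal and complete", {
  w_same <- matrix(rep(1:11, 5), 5, byrow = TRUE)
  sp <- fit_waveform_space(w_same)
  expect_lt(max(abs(score_waveforms(sp, w_same))), 1e-8)   # no variance
  set.seed(2)
  w <- matrix(rnorm(300), 20, 15)
  sp2 <- fit_waveform_space(w, n_axes_min = 15)
  G <- sp2$components %*% t(sp2$components)
  expect_lt(max(abs(G - diag(nrow(G)))), 1e-8)             # orthonormal
  expect_true(all(diff(sp2$explained_variance) <= 1e-12))  # nonincreasing
  # full reconstruction of the scaled, centered data
  z <- sweep(sweep(w, 2, sp2$center), 2, sp2$scale, "/")
  zc <- sweep(z, 2, sp2$mean_scaled)
  sc <- score_waveforms(sp2, w)
  expect_lt(max(abs(sc %*% sp2$components - zc)), 1e-8)
  expect_error(fit_waveform_space(w[1, , drop = FALSE]), "at least 2")
})

test_that("the mean training waveform scores zero on every axis", {
  cl <- two_cluster_bursts()
  sp <- fit_waveform_space(cl$w)
  sc_mean <- score_waveforms(sp, colMeans(cl$w))
  expect_lt(max(abs(sc_mean)), 1e-8)
  expect_error(score_waveforms(sp, matrix(0, 2, 10)), "shape")
})

test_that("a two-cluster set is separated along an early axis", {
  cl <- two_cluster_bursts()
  sp <- fit_waveform_space(cl$w)
  sc <- score_waveforms(sp, cl$w)
  cors <- abs(cor(sc[, 1:3], cl$cluster))
  ax <- which.max(cors)
  expect_gt(cors[ax], 0.95)
  # opposite cluster signs on the discriminating axis
  m1 <- mean(sc[cl$cluster == 1, ax]); m2 <- mean(sc[cl$cluster == 2, ax])
  expect_lt(m1 * m2, 0)
})

# bursts populating all four (channel, laterality) x period cells with
# prescribed per-cell scores on one axis
cell_bursts <- function(task_shift = c(ipsi_C3 = 0, contra_C4 = 0,
                                       ipsi_C4 = 0, contra_C3 = 0),
                        n_cell = 10, n_axes = 9) {
  grid <- expand.grid(channel = c("C3", "C4"),
                      class = c("left_hand", "right_hand"),
                      period = c("baseline", "task"),
                      idx = seq_len(n_cell), stringsAsFactors = FALSE)
  scores <- matrix(0, nrow(grid), n_axes)
  cellname <- ifelse(grid$channel == "C3",
                     ifelse(grid$class == "left_hand", "ipsi_C3",
                            "contra_C3"),
                     ifelse(grid$class == "right_hand", "ipsi_C4",
                            "contra_C4"))
  shift <- ifelse(grid$period == "task", task_shift[cellname], 0)
  scores[, 2] <- shift
  b <- fake_bursts(trial = seq_len(nrow(grid)), channel = grid$channel,
                   period = grid$period, class = grid$class,
                   waveforms = matrix(0, nrow(grid), 11))
  list(bursts = b, scores = scores)
}

test_that("modulation index follows its closed form on constructed cells", {
  roles <- channel_roles()
  # all scores constant -> all u = 0 -> I = 0
  cb0 <- cell_bursts()
  r0 <- modulation_index(cb0$scores, cb0$bursts, roles, m = 2)
  expect_equal(r0$I, 0)
  expect_equal(unname(r0$u), rep(0, 4))
  # u_ipsi^C3 = 2, others 0 -> I = 2
  cb2 <- cell_bursts(c(ipsi_C3 = 2, contra_C4 = 0, ipsi_C4 = 0,
                       contra_C3 = 0))
  r2 <- modulation_index(cb2$scores, cb2$bursts, roles, m = 2)
  expect_equal(r2$I, 2)
  expect_equal(r2$u[["ipsi_C3"]], 2)
  # contralateral C3 task shift delta -> I grows monotonically
  Is <- sapply(c(0.5, 1, 2), function(d) {
    cb <- cell_bursts(c(ipsi_C3 = 0, contra_C4 = 0, ipsi_C4 = 0,
                        contra_C3 = d))
    modulation_index(cb$scores, cb$bursts, roles, m = 2)$I
  })
  expect_true(all(diff(Is) > 0))
})

test_that("modulation index is invariant to score offsets and C3/C4 swap", {
  roles <- channel_roles()
  cb <- cell_bursts(c(ipsi_C3 = 1.3, contra_C4 = 0.4, ipsi_C4 = 0.2,
                      contra_C3 = 0.8))
  base <- modulation_index(cb$scores, cb$bursts, roles, m = 2)$I
  shifted <- cb$scores; shifted[, 2] <- shifted[, 2] + 5
  expect_equal(modulation_index(shifted, cb$bursts, roles, 2)$I, base)
  # swap C3 <-> C4 together with left <-> right
  sw <- cb$bursts
  sw$info$channel <- ifelse(sw$info$channel == "C3", "C4", "C3")
  sw$info$class <- ifelse(sw$info$class == "left_hand", "right_hand",
                          "left_hand")
  expect_equal(modulation_index(cb$scores, sw, roles, 2)$I, base)
})

test_that("modulation index names the empty cell in its error", {
  roles <- channel_roles()
  cb <- cell_bursts()
  drop <- !(cb$bursts$info$channel == "C3" &
              cb$bursts$info$class == "left_hand" &
              cb$bursts$info$period == "task")
  b <- cb$bursts
  b$info <- b$info[drop, , drop = FALSE]
  expect_error(modulation_index(cb$scores[drop, , drop = FALSE], b, roles, 2),
               "ipsi_C3")
})

test_that("axis selection takes the top three of components 2..9", {
  prof <- structure(list(I = c(`2` = 5, `3` = 1, `4` = 4, `5` = 2, `6` = 3,
                               `7` = 0, `8` = 0, `9` = 0), axes = 2:9),
                    class = "bb_modprofile")
  expect_equal(select_axes(prof), c(2, 4, 6))
  tie <- structure(list(I = setNames(rep(1, 8), 2:9), axes = 2:9),
                   class = "bb_modprofile")
  expect_equal(select_axes(tie), c(2, 3, 4))
  # axis 1 is never eligible even with a huge value
  with1 <- structure(list(I = setNames(c(100, rep(1, 8)), 1:9), axes = 1:9),
                     class = "bb_modprofile")
  expect_false(1 %in% select_axes(with1))
  short <- structure(list(I = c(`2` = 1, `3` = NA, `4` = NA, `5` = NA,
                                `6` = NA, `7` = NA, `8` = NA, `9` = NA),
                          axes = 2:9), class = "bb_modprofile")
  expect_error(select_axes(short), "fewer than 3")
})

test_that("kernels average the extreme score groups of each axis", {
  cl <- two_cluster_bursts(noise = 0.3)
  sp <- fit_waveform_space(cl$w)
  sc <- score_waveforms(sp, cl$w)
  ax <- which.max(abs(cor(sc[, 1:4], cl$cluster)))
  ks <- derive_kernels(sc, cl$w, axes = c(ax, ax %% 4 + 1, ax %% 4 + 2))
  expect_equal(nrow(ks$kernels), 6)
  expect_equal(ncol(ks$kernels), ncol(cl$w))
  expect_true(all(is.finite(ks$kernels)))
  # the discriminating axis extremes recover both templates
  r1 <- max(cor(ks$kernels[1, ], cl$t1), cor(ks$kernels[2, ], cl$t1))
  r2 <- max(cor(ks$kernels[1, ], cl$t2), cor(ks$kernels[2, ], cl$t2))
  expect_gt(r1, 0.9)
  expect_gt(r2, 0.9)
  # permutation invariance
  set.seed(4)
  perm <- sample(nrow(cl$w))
  ks2 <- derive_kernels(sc[perm, ], cl$w[perm, ], c(ax, ax %% 4 + 1,
                                                    ax %% 4 + 2))
  expect_equal(ks2$kernels, ks$kernels)
  # degenerate scores: empty-bin error path
  expect_error(derive_kernels(matrix(0, 10, 4), matrix(1, 10, 5), c(1, 2, 3)),
               "degenerate|empty")
})
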