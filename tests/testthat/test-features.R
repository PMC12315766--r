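test_that("kernel convolution acts as a centered same-length filter", {
  e <- make_test_epochs(n_trials = 1, n_channels = 1, fs = 50)
  e$data[] <- 0
  mid <- dim(e$data)[3] %/% 2
  e$data[1, 1, mid] <- 1                          # delta impulse
  k <- matrix(sin(seq(0, 2 * pi, length.out = 13)), 1)
  out <- convolve_kernels(e, k)[[1]]
  half <- 6
  expect_equal(out$data[1, 1, (mid - half):(mid + half)], k[1, ],
               tolerance = 1e-10)
  expect_lt(max(abs(out$data[1, 1, -((mid - half):(mid + half))])), 1e-10)
  # zero input -> zero output
  z <- e; z$data[] <- 0
  expect_lt(max(abs(convolve_kernels(z, k)[[1]]$data)), 1e-12)
  # kernel longer than the epoch
  expect_error(convolve_kernels(e, matrix(0, 1, dim(e$data)[3] + 1)),
               "longer")
})

test_that("matched kernels respond more than mismatched ones", {
  fs <- 250
  t1 <- make_burst_waveform(burst_family(17, n_cycles = 4), fs)
  t2 <- make_burst_waveform(burst_family(28, n_cycles = 4), fs)
  e <- make_test_epochs(n_trials = 1, n_channels = 1, fs = fs, seed = 3)
  e$data <- e$data * 0.1
  ctr <- 700; half <- (length(t1) - 1) / 2
  e$data[1, 1, (ctr - half):(ctr + half)] <-
    e$data[1, 1, (ctr - half):(ctr + half)] + t1
  outs <- convolve_kernels(e, rbind(t1, t2))
  peak_near <- function(o) max(abs(o$data[1, 1, (ctr - 5):(ctr + 5)]))
  expect_gt(peak_near(outs[[1]]), peak_near(outs[[2]]))
  # matched response peaks within 20 ms of the burst trough
  resp <- abs(outs[[1]]$data[1, 1, ])
  expect_lte(abs(which.max(resp) - ctr) / fs, 0.02)
})

test_that("band filtering produces the enumerated copies", {
  e <- make_test_epochs(n_trials = 2, n_channels = 2, fs = 250, seed = 2)
  expect_length(band_filter_copies(e, "mu", bank = FALSE), 1)
  expect_length(band_filter_copies(e, "mu", bank = TRUE), 3)
  beta <- band_filter_copies(e, "beta", bank = TRUE)
  expect_length(beta, 5)
  expect_equal(names(beta)[1], "15-18Hz")
  expect_length(band_filter_copies(e, "mu_beta", bank = TRUE), 8)
  # white noise through the 15-18 Hz bank: >= 90% variance within 14-19 Hz
  x <- beta[[1]]$data[1, 1, ]
  s <- amp_spectrum(x, 250)
  p_in <- sum(s$a[s$f >= 14 & s$f <= 19]^2)
  expect_gt(p_in / sum(s$a^2), 0.9)
})

test_that("CSP solves the generalized eigenproblem", {
  # identical class distributions -> eigenvalues ~ 0.5
  set.seed(6)
  tm <- default_timing(trial_end = 1, post_end = 1)
  ns <- 200
  d <- array(rnorm(40 * 3 * ns), c(40, 3, ns))
  e <- bb_epochs(d, 100, c("C3", "C4", "Cz"),
                 rep(c("left_hand", "right_hand"), 20), tm)
  m <- fit_csp(e, 2)
  expect_lt(max(abs(m$eigenvalues - 0.5)), 0.05)
  # orthogonal sources: class A varies on channel 1 only, B on channel 2
  d2 <- array(rnorm(40 * 2 * ns, sd = 0.01), c(40, 2, ns))
  lab <- rep(c("a", "b"), each = 20)
  d2[lab == "a", 1, ] <- rnorm(20 * ns)
  d2[lab == "b", 2, ] <- rnorm(20 * ns)
  e2 <- bb_epochs(d2, 100, c("c1", "c2"), lab, tm)
  m2 <- fit_csp(e2, 2)
  expect_equal(which.max(abs(m2$filters[1, ])), 1L)  # top filter -> ch 1
  expect_equal(which.max(abs(m2$filters[2, ])), 2L)  # bottom filter -> ch 2
  # stored eigenvalue satisfies w S1 w / (w (S1+S2) w) = lambda
  for (j in 1:2) {
    w <- m2$filters[j, ]
    lam <- as.numeric((w %*% m2$S1 %*% w) /
                        (w %*% (m2$S1 + m2$S2) %*% w))
    expect_equal(lam, m2$eigenvalues[j], tolerance = 1e-6)
  }
  # brute-force oracle: eigen of solve(S1+S2) %*% S1 gives the same lambdas
  or <- sort(Re(eigen(solve(m2$S1 + m2$S2) %*% m2$S1)$values))
  expect_equal(sort(m2$eigenvalues), or[c(1, length(or))], tolerance = 1e-8)
  expect_error(fit_csp(bb_epochs(d2[lab == "a", , , drop = FALSE], 100,
                                 c("c1", "c2"), rep("a", 20), tm), 2),
               "two classes")
})

test_that("CSP is equivariant under channel permutation", {
  sim <- simulate_epochs(simulation_config(n_trials_per_class = 6, seed = 5))
  e <- sim$epochs
  perm <- c(3, 1, 4, 2)
  ep <- e
  ep$data <- e$data[, perm, , drop = FALSE]
  ep$channel_names <- e$channel_names[perm]
  m1 <- fit_csp(e, 4)
  m2 <- fit_csp(ep, 4)
  # same filters up to the permutation (and sign)
  for (j in 1:4) {
    a <- m1$filters[j, perm]; b <- m2$filters[j, ]
    expect_gt(abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2)), 1 - 1e-6)
  }
  # features identical when model and data are permuted consistently
  f1 <- csp_features(m1, e)
  f2 <- csp_features(m2, ep)
  expect_equal(f1, f2, tolerance = 1e-8)
})

fit_csp_swapped <- function(e) {
  # same fit with class roles exchanged (relabel so sort order flips)
  e$labels <- ifelse(e$labels == "left_hand", "z_right", "a_left")
  fit_csp(e, 4)
}

test_that("complementary CSP eigenvalues pair to 1", {
  sim <- simulate_epochs(simulation_config(n_trials_per_class = 6, seed = 8))
  m <- fit_csp(sim$epochs, 4)
  swapped <- fit_csp_swapped(sim$epochs)
  expect_equal(sort(m$eigenvalues) + rev(sort(swapped$eigenvalues)),
               rep(1, 4), tolerance = 1e-8)
})

test_that("log-power features scale and floor as documented", {
  e <- make_test_epochs(n_trials = 4, n_channels = 3, fs = 50)
  m <- fit_csp(e, 2)
  f1 <- csp_features(m, e)
  expect_equal(dim(f1), c(4, 2))
  e2 <- e; e2$data <- 2 * e$data
  expect_equal(csp_features(m, e2), f1 + log(4), tolerance = 1e-10)
  ez <- e; ez$data[1, , ] <- 0
  expect_warning(fz <- csp_features(m, ez), "floored")
  expect_equal(fz[1, ], rep(log(1e-20), 2))
  expect_error(csp_features(m, make_test_epochs(n_channels = 2, fs = 50)),
               "shape")
})

test_that("feature assembly yields the standard column counts", {
  sim <- simulate_epochs(simulation_config(n_trials_per_class = 6, seed = 4))
  e <- sim$epochs
  fit_all <- function(copies) lapply(copies, fit_csp, n_components = 4)
  # 6 kernel copies x 4 CSP components = 24 features
  kern <- matrix(rnorm(6 * 33), 6)
  ck <- convolve_kernels(e, kern)
  fm <- assemble_features(ck, fit_all(ck))
  expect_equal(ncol(fm$values), 24)
  expect_equal(length(fm$feature_names), 24)
  expect_identical(fm$labels, e$labels)
  # single filter -> 4; banks -> 12 / 20 / 32
  single <- band_filter_copies(e, "mu", bank = FALSE)
  expect_equal(ncol(assemble_features(single, fit_all(single))$values), 4)
  mu3 <- band_filter_copies(e, "mu", bank = TRUE)
  expect_equal(ncol(assemble_features(mu3, fit_all(mu3))$values), 12)
  beta5 <- band_filter_copies(e, "beta", bank = TRUE)
  expect_equal(ncol(assemble_features(beta5, fit_all(beta5))$values), 20)
  mb8 <- band_filter_copies(e, "mu_beta", bank = TRUE)
  expect_equal(ncol(assemble_features(mb8, fit_all(mb8))$values), 32)
})
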