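# Stable-state-set labeling, region classification, trajectory evidence.

test_that("stable-state sets serialize and deserialize losslessly", {
  for (labels in list(character(0), "E_0", c("E_x", "E_co"),
                      c("E_0", "E_xz"), c("E_x", "E_xz"))) {
    ss <- stable_state_set(labels)
    back <- parse_stable_state_set(ss$key)
    expect_equal(back$labels, ss$labels)
    expect_equal(back$key, ss$key)
    expect_equal(back$display, ss$display)
  }
  expect_equal(stable_state_set(c("E_x", "E_co"))$display,
               "Coral only or coexistence")
  expect_equal(stable_state_set(character(0))$key, "empty")
})

test_that("printed coexistence routing points classify as stably coexisting", {
  lc <- fixtures("levins_culver")
  for (a in list(c(beta_y = 1.03941, beta_z = 1.76600,
                   gamma_y = 0.93685, gamma_z = 0.22883),
                 c(beta_y = 1.21871, beta_z = 1.48986,
                   gamma_y = 0.75558, gamma_z = 0.23395))) {
    cls <- classify_region(lc, a)
    expect_true("E_co" %in% cls$stable_set$labels)
  }
})

test_that("counts and stable sets are constant within a region", {
  lc <- fixtures("levins_culver")
  arr <- total_boundary(lc)
  rep0 <- c(beta_y = 1.03941, beta_z = 1.76600,
            gamma_y = 0.93685, gamma_z = 0.22883)
  base <- classify_region(lc, rep0)
  sig0 <- paste(sign(stabscape:::arr_eval(arr, matrix(rep0, 1))), collapse = ",")
  set.seed(6)
  got <- 0
  while (got < 10) {
    cand <- rep0 * exp(runif(4, -0.1, 0.1))
    names(cand) <- names(rep0)
    sig <- paste(sign(stabscape:::arr_eval(arr, matrix(cand, 1))), collapse = ",")
    if (sig != sig0) next  # rejection: stay inside the region
    got <- got + 1
    cls <- classify_region(lc, cand)
    expect_equal(cls$stable_set$key, base$stable_set$key)
    expect_equal(cls$n_real_positive, base$n_real_positive)
  }
})

test_that("trajectory evidence distinguishes convergence from decay cases", {
  s <- ode_system("x", "a", "-x")
  ev <- detect_limit_cycle_region(s, c(a = 1), c(x = 1), horizon = 50)
  expect_true(ev$bounded)
  expect_true(ev$converged)

  pp <- fixtures("predator_prey_s2")
  ev2 <- suppressWarnings(detect_limit_cycle_region(pp, c(A = 9/4),
                                    c(x = 1.8, y = 0.3), horizon = 400))
  expect_true(ev2$bounded)
  expect_true(ev2$converged)
  tail_state <- ev2$trajectory[nrow(ev2$trajectory), -1]
  expect_equal(unname(unlist(tail_state)), c(2, 2/9), tolerance = 1e-3)
})
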