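# Stokes-Mueller forward model and least-squares reconstruction.

test_that("generator states match closed-form polarization optics", {
  # horizontal polarizer, QWP aligned: half-intensity horizontal state
  expect_equal(psg_stokes(pol_states(0, 0, 0, 0)), c(0.5, 0.5, 0, 0))
  # QWP at 45 deg to a horizontal linear state: right-circular
  expect_equal(psg_stokes(pol_states(0, 45, 0, 0)), c(0.5, 0, 0, 0.5))
  # arbitrary angles agree with the explicit matrix product
  st <- pol_states(30, 10, 0, 0)
  oracle <- drop(mm_retarder(pi / 2, 10) %*% mm_polarizer(30) %*% c(1, 0, 0, 0))
  expect_equal(psg_stokes(st), oracle, tolerance = 1e-12)
  # generated states are fully polarized
  for (q in seq(0, 150, by = 30)) {
    s <- psg_stokes(pol_states(0, q, 0, 0))
    expect_equal(sum(s[2:4]^2), s[1]^2, tolerance = 1e-12)
  }
})

test_that("analyzer rows match closed-form products and the detection identity", {
  expect_equal(psa_row(pol_states(0, 0, 0, 0)), c(0.5, 0.5, 0, 0))
  expect_equal(psa_row(pol_states(0, 0, 0, 90)), c(0.5, -0.5, 0, 0))
  st <- pol_states(0, 0, 45, 10)
  oracle <- (mm_polarizer(10) %*% mm_retarder(pi / 2, 45))[1, ]
  expect_equal(psa_row(st), oracle, tolerance = 1e-12)

  # detected intensity identity: psa_row . M . psg_stokes
  set.seed(4)
  m <- random_physical_mueller()
  states <- default_pol_sequence()
  sim <- simulate_intensities(m, states)
  direct <- vapply(seq_len(nrow(states)), function(k) {
    drop(psa_row(states[k, ]) %*% m %*% psg_stokes(states[k, ]))
  }, numeric(1))
  expect_equal(sim, direct, tolerance = 1e-12)
})

test_that("crossed and aligned polarizer cases through identity sample", {
  seq_hv <- pol_states(0, 0, 0, 90)   # PSG horizontal, PSA vertical
  expect_equal(simulate_intensities(diag(4), seq_hv), 0)
  # aligned: generator passes half the unpolarized input, the aligned
  # analyzer then transmits the fully polarized beam completely
  seq_hh <- pol_states(0, 0, 0, 0)
  expect_equal(simulate_intensities(diag(4), seq_hh), 0.5)
})

test_that("default protocol is well conditioned and air calibration recovers identity", {
  states <- default_pol_sequence()
  expect_identical(nrow(states), 24L)
  expect_identical(qr(design_matrix(states))$rank, 16L)
  expect_lt(sequence_condition(states), 20)

  stack <- intensity_stack(
    array(simulate_intensities(diag(4), states), c(24, 1, 1)), states
  )
  expect_lt(max(abs(reconstruct_mueller(stack)[, , 1, 1] - diag(4))), 1e-10)
})

test_that("noise-free round trip recovers random physical matrices", {
  set.seed(11)
  states <- default_pol_sequence()
  for (i in 1:25) {
    m <- random_physical_mueller(scale = TRUE)
    stack <- intensity_stack(
      array(simulate_intensities(m, states), c(24, 1, 1)), states
    )
    expect_lt(max(abs(reconstruct_mueller(stack)[, , 1, 1] - m)), 1e-8)
  }
})

test_that("simulated intensities from physical samples are non-negative", {
  set.seed(12)
  states <- default_pol_sequence()
  for (i in 1:20) {
    expect_true(all(simulate_intensities(random_physical_mueller(), states) >= 0))
  }
})

test_that("reconstruction error grows linearly with small noise", {
  set.seed(13)
  states <- default_pol_sequence()
  m <- random_physical_mueller()
  err_at <- function(noise_sd) {
    mean(replicate(40, {
      stack <- intensity_stack(
        array(simulate_intensities(m, states, noise_sd), c(24, 1, 1)), states
      )
      max(abs(reconstruct_mueller(stack)[, , 1, 1] - m))
    }))
  }
  e1 <- err_at(1e-4); e2 <- err_at(2e-4); e4 <- err_at(4e-4)
  expect_gt(e2 / e1, 1.5); expect_lt(e2 / e1, 2.5)
  expect_gt(e4 / e2, 1.5); expect_lt(e4 / e2, 2.5)
})

test_that("degenerate inputs are rejected with informative errors", {
  states <- default_pol_sequence()
  expect_error(simulate_intensities(diag(c(-1, 1, 1, 1)), states), "m00")
  # truncated manifest: underdetermined
  short <- states[1:15, ]
  stack15 <- intensity_stack(array(0.1, c(15, 1, 1)), short)
  expect_error(reconstruct_mueller(stack15), "[Uu]nderdetermined")
  # 16+ frames but rank-deficient (no circular analyzer diversity)
  bad <- pol_states(0, rep(seq(0, 150, 30), 3), 0, rep(c(0, 45, 90), each = 6))
  stack18 <- intensity_stack(array(0.1, c(18, 1, 1)), bad)
  expect_error(reconstruct_mueller(stack18), "[Rr]ank-deficient")
  # frame/manifest mismatch
  expect_error(intensity_stack(array(0, c(23, 1, 1)), states), "23 frames")
})

test_that("masked pixels propagate as NA matrices without touching neighbours", {
  states <- default_pol_sequence()
  m <- mm_retarder(0.7, 25)
  mm_image <- array(rep(m, 4), c(4, 4, 2, 2))
  stack <- simulate_intensity_stack(mm_image, states)
  stack$frames[3, 1, 2] <- NA
  rec <- reconstruct_mueller(stack)
  expect_true(all(is.na(rec[, , 1, 2])))
  expect_lt(max(abs(rec[, , 1, 1] - m)), 1e-8)
  expect_lt(max(abs(rec[, , 2, 2] - m)), 1e-8)
})

test_that("normalize_mueller divides by m00, is idempotent, rejects m00 <= 0", {
  expect_equal(normalize_mueller(diag(c(2, 2, 2, 2))), diag(4))
  m <- normalize_mueller(random_physical_mueller(scale = TRUE))
  expect_equal(normalize_mueller(m), m)
  bad <- diag(4); bad[1, 1] <- 0
  expect_error(normalize_mueller(bad), "m00")
})

test_that("physical matrices map physical Stokes vectors to physical ones", {
  set.seed(14)
  for (i in 1:10) expect_true(is_physical_mueller(random_physical_mueller()))
  expect_false(is_physical_mueller(diag(c(1, 2, 2, 2))))  # overpolarizing
})
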