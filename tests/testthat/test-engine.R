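# The hourly engine: event assessment, the four execution cases, edge
# smoothing, stepping, termination and whole-run behaviour.

test_that("event assessment follows the categorical draw", {
  # all clocks eligible; extreme probabilities force a deterministic mask
  lab <- matrix(1L, 12, 12)
  lab[4:9, 4:9] <- 2L
  clock <- matrix(-1L, 12, 12)
  clock[lab == 2L] <- 24L
  st <- make_state(lab, clock)
  all_mit <- assess_events(st, sim_params(control = control_params(1, 0)), 1,
                           regimen = "Control")
  expect_equal(nrow(all_mit), 36)
  expect_true(all(all_mit$status == "mitotic"))
  all_q <- assess_events(st, sim_params(control = control_params(0, 0)), 1,
                         regimen = "Control")
  expect_true(all(all_q$status == "quiescent"))
  # non-eligible cells are absent from the mask
  clock2 <- clock
  clock2[5, 5] <- 3L
  st2 <- make_state(lab, clock2)
  m2 <- assess_events(st2, sim_params(), 1, regimen = "Control")
  expect_equal(nrow(m2), 35)
})

test_that("control event frequencies match the binomial oracle", {
  n <- 105
  lab <- matrix(2L, n, n) # uniform tumour; control ignores geometry
  clock <- matrix(24L, n, n)
  st <- make_state(lab, clock)
  set.seed(2024)
  mask <- assess_events(st, sim_params(), 1, regimen = "Control")
  ncell <- n * n
  p_mit_hat <- mean(mask$status == "mitotic")
  p_apop_hat <- mean(mask$status == "apoptotic")
  expect_lt(abs(p_mit_hat - 0.4), 3 * sqrt(0.4 * 0.6 / ncell))
  expect_lt(abs(p_apop_hat - 0.1), 3 * sqrt(0.1 * 0.9 / ncell))
})

test_that("edge mitosis deploys the daughter and re-establishes the margin", {
  st <- make_disc_state(0, n = 9) # isolated cell with six margin neighbours
  before <- state_counts(st)
  set.seed(1)
  st2 <- execute_mitosis(st, 4, 4)
  after <- state_counts(st2)
  expect_equal(after$n_tumour, before$n_tumour + 1)
  expect_false(has_tumour_bone_contact(st2$label))
  expect_lte(after$n_bone, before$n_bone)
})

test_that("interior mitosis shifts the structure outward along the path", {
  # seven-cell disc: the centre is the only interior cell
  st <- make_disc_state(1, n = 11)
  before <- state_counts(st)
  set.seed(7)
  st2 <- execute_mitosis(st, 5, 5)
  after <- state_counts(st2)
  expect_equal(after$n_tumour, before$n_tumour + 1)
  lab <- st2$label
  c0 <- 5L
  ring <- function(k) {
    out <- NULL
    for (q in 0:10) for (r in 0:10) {
      if (hex_graph_distance(q, r, c0, c0) == k) out <- rbind(out, c(q, r))
    }
    out
  }
  # manual application of the shift rule: the original disc stays tumour and
  # exactly one ring-2 site (the displaced outermost cell) joins it
  for (k in 0:1) {
    r_k <- ring(k)
    expect_true(all(lab[cbind(r_k[, 2] + 1, r_k[, 1] + 1)] == 2L))
  }
  r2 <- ring(2)
  expect_equal(sum(lab[cbind(r2[, 2] + 1, r2[, 1] + 1)] == 2L), 1)
  expect_false(has_tumour_bone_contact(lab))
})

test_that("mitosis conserves every other site", {
  set.seed(13)
  for (i in 1:20) {
    st <- make_disc_state(sample(1:3, 1))
    tum <- which(st$label == 2L, arr.ind = TRUE)
    pick <- tum[sample(nrow(tum), 1), ]
    before <- state_counts(st)
    st2 <- execute_mitosis(st, pick[2] - 1L, pick[1] - 1L)
    after <- state_counts(st2)
    expect_equal(after$n_tumour - before$n_tumour, 1)
    expect_equal(after$n_tumour + after$n_margin + after$n_bone,
                 before$n_tumour + before$n_margin + before$n_bone)
    expect_lte(after$n_bone, before$n_bone)
    expect_state_invariants(st2)
  }
})

test_that("edge apoptosis vacates the site into the margin", {
  st <- make_disc_state(0, n = 9)
  st2 <- execute_apoptosis(st, 4, 4)
  expect_equal(state_counts(st2)$n_tumour, 0)
  expect_equal(st2$label[5, 5], 1L)
  expect_equal(st2$status, "eradicated")
})

test_that("interior apoptosis shifts inward and leaves no hole", {
  set.seed(17)
  for (i in 1:30) {
    st <- make_disc_state(sample(2:3, 1))
    n <- nrow(st$label)
    c0 <- n %/% 2
    before <- state_counts(st)
    bone_before <- before$n_bone
    st2 <- execute_apoptosis(st, c0, c0) # centre cell is interior
    after <- state_counts(st2)
    expect_equal(before$n_tumour - after$n_tumour, 1)
    expect_false(has_interior_hole(st2$label))
    expect_equal(after$n_bone, bone_before) # apoptosis never digests bone
    expect_state_invariants(st2)
  }
})

test_that("smoothing removes protrusions and conserves mass", {
  # disc with a two-cell antenna: the tip has 5 non-tumour neighbours
  st <- make_disc_state(2, n = 13)
  lab <- st$label
  c0 <- 6L
  lab[c0 + 1, c0 + 3 + 1] <- 2L # (q = c0 + 3, r = c0)
  lab[c0 + 1, c0 + 4 + 1] <- 2L # antenna tip at (q = c0 + 4, r = c0)
  for (q in (c0 + 2):(c0 + 5)) for (r in (c0 - 1):(c0 + 1)) {
    if (lab[r + 1, q + 1] == 0L) lab[r + 1, q + 1] <- 1L
  }
  st <- make_state(lab)
  expect_gt(count_non_tumour_neighbours(lab, c0 + 4L, c0), 3L)
  before <- state_counts(st)
  set.seed(3)
  st2 <- smooth_edges(st)
  after <- state_counts(st2)
  expect_equal(after$n_tumour, before$n_tumour)
  if (!isTRUE(attr(st2, "cap_hit"))) {
    tum <- which(st2$label == 2L, arr.ind = TRUE)
    for (i in seq_len(nrow(tum))) {
      expect_lte(count_non_tumour_neighbours(st2$label, tum[i, 2] - 1L,
                                             tum[i, 1] - 1L), 3L)
    }
  }
  expect_state_invariants(st2)
})

test_that("an already smooth disc is left untouched", {
  st <- make_disc_state(3, n = 15)
  st2 <- smooth_edges(st)
  expect_identical(st2$label, st$label)
  expect_false(isTRUE(attr(st2, "cap_hit")))
})

test_that("a step with no eligible cells only advances the clocks", {
  # a hexagonal disc is already smooth, so nothing but the clocks may move
  st <- make_disc_state(3, n = 15, clock_value = 2L)
  st2 <- sim_step(st, engine_config("Control"), sim_params())
  expect_equal(st2$time_h, st$time_h + 1L)
  expect_identical(st2$label, st$label)
  expect_true(all(st2$clock[st2$label == 2L] == 3L))
  expect_equal(st2$last_step$n_mitoses, 0)
  expect_equal(st2$last_step$n_apoptoses, 0)
})

test_that("trajectories are reproducible and satisfy the count ledger", {
  t1 <- run_simulation(lesion_config(2, 1), engine_config("Control"), seed = 11)
  t2 <- run_simulation(lesion_config(2, 1), engine_config("Control"), seed = 11)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_identical(attr(t1, "status"), attr(t2, "status"))
  # hourly count ledger: size change equals mitoses minus apoptoses
  d <- diff(t1$n_tumour)
  expect_equal(d, (t1$n_mitoses - t1$n_apoptoses)[-1])
})

test_that("a zero follow-up returns the initial size only", {
  t0 <- run_simulation(lesion_config(2, 1), engine_config("Control",
                                                          follow_up_days = 0),
                       seed = 1)
  expect_equal(nrow(t0), 1)
  expect_equal(t0$n_tumour, 2)
})

test_that("eradication and boundary arrest terminate the run with a flag", {
  # certain apoptosis kills both cells at their first eligibility
  params <- sim_params(control = control_params(alpha1 = 0, alpha2 = 1))
  tr <- run_simulation(lesion_config(2, 1), engine_config("Control"), params,
                       seed = 2)
  expect_equal(attr(tr, "status"), "eradicated")
  expect_equal(tr$n_tumour[nrow(tr)], 0)
  expect_lte(nrow(tr), 25)
  # a tight grid arrests the growing run instead of erroring
  arr <- run_simulation(lesion_config(2, 1, n = 12), engine_config("Control"),
                        seed = 3)
  expect_equal(attr(arr, "status"), "boundary_arrest")
  expect_lt(nrow(arr), 361)
})

test_that("structural invariants hold after every step of random short runs", {
  set.seed(2025)
  for (i in 1:50) {
    a <- sample(2:6, 1)
    b <- sample(1:5, 1)
    regimen <- sample(c("Control", "Rad223"), 1)
    cfg <- engine_config(regimen, follow_up_days = 1.5)
    st <- initialize_lesion(lesion_config(a, b, n = 40,
                                          margin_thickness = sample(1:3, 1)))
    bone <- state_counts(st)$n_bone
    size <- state_counts(st)$n_tumour
    while (st$status == "running") {
      st <- sim_step(st, cfg, sim_params())
      bone <- expect_state_invariants(st, bone_before = bone)
      newsize <- state_counts(st)$n_tumour
      expect_equal(newsize - size,
                   st$last_step$n_mitoses - st$last_step$n_apoptoses)
      size <- newsize
      if (!isTRUE(st$last_step$cap_hit) && newsize > 0) {
        lab <- st$label
        tum <- which(lab == 2L, arr.ind = TRUE)
        over <- vapply(seq_len(nrow(tum)), function(j) {
          count_non_tumour_neighbours(lab, tum[j, 2] - 1L, tum[j, 1] - 1L) > 3L
        }, logical(1))
        expect_false(any(over))
      }
    }
    expect_true(st$status %in% c("time_elapsed", "eradicated", "boundary_arrest"))
  }
})

test_that("snapshots can be recorded along a run", {
  tr <- run_simulation(lesion_config(2, 1), engine_config("Control",
                                                          follow_up_days = 2),
                       seed = 4, snapshot_every = 24, keep_state = TRUE)
  snaps <- attr(tr, "snapshots")
  expect_equal(snaps$times[1:3], c(0, 24, 48))
  expect_equal(dim(snaps$labels[[1]]), c(120, 120))
  expect_equal(sum(snaps$labels[[1]] == 2L), 2)
  fs <- attr(tr, "final_state")
  expect_equal(state_counts(fs)$n_tumour, tr$n_tumour[nrow(tr)])
})
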