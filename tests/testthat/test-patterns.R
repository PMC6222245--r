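# Exploratory patterns and the iterative k-means mean-trajectory builder.

classified_stub <- function(descriptors, space = "average") {
  n <- length(descriptors)
  data.frame(patient_id = sprintf("pat%d", seq_len(n)),
             plan_id = sprintf("pl%d", seq_len(n)),
             electrode_id = "e1",
             ep_x = seq_len(n), ep_y = 0, ep_z = 10,
             tp_x = seq_len(n), tp_y = 0, tp_z = -10,
             space = space,
             entry_zone = vapply(descriptors, function(d) as.character(d[1]), ""),
             target_zone = vapply(descriptors, function(d) as.character(d[2]), ""),
             outlier = vapply(descriptors, function(d) any(is.na(d)), TRUE),
             stringsAsFactors = FALSE)
}

test_that("group_patterns partitions by exact descriptor equality", {
  cls <- classified_stub(list(c("A", "B"), c("A", "B"), c("C", "D")))
  pats <- group_patterns(cls)
  expect_length(pats, 2)
  expect_equal(vapply(pats, function(p) nrow(p$members), 0L), c(2L, 1L))
  expect_equal(pats[[1]]$entry_zone, "A")

  all_out <- classified_stub(list(c(NA, NA), c(NA, NA)))
  expect_length(group_patterns(all_out), 0)

  subj <- classified_stub(list(c("A", "B")), space = "subject")
  expect_error(group_patterns(subj), "average",
               class = "seeg_contract_error")
})

test_that("compute_U is the maximum same-descriptor count in a single plan", {
  p1 <- make_pattern(matrix(stats::rnorm(30), 5, 6))
  expect_equal(compute_U(p1), 1)

  p2 <- make_pattern(matrix(stats::rnorm(30), 5, 6),
                     plan_ids = c("a", "b", "b", "b", "c"))
  expect_equal(compute_U(p2), 3)

  counts <- c(rep("p1", 2), rep("p2", 5), "p3")
  p3 <- make_pattern(matrix(stats::rnorm(48), 8, 6), plan_ids = counts)
  expect_equal(compute_U(p3), 5)
})

test_that("a single-member pattern yields one mean trajectory with sigma 0", {
  x <- matrix(c(1, 2, 3, 4, 5, 6), 1, 6)
  mts <- build_mean_trajectories(make_pattern(x), U_init = 1, seed = 1)
  expect_length(mts, 1)
  expect_equal(mts[[1]]$mean_entry, c(1, 2, 3))
  expect_equal(mts[[1]]$mean_target, c(4, 5, 6))
  expect_equal(mts[[1]]$sigma_entry, 0)
  expect_equal(mts[[1]]$n_members, 1L)
})

test_that("an insignificant cluster triggers a rerun at k - 1", {
  # 100 members: two tight planted blobs (48 + 48) and 4 far stragglers that
  # k = 3 isolates as a 4-member cluster (< 5% of 100), forcing k = 2.
  set.seed(20)
  blob <- function(c6, n) matrix(rep(c6, each = n), n, 6) +
    matrix(stats::rnorm(6 * n, 0, 0.5), n, 6)
  x <- rbind(blob(c(0, 0, 0, 0, 0, 0), 48),
             blob(c(100, 0, 0, 100, 0, 0), 48),
             blob(c(200, 50, 0, 200, 50, 0), 4))
  mts <- build_mean_trajectories(make_pattern(x), U_init = 3, seed = 3)
  expect_length(mts, 2)
  expect_true(all(vapply(mts, `[[`, 0L, "n_members") >= 5))
  expect_equal(mts[[1]]$final_k, 2L)
  expect_equal(sweep_oracle_k(x, 3, 0.05, 3), 2L)
})

test_that("well-separated planted clusters are recovered within 1 mm", {
  set.seed(21)
  c1 <- c(0, 0, 20, 0, 0, -20); c2 <- c(40, 0, 20, 40, 0, -20)
  x <- rbind(matrix(rep(c1, each = 50), 50, 6),
             matrix(rep(c2, each = 50), 50, 6)) +
    matrix(stats::rnorm(600, 0, 2), 100, 6)
  mts <- build_mean_trajectories(make_pattern(x), U_init = 2, seed = 4)
  expect_length(mts, 2)
  # direct per-planted-group averaging oracle
  oracle1 <- colMeans(x[1:50, ]); oracle2 <- colMeans(x[51:100, ])
  got <- do.call(rbind, lapply(mts, function(m) c(m$mean_entry, m$mean_target)))
  d_to <- function(ctr) min(sqrt(rowSums((got - matrix(ctr, 2, 6,
                                                       byrow = TRUE))^2)))
  expect_lt(d_to(oracle1), 1)
  expect_lt(d_to(oracle2), 1)
  # sigma is the RMS radial dispersion of the assigned members
  rms <- function(pts, ctr) sqrt(mean(rowSums((pts - matrix(ctr, nrow(pts), 3,
                                                            byrow = TRUE))^2)))
  m1 <- mts[[which.min(abs(vapply(mts, function(m) m$mean_entry[1], 0)))]]
  expect_equal(m1$sigma_entry, rms(x[1:50, 1:3], m1$mean_entry),
               tolerance = 0.1)
})

test_that("iterative k matches the exhaustive-sweep oracle on fuzzed patterns", {
  set.seed(99)
  for (i in 1:60) {
    x <- random_pattern()
    U <- sample(1:4, 1)
    mts <- suppressWarnings(build_mean_trajectories(
      make_pattern(x), U_init = U, min_frac = 0.05, seed = i))
    expect_equal(mts[[1]]$final_k, sweep_oracle_k(x, U, 0.05, i),
                 info = paste("pattern", i))
    # conservation: members partition the pattern
    expect_equal(sum(vapply(mts, `[[`, 0L, "n_members")), nrow(x))
    # significance: every mT holds >= 5% of members, or k hit the floor
    sig <- vapply(mts, `[[`, 0L, "n_members") >= 0.05 * nrow(x)
    expect_true(all(sig) || mts[[1]]$final_k == 1)
  }
})

test_that("U exceeding the number of distinct points is clamped with a warning", {
  x <- matrix(rep(c(0, 0, 0, 10, 0, 0), each = 3), 3, 6)  # 1 distinct point
  expect_warning(mts <- build_mean_trajectories(make_pattern(x), U_init = 3,
                                                seed = 1),
                 "clamped")
  expect_length(mts, 1)
  expect_equal(mts[[1]]$n_members, 3L)
})

test_that("index_u orders clusters by size then entry lexicographic", {
  set.seed(30)
  x <- rbind(matrix(rep(c(0, 0, 0, 0, 0, -40), each = 30), 30, 6),
             matrix(rep(c(50, 0, 0, 50, 0, -40), each = 10), 10, 6)) +
    matrix(stats::rnorm(240, 0, 1), 40, 6)
  mts <- build_mean_trajectories(make_pattern(x), U_init = 2, seed = 5)
  expect_equal(vapply(mts, `[[`, 0L, "index_u"), 1:2)
  expect_gt(mts[[1]]$n_members, mts[[2]]$n_members)
})

test_that("space transforms move plans between subject and average space", {
  plans <- classified_stub(list(c("A", "B"), c("C", "D")))[
    , c("patient_id", "plan_id", "electrode_id",
        "ep_x", "ep_y", "ep_z", "tp_x", "tp_y", "tp_z", "space")]
  plans$space <- "subject"

  idn <- to_average_space(plans, diag(4))
  expect_equal(idn$ep_x, plans$ep_x)
  expect_equal(unique(idn$space), "average")
  expect_error(to_average_space(idn, diag(4)), "subject-space",
               class = "seeg_contract_error")

  tr <- diag(4); tr[1:3, 4] <- c(10, -5, 2)
  shifted <- to_average_space(plans, tr)
  expect_equal(shifted$ep_x, plans$ep_x + 10)
  expect_equal(shifted$tp_y, plans$tp_y - 5)

  set.seed(31)
  a <- random_affine()
  back <- to_subject_space(to_average_space(plans, a), a)
  expect_lt(max(abs(back$ep_x - plans$ep_x)), 1e-9)
  expect_lt(max(abs(back$tp_z - plans$tp_z)), 1e-9)
})
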