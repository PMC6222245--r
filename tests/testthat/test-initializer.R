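# Strategy mapping into subject space, assignment pairing, 2-sigma checks.

test_that("init_plan maps strategy mean trajectories through the inverse affine", {
  b <- tiny_model()
  ip <- init_plan(b, "S1", diag(4), patient_id = "px")
  expect_equal(nrow(ip), 2)
  expect_equal(ip$electrode_id, c("mT1", "mT2"))
  expect_equal(unique(ip$space), "subject")
  expect_equal(c(ip$ep_x[1], ip$ep_y[1], ip$ep_z[1]), c(0, 0, 30))

  tr <- diag(4); tr[1:3, 4] <- c(7, -3, 1)  # subject -> average translation
  ip2 <- init_plan(b, "S1", tr)
  expect_equal(ip2$ep_x, ip$ep_x - 7)
  expect_equal(ip2$ep_y, ip$ep_y + 3)
  expect_equal(ip2$tp_z, ip$tp_z - 1)

  expect_error(init_plan(b, "S9", diag(4)), "unknown strategy",
               class = "seeg_lookup_error")
})

test_that("an all-false strategy initialises an empty plan with a warning", {
  b <- tiny_model()
  b$strategies[[2]] <- list(strategy_id = "S2", name = NULL,
                            bits = c(FALSE, FALSE),
                            member_plan_ids = "p3", degenerate = TRUE)
  expect_warning(ip <- init_plan(b, "S2", diag(4)), "no mean trajectories")
  expect_equal(nrow(ip), 0)
})

test_that("assignment pairing beats greedy nearest-entry pairing", {
  b <- tiny_model()
  # all target points coincide across plans so only entry distances matter;
  # greedy (IP1 -> MP1) forces IP2 onto the distant MP2
  ip <- data.frame(patient_id = "px", plan_id = "px",
                   electrode_id = c("mT1", "mT2"),
                   ep_x = c(0, 50), ep_y = 0, ep_z = 0,
                   tp_x = 0, tp_y = 0, tp_z = -20,
                   space = "subject", mt_index = 1:2,
                   stringsAsFactors = FALSE)
  mp <- data.frame(patient_id = "px", plan_id = "px",
                   electrode_id = c("m1", "m2"),
                   ep_x = c(1, 0), ep_y = c(0, 2), ep_z = 0,
                   tp_x = 0, tp_y = 0, tp_z = -20,
                   space = "subject", stringsAsFactors = FALSE)
  pr <- match_trajectories(ip, mp, b)
  # brute force over the two permutations
  c11 <- 1; c12 <- 2; c21 <- 49; c22 <- sqrt(50^2 + 4)
  expect_lt(c12 + c21, c11 + c22)
  expect_equal(pr$electrode_id[pr$mt_index == 1], "m2")
  expect_equal(pr$electrode_id[pr$mt_index == 2], "m1")
  expect_equal(sum(pr$d_ep), c12 + c21, tolerance = 1e-12)
})

test_that("surplus trajectories are reported unpaired", {
  b <- tiny_model()
  ip <- init_plan(b, "S1", diag(4))
  ip3 <- rbind(ip, transform(ip[2, ], electrode_id = "mT9", mt_index = 2L,
                             ep_x = 500, tp_x = 480))
  ip3$mt_index <- c(1L, 2L, 2L)
  mp <- ip[, setdiff(names(ip), "mt_index")]
  mp$electrode_id <- c("m1", "m2")
  pr <- match_trajectories(ip3, mp, b)
  expect_equal(nrow(pr), 2)
  expect_equal(attr(pr, "unpaired_initialized"), "mT9")
  expect_length(attr(pr, "unpaired_manual"), 0)
})

test_that("descriptor constraints forbid cross-descriptor pairs", {
  b <- tiny_model()
  ip <- init_plan(b, "S1", diag(4))
  mp <- ip[, setdiff(names(ip), "mt_index")]
  mp$electrode_id <- c("m1", "m2")
  # manual descriptors say m1 matches mT2's zones and m2 matches mT1's
  desc <- data.frame(entry_zone = c("C", "A"), target_zone = c("D", "B"),
                     stringsAsFactors = FALSE)
  pr <- match_trajectories(ip, mp, b, manual_descriptors = desc)
  expect_equal(pr$electrode_id[pr$mt_index == 1], "m2")
  expect_equal(pr$electrode_id[pr$mt_index == 2], "m1")
})

test_that("solve_assignment equals the brute-force permutation minimum", {
  set.seed(55)
  for (i in 1:60) {
    n <- sample(2:6, 1)
    m <- if (n == 6) 6L else sample(n:6, 1)
    cost <- matrix(stats::runif(n * m, 0, 100), n, m)
    a <- solve_assignment(cost)
    expect_equal(sort(a), sort(unique(a)))  # one-to-one
    expect_equal(sum(cost[cbind(seq_len(n), a)]),
                 brute_force_assignment(cost), tolerance = 1e-9)
  }
})

test_that("the 2-sigma criterion is inclusive at the boundary", {
  b <- tiny_model()  # mT1: sigma_ep 2.5, sigma_tp 3.25
  pairing <- data.frame(mt_index = c(1L, 1L, 2L),
                        electrode_id = c("m1", "m2", "m3"),
                        d_ep = c(5, 5.000001, 1), d_tp = c(6.5, 6.5, 10),
                        stringsAsFactors = FALSE)
  attr(pairing, "unpaired_initialized") <- character()
  attr(pairing, "unpaired_manual") <- character()
  rep <- validate_mapping(pairing, b)
  expect_equal(rep$pairs$pass, c(TRUE, FALSE, FALSE))
  expect_equal(rep$fraction_mapped, 1 / 3)
})

test_that("singleton mean trajectories (sigma 0) only pass at exact zero", {
  b <- tiny_model()
  b$mean_trajectories[[1]]$sigma_entry <- 0
  b$mean_trajectories[[1]]$sigma_target <- 0
  b$mean_trajectories[[1]]$n_members <- 1L
  b$mean_trajectories[[1]]$member_refs <-
    b$mean_trajectories[[1]]$member_refs[1, ]
  pairing <- data.frame(mt_index = c(1L, 1L), electrode_id = c("m1", "m2"),
                        d_ep = c(0, 0.001), d_tp = c(0, 0),
                        stringsAsFactors = FALSE)
  rep <- validate_mapping(pairing, b)
  expect_equal(rep$pairs$pass, c(TRUE, FALSE))
  expect_true(all(rep$pairs$singleton_sigma))
})

test_that("noiseless end-to-end: initialised plan reproduces the manual plan", {
  spec0 <- cohort_spec(noise_sigma_mm = 0, plan_dropout_prob = 0,
                       n_plans = 8, seed = 13)
  co <- generate_cohort(spec0)
  m0 <- build_model(co$plans, co$affines, co$atlas, co$zone_config, seed = 1)
  m0 <- add_strategies(m0, cut_threshold = 0.45)
  pid <- "P001"
  sid <- m0$strategies[[which(vapply(m0$strategies, function(s) {
    pid %in% s$member_plan_ids
  }, TRUE))[1]]]$strategy_id
  ip <- init_plan(m0, sid, co$affines[[pid]], patient_id = pid)
  manual <- co$plans[co$plans$patient_id == pid, ]
  pr <- match_trajectories(ip, manual, m0)
  expect_equal(nrow(pr), nrow(manual))
  expect_lt(max(pr$d_ep, pr$d_tp), 1e-6)

  # with dispersions from a noisy run of the same design, every pair passes
  spec1 <- cohort_spec(n_plans = 8, seed = 13)
  co1 <- generate_cohort(spec1)
  m1 <- build_model(co1$plans, co1$affines, co1$atlas, co1$zone_config,
                    seed = 1)
  key <- function(mm) vapply(mm$mean_trajectories, function(mt) {
    paste(mt$entry_zone, mt$target_zone, mt$index_u)
  }, "")
  idx <- match(key(m0), key(m1))
  expect_false(anyNA(idx))
  for (y in seq_along(idx)) {
    m0$mean_trajectories[[y]]$sigma_entry <-
      m1$mean_trajectories[[idx[y]]]$sigma_entry
    m0$mean_trajectories[[y]]$sigma_target <-
      m1$mean_trajectories[[idx[y]]]$sigma_target
  }
  rep <- validate_mapping(pr, m0)
  expect_equal(rep$fraction_mapped, 1)
})

test_that("fraction mapped on noisy test subjects matches a Monte-Carlo oracle", {
  skip_if_not_installed("mclust")
  spec <- cohort_spec(n_plans = 50, seed = 23)
  co <- generate_cohort(spec)
  train <- sprintf("P%03d", 1:40); test <- sprintf("P%03d", 41:50)
  m <- build_model(co$plans[co$plans$patient_id %in% train, ],
                   co$affines, co$atlas, co$zone_config, seed = 1)
  m <- add_strategies(m, cut_threshold = 0.45)
  # identify each recovered strategy with its planted one via member plans
  strat_of <- vapply(m$strategies, function(s) {
    as.integer(unique(co$truth$plan_strategy[s$member_plan_ids]))
  }, 0L)
  passes <- integer(0)
  sigmas <- list()
  for (pid in test) {
    g <- co$truth$plan_strategy[[pid]]
    sid <- m$strategies[[which(strat_of == g)[1]]]$strategy_id
    ip <- init_plan(m, sid, co$affines[[pid]], patient_id = pid)
    manual <- co$plans[co$plans$patient_id == pid, ]
    rep <- validate_mapping(match_trajectories(ip, manual, m), m)
    passes <- c(passes, rep$pairs$pass)
    sigmas <- c(sigmas, lapply(seq_len(nrow(rep$pairs)), function(i) {
      c(rep$pairs$sigma_ep[i], rep$pairs$sigma_tp[i])
    }))
  }
  observed <- mean(passes)
  # Monte-Carlo oracle on the generative noise model: subject-space distance
  # is the average-space Gaussian offset scaled by the subject's (inverse)
  # affine; pass requires both EP and TP within twice the model dispersion
  set.seed(1234)
  draws <- 2000
  mc <- mean(vapply(sigmas, function(s2) {
    scale <- 1 / stats::runif(draws, 1 - spec$affine_jitter$scale_frac,
                              1 + spec$affine_jitter$scale_frac)
    dep <- scale * sqrt(stats::rchisq(draws, 3)) * spec$noise_sigma_mm
    dtp <- scale * sqrt(stats::rchisq(draws, 3)) * spec$noise_sigma_mm
    mean(dep <= 2 * s2[1] & dtp <= 2 * s2[2])
  }, 0))
  expect_lt(abs(observed - mc), 0.05)
})
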