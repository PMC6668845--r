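test_that("reward prediction initialization is small, positive, seeded", {
  set.seed(3)
  v <- replay_initialize(5, 0.01)
  expect_length(v, 5)
  expect_true(all(v >= 0 & v < 0.01))
  set.seed(3)
  expect_identical(replay_initialize(5, 0.01), v)
  expect_error(replay_initialize(5, 0), "positive")
})

test_that("replay likelihood is the normalized reward prediction", {
  expect_equal(replay_likelihood(c(1, 1, 2)), c(0.25, 0.25, 0.5))
  expect_equal(replay_likelihood(rep(7, 10)), rep(0.1, 10))
  expect_error(replay_likelihood(rep(0, 4)), "all-zero")
})

test_that("the TD update matches hand arithmetic on a single snippet", {
  # one reverse snippet tau = (2, 1): V(1) <- R(2) + gamma V(2) = 1.5
  p <- replay_params(alpha_td = 1, gamma = 0.5, beta_learn = 1,
                     snippet_length = 2, budget = 2)
  set.seed(1)
  v <- replay_learn(c(0, 1), c(0, 1), p)
  expect_equal(v, c(1.5, 1))

  # alpha = 0 degenerates to the identity
  p0 <- replay_params(alpha_td = 0, beta_learn = 0.5, budget = 200,
                      snippet_length = 5)
  set.seed(2)
  v0 <- runif(20, 0.5, 1)
  expect_equal(replay_learn(rep(1, 20), v0, p0), v0)
})

test_that("replay_learn agrees with an independently coded reference", {
  # same RNG stream, independently written loop of the update rule
  ref_learn <- function(reward, v, alpha, gamma, beta, s, budget) {
    n <- length(v)
    while (budget > 0) {
      t0 <- sample.int(n, 1, prob = v / sum(v))
      tau <- if (runif(1) < beta) t0:max(1, t0 - s + 1)
             else t0:min(n, t0 + s - 1)
      if (length(tau) >= 2)
        for (i in 2:length(tau))
          v[tau[i]] <- alpha * (reward[tau[i - 1]] + gamma * v[tau[i - 1]]) +
            (1 - alpha) * v[tau[i]]
      budget <- budget - length(tau)
    }
    v
  }
  n <- 40
  reward <- numeric(n)
  reward[c(10, 30)] <- 1
  set.seed(7)
  v0 <- replay_initialize(n, 0.01)
  p <- replay_params(alpha_td = 0.3, gamma = 0.8, beta_learn = 0.6,
                     snippet_length = 6, budget = 500)
  set.seed(99)
  got <- replay_learn(reward, v0, p)
  set.seed(99)
  want <- ref_learn(reward, v0, 0.3, 0.8, 0.6, 6, 500)
  expect_equal(got, want, tolerance = 1e-15)
})

test_that("zero reward contracts the prediction; likelihood stays normalized", {
  set.seed(5)
  v0 <- replay_initialize(30, 0.01)
  p <- replay_params(alpha_td = 0.5, gamma = 0.9, budget = 5000,
                     snippet_length = 5)
  v1 <- replay_learn(rep(0, 30), v0, p)
  expect_lt(max(v1), max(v0))
  expect_true(all(v1 >= 0))
  expect_equal(sum(replay_likelihood(v1)), 1, tolerance = 1e-12)
})

test_that("episode generation respects direction and budget", {
  g <- small_grid()
  ras <- encode_trajectory(
    make_trajectory(rbind(c(-0.4, 0), c(0.4, 0)), resolution = 50), g)
  n <- nrow(ras)
  directions <- function(ep)
    vapply(ep$snippets, function(s)
      s$indices[length(s$indices)] >= s$indices[1], logical(1))

  set.seed(1)
  fw <- replay_generate(ras, rep(1, n),
                        replay_params(beta_generate = 0, budget = 300))
  expect_true(all(directions(fw)))
  bw <- replay_generate(ras, rep(1, n),
                        replay_params(beta_generate = 1, budget = 300))
  expect_true(all(!vapply(bw$snippets, function(s)
    s$indices[length(s$indices)] > s$indices[1], logical(1))))

  # budget conservation across random parameter draws
  for (i in 1:10) {
    s_len <- sample(3:8, 1)
    budget <- sample(50:200, 1)
    ep <- replay_generate(ras, runif(n, 0.1, 1),
                          replay_params(beta_generate = runif(1),
                                        snippet_length = s_len,
                                        budget = budget))
    expect_gte(ep$total_samples, budget)
    expect_lte(ep$total_samples, budget + s_len - 1)
    # snippet windows are contiguous, in range, of length <= s
    for (sn in ep$snippets) {
      expect_lte(length(sn$indices), s_len)
      expect_true(all(abs(diff(sn$indices)) == 1))
      expect_true(all(sn$indices >= 1 & sn$indices <= n))
    }
  }
})

test_that("exactly 1000 snippets fit a 10000-sample budget at length 10", {
  # start indices confined to the interior so no window is truncated
  n <- 500
  v <- numeric(n)
  v[100:400] <- 1
  ras <- matrix(runif(n * 4), n, 4)
  set.seed(2)
  ep <- replay_generate(ras, v, replay_params(budget = 10000,
                                              snippet_length = 10))
  expect_equal(length(ep$snippets), 1000)
  expect_equal(ep$total_samples, 10000)
})

test_that("reverse snippets carry time-reversed patterns", {
  g <- small_grid()
  ras <- encode_trajectory(
    make_trajectory(rbind(c(-0.4, 0), c(0.4, 0)), resolution = 30), g)
  set.seed(4)
  ep <- replay_generate(ras, rep(1, nrow(ras)),
                        replay_params(beta_generate = 1, budget = 40,
                                      snippet_length = 4))
  sn <- ep$snippets[[1]]
  expect_equal(sn$patterns, t(ras[sn$indices, , drop = FALSE]))
  expect_true(sn$indices[1] >= sn$indices[length(sn$indices)])
})

test_that("snippet histogram counts coverage and conserves samples", {
  g <- small_grid()
  ras <- encode_trajectory(
    make_trajectory(rbind(c(-0.4, 0), c(0.4, 0)), resolution = 30), g)
  ep <- manual_episode(list(3:5), ras)
  h <- snippet_histogram(ep, nrow(ras))
  expect_equal(which(h > 0), 3:5)
  expect_equal(sum(h), ep$total_samples)

  empty <- manual_episode(list(), ras)
  expect_equal(snippet_histogram(empty, 10), integer(10))

  set.seed(9)
  ep2 <- replay_generate(ras, rep(1, nrow(ras)),
                         replay_params(budget = 500, beta_generate = 0.5))
  expect_equal(sum(snippet_histogram(ep2, nrow(ras))), ep2$total_samples)
})

test_that("episodes serialize to a data frame and back", {
  g <- small_grid()
  ras <- encode_trajectory(
    make_trajectory(rbind(c(-0.4, 0), c(0.4, 0)), resolution = 30), g)
  set.seed(8)
  ep <- replay_generate(list(ras, ras), list(rep(1, nrow(ras)),
                                             rep(2, nrow(ras))),
                        replay_params(budget = 200, beta_generate = 0.5))
  df <- episode_to_df(ep)
  back <- episode_from_df(df, list(ras, ras))
  expect_equal(length(back$snippets), length(ep$snippets))
  for (i in seq_along(ep$snippets)) {
    expect_equal(back$snippets[[i]]$indices, ep$snippets[[i]]$indices)
    expect_equal(back$snippets[[i]]$patterns, ep$snippets[[i]]$patterns)
  }
  expect_equal(back$total_samples, ep$total_samples)
})

test_that("reward propagation builds a gradient toward rewarded segments", {
  # likelihood along the efficient prefix exceeds the middle of the long
  # meandering detour, consistently across seeds
  sc <- scenario("fig1_abced")
  tr <- sc$trajectory
  tag <- function(l) tr$tags$index[tr$tags$label == l]
  abc <- tag("A"):tag("C")
  ce <- tag("C"):tag("E")
  mid_ce <- ce[seq(round(length(ce) / 3), round(2 * length(ce) / 3))]
  for (seed in 1:10) {
    set.seed(seed)
    v <- replay_learn(sc$reward, replay_initialize(n_samples(tr)),
                      replay_params())
    p <- replay_likelihood(v)
    expect_gt(mean(p[abc]), mean(p[mid_ce]))
  }
})

test_that("snippet coverage tracks reward distance and magnitude", {
  seg_cov <- function(reward_d, seed) {
    sc_c <- scenario("tmaze_abc", reward_d = reward_d)
    sc_d <- scenario("tmaze_abd", reward_d = reward_d)
    set.seed(seed)
    vs <- lapply(list(sc_c, sc_d), function(sc)
      replay_learn(sc$reward, replay_initialize(n_samples(sc$trajectory)),
                   replay_params()))
    g <- small_grid()
    rasters <- lapply(list(sc_c, sc_d), function(sc)
      encode_trajectory(sc$trajectory, g))
    ep <- replay_generate(rasters, vs, replay_params())
    tag <- function(tr, l) tr$tags$index[tr$tags$label == l]
    bc <- tag(sc_c$trajectory, "B"):tag(sc_c$trajectory, "C")
    bd <- tag(sc_d$trajectory, "B"):tag(sc_d$trajectory, "D")
    # per-index means: the arms differ in length, so compare densities
    c(bc = mean(snippet_histogram(ep, n_samples(sc_c$trajectory), 1)[bc]),
      bd = mean(snippet_histogram(ep, n_samples(sc_d$trajectory), 2)[bd]))
  }
  # equal rewards: the shorter B->C arm wins in the majority of seeds
  equal <- vapply(1:10, function(s) seg_cov(1, s), numeric(2))
  expect_gt(mean(equal["bc", ] > equal["bd", ]), 0.5)
  # 10x reward at D flips the preference
  strong <- vapply(1:10, function(s) seg_cov(10, s), numeric(2))
  expect_gt(mean(strong["bd", ] > strong["bc", ]), 0.5)
})

test_that("pure reverse replay propagates a terminal reward backwards", {
  n <- 30
  reward <- numeric(n)
  reward[n] <- 1
  p <- replay_params(alpha_td = 0.5, gamma = 0.9, beta_learn = 1,
                     snippet_length = 10, budget = 3000)
  set.seed(12)
  v0 <- replay_initialize(n, 1e-4)
  v <- replay_learn(reward, v0, p)
  # value reaches far before the reward and decays with distance from it
  expect_true(all(v[15:29] > max(v0)))
  expect_gt(stats::cor(15:29, v[15:29]), 0.9)
})
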