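params <- damage_params()

test_that("damage probability ramp has exact knots and linear middle", {
  expect_identical(damage_probability(5, params), 0)
  expect_identical(damage_probability(37.5, params), 1)
  expect_identical(damage_probability(50, params), 1)
  expect_identical(damage_probability(0, params), 0)
  expect_equal(damage_probability(21.25, params), 0.5)
  mid <- seq(5, 37.5, length.out = 11)
  expect_equal(damage_probability(mid, params), (mid - 5) / 32.5)
})

test_that("break selection: 16% sampling passes a binomial 3 sigma test", {
  set.seed(21)
  n <- 1e4
  ev <- data.frame(x = runif(n), y = runif(n), z = runif(n), edep_ev = 40)
  br <- select_breaks(ev, params)
  expect_lt(abs(nrow(br) - 0.16 * n), 3 * sqrt(n * 0.16 * 0.84))
  expect_true(all(br$strand %in% 1:2))
  # strands are balanced
  expect_lt(abs(sum(br$strand == 1) - nrow(br) / 2), 3 * sqrt(nrow(br) / 4))
  # sub-threshold events yield nothing
  ev$edep_ev <- 4.9
  expect_equal(nrow(select_breaks(ev, params)), 0)
  expect_equal(nrow(select_breaks(ev[0, ], params)), 0)
})

test_that("pair geometry at the clustering radius (strict inequality)", {
  two <- function(dist, strands) data.frame(
    x = c(0, dist), y = 0, z = 0, strand = strands, event_id = 1:2)
  s <- cluster_breaks(two(3.0, c(1, 2)), params)
  expect_equal(c(s$n_ssb, s$n_sdsb, s$n_cdsb), c(0, 1, 0))
  s <- cluster_breaks(two(3.3, c(1, 2)), params)
  expect_equal(c(s$n_ssb, s$n_sdsb, s$n_cdsb), c(2, 0, 0))
  s <- cluster_breaks(two(3.2, c(1, 2)), params)   # tie: not neighbours
  expect_equal(c(s$n_ssb, s$n_sdsb), c(2, 0))
  # same-strand pair is a tandem SSB cluster, not a DSB
  s <- cluster_breaks(two(1.0, c(1, 1)), params)
  expect_equal(c(s$n_ssb, s$n_sdsb, s$n_cdsb), c(2, 0, 0))
  # strandless definition promotes it to a DSB
  s <- cluster_breaks(two(1.0, c(1, 1)), damage_params(strandless = TRUE))
  expect_equal(c(s$n_ssb, s$n_sdsb), c(0, 1))
})

test_that("density-reachable chaining links breaks beyond eps transitively", {
  br <- data.frame(x = c(0, 2.5, 5.0), y = 0, z = 0,
                   strand = c(1L, 2L, 1L), event_id = 1:3)
  s <- cluster_breaks(br, params)
  expect_equal(c(s$n_ssb, s$n_sdsb, s$n_cdsb), c(0, 0, 1))
  expect_equal(s$sizes, 3L)
})

test_that("clustering matches the brute-force oracle on random clouds", {
  skip_if_not_installed("igraph")
  set.seed(22)
  for (i in 1:100) {
    n <- sample(2:200, 1)
    # mixed scales so some points cluster and some do not
    xyz <- matrix(runif(3 * n, 0, sample(c(10, 25, 60), 1)), n, 3)
    br <- data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                     strand = sample(1:2, n, TRUE), event_id = seq_len(n))
    ours <- cluster_breaks(br, params)
    oracle <- brute_force_summary(br, params$eps)
    expect_equal(ours$n_ssb, oracle$n_ssb)
    expect_equal(ours$n_sdsb, oracle$n_sdsb)
    expect_equal(ours$n_cdsb, oracle$n_cdsb)
  }
})

test_that("conservation: breaks = SSBs + sum of DSB cluster sizes", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(5:150, 1)
    br <- data.frame(x = runif(n, 0, 30), y = runif(n, 0, 30),
                     z = runif(n, 0, 30), strand = sample(1:2, n, TRUE),
                     event_id = seq_len(n))
    s <- cluster_breaks(br, params)
    expect_equal(s$n_ssb + sum(s$sizes), n)
    expect_equal(s$n_breaks, n)
  }
})

test_that("summary is invariant under permutation of the break list", {
  set.seed(24)
  n <- 80
  br <- data.frame(x = runif(n, 0, 20), y = runif(n, 0, 20),
                   z = runif(n, 0, 20), strand = sample(1:2, n, TRUE),
                   event_id = seq_len(n))
  a <- cluster_breaks(br, params)
  b <- cluster_breaks(br[sample(n), ], params)
  expect_equal(a$n_ssb, b$n_ssb)
  expect_equal(a$n_sdsb, b$n_sdsb)
  expect_equal(a$n_cdsb, b$n_cdsb)
  expect_equal(sort(a$sizes), sort(b$sizes))
})

test_that("growing eps never un-clusters breaks", {
  set.seed(25)
  n <- 120
  br <- data.frame(x = runif(n, 0, 25), y = runif(n, 0, 25),
                   z = runif(n, 0, 25), strand = sample(1:2, n, TRUE),
                   event_id = seq_len(n))
  # total breaks inside clusters of size >= 2 is monotone in eps
  in_cluster <- vapply(c(1, 2, 3.2, 5, 8), function(e) {
    s <- cluster_breaks(br, damage_params(eps = e))
    sum(as.integer(names(s$histogram)) * as.integer(s$histogram))
  }, 0)
  expect_true(all(diff(in_cluster) >= 0))
})

test_that("damage is scored within, never across, parent decays", {
  br_events <- data.frame(
    x = c(0, 1), y = 0, z = 0, edep_ev = 40,
    track_id = 1:2, decay_id = c(1L, 2L), kind = "alpha", strand = c(1L, 2L))
  set.seed(26)
  res <- score_damage(br_events, damage_params(dna_fraction = 1))
  # 1 nm apart but different decays: two SSBs, no DSB
  tot <- colSums(res$per_decay[, c("n_ssb", "n_sdsb", "n_cdsb")])
  expect_equal(unname(tot), c(2, 0, 0))
  same <- br_events
  same$decay_id <- 1L
  res2 <- score_damage(same, damage_params(dna_fraction = 1))
  expect_equal(unname(colSums(res2$per_decay[, c("n_ssb", "n_sdsb")])),
               c(0, 1))
  # zero decays -> zero summary
  res0 <- score_damage(br_events[0, ], params)
  expect_equal(nrow(res0$per_decay), 0)
  expect_equal(res0$n_decays, 0)
})

test_that("expected SSB count is linear in event count (Poisson thinning)", {
  set.seed(27)
  gen <- function(n) data.frame(
    x = runif(n, 0, 5000), y = runif(n, 0, 5000), z = runif(n, 0, 5000),
    edep_ev = 40, track_id = 1L, decay_id = 1L, kind = "alpha")
  ssb <- function(n, reps = 30) mean(vapply(seq_len(reps), function(i)
    cluster_breaks(select_breaks(gen(n), params), params)$n_ssb, 0))
  s1 <- ssb(400)
  s2 <- ssb(800)
  expect_equal(s2 / s1, 2, tolerance = 0.15)
})

test_that("event interchange format round-trips through disk", {
  set.seed(28)
  ev <- make_line_track_events(0.01, 2)
  path <- tempfile(fileext = ".tsv")
  write_events(ev, path)
  back <- read_events(path)
  expect_equal(back$edep_ev, ev$edep_ev, tolerance = 1e-9)
  expect_equal(back$x, ev$x, tolerance = 1e-9)
  expect_equal(back$kind, ev$kind)
})
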