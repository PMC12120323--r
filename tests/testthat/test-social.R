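test_that("hour binning is clock-aligned and receiver-specific", {
  rec <- toy_receivers(3)
  tags <- toy_tags(c("A", "B"))
  det <- tibble::tibble(
    timestamp = ts(c("2014-11-05 10:10:00", "2014-11-05 10:50:00",
                     "2014-11-05 10:59:00", "2014-11-05 11:01:00")),
    transmitter_id = c("A", "B", "A", "B"),
    receiver_id = c("R1", "R1", "R2", "R2"))
  ds <- toy_dataset(det, tags, rec)
  g <- group_by_window(ds)
  # A and B share the 10:00 bin at R1; the 10:59/11:01 pair straddles a
  # bin boundary at R2 and stays apart
  shared <- dplyr::count(g, sampling_period, receiver_id)
  expect_equal(sum(shared$n == 2), 1)
  expect_equal(shared$receiver_id[shared$n == 2], "R1")
  expect_equal(nrow(g), 4)
  expect_error(group_by_window(ds, period = as.Date(c("2020-01-01",
                                                      "2020-02-01"))),
               "no detections")
})

test_that("group membership equals brute-force bucketing on synthetic data", {
  sim <- simulate_detections(quick_scenario(seed = 23, assortment = 0.3))
  ds <- suppressMessages(filter_dataset(sim$detections, sim$tags,
                                        sim$receivers))
  g <- group_by_window(ds)
  brute <- unique(data.frame(
    sampling_period = floor(as.numeric(ds$detections$timestamp) / 3600),
    receiver_id = ds$detections$receiver_id,
    transmitter_id = ds$detections$transmitter_id))
  expect_equal(nrow(g), nrow(brute))
  key <- function(d) sort(paste(d$sampling_period, d$receiver_id,
                                d$transmitter_id))
  expect_equal(key(g), key(brute))
})

test_that("simple-ratio index hits its anchors and a hand-built value", {
  # always together in every period either was seen -> 1
  g1 <- tibble::tibble(sampling_period = rep(1:10, each = 2),
                       receiver_id = "R1",
                       transmitter_id = rep(c("A", "B"), 10))
  net1 <- simple_ratio_index(g1)
  expect_equal(net1$sri["A", "B"], 1)

  # never together -> 0
  g0 <- tibble::tibble(sampling_period = 1:10, receiver_id = "R1",
                       transmitter_id = rep(c("A", "B"), each = 5))
  expect_equal(simple_ratio_index(g0)$sri["A", "B"], 0)

  # x = 2, y_ab = 1, y_a = 3, y_b = 2 -> 2/8
  g2 <- dplyr::bind_rows(
    tibble::tibble(sampling_period = c(1, 1, 2, 2), receiver_id = "R1",
                   transmitter_id = c("A", "B", "A", "B")),      # together x2
    tibble::tibble(sampling_period = c(3, 3), receiver_id = c("R1", "R2"),
                   transmitter_id = c("A", "B")),                # apart
    tibble::tibble(sampling_period = 4:6, receiver_id = "R1",
                   transmitter_id = "A"),                        # A alone x3
    tibble::tibble(sampling_period = 7:8, receiver_id = "R2",
                   transmitter_id = "B"))                        # B alone x2
  net2 <- simple_ratio_index(g2)
  expect_equal(net2$sri["A", "B"], 0.25)
  pr <- net2$pairs
  expect_equal(unname(c(pr$x, pr$y_ab, pr$y_a, pr$y_b)), c(2, 1, 3, 2))
})

test_that("SRI equals the brute-force per-period oracle on random schedules", {
  for (s in 1:20) {
    g <- random_schedule(n_ind = sample(3:8, 1), n_periods = sample(5:40, 1),
                         seed = 100 + s)
    if (length(unique(g$transmitter_id)) < 2) next
    net <- simple_ratio_index(g)
    expect_equal(net$sri, oracle_sri(g), tolerance = 1e-15)
  }
})

test_that("SRI is symmetric, bounded and invariant to period relabeling", {
  g <- random_schedule(10, 50, seed = 77)
  net <- simple_ratio_index(g)
  expect_true(all(net$sri >= 0 & net$sri <= 1))
  expect_equal(net$sri, t(net$sri))
  expect_equal(unname(diag(net$sri)), rep(0, nrow(net$sri)))
  relabeled <- dplyr::mutate(g, sampling_period =
                               match(sampling_period,
                                     sort(unique(sampling_period))) + 5000L)
  expect_equal(simple_ratio_index(relabeled)$sri, net$sri)
})

test_that("assortativity hits its anchors and matches two independent oracles", {
  # all weight within classes
  w_in <- matrix(0, 4, 4)
  w_in[1, 2] <- w_in[2, 1] <- 0.7
  w_in[3, 4] <- w_in[4, 3] <- 0.2
  expect_equal(assortativity_coef(w_in, c("x", "x", "y", "y")), 1)

  # balanced two-class, between-classes only
  w_out <- matrix(0, 4, 4)
  w_out[1, 3] <- w_out[3, 1] <- 0.5
  w_out[2, 4] <- w_out[4, 2] <- 0.3
  expect_equal(assortativity_coef(w_out, c("x", "x", "y", "y")), -1)

  set.seed(55)
  for (i in 1:20) {
    n <- 12
    w <- matrix(runif(n * n) * (runif(n * n) < 0.4), n, n)
    w <- (w + t(w)) / 2; diag(w) <- 0
    if (sum(w) == 0) next
    lab <- sample(c("u", "v", "w"), n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    r <- assortativity_coef(w, lab)
    expect_equal(r, oracle_assortativity(w, lab), tolerance = 1e-12)
    # renaming classes cannot change r
    expect_equal(assortativity_coef(w, chartr("uvw", "pqr", lab)), r)
    # rescaling all weights cannot change r
    expect_equal(assortativity_coef(2 * w, lab), r)
  }
})

test_that("binary-weight assortativity agrees with igraph's nominal coefficient", {
  skip_if_not_installed("igraph")
  set.seed(66)
  n <- 15
  w <- matrix(runif(n * n) < 0.3, n, n) * 1
  w <- pmax(w, t(w)); diag(w) <- 0
  lab <- sample(c("p", "q"), n, replace = TRUE)
  gr <- igraph::graph_from_adjacency_matrix(w, mode = "undirected")
  ref <- igraph::assortativity_nominal(gr, factor(lab))
  expect_equal(assortativity_coef(w, lab), ref, tolerance = 1e-12)
})

test_that("assortativity rejects degenerate inputs", {
  w <- matrix(0, 3, 3)
  expect_error(assortativity_coef(w, c("a", "b", "a")), "empty network")
  w[1, 2] <- w[2, 1] <- 1
  expect_error(assortativity_coef(w, c("a", "a", "a")), "constant")
})

test_that("node permutation test detects structure and is scale invariant", {
  w <- matrix(0, 12, 12)
  lab <- rep(c("x", "y"), each = 6)
  for (i in 1:5) for (j in (i + 1):6) w[i, j] <- w[j, i] <- runif(1, 0.5, 1)
  for (i in 7:11) for (j in (i + 1):12) w[i, j] <- w[j, i] <- runif(1, 0.5, 1)
  pt <- node_permutation_test(w, lab, n_perm = 1000, seed = 5)
  expect_equal(pt$observed_r, 1)
  expect_lte(pt$p_value, 0.01)

  pt2 <- node_permutation_test(2 * w, lab, n_perm = 1000, seed = 5)
  expect_equal(pt2$observed_r, pt$observed_r)
  expect_equal(pt2$p_value, pt$p_value)
  expect_equal(pt2$permuted_r, pt$permuted_r)
})

test_that("permuted assortativity is centred near zero for larger networks", {
  set.seed(91)
  n <- 30
  w <- matrix(runif(n * n) * (runif(n * n) < 0.3), n, n)
  w <- (w + t(w)) / 2; diag(w) <- 0
  lab <- sample(c("x", "y", "z"), n, replace = TRUE)
  pt <- node_permutation_test(w, lab, n_perm = 1000, seed = 14)
  expect_lt(abs(mean(pt$permuted_r)), 0.05)
})

test_that("generator assortment raises observed conspecific assortativity", {
  r_at <- function(strength, seed) {
    sim <- simulate_detections(quick_scenario(seed = seed,
                                              assortment = strength,
                                              n_per_species = 8L))
    ds <- suppressMessages(filter_dataset(sim$detections, sim$tags,
                                          sim$receivers))
    net <- cooccurrence_network(ds)
    assortativity_coef(net, net$traits$species)
  }
  r0 <- vapply(1:3, function(s) r_at(0, s), 0)
  r5 <- vapply(1:3, function(s) r_at(0.5, s), 0)
  expect_gt(mean(r5), mean(r0))
})
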