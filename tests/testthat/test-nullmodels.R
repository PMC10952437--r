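toy_log <- function() {
  # two individuals at separate location-weeks with controlled visit times
  rbind(
    data.frame(tag_id = "A", location_id = "L1", year = 1L, week = 1L,
               day = 1L, timestamp_s = c(30000, 30010, 40000)),
    data.frame(tag_id = "B", location_id = "L2", year = 1L, week = 2L,
               day = 1L, timestamp_s = 7 * 86400 + c(30000, 30010, 40000)),
    data.frame(tag_id = "C", location_id = "L2", year = 1L, week = 2L,
               day = 1L, timestamp_s = 7 * 86400 + c(70000, 70010))
  )
}

test_that("the simple model resamples sources onto a virtual weekend", {
  vl <- toy_log()
  expect_error(simple_model_sample(vl, 10), "exceeds")

  one <- simple_model_sample(vl, 1, seed = 1)
  net <- build_network(build_gbi(detect_events(one, method = "gap")))
  expect_equal(net$meta$population_size, 1)
  expect_equal(classify_network(net)$n_edges, 0L)

  # per-individual visit-count multiset is conserved
  s <- simple_model_sample(vl, 3, seed = 2)
  expect_setequal(as.integer(table(s$tag_id)), c(3L, 3L, 2L))
  expect_false(is.unsorted(s$timestamp_s))
  # time of day preserved
  expect_setequal(round(s$timestamp_s %% 86400),
                  round(vl$timestamp_s %% 86400))
})

test_that("sources with identical times of day always co-occur", {
  vl <- toy_log()[1:6, ]  # A and B share identical times of day
  s <- simple_model_sample(vl, 2, seed = 3)
  ev <- detect_events(s, method = "gap")
  gbi <- build_gbi(ev)
  expect_equal(sri(gbi, 1, 2), 1)
})

test_that("checkerboard swaps preserve margins exactly", {
  id2 <- diag(2)
  colnames(id2) <- c("A", "B"); rownames(id2) <- 1:2
  sw <- social_foraging_permute(id2, n_swaps = 1, seed = 1)
  expect_equal(unname(sw), 1 - diag(2))  # the anti-identity
  expect_equal(rowSums(sw), rowSums(id2))
  expect_equal(colSums(sw), colSums(id2))

  set.seed(9)
  for (i in 1:10) {
    gbi <- random_gbi(sample(5:20, 1), sample(4:10, 1))
    p <- social_foraging_permute(gbi, n_swaps = 10000, seed = i)
    expect_identical(rowSums(p), rowSums(gbi))
    expect_identical(colSums(p), colSums(gbi))
    expect_true(all(p %in% 0:1))
  }

  allones <- matrix(1L, 3, 3, dimnames = list(1:3, c("A", "B", "C")))
  expect_warning(out <- social_foraging_permute(allones, n_swaps = 10,
                                                max_tries = 200),
                 "checkerboard")
  expect_identical(out, allones)
})

test_that("the swap chain explores the whole margin-fixed family", {
  # margins (1,1,1)/(1,1,1): the six 3x3 permutation matrices
  m0 <- diag(3)
  dimnames(m0) <- list(1:3, c("A", "B", "C"))
  seen <- character(0)
  m <- m0
  set.seed(4)
  for (i in 1:300) {
    m <- suppressWarnings(social_foraging_permute(m, n_swaps = 1))
    seen <- union(seen, paste(m, collapse = ""))
  }
  expect_equal(length(seen), 6)
})

test_that("null curves are deterministic under a fixed seed", {
  an <- fixture_analysis()
  c1 <- null_model_metrics(an, "social_foraging", n_replicates = 1, seed = 99)
  c2 <- null_model_metrics(an, "social_foraging", n_replicates = 1, seed = 99)
  expect_identical(c1, c2)
  obs <- null_model_metrics(an, "observed")
  expect_equal(nrow(obs), length(an$records))
  curves <- summarize_null_curves(rbind(obs, c1), bin_width = 5)
  expect_true(all(c("model", "n_bin", "metric", "mean", "se", "n") %in%
                    names(curves)))
  # the permuted networks keep the observed population sizes
  expect_setequal(c1$population_size, obs$population_size)
})
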