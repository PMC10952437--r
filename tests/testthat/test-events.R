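burst_stream <- function(centres, tags_per_burst, spread = 20, visits = 3,
                         seed = 1) {
  set.seed(seed)
  rows <- do.call(rbind, lapply(seq_along(centres), function(e) {
    tags <- tags_per_burst[[e]]
    data.frame(tag_id = rep(tags, each = visits),
               timestamp_s = rnorm(length(tags) * visits, centres[e], spread),
               day = 1L, stringsAsFactors = FALSE)
  }))
  rows <- rows[order(rows$timestamp_s), ]
  rownames(rows) <- NULL
  rows
}

test_that("well-separated bursts are recovered with their memberships", {
  st <- burst_stream(c(30000, 30000 + 3 * 3600),
                     list(sprintf("A%02d", 1:10), sprintf("B%02d", 1:10)),
                     seed = 2)
  for (m in c("gap", "gmm")) {
    ev <- detect_events(st, method = m)
    expect_equal(nrow(ev$events), 2)
    expect_setequal(ev$members[[1]], sprintf("A%02d", 1:10))
    expect_setequal(ev$members[[2]], sprintf("B%02d", 1:10))
  }
})

test_that("degenerate streams behave: single visit, unsorted input", {
  one <- data.frame(tag_id = "A", timestamp_s = 100, day = 1L)
  for (m in c("gap", "gmm")) {
    ev <- detect_events(one, method = m)
    expect_equal(nrow(ev$events), 1)
    expect_equal(ev$events$start_s, 100)
    expect_equal(ev$events$end_s, 100)
    expect_equal(ev$events$duration_s, 0)
  }
  bad <- data.frame(tag_id = c("A", "B"), timestamp_s = c(200, 100), day = 1L)
  expect_error(detect_events(bad), "sorted")
})

test_that("planted events are recovered and both methods agree when separation is wide", {
  st <- plant_events(30, gap_s = 1500, spread_s = 30, seed = 7)
  truth <- attr(st, "truth")
  gmm <- detect_events(st, method = "gmm")
  gap <- detect_events(st, method = "gap")
  hits <- vapply(split(seq_len(nrow(st)), truth), function(ix) {
    max(table(gmm$assignment[ix]))
  }, numeric(1))
  expect_gte(sum(hits) / nrow(st), 0.95)
  expect_identical(gmm$assignment, gap$assignment)
})

test_that("detection is deterministic and partitions all visits", {
  sim <- fixture_sim()
  vl <- sim$visit_log
  s <- vl[vl$location_id == vl$location_id[1] & vl$week == 1, ]
  s <- s[order(s$timestamp_s), ]
  e1 <- detect_events(s, method = "gmm")
  e2 <- detect_events(s, method = "gmm")
  expect_identical(e1$assignment, e2$assignment)
  expect_equal(sum(e1$events$n_visits), nrow(s))
  # events are non-overlapping and time ordered
  expect_true(all(diff(e1$events$start_s) > 0))
  expect_true(all(e1$events$start_s[-1] >= head(e1$events$end_s, -1)))
  # union of members equals distinct tags
  expect_setequal(unique(unlist(e1$members)), unique(s$tag_id))
})

test_that("the GBI matrix is the binary event-by-individual incidence", {
  st <- burst_stream(c(1000, 9000), list(c("A", "B"), "A"), seed = 3)
  ev <- detect_events(st, method = "gap")
  gbi <- build_gbi(ev)
  expect_equal(dim(gbi), c(2, 2))
  expect_equal(unname(gbi[, "A"]), c(1, 1))
  expect_equal(unname(gbi[, "B"]), c(1, 0))
  # duplicate visits of one bird in one event still yield a single 1
  expect_true(all(gbi %in% 0:1))
  expect_equal(rowSums(gbi), setNames(ev$events$n_members, rownames(gbi)))

  empty <- list(events = data.frame(), members = list())
  m0 <- build_gbi(empty)
  expect_true(isTRUE(attr(m0, "empty")))
})

test_that("long-event flag follows the 12-minute threshold", {
  st <- burst_stream(c(1000, 9000), list(c("A", "B"), c("A", "B")), seed = 4)
  ev <- detect_events(st, method = "gap")
  expect_false(flag_long_event_networks(ev))
  # one event lasting 9.3 h
  long <- data.frame(tag_id = rep("A", 5),
                     timestamp_s = seq(0, 9.3 * 3600, length.out = 5),
                     day = 1L)
  evl <- detect_events(long, method = "gap", gap_s = 3 * 3600)
  expect_equal(max_event_duration(evl), 9.3 * 3600)
  expect_true(flag_long_event_networks(evl))
  empty <- list(events = data.frame())
  expect_false(flag_long_event_networks(empty))
})
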