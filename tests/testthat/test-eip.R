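gates5 <- gate_labels(gate_spec())

seq_named <- function(resps) stats::setNames(resps, gates5)

test_that("identify_point honours the stability rule on canonical cases", {
  # correct at all gates -> earliest gate
  r <- identify_point(seq_named(rep("anger", 5)), "anger", 1448)
  expect_identical(r$identification_gate, "G200")
  expect_identical(r$eip_ms, 200)

  # an intervening deviation resets the point to after the deviation
  r <- identify_point(seq_named(c("anger", "anger", "fear", "anger", "anger")),
                      "anger", 1448)
  expect_identical(r$identification_gate, "G600")
  expect_identical(r$eip_ms, 600)

  # never the target at full duration -> error, no latency
  r <- identify_point(seq_named(c("anger", "anger", "anger", "anger", "fear")),
                      "anger", 1448)
  expect_identical(r$status, "error")
  expect_true(is.na(r$eip_ms))

  # first correct only at the full expression -> latency is the full duration
  r <- identify_point(seq_named(c("fear", "fear", "fear", "fear", "anger")),
                      "anger", 2000)
  expect_identical(r$eip_ms, 2000)

  # a neutral break counts like any other deviation
  r <- identify_point(seq_named(c("anger", "neutral", "anger", "anger", "anger")),
                      "anger", 1448)
  expect_identical(r$identification_gate, "G500")
})

test_that("missing or malformed gate sequences are handled", {
  part <- stats::setNames(c("anger", "anger"), c("G200", "GFULL"))
  expect_identical(identify_point(part, "anger", 1000)$status, "incomplete")

  swapped <- stats::setNames(rep("anger", 5), gates5[c(2, 1, 3, 4, 5)])
  expect_error(identify_point(swapped, "anger", 1000), "ascending")
  dup <- stats::setNames(rep("anger", 5), c("G200", "G200", "G500", "G600", "GFULL"))
  expect_error(identify_point(dup, "anger", 1000), "duplicate")
})

test_that("identify_point equals the brute-force suffix oracle on sampled patterns", {
  labs <- response_labels()
  set.seed(5)
  for (i in 1:300) {
    resp <- sample(labs, 5, replace = TRUE)
    got <- identify_point(seq_named(resp), "anger", 1500)
    want <- bf_identify(resp, "anger", 1500)
    expect_identical(got$status, want$status)
    expect_identical(got$eip_ms, want$eip_ms)
  }
})

test_that("making a wrong response correct never increases the EIP", {
  labs <- response_labels()
  set.seed(8)
  val <- function(resp) {
    r <- identify_point(seq_named(resp), "anger", 3000)
    if (r$status == "identified") r$eip_ms else Inf
  }
  for (i in 1:100) {
    resp <- sample(labs, 5, replace = TRUE)
    wrong <- which(resp != "anger")
    if (length(wrong) == 0) next
    fixed <- resp
    fixed[sample(wrong, 1)] <- "anger"
    expect_lte(val(fixed), val(resp))
  }
})

test_that("eip_table partitions all pairs and matches per-pair identify_point", {
  ds <- simulate_dataset(small_config(13))
  eips <- eip_table(ds)
  n_pairs <- nrow(ds$participants) * nrow(ds$items)
  expect_identical(nrow(eips), as.integer(n_pairs))
  expect_true(all(eips$status %in% c("identified", "error", "incomplete")))
  expect_identical(sum(eips$status == "incomplete"), 0L)

  flat <- ds$records |> dplyr::left_join(ds$items, by = "item_id")
  for (k in sample(nrow(eips), 25)) {
    row <- eips[k, ]
    sub <- flat[flat$participant_id == row$participant_id &
                  flat$item_id == row$item_id, ]
    sub <- sub[order(match(sub$gate, gates5)), ]
    want <- identify_point(stats::setNames(sub$response, sub$gate),
                           target_response(sub$emotion[1]),
                           sub$full_duration_ms[1])
    expect_identical(row$status, want$status)
    expect_identical(row$eip_ms, want$eip_ms)
  }
})

test_that("pairs missing a gate are incomplete, not errors", {
  ds <- tiny_dataset()
  drop <- ds$records$participant_id == "arab_p01" &
    ds$records$item_id == "voc1" & ds$records$gate == "G500"
  ds$records <- ds$records[!drop, ]
  eips <- eip_table(ds)
  row <- eips[eips$participant_id == "arab_p01" & eips$item_id == "voc1", ]
  expect_identical(row$status, "incomplete")
  # incompletes are excluded from frequency totals
  gft <- gate_frequency_table(eips, by = "emotion")
  expect_identical(unique(gft$n_total[gft$emotion == "anger"]), 1L)
})

test_that("gate_frequency_table reproduces printed-row arithmetic exactly", {
  # frequencies and totals from published, rounding-consistent rows
  make_records <- function(counts, errors, full_ms = 1500) {
    n <- sum(counts) + errors
    tibble::tibble(
      participant_id = sprintf("p%03d", seq_len(n)),
      item_id = "i1", emotion = "anger",
      status = c(rep("identified", sum(counts)), rep("error", errors)),
      identification_gate = c(rep(gates5, counts), rep(NA, errors)),
      eip_ms = c(gate_duration_ms(rep(gates5, counts), gate_spec(), full_ms),
                 rep(NA, errors))
    )
  }
  # anger vocalizations, first listener group: 151/15/7/9/19 of 250, 49 errors
  gft <- gate_frequency_table(make_records(c(151, 15, 7, 9, 19), 49),
                              by = "emotion")
  expect_identical(gft$cum_pct, c(60, 66, 69, 73, 80))
  expect_identical(unique(gft$n_errors), 49L)
  expect_identical(unique(gft$error_pct), 20)
  expect_identical(unique(gft$n_total), 250L)

  # anger vocalizations, second listener group: 189/21/17/3/1 of 250, 19 errors
  gft <- gate_frequency_table(make_records(c(189, 21, 17, 3, 1), 19),
                              by = "emotion")
  expect_identical(gft$cum_pct, c(76, 84, 91, 92, 92))
  expect_identical(unique(gft$error_pct), 8)

  # single record identified at the first gate
  gft <- gate_frequency_table(make_records(c(1, 0, 0, 0, 0), 0), by = "emotion")
  expect_identical(gft$cum_pct, c(100, 100, 100, 100, 100))
  expect_identical(unique(gft$n_errors), 0L)
})

test_that("cumulative percents are non-decreasing and close at 100 - error%", {
  ds <- simulate_dataset(small_config(17))
  gft <- gate_frequency_table(eip_table(ds))
  by_cell <- split(gft, gft[c("group", "event_type", "language", "emotion")],
                   drop = TRUE)
  for (cell in by_cell) {
    cell <- cell[order(match(cell$gate, gates5)), ]
    expect_true(all(diff(cell$cum_pct) >= 0))
    expect_lte(abs(cell$cum_pct[5] + cell$error_pct[1] - 100), 1)
  }
})

test_that("eip_summary reports exact mean/SD arithmetic", {
  rec <- tibble::tibble(
    participant_id = "p1", item_id = sprintf("i%d", 1:2), emotion = "anger",
    status = "identified", identification_gate = c("G200", "G600"),
    eip_ms = c(200, 600)
  )
  s <- eip_summary(rec, grouping = "emotion")
  expect_equal(s$eip_mean_ms, 400)
  expect_equal(s$eip_sd_ms, sd(c(200, 600)))

  all200 <- rec
  all200$eip_ms <- 200
  s <- eip_summary(all200, grouping = "emotion")
  expect_equal(s$eip_mean_ms, 200)
  expect_equal(s$eip_sd_ms, 0)

  # a 20-record fixture against direct arithmetic
  set.seed(4)
  vals <- sample(c(200, 400, 500, 600, 1500), 20, replace = TRUE)
  rec20 <- tibble::tibble(
    participant_id = "p1", item_id = sprintf("i%d", 1:20), emotion = "fear",
    status = "identified", identification_gate = "G200", eip_ms = vals
  )
  s <- eip_summary(rec20, grouping = "emotion")
  expect_equal(s$eip_mean_ms, mean(vals))
  expect_equal(s$eip_sd_ms, sd(vals))

  # happiness_pleasure excluded by default, retained on request
  mix <- dplyr::bind_rows(
    rec,
    dplyr::mutate(rec, emotion = "happiness_pleasure", eip_ms = 5000,
                  item_id = paste0(item_id, "hp"))
  )
  expect_identical(eip_summary(mix, grouping = "status")$n_identified, 2L)
  expect_identical(
    eip_summary(mix, grouping = "status", exclude_categories = NULL)$n_identified,
    4L
  )
})

test_that("groups with zero identified records are reported missing", {
  rec <- tibble::tibble(
    participant_id = "p1", item_id = "i1", emotion = "anger",
    status = "error", identification_gate = NA_character_, eip_ms = NA_real_
  )
  s <- eip_summary(rec, grouping = "emotion")
  expect_identical(s$n_identified, 0L)
  expect_true(is.na(s$eip_mean_ms))
})
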