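test_that("confusion matrices have exact cell counts and conserve records", {
  ds <- tiny_dataset()
  # single-stratum matrix over the whole dataset per participant x gate x item type
  mats <- confusion_matrix(ds, stratifiers = c("group", "event_type", "gate"))
  expect_length(mats, 20)  # 2 groups x 2 event types x 5 gates
  total <- sum(vapply(mats, function(m) sum(m$counts), numeric(1)))
  expect_equal(total, nrow(ds$records))  # conservation over all strata
  # each stratum here holds exactly one record
  expect_true(all(vapply(mats, function(m) sum(m$counts), numeric(1)) == 1))
})

test_that("one anger->anger record yields a single unit cell", {
  ds <- tiny_dataset()
  ds$records <- ds$records[ds$records$item_id == "voc1" &
                             ds$records$gate == "G200" &
                             ds$records$participant_id == "chinese_p01", ]
  mats <- confusion_matrix(ds, stratifiers = "gate")
  expect_length(mats, 1)
  m <- mats[[1]]$counts
  expect_identical(sum(m), 1L)
  expect_identical(m["anger", "anger"], 1L)
})

test_that("confusion matrices are invariant to record order", {
  ds <- simulate_dataset(small_config(7))
  ds2 <- ds
  set.seed(1)
  ds2$records <- ds2$records[sample(nrow(ds2$records)), ]
  a <- confusion_matrix(ds, stratifiers = c("group", "gate"))
  b <- confusion_matrix(ds2, stratifiers = c("group", "gate"))
  expect_identical(lapply(a, `[[`, "counts"), lapply(b, `[[`, "counts"))
})

test_that("hu_score matches hand evaluation of A^2/(B*C) and its bounds", {
  counts <- matrix(
    c(6, 2, 1, 1, 0,    # anger row: A = 6, B = 10
      6, 3, 2, 1, 0),   # sadness row also uses 'anger' 6 times -> C = 12
    nrow = 2, byrow = TRUE,
    dimnames = list(emotion = c("anger", "sadness"),
                    response = response_labels())
  )
  m <- structure(list(stratum = tibble::tibble(), counts = counts),
                 class = "confusion_matrix")
  expect_equal(hu_score(m, "anger"), 36 / 120)  # = 0.30
  expect_equal(hu_score(m, "anger"), bf_hu(counts, "anger"))

  # perfect responder: A = B = C -> 1
  perfect <- counts * 0L
  perfect["anger", "anger"] <- 10L
  perfect["sadness", "sadness"] <- 10L
  mp <- structure(list(stratum = tibble::tibble(), counts = perfect),
                  class = "confusion_matrix")
  expect_identical(hu_score(mp, "anger"), 1)

  # target label never used: A = C = 0 -> 0 by convention
  never <- counts
  never[, "anger"] <- 0L
  never["anger", "fear"] <- 10L
  mn <- structure(list(stratum = tibble::tibble(), counts = never),
                  class = "confusion_matrix")
  expect_identical(hu_score(mn, "anger"), 0)

  # B = 0 is undefined
  empty <- counts
  empty["anger", ] <- 0L
  me <- structure(list(stratum = tibble::tibble(), counts = empty),
                  class = "confusion_matrix")
  expect_error(hu_score(me, "anger"), "B = 0")
})

test_that("hu_table composes with hu_score applied to explicit matrices", {
  ds <- simulate_dataset(small_config(3))
  hu <- hu_table(ds)
  strat <- c("participant_id", "group", "event_type", "language", "gate")
  mats <- confusion_matrix(ds, stratifiers = strat)
  for (m in mats[seq(1, length(mats), by = 7)]) {  # spot-check a spread
    for (emo in rownames(m$counts)) {
      row <- dplyr::inner_join(hu, m$stratum, by = strat)
      row <- row[row$emotion == emo, ]
      expect_equal(row$hu, hu_score(m, emo))
    }
  }
})

test_that("Hu equals hit rate x precision, lies in [0,1], and is duplication-invariant", {
  set.seed(99)
  for (i in 1:25) {
    counts <- matrix(rpois(10, 3), nrow = 2,
                     dimnames = list(emotion = c("anger", "fear"),
                                     response = response_labels()))
    counts["anger", ] <- counts["anger", ] + 1  # B > 0
    counts["fear", ] <- counts["fear", ] + 1
    m <- structure(list(stratum = tibble::tibble(), counts = counts),
                   class = "confusion_matrix")
    for (emo in c("anger", "fear")) {
      h <- hu_score(m, emo)
      A <- counts[emo, emo]; B <- sum(counts[emo, ]); C <- sum(counts[, emo])
      expect_gte(h, 0)
      expect_lte(h, 1)
      if (A > 0) {
        expect_equal(h, (A / B) * (A / C))
        expect_lte(h, min(A / B, A / C))
      }
      m3 <- structure(list(stratum = tibble::tibble(), counts = counts * 3L),
                      class = "confusion_matrix")
      expect_equal(hu_score(m3, emo), h)
    }
  }
})

test_that("a perfect synthetic dataset scores Hu = 1 everywhere", {
  ds <- tiny_dataset()  # every response is the target
  hu <- hu_table(ds)
  expect_true(all(hu$hu == 1))
})

test_that("uniform guessing yields raw hit rate ~0.2 and Hu below it", {
  cfg <- small_config(21, n_participants = 10, n_items = 10)
  cfg$conditions$lapse <- 1  # pure uniform guessing over the 5 labels
  ds <- simulate_dataset(cfg)
  flat <- ds$records |>
    dplyr::left_join(ds$items, by = "item_id")
  raw_hit <- mean(flat$response == target_response(flat$emotion))
  expect_equal(raw_hit, 0.2, tolerance = 0.05)
  hu <- hu_table(ds)
  expect_lt(mean(hu$hu), 0.2)
})

test_that("neutral proportions and confidence means match direct counts", {
  ds <- tiny_dataset()
  ds$records$response[1:3] <- "neutral"
  np <- neutral_proportion(ds, stratifiers = "group")
  # rows 1:3 all belong to arab_p01 (sorted first)
  expect_equal(np$prop_neutral[np$group == "arab"], 3 / 10)
  expect_equal(np$prop_neutral[np$group == "chinese"], 0)

  ds$records$confidence <- rep(c(1L, 7L), 10)
  cs <- confidence_summary(ds, stratifiers = "group")
  expect_equal(cs$mean_confidence, c(4, 4))

  ds$records$confidence[ds$records$participant_id == "arab_p01"] <- NA_integer_
  cs2 <- confidence_summary(ds, stratifiers = "group")
  expect_true(is.na(cs2$mean_confidence[cs2$group == "arab"]))
  expect_identical(cs2$n_rated[cs2$group == "arab"], 0L)
})
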