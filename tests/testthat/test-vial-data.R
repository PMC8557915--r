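test_that("per-class fecundity normalises and extrapolates the 18-h window", {
  # 30 pupae / 20 females over 18 h of a 3.5-day class: 1.5 * 84/18 = 7
  expect_equal(perClassFecundity(30, 20, 18, 3.5), 7)
  expect_equal(perClassFecundity(0, 12, 18, 3), 0)
  # window equal to the full class: pure per-female count
  expect_equal(perClassFecundity(20, 20, 72, 3), 1)
  # raw mode skips the extrapolation
  expect_equal(perClassFecundity(30, 20, 18, 3.5, extrapolation = "raw"), 1.5)
  # invariant to joint scaling of counts
  expect_equal(perClassFecundity(30, 20, 18, 3.5),
               perClassFecundity(30 * 7, 20 * 7, 18, 3.5))
  expect_error(perClassFecundity(5, 0, 18, 3), "undefined")
  expect_warning(f0 <- perClassFecundity(0, 0, 18, 3), "set to 0")
  expect_equal(f0, 0)
})

test_that("interval survival handles censoring as non-informative loss", {
  expect_equal(intervalSurvival(20, 2, 0), 0.9)
  expect_equal(intervalSurvival(20, 2, 2), 16 / 18)
  expect_equal(intervalSurvival(20, 0, 0), 1)
  # alternative mode counts losses as deaths
  expect_equal(intervalSurvival(20, 2, 2, censoring = "deaths"), 16 / 20)
  expect_true(is.na(intervalSurvival(0, 0, 0)))
  expect_error(intervalSurvival(5, 4, 2), "exceed")
})

test_that("VialRecord validity enforces counts, ordering and conservation", {
  v <- makeVial()
  expect_s4_class(v, "VialRecord")
  expect_equal(initialEggCount(v), 30L)
  bad <- makeIntervalTable()
  bad$female_deaths[2] <- 50L
  expect_error(VialRecord("v", "t", 1L, 1L, bad), "exceed")
  bad2 <- makeIntervalTable()
  bad2$females_at_start[3] <- bad2$females_at_start[3] + 1L
  expect_error(VialRecord("v", "t", 1L, 1L, bad2), "conserved")
  bad3 <- makeIntervalTable()
  bad3$start_day[2] <- bad3$start_day[1]
  expect_error(VialRecord("v", "t", 1L, 1L, bad3))
})

test_that("vial tables round-trip through the CSV interchange format", {
  vials <- VialRecordList(makeVial("v1", "A"), makeVial("v2", "B"))
  vf <- tempfile(fileext = ".csv")
  itf <- tempfile(fileext = ".csv")
  writeVialTable(vials, vf, itf)
  back <- readVialTable(vf, itf)
  expect_length(back, 2L)
  expect_equal(names(back), c("v1", "v2"))
  for (id in names(back)) {
    expect_equal(intervals(back[[id]]), intervals(vials[[id]]))
    expect_equal(treatment(back[[id]]), treatment(vials[[id]]))
    expect_equal(nrow(intervals(back[[id]])), 8L)
  }
  # empty table: empty list plus warning
  writeVialTable(VialRecordList(list()), vf, itf)
  expect_warning(empty <- readVialTable(vf, itf), "empty")
  expect_length(empty, 0L)
})

test_that("malformed rows are reported with line numbers", {
  vials <- VialRecordList(makeVial("v1"))
  vf <- tempfile(fileext = ".csv"); itf <- tempfile(fileext = ".csv")
  writeVialTable(vials, vf, itf)
  it <- read.csv(itf)
  it$female_deaths[3] <- it$females_at_start[3] + 5L
  write.csv(it, itf, row.names = FALSE)
  expect_error(readVialTable(vf, itf), "line\\(s\\) 4")
  it <- read.csv(itf)
  it$female_deaths[3] <- -1L
  write.csv(it, itf, row.names = FALSE)
  expect_error(readVialTable(vf, itf), "line\\(s\\) 4")
  # missing mandatory column is a schema error
  write.csv(it[setdiff(names(it), "pupae_count")], itf, row.names = FALSE)
  expect_error(readVialTable(vf, itf), "missing mandatory column")
})

test_that("contamination filter removes only consecutive above-threshold weeks", {
  vials <- VialRecordList(makeVial("v1"), makeVial("v2"), makeVial("v3"))
  logs <- rbind(
    # v1: 250 and 300 CFU of unexpected morphology in weeks 2 and 3 -> removed
    data.frame(vial_id = "v1", week = 1:4, cfu_per_fly = c(0, 250, 300, 10),
               unexpected_morphology = c(FALSE, TRUE, TRUE, FALSE)),
    # v2: flagged weeks 1 and 3 are not consecutive -> kept
    data.frame(vial_id = "v2", week = 1:4, cfu_per_fly = c(250, 0, 250, 0),
               unexpected_morphology = c(TRUE, FALSE, TRUE, FALSE)),
    # v3: always below the 200 CFU threshold -> kept
    data.frame(vial_id = "v3", week = 1:4, cfu_per_fly = 199,
               unexpected_morphology = TRUE))
  res <- contaminationFilter(vials, logs)
  expect_equal(res$removed, "v1")
  expect_equal(names(res$kept), c("v2", "v3"))
  # threshold +Inf removes nothing
  expect_length(contaminationFilter(vials, logs, thresholdCfu = Inf)$removed, 0L)
  # one flagged week at threshold 0 removes everything flagged
  all3 <- contaminationFilter(vials, logs, thresholdCfu = 0,
                              consecutiveWeeks = 1L)
  expect_setequal(all3$removed, c("v1", "v2", "v3"))
  logs$vial_id[1] <- "ghost"
  expect_error(contaminationFilter(vials, logs), "unknown vial")
})

test_that("survival records encode deaths, losses and end-of-study censoring", {
  iv <- data.frame(start_day = c(10, 13, 17, 20, 24, 27), class_length_days = c(3, 4, 3, 4, 3, 4),
                   laying_window_hours = 18, pupae_count = 0,
                   females_at_start = c(3, 3, 2, 2, 2, 2),
                   female_deaths = c(0, 1, 0, 0, 0, 0),
                   females_censored = 0)
  v <- VialRecord("v1", "t", 1L, 1L, iv)
  rec <- toSurvivalRecords(VialRecordList(v))
  expect_equal(nrow(rec), 3L)
  expect_equal(sort(rec$time_days), c(17, 31, 31))
  expect_equal(rec$event[rec$time_days == 17], 1L)
  expect_equal(sum(rec$event), 1L)

  # losses are event = 0 at the interval end
  iv$female_deaths <- 0
  iv$females_censored <- c(0, 1, 0, 0, 0, 0)
  iv$females_at_start <- c(3, 3, 2, 2, 2, 2)
  rec2 <- toSurvivalRecords(VialRecordList(VialRecord("v1", "t", 1L, 1L, iv)))
  expect_equal(sum(rec2$event), 0L)

  # conservation: events match total interval deaths; one record per female
  set.seed(42)
  study <- simulateStudy(studyDesign(seed = 42L))
  rec3 <- toSurvivalRecords(study$vials)
  deathTotal <- sum(vapply(study$vials, function(v)
    sum(intervals(v)$female_deaths), numeric(1)))
  initTotal <- sum(vapply(study$vials, initialEggCount, integer(1)))
  expect_equal(sum(rec3$event), deathTotal)
  expect_equal(nrow(rec3), initTotal)
})
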