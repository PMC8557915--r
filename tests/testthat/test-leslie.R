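test_that("Leslie matrices place f on the top row and s on the subdiagonal", {
  m <- as.matrix(buildLeslie(VitalSchedule(c(0, 4, 2, 0), c(1, 0.9, 0.8))))
  expect_equal(dim(m), c(4L, 4L))
  expect_equal(unname(m[1, ]), c(0, 4, 2, 0))
  expect_equal(unname(m[cbind(2:4, 1:3)]), c(1, 0.9, 0.8))
  m[1, ] <- 0
  m[cbind(2:4, 1:3)] <- 0
  expect_true(all(m == 0))
  expect_equal(unname(as.matrix(buildLeslie(c(5, 0), 0.5))),
               rbind(c(5, 0), c(0.5, 0)))
  expect_error(buildLeslie(c(0, 4, 2), c(1, 0.9, 0.8)), "length")
  expect_error(buildLeslie(c(0, 4), c(1.2)))   # s outside [0,1]
  expect_error(buildLeslie(c(-1, 4), c(1)))    # negative f
})

test_that("dominant eigenvalue equals known roots", {
  expect_equal(as.numeric(dominantEigenvalue(buildLeslie(c(5, 0), 0.5))), 5)
  expect_equal(as.numeric(dominantEigenvalue(VitalSchedule(c(0, 0, 0), c(1, 0.5)))), 0)
  # positive root of lambda^3 - 4*lambda - 1.8 = 0, located by bisection
  lo <- 0; hi <- 10
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (mid^3 - 4 * mid - 1.8 > 0) hi <- mid else lo <- mid
  }
  expect_equal(as.numeric(dominantEigenvalue(VitalSchedule(c(0, 4, 2, 0), c(1, 0.9, 0.8)))),
               lo, tolerance = 1e-10)
})

test_that("Euler-Lotka solver matches closed forms and satisfies its equation", {
  expect_equal(eulerLotkaLambda(VitalSchedule(c(5, 0), 0.5)), 5)
  expect_equal(eulerLotkaLambda(VitalSchedule(c(0, 2), 1)), sqrt(2))
  expect_equal(eulerLotkaLambda(VitalSchedule(c(0, 0), 0.7)), 0)
  set.seed(11)
  for (i in 1:25) {
    sc <- randomSchedule()
    lam <- eulerLotkaLambda(sc)
    if (lam > 0)
      expect_equal(elLHS(fecundities(sc), survivals(sc), lam), 1,
                   tolerance = 1e-9)
  }
})

test_that("eigenvalue and Euler-Lotka agree on random schedules", {
  set.seed(101)
  for (i in 1:200) {
    sc <- randomSchedule()
    le <- as.numeric(dominantEigenvalue(sc))
    el <- eulerLotkaLambda(sc)
    expect_lt(abs(le - el) / max(el, 1e-12), 1e-8)
  }
})

test_that("closed form for 2x2 Leslie matrices holds to near machine precision", {
  set.seed(7)
  for (i in 1:50) {
    f1 <- runif(1, 0, 8); f2 <- runif(1, 0, 8); s1 <- runif(1)
    expected <- (f1 + sqrt(f1^2 + 4 * s1 * f2)) / 2
    expect_equal(as.numeric(dominantEigenvalue(VitalSchedule(c(f1, f2), s1))),
                 expected, tolerance = 1e-12)
  }
})

test_that("schedules from vials carry the three boundary assumptions", {
  v <- makeVial()
  sc <- assembleSchedule(v)
  expect_length(fecundities(sc), 10L)     # 8 intervals + pre-adult + terminal
  expect_equal(fecundities(sc)[1], 0)
  expect_equal(fecundities(sc)[10], 0)
  expect_equal(survivals(sc)[1], 1)
  iv <- intervals(v)
  expect_equal(fecundities(sc)[2],
               perClassFecundity(iv$pupae_count[1], iv$females_at_start[1],
                                 18, iv$class_length_days[1]))
  expect_equal(survivals(sc)[2],
               intervalSurvival(iv$females_at_start[1], iv$female_deaths[1],
                                iv$females_censored[1]))

  # extinction after interval 3: trailing classes flatten to f = 0, s = 0
  iv2 <- makeIntervalTable(deaths = c(1, 1, 28, 0, 0, 0, 0, 0),
                           censored = rep(0L, 8), females0 = 30L)
  sc2 <- assembleSchedule(VialRecord("x", "t", 1L, 1L, iv2))
  expect_equal(survivals(sc2)[4], 0)      # nobody survives interval 3
  expect_true(all(fecundities(sc2)[5:10] == 0))
  expect_true(all(survivals(sc2)[5:9] == 0))

  # all-zero pupae counts: zero f everywhere, lambda 0
  sc3 <- assembleSchedule(makeVial(pupae = rep(0L, 8)))
  expect_true(all(fecundities(sc3) == 0))
  expect_equal(as.numeric(dominantEigenvalue(sc3)), 0)

  iv4 <- makeIntervalTable()
  iv4$females_at_start <- 0L
  iv4$female_deaths <- 0L
  iv4$females_censored <- 0L
  iv4$pupae_count <- 0L
  expect_error(assembleSchedule(VialRecord("y", "t", 1L, 1L, iv4)),
               "no interval with females")
})

test_that("appending a terminal f=0 class never changes lambda", {
  set.seed(21)
  for (i in 1:50) {
    sc <- randomSchedule()
    lam <- eulerLotkaLambda(sc)
    ext <- VitalSchedule(c(fecundities(sc), 0), c(survivals(sc), runif(1)))
    expect_lt(abs(as.numeric(dominantEigenvalue(ext)) - lam), 1e-12 + 1e-12 * lam)
  }
})

test_that("lambda responds monotonically to vital rates", {
  set.seed(33)
  for (i in 1:30) {
    sc <- randomSchedule(sample(3:10, 1))
    lam <- eulerLotkaLambda(sc)
    f <- fecundities(sc); s <- survivals(sc)
    j <- sample(seq_along(f), 1)
    f2 <- f; f2[j] <- f2[j] * runif(1)     # decrease one fecundity
    expect_lte(eulerLotkaLambda(VitalSchedule(f2, s)), lam + 1e-12)
    j <- sample(seq_along(s), 1)
    s2 <- s; s2[j] <- s2[j] * runif(1)     # decrease one survival
    expect_lte(eulerLotkaLambda(VitalSchedule(f, s2)), lam + 1e-12)
    s3 <- s; s3[j] <- min(1, s3[j] * 1.5)  # increase never decreases
    expect_gte(eulerLotkaLambda(VitalSchedule(f, s3)), lam - 1e-12)
  }
})

test_that("lambda scales linearly with f when only one class reproduces", {
  set.seed(5)
  for (i in 1:20) {
    k <- sample(3:8, 1)
    f <- numeric(k); j <- sample(2:k, 1)
    f[j] <- runif(1, 0.5, 10)
    s <- runif(k - 1, 0.2, 1)
    c0 <- runif(1, 0.1, 5)
    lam1 <- eulerLotkaLambda(VitalSchedule(f, s))
    lam2 <- eulerLotkaLambda(VitalSchedule(f * c0, s))
    # lambda^j = l_j f_j, so scaling f by c scales lambda by c^(1/j)
    expect_equal(lam2, lam1 * c0^(1 / j), tolerance = 1e-8)
  }
})

test_that("vialFitness returns one lambda per vial", {
  vials <- VialRecordList(makeVial("v1", "A"), makeVial("v2", "B",
                                                        pupae = rep(0L, 8)))
  fit <- vialFitness(vials)
  expect_equal(fit$vial_id, c("v1", "v2"))
  expect_true(fit$lambda[1] > 0)
  expect_equal(fit$lambda[2], 0)
})
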