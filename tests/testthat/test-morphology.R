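test_that("erosion and dilation match the brute-force fits/hits oracle", {
  se3 <- structuringElement("square", 3L)
  seD <- structuringElement("disc", 5L)
  withr::with_seed(101, {
    for (i in 1:20) {
      nr <- sample(8:32, 1); nc <- sample(8:32, 1)
      img <- matrix(rbinom(nr * nc, 1, runif(1, 0.2, 0.8)), nr, nc)
      se <- if (i %% 2 == 0) se3 else seD
      expect_equal(morphErode(img, se), oracleMorph(img, se, dilate = FALSE))
      expect_equal(morphDilate(img, se), oracleMorph(img, se, dilate = TRUE))
    }
  })
})

test_that("degenerate structuring-element cases behave per the definitions", {
  se <- structuringElement("square", 3L)
  allFg <- matrix(1, 10, 10)
  expect_equal(morphErode(allFg, se), allFg)   # S fits everywhere (reflect pad)
  allBg <- matrix(0, 10, 10)
  expect_equal(morphDilate(allBg, se), allBg)  # S hits nothing
  single <- matrix(0, 9, 9); single[5, 5] <- 1
  expect_equal(morphErode(single, se), matrix(0, 9, 9))  # S cannot fit
  dil <- morphDilate(single, se)
  expect_equal(sum(dil), 9)                    # 3x3 block
  expect_true(all(dil[4:6, 4:6] == 1))
})

test_that("opening is idempotent, anti-extensive, and erode-then-dilate", {
  se <- structuringElement("square", 3L)
  withr::with_seed(7, {
    for (i in 1:5) {
      img <- matrix(runif(400, 0, 255), 20, 20)
      op <- morphOpen(img, se)
      expect_equal(op, morphDilate(morphErode(img, se), se))
      expect_equal(morphOpen(op, se), op)
      expect_true(all(op <= img + 1e-12))
    }
  })
})

test_that("opening removes speckles while preserving a large disc", {
  d <- sqrt(outer((0:29 - 15)^2, (0:29 - 15)^2, "+"))
  disc <- (d <= 8) * 1
  noisy <- disc
  withr::with_seed(3, {
    speckles <- sample(which(disc == 0 & d > 11), 12)
    noisy[speckles] <- 1
  })
  opened <- morphOpen(noisy, structuringElement("square", 3L))
  expect_true(all(opened[speckles] == 0))
  interior <- d <= 7
  expect_equal(opened[interior], disc[interior])
})

test_that("structuring elements are validated", {
  expect_error(structuringElement("square", 4L), "odd")
  expect_error(morphErode(matrix(0, 4, 4), matrix(TRUE, 2, 2)), "odd")
  expect_equal(sum(structuringElement("disc", 5L)), 13)  # discrete disc, d <= r
})
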