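make_imu_tibble <- function(n = 20) {
  imus <- tibble::tibble(time = (0:(n - 1)) / 100)
  for (j in 1:9) {
    for (ch in c("ax", "ay", "az", "gx", "gy", "gz")) {
      imus[[paste0("imu", j, "_", ch)]] <- rep(0, n)
    }
  }
  imus
}

test_that("homologous matrices have the right shape and norms", {
  imus <- make_imu_tibble(20)
  for (j in 1:9) imus[[paste0("imu", j, "_az")]] <- rep(9.81, 20)
  mats <- build_homologous_matrices(imus)
  expect_named(mats, c("A_X", "A_Y", "A_Z", "A_ToT",
                       "Omega_X", "Omega_Y", "Omega_Z", "Omega_ToT"))
  for (m in mats) expect_equal(dim(m), c(20L, 9L))
  expect_true(all(mats$A_Z == 9.81))
  expect_true(all(abs(mats$A_ToT - 9.81) < 1e-12))

  imus$imu3_ax[1] <- 3; imus$imu3_ay[1] <- 4; imus$imu3_az[1] <- 0
  m2 <- build_homologous_matrices(imus)
  expect_equal(unname(m2$A_ToT[1, 3]), 5)  # 3-4-5 norm
})

test_that("z-scoring standardises, is idempotent and scale-invariant", {
  withr::with_seed(21, {
    m <- matrix(rnorm(200 * 9, mean = 3, sd = 2), 200, 9,
                dimnames = list(NULL, paste0("imu", 1:9)))
  })
  attr(m, "family") <- "A_Y"
  z <- zscore_columns(m)
  expect_lt(max(abs(colMeans(z))), 1e-12)
  expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-12)
  expect_equal(unclass(zscore_columns(z)), unclass(z), tolerance = 1e-12,
               ignore_attr = TRUE)
  m2 <- m; m2[, 2] <- 2 * m2[, 1]
  z2 <- zscore_columns(m2)
  expect_equal(z2[, 1], z2[, 2], tolerance = 1e-12, ignore_attr = TRUE)

  mc <- m; mc[, 4] <- 1
  expect_error(zscore_columns(mc), "imu4")
})

test_that("rank-1 structure concentrates in PC1 with near-unit loadings", {
  withr::with_seed(8, {
    base <- sin(2 * pi * 0.25 * (1:500) / 100)
    m <- sapply(1:9, function(j) base + rnorm(500, 0, 1e-3))
  })
  colnames(m) <- paste0("imu", 1:9)
  pca <- pca_loadings(zscore_columns(m))
  expect_gt(pca$explained[1], 0.99)
  expect_true(all(abs(pca$loadings[, 1]) > 0.99))
})

test_that("two-variable PCA explained fraction follows (1+r)/2", {
  withr::with_seed(40, {
    # orthonormal columns that are also exactly mean-free (orthogonal to the
    # intercept), so the sample correlation is exactly r
    q <- qr.Q(qr(cbind(1, matrix(rnorm(400), 200, 2))))
    z <- q[, 2:3]
  })
  r <- 0.6
  x1 <- z[, 1]
  x2 <- r * z[, 1] + sqrt(1 - r^2) * z[, 2]
  m <- cbind(a = x1, b = x2)
  pca <- pca_loadings(zscore_columns(m))
  expect_equal(pca$explained[1], (1 + r) / 2, tolerance = 1e-10)
})

test_that("PCA identities hold: variance fractions, loadings, reconstruction", {
  withr::with_seed(3, {
    m <- matrix(rnorm(300 * 9), 300, 9, dimnames = list(NULL, paste0("imu", 1:9)))
    m[, 7] <- m[, 7] + 2 * sin((1:300) / 10)
  })
  z <- zscore_columns(m)
  pca <- pca_loadings(z)
  expect_equal(sum(pca$explained), 1, tolerance = 1e-12)
  expect_equal(unname(rowSums(pca$loadings^2)), rep(1, 9), tolerance = 1e-10)
  # scores pairwise uncorrelated, unit variance
  cc <- cor(pca$scores)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-10)
  # reconstruction of the standardised matrix
  rec <- pca$scores %*% t(pca$loadings)
  expect_lt(max(abs(rec - z)), 1e-10)
  # loading = correlation between variable and score
  expect_equal(unname(cor(z[, 7], pca$scores[, 1])),
               unname(pca$loadings[7, 1]), tolerance = 1e-10)
})

test_that("sign conventions: retained rho >= 0; column flips leave |loadings| alone", {
  withr::with_seed(14, {
    s <- sin(2 * pi * (1:400) / 80)
    m <- sapply(1:9, function(j) j * s + rnorm(400, 0, 0.5))
  })
  colnames(m) <- paste0("imu", 1:9)
  pca <- pca_loadings(zscore_columns(m))
  match_pos <- best_matching_pc(pca, s - mean(s))
  match_neg <- best_matching_pc(pca, -(s - mean(s)))
  expect_gte(match_pos$rho, 0)
  expect_gte(match_neg$rho, 0)
  expect_equal(match_pos$rho, match_neg$rho, tolerance = 1e-12)

  m2 <- m; m2[, 5] <- -m2[, 5]
  pca2 <- pca_loadings(zscore_columns(m2))
  expect_equal(pca2$explained, pca$explained, tolerance = 1e-10)
  expect_equal(abs(pca2$loadings), abs(pca$loadings), tolerance = 1e-8)
})

test_that("best-matching PC finds an exact score and flags orthogonal volumes", {
  withr::with_seed(14, {
    s <- sin(2 * pi * (1:400) / 80)
    m <- sapply(1:9, function(j) s + rnorm(400, 0, 0.05))
  })
  colnames(m) <- paste0("imu", 1:9)
  pca <- pca_loadings(zscore_columns(m))
  self <- best_matching_pc(pca, pca$scores[, 1])
  expect_equal(self$pc, 1L)
  expect_equal(self$rho, 1, tolerance = 1e-12)

  orth <- cos(2 * pi * (1:400) / 80)  # quadrature: near-zero correlation
  null_match <- best_matching_pc(pca, orth - mean(orth))
  expect_lt(null_match$rho, 0.25)
})

test_that("threshold selection arithmetic matches the shared-variance rule", {
  expect_gt(0.32^2, 0.10)
  expect_equal(0.32^2, 0.1024)
  matches <- tidyr::crossing(
    subject_id = c("S01", "S02"), repetition = 1L,
    family = "A_ToT", target = "AB",
    tibble::tibble(imu = paste0("imu", 1:9),
                   loading = c(0.1, 0.1, 0.1, 0.1, 0.33, 0.1, 0.50, 0.1, 0.40))
  )
  sel <- aggregate_and_select(matches, threshold = 0.32)
  picked <- sel$imu[sel$selected]
  expect_setequal(picked, c("imu5", "imu7", "imu9"))
})

test_that("on a noisy synthetic cohort, A_Y selection picks the lateral abdominal IMUs", {
  co <- tiny_cohort()
  res <- select_sensors(co)
  ay_ab <- dplyr::filter(tidy(res$selection), family == "A_Y", target == "AB")
  picked <- ay_ab$imu[ay_ab$selected]
  expect_true(all(c("imu7", "imu9") %in% picked))
  # midline and thoracic IMUs carry no lateral abdominal tilt
  expect_false(any(c("imu4", "imu5", "imu6", "imu8") %in% picked))
  # correlation of the retained PC with V_AB is high (gravity-tilt mechanism)
  m <- dplyr::filter(res$matches, family == "A_Y", target == "AB")
  expect_gt(min(m$rho), 0.95)
})
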