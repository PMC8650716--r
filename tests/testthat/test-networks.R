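toy_activity <- function(m, ids = sprintf("P%02d", seq_len(nrow(m)))) {
  colnames(m) <- sprintf("region_%03d", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(participant_id = ids),
                   tibble::as_tibble(m))
}

test_that("region means average in-mask voxels per parcel", {
  img <- array(0, c(2, 2, 1))
  img[1, 1, 1] <- 10; img[2, 1, 1] <- 20; img[1, 2, 1] <- 5
  parc <- array(0L, c(2, 2, 1))
  parc[1, 1, 1] <- 1L; parc[2, 1, 1] <- 1L; parc[1, 2, 1] <- 2L
  rm <- region_means(img, parc)
  expect_equal(rm$mean_cbf[rm$region == 1], 15)
  expect_equal(rm$mean_cbf[rm$region == 2], 5)
  # uniform image: every region mean equals the constant
  uni <- region_means(array(7, c(2, 2, 1)), parc)
  expect_true(all(uni$mean_cbf == 7))
  # region fully outside the mask is dropped with a warning
  mask <- array(TRUE, c(2, 2, 1)); mask[1, 2, 1] <- FALSE
  expect_warning(rm2 <- region_means(img, parc, mask), "dropped")
  expect_equal(rm2$region, 1)
})

test_that("region means equal a per-region loop oracle on random input", {
  set.seed(31)
  dims <- c(6, 6, 4)
  img <- array(rnorm(prod(dims), 50, 10), dims)
  parc <- array(sample(0:7, prod(dims), replace = TRUE), dims)
  mask <- array(runif(prod(dims)) > 0.2, dims)
  got <- region_means(img, parc, mask)
  for (r in got$region) {
    sel <- parc == r & mask
    expect_equal(got$mean_cbf[got$region == r], mean(img[sel]))
  }
})

test_that("gm centering subtracts each participant's global mean", {
  tbl <- toy_activity(rbind(c(50, 60, 70), c(5, 5, 5)))
  cen <- gm_center(tbl)
  expect_equal(unlist(cen[1, -1], use.names = FALSE), c(-10, 0, 10))
  expect_equal(unlist(cen[2, -1], use.names = FALSE), c(0, 0, 0))
  set.seed(32)
  big <- toy_activity(matrix(rnorm(28 * 100, 50, 8), 28, 100))
  cen_big <- gm_center(big)
  expect_lt(max(abs(rowMeans(as.matrix(cen_big[-1])))), 1e-10)
  expect_equal(attr(cen_big, "centering")$gm_mean,
               rowMeans(as.matrix(big[-1])))
  big[[2]][3] <- NA
  expect_error(gm_center(big), class = "stressnets_validation_error")
})

test_that("network extraction yields one component per participant", {
  set.seed(33)
  cen <- gm_center(toy_activity(matrix(rnorm(28 * 100, 50, 8), 28, 100)))
  model <- fit_networks(cen)
  expect_equal(ncol(model$loadings), 28)
  expect_equal(ncol(model$scores), 28)
  # reconstruction and orthonormality
  rec <- model$scores %*% t(model$loadings)
  cen_m <- as.matrix(cen[-1])
  expect_lt(max(abs(rec - cen_m)) / max(abs(cen_m)), 1e-8)
  expect_equal(crossprod(model$loadings), diag(28), ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_true(all(diff(model$singular_values) <= 1e-8))
  # fewer regions than participants is a configuration error
  small <- gm_center(toy_activity(matrix(rnorm(10 * 6), 10, 6)))
  expect_error(fit_networks(small), class = "stressnets_config_error")
})

test_that("a rank-one signal is recovered in the first component", {
  set.seed(34)
  L <- rnorm(40); L <- L - mean(L); L <- L / sqrt(sum(L^2))
  s <- rnorm(8, 0, 3)
  cen <- gm_center(toy_activity(s %*% t(L) + 50))
  model <- fit_networks(cen)
  expect_lt(max(abs(abs(model$loadings[, 1]) - abs(L))), 1e-8)
  expect_lt(max(model$singular_values[-1]), 1e-10)
  # sign convention: largest-magnitude loading is positive
  for (j in 1:2) {
    l <- model$loadings[, j]
    expect_gte(l[which.max(abs(l))], 0)
  }
})

test_that("scores and loadings match a dense SVD oracle up to sign", {
  set.seed(35)
  cen <- gm_center(toy_activity(matrix(rnorm(6 * 10), 6, 10)))
  model <- fit_networks(cen)
  sv <- svd(as.matrix(cen[-1]))
  expect_equal(model$singular_values, sv$d, tolerance = 1e-10)
  for (j in 1:6) {
    expect_equal(abs(model$loadings[, j]), abs(sv$v[, j]),
                 ignore_attr = TRUE, tolerance = 1e-8)
    expect_equal(abs(model$scores[, j]), abs(sv$u[, j] * sv$d[j]),
                 ignore_attr = TRUE, tolerance = 1e-8)
  }
})

test_that("stage projection is the matrix product onto the loadings", {
  set.seed(36)
  cen <- gm_center(toy_activity(matrix(rnorm(8 * 20), 8, 20)))
  model <- fit_networks(cen)
  # self-consistency: projecting the stress stage returns its own scores
  self <- project_stage(cen, model)
  expect_equal(as.matrix(self[-1]), model$scores, ignore_attr = TRUE,
               tolerance = 1e-10)
  # zero stage projects to zero
  zero <- toy_activity(matrix(0, 8, 20))
  expect_true(all(as.matrix(project_stage(zero, model)[-1]) == 0))
  # explicit product oracle on another random stage
  other <- gm_center(toy_activity(matrix(rnorm(8 * 20), 8, 20)))
  proj <- project_stage(other, model)
  expect_equal(as.matrix(proj[-1]),
               as.matrix(other[-1]) %*% model$loadings,
               ignore_attr = TRUE)
  # region mismatch is an alignment error
  wrong <- other
  names(wrong)[2] <- "region_x"
  expect_error(project_stage(wrong, model),
               class = "stressnets_alignment_error")
})

test_that("differential activity telescopes and propagates missing baseline 2", {
  mk <- function(vals) toy_activity(matrix(vals, ncol = 1), ids = "P01") |>
    stats::setNames(c("participant_id", "net_1"))
  d <- differential_activity(mk(0.5), mk(2.0), mk(1.0))
  expect_equal(d$exposure$net_1, 1.5)
  expect_equal(d$cessation$net_1, -1.0)
  # identical scores across stages: both planes zero
  d0 <- differential_activity(mk(1), mk(1), mk(1))
  expect_equal(d0$exposure$net_1, 0); expect_equal(d0$cessation$net_1, 0)
  # telescoping identity on random inputs
  set.seed(37)
  b1 <- toy_activity(matrix(rnorm(12), 4, 3))
  st <- toy_activity(matrix(rnorm(12), 4, 3))
  b2 <- toy_activity(matrix(rnorm(12), 4, 3))
  names(b1)[-1] <- names(st)[-1] <- names(b2)[-1] <- paste0("net_", 1:3)
  dd <- differential_activity(b1, st, b2)
  expect_equal(as.matrix(dd$exposure[-1]) + as.matrix(dd$cessation[-1]),
               as.matrix(b2[-1]) - as.matrix(b1[-1]))
  # a participant absent from baseline 2 gets NA cessation
  dd2 <- differential_activity(b1, st, b2[-2, ])
  expect_true(all(is.na(dd2$cessation[2, -1])))
  expect_false(anyNA(dd2$exposure))
})

test_that("winner-takes-all assigns regions by maximal absolute loading", {
  l <- rbind(c(0.2, 0.9, 0.1), c(-0.8, 0.3, 0.1), c(0.5, 0.5, 0))
  rownames(l) <- paste0("r", 1:3)
  wta <- winner_takes_all(l)
  expect_equal(wta$network, c(2L, 1L, 1L))  # abs value; tie -> lower index
  expect_equal(wta$loading, c(0.9, -0.8, 0.5))
  # signed variant picks the signed maximum
  wta_s <- winner_takes_all(l, signed = TRUE)
  expect_equal(wta_s$network[2], 2L)
})

test_that("rescaling CBF rescales scores but not assignments", {
  set.seed(38)
  tbl <- toy_activity(matrix(rnorm(8 * 20, 50, 5), 8, 20))
  m1 <- fit_networks(gm_center(tbl))
  tbl2 <- tbl; tbl2[-1] <- tbl2[-1] * 3
  m2 <- fit_networks(gm_center(tbl2))
  expect_equal(m2$scores, 3 * m1$scores, tolerance = 1e-8)
  expect_equal(winner_takes_all(m2)$network, winner_takes_all(m1)$network)
})
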