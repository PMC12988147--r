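test_that("partial correlation matches the first-order closed form", {
  # exact linear dependence survives residualization
  expect_equal(partial_corr(1:4, c(2, 4, 6, 8), c(3, 1, 4, 2)), 1.0)

  set.seed(42)
  for (rep in 1:5) {
    x <- rnorm(10); y <- rnorm(10); z <- rnorm(10)
    expect_equal(partial_corr(x, y, z), oracle_partial_corr(x, y, z),
                 tolerance = 1e-10)
  }
  expect_error(partial_corr(1:4, c(2, 4, 6, 8), rep(1, 4)), "zero variance")
  expect_error(partial_corr(rep(2, 4), 1:4, 1:4), "zero variance")
})

test_that("reference network matches element-wise residualization", {
  vt <- tiny_volume_table(5, 3, seed = 2)
  # all five subjects are < 30 so they all enter the reference
  ref <- build_reference(vt, cutoff = 30, min_ref = 5)
  expect_equal(ref$n_ref, 5)
  vols <- volume_matrix(vt)
  for (i in 1:3) for (j in 1:3) {
    if (i != j) {
      expect_equal(ref$r_ref[i, j],
                   oracle_partial_corr(vols[, i], vols[, j], vt$icv),
                   tolerance = 1e-10)
    }
  }
  expect_equal(diag(ref$r_ref), setNames(rep(1, 3), colnames(vols)))

  # identical regions correlate at exactly 1
  vt2 <- tibble::as_tibble(vt)
  vt2$R002 <- vt2$R001
  ref2 <- build_reference(as_volume_table(vt2, synthetic_atlas(3, 0)),
                          cutoff = 30, min_ref = 5)
  expect_equal(ref2$r_ref[1, 2], 1)
})

test_that("individual networks satisfy the z contract and match full recomputation", {
  atlas <- synthetic_atlas(4, prop_subcortical = 0)
  set.seed(8)
  tab <- dplyr::bind_cols(
    tibble::tibble(subject_id = sprintf("S%04d", 1:6),
                   age = c(22, 24, 25, 27, 28, 55), sex = rep("F", 6),
                   education = rep(12, 6), icv = runif(6, 1300, 1700)),
    tibble::as_tibble(matrix(runif(24, 5, 15), 6,
                             dimnames = list(NULL, atlas$region_id))))
  vt <- as_volume_table(tab, atlas)
  ref <- build_reference(vt, cutoff = 30, min_ref = 5)
  expect_equal(ref$n_ref, 5)
  net <- individual_network(ref, vt[6, ])

  # z-scoring contract on the off-diagonal upper triangle
  up <- net$z[upper.tri(net$z)]
  expect_lt(abs(mean(up)), 1e-9)
  expect_lt(abs(sd(up) - 1), 1e-9)
  expect_equal(net$z, t(net$z))
  expect_equal(diag(net$z), setNames(rep(0, 4), atlas$region_id))

  # D equals the brute-force difference of the two correlation matrices
  vols <- volume_matrix(vt)
  p_or <- matrix(NA_real_, 4, 4)
  r_or <- matrix(NA_real_, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    r_or[i, j] <- if (i == j) 1 else
      oracle_partial_corr(vols[1:5, i], vols[1:5, j], vt$icv[1:5])
    p_or[i, j] <- if (i == j) 1 else
      oracle_partial_corr(vols[, i], vols[, j], vt$icv)
  }
  expect_equal(unname(net$d), p_or - r_or, tolerance = 1e-10)

  # reference subjects are refused
  expect_error(individual_network(ref, vt[1, ]), "reference")
})

test_that("z networks are invariant to common rescaling of all volumes", {
  vt <- tiny_volume_table(8, 5, seed = 3)
  tab <- tibble::as_tibble(vt)
  tab$age[8] <- 45
  atlas <- synthetic_atlas(5, prop_subcortical = 0)
  vt <- as_volume_table(tab, atlas)
  ref <- build_reference(vt, cutoff = 30, min_ref = 5)
  net <- individual_network(ref, vt[8, ])

  tab2 <- tab
  tab2[, atlas$region_id] <- tab2[, atlas$region_id] * 3.7
  vt2 <- as_volume_table(tab2, atlas)
  ref2 <- build_reference(vt2, cutoff = 30, min_ref = 5)
  net2 <- individual_network(ref2, vt2[8, ])
  expect_equal(net$z, net2$z, tolerance = 1e-9)
})

test_that("batch construction covers eligible subjects and ignores row order", {
  truth <- synthetic_truth(n_subjects = 40, n_regions = 10, seed = 17)
  vt <- generate_volumes(truth)
  ref <- build_reference(vt, cutoff = 30)
  nets <- batch_individual_networks(vt, ref)
  expect_equal(nrow(nets), sum(vt$age >= 30))

  perm <- vt[sample(nrow(vt)), ]
  ref_p <- build_reference(perm, cutoff = 30)
  nets_p <- batch_individual_networks(perm, ref_p)
  expect_equal(nets_p, nets)

  young <- vt[vt$age < 30, ]
  ref_y <- build_reference(young, cutoff = 99)
  expect_warning(out <- batch_individual_networks(young, ref_y), "empty")
  expect_equal(nrow(out), 0)
})

test_that("perturbation magnitude shrinks as the reference grows", {
  meds <- sapply(c(20, 80, 320), function(n_ref) {
    dvals <- sapply(1:12, function(s) {
      set.seed(1000 + s)
      p <- 8
      vols <- matrix(rnorm((n_ref + 1) * p, 10, 1.5), n_ref + 1, p)
      icv <- runif(n_ref + 1, 1300, 1700)
      tab <- dplyr::bind_cols(
        tibble::tibble(subject_id = sprintf("S%04d", 1:(n_ref + 1)),
                       age = c(rep(25, n_ref), 50), sex = "F",
                       education = 12, icv = icv),
        tibble::as_tibble(`colnames<-`(vols, sprintf("R%03d", 1:p))))
      vt <- as_volume_table(tab, synthetic_atlas(p, 0))
      ref <- build_reference(vt, cutoff = 30)
      net <- individual_network(ref, vt[n_ref + 1, ])
      mean(abs(net$d[upper.tri(net$d)]))
    })
    median(dvals)
  })
  expect_true(all(diff(meds) < 0))
})
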