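test_that("identity-effort noiseless phantom has J = 1 and equal images", {
  ph <- simulate_phantom(effort = 1.0, heterogeneity = 0,
                         disease_fraction = 0, noise_sd_frc = 0,
                         noise_sd_tlc = 0, seed = 3,
                         shape = c(20, 20, 20))
  m <- ph$M_FRC$data == 1
  expect_equal(max(abs(ph$J_FRC$J$data[m] - 1)), 0, tolerance = 1e-9)
  expect_identical(ph$M_FRC$data, ph$M_TLC$data)
  expect_equal(ph$I_TLC$data[m], ph$I_FRC$data[m], tolerance = 1e-6)
})

test_that("pure affine effort gives constant reciprocal Jacobians", {
  ph <- simulate_phantom(effort = 2.0, heterogeneity = 0,
                         disease_fraction = 0, noise_sd_frc = 0,
                         noise_sd_tlc = 0, seed = 5,
                         shape = c(24, 24, 24))
  mf <- ph$M_FRC$data == 1
  mt <- ph$M_TLC$data == 1
  expect_equal(unique(round(ph$J_FRC$J$data[mf], 9)), 2.0)
  expect_equal(unique(round(ph$J_TLC$J$data[mt], 9)), 0.5)
  expect_equal(ph$effort_true, 2.0, tolerance = 1e-9)
})

test_that("noiseless cases satisfy tissue-mass conservation", {
  for (s in c(2, 7)) {
    ph <- clean_phantom(seed = s, shape = c(24, 24, 24))
    m <- ph$M_FRC$data == 1
    pts <- jacreg:::grid_points(grid3d(dim(ph$I_FRC$data),
                                       ph$I_FRC$spacing))[m, ]
    hx <- deform_apply(ph$h, pts)
    i_tlc_at_h <- jacreg:::interp_trilinear(ph$I_TLC$data, ph$I_TLC$spacing,
                                            ph$I_TLC$origin, hx)
    lhs <- ph$I_FRC$data[m] + 1000
    rhs <- ph$J_FRC$J$data[m] * (i_tlc_at_h + 1000)
    rel <- abs(lhs - rhs) / pmax(lhs, 1)
    expect_lte(median(rel), 0.02)
  }
})

test_that("masks equal the analytic lung support sampled in each frame", {
  ph <- clean_phantom(seed = 4, shape = c(24, 24, 24))
  # FRC mask voxels must map into the TLC mask region under h (interior)
  expect_gte(mean(ph$J_FRC$J$data[ph$M_FRC$data == 1]) /
               (sum(ph$M_TLC$data) / sum(ph$M_FRC$data)), 0.97)
  # lobe labels partition each mask
  expect_true(check_partition(ph$lobes$FRC, ph$M_FRC))
  expect_true(check_partition(ph$lobes$TLC, ph$M_TLC))
  expect_gte(length(unique(ph$lobes$FRC$data[ph$lobes$FRC$data > 0])), 2)
})

test_that("achieved volume ratio tracks the latent effort within 5%", {
  ph <- clean_phantom(seed = 8, effort = 1.8, disease_fraction = 0.1,
                      shape = c(24, 24, 24))
  expect_equal(ph$effort_true,
               mean(ph$J_FRC$J$data[ph$M_FRC$data == 1]))
  expect_lt(abs(ph$effort_true - 1.8) / 1.8, 0.05 + 0.1 * 0.45)
})

test_that("trapped pockets have Jacobian closer to 1 than parenchyma", {
  ph <- clean_phantom(seed = 6, effort = 1.9, disease_fraction = 0.2,
                      shape = c(24, 24, 24))
  parts <- ph$h$parts
  fam <- vapply(parts, function(p) p$family, "")
  rad <- parts[[which(fam == "radial")]]
  m <- ph$M_FRC$data == 1
  pts <- jacreg:::grid_points(grid3d(dim(ph$I_FRC$data), 3))[m, ]
  j <- ph$J_FRC$J$data[m]
  dmin <- apply(rad$centers, 1, function(p)
    sqrt(rowSums(sweep(pts, 2, p)^2)))
  in_pocket <- apply(dmin, 1, min) < min(rad$width)
  expect_true(any(in_pocket))
  expect_lt(mean(abs(j[in_pocket] - 1)), mean(abs(j[!in_pocket] - 1)))
})

test_that("effort is unidentifiable from the FRC image alone", {
  a <- clean_phantom(seed = 12, effort = 1.3, shape = c(20, 20, 20))
  b <- clean_phantom(seed = 12, effort = 2.1, shape = c(20, 20, 20))
  expect_equal(a$I_FRC$data, b$I_FRC$data, tolerance = 1e-9)
  expect_identical(a$M_FRC$data, b$M_FRC$data)
  expect_gt(b$effort_true - a$effort_true, 0.5)
})

test_that("cohorts are deterministic and stratified", {
  c1 <- simulate_cohort(7, seed = 5, shape = c(16, 16, 16))
  c2 <- simulate_cohort(7, seed = 5, shape = c(16, 16, 16))
  expect_identical(lapply(c1, `[[`, "I_FRC"), lapply(c2, `[[`, "I_FRC"))
  expect_identical(vapply(c1, `[[`, 0, "effort_true"),
                   vapply(c2, `[[`, 0, "effort_true"))
  ids <- vapply(c1, `[[`, "", "case_id")
  expect_equal(anyDuplicated(ids), 0L)
  bins <- vapply(c1, `[[`, 0L, "severity_bin")
  expect_equal(sort(bins), 1:7)
})

test_that("disease burden lowers the cohort-mean Jacobian at fixed effort", {
  jm <- vapply(c(0, 0.12, 0.25), function(df) {
    ph <- clean_phantom(seed = 21, effort = 1.8, disease_fraction = df,
                        shape = c(24, 24, 24))
    mean(ph$J_FRC$J$data[ph$M_FRC$data == 1])
  }, 0)
  expect_true(all(diff(jm) < 0))
})

test_that("phantom cases survive a write/read round trip", {
  ph <- clean_phantom(seed = 13, shape = c(16, 16, 16))
  dir <- withr::local_tempdir()
  write_phantom(ph, dir)
  ph2 <- read_phantom_case(file.path(dir, ph$case_id))
  expect_equal(ph2$I_FRC$data, ph$I_FRC$data, tolerance = 1e-5)
  expect_identical(ph2$M_TLC$data, ph$M_TLC$data)
  expect_equal(ph2$effort_true, ph$effort_true, tolerance = 1e-9)
  expect_equal(ph2$J_FRC$J$data, ph$J_FRC$J$data, tolerance = 1e-6)
})

test_that("phantom PRM maps partition each mask and include disease classes", {
  ph <- clean_phantom(seed = 22, shape = c(24, 24, 24),
                      disease_fraction = 0.2)
  expect_true(check_partition(ph$prm$FRC, ph$M_FRC))
  expect_true(check_partition(ph$prm$TLC, ph$M_TLC))
  classes <- unique(ph$prm$FRC$data[ph$M_FRC$data == 1])
  expect_true(1 %in% classes)          # normal parenchyma present
  expect_gte(length(classes), 2)       # plus at least one disease class
})

test_that("severity bins show decreasing ground-truth mean Jacobian", {
  cohort <- simulate_cohort(12, n_bins = 3, seed = 31,
                            shape = c(20, 20, 20))
  sev <- vapply(cohort, `[[`, 0L, "severity_bin")
  jmu <- vapply(cohort, `[[`, 0, "effort_true")
  bin_means <- tapply(jmu, sev, mean)
  expect_true(all(diff(bin_means) < 0))
})
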