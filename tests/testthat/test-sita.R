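test_that("correction matrix columns are binomial mass-shift kernels", {
  expect_equal(correction_matrix(4, 0, 1), diag(5))

  C1 <- correction_matrix(1, 0.011, 1)
  expect_equal(C1[, 1], c(0.989, 0.011))

  C3 <- correction_matrix(3, 0.011, 1)
  expect_equal(C3[2, 1], 3 * 0.011 * 0.989^2)
  expect_equal(colSums(C3), rep(1, 4))

  # impure tracer shifts label down from fully labeled species
  Cp <- correction_matrix(2, 0, 0.99)
  expect_equal(Cp[, 3], dbinom(0:2, 2, 0.99))

  expect_error(correction_matrix(3, 0.6, 1), "p13_natural")
  expect_error(correction_matrix(3, 0.01, 0), "tracer_purity")
})

test_that("correction recovers pure and trivially-corrected spectra", {
  C <- correction_matrix(4, 0.0107, 0.99)
  sp <- isotopolog_spectrum("met", 4, 1000 * C[, 1])
  expect_equal(correct_natural_abundance(sp, 0.0107, 0.99)$fractions,
               c(1, 0, 0, 0, 0), tolerance = 1e-9)

  sp2 <- isotopolog_spectrum("met", 3, c(10, 20, 30, 40))
  expect_equal(correct_natural_abundance(sp2, 0, 1)$fractions,
               c(10, 20, 30, 40) / 100)
})

test_that("forward convolution then correction is the identity", {
  mid <- mid_profile("met", c(0.2, 0, 0.5, 0.3))
  sp <- apply_natural_abundance(mid, 0.011, 1, total = 500)
  back <- correct_natural_abundance(sp, 0.011, 1)
  expect_lt(max(abs(back$fractions - mid$fractions)), 1e-6)

  set.seed(123)
  for (rep in 1:40) {
    n <- sample(3:6, 1)
    fr <- random_mid(n)
    sp <- apply_natural_abundance(mid_profile("m", fr), 0.0107, 0.99,
                                  total = stats::runif(1, 10, 1e4))
    back <- correct_natural_abundance(sp, 0.0107, 0.99)
    expect_lt(max(abs(back$fractions - fr)), 1e-6)
    expect_true(all(back$fractions >= 0))
    expect_equal(sum(back$fractions), 1, tolerance = 1e-9)
  }
})

test_that("labeled/unlabeled abundances split the pool at M+0", {
  sp <- isotopolog_spectrum("met", 3, c(1, 1, 1, 1), protein_ug = 10)
  ab <- labeled_abundance(sp, mid_profile("met", c(1, 0, 0, 0)),
                          total_pool = 100)
  expect_equal(ab$labeled_c13, 0)
  expect_equal(ab$unlabeled_c12, 10)

  ab2 <- labeled_abundance(sp, mid_profile("met", c(0.4, 0, 0.6, 0)),
                           total_pool = 100)
  expect_equal(ab2$labeled_c13, 6)
  expect_equal(ab2$unlabeled_c12, 4)

  sp20 <- isotopolog_spectrum("met", 3, c(1, 1, 1, 1), protein_ug = 20)
  ab3 <- labeled_abundance(sp20, mid_profile("met", c(0.4, 0, 0.6, 0)),
                           total_pool = 100)
  expect_equal(ab3$labeled_c13, ab2$labeled_c13 / 2)
  expect_equal(ab3$unlabeled_c12, ab2$unlabeled_c12 / 2)

  sp_bad <- sp; sp_bad$protein_ug <- 0
  expect_error(labeled_abundance(sp_bad, mid_profile("met", c(1, 0, 0, 0))),
               "protein")
})

test_that("surrogate ratios follow the citrate/pyruvate fraction arithmetic", {
  pyr <- mid_profile("pyruvate", c(0.4, 0, 0, 0.6))
  cit <- mid_profile("citrate", c(0.25, 0, 0.30, 0.15, 0.3, 0, 0))
  expect_equal(pdh_surrogate(cit, pyr), 0.5)
  expect_equal(pc_surrogate(cit, pyr), 0.25)

  cit0 <- mid_profile("citrate", c(0.7, 0, 0, 0, 0.3, 0, 0))
  expect_equal(pdh_surrogate(cit0, pyr), 0)
  expect_equal(pc_surrogate(cit0, pyr), 0)

  pyr0 <- mid_profile("pyruvate", c(1, 0, 0, 0))
  expect_true(is_flagged(pdh_surrogate(cit, pyr0)))
})

test_that("surrogate ratios are invariant to uniform intensity scaling", {
  set.seed(9)
  raw_c <- stats::runif(7, 1, 100)
  raw_p <- stats::runif(4, 1, 100)
  mids <- function(k_c, k_p) {
    list(c = correct_natural_abundance(
           isotopolog_spectrum("citrate", 6, k_c * raw_c)),
         p = correct_natural_abundance(
           isotopolog_spectrum("pyruvate", 3, k_p * raw_p)))
  }
  a <- mids(1, 1); b <- mids(250, 0.04)
  expect_equal(pdh_surrogate(a$c, a$p), pdh_surrogate(b$c, b$p))
  expect_equal(pc_surrogate(a$c, a$p), pc_surrogate(b$c, b$p))
})

test_that("spectra CSV round trip and sample summary work end to end", {
  cfg <- label_network_config(phi_pdh = 0.6, phi_pc = 0.2, seed = 4)
  mids <- simulate_mids(cfg)
  spectra <- lapply(mids[c("pyruvate", "citrate")], apply_natural_abundance,
                    total = 1000)
  rows <- do.call(rbind, lapply(spectra, function(sp)
    data.frame(metabolite = sp$metabolite, n_carbons = sp$n_carbons,
               mass_shift = 0:sp$n_carbons, intensity = sp$intensities,
               sample_id = "S1", protein_ug = 12)))
  f <- tempfile(fileext = ".csv")
  utils::write.csv(rows, f, row.names = FALSE)
  res <- sita_correct_samples(read_spectra(f))
  expect_equal(res$mids$S1$citrate$fractions, mids$citrate$fractions,
               tolerance = 1e-6)
  got <- res$summary
  pdh_row <- got$value[got$quantity == "citrate_m2_over_pyruvate_m3"]
  expect_equal(pdh_row, pdh_surrogate(mids$citrate, mids$pyruvate),
               tolerance = 1e-6, ignore_attr = TRUE)
  file.remove(f)
})
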