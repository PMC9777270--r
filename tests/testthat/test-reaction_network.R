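test_that("species catalog matches the model structure", {
  cat <- species_catalog()
  expect_equal(nrow(cat), 14L)
  expect_false(anyDuplicated(cat$symbol) > 0)
  # immobile: naive pools and necrotic debris
  expect_identical(cat$symbol[!cat$motile], c("Mn", "Tn", "N"))
  # solid constituents are exactly the dendritic/cancer/necrotic populations
  expect_identical(which(cat$solid), 7:10)
  expect_identical(solid_species(), 7:10)
  # cytokines diffuse; HMGB1 has its own coefficient
  expect_identical(cat$diffusion[cat$symbol == "H"], "H")
  expect_true(all(cat$diffusion[cat$role == "cytokine"] != "none"))
})

test_that("calibrated sets have the unit state as an exact stable equilibrium", {
  expect_lt(max(abs(reaction_rhs(rep(1, 14), rp1))), 1e-10)
  ev <- eigen(reaction_jacobian(rep(1, 14), rp1), only.values = TRUE)$values
  expect_lt(max(Re(ev)), 0)
  # determinism: the same seed reproduces the identical set
  expect_identical(synthesize_parameters(1)$rates, rp1$rates)
  # a different seed yields a different but equally calibrated set
  rp3 <- synthesize_parameters(3)
  expect_false(identical(rp3$rates, rp1$rates))
  expect_lt(max(abs(reaction_rhs(rep(1, 14), rp3))), 1e-10)
})

test_that("vector field cannot push a nonnegative state negative", {
  # at the boundary of the orthant each component's rate is nonnegative
  for (i in 1:14) {
    x <- rep(1, 14)
    x[i] <- 0
    expect_gte(reaction_rhs(x, rp1)[i], 0)
  }
  # all-zero cell state with zero naive supply: no negative rates
  z <- rp1$rates
  z[c("A_Mn", "A_Tn", "A_Dn")] <- 0
  rp0 <- reaction_parameters(z)
  expect_true(all(reaction_rhs(rep(0, 14), rp0) >= 0))
  expect_error(reaction_rhs(rep(-1, 14), rp1), "negative")
  expect_error(reaction_rhs(c(NaN, rep(1, 13)), rp1), "non-finite")
})

test_that("analytic Jacobian matches central finite differences", {
  set.seed(101)
  h <- 1e-6
  worst <- 0
  for (rep in 1:100) {
    x <- runif(14, 0.3, 2)
    J <- reaction_jacobian(x, rp1)
    Jfd <- matrix(0, 14, 14)
    for (j in 1:14) {
      xp <- x; xm <- x
      xp[j] <- xp[j] + h; xm[j] <- xm[j] - h
      Jfd[, j] <- (reaction_rhs(xp, rp1) - reaction_rhs(xm, rp1)) / (2 * h)
    }
    worst <- max(worst, max(abs(J - Jfd)) / max(abs(J)))
  }
  expect_lt(worst, 1e-5)
})

test_that("Jacobian has the network's structural zeros and linear decays", {
  J <- reaction_jacobian(runif(14, 0.5, 1.5), rp1)
  # no interaction edge: naive macrophages do not sense naive T cells,
  # necrotic cells do not sense cytokine mu1, cancer does not sense Mn
  expect_identical(J["Mn", "Tn"], 0)
  expect_identical(J["N", "mu1"], 0)
  expect_identical(J["C", "Mn"], 0)
  # linear decay contributes exactly -d on the diagonal of a pure-decay row
  expect_equal(J["N", "N"], -unname(rp1$rates["d_N"]))
  expect_equal(J["Ig", "Ig"], -unname(rp1$rates["d_Ig"]))
})

test_that("a perturbed rate shifts the unit-state residual by its analytic term", {
  z <- rp1$rates
  delta <- 0.1 * z[["l_m2_M"]]
  z[["l_m2_M"]] <- z[["l_m2_M"]] + delta
  rp_pert <- reaction_parameters(z)
  res <- reaction_rhs(rep(1, 14), rp_pert)
  # only the mu2 balance changes, by exactly the added production at ones
  expect_equal(unname(res[13]), unname(delta), tolerance = 1e-12)
  expect_lt(max(abs(res[-13])), 1e-12)
})

test_that("synthetic networks carry the documented interaction signs", {
  for (s in c(1, 2, 5)) {
    rp <- synthesize_parameters(s)
    S <- -solve(reaction_jacobian(rep(1, 14), rp))
    expect_gt(sum(S[solid_species(), 2]), 0)   # macrophage supply grows V
    expect_lt(S[9, 6], 0)                      # cytotoxic supply shrinks C
  }
})

test_that("term-by-term export balances production against removal", {
  df <- export_reaction_terms(rp1)
  expect_equal(nrow(df), 14L)
  expect_lt(max(abs(df$net)), 1e-10)
  expect_true(all(df$removal_rate >= 0))
  f <- tempfile(fileext = ".csv")
  export_reaction_terms(rp1, file = f)
  expect_true(file.exists(f))
  unlink(f)
})
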