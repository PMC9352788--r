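test_that("stationary distribution: closed form, defining property, frozen value", {
  # 2-state chain: pi proportional to (k_off, k_on * L)
  Q <- build_rate_matrix(micro_rates(2, 1), L_free = 0.5)
  expect_equal(stationary_distribution(Q), c(1, 1) / 2, tolerance = 1e-12)
  Q <- build_rate_matrix(micro_rates(4, 1), L_free = 0.25)
  expect_equal(stationary_distribution(Q), c(0.5, 0.5), tolerance = 1e-12)

  set.seed(5)
  for (rep in 1:20) {
    inst <- random_instance()
    Q <- build_rate_matrix(inst$rates, inst$L)
    pi <- stationary_distribution(Q)
    expect_equal(sum(pi), 1, tolerance = 1e-12)
    expect_true(all(pi > 0))
    expect_lt(max(abs(Q$QT %*% pi)), 1e-10 * max(abs(Q$QT)))
  }

  # frozen high-precision null-space solution, bivalent reported rates
  Q <- build_rate_matrix(biv$qc$rates, L_free = 0.1)
  expect_equal(stationary_distribution(Q),
               c(0.022380977445, rep(0.128739221269, 4),
                 rep(0.231331068739, 2)), tolerance = 1e-9)
  expect_error(stationary_distribution(build_rate_matrix(biv$qc$rates, 0)),
               "reducible")
})

test_that("memberships are a fuzzy partition built from the slow subspace", {
  set.seed(6)
  for (rep in 1:20) {
    inst <- random_instance()
    Q <- build_rate_matrix(inst$rates, inst$L)
    chi <- pcca_memberships(Q)$chi
    expect_true(all(chi >= 0 & chi <= 1))
    expect_equal(rowSums(chi), rep(1, nrow(chi)), tolerance = 1e-10)
    # unbound macro state carries the unbound micro state
    expect_gte(chi[1, "unbound"], chi[1, "bound"])
  }
  # columns lie in the span of the eigenvectors used (projection residual)
  Q <- build_rate_matrix(biv$qc$rates, L_free = 0.1)
  mem <- pcca_memberships(Q)
  e <- eigen(t(Q$QT))
  ord <- order(abs(Re(e$values)))
  basis <- Re(e$vectors[, c(ord[1], ord[mem$selected])])
  proj <- basis %*% qr.solve(basis, mem$chi)
  expect_lt(max(abs(proj - mem$chi)), 1e-8)
})

test_that("uncoupled blocks cluster crisply and s = 1 gives the identity", {
  # two disconnected 2-state chains: memberships crisp 0/1 by block
  block <- function(kon, koff) matrix(c(-kon, kon, koff, -koff), 2, 2)
  QT <- rbind(cbind(block(3, 1), matrix(0, 2, 2)),
              cbind(matrix(0, 2, 2), block(0.2, 0.05)))
  chi <- pcca_memberships(QT, unbound = 1L)$chi
  expect_equal(sort(unique(round(as.vector(chi), 10))), c(0, 1))
  expect_identical(chi[1, ], chi[2, ])   # first block together
  expect_identical(chi[3, ], chi[4, ])   # second block together

  Q1 <- build_rate_matrix(micro_rates(3, 2), L_free = 0.4)
  chi1 <- pcca_memberships(Q1)$chi
  expect_equal(unname(chi1), diag(2), tolerance = 1e-12)
})

test_that("coarse graining preserves generator structure and the identity case", {
  # chi = identity on a 2-state chain: Q_c equals Q exactly
  Q <- build_rate_matrix(micro_rates(3, 2), L_free = 0.4)
  cg <- coarse_grain(Q)
  expect_equal(unname(cg$Qc_T), Q$QT, tolerance = 1e-12)
  expect_equal(cg$k_on_macro, 3, tolerance = 1e-12)
  expect_equal(cg$k_off_macro, 2, tolerance = 1e-12)

  set.seed(8)
  for (rep in 1:20) {
    inst <- random_instance()
    Q <- build_rate_matrix(inst$rates, inst$L)
    cg <- coarse_grain(Q)
    expect_lt(max(abs(colSums(cg$Qc_T))), 1e-8 * max(abs(cg$Qc_T)))
    expect_gt(cg$K_a_macro, 0)
    # the projection agrees with the membership-weighted stationary
    # occupancy ratio (independent route to K_a)
    expect_equal(cg$K_a_macro, ka_occupancy_oracle(Q), tolerance = 1e-8)
  }
})

test_that("macroscopic K_a is invariant under micro-state permutation", {
  Q <- build_rate_matrix(biv$qc$rates, L_free = 0.02)
  K0 <- coarse_grain(Q)$K_a_macro
  set.seed(9)
  for (rep in 1:5) {
    perm <- c(1L, 1L + sample(6L))   # keep the unbound state first
    QTp <- Q$QT[perm, perm]
    chi <- pcca_memberships(QTp, unbound = 1L)
    pi <- stationary_distribution(QTp)
    Kp <- coarse_grain(QTp, chi, pi, L_free = 0.02)$K_a_macro
    expect_equal(Kp, K0, tolerance = 1e-9)
  }
})

test_that("per-injection association constants: s = 1 constant, frozen bivalent series", {
  K <- association_constants(micro_rates(6, 2), c(0.001, 0.05, 2))
  expect_equal(K, rep(3, 3), tolerance = 1e-10)

  # frozen cross-implementation recomputation along the reference
  # free-ligand series (cumulative mode)
  lig <- free_ligand_series(biv$qc$rates, biv$qc$n, biv_conc)
  expect_equal(lig$K,
               c(427.58948920608265, 411.3912247582642, 393.3750522540593,
                 372.4287008807097, 346.7742421249363, 313.956075044713,
                 271.4023226254725, 217.3096834318597, 151.66274873292795,
                 80.60806973390062, 31.024049554628956, 13.931731196334566,
                 8.091251528508616, 5.448142506395071),
               tolerance = 1e-6)
  expect_equal(coarse_grain(build_rate_matrix(biv$qc$rates, 0.1))$K_a_macro,
               111.65878092996013, tolerance = 1e-8)
})

test_that("slowest ligand-exchanging rate matches the coarse model when separation is good", {
  # for a well separated chain the nonzero eigenvalue of Q_c approximates
  # the corresponding micro eigenvalue: k_on*[L] + k_off ~ -lambda_sel
  Q <- build_rate_matrix(micro_rates(c(10, 0.1), c(0.1, 10)), L_free = 0.01)
  mem <- pcca_memberships(Q)
  cg <- coarse_grain(Q, mem)
  lam_sel <- abs(mem$eigenvalues[mem$selected])
  expect_equal(cg$k_on_macro * 0.01 + cg$k_off_macro, lam_sel,
               tolerance = 0.05)
})
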