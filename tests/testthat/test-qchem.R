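# Quantum engine: integrals against closed-form and finite-difference
# oracles, SCF physics, Mulliken populations, nucleophilicity profiles.

test_that("engine one-electron s integrals match the closed forms", {
  # two s primitives on different centers, coords in bohr
  A <- c(0, 0, 0); B <- c(0.4, -0.3, 1.1)
  a <- 0.9; b <- 1.7
  ints <- engine_integrals(c(1, 1), rbind(A, B),   # bohr
                           shell_l = c(0, 0), shell_atom = c(1, 2),
                           exps = list(a, b))
  nn <- norm_s(a) * norm_s(b)
  expect_equal(ints$S[1, 2], nn * oracle_overlap_ss(a, A, b, B),
               tolerance = 1e-10)
  expect_equal(ints$T[1, 2], nn * oracle_kinetic_ss(a, A, b, B),
               tolerance = 1e-10)
  v_exp <- oracle_nuclear_ss(a, A, b, B, 1, A) +
    oracle_nuclear_ss(a, A, b, B, 1, B)
  expect_equal(ints$V[1, 2], nn * v_exp, tolerance = 1e-10)
  expect_equal(eri_at(ints, 1, 2, 1, 2),
               nn^2 * oracle_eri_ssss(a, A, b, B, a, A, b, B),
               tolerance = 1e-10)
  expect_equal(eri_at(ints, 1, 1, 2, 2),
               norm_s(a)^2 * norm_s(b)^2 *
                 oracle_eri_ssss(a, A, a, A, b, B, b, B),
               tolerance = 1e-10)
})

test_that("engine p integrals match finite differences of s integrals", {
  A <- c(0.2, 0.1, -0.3); B <- c(-0.5, 0.8, 0.4)
  a <- 1.1; b <- 0.6
  # shells: p on atom 1, s on atom 2 -> basis: px py pz s (coords in bohr)
  ints <- engine_integrals(c(6, 1), rbind(A, B),
                           shell_l = c(1, 0), shell_atom = c(1, 2),
                           exps = list(a, b))
  nn <- norm_p(a) * norm_s(b)
  s_fd <- oracle_px_via_fd(function(Ax) oracle_overlap_ss(a, Ax, b, B), a, A)
  expect_equal(ints$S[1, 4], nn * s_fd, tolerance = 1e-7)
  t_fd <- oracle_px_via_fd(function(Ax) oracle_kinetic_ss(a, Ax, b, B), a, A)
  expect_equal(ints$T[1, 4], nn * t_fd, tolerance = 1e-7)
  # nuclear attraction: differentiate only the orbital center (the FD
  # oracle keeps the point charges fixed, matching the basis-function
  # derivative identity)
  C1 <- c(1.5, -0.7, 0.2)
  ints2 <- engine_integrals(c(6, 1), rbind(C1, B),
                            shell_l = c(1, 0), shell_atom = c(1, 2),
                            exps = list(a, b))
  # engine puts the p shell on atom 1 at C1; differentiate only the orbital
  # center via a 3-center oracle with charges fixed at C1 and B
  v_fd2 <- oracle_px_via_fd(function(Ax) {
    oracle_nuclear_ss(a, Ax, b, B, 6, C1) +
      oracle_nuclear_ss(a, Ax, b, B, 1, B)
  }, a, C1)
  expect_equal(ints2$V[1, 4], nn * v_fd2, tolerance = 1e-6)
  # two-electron (px s | s s)
  e_fd <- oracle_px_via_fd(function(Ax) {
    oracle_eri_ssss(a, Ax, b, B, b, B, b, B)
  }, a, A)
  expect_equal(eri_at(ints, 1, 4, 4, 4), norm_p(a) * norm_s(b)^3 * e_fd,
               tolerance = 1e-7)
})

test_that("H2 RHF energy matches an independent closed-form calculation", {
  # contracted STO-3G hydrogen rebuilt from the oracle formulas only
  sh <- basis_shells("H")[[1]]
  ex <- sh$exps
  cf <- sh$coefs * vapply(ex, norm_s, 1)          # normalized primitives
  # contracted self-overlap for final normalization
  self_ov <- 0
  for (i in 1:3) for (j in 1:3) {
    self_ov <- self_ov + cf[i] * cf[j] *
      oracle_overlap_ss(ex[i], c(0, 0, 0), ex[j], c(0, 0, 0))
  }
  cf <- cf / sqrt(self_ov)
  A <- c(0, 0, 0); B <- c(0, 0, 0.74 / 0.52917721092)
  contr2 <- function(f, P1, P2) {
    out <- 0
    for (i in 1:3) for (j in 1:3) {
      out <- out + cf[i] * cf[j] * f(ex[i], P1, ex[j], P2)
    }
    out
  }
  contr4 <- function(P1, P2, P3, P4) {
    out <- 0
    for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3) {
      out <- out + cf[i] * cf[j] * cf[k] * cf[l] *
        oracle_eri_ssss(ex[i], P1, ex[j], P2, ex[k], P3, ex[l], P4)
    }
    out
  }
  S12 <- contr2(oracle_overlap_ss, A, B)
  h11 <- contr2(oracle_kinetic_ss, A, A) +
    contr2(function(a, x, b, y) {
      oracle_nuclear_ss(a, x, b, y, 1, A) + oracle_nuclear_ss(a, x, b, y, 1, B)
    }, A, A)
  h12 <- contr2(oracle_kinetic_ss, A, B) +
    contr2(function(a, x, b, y) {
      oracle_nuclear_ss(a, x, b, y, 1, A) + oracle_nuclear_ss(a, x, b, y, 1, B)
    }, A, B)
  # bonding MO by symmetry; its self-repulsion from the AO integrals
  c_mo <- 1 / sqrt(2 * (1 + S12))
  J1111 <- contr4(A, A, A, A); J1122 <- contr4(A, A, B, B)
  J1112 <- contr4(A, A, A, B); J1212 <- contr4(A, B, A, B)
  jmm <- c_mo^4 * (2 * J1111 + 2 * J1122 + 8 * J1112 + 4 * J1212)
  # E = 2 h_MM + J_MM + E_nuc with h_MM = c^2 (h11 + 2 h12 + h22)
  h_mm <- c_mo^2 * (2 * h11 + 2 * h12)
  e_oracle <- 2 * h_mm + jmm + 1 / sqrt(sum((A - B)^2))

  st <- list(atom_symbols = c("H", "H"),
             coordinates = matrix(c(0, 0, 0, 0, 0, 0.74), 2, 3, byrow = TRUE))
  w <- run_rhf(st, conv_tol = 1e-9)
  expect_equal(w$energy, e_oracle, tolerance = 1e-8)
  # bonding MO has equal weight on both atoms
  p <- homo_mulliken_populations(w)
  expect_equal(unname(p), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("basis sizes and occupations follow from the AO count", {
  st <- embed_3d("O")           # water after H addition
  w <- run_rhf(st)
  expect_equal(w$n_basis, 7L)   # O: 2s shells + 1p shell = 5, plus 2 H
  expect_equal(w$homo_index, 5L)
  expect_lt(w$orbital_energies[w$homo_index], 0)  # bound HOMO
  expect_equal(sort(w$orbital_energies), w$orbital_energies)
})

test_that("wavefunctions are orthonormal and Mulliken closure holds", {
  for (smiles in c("C=C", "C1CO1")) {
    st <- embed_3d(smiles)
    w <- run_rhf(st)
    M <- t(w$C) %*% w$S %*% w$C
    expect_lt(max(abs(M - diag(nrow(M)))), 1e-6)
    # total Mulliken population over occupied MOs equals the electron count
    nocc <- w$homo_index
    total <- 0
    for (k in seq_len(nocc)) {
      ck <- w$C[, k]
      total <- total + 2 * sum(ck * as.vector(w$S %*% ck))
    }
    expect_equal(total, w$n_electrons, tolerance = 1e-5)
    # single-MO partition sums to one
    expect_equal(sum(homo_mulliken_populations(w)), 1, tolerance = 1e-6)
  }
})

test_that("embedding is seeded, deterministic, and validates species", {
  st1 <- embed_3d("C=C", seed = 42L)
  polytag_clear_cache()
  st2 <- embed_3d("C=C", seed = 42L)
  expect_identical(st1$coordinates, st2$coordinates)
  # double-bond length in the tabulated range
  cc <- sqrt(sum((st1$coordinates[1, ] - st1$coordinates[2, ])^2))
  expect_gt(cc, 1.30); expect_lt(cc, 1.40)
  expect_equal(st1$atom_symbols[1:2], c("C", "C"))
  expect_error(embed_3d("[CH3]"), "open shell")
  expect_error(embed_3d("[NH4+]"), "net charge")
})

test_that("unsupported methods and elements are refused clearly", {
  st <- embed_3d("C=C")
  expect_error(run_rhf(st, method = "B3LYP"), "not implemented")
  expect_error(run_rhf(list(atom_symbols = c("S", "H", "H"),
                            coordinates = matrix(rnorm(9), 3, 3)),
                       basis = "STO-3G"), "unsupported element")
})

test_that("nucleophilicity profiles are normalized, ranked, and symmetric", {
  prof <- reactivity_profile("C=C")
  # symmetry-equivalent carbons agree
  expect_lt(abs(prof$nucleophilicity[1] - prof$nucleophilicity[2]), 1e-3)
  # R_X >= 0 and sums to 1/(1 - eps_HOMO)
  expect_true(all(prof$nucleophilicity >= -1e-12))
  expect_equal(sum(prof$nucleophilicity), 1 / (1 - prof$homo_energy),
               tolerance = 1e-9)
  # ranking by R_X is the ranking by HOMO population (shared denominator)
  expect_identical(order(-prof$nucleophilicity, seq_along(prof$nucleophilicity)),
                   order(-prof$homo_population, seq_along(prof$homo_population)))
  expect_setequal(prof$ranking, seq_along(prof$nucleophilicity))
})

test_that("butadiene terminal carbons out-rank inner carbons, as the
           Hueckel chain model predicts independently", {
  w_huckel <- hueckel_homo_weights(4)
  expect_gt(w_huckel[1], w_huckel[2])  # oracle: terminal > inner
  prof <- reactivity_profile("C=CC=C")
  rx <- prof$nucleophilicity[1:4]      # canonical order: C1 C2 C3 C4 chain
  expect_gt(rx[1], rx[2])
  expect_gt(rx[4], rx[3])
  # symmetry-equivalent pairs agree
  expect_lt(abs(rx[1] - rx[4]), 1e-3)
  expect_lt(abs(rx[2] - rx[3]), 1e-3)
})

test_that("profiles are reproducible from scratch for a fixed seed", {
  p1 <- reactivity_profile("CC1CO1", cache = FALSE)
  polytag_clear_cache()
  p2 <- reactivity_profile("CC1CO1", cache = FALSE)
  expect_identical(p1$nucleophilicity, p2$nucleophilicity)
  expect_identical(p1$ranking, p2$ranking)
  expect_identical(p1$homo_energy, p2$homo_energy)
})

test_that("XYZ export writes the embedded geometry", {
  st <- embed_3d("C=C")
  path <- tempfile(fileext = ".xyz")
  write_xyz(st, path)
  lines <- readLines(path)
  expect_equal(as.integer(lines[1]), length(st$atom_symbols))
  expect_match(lines[3], "^C ")
})
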