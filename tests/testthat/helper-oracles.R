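# Independent oracles used across the suite.  These deliberately avoid the
# package's McMurchie-Davidson code path: one-electron and two-electron
# integrals over s-type Gaussians use the textbook closed forms, p-type
# values are obtained from them by numerical center differentiation, and
# the conjugated-chain orbital ordering comes from a Hueckel model.

# ---- closed-form integrals over unnormalized s Gaussians -------------------

oracle_F0 <- function(t) {
  ifelse(t < 1e-12, 1 - t / 3, 0.5 * sqrt(pi / t) * erf_v(sqrt(t)))
}
erf_v <- function(x) 2 * pnorm(x * sqrt(2)) - 1

oracle_overlap_ss <- function(a, A, b, B) {
  p <- a + b
  ab2 <- sum((A - B)^2)
  (pi / p)^1.5 * exp(-a * b / p * ab2)
}

oracle_kinetic_ss <- function(a, A, b, B) {
  p <- a + b; mu <- a * b / p
  ab2 <- sum((A - B)^2)
  mu * (3 - 2 * mu * ab2) * oracle_overlap_ss(a, A, b, B)
}

oracle_nuclear_ss <- function(a, A, b, B, Z, C) {
  p <- a + b
  P <- (a * A + b * B) / p
  ab2 <- sum((A - B)^2)
  -Z * 2 * pi / p * exp(-a * b / p * ab2) * oracle_F0(p * sum((P - C)^2))
}

oracle_eri_ssss <- function(a, A, b, B, c, C, d, D) {
  p <- a + b; q <- c + d
  P <- (a * A + b * B) / p
  Q <- (c * C + d * D) / q
  ab2 <- sum((A - B)^2); cd2 <- sum((C - D)^2)
  pref <- 2 * pi^2.5 / (p * q * sqrt(p + q))
  pref * exp(-a * b / p * ab2 - c * d / q * cd2) *
    oracle_F0(p * q / (p + q) * sum((P - Q)^2))
}

# a p_x-type primitive is the derivative of an s primitive with respect to
# its center: p_x(r; a, A) = (1/(2a)) d/dA_x s(r; a, A).  Central finite
# differences over the closed forms above therefore give independent
# p-function integrals.
oracle_px_via_fd <- function(f, a, A, h = 1e-5) {
  (f(A + c(h, 0, 0)) - f(A - c(h, 0, 0))) / (2 * h) / (2 * a)
}

# ---- direct access to the compiled integral engine -------------------------

# build integrals for explicit shells (exponents unnormalized single
# primitives, coords in bohr) and return S, T, V, eri accessor
engine_integrals <- function(zs, coords_bohr, shell_l, shell_atom, exps) {
  ints <- polytag:::.integrals_cpp(
    as.integer(zs), coords_bohr, as.integer(shell_l),
    as.integer(shell_atom),
    lapply(exps, identity), lapply(exps, function(e) rep(1, length(e))))
  ints
}

eri_at <- function(ints, i, j, k, l) {
  pidx <- function(a, b) {
    a <- a - 1; b <- b - 1
    if (a >= b) a * (a + 1) / 2 + b else b * (b + 1) / 2 + a
  }
  ints$eri[pidx(pidx(i, j) + 1, pidx(k, l) + 1) + 1]
}

# normalization constants the engine applies to its basis functions
norm_s <- function(a) (2 * a / pi)^0.75
norm_p <- function(a) (2 * a / pi)^0.75 * 2 * sqrt(a)

# ---- Hueckel chain model ---------------------------------------------------

# pi-orbital coefficients of a linear conjugated chain; returns the HOMO
# weight per site for n_electrons = n_sites (half filling)
hueckel_homo_weights <- function(n_sites) {
  H <- matrix(0, n_sites, n_sites)
  for (i in seq_len(n_sites - 1)) H[i, i + 1] <- H[i + 1, i] <- -1
  es <- eigen(H, symmetric = TRUE)
  homo <- order(es$values)[n_sites / 2]
  es$vectors[, homo]^2
}

# ---- misc ------------------------------------------------------------------

write_temp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}

fixture_records <- function(names = NULL) {
  fx <- builtin_fixtures()
  if (!is.null(names)) fx <- fx[fx$polymer_name %in% names, ]
  data.frame(polymer_name = fx$polymer_name, raw_smiles = fx$smiles,
             stringsAsFactors = FALSE)
}
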