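# Quantum-chemical reactivity: 3D embedding, restricted Hartree-Fock, and
# the per-atom nucleophilicity index.
#
# The nucleophilicity of atom X is the Mulliken population the HOMO places
# on X divided by (1 - e_HOMO), with the orbital energy in hartree:
#
#     R_X = p_X / (1 - e_HOMO),   p_X = sum_{a in X} sum_b C_{a,n} S_ab C_{b,n}
#
# The denominator is atom-independent, so the R_X ranking always equals the
# p_X ranking; the index is kept on the familiar scale nonetheless.  A
# literal |C|^2 mode (no overlap weighting) is available for comparison.

BOHR_PER_ANGSTROM <- 1 / 0.52917721092

#' Embed a molecule in 3D
#'
#' Hydrogens are added, one conformer is generated with seeded
#' distance-geometry embedding, and the geometry is relaxed with the
#' Universal Force Field (default cap 5000 steps).  Deterministic for a
#' fixed seed.  Only neutral closed-shell species are accepted (the SCF
#' backend is spin-restricted).
#'
#' @param smiles Single-component SMILES.
#' @param seed Integer conformer seed (default 42).
#' @param max_iters Force-field step cap.
#' @return Object of class `polytag_structure`: `atom_symbols`,
#'   `coordinates` (N x 3 matrix, Angstrom), `heavy_indices` (0-based
#'   indices into the canonical heavy-atom order), `canonical_smiles`,
#'   `total_charge`, `spin_multiplicity`, `embed_seed`.
#' @export
embed_3d <- function(smiles, seed = 42L, max_iters = 5000L) {
  info <- mol_info(smiles)
  if (info$net_charge != 0L) {
    stop("unsupported species (net charge ", info$net_charge,
         "): the restricted SCF backend handles neutral molecules only",
         call. = FALSE)
  }
  if (info$n_radical_electrons > 0L || info$n_electrons %% 2L != 0L) {
    stop("unsupported species (open shell): odd electron count or radical",
         call. = FALSE)
  }
  key <- cache_key("embed", info$canonical_smiles, seed, max_iters)
  res <- bridge_cached(key, list(op = "embed", smiles = info$canonical_smiles,
                                 seed = as.integer(seed),
                                 max_iters = as.integer(max_iters)))
  if (!isTRUE(res$ok)) stop("embedding failed: ", res$error, call. = FALSE)
  coords <- do.call(rbind, lapply(res$coordinates, as.numeric))
  symbols <- unlist(res$symbols)
  if (!all(is.finite(coords))) stop("embedding produced non-finite coordinates",
                                    call. = FALSE)
  dmin <- min(stats::dist(coords))
  if (dmin < 0.5) stop("embedding produced overlapping atoms (min distance ",
                       round(dmin, 3), " Angstrom)", call. = FALSE)
  structure(list(
    atom_symbols = symbols,
    coordinates = coords,
    heavy_indices = as.integer(unlist(res$heavy_indices)),
    canonical_smiles = res$canonical_smiles,
    total_charge = 0L,
    spin_multiplicity = 1L,
    embed_seed = as.integer(seed)
  ), class = "polytag_structure")
}

#' Write a structure as an XYZ file
#' @param structure `polytag_structure` from [embed_3d()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(structure, path) {
  n <- length(structure$atom_symbols)
  lines <- c(as.character(n), structure$canonical_smiles,
             sprintf("%-2s %14.8f %14.8f %14.8f", structure$atom_symbols,
                     structure$coordinates[, 1], structure$coordinates[, 2],
                     structure$coordinates[, 3]))
  writeLines(lines, path)
  invisible(path)
}

build_shell_spec <- function(symbols, basis) {
  shell_l <- integer(); shell_atom <- integer()
  shell_exps <- list(); shell_coefs <- list()
  for (i in seq_along(symbols)) {
    for (sh in basis_shells(symbols[i], basis)) {
      shell_l <- c(shell_l, sh$l)
      shell_atom <- c(shell_atom, i)
      shell_exps <- c(shell_exps, list(sh$exps))
      shell_coefs <- c(shell_coefs, list(sh$coefs))
    }
  }
  list(l = shell_l, atom = shell_atom, exps = shell_exps, coefs = shell_coefs)
}

#' Run a restricted Hartree-Fock calculation
#'
#' In-process SCF: McMurchie-Davidson integrals (compiled), symmetric
#' orthogonalization, DIIS-accelerated iterations, with one damped retry on
#' non-convergence.
#'
#' @param structure `polytag_structure` from [embed_3d()], or a list with
#'   `atom_symbols` and `coordinates` (Angstrom) for ad-hoc geometries.
#' @param basis "STO-3G" (default) or "6-31G*".
#' @param method Only "RHF" is implemented; other values error.
#' @param conv_tol Convergence threshold on the DIIS error norm.
#' @param max_iter SCF iteration cap per attempt.
#' @return Object of class `polytag_wfn`: MO coefficient matrix `C`
#'   (AO x MO), AO overlap `S`, `orbital_energies` (hartree, ascending),
#'   `homo_index` (1-based), `ao_to_atom` (1-based atom index per AO),
#'   `n_electrons`, `energy` (total, hartree), `converged`, plus the inputs.
#' @export
run_rhf <- function(structure, basis = "STO-3G", method = "RHF",
                    conv_tol = 1e-7, max_iter = 150L) {
  if (toupper(method) != "RHF") {
    stop("method ", method, " is not implemented; only RHF is supported",
         call. = FALSE)
  }
  symbols <- structure$atom_symbols
  z <- ELEMENT_Z[symbols]
  if (anyNA(z)) {
    stop("unsupported element(s): ",
         paste(unique(symbols[is.na(z)]), collapse = ", "), call. = FALSE)
  }
  n_el <- sum(z)
  if (n_el %% 2L != 0L) stop("odd electron count; RHF requires closed shell",
                             call. = FALSE)
  spec <- build_shell_spec(symbols, basis)
  ints <- .integrals_cpp(as.integer(z),
                         structure$coordinates * BOHR_PER_ANGSTROM,
                         as.integer(spec$l), as.integer(spec$atom),
                         spec$exps, spec$coefs)
  scf <- scf_solve(ints, n_el, conv_tol = conv_tol, max_iter = max_iter)
  if (!scf$converged) {
    scf <- scf_solve(ints, n_el, conv_tol = conv_tol,
                     max_iter = 4L * max_iter, damping = 0.5)
  }
  if (!scf$converged) stop("SCF failed to converge", call. = FALSE)
  structure(list(
    C = scf$C, S = ints$S, orbital_energies = scf$eps,
    homo_index = n_el %/% 2L,
    ao_to_atom = as.integer(ints$bf_atom),
    n_electrons = n_el, energy = scf$energy,
    converged = TRUE, basis = basis, method = "RHF",
    atom_symbols = symbols, n_basis = ints$n_basis
  ), class = "polytag_wfn")
}

# core SCF loop; `ints` is the list returned by .integrals_cpp
scf_solve <- function(ints, n_el, conv_tol = 1e-7, max_iter = 150L,
                      damping = 0, diis_max = 8L) {
  S <- ints$S; H <- ints$T + ints$V
  n <- ints$n_basis; nocc <- n_el %/% 2L
  es <- eigen(S, symmetric = TRUE)
  keep <- es$values > 1e-8
  X <- es$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(es$values[keep]), sum(keep))
  solve_fock <- function(F) {
    Ft <- crossprod(X, F %*% X)
    ef <- eigen((Ft + t(Ft)) / 2, symmetric = TRUE)
    ord <- order(ef$values)
    C <- X %*% ef$vectors[, ord, drop = FALSE]
    list(C = C, eps = ef$values[ord])
  }
  mo <- solve_fock(H)
  D <- 2 * tcrossprod(mo$C[, seq_len(nocc), drop = FALSE])
  e_old <- Inf
  fock_list <- list(); err_list <- list()
  for (it in seq_len(max_iter)) {
    G <- .fock_g_cpp(D, ints$eri, n)
    fmat <- H + G
    # E = 1/2 tr[D (H + F)] + E_nuc for the density G was built from
    energy <- 0.5 * sum(D * (2 * H + G)) + ints$e_nuc
    err <- fmat %*% D %*% S - S %*% D %*% fmat
    err <- crossprod(X, err %*% X)   # orthonormal-basis DIIS error
    fock_list <- c(fock_list, list(fmat))
    err_list <- c(err_list, list(err))
    if (length(fock_list) > diis_max) {
      fock_list <- fock_list[-1]; err_list <- err_list[-1]
    }
    m <- length(fock_list)
    if (m > 1L) {
      B <- matrix(0, m + 1L, m + 1L)
      for (a in seq_len(m)) for (b in seq_len(m)) {
        B[a, b] <- sum(err_list[[a]] * err_list[[b]])
      }
      B[m + 1L, seq_len(m)] <- B[seq_len(m), m + 1L] <- -1
      rhs <- c(rep(0, m), -1)
      w <- tryCatch(solve(B, rhs)[seq_len(m)], error = function(e) NULL)
      if (!is.null(w) && all(is.finite(w))) {
        fmat <- Reduce(`+`, Map(`*`, fock_list, w))
      }
    }
    mo <- solve_fock(fmat)
    D_new <- 2 * tcrossprod(mo$C[, seq_len(nocc), drop = FALSE])
    if (damping > 0) D_new <- (1 - damping) * D_new + damping * D
    de <- abs(energy - e_old)
    derr <- max(abs(err))
    D <- D_new; e_old <- energy
    if (derr < conv_tol && de < 1e-9) {
      return(list(converged = TRUE, C = mo$C, eps = mo$eps, energy = energy,
                  D = D, n_iter = it))
    }
  }
  list(converged = FALSE, C = mo$C, eps = mo$eps, energy = e_old, D = D,
       n_iter = max_iter)
}

#' Mulliken population of the HOMO, per atom
#'
#' Partitions the (normalized) HOMO density over atoms with the overlap
#' weighting of Mulliken analysis; populations sum to one.  With
#' `raw_coefficients = TRUE` the literal squared-coefficient sum is used
#' instead (no overlap weighting, no exact normalization).
#'
#' @param wfn `polytag_wfn` from [run_rhf()].
#' @param raw_coefficients Use plain `sum(C^2)` per atom.
#' @return Named numeric vector, one entry per atom (names = element symbol
#'   + 1-based atom number).
#' @export
homo_mulliken_populations <- function(wfn, raw_coefficients = FALSE) {
  c_h <- wfn$C[, wfn$homo_index]
  contrib <- if (raw_coefficients) c_h^2 else c_h * as.vector(wfn$S %*% c_h)
  n_atoms <- length(wfn$atom_symbols)
  out <- vapply(seq_len(n_atoms),
                function(a) sum(contrib[wfn$ao_to_atom == a]), numeric(1))
  names(out) <- paste0(wfn$atom_symbols, seq_len(n_atoms))
  out
}

#' Per-atom nucleophilicity profile
#'
#' @param wfn `polytag_wfn` from [run_rhf()].
#' @param raw_coefficients Passed to [homo_mulliken_populations()].
#' @return Object of class `polytag_profile`: `homo_population` (p_X),
#'   `nucleophilicity` (R_X), `ranking` (1-based atom indices, R_X
#'   descending, ties by lower index), `homo_energy` (hartree),
#'   `atom_symbols`.
#' @export
nucleophilicity_profile <- function(wfn, raw_coefficients = FALSE) {
  eps_homo <- wfn$orbital_energies[wfn$homo_index]
  if (eps_homo >= 1) {
    stop("HOMO energy ", round(eps_homo, 4), " hartree >= 1; ",
         "nucleophilicity denominator would be non-positive", call. = FALSE)
  }
  p <- homo_mulliken_populations(wfn, raw_coefficients = raw_coefficients)
  r <- p / (1 - eps_homo)
  ranking <- order(-r, seq_along(r))
  structure(list(
    homo_population = p, nucleophilicity = r, ranking = ranking,
    homo_energy = eps_homo, atom_symbols = wfn$atom_symbols
  ), class = "polytag_profile")
}

#' Full reactivity profile for a monomer SMILES
#'
#' Convenience wrapper: embed, run RHF, profile.  The returned profile
#' carries `heavy_indices` mapping canonical heavy-atom order (0-based, as
#' used by [mol_info()] matches) to positions in the profile vectors.
#'
#' @inheritParams embed_3d
#' @inheritParams run_rhf
#' @return `polytag_profile` with an extra `heavy_indices` element.
#' @export
reactivity_profile <- function(smiles, seed = 42L, basis = "STO-3G",
                               method = "RHF", max_iters = 5000L,
                               cache = TRUE) {
  key <- cache_key("profile", smiles, seed, basis, method, max_iters)
  if (cache) {
    hit <- .polytag$cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  st <- embed_3d(smiles, seed = seed, max_iters = max_iters)
  wfn <- run_rhf(st, basis = basis, method = method)
  prof <- nucleophilicity_profile(wfn)
  prof$heavy_indices <- st$heavy_indices
  prof$canonical_smiles <- st$canonical_smiles
  if (cache) assign(key, prof, envir = .polytag$cache)
  prof
}

# R_X value for a 0-based canonical heavy-atom index
profile_rx <- function(profile, heavy_idx0) {
  pos <- match(heavy_idx0, profile$heavy_indices)
  profile$nucleophilicity[pos]
}
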