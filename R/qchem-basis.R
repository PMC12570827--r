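# Gaussian basis-set data.
#
# STO-3G is generated from the published universal three-Gaussian
# least-squares fits to 1s and 2sp Slater orbitals, scaled per element by
# the standard molecular Slater exponents (alpha -> alpha * zeta^2) -- which
# is exactly how the tabulated STO-3G parameter lists are defined.  The fit
# constants are stored via the hydrogen (zeta = 1.24) and carbon
# (zeta_2sp = 1.72) reference values.
#
# 6-31G* is shipped for H, C, N and O only and is exercised far less than
# STO-3G; it is provided for method-sensitivity checks, not for the
# validated default protocol.

ELEMENT_Z <- c(H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8,
               F = 9, Ne = 10)

# standard molecular Slater exponents (1s; 2sp where applicable)
STO3G_ZETA <- list(
  H = 1.24, He = 1.69,
  Li = c(2.69, 0.80), Be = c(3.68, 1.15), B = c(4.68, 1.45),
  C = c(5.67, 1.72), N = c(6.67, 1.95), O = c(7.66, 2.25),
  F = c(8.65, 2.55), Ne = c(9.64, 2.88)
)

# universal fits (zeta = 1), recovered from the reference tabulations
STO3G_FIT <- list(
  s1 = list(
    exps = c(3.425250914, 0.6239137298, 0.1688554040) / 1.24^2,
    coefs = c(0.1543289673, 0.5353281423, 0.4446345422)
  ),
  sp2 = list(
    exps = c(2.941249355, 0.6834830964, 0.2222899159) / 1.72^2,
    coefs_s = c(-0.09996722919, 0.3995128261, 0.7001154689),
    coefs_p = c(0.1559162750, 0.6076837186, 0.3919573931)
  )
)

# 6-31G split-valence data plus a single d polarization shell (6-31G*)
BASIS_631GS <- list(
  H = list(
    list(l = 0, exps = c(18.7311370, 2.8253937, 0.6401217),
         coefs = c(0.03349460, 0.23472695, 0.81375733)),
    list(l = 0, exps = 0.1612778, coefs = 1.0)
  ),
  C = list(
    list(l = 0,
         exps = c(3047.5249, 457.36951, 103.94869, 29.210155, 9.2866630,
                  3.1639270),
         coefs = c(0.0018347, 0.0140373, 0.0688426, 0.2321844, 0.4679413,
                   0.3623120)),
    list(l = 0, exps = c(7.8682724, 1.8812885, 0.5442493),
         coefs = c(-0.1193324, -0.1608542, 1.1434564)),
    list(l = 1, exps = c(7.8682724, 1.8812885, 0.5442493),
         coefs = c(0.0689991, 0.3164240, 0.7443083)),
    list(l = 0, exps = 0.1687144, coefs = 1.0),
    list(l = 1, exps = 0.1687144, coefs = 1.0),
    list(l = 2, exps = 0.8, coefs = 1.0)
  ),
  N = list(
    list(l = 0,
         exps = c(4173.5110, 627.45790, 142.90210, 40.234330, 12.820210,
                  4.3904370),
         coefs = c(0.0018348, 0.0139950, 0.0685870, 0.2322410, 0.4690700,
                   0.3604550)),
    list(l = 0, exps = c(11.626358, 2.7162800, 0.7722180),
         coefs = c(-0.1149610, -0.1691180, 1.1458520)),
    list(l = 1, exps = c(11.626358, 2.7162800, 0.7722180),
         coefs = c(0.0675800, 0.3239070, 0.7408950)),
    list(l = 0, exps = 0.2120313, coefs = 1.0),
    list(l = 1, exps = 0.2120313, coefs = 1.0),
    list(l = 2, exps = 0.8, coefs = 1.0)
  ),
  O = list(
    list(l = 0,
         exps = c(5484.6717, 825.23495, 188.04696, 52.964500, 16.897570,
                  5.7996353),
         coefs = c(0.0018311, 0.0139501, 0.0684451, 0.2327143, 0.4701930,
                   0.3585209)),
    list(l = 0, exps = c(15.539616, 3.5999336, 1.0137618),
         coefs = c(-0.1107775, -0.1480263, 1.1307670)),
    list(l = 1, exps = c(15.539616, 3.5999336, 1.0137618),
         coefs = c(0.0708743, 0.3397528, 0.7271586)),
    list(l = 0, exps = 0.2700058, coefs = 1.0),
    list(l = 1, exps = 0.2700058, coefs = 1.0),
    list(l = 2, exps = 0.8, coefs = 1.0)
  )
)

sto3g_shells <- function(symbol) {
  zeta <- STO3G_ZETA[[symbol]]
  if (is.null(zeta)) {
    stop("element ", symbol, " not supported at STO-3G (available: ",
         paste(names(STO3G_ZETA), collapse = ", "), ")", call. = FALSE)
  }
  shells <- list(list(l = 0, exps = STO3G_FIT$s1$exps * zeta[1]^2,
                      coefs = STO3G_FIT$s1$coefs))
  if (length(zeta) > 1L) {
    sp_exps <- STO3G_FIT$sp2$exps * zeta[2]^2
    shells <- c(shells, list(
      list(l = 0, exps = sp_exps, coefs = STO3G_FIT$sp2$coefs_s),
      list(l = 1, exps = sp_exps, coefs = STO3G_FIT$sp2$coefs_p)
    ))
  }
  shells
}

#' Shells of a basis set for one element
#'
#' @param symbol Element symbol (e.g. "C").
#' @param basis "STO-3G" (default; H through Ne) or "6-31G*" (H, C, N, O).
#' @return List of shells, each `list(l, exps, coefs)`.
#' @export
basis_shells <- function(symbol, basis = "STO-3G") {
  basis <- toupper(basis)
  if (basis == "STO-3G") return(sto3g_shells(symbol))
  if (basis %in% c("6-31G*", "6-31G(D)")) {
    sh <- BASIS_631GS[[symbol]]
    if (is.null(sh)) {
      stop("element ", symbol, " not available in the shipped 6-31G* set ",
           "(available: ", paste(names(BASIS_631GS), collapse = ", "), ")",
           call. = FALSE)
    }
    return(sh)
  }
  stop("unsupported basis ", basis, " (use STO-3G or 6-31G*)", call. = FALSE)
}
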