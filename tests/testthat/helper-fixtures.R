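# shared fixtures and independent oracles

fix_globule_dimer <- function(seed = 3, n = 24, contacts = 12) {
  make_dimer(synthetic_dimer_spec(n, n, contacts, seed = seed))
}

fix_helix_dimer <- function(contacts = 15, n = 20, seed = 1) {
  make_dimer(synthetic_dimer_spec(n, n, contacts,
                                  geometry = "helix_pair", seed = seed))
}

# monomer from a bare coordinate matrix (test-only constructor)
monomer_from_coords <- function(coords, chain_id = "A", resid = "ALA") {
  n <- nrow(coords)
  dimerdyn:::new_monomer_structure(
    tibble::tibble(chain = chain_id, resno = seq_len(n),
                   resno_pdb = as.character(seq_len(n)), resid = resid,
                   x = coords[, 1], y = coords[, 2], z = coords[, 3]),
    chain_id = chain_id
  )
}

dimer_from_monomers <- function(A, B) {
  dimerdyn:::new_dimer_structure(A, B, atoms = NULL, metadata = list())
}

# C2-symmetric homodimer: chain B is chain A rotated by pi about z and
# shifted along x so the chains touch without clashing
c2_homodimer <- function(seed = 4, n = 20) {
  A <- make_monomer(n, "globule", seed = seed, chain_id = "A")
  cA <- ca_coords(A)
  Rz <- diag(c(-1, -1, 1))
  for (d in seq(30, 4, by = -0.25)) {
    cB <- cA %*% t(Rz)
    cB[, 1] <- cB[, 1] + d
    dmin <- min(as.matrix(pdist2(cA, cB)))
    ncon <- sum(pdist2(cA, cB) <= 7.5^2)
    if (dmin < 3.2^2) break
    if (ncon >= 6) {
      B <- monomer_from_coords(cB, "B")
      return(dimer_from_monomers(A, B))
    }
  }
  stop("could not build C2 homodimer fixture")
}

pdist2 <- function(X, Y) {
  outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * X %*% t(Y)
}

# random symmetric positive-definite matrix
rand_spd <- function(n) {
  A <- matrix(stats::rnorm(n * n), n)
  crossprod(A) + diag(n) * 0.5
}

# independent per-residue RMSF oracle: pseudo-inverse diagonal blocks
ginv_rmsf <- function(M) {
  Mp <- MASS::ginv(M)
  n <- nrow(M) / 3
  vapply(seq_len(n), function(i) {
    b <- (3 * i - 2):(3 * i)
    sqrt(sum(diag(Mp[b, b])))
  }, numeric(1))
}

# classic-format DSSP lines with states at the documented fixed columns
dssp_fixture_lines <- function(chain, resno, aa, ss) {
  hdr <- c(
    "==== Secondary Structure Definition by the program DSSP ====",
    "REFERENCE ...",
    paste0("  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    ",
           "O-->H-N    N-H-->O    O-->H-N    TCO  KAPPA ALPHA  PHI   PSI"))
  body <- vapply(seq_along(resno), function(i) {
    paste0(sprintf("%5d", i),
           if (aa[i] == "!") "      " else sprintf("%5d ", resno[i]),
           chain[i], " ", aa[i], "  ", ss[i], "   0.0")
  }, character(1))
  c(hdr, body)
}

helix_trace_pts <- function(n) {
  i <- seq_len(n) - 1
  th <- i * 100 * pi / 180
  cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * i)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
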