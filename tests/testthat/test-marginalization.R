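test_that("block partition is exact and reports uncoupled partners", {
  d <- fix_globule_dimer(seed = 3)
  net <- build_network(d)
  part <- partition_network(net, "A")
  re <- rbind(cbind(part$M_A, part$G), cbind(t(part$G), part$M_B))
  expect_identical(re, unname(net$stiffness))

  d0 <- make_dimer(synthetic_dimer_spec(16, 16, 0, seed = 2))
  net0 <- build_network(d0)
  part0 <- partition_network(net0, "A")
  expect_identical(max(abs(part0$G)), 0)
  expect_error(marginalize_partner(part0), "not coupled")

  expect_error(partition_network(net, "Q"), "unknown chain")
})

test_that("Schur complement equals the Gaussian marginalization oracle on
           random SPD matrices", {
  set.seed(42)
  for (rep in 1:50) {
    n <- sample(9:60, 1)
    nA <- sample(3:(n - 3), 1)
    M <- rand_spd(n)
    iA <- 1:nA; iB <- (nA + 1):n
    schur <- M[iA, iA] - M[iA, iB] %*% solve(M[iB, iB], M[iB, iA])
    # oracle: precision of the marginal = inverse of the covariance block
    cov_full <- solve(M)
    oracle <- solve(cov_full[iA, iA])
    expect_lt(max(abs(schur - oracle)) / max(abs(oracle)), 1e-10)
    # and the package path on the same partitioned matrix
    part <- structure(list(M_A = M[iA, iA], M_B = M[iB, iB],
                           G = M[iA, iB, drop = FALSE],
                           nodes_A = NULL, nodes_B = NULL,
                           first_chain_id = "A"),
                      class = "block_partition")
    eff <- marginalize_partner(part)
    expect_lt(max(abs(eff$stiffness - oracle)) / max(abs(oracle)), 1e-10)
  }
})

test_that("the effective network keeps exactly the six rigid motions of the
           retained monomer and only softens it", {
  d <- fix_globule_dimer(seed = 3)
  net <- build_network(d)
  part <- partition_network(net, "A")
  eff <- marginalize_partner(part)

  sp <- mode_spectrum(eff$stiffness)
  expect_identical(sp$n_zero, 6L)
  # null space spans rigid motions of monomer A
  coords <- ca_coords(d$first)
  nullv <- sp$vectors[, 1:6]
  rigid <- cbind(
    as.vector(t(matrix(rep(c(1, 0, 0), nrow(coords)), ncol = 3, byrow = TRUE))),
    as.vector(t(matrix(rep(c(0, 1, 0), nrow(coords)), ncol = 3, byrow = TRUE))),
    as.vector(t(matrix(rep(c(0, 0, 1), nrow(coords)), ncol = 3, byrow = TRUE))),
    as.vector(t(t(apply(coords, 1, function(r) cross3(c(1, 0, 0), r))))),
    as.vector(t(t(apply(coords, 1, function(r) cross3(c(0, 1, 0), r))))),
    as.vector(t(t(apply(coords, 1, function(r) cross3(c(0, 0, 1), r)))))
  )
  # each rigid vector is annihilated by the effective stiffness
  expect_lt(max(abs(eff$stiffness %*% rigid)) / max(sp$values), 1e-9)
  expect_identical(qr(cbind(nullv, rigid))$rank, 6L)

  # PSD, and M_A - M_A_eff PSD: integration can only soften
  evS <- eigen(eff$stiffness, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(evS), -1e-9 * max(evS))
  evD <- eigen(part$M_A - eff$stiffness, symmetric = TRUE,
               only.values = TRUE)$values
  expect_gt(min(evD), -1e-9 * max(abs(evD)))
})

test_that("bound mobility never exceeds unbound mobility, residue by
           residue", {
  fixtures <- list(fix_globule_dimer(seed = 3),
                   fix_globule_dimer(seed = 13, contacts = 18),
                   fix_helix_dimer(contacts = 12, seed = 2))
  for (d in fixtures) {
    pp <- bound_unbound_profiles(d)
    expect_true(all(pp$rmsf_bound <= pp$rmsf_unbound + 1e-9))
  }
})

test_that("the partner's influence is local: distant residues keep their
           unbound mobility", {
  # long helix contacting a short partner only near its top end
  Ac <- helix_trace_pts(60)
  Bc <- helix_trace_pts(10)
  Bc[, 1] <- Bc[, 1] + 7.2
  Bc[, 3] <- Bc[, 3] + 1.5 * 48
  A <- monomer_from_coords(Ac, "A")
  B <- monomer_from_coords(Bc, "B")
  d <- dimer_from_monomers(A, B)
  ic <- interchain_contacts(d, 7.5)
  expect_gte(nrow(ic), 3)

  pp <- bound_unbound_profiles(d)
  dmin <- apply(pdist2(Ac, Bc), 1, function(v) sqrt(min(v)))
  far <- dmin > 2 * 7.5
  expect_gte(sum(far), 10)
  rel <- abs(pp$rmsf_bound[far] - pp$rmsf_unbound[far]) /
    pp$rmsf_unbound[far]
  expect_lt(max(rel), 0.02)
})

test_that("in a symmetric homodimer the two subunit-frame bound profiles
           coincide", {
  d <- c2_homodimer(seed = 4)
  net <- build_network(d)

  bound_for <- function(chain_id) {
    part <- partition_network(net, chain_id)
    eff <- marginalize_partner(part)
    rmsf_profile(mode_spectrum(eff$stiffness), nodes = part$nodes_A,
                 frame = "subunit")
  }
  pa <- bound_for("A")
  pb <- bound_for("B")
  expect_lt(max(abs(pa$rmsf - pb$rmsf)), 1e-8)

  # complex frame: the two chains' profiles also coincide by symmetry
  sp <- mode_spectrum(net)
  prof <- rmsf_profile(sp, frame = "complex")
  expect_lt(max(abs(prof$rmsf[prof$chain == "A"] -
                      prof$rmsf[prof$chain == "B"])), 1e-8)
})

test_that("subunit-frame RMSF from the effective network matches the
           projected complex pseudo-inverse route", {
  d <- fix_globule_dimer(seed = 3)
  net <- build_network(d)
  part <- partition_network(net, "A")
  eff <- marginalize_partner(part)
  bound <- rmsf_profile(mode_spectrum(eff$stiffness), nodes = part$nodes_A)

  # independent route: pin chain A's rigid-body modes in the complex matrix
  # with an explicit projector penalty, invert the whole complex matrix,
  # take the chain-A covariance block, and project the penalty gauge back
  # out. For any penalty strength this reproduces the subunit-frame
  # covariance, i.e. the pseudo-inverse of the effective stiffness.
  nA <- nrow(part$nodes_A)
  nT <- nrow(net$nodes)
  iA <- 1:(3 * nA)
  coords <- ca_coords(d$first)
  rigid <- cbind(
    rep(c(1, 0, 0), nA), rep(c(0, 1, 0), nA), rep(c(0, 0, 1), nA),
    as.vector(apply(coords, 1, function(r) cross3(c(1, 0, 0), r))),
    as.vector(apply(coords, 1, function(r) cross3(c(0, 1, 0), r))),
    as.vector(apply(coords, 1, function(r) cross3(c(0, 0, 1), r)))
  )
  Q <- qr.Q(qr(rigid))
  P <- diag(3 * nA) - tcrossprod(Q)
  Rfull <- rbind(Q, matrix(0, 3 * (nT - nA), 6))
  cpen <- mean(diag(net$stiffness))
  C_aug <- solve(net$stiffness + cpen * tcrossprod(Rfull))
  C_sub <- P %*% C_aug[iA, iA] %*% P
  oracle <- vapply(seq_len(nA), function(i) {
    b <- (3 * i - 2):(3 * i)
    sqrt(sum(diag(C_sub[b, b])))
  }, numeric(1))
  expect_lt(max(abs(bound$rmsf - oracle) / oracle), 1e-6)
})
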