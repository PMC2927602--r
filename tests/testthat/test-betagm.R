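test_that("stiffness matrix is symmetric, PSD and annihilates rigid-body
           motions", {
  g <- make_monomer(24, "globule", seed = 6)
  M <- build_network(g)$stiffness
  expect_lt(max(abs(M - t(M))), 1e-12)

  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10 * max(ev))

  n <- nrow(g)
  coords <- ca_coords(g)
  # uniform translations
  for (ax in 1:3) {
    t_vec <- as.vector(t(matrix(rep(diag(3)[ax, ], n), ncol = 3,
                                byrow = TRUE)))
    expect_lt(max(abs(M %*% t_vec)), 1e-10 * max(ev))
  }
  # infinitesimal rotations about each axis
  for (ax in 1:3) {
    omega <- diag(3)[ax, ]
    rot <- t(apply(coords, 1, function(r) cross3(omega, r)))
    r_vec <- as.vector(t(rot))
    r_vec <- r_vec / sqrt(sum(r_vec^2))
    expect_lt(max(abs(M %*% r_vec)), 1e-9 * max(ev))
  }
})

test_that("residue coupling blocks follow the centroid contact graph
           (independent distance enumeration)", {
  m <- make_monomer(12, "helix")
  net <- build_network(m)
  M <- net$stiffness
  n <- nrow(m)
  coords <- ca_coords(m)

  # independent reconstruction of centroid positions and supports
  cent <- list()
  for (i in seq_len(n))
    cent[[length(cent) + 1]] <- list(pos = coords[i, ], support = i)
  for (i in 2:(n - 1)) {
    w <- 2 * coords[i, ] - coords[i - 1, ] - coords[i + 1, ]
    cent[[length(cent) + 1]] <-
      list(pos = coords[i, ] + 3 * w / sqrt(sum(w^2)),
           support = c(i - 1, i, i + 1))
  }
  # expected residue-block adjacency from all coupled centroid pairs
  expected <- diag(n) > 0
  for (a in seq_along(cent)) for (b in seq_along(cent)) {
    if (a >= b) next
    same_owner <- length(intersect(cent[[a]]$support, cent[[b]]$support)) ==
      max(length(cent[[a]]$support), length(cent[[b]]$support)) &&
      identical(cent[[a]]$support, cent[[b]]$support)
    d <- sqrt(sum((cent[[a]]$pos - cent[[b]]$pos)^2))
    owner_a <- if (length(cent[[a]]$support) == 1) cent[[a]]$support else
      cent[[a]]$support[2]
    owner_b <- if (length(cent[[b]]$support) == 1) cent[[b]]$support else
      cent[[b]]$support[2]
    bonded <- length(cent[[a]]$support) == 1 &&
      length(cent[[b]]$support) == 1 && abs(owner_a - owner_b) == 1
    if (owner_a != owner_b && (d <= 7.5 || bonded)) {
      for (i in cent[[a]]$support) for (j in cent[[b]]$support) {
        expected[i, j] <- TRUE; expected[j, i] <- TRUE
      }
    }
  }
  observed <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    bi <- (3 * i - 2):(3 * i); bj <- (3 * j - 2):(3 * j)
    observed[i, j] <- max(abs(M[bi, bj])) > 1e-10
  }
  expect_identical(observed, expected | diag(n) > 0)
})

test_that("well-separated chains produce a block-diagonal matrix with twelve
           zero modes", {
  A <- make_monomer(8, "helix", chain_id = "A")
  Bc <- helix_trace_pts(8); Bc[, 1] <- Bc[, 1] + 40
  B <- monomer_from_coords(Bc, "B")
  net <- build_network(dimer_from_monomers(A, B))
  M <- net$stiffness
  iA <- 1:(3 * 8); iB <- (3 * 8 + 1):(3 * 16)
  expect_identical(max(abs(M[iA, iB])), 0)
  expect_identical(mode_spectrum(net)$n_zero, 12L)
})

test_that("mode-sum RMSF equals the pseudo-inverse oracle and scales as
           1/sqrt(k)", {
  g <- make_monomer(26, "globule", seed = 8)
  net <- build_network(g)
  sp <- mode_spectrum(net)
  prof <- rmsf_profile(sp)
  oracle <- ginv_rmsf(net$stiffness)
  expect_lt(max(abs(prof$rmsf - oracle) / oracle), 1e-6)

  net4 <- build_network(g, enm_params(k = 4))
  prof4 <- rmsf_profile(mode_spectrum(net4))
  expect_equal(prof4$rmsf, prof$rmsf / 2, tolerance = 1e-10)
})

test_that("spectra and fluctuations are invariant under rigid-body moves of
           the input", {
  g <- make_monomer(22, "globule", seed = 10)
  sp <- mode_spectrum(build_network(g))
  prof <- rmsf_profile(sp)

  th <- 0.83
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- ca_coords(g) %*% t(R)
  g2 <- g
  g2$x <- xyz[, 1] + 11.2; g2$y <- xyz[, 2] - 4.5; g2$z <- xyz[, 3] + 0.7
  sp2 <- mode_spectrum(build_network(g2))
  expect_lt(max(abs(sp2$values - sp$values)) / max(sp$values), 1e-8)
  prof2 <- rmsf_profile(sp2)
  expect_lt(max(abs(prof2$rmsf - prof$rmsf) / prof$rmsf), 1e-6)
})

test_that("eigenvectors are orthonormal and removing a non-bonded contact
           never stiffens the structure", {
  g <- make_monomer(24, "globule", seed = 12)
  net <- build_network(g)
  sp <- mode_spectrum(net)
  VtV <- crossprod(sp$vectors)
  expect_lt(max(abs(VtV - diag(nrow(VtV)))), 1e-8)

  base_sum <- sum(rmsf_profile(sp)$rmsf^2)
  nb <- which(net$couplings$kind == "nonbonded")
  dropped <- 0
  for (p in utils::head(nb, 12)) {
    gg <- as.numeric(net$G[p, ])
    M2 <- net$stiffness - net$couplings$kappa[p] * tcrossprod(gg)
    sp2 <- mode_spectrum(M2)
    if (sp2$n_zero != 6) next   # contact removal disconnected something
    expect_gte(sum(rmsf_profile(sp2)$rmsf^2), base_sum - 1e-9)
    dropped <- dropped + 1
  }
  expect_gte(dropped, 5)
})
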