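sphere_atoms <- function(centers, radius = 1.9, resid = "GLY") {
  tibble::tibble(
    chain = "A", resno = seq_len(nrow(centers)), resid = resid,
    elety = "CA", elesy = "C",
    x = centers[, 1], y = centers[, 2], z = centers[, 3],
    radius = radius
  )
}

test_that("single-sphere and two-sphere limits match closed forms", {
  r <- 1.9
  one <- sphere_atoms(matrix(0, 1, 3), radius = r)
  a1 <- attr(compute_asa(one, n_points = 960), "total_asa")
  exact <- 4 * pi * (r + 1.4)^2
  expect_lt(abs(a1 - exact) / exact, 0.005)

  apart <- sphere_atoms(rbind(c(0, 0, 0), c(50, 0, 0)), radius = r)
  a2 <- attr(compute_asa(apart, n_points = 960), "total_asa")
  expect_lt(abs(a2 - 2 * exact) / (2 * exact), 0.005)

  merged <- sphere_atoms(rbind(c(0, 0, 0), c(0, 0, 0)), radius = r)
  a3 <- attr(compute_asa(merged, n_points = 960), "total_asa")
  expect_lt(abs(a3 - exact) / exact, 0.005)
})

test_that("a three-sphere arrangement agrees with high-density brute-force
           sampling", {
  centers <- rbind(c(0, 0, 0), c(3.1, 0.4, 0), c(1.4, 2.8, 0.9))
  atoms <- sphere_atoms(centers, radius = 1.8)
  coarse <- attr(compute_asa(atoms, n_points = 960), "total_asa")
  fine <- attr(compute_asa(atoms, n_points = 10000), "total_asa")
  expect_lt(abs(coarse - fine) / fine, 0.01)
})

test_that("results are stable under doubling of the sampling density", {
  d <- fix_globule_dimer(seed = 3)
  a1 <- compute_asa(d$atoms, n_points = 1920)
  a2 <- compute_asa(d$atoms, n_points = 3840)
  # exposed residues converge to 2%; near-buried ones carry sampling noise
  # on the order of a point weight, so compare totals there instead
  exposed <- a2$asa >= 25
  expect_gt(sum(exposed), 10)
  rel <- abs(a1$asa[exposed] - a2$asa[exposed]) / a2$asa[exposed]
  expect_lt(max(rel), 0.02)
  expect_lt(abs(attr(a1, "total_asa") - attr(a2, "total_asa")) /
              attr(a2, "total_asa"), 0.01)
})

test_that("interface area equals the summed per-residue ASA loss and
           vanishes without contact", {
  d <- fix_globule_dimer(seed = 3)
  ann <- dimer_accessibility(d, n_points = 480)
  expect_equal(attr(ann, "interface_area"), sum(ann$delta_asa),
               tolerance = 1e-9)
  expect_gt(attr(ann, "interface_area"), 0)

  d0 <- make_dimer(synthetic_dimer_spec(16, 16, 0, seed = 2))
  ann0 <- dimer_accessibility(d0, n_points = 480)
  expect_lt(attr(ann0, "interface_area"), 1e-6)
  expect_identical(attr(ann0, "interface_size"), 0L)
  expect_identical(unname(attr(ann0, "semi_interface_sizes")), c(0L, 0L))
})

test_that("surface classification follows the relative-accessibility
           threshold", {
  # one sphere fully caged by neighbors: buried at the 5% threshold
  phi <- seq(0, pi, length.out = 6)[2:5]
  theta <- seq(0, 2 * pi, length.out = 9)[-9]
  shell <- do.call(rbind, lapply(phi, function(p)
    t(vapply(theta, function(t)
      3.4 * c(sin(p) * cos(t), sin(p) * sin(t), cos(p)), numeric(3)))))
  shell <- rbind(shell, c(0, 0, 3.4), c(0, 0, -3.4))
  centers <- rbind(c(0, 0, 0), shell)
  atoms <- sphere_atoms(centers, radius = 1.9, resid = "ALA")
  rec <- compute_asa(atoms, n_points = 960)
  expect_lt(rec$rasa[rec$resno == 1], 5)
  expect_gt(max(rec$rasa), 5)
})

test_that("unknown elements fall back to a default radius with a warning
           and inconsistent records are rejected", {
  odd <- tibble::tibble(chain = "A", resno = 1, resid = "UNK",
                        elety = "XX", elesy = "XX", x = 0, y = 0, z = 0)
  expect_warning(compute_asa(odd), "default")

  d <- fix_globule_dimer(seed = 3)
  cplx <- compute_asa(d$atoms, n_points = 240)
  mA <- compute_asa(d$atoms[d$atoms$chain == "A", ], n_points = 240)
  mB_wrong <- compute_asa(d$atoms[d$atoms$chain == "B", ],
                          probe_radius = 2.0, n_points = 240)
  expect_error(classify_residues(cplx, list(mA, mB_wrong)),
               "probe")
})
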