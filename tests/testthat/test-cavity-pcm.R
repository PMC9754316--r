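# Cavity tessellation and the discretized IEF operators, validated against
# sphere geometry, the closed-surface sum rule, Gauss's law and the Born
# model.

single_sphere <- function(epsilon = 46.7, lev = 3) {
  g <- geometry("H", matrix(0, 1, 3))
  build_cavity(g, solvent_params(epsilon = epsilon, tess_level = lev))
}

test_that("tessellation reproduces sphere areas and the burial filter", {
  cav <- single_sphere(lev = 2)
  R <- cav$sphere_radii[1]
  expect_equal(sum(cav$areas), 4 * pi * R^2, tolerance = 0.005 * 4 * pi * R^2)
  expect_equal(rowSums(cav$normals^2), rep(1, cav$n_tess), tolerance = 1e-12)
  expect_true(all(cav$areas > 0))

  # two disjoint spheres: full area of both
  g2 <- molecule_fixture("h2", r = 6)
  cav2 <- build_cavity(g2, solvent_params(tess_level = 2))
  expect_equal(sum(cav2$areas), 2 * sum(cav$areas), tolerance = 1e-6)

  # overlapping spheres lose area; normals point away from owning centers
  g3 <- molecule_fixture("h2", r = 1.0)
  cav3 <- build_cavity(g3, solvent_params(tess_level = 2))
  expect_lt(sum(cav3$areas), 2 * sum(cav$areas))
  own <- cav3$sphere_centers[cav3$sphere_of, ]
  expect_true(all(rowSums((cav3$centers - own) * cav3$normals) > 0))
})

test_that("double-layer operator obeys the closed-surface sum rule", {
  cav <- single_sphere(lev = 3)
  sda <- build_SDA(cav)
  # exact by construction after the diagonal fix
  expect_equal(as.vector(sda$D %*% cav$areas),
               rep(-2 * pi, cav$n_tess), tolerance = 1e-10)
  # converging discretization before the fix
  Doff <- sda$D; diag(Doff) <- 0
  off <- as.vector(Doff %*% cav$areas)
  expect_true(all(abs(off + 2 * pi) < 0.05 * 2 * pi))
  # S positive definite
  expect_gt(min(eigen(sda$S, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("response matrix satisfies Gauss's law, the Born model and limits", {
  cav <- single_sphere(lev = 3)
  R <- cav$sphere_radii[1]
  sda <- build_SDA(cav)
  V <- 1 / sqrt(rowSums(cav$centers^2))  # unit point charge at center
  for (eps in c(46.7, 78.39)) {
    Q <- response_matrix(sda$S, sda$D, sda$A, eps)
    q <- apply_response(Q, V)
    expect_equal(sum(q), -(eps - 1) / eps, tolerance = 0.01 * (eps - 1) / eps)
    born <- -(1 - 1 / eps) / (2 * R)
    expect_equal(0.5 * sum(V * q), born, tolerance = 0.02 * abs(born))
    # response is symmetric negative semidefinite
    expect_equal(Q, t(Q), tolerance = 1e-14)
    expect_lt(max(eigen(Q, symmetric = TRUE, only.values = TRUE)$values), 1e-10)
  }
  # vacuum limit
  expect_equal(response_matrix(sda$S, sda$D, sda$A, 1),
               matrix(0, cav$n_tess, cav$n_tess))
  expect_lt(max(abs(response_matrix(sda$S, sda$D, sda$A, 1 + 1e-9))), 1e-8)
  # conductor limit recovers the full enclosed charge
  Qc <- response_matrix(sda$S, sda$D, sda$A, 1e6)
  expect_equal(sum(apply_response(Qc, V)), -1, tolerance = 0.01)
})

test_that("Born error decreases monotonically with tessellation level", {
  errs <- vapply(1:3, function(lev) {
    cav <- single_sphere(lev = lev)
    R <- cav$sphere_radii[1]
    sda <- build_SDA(cav)
    Q <- response_matrix(sda$S, sda$D, sda$A, 46.7)
    V <- 1 / sqrt(rowSums(cav$centers^2))
    born <- -(1 - 1 / 46.7) / (2 * R)
    abs(0.5 * sum(V * apply_response(Q, V)) - born)
  }, 0)
  expect_true(all(diff(errs) < 0) || all(errs < 1e-4 * 0.18))
})

test_that("apply_response is linear and checks dimensions", {
  cav <- single_sphere(lev = 1)
  sda <- build_SDA(cav)
  Q <- response_matrix(sda$S, sda$D, sda$A, 10)
  V <- rnorm(cav$n_tess)
  expect_equal(apply_response(Q, 0 * V), rep(0, cav$n_tess))
  expect_equal(apply_response(Q, 2 * V), 2 * apply_response(Q, V),
               tolerance = 1e-12)
  expect_error(apply_response(Q, V[-1]), "N_tess")
})

test_that("H3+ total apparent charge follows Gauss's law for +3 nuclei", {
  p <- h3plus_problem()
  v_N <- nuclear_potential(p$geometry, p$cavity$centers)
  q <- apply_response(p$Q, v_N)
  eps <- 46.7
  expect_equal(sum(q), -3 * (eps - 1) / eps, tolerance = 0.02 * 3)
  expect_true(all(v_N > 0))
})

test_that("cavity TSV export round-trips the tessera table", {
  cav <- single_sphere(lev = 1)
  f <- tempfile(fileext = ".tsv")
  write_cavity_tsv(cav, f)
  tab <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), cav$n_tess)
  expect_equal(tab$area, cav$areas, tolerance = 1e-12)
})
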