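test_that("geometric variability matches hand-evaluated configurations", {
  # singleton group
  pts <- rbind(c(0, 0), c(3, 0))
  expect_equal(unname(geometric_variability(dist(pts), c(1, 2))), c(0, 0))
  # two points at distance t: V = t^2 / 4
  t <- 2.5
  expect_equal(unname(geometric_variability(matrix(c(0, t, t, 0), 2), c(1, 1))),
               t^2 / 4)
  # equilateral triangle of side 1: V = 1/3
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  expect_equal(unname(geometric_variability(dist(tri), rep(1, 3))), 1 / 3,
               tolerance = 1e-12)
})

test_that("between-group squared distance matches centroid geometry", {
  # two singletons: delta^2 = squared distance
  pts <- rbind(c(0, 0), c(3, 4))
  g <- between_group_distances(dist(pts), c(1, 2))
  expect_equal(g$delta2[1, 2], 25)
  expect_equal(diag(g$delta2), c(0, 0), ignore_attr = TRUE)
  # coincident pairs with centroids at distance t: delta^2 = t^2
  t <- 1.7
  pts2 <- rbind(c(0, 0), c(0, 0), c(t, 0), c(t, 0))
  g2 <- between_group_distances(dist(pts2), c(1, 1, 2, 2))
  expect_equal(g2$delta2[1, 2], t^2, tolerance = 1e-12)
  # symmetry on a random partition
  set.seed(5)
  pts3 <- matrix(rnorm(30), 15, 2)
  g3 <- between_group_distances(dist(pts3), rep(1:3, each = 5))
  expect_equal(g3$delta2, t(g3$delta2))
})

test_that("proximity function recovers squared distances to group centres", {
  # probe coincides with a singleton
  pts <- rbind(c(1, 1), c(5, 5))
  v <- geometric_variability(dist(pts), c(1, 2))
  phi <- proximity(euclid_to(pts, c(1, 1)), c(1, 2), v)
  expect_equal(unname(phi[1]), 0)
  # probe at distance t from a singleton: phi^2 = t^2
  expect_equal(unname(phi[2]), 32)  # dist((1,1),(5,5))^2
  # probe equidistant (1) from a two-point group of side 1: 1 - 1/4 = 3/4
  seg <- rbind(c(0, 0), c(1, 0))
  v2 <- geometric_variability(dist(seg), c(1, 1))
  phi2 <- proximity(c(1, 1), c(1, 1), v2)
  expect_equal(unname(phi2), 0.75)
  expect_error(proximity(c(1, 1, 1), c(1, 2), v), "length")
})

test_that("the INCA statistic solves the constrained minimisation exactly", {
  # two singletons at (0,0), (2,0); probe (1,1): W = 1, alpha = (1/2, 1/2)
  pts <- rbind(c(0, 0), c(2, 0))
  st <- inca_w(dist(pts), euclid_to(pts, c(1, 1)), c(1, 2))
  expect_equal(st$W, 1, tolerance = 1e-12)
  expect_equal(unname(st$alpha), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(unname(st$U), c(1, 1), tolerance = 1e-12)
  # probe on the segment between the centres: W = 0
  st0 <- inca_w(dist(pts), euclid_to(pts, c(0.7, 0)), c(1, 2))
  expect_equal(st0$W, 0, tolerance = 1e-10)
  # weights always sum to one
  expect_equal(sum(st$alpha), 1, tolerance = 1e-10)
})

test_that("linear-system W agrees with brute-force minimisation on random instances", {
  set.seed(99)
  for (r in 1:220) {
    k <- sample(2:4, 1)
    cl <- make_clusters(matrix(rnorm(k * 3, sd = 2), k, 3), n_per = 3, sd = 0.5)
    probe <- rnorm(3, sd = 2)
    d <- as.matrix(dist(cl$points))
    geom <- between_group_distances(d, cl$labels)
    phi2 <- proximity(euclid_to(cl$points, probe), cl$labels, geom)
    st <- inca_statistic(phi2, geom)
    expect_equal(st$W, brute_force_w(phi2, geom$delta2), tolerance = 1e-6)
    expect_equal(unname(st$U), unname(phi2) - st$W)
  }
})

test_that("W is invariant to rigid motions and scales with the square of distances", {
  set.seed(123)
  cl <- make_clusters(rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0)), 4, sd = 0.5)
  probe <- c(1, 1, 3)
  d <- as.matrix(dist(cl$points))
  st <- inca_w(d, euclid_to(cl$points, probe), cl$labels)
  for (i in 1:5) {
    Q <- random_rotation(3)
    shift <- rnorm(3)
    ptsR <- sweep(cl$points %*% Q, 2, shift, "+")
    probeR <- drop(probe %*% Q) + shift
    stR <- inca_w(as.matrix(dist(ptsR)), euclid_to(ptsR, probeR), cl$labels)
    expect_equal(stR$W, st$W, tolerance = 1e-8 * max(1, st$W))
  }
  # c^2 scaling of V, Delta^2, phi^2, W and U
  cfac <- 3.7
  v <- geometric_variability(d, cl$labels)
  g <- between_group_distances(d, cl$labels)
  phi <- proximity(euclid_to(cl$points, probe), cl$labels, v)
  v_s <- geometric_variability(cfac * d, cl$labels)
  g_s <- between_group_distances(cfac * d, cl$labels)
  phi_s <- proximity(cfac * euclid_to(cl$points, probe), cl$labels, v_s)
  st_s <- inca_w(cfac * d, cfac * euclid_to(cl$points, probe), cl$labels)
  expect_equal(v_s, cfac^2 * v, tolerance = 1e-10)
  expect_equal(g_s$delta2, cfac^2 * g$delta2, tolerance = 1e-10)
  expect_equal(phi_s, cfac^2 * phi, tolerance = 1e-10)
  expect_equal(st_s$W, cfac^2 * st$W, tolerance = 1e-10)
  expect_equal(st_s$U, cfac^2 * st$U, tolerance = 1e-8)
})

test_that("W and U stay non-negative for Euclidean-embeddable distances", {
  set.seed(7)
  for (i in 1:25) {
    k <- sample(2:4, 1)
    cl <- make_clusters(matrix(rnorm(k * 5, sd = 3), k, 5), 3, sd = 1)
    probe <- rnorm(5, sd = 3)
    st <- inca_w(as.matrix(dist(cl$points)), euclid_to(cl$points, probe), cl$labels)
    expect_gte(st$W, 0)
    expect_true(all(st$U >= -1e-8 * max(1, st$W)))
  }
})

test_that("W vanishes when the cluster centres affinely span the space", {
  set.seed(17)
  # k singleton clusters spanning a (k-1)-simplex in k-1 dimensions: any
  # probe in that space lies in the affine hull of the centres
  for (k in 3:5) {
    centers <- matrix(rnorm(k * (k - 1), sd = 2), k, k - 1)
    probe <- rnorm(k - 1, sd = 2)
    st <- inca_w(as.matrix(dist(centers)), euclid_to(centers, probe), seq_len(k))
    expect_lt(abs(st$W), 1e-6)
  }
})

test_that("a single reference group degenerates to the proximity", {
  pts <- rbind(c(0, 0), c(1, 0))
  st <- inca_w(dist(pts), c(1, 1), c(1, 1))
  expect_equal(st$W, 0.75)
  expect_equal(st$U, 0, ignore_attr = TRUE)
})

test_that("allocation picks the smallest projection, ties to the lowest index", {
  expect_equal(unname(allocate(c(137.9698, 137.3148, 7.615953))), 3L)
  expect_equal(unname(allocate(c(1, 1))), 1L)
  expect_equal(unname(allocate(c(5, 2, 9))), 2L)
})
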