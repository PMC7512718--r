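test_that("row condition matches hand sums", {
  # isolated node passes whenever mu > 0
  iso <- spread_network(cbind(1L, 2L), n_nodes = 3L)
  par <- node_params(rep(0.2, 3), rep(0.9, 3), rep(0.9, 3))
  expect_true(row_condition(par, iso)$pass[3])
  expect_true(col_condition(par, iso)$pass[3])

  # path_2: node 1 sum = beta_1 * r_2 = 0.3 * 0.5 = 0.15 < mu_1 = 0.2
  p2 <- toy_network("path_2")
  parp <- node_params(mu = c(0.2, 0.5), beta = c(0.3, 0.9), r = c(0.2, 0.5))
  rc <- row_condition(parp, p2)
  expect_true(rc$pass[1])
  expect_equal(rc$margin[1], 0.2 - 0.15)

  # star_5 hub: 0.5 * (5 * 0.5) = 1.25 >= 0.5 -> fails
  star <- toy_network("star_5")
  pars <- node_params(rep(0.5, 6), rep(0.5, 6), rep(0.5, 6))
  rcs <- row_condition(pars, star)
  expect_false(rcs$pass[1])
  expect_equal(rcs$margin[1], 0.5 - 1.25)
  expect_true(all(rcs$pass[2:6])) # leaves: 0.5 * 0.5 = 0.25 < 0.5
})

test_that("column condition matches hand sums and coincides with row for symmetric params", {
  p2 <- toy_network("path_2")
  parp <- node_params(mu = c(0.2, 0.5), beta = c(0.9, 0.3), r = c(0.2, 0.5))
  cc <- col_condition(parp, p2)
  # node 1: r_1 * beta_2 = 0.2 * 0.3 = 0.06 < 0.2
  expect_true(cc$pass[1])
  expect_equal(cc$margin[1], 0.2 - 0.06)

  # beta_i = r_i = c for all i: both sums reduce to c * sum of neighbour c
  set.seed(13)
  for (k in 1:10) {
    n <- sample(5:15, 1)
    net <- random_net(n, 0.4)
    cvec <- runif(1, 0.1, 0.6)
    par <- node_params(runif(n, 0.2, 0.7), rep(cvec, n), rep(cvec, n))
    expect_equal(row_condition(par, net)$pass, col_condition(par, net)$pass)
    expect_equal(row_condition(par, net)$margin, col_condition(par, net)$margin)
  }
})

test_that("boundary equality counts as a violation", {
  # path_2 with beta_1 r_2 exactly equal to mu_1
  p2 <- toy_network("path_2")
  par <- node_params(mu = c(0.2, 0.5), beta = c(0.4, 0.3), r = c(0.2, 0.5))
  rc <- row_condition(par, p2) # 0.4 * 0.5 = 0.2 = mu_1
  expect_equal(rc$margin[1], 0)
  expect_false(rc$pass[1])
  expect_true(1L %in% select_controlled_nodes(par, p2, criterion = "row"))
})

test_that("spectral radius agrees with closed forms and dense eigensolver", {
  # beta = 0: matrix is diagonal, sigma = max(1 - mu)
  p2 <- toy_network("path_2")
  par0 <- node_params(c(0.3, 0.6), c(0, 0), c(0.5, 0.5))
  expect_equal(spectral_radius(par0, p2), 0.7, tolerance = 1e-9)

  # symmetric 2x2: eigenvalues (1 - mu) +/- m -> sigma = 0.5 + 0.2
  par <- node_params(c(0.5, 0.5), c(0.5, 0.5), c(0.4, 0.4))
  expect_equal(spectral_radius(par, p2), 0.7, tolerance = 1e-9)

  # random fixtures against base eigen() on the dense matrix
  set.seed(17)
  for (k in 1:20) {
    n <- sample(5:40, 1)
    net <- random_net(n, 0.3)
    parr <- random_params(n, 0, 1)
    dense <- diag(1 - parr$mu) + as.matrix(contact_slope_bound(parr, net))
    sigma_dense <- max(Mod(eigen(dense, only.values = TRUE)$values))
    expect_equal(spectral_radius(parr, net), sigma_dense, tolerance = 1e-6)
  }
})

test_that("Gerschgorin bound dominates the spectral radius", {
  p2 <- toy_network("path_2")
  par0 <- node_params(c(0.3, 0.6), c(0, 0), c(0.5, 0.5))
  expect_equal(gerschgorin_bound(par0, p2), 0.7) # diagonal case: exact

  par <- node_params(c(0.5, 0.5), c(0.5, 0.5), c(0.4, 0.4))
  expect_equal(gerschgorin_bound(par, p2), 0.7) # symmetric 2x2 attains it

  set.seed(19)
  for (k in 1:100) {
    net <- random_net(20, 0.3)
    parr <- random_params(20, 0, 1)
    dense <- diag(1 - parr$mu) + as.matrix(contact_slope_bound(parr, net))
    sigma <- max(Mod(eigen(dense, only.values = TRUE)$values))
    expect_gte(gerschgorin_bound(parr, net), sigma - 1e-8)
  }
})

test_that("all nodes passing the row condition forces sigma < 1", {
  set.seed(23)
  for (k in 1:20) {
    net <- random_net(15, 0.4)
    par <- certified_params(net, "row")
    expect_true(all(row_condition(par, net)$pass))
    expect_lt(spectral_radius(par, net), 1)
  }
})

test_that("linear bound trajectories decay geometrically and dominate the dynamics", {
  set.seed(29)
  net <- random_net(12, 0.4)
  par <- certified_params(net, "row")

  # zero start stays zero
  expect_true(all(linear_bound_trajectory(rep(0, 12), par, net) == 0))

  # sigma < 1: max-norm below 1e-6 within the geometric-decay step count
  sigma <- spectral_radius(par, net)
  expect_lt(sigma, 1)
  x0 <- rep(1, 12)
  n_needed <- ceiling(log(1e-6 / max(x0)) / log(sigma)) + 25L
  xt <- linear_bound_trajectory(x0, par, net, n_steps = n_needed)
  expect_lt(max(xt[nrow(xt), ]), 1e-6)

  # row mode dominates the nonlinear trajectory entrywise; the column
  # recursion controls the network average (one step ahead), which is the
  # inequality the column certificate rests on
  for (k in 1:50) {
    n <- sample(5:12, 1)
    netk <- random_net(n, 0.4)
    park <- random_params(n, 0, 1)
    p0 <- runif(n)
    tr <- simulate_spread(netk, park, p0, 30)
    xb <- linear_bound_trajectory(p0, park, netk, n_steps = 30, mode = "row")
    expect_true(all(tr$states <= xb + 1e-10))
    g <- 1 - park$mu +
      as.numeric(Matrix::colSums(contact_slope_bound(park, netk)))
    for (s in 1:30) {
      expect_lte(mean(tr$states[s + 1, ]), mean(g * tr$states[s, ]) + 1e-10)
    }
  }
})

test_that("selected violators are exactly the failing nodes and their removal certifies the rest", {
  star <- toy_network("star_5")
  pars <- node_params(rep(0.5, 6), rep(0.5, 6), rep(0.5, 6))
  expect_equal(select_controlled_nodes(pars, star, criterion = "row"), 1L)

  # all nodes passing -> empty set
  net <- local({ set.seed(37); random_net(10, 0.4) })
  par_ok <- local({ set.seed(38); certified_params(net, "col") })
  expect_length(select_controlled_nodes(par_ok, net, criterion = "col"), 0L)

  # zero-dynamics stability: unlinking the violators leaves a subnetwork on
  # which every remaining node passes, and simulation decays to zero
  set.seed(39)
  for (k in 1:20) {
    n <- sample(10:25, 1)
    netk <- random_net(n, 0.3)
    park <- random_params(n)
    for (criterion in c("row", "col")) {
      vc <- select_controlled_nodes(park, netk, criterion = criterion)
      keep <- setdiff(seq_len(n), vc)
      sub_edges <- netk$edges[netk$edges[, 1] %in% keep &
                                netk$edges[, 2] %in% keep, , drop = FALSE]
      subnet <- spread_network(sub_edges, n_nodes = n)
      cond <- if (criterion == "row") row_condition(park, subnet)
              else col_condition(park, subnet)
      expect_true(all(cond$pass[keep]))
      p0 <- runif(n); p0[vc] <- 0
      tr <- simulate_spread(subnet, park, p0, 400, record_states = FALSE)
      expect_lt(max(tr$p_final), 1e-6)
    }
  }
})

test_that("stability report bundles margins, violators and sigma; CSV export", {
  star <- toy_network("star_5")
  pars <- node_params(rep(0.5, 6), rep(0.5, 6), rep(0.5, 6))
  rep_ <- stability_report(pars, star)
  expect_equal(rep_$violators_row, 1L)
  expect_equal(rep_$violators_col, 1L)
  expect_equal(rep_$row_margin, row_condition(pars, star)$margin)
  expect_equal(rep_$spectral_radius, spectral_radius(pars, star),
               tolerance = 1e-9)

  path <- withr::local_tempfile(fileext = ".csv")
  write_stability_report(rep_, path)
  df <- read.csv(path)
  expect_equal(names(df),
               c("node", "row_margin", "col_margin",
                 "controlled_row", "controlled_col"))
  expect_equal(df$node, 0:5)
  expect_equal(df$controlled_row, c(1L, rep(0L, 5)))
})
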