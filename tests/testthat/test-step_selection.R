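# d_max, raster lookups, disc means, subsetting, and logistic selection fits.

test_that("max_step uses only single-interval steps", {
  tr <- make_traj(rbind(c(0, 0), c(100, 0), c(300, 0), c(800, 0)))
  expect_equal(max_step(tr), 500)

  tr2 <- make_traj(rbind(c(0, 0), c(250, 0)))
  expect_equal(max_step(tr2), 250)

  # an 8-h gap (invalid middle fix) must not contribute a 2-interval step
  tr3 <- make_traj(rbind(c(0, 0), c(0, 0), c(5000, 0), c(5100, 0)),
                   valid = c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(max_step(tr3), 100)

  tr4 <- make_traj(rbind(c(0, 0), c(0, 0), c(1, 1)),
                   valid = c(TRUE, FALSE, TRUE))
  expect_error(max_step(tr4), "no consecutive")
})

test_that("raster cell lookups agree with a nearest-center oracle", {
  set.seed(55)
  g <- ascii_grid(matrix(stats::rnorm(40 * 60), 40, 60),
                  xll = 1000, yll = 2000, cellsize = 30)
  # oracle: brute-force nearest cell center
  centers <- expand.grid(row = 1:40, col = 1:60)
  cx <- g$xll + (centers$col - 0.5) * 30
  cy <- g$yll + (40 - centers$row + 0.5) * 30
  pts_x <- stats::runif(1000, 1000, 1000 + 60 * 30)
  pts_y <- stats::runif(1000, 2000, 2000 + 40 * 30)
  got <- grid_value_at(g, pts_x, pts_y)
  want <- vapply(seq_len(1000), function(i) {
    k <- which.min((cx - pts_x[i])^2 + (cy - pts_y[i])^2)
    g$values[centers$row[k], centers$col[k]]
  }, numeric(1))
  expect_equal(got, want)
  # outside the grid -> NA
  expect_true(is.na(grid_value_at(g, 0, 0)))
})

test_that("disc means equal a brute-force all-cells scan exactly", {
  set.seed(77)
  g <- ascii_grid(matrix(stats::rnorm(50 * 50), 50, 50), cellsize = 30)
  g$values[sample(2500, 100)] <- NA   # nodata holes
  centers <- expand.grid(row = 1:50, col = 1:50)
  cx <- (centers$col - 0.5) * 30
  cy <- (50 - centers$row + 0.5) * 30
  for (k in 1:20) {
    px <- stats::runif(1, 100, 1400); py <- stats::runif(1, 100, 1400)
    r <- stats::runif(1, 40, 400)
    inside <- (cx - px)^2 + (cy - py)^2 <= r^2
    vals <- g$values[cbind(centers$row[inside], centers$col[inside])]
    vals <- vals[!is.na(vals)]
    expect_equal(grid_disc_mean(g, px, py, r), mean(vals))
  }
})

test_that("checkerboard disc mean sits at the value midpoint", {
  v <- outer(1:100, 1:100, function(i, j) ifelse((i + j) %% 2 == 0, 50, 100))
  g <- ascii_grid(v, cellsize = 30)
  expect_equal(grid_disc_mean(g, 1500, 1500, 600), 75, tolerance = 1)
})

test_that("a sub-cell disc falls back to the center cell", {
  g <- ascii_grid(matrix(1:9, 3, 3, byrow = TRUE), cellsize = 30)
  # point near a cell corner, radius smaller than half a cell
  got <- grid_disc_mean(g, 31, 31, 5)
  expect_equal(got, grid_value_at(g, 31, 31))
})

test_that("ASCII grid round-trips through disk", {
  g <- ascii_grid(matrix(stats::rnorm(12), 3, 4), xll = 10, yll = 20,
                  cellsize = 30)
  g$values[2, 2] <- NA
  p <- tempfile(fileext = ".asc")
  write_ascii_grid(g, p, digits = 10)
  g2 <- read_ascii_grid(p)
  expect_equal(g2$values, g$values, tolerance = 1e-8)
  expect_equal(c(g2$xll, g2$yll, g2$cellsize), c(10, 20, 30))
})

test_that("pairs are built from valid consecutive fixes and skip raster gaps", {
  sim <- simulate_forager(sim_config(seed = 14, duration_days = 30))
  tr <- sim$trajectory
  rng <- range(c(tr$x, tr$y), na.rm = TRUE)
  g <- simulate_raster(99, extent = c(rng[1] - 500, rng[2] + 500,
                                      rng[1] - 500, rng[2] + 500))
  run <- run_pii(tr, window = 15)
  pairs <- build_pairs(tr, g, run$labels$behavior, run$labels$circadian)
  expect_gt(nrow(pairs), 0)
  expect_true(all(is.finite(pairs$used_value) & is.finite(pairs$avail_mean)))
  # no pair where the previous fix was missed
  prev_valid <- tr$valid[match(pairs$seq, tr$seq) - 1L]
  expect_true(all(prev_valid))
  expect_equal(attr(pairs, "d_max"), max_step(tr))
})

test_that("the 3x3 partition is exhaustive, disjoint, and flags empties", {
  grid <- expand.grid(circadian = c("nocturnal", "crepuscular", "diurnal"),
                      behavior = c("directed", "search", "cache"),
                      stringsAsFactors = FALSE)
  pairs <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
    data.frame(animal_id = "A", seq = i, used_value = 1, avail_mean = 1,
               circadian = grid$circadian[i], behavior = grid$behavior[i])))
  pairs <- pairs[rep(seq_len(9), each = 10), ]
  subs <- partition_subsets(pairs)
  expect_length(subs, 9L)
  expect_true(all(vapply(subs, nrow, integer(1)) == 10L))
  expect_length(attr(subs, "empty"), 0L)

  no_dd <- pairs[!(pairs$circadian == "diurnal" & pairs$behavior == "directed"), ]
  subs2 <- partition_subsets(no_dd)
  expect_equal(attr(subs2, "empty"), "diurnal.directed")
  expect_equal(sum(vapply(subs2, nrow, integer(1))), nrow(no_dd))
})

test_that("no contrast gives beta ~ 0; degenerate subsets are flagged", {
  set.seed(3)
  v <- stats::rnorm(100, 83, 2)
  same <- data.frame(animal_id = "A", seq = 1:100, used_value = v,
                     avail_mean = v, circadian = "diurnal",
                     behavior = "search")
  f <- fit_selection(same, subset_id = "diurnal.search")
  expect_true(f$converged)
  expect_lt(abs(f$beta), 1e-6)
  expect_equal(f$n_pairs, 100L)

  # constant covariate -> no-contrast note
  const <- same; const$used_value <- 83; const$avail_mean <- 83
  fc <- fit_selection(const)
  expect_false(fc$converged)
  expect_match(fc$note, "no contrast")

  # perfectly separated toy subset
  sep <- data.frame(animal_id = "A", seq = 1:30,
                    used_value = stats::rnorm(30, 100, 1),
                    avail_mean = stats::rnorm(30, 0, 1),
                    circadian = "nocturnal", behavior = "cache")
  fs <- fit_selection(sep)
  expect_false(fs$converged)
  expect_true(fs$separation || grepl("separation", fs$note))

  # below the minimum subset size
  ft <- fit_selection(same[1:10, ])
  expect_false(ft$converged)
  expect_match(ft$note, "< 20")
})

test_that("known selection strength is recovered from simulated pairs", {
  pairs <- simulate_selection_pairs(500, beta = 1, seed = 42)
  f <- fit_selection(pairs)
  expect_true(f$converged)
  expect_true(abs(f$beta - 1) < 3 * f$se)
})

test_that("the nonstationarity report orders betas and flags insufficiency", {
  res <- data.frame(
    subset = c("nocturnal.cache", "diurnal.search", "diurnal.directed"),
    circadian = c("nocturnal", "diurnal", "diurnal"),
    behavior = c("cache", "search", "directed"),
    beta = c(1.2, -0.8, NA), se = c(0.1, 0.1, NA),
    n_pairs = c(100L, 100L, 5L),
    converged = c(TRUE, TRUE, FALSE), note = "",
    stringsAsFactors = FALSE)
  class(res) <- c("selection_results", "data.frame")
  rep_ <- nonstationarity_report(res)
  expect_equal(rep_$subset, c("nocturnal.cache", "diurnal.search"))
  expect_true(all(diff(rep_$beta) <= 0))
  expect_null(attr(rep_, "message"))

  rep1 <- nonstationarity_report(res[1, ])
  expect_match(attr(rep1, "message"), "1 estimable")
})

test_that("constructed opposing selection is ordered correctly across subsets", {
  # positive selection at night in the cache state, negative by day while
  # searching -- built directly into the pair covariates
  p_pos <- simulate_selection_pairs(200, beta = 1.5, seed = 8)
  p_neg <- simulate_selection_pairs(200, beta = -1.5, seed = 9)
  p_neg$circadian <- "diurnal"; p_neg$behavior <- "search"
  res <- fit_selection_all(rbind(p_pos, p_neg))
  rep_ <- nonstationarity_report(res)
  expect_equal(rep_$subset[1], "nocturnal.cache")
  expect_equal(rep_$subset[nrow(rep_)], "diurnal.search")
  expect_lt(rep_$ci_hi[nrow(rep_)], rep_$ci_lo[1])
})
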