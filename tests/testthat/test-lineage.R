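mk_lineage_ts <- function() {
  # root divides at 47.3 h; daughter a divides at 55.8 h; all others censored
  dt <- 10
  h <- 60
  pts <- dplyr::bind_rows(
    tibble::tibble(cell_id = "r", frame = 0:283, t_min = (0:283) * dt,
                   x_um = 0, y_um = 0, z_um = 0, myog = "negative"),
    tibble::tibble(cell_id = "a", frame = 283:334, t_min = (283:334) * dt,
                   x_um = 1, y_um = 0, z_um = 0, myog = "negative"),
    tibble::tibble(cell_id = "b", frame = 283:432, t_min = (283:432) * dt,
                   x_um = -1, y_um = 0, z_um = 0, myog = "negative"),
    tibble::tibble(cell_id = "aa", frame = 334:432, t_min = (334:432) * dt,
                   x_um = 2, y_um = 0, z_um = 0, myog = "positive"),
    tibble::tibble(cell_id = "ab", frame = 334:432, t_min = (334:432) * dt,
                   x_um = 3, y_um = 0, z_um = 0, myog = "negative"))
  lin <- tibble::tibble(
    cell_id = c("r", "a", "b", "aa", "ab"),
    parent_id = c(NA, "r", "r", "a", "a"),
    birth_t = c(0, 47.3, 47.3, 55.8, 55.8) * h,
    end_t = c(47.3 * h, 55.8 * h, 4320, 4320, 4320),
    end_reason = c("division", "division", "censored", "censored",
                   "censored"),
    fate = c("negative", "negative", "negative", "positive", "negative"))
  track_set(pts, lin, dt = dt)
}

test_that("cell-cycle durations split by generation", {
  ts <- mk_lineage_ts()
  d <- cell_cycle_durations(ts)
  expect_equal(d$duration_h[d$cell_id == "r"], 47.3, tolerance = 1e-3)
  expect_equal(d$duration_h[d$cell_id == "a"], 8.5, tolerance = 1e-2)
  expect_equal(d$generation[match(c("r", "a", "aa"), d$cell_id)],
               c(1L, 2L, 3L))
  expect_true(all(d$censored[d$cell_id %in% c("b", "aa", "ab")]))
  m <- mean_cycle_durations(d, min_window_h = 0)
  expect_equal(m$mean_h[m$generation_group == "1"], 47.3, tolerance = 1e-3)
  expect_equal(m$mean_h[m$generation_group == ">=2"], 8.5, tolerance = 1e-2)

  bad <- ts
  bad$lineage$end_t[1] <- -5
  expect_error(cell_cycle_durations(bad), "before birth")
})

test_that("division modes follow the daughters' fates", {
  expect_identical(classify_division("negative", "negative"), "SCDp")
  expect_identical(classify_division("positive", "positive"), "SCDd")
  expect_identical(classify_division("positive", "negative"), "ACD")
  expect_identical(classify_division("negative", "positive"), "ACD")
  expect_identical(classify_division("positive", "unknown"), "unclassified")
  expect_identical(
    classify_division(c("negative", "positive"), c("negative", "unknown")),
    c("SCDp", "unclassified"))
})

test_that("fate reading honours endpoint and live-reporter modes", {
  ts <- mk_lineage_ts()
  expect_identical(fate_at_classification(ts, "aa", "endpoint"), "positive")
  expect_identical(fate_at_classification(ts, "ab", "endpoint"), "negative")
  expect_identical(fate_at_classification(ts, "aa", "live"), "positive")

  # live mode: positivity appearing 9 h post-mitosis still counts
  dt <- 10
  pts <- tibble::tibble(cell_id = "x", frame = 0:100, t_min = (0:100) * dt,
                        x_um = 0, y_um = 0, z_um = 0,
                        myog = ifelse((0:100) * dt >= 9 * 60, "positive",
                                      "negative"))
  ts2 <- track_set(pts, dt = dt)
  expect_identical(fate_at_classification(ts2, "x", "live"), "positive")
  expect_identical(fate_at_classification(ts2, "x", "endpoint"), "positive")

  pts$myog <- "unknown"
  ts3 <- track_set(pts, dt = dt)
  expect_identical(fate_at_classification(ts3, "x", "live"), "unknown")
})

test_that("division orientation follows the fibre-contact rule", {
  expect_identical(division_orientation("contact", "contact"), "planar")
  expect_identical(division_orientation("contact", "no_contact"),
                   "perpendicular")
  expect_identical(division_orientation("no_contact", "contact"),
                   "perpendicular")
  expect_identical(division_orientation("unknown", "contact"),
                   "undetermined")
})

test_that("differentiation index counts fate-known survivors", {
  mk <- function(fates) {
    n <- length(fates)
    pts <- tibble::tibble(cell_id = paste0("c", seq_len(n)),
                          frame = 0L, t_min = 0, x_um = 0, y_um = 0,
                          z_um = 0)
    lin <- tibble::tibble(cell_id = paste0("c", seq_len(n)),
                          parent_id = NA_character_, birth_t = 0, end_t = 0,
                          end_reason = "censored", fate = fates)
    track_set(pts, lin, dt = 10)
  }
  expect_equal(differentiation_index(mk(rep("negative", 10)))$index, 0)
  di <- differentiation_index(mk(c(rep("positive", 3), "negative")))
  expect_equal(di$index, 0.75)
  di2 <- differentiation_index(mk(rep("unknown", 4)))
  expect_true(is.na(di2$index))
  expect_identical(attr(di2, "flag"), "no_fate_known")
})

test_that("proliferation index is the ratio of live cell counts", {
  ts <- mk_lineage_ts()
  # 1 founder -> 3 survivors at the endpoint
  expect_equal(proliferation_index(ts)$index, 3)

  single <- make_track(matrix(0, 5, 2))
  expect_equal(proliferation_index(single)$index, 1)

  # 3 synchronous divisions: 1 founder -> 8 cells
  dt <- 10
  cells <- list(list(id = "f", p = NA, b = 0, e = 100, r = "division"))
  k <- 0
  for (gen in 1:3) {
    prev <- Filter(function(c) c$e == 100 * gen & c$r == "division", cells)
    for (c0 in prev) for (j in 1:2) {
      k <- k + 1
      cells[[length(cells) + 1]] <- list(
        id = paste0(c0$id, "_", j, gen), p = c0$id, b = 100 * gen,
        e = if (gen < 3) 100 * (gen + 1) else 400,
        r = if (gen < 3) "division" else "censored")
    }
  }
  pts <- dplyr::bind_rows(lapply(cells, function(c)
    tibble::tibble(cell_id = c$id, frame = as.integer(c$b / dt):(c$e / dt),
                   t_min = seq(c$b, c$e, by = dt), x_um = 0, y_um = 0,
                   z_um = 0)))
  lin <- dplyr::bind_rows(lapply(cells, function(c)
    tibble::tibble(cell_id = c$id, parent_id = c$p, birth_t = c$b,
                   end_t = c$e, end_reason = c$r, fate = "unknown")))
  ts8 <- track_set(pts, lin, dt = dt)
  expect_equal(proliferation_index(ts8)$index, 8)
  expect_error(proliferation_index(ts8, t_ref_min = -50), "no cells alive")
})

test_that("proliferation of a fusion-free preset matches the branching
           expectation", {
  p <- wt_small(diff_index_target = 0.999)  # effectively no fusion
  sc <- simulate_lineages(p, 150, seed = 88)
  got <- proliferation_index(sc$tracks_true)$index
  # independent oracle: direct Monte-Carlo of the branching law
  set.seed(999)
  n_end <- replicate(3000, {
    q <- 1 - (p$p_modes[["SCDd"]] + p$p_modes[["ACD"]] / 2)
    total <- 1
    t_next <- c(rgamma(1, shape = (47.3 / 8)^2, rate = (47.3 / 8)^2 / 47.3))
    gen <- c(1)
    while (length(t_next)) {
      i <- which.min(t_next)
      if (t_next[i] > p$duration_h || gen[i] >= p$max_generation) {
        t_next <- t_next[-i]; gen <- gen[-i]; next
      }
      total <- total + 1
      kids <- rbinom(1, 2, q)    # negative daughters keep cycling
      born <- t_next[i]; g <- gen[i]
      t_next <- t_next[-i]; gen <- gen[-i]
      if (kids > 0) {
        sh <- (8.5 / 2)^2
        t_next <- c(t_next, born + rgamma(kids, shape = sh, rate = sh / 8.5))
        gen <- c(gen, rep(g + 1, kids))
      }
    }
    total
  })
  expect_lt(abs(got - mean(n_end)) / mean(n_end), 0.15)
})

test_that("shape metrics implement circularity and the myotube call", {
  r <- 5
  circle <- shape_metrics(pi * r^2, 2 * pi * r, 2 * r, 2 * r)
  expect_equal(circle$circularity, 1)
  expect_equal(circle$aspect_ratio, 1)
  expect_false(circle$is_myotube)

  a <- 4
  square <- shape_metrics(a^2, 4 * a, a * sqrt(2), a)
  expect_equal(square$circularity, pi / 4, tolerance = 1e-12)

  expect_true(shape_metrics(10, 20, 9, 3)$is_myotube)
  expect_false(shape_metrics(10, 20, 6, 3)$is_myotube)
  expect_error(shape_metrics(-1, 20, 9, 3), "positive")
  expect_error(shape_metrics(10, 20, 2, 3), "max_diameter")
})

test_that("MYOG onset and re-division summaries handle edge cases", {
  neg <- mk_lineage_ts()
  neg$points$myog <- "negative"
  neg$lineage$fate <- "negative"
  res <- myog_onset_and_redivision(neg)
  expect_length(res$onset_delays_h, 0L)
  expect_true(is.na(res$redivision$fraction) ||
                res$redivision$n_positive == 0)

  ts <- mk_lineage_ts()   # one positive daughter, never divides again
  res2 <- myog_onset_and_redivision(ts)
  expect_equal(res2$redivision$fraction, 0)
  expect_equal(res2$redivision$n_positive, 1L)
})

test_that("division-mode fractions sum to one and recover the preset", {
  sc <- simulate_lineages(muscle_preset("mdx", duration_h = 60), 120,
                          seed = 99)
  div <- division_records(sc$tracks_true, fate_mode = "endpoint")
  mf <- division_mode_fractions(div)
  expect_equal(sum(mf$fraction), 1, tolerance = 1e-12)
  n <- sum(mf$n)
  p_t <- muscle_preset("mdx")$p_modes
  for (m in c("ACD", "SCDd", "SCDp")) {
    se <- sqrt(p_t[[m]] * (1 - p_t[[m]]) / n)
    expect_lt(abs(mf$fraction[mf$mode == m] - p_t[[m]]), 3 * se + 0.02)
  }
  # classified modes match the generator's truth division by division
  truth <- sc$truth$divisions$mode[match(div$mother_id,
                                         sc$truth$divisions$mother_id)]
  expect_identical(div$mode, truth)
})

test_that("generation-1 and later durations recover the preset timing", {
  p <- wt_small()
  sc <- simulate_lineages(p, 80, seed = 101)
  m <- mean_cycle_durations(cell_cycle_durations(sc$tracks_true))
  g1 <- m[m$generation_group == "1", ]
  expect_lt(abs(g1$mean_h - p$activation_mean_h), 3 * g1$se_h + 0.1)
  g2 <- m[m$generation_group == ">=2", ]
  expect_lt(abs(g2$mean_h - p$cycle_mean_h), 3 * g2$se_h + 0.1)
})

test_that("slower cycling increases censoring", {
  fast <- simulate_lineages(wt_small(), 60, seed = 7)
  slow <- simulate_lineages(wt_small(cycle_mean_h = 20), 60, seed = 7)
  cens <- function(sc) {
    d <- cell_cycle_durations(sc$tracks_true)
    mean(d$censored[d$generation >= 2])
  }
  expect_gt(cens(slow), cens(fast))
})

test_that("orientation is independent of division mode in the generator", {
  pvals <- vapply(1:10, function(seed) {
    sc <- simulate_lineages(wt_small(), 60, seed = 200 + seed)
    div <- division_records(sc$tracks_true, fate_mode = "endpoint")
    keep <- div$orientation != "undetermined" & div$mode != "unclassified"
    suppressWarnings(
      stats::chisq.test(table(div$mode[keep], div$orientation[keep]))$p.value)
  }, numeric(1))
  expect_gte(sum(pvals > 0.01), 9L)
})
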