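test_that("distances: plane metric and minimum-image wrap-around", {
  expect_equal(tree_distance(0, 0, 3, 4), 5)
  expect_equal(tree_distance(1, 1, 119, 1, "euclidean"), 118)
  expect_equal(tree_distance(1, 1, 119, 1, "torus",
                             stand_width = 120, stand_height = 140), 2)
  expect_equal(tree_distance(5, 1, 5, 139, "torus",
                             stand_width = 120, stand_height = 140), 2)
})

test_that("fixed-radius search uses a closed boundary and allows isolation", {
  sm <- make_stand(make_trees(x = c(60, 60, 60, 60),
                              y = c(70, 74.9, 75, 75.1)))
  cmp <- find_competitors_radius("t001", sm, radius = 5, edge = "none")
  expect_setequal(cmp$tree_id, c("t002", "t003"))   # 4.9 in, 5.0 in, 5.1 out
  expect_equal(cmp$distance, c(4.9, 5.0))

  lone <- make_stand(make_trees(x = c(10, 100), y = c(10, 130)))
  expect_equal(nrow(find_competitors_radius("t001", lone, radius = 5,
                                            edge = "none")), 0)
  expect_equal(hegyi_index(10, numeric(0), numeric(0)), 0)
})

test_that("quadrant rule picks nearest per sector with substitution", {
  # subject centered; two trees in sector I, one each in II and III, none
  # in IV: expect the 1 m sector-I tree, the II and III trees, and the 2 m
  # sector-I tree substituted for the empty sector IV
  sm <- make_stand(make_trees(x = c(60, 61, 62, 60, 59),
                              y = c(70, 70, 70, 71, 70),
                              id = c("s", "q1near", "q1far", "q2", "q3")))
  cmp <- find_competitors_quadrant("s", sm, n = 4, edge = "none")
  expect_setequal(cmp$tree_id, c("q1near", "q2", "q3", "q1far"))
  expect_true(is.na(cmp$quadrant[cmp$tree_id == "q1far"]))
  expect_equal(cmp$distance[cmp$tree_id == "q1far"], 2)

  # equidistant neighbours: deterministic under the tree_id tie-break
  sm2 <- make_stand(make_trees(x = 60 + c(0, 1, 1, 1, -1),
                               y = 70 + c(0, 0.5, 0.5, -0.5, 0.5),
                               id = c("s", "b", "a", "c", "d")))
  pick1 <- find_competitors_quadrant("s", sm2, n = 4, edge = "none")
  pick2 <- find_competitors_quadrant("s", sm2, n = 4, edge = "none")
  expect_identical(pick1, pick2)
  # "a" beats "b" at the shared position in sector I
  expect_true("a" %in% pick1$tree_id[pick1$quadrant %in% 1])

  expect_error(find_competitors_quadrant("s", sm2[1:3, ], n = 4),
               "competitors")
})

test_that("Hegyi index evaluates its formula directly", {
  expect_equal(hegyi_index(10, 20, 4), 0.4)
  expect_equal(hegyi_index(10, c(10, 5), c(0, 4)), 1.1)
})

test_that("distance-independent plot indices match hand computations", {
  tr <- make_trees(x = c(5, 10, 15), y = c(5, 5, 5), dbh = c(10, 20, 30))
  sm <- make_stand(tr)
  all_rule <- function(t) rep(TRUE, nrow(t))
  expect_equal(plot_competition_index(sm, sm, "SD"), 60)
  expect_equal(plot_competition_index(sm, sm, "SRD",
                                      dominant_rule = all_rule), 3)
  one <- make_stand(make_trees(x = 5, y = 5, dbh = 20))
  expect_equal(plot_competition_index(one, one, "SBA"), pi * 0.1^2)
  expect_error(plot_competition_index(sm, sm, "XX"))
})

test_that("neighbour-search SHGR equals the brute-force double loop", {
  for (seed in 1:5) {
    sm <- random_stand(30, seed = seed)
    ci <- competition_indices(sm)
    for (k in seq_len(nrow(ci))) {
      expect_equal(ci$SHGR[k], shgr_plot_brute(sm, ci$plot_id[k]),
                   tolerance = 1e-10)
    }
  }
})

test_that("torus and explicit tiling agree for sub-half-stand radii", {
  sm <- random_stand(40, seed = 3)
  for (id in sm$tree_id) {
    a <- find_competitors_radius(id, sm, radius = 5, edge = "torus")
    b <- find_competitors_radius(id, sm, radius = 5, edge = "tiling")
    expect_equal(a$tree_id, b$tree_id)
    expect_equal(a$distance, b$distance, tolerance = 1e-12)
  }
})

test_that("index units: DBH rescaling acts as the formulas dictate", {
  sm <- random_stand(35, seed = 11)
  scaled <- sm
  scaled$dbh <- sm$dbh * 3
  ci <- competition_indices(sm)
  ci3 <- competition_indices(scaled)
  expect_equal(ci3$SRD, ci$SRD, tolerance = 1e-10)   # ratio structure
  expect_equal(ci3$SHGN, ci$SHGN, tolerance = 1e-10)
  expect_equal(ci3$SHGR, ci$SHGR, tolerance = 1e-10)
  expect_equal(ci3$SD, 3 * ci$SD)                    # linear
  expect_equal(ci3$SDD, 3 * ci$SDD)
  expect_equal(ci3$SBA, 9 * ci$SBA)                  # quadratic
})

test_that("Hegyi index is monotone in competitor size and proximity", {
  set.seed(4)
  for (i in 1:20) {
    dbh_s <- runif(1, 2, 30)
    dbh_c <- runif(3, 2, 30)
    dist <- runif(3, 0.5, 6)
    base <- hegyi_index(dbh_s, dbh_c, dist)
    bigger <- dbh_c + c(runif(1, 0.1, 5), 0, 0)
    closer <- pmax(dist - c(runif(1, 0, 0.4), 0, 0), 0)
    expect_gte(hegyi_index(dbh_s, bigger, dist), base)
    expect_gte(hegyi_index(dbh_s, dbh_c, closer), base)
  }
})

test_that("cyclic coordinate shifts on the torus leave SHGR unchanged", {
  sm <- random_stand(25, seed = 8)
  w <- attr(sm, "stand_width")
  h <- attr(sm, "stand_height")
  shifted <- sm
  shifted$x <- (sm$x + 13.7) %% w
  shifted$y <- (sm$y + 31.2) %% h
  for (id in sm$tree_id) {
    a <- find_competitors_radius(id, sm, radius = 5, edge = "torus")
    b <- find_competitors_radius(id, shifted, radius = 5, edge = "torus")
    expect_equal(hegyi_index(sm$dbh[sm$tree_id == id], a$dbh, a$distance),
                 hegyi_index(sm$dbh[sm$tree_id == id], b$dbh, b$distance),
                 tolerance = 1e-10)
  }
})
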