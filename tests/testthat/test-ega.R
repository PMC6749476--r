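# Twenty hand-labeled (reference, measured) pairs spanning every zone of
# both grids and both sides of the ISO band, derived by applying the
# published Clarke inequalities, the type-1 consensus-grid boundary
# polylines, and the ISO 15197:2013 rule by hand.
battery <- data.frame(
  pg  = c(100, 100, 100,  60,  50, 200, 200,  80, 150, 250,
          400,  55,  58, 130,  20,  20, 460,  90,  90, 350),
  cgm = c(100, 110, 130,  60, 200, 250, 170, 175,  20, 100,
           62,  65,  71, 205,  44,  80, 560, 104, 106, 350),
  clarke = c("A", "A", "B", "A", "E", "B", "A", "B", "C", "D",
             "E", "A", "D", "B", "A", "D", "B", "A", "A", "A"),
  parkes = c("A", "A", "B", "A", "D", "A", "A", "C", "C", "C",
             "D", "A", "A", "B", "A", "C", "A", "A", "A", "A"),
  iso = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
          FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE),
  stringsAsFactors = FALSE)

test_that("Clarke zones match the hand-labeled battery", {
  expect_equal(clarke_zone(battery$pg, battery$cgm), battery$clarke)
  expect_error(clarke_zone(-1, 100), "positive")
})

test_that("Parkes type-1 zones match the hand-labeled battery", {
  expect_equal(parkes_zone(battery$pg, battery$cgm), battery$parkes)
  expect_error(parkes_zone(100, 0), "positive")
  expect_error(parkes_zone(100, 100, grid = "type2"), "type 1")
  v <- parkes_vertices()
  expect_setequal(unique(v$boundary), c("AB", "BC", "CD", "DE"))
})

test_that("ISO 15197 band is +/-15 mg/dL below 100 and +/-15% at or above", {
  expect_true(iso_acceptable(90, 104))
  expect_false(iso_acceptable(90, 106))
  expect_true(iso_acceptable(200, 230))   # inclusive boundary
  expect_false(iso_acceptable(200, 231))
  expect_equal(iso_acceptable(battery$pg, battery$cgm), battery$iso)
})

test_that("both grids partition the plane and agree on the identity line", {
  g <- seq(20, 550, length.out = 120)
  grid <- expand.grid(pg = g, cgm = g)
  cz <- clarke_zone(grid$pg, grid$cgm)
  pz <- parkes_zone(grid$pg, grid$cgm)
  expect_true(all(cz %in% c("A", "B", "C", "D", "E")))
  expect_true(all(pz %in% c("A", "B", "C", "D", "E")))
  expect_true(all(clarke_zone(g, g) == "A"))
  expect_true(all(parkes_zone(g, g) == "A"))
  expect_true(all(iso_acceptable(g, g)))
  # type-1 consensus grid has no E below the identity line
  expect_false(any(pz[grid$cgm < grid$pg] == "E"))
})

test_that("zone severity is monotone when the reading moves away from the reference", {
  sev <- function(z) match(z, c("A", "B", "C", "D", "E"))
  for (pg in c(40, 58, 90, 150, 250, 400)) {
    up <- seq(pg, 550, length.out = 150)
    down <- seq(pg, 21, length.out = 150)
    for (fn in list(clarke_zone, parkes_zone)) {
      expect_true(all(diff(sev(fn(rep(pg, 150), up))) >= 0))
      expect_true(all(diff(sev(fn(rep(pg, 150), down))) >= 0))
    }
  }
})

test_that("ISO-acceptable pairs with reference >= 75 mg/dL are Clarke zone A", {
  g <- seq(75, 550, length.out = 200)
  grid <- expand.grid(pg = g, cgm = seq(20, 550, length.out = 200))
  ok <- iso_acceptable(grid$pg, grid$cgm)
  expect_true(all(clarke_zone(grid$pg[ok], grid$cgm[ok]) == "A"))
})

test_that("zone summaries report exact percentages by period and source", {
  pairs <- data.frame(
    pg = c(100, 100, 100, 100, 250, 58, 100, 100),
    cgm = c(100, 130, 250, 95, 100, 71, 119, 121),
    ecgm = c(100, 105, 110, 95, 250, 58, 100, 100),
    in_exercise = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  zs <- zone_summary(pairs, "clarke")
  pick <- function(period, source, zone)
    zs$pct[zs$period == period & zs$source == source & zs$zone == zone]
  # exercise CGM: A, B, C, A -> 50/25/25
  expect_equal(pick("exercise", "cgm", "A"), 50)
  expect_equal(pick("exercise", "cgm", "B"), 25)
  expect_equal(pick("exercise", "cgm", "C"), 25)
  # rest CGM: D, D, A, B
  expect_equal(pick("rest", "cgm", "D"), 50)
  # corrected pairs all in A, every period
  expect_equal(pick("total", "ecgm", "A"), 100)
  # percentages sum to 100 within rounding
  sums <- tapply(zs$pct, interaction(zs$period, zs$source), sum)
  expect_true(all(abs(sums - 100) < 0.3))
  # ISO summary has two zones
  zi <- zone_summary(pairs, "iso")
  expect_setequal(unique(zi$zone), c("OK", "not_OK"))
  # empty exercise subset warns and omits the rows
  expect_warning(z2 <- zone_summary(pairs[!pairs$in_exercise, ], "clarke"),
                 "exercise")
  expect_false("exercise" %in% z2$period)
})
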