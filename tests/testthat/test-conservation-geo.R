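# Range metrics, endemism classes, richness accounting, syntopy, ranks.

test_that("haversine distances match the closed form and geosphere", {
  expect_equal(haversine_km(0, 0, 0, 1), 2 * pi * 6371 / 360,
               tolerance = 1e-6)
  expect_equal(max_diameter(c(0, 0), c(0, 1)), 111.195, tolerance = 1e-3)
  expect_equal(max_diameter(45.5, 14.2), 0)

  set.seed(43)
  lat <- runif(6, 44, 47); lon <- runif(6, 13, 16)
  ref <- max(geosphere::distm(cbind(lon, lat),
                              fun = function(p1, p2)
                                geosphere::distHaversine(p1, p2,
                                                         r = 6371000)))
  expect_equal(max_diameter(lat, lon), ref / 1000, tolerance = 1e-6)

  # permutation invariance
  perm <- sample(6)
  expect_equal(max_diameter(lat[perm], lon[perm]),
               max_diameter(lat, lon))
})

test_that("MCP area is zero for degenerate inputs and accurate otherwise", {
  expect_equal(mcp_area(45, 14), 0)
  expect_equal(mcp_area(c(45, 45.3), c(14, 14.4)), 0)
  expect_equal(mcp_area(c(45, 45.1, 45.2), c(14, 14, 14)), 0,
               tolerance = 1e-6)   # one meridian: collinear

  # 0.1 x 0.1 degree square at the equator: (0.1 * 111.195)^2 km^2
  a <- mcp_area(c(0, 0, 0.1, 0.1), c(0, 0.1, 0, 0.1))
  expect_equal(a, (0.1 * 2 * pi * 6371 / 360)^2, tolerance = 0.005 * 123.6)

  # independent spherical computation
  ref <- geosphere::areaPolygon(cbind(c(0, 0.1, 0.1, 0),
                                      c(0, 0, 0.1, 0.1)),
                                a = 6371000, f = 0) / 1e6
  expect_equal(a, ref, tolerance = 0.005 * ref)
})

test_that("MCP area is invariant to permutation, duplication, translation", {
  set.seed(47)
  lat <- runif(8, 45, 46); lon <- runif(8, 14, 15)
  a0 <- mcp_area(lat, lon)
  perm <- sample(8)
  expect_equal(mcp_area(lat[perm], lon[perm]), a0)
  expect_equal(mcp_area(c(lat, lat[1:3]), c(lon, lon[1:3])), a0)
  expect_equal(mcp_area(lat + 0.8, lon - 0.5), a0, tolerance = 0.001 * a0)
})

test_that("endemism classes follow site counts then area bins", {
  expect_equal(endemism_class(1, 0), "single-site")
  expect_equal(endemism_class(2, 0), "two-site")
  expect_equal(endemism_class(NA, 139), "<500 km2")
  expect_equal(endemism_class(NA, 2922), "500-5000 km2")
  expect_equal(endemism_class(NA, 500), "500-5000 km2")  # left-inclusive
  expect_equal(endemism_class(NA, 6000), ">5000 km2")
})

test_that("the published range table partitions into the expected classes", {
  t1 <- paper_fixtures()$table1
  cls <- endemism_class(t1$n_sites, t1$area_km2)
  expect_equal(unname(table(factor(cls, c("single-site", "two-site",
                                          "<500 km2", "500-5000 km2",
                                          ">5000 km2")))),
               array(c(5L, 2L, 3L, 6L, 0L)), ignore_attr = TRUE)
})

test_that("conservation ranks follow the endemism x ED quadrants", {
  expect_equal(conservation_rank(0.084, 1, 0), "1")    # high/high
  expect_equal(conservation_rank(0.037, 1, 0), "2b")   # high endemism, low ED
  expect_equal(conservation_rank(0.030, NA, 10000), "3")
  expect_equal(conservation_rank(0.080, NA, 10000), "2a")
  # intermediate ED resolved by the binary split
  expect_equal(conservation_rank(0.061, 1, 0), "1")
  expect_equal(conservation_rank(0.059, 1, 0), "2b")
  expect_error(conservation_rank(NA, 1, 0), "missing ED")
})

test_that("conservation_table assembles ranges, ED, class and rank", {
  t1 <- paper_fixtures()$table1
  ct <- conservation_table(
    t1[, c("species", "n_sites", "area_km2", "max_diameter_km")],
    setNames(t1$ED, t1$species))
  expect_equal(nrow(ct), 16L)
  expect_true(all(ct$rank %in% c("1", "2a", "2b", "3")))
  expect_equal(ct$rank[ct$species == "Niphargus kordunenensis"], "1")
  expect_equal(ct$rank[ct$species == "Niphargus kapelanus"], "2b")
})

test_that("syntopy detection lists co-occurring species pairs once per site", {
  occ <- paper_fixtures()$occurrences
  syn <- detect_syntopy(occ)
  expect_equal(length(unique(syn$site_id)), 5L)
  pair <- syn$species_a == "Niphargus gottscheeanensis" &
    syn$species_b == "Niphargus podpecanus"
  expect_equal(sum(pair), 3L)

  # all-allopatric synthetic data
  tb <- quiet(simulate_truth_bundle(simulation_config(
    n_species = 4, tips_per_species = 2,
    loci = list(COI = list(length = 120L, kappa = 4)), seed = 53)))
  expect_equal(nrow(detect_syntopy(tb$occurrences)), 0L)

  # three species at one site -> three pairs
  occ3 <- as_occurrences(data.frame(
    specimen_id = c("a", "b", "c"), species = c("x", "y", "z"),
    site_id = "s", lat = 45, lon = 14, country = "SI", basin = "Danube"))
  expect_equal(nrow(detect_syntopy(occ3)), 3L)
})

test_that("richness accounting compares nominal and revised taxonomies", {
  fx <- paper_fixtures()
  rr <- richness_accounting(fx$occurrences, fx$taxonomy_map)
  slo <- rr$country[rr$country$country == "Slovenia", ]
  expect_equal(slo$n_nominal, 1L)
  expect_equal(slo$n_revised, 12L)
  expect_equal(slo$ratio, 12)

  # after >= before everywhere; site increments match syntopies
  expect_true(all(rr$site$alpha_revised >= rr$site$alpha_nominal))
  expect_true(all(rr$country$n_revised >= rr$country$n_nominal))
  expect_true(all(rr$basin$n_revised >= rr$basin$n_nominal))
  syn <- detect_syntopy(fx$occurrences)
  expect_equal(sum(rr$site$alpha_revised - rr$site$alpha_nominal),
               nrow(syn))
  expect_setequal(rr$increased_sites, unique(syn$site_id))

  # single site, single species
  occ1 <- as_occurrences(data.frame(
    specimen_id = "a", species = "x", site_id = "s",
    lat = 45, lon = 14, country = "SI", basin = "Danube"))
  rr1 <- richness_accounting(occ1, data.frame(nominal = "x0",
                                              revised = "x"))
  expect_equal(rr1$site$alpha_nominal, 1L)
  expect_equal(rr1$site$alpha_revised, 1L)

  expect_error(richness_accounting(occ1, data.frame(nominal = "y0",
                                                    revised = "y")),
               "unmapped species")
})

test_that("all newly described species fall in the Danube basin fixture", {
  fx <- paper_fixtures()
  new_sp <- fx$table2$species[fx$table2$status == "new"]
  # names differ in one printed spelling (kordunensis/kordunenensis)
  occ_new <- fx$occurrences[
    fx$occurrences$species %in% c(new_sp, "Niphargus kordunenensis"), ]
  expect_true(all(occ_new$basin == "Danube"))
})
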