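test_that("a hand-written two-series Tucson file parses to the counted ages", {
  f <- tempfile(fileext = ".rwl")
  writeLines(c(
    "TREE01A    1   120   110   105    98    95    90    88    85    82",
    "TREE01A   10    80    75    70   999",
    "TREE02B    1   200   190   180   175   170   165   160   150   145",
    "TREE02B   10   140   135   130   125   120   115   110   105   100    98",
    "TREE02B   20    95    90    85    80    75    70   999"
  ), f)
  rings <- read_rwl(f)
  ages <- tapply(rings$age, rings$tree_id, max)
  expect_equal(sort(unname(ages)), c(12, 25))
  # 0.01 mm units from the 999 marker
  expect_equal(rings$rw_mm[rings$tree_id == "TREE01A" & rings$age == 1], 1.20)
  expect_equal(rings$last_year[rings$tree_id == "TREE02B"][1], 25L)
})

test_that("write/read round trip preserves a 37-ring series at format precision", {
  set.seed(5)
  w <- round(runif(37, 0.1, 3), 2)
  rings <- make_rings("RT01", w, last_year = 1987L)
  f <- tempfile(fileext = ".rwl")
  write_rwl(rings, f)
  back <- read_rwl(f)
  expect_equal(back$rw_mm, w)
  expect_equal(max(back$age), 37L)
  expect_equal(back$last_year[1], 1987L)
})

test_that("the 0.001 mm dialect with -9999 markers is auto-detected", {
  rings <- make_rings("MM01", c(1.234, 0.567, 2.001))
  f <- tempfile(fileext = ".rwl")
  write_rwl(rings, f, units = "0.001")
  back <- read_rwl(f)
  expect_equal(back$rw_mm, c(1.234, 0.567, 2.001))
})

test_that("empty and malformed files are handled explicitly", {
  f <- tempfile()
  writeLines(character(0), f)
  expect_warning(out <- read_rwl(f), "empty")
  expect_equal(nrow(out), 0)
  writeLines(c("GOOD01     1   100   110   999", "BAD02      1   abc"), f)
  expect_error(read_rwl(f), "line 2")
  writeLines(c("A01        1   100   999", "B02        1   100 -9999"), f)
  expect_error(read_rwl(f), "mixed units")
})

test_that("duplicate cores merge by per-age mean with the trailing age kept", {
  rings <- rbind(make_rings("01a", c(1, 1, 1)), make_rings("01b", c(3, 3, 3, 3)))
  m <- merge_duplicate_cores(rings)
  expect_equal(unique(m$tree_id), "01")
  expect_equal(m$rw_mm, c(2, 2, 2, 3))
  rep <- attr(m, "merge_report")
  expect_equal(rep$n_members, 2L)
})

test_that("the last-character stem rule merges and separates as specified", {
  rings <- rbind(make_rings("T1", rep(1, 12)), make_rings("T2", rep(2, 12)),
                 make_rings("AB1", rep(1, 12)), make_rings("CD1", rep(2, 12)))
  m <- merge_duplicate_cores(rings)
  ids <- unique(m$tree_id)
  expect_true("T" %in% ids)         # T1, T2 share stem "T"
  expect_true(all(c("AB1", "CD1") %in% ids))  # different stems: untouched
  single <- make_rings("LONE1", rep(1, 12))
  expect_equal(merge_duplicate_cores(single)$rw_mm, single$rw_mm)
})

test_that("separator-suffixed core IDs merge and conflicting metadata errors", {
  rings <- rbind(make_rings("ID1-1", rep(1, 12)), make_rings("ID1-2", rep(3, 12)))
  m <- merge_duplicate_cores(rings)
  expect_equal(unique(m$tree_id), "ID1")
  expect_equal(unique(m$rw_mm), 2)
  bad <- rbind(make_rings("X1a", rep(1, 12), species = "SP1"),
               make_rings("X1b", rep(1, 12), species = "SP2"))
  expect_error(merge_duplicate_cores(bad), "differing site or species")
})

test_that("tree summaries follow the early-growth / age / diameter arithmetic", {
  s <- summarize_trees(make_rings("A", rep(1, 10)))
  expect_equal(s$rw_early, 1)
  expect_equal(s$age, 10L)
  expect_equal(s$max_diameter, 20)
  s2 <- summarize_trees(make_rings("B", c(2, 2, 2, 2, 2, 1, 1, 1, 1, 1, 0.5, 0.5)))
  expect_equal(s2$rw_early, 1.5)
  expect_equal(s2$age, 12L)
  expect_equal(s2$max_diameter, 2 * (5 * 2 + 5 * 1 + 2 * 0.5))
  # early growth ignores rings after age 10
  s3 <- summarize_trees(make_rings("C", c(rep(1.5, 10), rep(9, 30))))
  expect_equal(s3$rw_early, 1.5)
})

test_that("trees with fewer than ten rings are excluded and counted", {
  rings <- rbind(make_rings("OK1", rep(1, 11)), make_rings("SHORT", rep(1, 9)))
  s <- summarize_trees(rings)
  expect_equal(s$tree_id, "OK1")
  expect_equal(attr(s, "excluded"), "SHORT")
})

test_that("death classification uses a strict pre-1900 rule", {
  expect_equal(classify_dead(c(1899L, 1900L, NA)), c("dead", "alive", "unknown"))
  # explicit flags override the calendar rule
  expect_equal(classify_dead(c(1950L, 1950L), status = c("subfossil", "alive")),
               c("subfossil", "alive"))
})

test_that("site filter applies count and age-evenness thresholds", {
  even <- data.frame(tree_id = sprintf("a%d", 1:25), site_id = "EVEN", species = "S",
                     rw_early = 1, age = 80, stringsAsFactors = FALSE)
  flt <- filter_sites(even)
  expect_equal(nrow(flt$summaries), 0)
  expect_match(flt$report$reason, "CV_age")

  uneven <- data.frame(tree_id = sprintf("b%d", 1:4), site_id = "UNEV", species = "S",
                       rw_early = 1, age = c(50, 100, 150, 200), stringsAsFactors = FALSE)
  flt2 <- filter_sites(uneven, min_records = 4)
  expect_equal(flt2$report$cv_age_pct, sd(c(50, 100, 150, 200)) / 125 * 100)
  expect_equal(nrow(flt2$summaries), 4)

  small <- data.frame(tree_id = sprintf("c%d", 1:19), site_id = "SMALL", species = "S",
                      rw_early = 1, age = round(runif(19, 40, 200)), stringsAsFactors = FALSE)
  flt3 <- filter_sites(small)
  expect_equal(nrow(flt3$summaries), 0)
  expect_match(flt3$report$reason, "too few")
})

test_that("species filter boundaries are strict/inclusive as documented", {
  mk <- function(sp, n, nsite) data.frame(
    tree_id = sprintf("%s%03d", sp, 1:n), site_id = sprintf("S%d", rep_len(1:nsite, n)),
    species = sp, rw_early = 1, age = 100, stringsAsFactors = FALSE)
  d <- rbind(mk("BIG", 305, 12), mk("SMALL", 40, 1), mk("EDGE", 150, 3))
  rep <- filter_species(d)
  expect_true(rep$species_level[rep$species == "BIG"])
  expect_true(rep$within_species[rep$species == "BIG"])
  expect_true(rep$species_level[rep$species == "SMALL"])
  expect_false(rep$within_species[rep$species == "SMALL"])
  expect_false(rep$within_species[rep$species == "EDGE"])  # strictly more than 150
})

test_that("filters are idempotent and account for every tree", {
  pop <- generate_population(synth_config(n_trees = 400, seed = 7))
  s <- summarize_trees(pop$rings)
  f1 <- filter_sites(s)
  f2 <- filter_sites(f1$summaries)
  expect_equal(f1$summaries, f2$summaries, ignore_attr = TRUE)
  expect_equal(sum(f1$report$n), nrow(s))
})

test_that("CSV dialects round trip", {
  pop <- generate_population(synth_config(n_trees = 20, seed = 8))
  f <- tempfile(fileext = ".csv")
  write_rings_csv(pop$rings, f)
  back <- read_rings_csv(f)
  expect_equal(back$rw_mm, pop$rings$rw_mm)
  g <- tempfile(fileext = ".csv")
  write_sites_csv(pop$sites, g)
  expect_equal(read_sites_csv(g)$mat_c, pop$sites$mat_c)
})
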