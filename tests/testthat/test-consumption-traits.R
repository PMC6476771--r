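make_fap <- function(totals) {
  # one taxon, one month per season, monthly FAP equal to the seasonal total
  months <- c(LDS = 1L, LRS = 4L, SDS = 7L, SRS = 9L)
  tibble::tibble(taxon = "T", month = unname(months[names(totals)]),
                 fap = unname(totals))
}

test_that("season split takes the two largest FAP totals as high", {
  fap <- make_fap(c(LDS = 10, LRS = 8, SDS = 3, SRS = 2))
  sp <- season_split(fap)
  expect_equal(sp$group[sp$season %in% c("LDS", "LRS")], c("high", "high"))
  expect_equal(sp$group[sp$season %in% c("SDS", "SRS")], c("low", "low"))
  # all-equal totals: deterministic fixed-order tie-break with a warning
  expect_warning(sp2 <- season_split(make_fap(c(LDS = 1, LRS = 1, SDS = 1,
                                                SRS = 1))), "tie")
  expect_equal(sp2$group, c("high", "high", "low", "low"))
})

test_that("designed masting seasons are classified high", {
  gen <- generate_dataset(generator_config(n_taxa = 6, samples_per_month = 3,
                                           nests_per_season = 5), seed = 21)
  sc <- diet_scores(gen$dataset)
  sp <- season_split(sc$fap)
  # the generator puts community fruiting in the rainy seasons
  expect_setequal(sp$season[sp$group == "high"], c("LRS", "SRS"))
})

test_that("fallback candidacy needs >=3 fruiting seasons and opposed trends", {
  months <- c(1L, 4L, 7L, 9L) # one per season: LDS, LRS, SDS, SRS
  split <- tibble::tibble(season = c("LDS", "LRS", "SDS", "SRS"),
                          total_fap = c(1, 10, 2, 10),
                          group = c("low", "high", "low", "high"))
  fap <- tibble::tibble(
    taxon = rep(c("fb", "two_seasons", "follows"), each = 4),
    month = rep(months, 3),
    fap = c(1, 5, 1, 5,    # fb: fruits all 4 seasons, higher in high seasons
            0, 5, 0, 5,    # two_seasons: only 2 fruiting seasons
            1, 5, 1, 5))   # follows availability
  mcs <- tibble::tibble(
    taxon = rep(c("fb", "two_seasons", "follows"), each = 4),
    month = rep(months, 3),
    mcs = c(0.5, 0.1, 0.5, 0.1,   # consumed against the trend
            0.5, 0.1, 0.5, 0.1,
            0.1, 0.5, 0.1, 0.5))  # consumed with the trend
  prof <- seasonal_profile(fap, mcs)
  cand <- fallback_candidates(prof, split)
  expect_true(cand$candidate[cand$taxon == "fb"])
  expect_false(cand$candidate[cand$taxon == "two_seasons"])
  expect_false(cand$candidate[cand$taxon == "follows"])
  # MCS floor excludes rarely eaten taxa
  mcs_tiny <- dplyr::mutate(mcs, mcs = .data$mcs / 1e4)
  cand2 <- fallback_candidates(seasonal_profile(fap, mcs_tiny), split,
                               mcs_floor = 0.001)
  expect_false(any(cand2$candidate))
})

test_that("fallback is assigned before preferred, with round(N/3) list size", {
  gis <- tibble::tibble(
    taxon = sprintf("t%02d", 1:15), gis = 15:1, pe = 1,
    status = "classified") |> rank_preference()
  cand <- tibble::tibble(
    taxon = sprintf("t%02d", 1:15),
    mcs_low = c(0.9, 0.8, 0.7, rep(0, 12)),
    candidate = c(TRUE, TRUE, TRUE, rep(FALSE, 12)))
  lists <- assign_lists(gis, cand)
  expect_equal(lists$target, 5) # round(15/3)
  expect_setequal(lists$fallback, c("t01", "t02", "t03"))
  # top-GIS taxa t01..t03 are fallback, so preferred fills from the next ranks
  expect_setequal(lists$preferred, c("t04", "t05", "t06", "t07", "t08"))
  expect_setequal(lists$both, c("t01", "t02", "t03"))
  expect_length(intersect(lists$preferred, lists$fallback), 0)
  # no candidates: preferred = top round(N/3) by GIS
  lists2 <- assign_lists(gis, dplyr::mutate(cand, candidate = FALSE))
  expect_length(lists2$fallback, 0)
  expect_equal(lists2$preferred, sprintf("t%02d", 1:5))
  # over-long candidate list truncated by descending low-season MCS
  cand3 <- dplyr::mutate(cand, candidate = TRUE,
                         mcs_low = seq(0.15, 0.01, length.out = 15))
  lists3 <- assign_lists(gis, cand3)
  expect_equal(lists3$fallback, sprintf("t%02d", 1:5))
})

test_that("trait collapse is total, deterministic, and fallback-first", {
  expect_equal(collapse_trait("preferred", "preferred"), "Preferred apes")
  expect_equal(collapse_trait("fallback", "fallback"), "Fallback apes")
  expect_equal(collapse_trait("preferred", "neither"), "Preferred gorilla")
  expect_equal(collapse_trait("UC", "preferred"), "Preferred chimpanzee")
  expect_equal(collapse_trait("neither", "fallback"), "Fallback chimpanzee")
  expect_equal(collapse_trait("neither", "neither"), "none")
  expect_equal(collapse_trait("UC", "UC"), "none")
  # cross-ape conflict resolves to the fallback side
  expect_equal(collapse_trait("fallback", "preferred"), "Fallback gorilla")
  expect_equal(collapse_trait("preferred", "fallback"), "Fallback chimpanzee")
  # totality over the full status grid
  statuses <- c("preferred", "fallback", "neither", "UC")
  grid <- expand.grid(g = statuses, c = statuses, stringsAsFactors = FALSE)
  out <- collapse_trait(grid$g, grid$c)
  expect_length(out, 16)
  expect_true(all(out %in% c("Preferred apes", "Preferred gorilla",
                             "Preferred chimpanzee", "Fallback apes",
                             "Fallback gorilla", "Fallback chimpanzee",
                             "none")))
  expect_error(collapse_trait("meh", "preferred"), "statuses")
})

test_that("per-ape lists are disjoint and candidates satisfy the criteria", {
  gen <- generate_dataset(generator_config(), seed = 31)
  sc <- diet_scores(gen$dataset)
  tr <- consumption_traits(sc, gen$dataset$calendar)
  for (a in ape_codes()) {
    l <- tr$lists[[a]]
    expect_length(intersect(l$preferred, l$fallback), 0)
    expect_lte(length(l$preferred), l$target)
    prof <- seasonal_profile(sc$fap, sc$mcs[[a]], gen$dataset$calendar)
    cand <- fallback_candidates(prof, tr$split)
    expect_true(all(l$fallback %in% cand$taxon[cand$candidate]))
    expect_true(all(cand$fruiting_seasons[cand$candidate] >= 3))
  }
})

test_that("designed fallback taxa are recovered on synthetic data", {
  gen <- generate_dataset(generator_config(), seed = 41)
  sc <- diet_scores(gen$dataset)
  tr <- consumption_traits(sc, gen$dataset$calendar)
  for (a in ape_codes()) {
    expect_true(all(gen$truth$fallback_taxa %in% tr$lists[[a]]$fallback))
  }
  # and they collapse to the joint fallback trait
  tab <- tr$table
  expect_true(all(tab$trait[tab$taxon %in% gen$truth$fallback_taxa] ==
                    "Fallback apes"))
})
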